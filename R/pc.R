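#' PC-stable structure learning
#'
#' Constraint-based skeleton search: starting from the complete undirected
#' graph, an edge x-y is removed as soon as some conditioning set Z drawn
#' from the current neighbors of x or y (of size 0, 1, 2, ... up to
#' `max_cond`) makes the G-squared test accept independence at level
#' `alpha`. Neighbor sets are frozen within each level (the "stable"
#' variant), so the result does not depend on edge processing order.
#' V-structures are then oriented from the recorded separating sets, Meek
#' rules propagate orientations, and any remaining undirected edges are
#' oriented by variable order (recorded in the provenance table; the
#' screen's conclusions use adjacency only, which is orientation-free).
#'
#' @param data a `discrete_panel`.
#' @param alpha significance level of the conditional-independence tests.
#' @param max_cond maximum conditioning-set size.
#' @return a `network_structure` with per-edge provenance: removed pairs
#'   carry the separating set and its p-value, kept edges the largest
#'   p-value observed across tested sets.
#' @export
learn_structure_pc <- function(data, alpha = 0.05, max_cond = 3L) {
  stopifnot(inherits(data, "discrete_panel"))
  vars <- data$vars
  p <- length(vars)
  if (p < 2L)
    return(new_network_structure(vars, matrix(0L, p, p), method = "pc"))
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepset <- vector("list", p * p)   # indexed (i-1)*p + j
  max_p <- matrix(0, p, p)          # largest accepting-side p seen per pair
  removed <- list()

  for (l in 0:max_cond) {
    nb <- lapply(seq_len(p), function(i) which(adj[i, ]))
    if (!any(vapply(seq_len(p), function(i) length(nb[[i]]) - 1L >= l,
                    logical(1))))
      break
    pr <- which(adj & upper.tri(adj), arr.ind = TRUE)
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1L]; j <- pr[k, 2L]
      gone <- FALSE
      for (side in list(c(i, j), c(j, i))) {
        cand <- setdiff(nb[[side[1L]]], side)
        if (length(cand) < l) next
        subsets <- if (l == 0L) list(integer(0))
                   else if (length(cand) == 1L) list(cand)  # combn scalar trap
                   else asplit(utils::combn(cand, l), 2L)
        for (S in subsets) {
          res <- ci_test_g2(i, j, as.integer(S), data)
          max_p[i, j] <- max_p[j, i] <- max(max_p[i, j], res$p_value)
          if (res$p_value > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepset[[(i - 1L) * p + j]] <- as.integer(S)
            sepset[[(j - 1L) * p + i]] <- as.integer(S)
            removed[[length(removed) + 1L]] <-
              data.frame(from = vars[i], to = vars[j], type = "removed",
                         p_value = res$p_value,
                         sepset = paste(vars[S], collapse = ";"))
            gone <- TRUE
            break
          }
        }
        if (gone) break
      }
    }
  }

  # orient v-structures: i - j - k with i,k nonadjacent and j not in sepset
  g <- matrix(0L, p, p)           # g[i,j]=1: arrow or half of an undirected edge
  g[adj] <- 1L
  for (j in seq_len(p)) {
    nbj <- which(adj[j, ])
    if (length(nbj) < 2L) next
    for (a in nbj) for (b in nbj) {
      if (a >= b || adj[a, b]) next
      S <- sepset[[(a - 1L) * p + b]]
      if (!is.null(S) && !(j %in% S)) {
        g[a, j] <- 1L; g[j, a] <- 0L
        g[b, j] <- 1L; g[j, b] <- 0L
      }
    }
  }
  g <- meek_orient(g)

  # orient leftover undirected edges by variable order, never creating a cycle
  directed <- (g == 1L) & (t(g) == 0L)
  forced <- NULL
  und <- which((g == 1L) & (t(g) == 1L) & upper.tri(g), arr.ind = TRUE)
  amat <- matrix(0L, p, p)
  amat[directed] <- 1L
  if (nrow(und)) {
    und <- und[order(und[, 1L], und[, 2L]), , drop = FALSE]
    for (k in seq_len(nrow(und))) {
      i <- und[k, 1L]; j <- und[k, 2L]
      if (!creates_cycle(amat, i, j)) amat[i, j] <- 1L else amat[j, i] <- 1L
      forced <- rbind(forced, data.frame(from = vars[i], to = vars[j],
                                         type = "order_oriented",
                                         p_value = max_p[i, j], sepset = ""))
    }
  }
  kept <- which(amat > 0, arr.ind = TRUE)
  prov <- rbind(
    if (nrow(kept)) data.frame(from = vars[kept[, 1L]], to = vars[kept[, 2L]],
                               type = "kept",
                               p_value = max_p[cbind(kept[, 1L], kept[, 2L])],
                               sepset = ""),
    if (length(removed)) do.call(rbind, removed),
    forced)
  st <- new_network_structure(vars, amat, provenance = prov, method = "pc")
  st$alpha <- alpha
  st
}

# Meek rules 1-3 on a mixed graph (1/1 = undirected, 1/0 = directed)
meek_orient <- function(g) {
  p <- nrow(g)
  repeat {
    changed <- FALSE
    und <- which((g == 1L) & (t(g) == 1L), arr.ind = TRUE)
    for (k in seq_len(nrow(und))) {
      a <- und[k, 1L]; b <- und[k, 2L]   # candidate a -> b
      if (!(g[a, b] == 1L && g[b, a] == 1L)) next
      orient <- FALSE
      # R1: c -> a, c and b nonadjacent
      parents_a <- which(g[, a] == 1L & g[a, ] == 0L)
      for (cc in parents_a) {
        if (g[cc, b] == 0L && g[b, cc] == 0L) { orient <- TRUE; break }
      }
      # R2: a -> c -> b
      if (!orient) {
        ch_a <- which(g[a, ] == 1L & g[, a] == 0L)
        for (cc in ch_a) if (g[cc, b] == 1L && g[b, cc] == 0L) {
          orient <- TRUE; break
        }
      }
      # R3: a - c -> b and a - d -> b with c, d nonadjacent
      if (!orient) {
        und_a <- which(g[a, ] == 1L & g[, a] == 1L)
        into_b <- und_a[vapply(und_a,
                               function(cc) g[cc, b] == 1L && g[b, cc] == 0L,
                               logical(1))]
        if (length(into_b) >= 2L) {
          for (c1 in into_b) {
            for (c2 in into_b) {
              if (c1 < c2 && g[c1, c2] == 0L && g[c2, c1] == 0L) {
                orient <- TRUE; break
              }
            }
            if (orient) break
          }
        }
      }
      if (orient) { g[b, a] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  g
}
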