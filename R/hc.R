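# Decomposable BIC family score for one node given a parent set:
# multinomial log-likelihood minus (log n / 2) * free parameters.
family_score <- function(dp, j, parents, cache = NULL) {
  key <- paste0(j, "|", paste(sort(parents), collapse = ","))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  aj <- dp$arity[j]
  zc <- combine_codes(dp, parents)
  code <- dp$values[, j] + aj * (zc$code - 1L)
  M <- matrix(tabulate(code, nbins = aj * zc$arity), aj, zc$arity)
  tot <- colSums(M)
  pos <- M > 0
  ll <- sum(M[pos] * log(M[pos])) - sum(tot[tot > 0] * log(tot[tot > 0]))
  score <- unname(ll - (log(dp$n) / 2) * (aj - 1) * zc$arity)
  if (!is.null(cache)) cache[[key]] <- score
  score
}

#' BIC score of a network structure
#'
#' Decomposable sum over nodes of the multinomial log-likelihood of the
#' node given its parents, penalized by `(log n / 2)` per free parameter.
#' Adding a parent can never decrease the likelihood term; the penalty is
#' what arbitrates structure.
#'
#' @param structure a `network_structure` over the panel's variables.
#' @param data a `discrete_panel`.
#' @return scalar score (larger is better).
#' @export
bic_score <- function(structure, data) {
  stopifnot(inherits(structure, "network_structure"),
            inherits(data, "discrete_panel"))
  idx <- match(structure$nodes, data$vars)
  if (anyNA(idx)) stop("structure has node(s) absent from the data")
  if (!is_dag_amat(structure$amat)) stop("structure contains a cycle")
  total <- 0
  for (k in seq_along(structure$nodes)) {
    parents <- idx[which(structure$amat[, k] > 0)]
    total <- total + family_score(data, idx[k], parents)
  }
  total
}

#' Hill-climbing structure learning with BIC
#'
#' Greedy search over DAGs by add / delete / reverse single-arc moves,
#' accepting the move with the largest positive BIC gain until a local
#' optimum; `restarts` random perturbations of the incumbent are then
#' re-climbed and the best-scoring DAG over all climbs is returned.
#' Deterministic given `seed`.
#'
#' @param data a `discrete_panel`.
#' @param restarts number of random restarts after the first climb.
#' @param seed integer seed.
#' @param max_parents cap on parents per node (tractability on small panels).
#' @return a `network_structure` with the total BIC in `$score` and
#'   per-edge score deltas in the provenance table.
#' @export
learn_structure_hc <- function(data, restarts = 10L, seed = 1L,
                               max_parents = 4L) {
  stopifnot(inherits(data, "discrete_panel"))
  vars <- data$vars
  p <- length(vars)
  cache <- new.env(parent = emptyenv())
  fs <- function(j, parents) family_score(data, j, parents, cache)
  node_score <- function(amat, j) fs(j, which(amat[, j] > 0))

  climb <- function(amat) {
    sc <- vapply(seq_len(p), function(j) node_score(amat, j), numeric(1))
    repeat {
      best <- list(delta = 0)
      for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        if (amat[i, j] == 0L && amat[j, i] == 0L) {
          if (sum(amat[, j]) >= max_parents) next
          if (creates_cycle(amat, i, j)) next
          d <- fs(j, c(which(amat[, j] > 0), i)) - sc[j]
          if (d > best$delta + 1e-9)
            best <- list(delta = d, op = "add", i = i, j = j)
        } else if (amat[i, j] == 1L) {
          pj <- which(amat[, j] > 0)
          d_del <- fs(j, setdiff(pj, i)) - sc[j]
          if (d_del > best$delta + 1e-9)
            best <- list(delta = d_del, op = "del", i = i, j = j)
          # reverse i -> j
          a2 <- amat; a2[i, j] <- 0L
          if (sum(amat[, i]) < max_parents && !creates_cycle(a2, j, i)) {
            d <- d_del + fs(i, c(which(amat[, i] > 0), j)) - sc[i]
            if (d > best$delta + 1e-9)
              best <- list(delta = d, op = "rev", i = i, j = j)
          }
        }
      }
      if (best$delta <= 0) break
      i <- best$i; j <- best$j
      if (best$op == "add") {
        amat[i, j] <- 1L
      } else if (best$op == "del") {
        amat[i, j] <- 0L
      } else {
        amat[i, j] <- 0L; amat[j, i] <- 1L
        sc[i] <- node_score(amat, i)
      }
      sc[j] <- node_score(amat, j)
    }
    list(amat = amat, score = sum(vapply(seq_len(p),
                                         function(j) node_score(amat, j),
                                         numeric(1))))
  }

  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  best <- climb(matrix(0L, p, p))
  for (r in seq_len(restarts)) {
    amat <- best$amat
    # perturb: toggle a few random arcs, keeping the graph acyclic
    for (k in seq_len(2L)) {
      i <- sample.int(p, 1L); j <- sample.int(p, 1L)
      if (i == j) next
      if (amat[i, j] == 1L) amat[i, j] <- 0L
      else if (amat[j, i] == 0L && sum(amat[, j]) < max_parents &&
               !creates_cycle(amat, i, j)) amat[i, j] <- 1L
    }
    cand <- climb(amat)
    if (cand$score > best$score + 1e-9) best <- cand
  }
  ed <- which(best$amat > 0, arr.ind = TRUE)
  prov <- if (nrow(ed)) {
    delta <- vapply(seq_len(nrow(ed)), function(k) {
      i <- ed[k, 1L]; j <- ed[k, 2L]
      pj <- which(best$amat[, j] > 0)
      fs(j, pj) - fs(j, setdiff(pj, i))
    }, numeric(1))
    data.frame(from = vars[ed[, 1L]], to = vars[ed[, 2L]], type = "kept",
               score_delta = delta)
  } else NULL
  st <- new_network_structure(vars, best$amat, provenance = prov,
                              score = best$score, method = "hc")
  st
}
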