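#' Build a dominance matrix from agonistic interactions
#'
#' Tabulates decided conflicts into a square win-count matrix
#' `X[i, j]` = number of times individual `i` beat individual `j`.
#' Interactions with outcome `"undecided"` carry no winner and are skipped;
#' only conflicts that clearly allowed scoring a winner and a loser enter
#' the hierarchy.
#'
#' @param interactions A data frame of agonistic interactions as produced by
#'   [simulate_interactions()], with columns `aggressor`, `victim`, `winner`
#'   and `outcome`.
#' @param ids Character vector of all individual IDs (row/column order of the
#'   result). Defaults to the sorted union of IDs seen in `interactions`.
#' @return An object of class `dominance_matrix`: an integer matrix with zero
#'   diagonal and `dimnames` equal to `ids`.
#' @examples
#' ints <- data.frame(aggressor = c("A", "A", "B"), victim = c("B", "B", "A"),
#'                    winner = c("A", "A", "B"), outcome = "end_conflict")
#' build_matrix(ints)
#' @export
build_matrix <- function(interactions, ids = NULL) {
  needed <- c("aggressor", "victim", "winner", "outcome")
  missing_cols <- setdiff(needed, names(interactions))
  if (length(missing_cols))
    stopf("interactions lack column(s): %s", paste(missing_cols, collapse = ", "))
  if (is.null(ids))
    ids <- sort(unique(c(interactions$aggressor, interactions$victim)))
  ids <- as.character(ids)
  decided <- interactions[interactions$outcome != "undecided" &
                            !is.na(interactions$winner), , drop = FALSE]
  bad <- !(decided$aggressor %in% ids & decided$victim %in% ids &
             decided$winner %in% ids)
  if (any(bad))
    stopf("unknown individual ID in interaction row(s): %s",
          paste(utils::head(which(bad), 5), collapse = ", "))
  loser <- ifelse(decided$winner == decided$aggressor,
                  decided$victim, decided$aggressor)
  X <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(decided)) {
    tab <- table(factor(decided$winner, ids), factor(loser, ids))
    X <- X + unclass(tab)
    storage.mode(X) <- "integer"
    dimnames(X) <- list(ids, ids)
  }
  diag(X) <- 0L
  structure(X, class = c("dominance_matrix", "matrix", "array"))
}

as_dominance_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) != ncol(X)) stopf("dominance matrix must be square")
  if (any(X < 0)) stopf("dominance matrix counts must be nonnegative")
  if (any(diag(X) != 0)) stopf("dominance matrix diagonal must be zero")
  if (is.null(rownames(X))) {
    ids <- paste0("id", seq_len(nrow(X)))
    dimnames(X) <- list(ids, ids)
  }
  X
}

# dyad direction matrix: 1 if i strictly beat j more often; unknown dyads
# (0-0) and exact nonzero ties remain 0 in both directions
dyad_directions <- function(X) {
  D <- (X > t(X)) * 1L
  D
}

# dyads with no decided direction (unknown 0-0 or tied k-k), as index pairs
undirected_dyads <- function(X) {
  n <- nrow(X)
  out <- which(upper.tri(X) & X == t(X), arr.ind = TRUE)
  out
}

landau_h_from_V <- function(V) {
  n <- length(V)
  12 / (n^3 - n) * sum((V - (n - 1) / 2)^2)
}

#' Landau's linearity index h
#'
#' Measures the linearity of a dominance hierarchy from the number of
#' individuals each animal dominates: `h = 12 / (N^3 - N) * sum_a (V_a -
#' (N - 1) / 2)^2`, where `V_a` is the number of individuals `a` dominates
#' (dyad direction taken as the strict majority of wins). The index ranges
#' from 0 (nonlinear, e.g. a circular triad) to 1 (perfectly linear).
#'
#' `landau_h` requires every dyad to have a decided direction; with unknown
#' or tied dyads use [landau_h_prime()], which corrects for them.
#'
#' @param X A `dominance_matrix` (or plain square count matrix).
#' @return The index, a number in `[0, 1]`.
#' @references Landau, H. G. (1951) On dominance relations and the structure
#'   of animal societies. Bulletin of Mathematical Biophysics 13, 1-19.
#' @examples
#' X <- matrix(0, 4, 4)
#' X[upper.tri(X)] <- 1   # fully transitive: h = 1
#' landau_h(X)
#' @export
landau_h <- function(X) {
  X <- as_dominance_matrix(X)
  n <- nrow(X)
  if (n < 3) stopf("Landau's h requires at least 3 individuals")
  if (nrow(undirected_dyads(X)) > 0)
    stopf(paste("matrix has unknown or tied dyads; use landau_h_prime(),",
                "which corrects for them"))
  V <- rowSums(dyad_directions(X))
  landau_h_from_V(V)
}

#' Corrected linearity index h' with randomisation test
#'
#' Landau's index adjusted for unknown relationships: every dyad with no
#' decided direction (never-interacting pairs and exact ties) is assigned a
#' random direction, `h` is computed, and `h'` is the mean over
#' `n_random` such random completions. Significance is assessed by comparing
#' the observed `h'` against `h` computed on fully random tournaments of the
#' same size: `p = (count(h_random >= h') + 1) / (n_random + 1)`.
#'
#' @inheritParams landau_h
#' @param n_random Number of randomisations (default 10000).
#' @param seed Integer seed for the randomisation streams.
#' @return A list of class `linearity_result` with elements `h` (raw index,
#'   `NA` when undecided dyads exist), `h_prime`, `p_value`,
#'   `n_randomizations` and `n_unknown_dyads` (undirected dyads, ties
#'   included).
#' @examples
#' X <- matrix(0, 5, 5); X[upper.tri(X)] <- 2
#' landau_h_prime(X, n_random = 500, seed = 1)
#' @export
landau_h_prime <- function(X, n_random = 10000, seed = 1) {
  X <- as_dominance_matrix(X)
  n <- nrow(X)
  if (n < 3) stopf("h' requires at least 3 individuals")
  if (!is_count(n_random) || n_random < 1) stopf("n_random must be >= 1")
  D <- dyad_directions(X)
  und <- undirected_dyads(X)
  n_und <- nrow(und)
  V_base <- rowSums(D)
  with_seed(seed, {
    if (n_und == 0) {
      h_prime <- landau_h_from_V(V_base)
    } else {
      hs <- vapply(seq_len(n_random), function(k) {
        flip <- runif(n_und) < 0.5
        V <- V_base
        winners <- ifelse(flip, und[, 1], und[, 2])
        tab <- tabulate(winners, nbins = n)
        landau_h_from_V(V + tab)
      }, numeric(1))
      h_prime <- mean(hs)
    }
    # null: direction of every dyad random
    n_dyads <- n * (n - 1) / 2
    ij <- which(upper.tri(D), arr.ind = TRUE)
    h_null <- vapply(seq_len(n_random), function(k) {
      flip <- runif(n_dyads) < 0.5
      winners <- ifelse(flip, ij[, 1], ij[, 2])
      landau_h_from_V(tabulate(winners, nbins = n))
    }, numeric(1))
  })
  p <- (sum(h_null >= h_prime) + 1) / (n_random + 1)
  structure(list(h = if (n_und == 0) landau_h_from_V(V_base) else NA_real_,
                 h_prime = h_prime, p_value = p,
                 n_randomizations = n_random, n_unknown_dyads = n_und),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("Linearity of hierarchy\n  h' = %.4f (p = %.4g, %d randomisations)\n",
              x$h_prime, x$p_value, x$n_randomizations))
  cat(sprintf("  undirected (unknown/tied) dyads: %d\n", x$n_unknown_dyads))
  invisible(x)
}

# (I, SI) of an order: I = dyads whose majority direction opposes the order,
# SI = summed rank distance of those dyads
isi_cost <- function(X, order) {
  Xo <- X[order, order, drop = FALSE]
  lower_wins <- t(Xo)[upper.tri(Xo)]   # wins of the lower-ranked over higher
  upper_wins <- Xo[upper.tri(Xo)]
  inc <- lower_wins > upper_wins
  ij <- which(upper.tri(Xo), arr.ind = TRUE)
  c(I = sum(inc), SI = sum((ij[inc, 2] - ij[inc, 1])))
}

isi_local_search <- function(X, order) {
  n <- length(order)
  best <- isi_cost(X, order)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cand <- order
        cand[c(i, j)] <- cand[c(j, i)]
        cost <- isi_cost(X, cand)
        if (cost[1] < best[1] || (cost[1] == best[1] && cost[2] < best[2])) {
          order <- cand
          best <- cost
          improved <- TRUE
        }
      }
    }
  }
  list(order = order, cost = best)
}

#' I&SI rank order
#'
#' Finds a rank order most consistent with a linear hierarchy by first
#' minimising the number of inconsistencies I (dyads whose majority win
#' direction opposes the order) and then, holding I, the total strength of
#' inconsistencies SI (the summed rank distances of inconsistent dyads).
#' The search starts from the order of descending win proportion and
#' performs pairwise-swap hill climbing, restarted `n_tries` times from
#' random perturbations.
#'
#' @inheritParams landau_h
#' @param n_tries Number of random restarts after the deterministic first
#'   pass (default 20).
#' @param seed Integer seed for the restarts.
#' @return A list of class `rank_order`: `order` (IDs, best first), `ranks`
#'   (named integer vector, 1 = top), `I`, `SI`, and `unique` (`FALSE` when
#'   another inspected order achieved the same (I, SI)).
#' @references de Vries, H. (1998) Finding a dominance order most consistent
#'   with a linear hierarchy. Animal Behaviour 55, 827-843.
#' @export
isi_rank <- function(X, n_tries = 20, seed = 1) {
  X <- as_dominance_matrix(X)
  n <- nrow(X)
  if (n < 2) stopf("rank order requires at least 2 individuals")
  ids <- rownames(X)
  wins <- rowSums(X)
  losses <- colSums(X)
  prop <- ifelse(wins + losses > 0, wins / (wins + losses), 0)
  init <- order(-prop, -wins, seq_len(n))   # deterministic initial order
  res <- isi_local_search(X, init)
  ties_seen <- FALSE
  if (n_tries > 0) {
    restarts <- derive_seeds(seed, n_tries)
    for (k in seq_len(n_tries)) {
      start <- with_seed(restarts[k], sample(res$order))
      cand <- isi_local_search(X, start)
      better <- cand$cost[1] < res$cost[1] ||
        (cand$cost[1] == res$cost[1] && cand$cost[2] < res$cost[2])
      same <- all(cand$cost == res$cost) && !identical(cand$order, res$order)
      if (same) ties_seen <- TRUE
      if (better) { res <- cand; ties_seen <- FALSE }
    }
  }
  ranks <- setNames(match(seq_len(n), res$order), ids)
  structure(list(order = ids[res$order], ranks = ranks,
                 I = unname(res$cost[1]), SI = unname(res$cost[2]),
                 unique = !ties_seen),
            class = "rank_order")
}

#' @export
print.rank_order <- function(x, ...) {
  cat(sprintf("I&SI rank order (I = %d, SI = %d%s)\n", x$I, x$SI,
              if (!x$unique) ", non-unique" else ""))
  cat("  ", paste(x$order, collapse = " > "), "\n")
  invisible(x)
}

#' Directional consistency index
#'
#' For each dyad with at least one decided interaction let `H` be the count
#' in the more frequent direction and `L` the count in the less frequent one;
#' the DCI is `sum(H - L) / sum(H + L)` over dyads. It ranges from 0
#' (complete bidirectional exchange) to 1 (complete unidirectionality).
#'
#' @inheritParams landau_h
#' @return The index, a number in `[0, 1]`.
#' @references van Hooff, J.A.R.A.M. & Wensing, J.A.B. (1987) Dominance and
#'   its behavioural measures in a captive wolf pack.
#' @export
dci <- function(X) {
  X <- as_dominance_matrix(X)
  up <- X[upper.tri(X)]
  lo <- t(X)[upper.tri(X)]
  tot <- up + lo
  if (sum(tot) == 0) stopf("DCI undefined on an all-zero matrix")
  sum(abs(up - lo)) / sum(tot)
}
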