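#' Spearman rank correlation with a significance test
#'
#' Rank-based correlation with midrank handling of ties. For `n <= 9` and
#' tie-free data the p-value is exact (permutation distribution); otherwise
#' the t approximation is used. A thin, typed wrapper around
#' [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length (`n >= 4`).
#' @return A list of class `rank_correlation` with `r_s`, `n` and `p_value`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 4) stopf("need at least 4 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stopf("constant vector: rank correlation undefined")
  exact <- length(x) <= 9 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact))
  structure(list(r_s = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r_s = %.3f, N = %d, P = %.4g\n",
              x$r_s, x$n, x$p_value))
  invisible(x)
}

#' Chi-square goodness-of-fit test
#'
#' Pearson goodness-of-fit of observed counts against expected proportions
#' (equal by default): `sum((O - E)^2 / E)` on `cells - 1` degrees of
#' freedom. Used, e.g., to ask whether a grunt more often ends a conflict
#' than is followed by continued aggression.
#'
#' @param observed Nonnegative integer counts (at least 2 cells).
#' @param expected Expected proportions, recycled-free, summing to 1;
#'   default equal.
#' @return A list with `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @examples
#' chisq_gof(c(400, 13))   # end of conflict vs continued aggression
#' @export
chisq_gof <- function(observed, expected = NULL) {
  if (length(observed) < 2) stopf("need at least 2 cells")
  if (any(observed < 0)) stopf("counts must be nonnegative")
  if (is.null(expected)) expected <- rep(1 / length(observed), length(observed))
  if (length(expected) != length(observed))
    stopf("expected proportions must match observed cells")
  if (any(expected <= 0)) stopf("expected proportions must be positive")
  expected <- expected / sum(expected)
  ht <- suppressWarnings(chisq.test(observed, p = expected))
  list(statistic = unname(ht$statistic), df = as.integer(ht$parameter),
       p_value = ht$p.value, observed = observed,
       expected = expected * sum(observed))
}

#' Per-individual grunt counts
#'
#' Counts the grunts emitted by each individual across an interaction log.
#' Individuals listed in `ids` but never grunting get a zero; with no `ids`
#' only observed callers appear.
#'
#' @param interactions Interaction data frame with `grunt_emitted` and
#'   `grunt_caller` columns (see [simulate_interactions()]).
#' @param ids Optional character vector fixing the output order.
#' @return Named integer vector of grunt counts.
#' @export
grunt_counts <- function(interactions, ids = NULL) {
  g <- interactions[interactions$grunt_emitted %in% TRUE, , drop = FALSE]
  callers <- g$grunt_caller
  if (is.null(ids)) {
    if (!length(callers)) return(setNames(integer(0), character(0)))
    ids <- sort(unique(callers))
  }
  tab <- table(factor(callers, levels = ids))
  setNames(as.integer(tab), ids)
}

#' Latency from grunt to conflict resolution
#'
#' Mean and SD of the delay between a grunt and the end of the conflict,
#' separately for conflicts that ended and for those where aggression
#' continued.
#'
#' @inheritParams grunt_counts
#' @return Data frame with one row per outcome class: `outcome`, `n`,
#'   `mean_latency_s`, `sd_latency_s`.
#' @export
latency_summary <- function(interactions) {
  g <- interactions[interactions$grunt_emitted %in% TRUE &
                      !is.na(interactions$latency_s), , drop = FALSE]
  classes <- c("end_conflict", "aggression_continued")
  rows <- lapply(classes, function(cl) {
    lat <- g$latency_s[g$outcome == cl]
    data.frame(outcome = cl, n = length(lat),
               mean_latency_s = if (length(lat)) mean(lat) else NA_real_,
               sd_latency_s = if (length(lat) > 1) sd(lat) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Per-individual acoustic summary table
#'
#' Per-individual mean and SD of duration, peak frequency at the call
#' centre, mean minimum frequency, mean bandwidth and HNR at the centre,
#' together with rank, sex and call count, ordered by rank. Individuals with
#' no calls (e.g. an alpha that never grunts) appear as a row of `NA`
#' summaries rather than being dropped.
#'
#' @param features A feature table (data frame) with at least `caller`,
#'   `sex`, `rank` and the acoustic parameter columns named as in
#'   [measure_element()].
#' @param individuals Optional data frame with `id`, `sex`, `rank` covering
#'   animals absent from `features`.
#' @return Data frame, one row per individual, ordered by rank.
#' @export
table1_report <- function(features, individuals = NULL) {
  if (is.null(individuals)) {
    individuals <- unique(features[, c("caller", "sex", "rank")])
    names(individuals)[1] <- "id"
  }
  individuals <- individuals[order(individuals$rank), , drop = FALSE]
  params <- c("duration_s", "peak_freq_centre_hz", "min_freq_mean_hz",
              "bandwidth_mean_hz", "hnr_centre_db")
  rows <- lapply(seq_len(nrow(individuals)), function(i) {
    id <- individuals$id[i]
    sub <- features[features$caller == id, , drop = FALSE]
    out <- data.frame(id = id, rank = individuals$rank[i],
                      sex = individuals$sex[i], n_calls = nrow(sub))
    for (p in params) {
      out[[paste0(p, "_mean")]] <- if (nrow(sub)) mean(sub[[p]]) else NA_real_
      out[[paste0(p, "_sd")]] <- if (nrow(sub) > 1) sd(sub[[p]]) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}
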