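#' Fisher discriminant function analysis
#'
#' Computes the discriminant axes as eigenvectors of `W^-1 B`, where `W` is
#' the pooled within-class scatter and `B` the between-class scatter, via
#' symmetric whitening. Axes are scaled so the pooled within-class variance
#' of each discriminant score is 1, ordered by decreasing eigenvalue, and
#' sign-fixed so the largest-magnitude standardized coefficient on each axis
#' is positive. A near-singular `W` is stabilised with a small ridge
#' (`1e-8 * mean(diag(W))`), reported in the result.
#'
#' @param table Data frame holding the predictor columns and the class
#'   label column.
#' @param class_label Name of the label column (e.g. `"caller"` or `"sex"`).
#' @param columns Predictor column names; default: all numeric columns
#'   except `rank`.
#' @return Object of class `dfa_model`: class means, scatter matrices,
#'   `axes` (p x r raw coefficients), `eigenvalues`,
#'   `percent_variance` per axis, `standardized_coefficients`, class priors
#'   (equal), plus bookkeeping (`n`, `classes`, `columns`, `ridge_used`).
#' @examples
#' tab <- data.frame(caller = rep(c("a", "b"), each = 20),
#'                   f1 = c(rnorm(20), rnorm(20, 3)), f2 = rnorm(40))
#' fit_dfa(tab, "caller")
#' @export
fit_dfa <- function(table, class_label, columns = NULL) {
  if (!class_label %in% names(table)) stopf("no column `%s`", class_label)
  if (is.null(columns)) {
    columns <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1))], c("rank"))
  }
  X <- as.matrix(table[, columns, drop = FALSE])
  y <- factor(table[[class_label]])
  g <- nlevels(y)
  if (g < 2) stopf("need at least 2 classes")
  n <- nrow(X)
  p <- ncol(X)
  counts <- table(y)
  if (any(counts <= p))
    warning(sprintf("class(es) with <= %d rows: within-class scatter may be unstable", p))
  grand <- colMeans(X)
  means <- do.call(rbind, lapply(levels(y), function(l)
    colMeans(X[y == l, , drop = FALSE])))
  rownames(means) <- levels(y)
  W <- matrix(0, p, p)
  for (l in levels(y)) {
    Xi <- X[y == l, , drop = FALSE]
    d <- sweep(Xi, 2, means[l, ])
    W <- W + crossprod(d)
  }
  B <- matrix(0, p, p)
  for (l in levels(y)) {
    d <- means[l, ] - grand
    B <- B + counts[[l]] * tcrossprod(d)
  }
  ridge_used <- FALSE
  Wn <- W / (n - g)                       # pooled within-class covariance
  ch <- tryCatch(chol(Wn), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < 1e-10) {
    Wn <- Wn + diag(1e-8 * mean(diag(Wn)), p)
    ch <- chol(Wn)
    ridge_used <- TRUE
  }
  # whiten: M = R^-T (B/(n-g)) R^-1 is symmetric; eigvecs map back via R^-1
  Rinv <- backsolve(ch, diag(p))
  M <- t(Rinv) %*% (B / (n - g)) %*% Rinv
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  r <- min(g - 1, p)
  lambda <- pmax(eg$values[seq_len(r)], 0)
  A <- Rinv %*% eg$vectors[, seq_len(r), drop = FALSE]   # within-whitened axes
  # standardized coefficients: raw coefficients scaled by within-class SDs
  std <- A * sqrt(diag(Wn))
  for (k in seq_len(r)) {
    j <- which.max(abs(std[, k]))
    if (std[j, k] < 0) { A[, k] <- -A[, k]; std[, k] <- -std[, k] }
  }
  rownames(A) <- rownames(std) <- columns
  colnames(A) <- colnames(std) <- paste0("DF", seq_len(r))
  pct <- if (sum(lambda) > 0) 100 * lambda / sum(lambda) else rep(0, r)
  structure(list(
    columns = columns, class_label = class_label, classes = levels(y),
    n = n, class_counts = as.integer(counts),
    class_means = means, grand_mean = grand,
    pooled_within_scatter = W, between_scatter = B,
    within_covariance = Wn,
    axes = A, eigenvalues = lambda, percent_variance = pct,
    standardized_coefficients = std,
    class_scores = means %*% A,             # class means in discriminant space
    ridge_used = ridge_used),
    class = "dfa_model")
}

#' @export
print.dfa_model <- function(x, ...) {
  cat(sprintf("Discriminant function analysis: %d classes, %d predictors, N = %d\n",
              length(x$classes), length(x$columns), x$n))
  cat(sprintf("  eigenvalues: %s\n",
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")))
  cat(sprintf("  %% variance:  %s\n",
              paste(sprintf("%.1f", x$percent_variance), collapse = ", ")))
  invisible(x)
}

#' Wilks' Lambda and Bartlett's chi-square approximation
#'
#' `Lambda = prod(1 / (1 + lambda_k))` over the eigenvalues of `W^-1 B`,
#' with Bartlett's approximation `chi2 = -(n - 1 - (p + g)/2) * log(Lambda)`
#' on `p * (g - 1)` degrees of freedom.
#'
#' @param model A fitted [fit_dfa()] model.
#' @return List with `lambda`, `chi_square`, `df`, `p_value`.
#' @export
wilks_lambda <- function(model) {
  stopifnot(inherits(model, "dfa_model"))
  lam <- prod(1 / (1 + model$eigenvalues))
  n <- model$n
  p <- length(model$columns)
  g <- length(model$classes)
  chi2 <- -(n - 1 - (p + g) / 2) * log(lam)
  df <- p * (g - 1)
  list(lambda = lam, chi_square = chi2, df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Balanced training/held-out split
#'
#' Draws exactly `n_per_class` training rows per class at random; all
#' remaining rows are held out. Training and held-out sets are disjoint.
#'
#' @inheritParams fit_dfa
#' @param n_per_class Training rows per class.
#' @param seed Integer seed.
#' @return List with `training` and `held_out` data frames and the drawn
#'   `training_rows` indices.
#' @export
balanced_subsample <- function(table, class_label, n_per_class, seed = 1) {
  y <- factor(table[[class_label]])
  counts <- table(y)
  short <- names(counts)[counts < n_per_class]
  if (length(short))
    stopf("class(es) with fewer than %d rows: %s", n_per_class,
          paste(short, collapse = ", "))
  idx <- with_seed(seed, unlist(lapply(levels(y), function(l) {
    sample(which(y == l), n_per_class)
  }), use.names = FALSE))
  held <- setdiff(seq_len(nrow(table)), idx)
  if (!length(held))
    warning("held-out set is empty: n_per_class equals every class size")
  list(training = table[idx, , drop = FALSE],
       held_out = table[held, , drop = FALSE],
       training_rows = idx)
}

#' Classify rows with a fitted discriminant model
#'
#' Assigns each row to the class whose mean is nearest in the discriminant
#' space (Euclidean distance there equals Mahalanobis distance under the
#' pooled within-class covariance restricted to the discriminant subspace);
#' priors are equal.
#'
#' @param object A `dfa_model`.
#' @param newdata Data frame containing the model's predictor columns.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.dfa_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$columns, drop = FALSE])
  S <- X %*% object$axes
  C <- object$class_scores
  d2 <- outer(rowSums(S^2), rowSums(C^2), "+") - 2 * S %*% t(C)
  factor(object$classes[max.col(-d2, ties.method = "first")],
         levels = object$classes)
}

#' Cross-validate a discriminant model on held-out calls
#'
#' @param model A `dfa_model`.
#' @param held_out Data frame of rows not used for fitting.
#' @return List with `accuracy_percent`, `per_class_percent`, `n`, and the
#'   `confusion` matrix (true class x assigned class).
#' @export
cross_validate <- function(model, held_out) {
  if (!nrow(held_out)) stopf("held-out set is empty")
  truth <- factor(held_out[[model$class_label]], levels = model$classes)
  pred <- predict(model, held_out)
  confusion <- table(truth = truth, assigned = pred)
  correct <- diag(confusion)
  totals <- rowSums(confusion)
  per_class <- ifelse(totals > 0, 100 * correct / totals, NA_real_)
  list(accuracy_percent = 100 * sum(correct) / sum(totals),
       per_class_percent = per_class, n = sum(totals),
       confusion = confusion)
}

# one pDFA statistic: mean held-out accuracy over n_selections balanced draws
pdfa_statistic <- function(table, class_label, columns, n_per_class,
                           n_selections, seeds) {
  accs <- vapply(seq_len(n_selections), function(s) {
    split <- balanced_subsample(table, class_label, n_per_class,
                                seed = seeds[s])
    model <- fit_dfa(split$training, class_label, columns)
    if (!nrow(split$held_out)) return(NA_real_)
    cross_validate(model, split$held_out)$accuracy_percent
  }, numeric(1))
  mean(accs)
}

#' Permuted DFA for caller identity
#'
#' Tests whether calls carry individual signatures while respecting the
#' repeated-measures structure. The observed statistic is the mean held-out
#' classification accuracy over `n_selections` balanced subsamples
#' (`n_per_class` training calls per caller). The null distribution repeats
#' the identical procedure after permuting caller labels across calls,
#' restricted within levels of `restriction` (typically sex) so that
#' permutations respect the design; `p = (count(permuted >= observed) + 1) /
#' (n_permutations + 1)`.
#'
#' @inheritParams fit_dfa
#' @param n_per_class Training calls per caller (default 37).
#' @param n_selections Balanced subsamples averaged per statistic
#'   (default 100).
#' @param n_permutations Label permutations (default 1000).
#' @param restriction Name of the restriction factor column, or `NULL` for
#'   unrestricted permutation (a warning is issued if the named column is
#'   absent).
#' @param seed Integer seed.
#' @return Object of class `pdfa_result` with `original_mean_accuracy`,
#'   `permuted_mean_accuracy`, `p_value`, `n_selections`, `n_permutations`,
#'   `design`, and `permuted_accuracies`.
#' @export
pdfa_identity <- function(table, class_label = "caller", columns = NULL,
                          n_per_class = 37, n_selections = 100,
                          n_permutations = 1000, restriction = "sex",
                          seed = 1) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (is.null(columns)) {
    columns <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1))], c("rank"))
  }
  if (!is.null(restriction) && !restriction %in% names(table)) {
    warning(sprintf(
      "restriction factor `%s` not found; falling back to unrestricted permutation",
      restriction))
    restriction <- NULL
  }
  seeds <- derive_seeds(seed, n_selections + n_permutations * (n_selections + 1))
  orig <- pdfa_statistic(table, class_label, columns, n_per_class,
                         n_selections, seeds[seq_len(n_selections)])
  strata <- if (is.null(restriction)) rep(1L, nrow(table))
            else as.integer(factor(table[[restriction]]))
  perm <- vapply(seq_len(n_permutations), function(b) {
    base_i <- n_selections + (b - 1) * (n_selections + 1)
    tab_b <- table
    tab_b[[class_label]] <- with_seed(seeds[base_i + 1], {
      lab <- table[[class_label]]
      for (s in unique(strata)) {
        i <- which(strata == s)
        lab[i] <- lab[i][sample(length(i))]
      }
      lab
    })
    pdfa_statistic(tab_b, class_label, columns, n_per_class, n_selections,
                   seeds[base_i + 1 + seq_len(n_selections)])
  }, numeric(1))
  p <- (sum(perm >= orig) + 1) / (n_permutations + 1)
  structure(list(original_mean_accuracy = orig,
                 permuted_mean_accuracy = mean(perm),
                 p_value = p, n_selections = n_selections,
                 n_permutations = n_permutations,
                 design = "crossed_restricted",
                 permuted_accuracies = perm),
            class = "pdfa_result")
}

#' Permuted DFA for sex with caller as nested factor
#'
#' Tests for acoustic differences between the sexes while controlling for
#' caller identity: calls always stay with their caller, and the null
#' permutation reassigns whole individuals to sexes. Each statistic draws
#' `n_individuals_per_sex` callers per sex and `n_per_class` calls per
#' selected caller, fits the discriminant model on the sex label, and
#' averages held-out accuracy over `n_selections` draws.
#'
#' @inheritParams pdfa_identity
#' @param n_per_class Calls drawn per selected individual (default 36).
#' @param n_individuals_per_sex Individuals drawn per sex (default 8).
#' @param caller_label Name of the caller column (default `"caller"`).
#' @param sex_label Name of the sex column (default `"sex"`).
#' @return A `pdfa_result` with `design = "nested"`.
#' @export
pdfa_sex <- function(table, columns = NULL, n_per_class = 36,
                     n_individuals_per_sex = 8, n_selections = 100,
                     n_permutations = 100, caller_label = "caller",
                     sex_label = "sex", seed = 1) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (is.null(columns)) {
    columns <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1))], c("rank"))
  }
  caller_sex <- unique(table[, c(caller_label, sex_label)])
  if (anyDuplicated(caller_sex[[caller_label]]))
    stopf("each caller must have a single sex")
  sex_of <- setNames(as.character(caller_sex[[sex_label]]),
                     caller_sex[[caller_label]])
  sexes <- sort(unique(sex_of))
  if (length(sexes) != 2) stopf("need exactly 2 sexes")
  per_sex <- table(sex_of)
  if (any(per_sex < n_individuals_per_sex))
    stopf("need at least %d individuals per sex", n_individuals_per_sex)

  one_stat <- function(sex_assign, seeds_sel) {
    accs <- vapply(seq_len(n_selections), function(s) {
      with_seed(seeds_sel[s], {
        chosen <- unlist(lapply(sexes, function(sx) {
          ids <- names(sex_assign)[sex_assign == sx]
          sample(ids, n_individuals_per_sex)
        }), use.names = FALSE)
        rows_train <- integer(0)
        for (id in chosen) {
          i <- which(table[[caller_label]] == id)
          if (length(i) < n_per_class)
            stopf("caller %s has fewer than %d calls", id, n_per_class)
          rows_train <- c(rows_train, sample(i, n_per_class))
        }
        tab <- table
        tab[[sex_label]] <- sex_assign[as.character(tab[[caller_label]])]
        train <- tab[rows_train, , drop = FALSE]
        held <- tab[setdiff(which(tab[[caller_label]] %in% chosen),
                            rows_train), , drop = FALSE]
        model <- fit_dfa(train, sex_label, columns)
        if (!nrow(held)) return(NA_real_)
        cross_validate(model, held)$accuracy_percent
      })
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }

  seeds <- derive_seeds(seed, n_selections + n_permutations * (n_selections + 1))
  orig <- one_stat(sex_of, seeds[seq_len(n_selections)])
  n_each <- as.integer(per_sex[sexes])
  perm <- vapply(seq_len(n_permutations), function(b) {
    base_i <- n_selections + (b - 1) * (n_selections + 1)
    assign_b <- with_seed(seeds[base_i + 1], {
      setNames(sample(rep(sexes, n_each)), names(sex_of))
    })
    one_stat(assign_b, seeds[base_i + 1 + seq_len(n_selections)])
  }, numeric(1))
  p <- (sum(perm >= orig) + 1) / (n_permutations + 1)
  structure(list(original_mean_accuracy = orig,
                 permuted_mean_accuracy = mean(perm),
                 p_value = p, n_selections = n_selections,
                 n_permutations = n_permutations,
                 design = "nested",
                 permuted_accuracies = perm),
            class = "pdfa_result")
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf("Permuted DFA (%s design)\n", x$design))
  cat(sprintf("  original mean accuracy: %.2f%%\n", x$original_mean_accuracy))
  cat(sprintf("  permuted mean accuracy: %.2f%% (%d permutations)\n",
              x$permuted_mean_accuracy, x$n_permutations))
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' Exact binomial test of classification accuracy against chance
#'
#' One-sided exact tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`,
#' with `p0` the chance classification rate (1 / number of classes).
#'
#' @param k_correct Number of correctly classified calls.
#' @param n_total Number of classified calls.
#' @param p0 Chance rate in (0, 1).
#' @return The one-sided p-value.
#' @examples
#' binomial_vs_chance(43, 234, 1/18)
#' @export
binomial_vs_chance <- function(k_correct, n_total, p0) {
  if (!is_count(k_correct) || !is_count(n_total) || k_correct > n_total)
    stopf("need integer 0 <= k_correct <= n_total")
  if (p0 <= 0 || p0 >= 1) stopf("p0 must be in (0, 1)")
  pbinom(k_correct - 1, n_total, p0, lower.tail = FALSE)
}
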