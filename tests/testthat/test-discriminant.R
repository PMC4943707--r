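test_that("a six-point toy problem matches a brute-force eigendecomposition", {
  tab <- data.frame(
    caller = rep(c("a", "b", "c"), each = 2),
    f1 = c(0, 1, 4, 5, 8, 9),
    f2 = c(0, 2, 1, 3, 5, 9))
  m <- suppressWarnings(fit_dfa(tab, "caller"))  # 2 rows/class: toy size

  X <- as.matrix(tab[, c("f1", "f2")])
  y <- tab$caller
  W <- matrix(0, 2, 2); B <- matrix(0, 2, 2)
  grand <- colMeans(X)
  for (l in unique(y)) {
    Xi <- X[y == l, ]
    d <- sweep(Xi, 2, colMeans(Xi))
    W <- W + crossprod(d)
    B <- B + nrow(Xi) * tcrossprod(colMeans(Xi) - grand)
  }
  ev <- sort(Re(eigen(solve(W) %*% B)$values), decreasing = TRUE)
  expect_equal(m$eigenvalues, ev[1:2], tolerance = 1e-8)
  # Wilks via the determinant-ratio identity det(W)/det(W+B)
  wl <- wilks_lambda(m)
  expect_equal(wl$lambda, det(W) / det(W + B), tolerance = 1e-8)
  expect_equal(sum(m$percent_variance), 100)
  # sign convention: dominant standardized coefficient positive
  expect_true(all(apply(m$standardized_coefficients, 2,
                        function(cc) cc[which.max(abs(cc))] > 0)))
})

test_that("wilks_lambda closed forms hold", {
  fake <- structure(list(eigenvalues = c(0, 0), n = 50, columns = c("a", "b"),
                         classes = c("x", "y", "z")), class = "dfa_model")
  expect_identical(wilks_lambda(fake)$lambda, 1)
  fake1 <- structure(list(eigenvalues = 1, n = 50, columns = c("a", "b"),
                          classes = c("x", "y")), class = "dfa_model")
  expect_identical(wilks_lambda(fake1)$lambda, 0.5)
})

test_that("identical class distributions give null eigenvalues and chance
           accuracy", {
  tab <- make_class_table(2, 150, p = 3, delta = 0, seed = 1)
  m <- fit_dfa(tab, "caller")
  expect_lt(max(m$eigenvalues), 0.1)
  split <- balanced_subsample(tab, "caller", 100, seed = 2)
  cv <- cross_validate(fit_dfa(split$training, "caller"), split$held_out)
  expect_gt(cv$accuracy_percent, 30)
  expect_lt(cv$accuracy_percent, 70)
})

test_that("well-separated classes classify almost perfectly and agree with
           an independent LDA implementation", {
  tab <- make_class_table(3, 60, p = 3, delta = 6, seed = 3)
  split <- balanced_subsample(tab, "caller", 40, seed = 4)
  m <- fit_dfa(split$training, "caller")
  cv <- cross_validate(m, split$held_out)
  expect_gt(cv$accuracy_percent, 99)

  ld <- MASS::lda(split$training[, m$columns],
                  grouping = split$training$caller,
                  prior = rep(1 / 3, 3))
  pred_mass <- predict(ld, split$held_out[, m$columns])$class
  pred_ours <- predict(m, split$held_out)
  expect_gt(mean(as.character(pred_mass) == as.character(pred_ours)), 0.99)
})

test_that("balanced subsampling is exact, disjoint and reproducible", {
  tab <- make_class_table(4, 50, seed = 5)
  sp <- balanced_subsample(tab, "caller", 37, seed = 6)
  expect_true(all(table(sp$training$caller) == 37))
  expect_true(all(table(sp$held_out$caller) == 13))
  expect_length(intersect(rownames(sp$training), rownames(sp$held_out)), 0)
  sp2 <- balanced_subsample(tab, "caller", 37, seed = 6)
  expect_identical(sp$training_rows, sp2$training_rows)
  expect_error(balanced_subsample(tab, "caller", 51, seed = 1), "fewer")
  expect_warning(balanced_subsample(tab, "caller", 50, seed = 1), "empty")
})

test_that("per-class accuracies aggregate to the overall rate", {
  tab <- make_class_table(3, 40, delta = 2, seed = 7)
  sp <- balanced_subsample(tab, "caller", 25, seed = 8)
  cv <- cross_validate(fit_dfa(sp$training, "caller"), sp$held_out)
  counts <- table(sp$held_out$caller)
  expect_equal(sum(cv$per_class_percent * counts) / sum(counts),
               cv$accuracy_percent)
})

test_that("binomial test against chance matches a direct tail sum", {
  expect_equal(binomial_vs_chance(10, 10, 0.25), 0.25^10)
  k <- round(0.185 * 234)
  direct <- sum(vapply(k:234, function(i)
    choose(234, i) * (1 / 18)^i * (17 / 18)^(234 - i), numeric(1)))
  expect_equal(binomial_vs_chance(k, 234, 1 / 18), direct)
  expect_lt(binomial_vs_chance(k, 234, 1 / 18), 0.001)
  expect_gte(binomial_vs_chance(13, 234, 1 / 18), 0.5)
})

test_that("identity pDFA is deterministic, warns on a missing restriction
           factor, and detects strong signatures", {
  tab <- make_class_table(5, 20, p = 3, delta = 4, seed = 9,
                          sexes = c("M", "M", "F", "F", "F"))
  r1 <- pdfa_identity(tab, n_per_class = 12, n_selections = 3,
                      n_permutations = 30, seed = 10)
  r2 <- pdfa_identity(tab, n_per_class = 12, n_selections = 3,
                      n_permutations = 30, seed = 10)
  expect_identical(r1, r2)
  expect_lt(r1$p_value, 0.05)
  expect_gt(r1$original_mean_accuracy, 90)
  # restricted permutation keeps the sex-level signal, so the null accuracy
  # sits above the 20% naive chance but well below the original
  expect_gt(r1$original_mean_accuracy, r1$permuted_mean_accuracy + 20)
  expect_lt(r1$permuted_mean_accuracy, 60)

  tab2 <- tab; tab2$sex <- NULL
  expect_warning(pdfa_identity(tab2, n_per_class = 12, n_selections = 2,
                               n_permutations = 5, seed = 1),
                 "unrestricted")
})

test_that("sex pDFA controls for caller and finds only true sex effects", {
  herd_cfg <- herd_config(n_individuals = 18,
                          sex_labels = rep(c("M", "F"), 9), seed = 11)
  herd <- generate_herd(herd_cfg)
  tab <- simulate_feature_table(herd, 30, seed = 12)
  null_res <- pdfa_sex(tab, n_per_class = 20, n_individuals_per_sex = 8,
                       n_selections = 3, n_permutations = 30, seed = 13)
  expect_gt(null_res$p_value, 0.05)
  expect_identical(null_res$design, "nested")
  expect_identical(null_res,
                   pdfa_sex(tab, n_per_class = 20, n_individuals_per_sex = 8,
                            n_selections = 3, n_permutations = 30,
                            seed = 13))

  # inject a strong sex effect (4 within-SD shift on duration scale)
  tab_fx <- tab
  shift <- 4 * attr(herd, "config")$within_individual_sd["duration_s"]
  tab_fx$duration_s <- tab_fx$duration_s + ifelse(tab_fx$sex == "M", shift, 0)
  fx <- pdfa_sex(tab_fx, n_per_class = 20, n_individuals_per_sex = 8,
                 n_selections = 3, n_permutations = 60, seed = 14)
  expect_lt(fx$p_value, 0.05)
  expect_gt(fx$original_mean_accuracy, 80)

  expect_error(pdfa_sex(tab, n_individuals_per_sex = 12), "at least")
})
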