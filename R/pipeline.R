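#' Configuration for an end-to-end pipeline run
#'
#' Assembles every stage parameter with its default. Any random stage takes
#' its seed from `seed` (one derived seed per stage, all recorded in the run
#' log).
#'
#' @param seed Master seed.
#' @param herd A [herd_config()] for synthetic mode.
#' @param interactions_csv,features_csv Optional paths to observed data; when
#'   given they replace the corresponding synthetic stage.
#' @param n_interactions Interactions to simulate (default 1880).
#' @param calls_per_individual Calls per caller in the synthetic feature
#'   table (default 50).
#' @param n_randomizations Randomisations for the linearity test
#'   (default 10000).
#' @param vif_threshold,outlier_quantile Preprocessing settings.
#' @param dfa_n_per_class Training calls per caller for the balanced DFA
#'   (default 37).
#' @param pdfa_n_selections,pdfa_n_permutations Permuted-DFA effort for the
#'   caller-identity test (defaults 10 and 100 for a tractable full run;
#'   raise to 100/1000 for a production analysis).
#' @param sex_n_per_class,sex_n_individuals,sex_n_selections,sex_n_permutations
#'   Permuted-DFA design for the sex test.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(seed = 1,
                            herd = herd_config(seed = seed),
                            interactions_csv = NULL,
                            features_csv = NULL,
                            n_interactions = 1880,
                            calls_per_individual = 50,
                            n_randomizations = 10000,
                            vif_threshold = 2,
                            outlier_quantile = 0.975,
                            dfa_n_per_class = 37,
                            pdfa_n_selections = 10,
                            pdfa_n_permutations = 100,
                            sex_n_per_class = 36,
                            sex_n_individuals = 8,
                            sex_n_selections = 10,
                            sex_n_permutations = 50) {
  cfg <- structure(as.list(environment()), class = "run_config")
  for (nm in c("n_interactions", "n_randomizations", "pdfa_n_selections",
               "pdfa_n_permutations", "sex_n_selections",
               "sex_n_permutations", "dfa_n_per_class",
               "calls_per_individual")) {
    if (!is_count(cfg[[nm]]) || cfg[[nm]] < 1)
      stopf("`%s` must be a positive integer", nm)
  }
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> dominance inference -> feature table
#' -> preprocessing -> conventional and permuted discriminant analysis ->
#' conflict and rank statistics, persisting every intermediate as CSV plus
#' a consolidated plain-text summary and a run log with every seed. Given
#' the same config and seed the numeric outputs are identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with every stage result (`herd`,
#'   `interactions`, `dominance`, `features`, `preprocess`, `dfa`,
#'   `pdfa_identity`, `pdfa_sex`, `stats`) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("vocrank_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 8)
  log_lines <- c(
    sprintf("vocrank %s", as.character(utils::packageVersion("vocrank"))),
    sprintf("master seed: %d", config$seed),
    sprintf("stage seeds: %s", paste(seeds, collapse = " ")))

  herd <- run_stage("herd", generate_herd(config$herd))
  write.csv(herd, file.path(out_dir, "herd.csv"), row.names = FALSE)

  interactions <- run_stage("interactions", {
    if (!is.null(config$interactions_csv))
      read.csv(config$interactions_csv)
    else simulate_interactions(herd, config$n_interactions, seed = seeds[1])
  })
  write.csv(interactions, file.path(out_dir, "interactions.csv"),
            row.names = FALSE)

  dom <- run_stage("dominance", {
    X <- build_matrix(interactions, ids = herd$id)
    lin <- landau_h_prime(X, n_random = config$n_randomizations,
                          seed = seeds[2])
    rk <- isi_rank(X, seed = seeds[3])
    list(matrix = X, linearity = lin, rank = rk, dci = dci(X))
  })
  write.csv(as.data.frame(unclass(dom$matrix)),
            file.path(out_dir, "dominance_matrix.csv"))
  write.csv(data.frame(id = names(dom$rank$ranks), rank = dom$rank$ranks),
            file.path(out_dir, "rank_order.csv"), row.names = FALSE)

  features <- run_stage("features", {
    if (!is.null(config$features_csv)) read.csv(config$features_csv)
    else simulate_feature_table(herd, config$calls_per_individual,
                                seed = seeds[4], skip_top_rank = TRUE)
  })
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)

  prep <- run_stage("preprocess",
                    preprocess_features(features,
                                        vif_threshold = config$vif_threshold,
                                        outlier_quantile = config$outlier_quantile,
                                        seed = seeds[5]))
  write.csv(prep$report$vif_elimination_trace,
            file.path(out_dir, "vif_trace.csv"), row.names = FALSE)
  write.csv(prep$table, file.path(out_dir, "features_preprocessed.csv"),
            row.names = FALSE)

  # balanced designs cannot exceed the smallest class after outlier removal
  n_train <- min(config$dfa_n_per_class,
                 min(table(prep$table$caller)) - 1L)
  if (n_train < config$dfa_n_per_class)
    log_lines <- c(log_lines, sprintf(
      "note: training calls per caller reduced to %d (smallest class)",
      n_train))

  dfa <- run_stage("dfa", {
    cols <- prep$report$retained_variables
    split <- balanced_subsample(prep$table, "caller",
                                n_train, seed = seeds[6])
    model <- fit_dfa(split$training, "caller", cols)
    cv <- cross_validate(model, split$held_out)
    wl <- wilks_lambda(model)
    k <- round(cv$accuracy_percent / 100 * cv$n)
    list(model = model, cv = cv, wilks = wl,
         chance_percent = 100 / length(model$classes),
         binomial_p = binomial_vs_chance(k, cv$n,
                                         1 / length(model$classes)))
  })
  write.csv(data.frame(variable = rownames(dfa$model$standardized_coefficients),
                       dfa$model$standardized_coefficients),
            file.path(out_dir, "dfa_coefficients.csv"), row.names = FALSE)
  write.csv(as.data.frame(unclass(dfa$cv$confusion)),
            file.path(out_dir, "dfa_confusion.csv"), row.names = FALSE)

  pid <- run_stage("pdfa_identity",
                   pdfa_identity(prep$table,
                                 columns = prep$report$retained_variables,
                                 n_per_class = n_train,
                                 n_selections = config$pdfa_n_selections,
                                 n_permutations = config$pdfa_n_permutations,
                                 seed = seeds[7]))
  psex <- run_stage("pdfa_sex", {
    per_sex <- table(unique(prep$table[, c("caller", "sex")])$sex)
    n_ind <- min(config$sex_n_individuals, per_sex)
    per_caller <- table(prep$table$caller)
    n_calls <- min(config$sex_n_per_class, per_caller - 1L)
    pdfa_sex(prep$table, columns = prep$report$retained_variables,
             n_per_class = n_calls, n_individuals_per_sex = n_ind,
             n_selections = config$sex_n_selections,
             n_permutations = config$sex_n_permutations, seed = seeds[8])
  })

  stats <- run_stage("stats", {
    counts <- grunt_counts(interactions, ids = herd$id)
    est_rank <- dom$rank$ranks[herd$id]
    r_counts <- spearman(est_rank, counts)
    per_ind <- table1_report(features,
                             individuals = data.frame(id = herd$id,
                                                      sex = herd$sex,
                                                      rank = est_rank))
    with_calls <- per_ind[per_ind$n_calls > 0, ]
    r_minfreq <- spearman(with_calls$rank, with_calls$min_freq_mean_hz_mean)
    outc <- c(end_conflict = sum(interactions$grunt_emitted %in% TRUE &
                                   interactions$outcome == "end_conflict"),
              aggression_continued = sum(interactions$outcome ==
                                           "aggression_continued"))
    list(grunt_counts = counts, spearman_rank_counts = r_counts,
         spearman_rank_minfreq = r_minfreq,
         outcome_counts = outc, outcome_test = chisq_gof(unname(outc)),
         latency = latency_summary(interactions), table1 = per_ind)
  })
  write.csv(stats$table1, file.path(out_dir, "per_individual_report.csv"),
            row.names = FALSE)

  summary_lines <- c(
    "== vocrank pipeline summary ==",
    sprintf("[dominance] h' = %.3f (p = %.4g), DCI = %.3f, I&SI: I = %d, SI = %d",
            dom$linearity$h_prime, dom$linearity$p_value, dom$dci,
            dom$rank$I, dom$rank$SI),
    sprintf("[preprocess] %d outliers removed; retained: %s",
            prep$report$n_outliers_removed,
            paste(prep$report$retained_variables, collapse = ", ")),
    sprintf("[dfa] Wilks Lambda = %.3f (chi2 = %.1f, df = %d, p = %.3g); CV accuracy = %.1f%% (chance %.1f%%, binomial p = %.3g)",
            dfa$wilks$lambda, dfa$wilks$chi_square, dfa$wilks$df,
            dfa$wilks$p_value, dfa$cv$accuracy_percent, dfa$chance_percent,
            dfa$binomial_p),
    sprintf("[dfa] first two functions explain %.0f%% of variance",
            sum(dfa$model$percent_variance[seq_len(min(2, length(dfa$model$percent_variance)))])),
    sprintf("[pdfa identity] original %.1f%% vs permuted %.1f%%, p = %.4g",
            pid$original_mean_accuracy, pid$permuted_mean_accuracy,
            pid$p_value),
    sprintf("[pdfa sex] original %.1f%% vs permuted %.1f%%, p = %.4g",
            psex$original_mean_accuracy, psex$permuted_mean_accuracy,
            psex$p_value),
    sprintf("[conflict] grunts ended %d conflicts vs %d continued (chi2 = %.2f, df = %d, p = %.3g)",
            stats$outcome_counts[1], stats$outcome_counts[2],
            stats$outcome_test$statistic, stats$outcome_test$df,
            stats$outcome_test$p_value),
    sprintf("[rank] Spearman rank~grunt count: r_s = %.2f (p = %.3g); rank~mean min freq: r_s = %.2f (p = %.3g)",
            stats$spearman_rank_counts$r_s, stats$spearman_rank_counts$p_value,
            stats$spearman_rank_minfreq$r_s,
            stats$spearman_rank_minfreq$p_value))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  writeLines(c(log_lines, summary_lines), file.path(out_dir, "run_log.txt"))

  invisible(list(herd = herd, interactions = interactions, dominance = dom,
                 features = features, preprocess = prep, dfa = dfa,
                 pdfa_identity = pid, pdfa_sex = psex, stats = stats,
                 out_dir = out_dir))
}
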