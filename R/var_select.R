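# Mean OOB MSE over a few forests refit with derived seeds; the jitter
# (sd across refits) feeds the one-standard-error rule.
replicate_oob <- function(design, response, config, n_rep, ntree, offset) {
  errs <- vapply(seq_len(n_rep), function(f) {
    cfg <- forest_config(ntree = ntree, mtry = NULL,
                         nodesize = config$nodesize,
                         seed = derive_seed(config$seed, offset + f))
    oob_mse(fit_forest(design, response, cfg))
  }, numeric(1))
  c(mean = mean(errs), sd = stats::sd(errs))
}

# One-SE elbow: smallest prefix whose mean nested error is within `tol`
# of the minimum.
select_prefix <- function(errors, tol) {
  min(which(errors <= min(errors) + tol))
}

#' Step 1: importance ranking and thresholding
#'
#' Permutation importance is averaged over `n_forests` independently seeded
#' forests (default mtry of `floor(P/3)`), predictors are ranked in
#' descending mean importance, and those with strictly positive mean
#' importance are retained.
#'
#' @param design data frame of predictors.
#' @param response numeric response.
#' @param config a [forest_config()] supplying `nodesize` and the base seed.
#' @param n_forests forests averaged (default 25).
#' @param ntree trees per selection forest (default 1000; importance ranks
#'   are stabilized by averaging over forests rather than by tree count).
#' @return List with `ranked_vars`, `retained_threshold`, `mean_importance`
#'   (named, in ranked order). When no importance is positive the retained
#'   set is empty and a warning is raised.
#' @export
threshold_step <- function(design, response, config = forest_config(),
                           n_forests = 25, ntree = 1000) {
  p <- ncol(design)
  if (p < 2) stop("need at least 2 predictors")
  imp <- matrix(0, n_forests, p, dimnames = list(NULL, colnames(design)))
  for (f in seq_len(n_forests)) {
    cfg <- forest_config(ntree = ntree, mtry = NULL,
                         nodesize = config$nodesize,
                         seed = derive_seed(config$seed, 200 + f))
    m <- fit_forest(design, response, cfg)
    raw <- randomForest::importance(m$rf, scale = FALSE)[, "%IncMSE"]
    imp[f, ] <- 100 * raw / oob_mse(m)
  }
  mean_imp <- sort(colMeans(imp), decreasing = TRUE)
  ranked <- names(mean_imp)
  retained <- ranked[mean_imp > 0]
  if (!length(retained))
    warning("no predictor has positive mean importance; empty retention")
  list(ranked_vars = ranked, retained_threshold = retained,
       mean_importance = mean_imp)
}

#' Step 2: interpretation set by nested out-of-bag errors
#'
#' Forests are fit on nested prefixes of the ranked retained variables
#' (top-1, top-2, ...). Each prefix's OOB MSE is averaged over `n_rep`
#' refits; the interpretation set is the smallest prefix whose mean error is
#' within one Monte-Carlo standard error of the minimum.
#'
#' @param ranked_retained character vector of retained variables in
#'   descending importance order.
#' @inheritParams threshold_step
#' @param n_rep refits per nested model (default 10).
#' @return List with `interpretation_set`, `nested_oob_errors` (mean per
#'   prefix), `nested_oob_sd` and `tolerance` (the SE used).
#' @export
interpretation_step <- function(ranked_retained, design, response,
                                config = forest_config(), n_rep = 10,
                                ntree = 1000) {
  k <- length(ranked_retained)
  if (!k) stop("empty retained set")
  stats_mat <- vapply(seq_len(k), function(j) {
    replicate_oob(design[ranked_retained[seq_len(j)]], response,
                  config, n_rep, ntree, offset = 300 + 50 * j)
  }, numeric(2))
  means <- stats_mat["mean", ]; sds <- stats_mat["sd", ]
  j_min <- which.min(means)
  tol <- sds[j_min] / sqrt(n_rep)
  j_sel <- select_prefix(means, tol)
  list(interpretation_set = ranked_retained[seq_len(j_sel)],
       nested_oob_errors = means, nested_oob_sd = sds, tolerance = tol)
}

#' Step 3: parsimonious prediction set
#'
#' Greedy forward pass over the interpretation set in rank order: a variable
#' is added only when it lowers the OOB MSE by more than a data-driven
#' threshold, taken as the mean absolute difference between successive
#' nested-model errors beyond the interpretation set (the "noise floor" of
#' the nested error sequence); when that stretch is too short the fallback
#' is a 1% relative improvement. Highly correlated redundant variables are
#' thereby excluded.
#'
#' @param interpretation_set character vector (rank order).
#' @inheritParams interpretation_step
#' @param nested_errors the full nested error sequence from step 2 (used for
#'   the threshold); optional.
#' @param fallback_rel minimal relative improvement floor (default 0.05:
#'   out-of-bag gains below 5% of the current model error are within the
#'   ensemble-diversity noise a redundant correlated variable can produce).
#' @return List with `prediction_set` and `threshold`.
#' @export
prediction_step <- function(interpretation_set, design, response,
                            config = forest_config(), nested_errors = NULL,
                            n_rep = 10, ntree = 1000, fallback_rel = 0.05) {
  if (!length(interpretation_set)) stop("empty interpretation set")
  k <- length(interpretation_set)
  base <- replicate_oob(design[interpretation_set[1]], response, config,
                        n_rep, ntree, offset = 600)
  # data-driven threshold: jitter of the nested-error tail beyond the
  # interpretation set, floored at a minimal relative improvement so that
  # sub-percent ensemble-diversity gains never justify a redundant variable
  thr <- fallback_rel * base[["mean"]]
  if (!is.null(nested_errors) && length(nested_errors) > k + 1) {
    tail_err <- nested_errors[k:length(nested_errors)]
    thr <- max(thr, mean(abs(diff(tail_err))))
  }
  sel <- interpretation_set[1]
  cur <- base[["mean"]]
  for (j in seq_len(k)[-1]) {
    cand <- replicate_oob(design[c(sel, interpretation_set[j])], response,
                          config, n_rep, ntree, offset = 600 + 37 * j)
    if (cur - cand[["mean"]] > thr) {
      sel <- c(sel, interpretation_set[j])
      cur <- cand[["mean"]]
    }
  }
  list(prediction_set = sel, threshold = unname(thr))
}

#' Three-step variable selection
#'
#' Threshold (positive mean permutation importance), interpretation
#' (lowest-OOB-error nested prefix under a one-standard-error rule), and
#' prediction (greedy correlation-pruning pass) steps, yielding the
#' parsimonious prediction model.
#'
#' @inheritParams threshold_step
#' @param n_rep refits per nested/greedy model evaluation.
#' @return An object of class `selection_result`: `ranked_vars`,
#'   `retained_threshold`, `interpretation_set`, `prediction_set`,
#'   `nested_oob_errors`, `diagnostics` (per-step thresholds), and the
#'   importance means from step 1.
#' @export
var_select <- function(design, response, config = forest_config(),
                       n_forests = 25, n_rep = 10, ntree = 1000) {
  s1 <- threshold_step(design, response, config, n_forests, ntree)
  if (!length(s1$retained_threshold)) {
    return(structure(
      list(ranked_vars = s1$ranked_vars, retained_threshold = character(0),
           interpretation_set = character(0), prediction_set = character(0),
           nested_oob_errors = numeric(0), mean_importance = s1$mean_importance,
           diagnostics = list(step1 = "no positive importance")),
      class = "selection_result"))
  }
  s2 <- interpretation_step(s1$retained_threshold, design, response, config,
                            n_rep, ntree)
  s3 <- prediction_step(s2$interpretation_set, design, response, config,
                        nested_errors = s2$nested_oob_errors,
                        n_rep = n_rep, ntree = ntree)
  structure(
    list(ranked_vars = s1$ranked_vars,
         retained_threshold = s1$retained_threshold,
         interpretation_set = s2$interpretation_set,
         prediction_set = s3$prediction_set,
         nested_oob_errors = s2$nested_oob_errors,
         mean_importance = s1$mean_importance,
         diagnostics = list(interp_tolerance = s2$tolerance,
                            pred_threshold = s3$threshold)),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Three-step variable selection\n")
  cat("  ranked:        ", paste(x$ranked_vars, collapse = ", "), "\n")
  cat("  retained (+):  ", paste(x$retained_threshold, collapse = ", "), "\n")
  cat("  interpretation:", paste(x$interpretation_set, collapse = ", "), "\n")
  cat("  prediction:    ", paste(x$prediction_set, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection report
#'
#' A CSV of the nested error path and per-variable membership flags plus a
#' human-readable log of each step's decision.
#'
#' @param result a `selection_result`.
#' @param dir output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_selection_report <- function(result, dir) {
  stopifnot(inherits(result, "selection_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "selection_report.csv")
  txt <- file.path(dir, "selection_log.txt")
  df <- data.frame(
    variable = result$ranked_vars,
    mean_importance = unname(result$mean_importance[result$ranked_vars]),
    retained = result$ranked_vars %in% result$retained_threshold,
    interpretation = result$ranked_vars %in% result$interpretation_set,
    prediction = result$ranked_vars %in% result$prediction_set,
    nested_oob_mse = c(result$nested_oob_errors,
                       rep(NA, length(result$ranked_vars) -
                             length(result$nested_oob_errors))))
  write.csv(df, csv, row.names = FALSE)
  writeLines(c(
    "Three-step variable selection",
    paste("step 1 retained:", paste(result$retained_threshold, collapse = ", ")),
    paste("step 2 interpretation set:",
          paste(result$interpretation_set, collapse = ", ")),
    paste("step 3 prediction set:",
          paste(result$prediction_set, collapse = ", ")),
    paste("diagnostics:",
          paste(names(result$diagnostics),
                vapply(result$diagnostics, function(d)
                  paste(format(d, digits = 4), collapse = " "), ""),
                sep = "=", collapse = "; "))), txt)
  invisible(c(csv, txt))
}
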