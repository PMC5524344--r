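#' Random-forest configuration
#'
#' Defaults follow the pipeline's reference settings for a 12-predictor
#' design at small n: 4000 trees, 9 candidate predictors per split, terminal
#' nodes grown to size 1. `mtry = NULL` falls back to `floor(P/3)` at fit
#' time (the standard regression-forest default), which is what the
#' selection stages use.
#'
#' @param ntree number of trees (>= 1).
#' @param mtry candidate predictors per split, or `NULL` for `floor(P/3)`.
#' @param nodesize minimal terminal node size (>= 1).
#' @param seed integer seed controlling all fit randomness.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(ntree = 4000, mtry = 9, nodesize = 1, seed = 1) {
  stopifnot(ntree >= 1, nodesize >= 1, is.null(mtry) || mtry >= 1)
  structure(list(ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 nodesize = as.integer(nodesize),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Fit a random-forest regression of log concentration
#'
#' Grows `ntree` CART regression trees on bootstrap resamples (n draws with
#' replacement, so on average about one-third of cases are out-of-bag per
#' tree), sampling `mtry` predictors without replacement at each node and
#' splitting by variance reduction down to `nodesize`. Fitting is delegated
#' to the \pkg{randomForest} ensemble engine; the fitted object additionally
#' stores the training design, response, out-of-bag predictions and the
#' (1/n) training response variance used by [pct_var_explained()]. The fit
#' is fully reproducible from `config$seed`.
#'
#' @param design data frame of numeric predictors (no id/response columns;
#'   see [design_matrix()]).
#' @param response numeric response (natural-log concentration).
#' @param config a [forest_config()].
#' @return An object of class `forest_model`.
#' @export
fit_forest <- function(design, response, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  design <- as.data.frame(design)
  if (nrow(design) < 5) stop("need at least 5 cases")
  if (length(response) != nrow(design)) stop("response length mismatch")
  if (anyNA(design) || anyNA(response))
    stop("missing values in design or response; impute or drop before fitting")
  if (!all(vapply(design, is.numeric, logical(1))))
    stop("all predictors must be numeric")
  if (stats::var(response) == 0) stop("constant response")
  p <- ncol(design)
  mtry <- if (is.null(config$mtry)) max(1L, floor(p / 3)) else config$mtry
  if (mtry > p) stop(sprintf("mtry (%d) exceeds predictor count (%d)", mtry, p))
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = design, y = response,
    ntree = config$ntree, mtry = mtry, nodesize = config$nodesize,
    importance = TRUE, keep.inbag = TRUE, keep.forest = TRUE)
  structure(
    list(rf = rf, design = design, response = response,
         config = config, mtry = mtry,
         oob_pred = unname(rf$predicted),
         sigma2 = mean((response - mean(response))^2)),
    class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf(
    "forest_model: %d trees, mtry %d, nodesize %d, n = %d, P = %d\n",
    x$config$ntree, x$mtry, x$config$nodesize,
    nrow(x$design), ncol(x$design)))
  cat(sprintf("  OOB MSE %.4f, %% variance explained %.1f\n",
              oob_mse(x), pct_var_explained(x)))
  invisible(x)
}

#' Out-of-bag mean squared error
#'
#' `(1/n) * sum_i (y_i - ybar_i^OOB)^2`, where `ybar_i^OOB` is the mean
#' prediction for case *i* over the trees in whose bootstrap sample *i* did
#' not appear.
#'
#' @param model a `forest_model`.
#' @return OOB MSE in squared log-units.
#' @export
oob_mse <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  if (anyNA(model$oob_pred) || any(!is.finite(model$oob_pred)))
    stop("some cases were never out-of-bag; increase ntree")
  mean((model$response - model$oob_pred)^2)
}

#' Percent variance explained
#'
#' `100 * (1 - MSE_oob / sigma^2(y))` with `sigma^2(y)` the 1/n-denominator
#' training response variance (matching the OOB MSE convention; at small n
#' the n/(n-1) alternative differs by under 2%). Can be negative when the
#' model is worse than the constant mean.
#'
#' @param model a `forest_model`.
#' @return Percent variance explained.
#' @export
pct_var_explained <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  if (model$sigma2 <= 0) stop("constant response")
  100 * (1 - oob_mse(model) / model$sigma2)
}

# per-tree OOB predictions for a design: n x ntree matrix + OOB mask
tree_predictions <- function(model, design) {
  pred <- predict(model$rf, design, predict.all = TRUE)$individual
  unname(pred)
}

#' Permutation variable importance
#'
#' For each predictor *p*: per tree *k*, the MSE of tree *k*'s out-of-bag
#' cases with *p*'s values randomly permuted, minus tree *k*'s unpermuted
#' OOB MSE; averaged over trees, then expressed as a percent increase
#' relative to the model's overall OOB MSE. This is the raw (not
#' sd-standardized) permutation importance; rank order, which downstream
#' variable selection consumes, agrees with the sd-scaled variant.
#'
#' @param model a `forest_model`.
#' @param seed seed for the permutations (default: derived from the fit
#'   seed).
#' @return A data frame of class `importance_table` with columns `variable`,
#'   `raw_inc_mse` and `pct_inc_mse`, ordered by descending importance.
#' @export
permutation_importance <- function(model, seed = NULL) {
  stopifnot(inherits(model, "forest_model"))
  if (is.null(seed)) seed <- derive_seed(model$config$seed, 101)
  x <- model$design; y <- model$response
  oob <- model$rf$inbag == 0                       # n x ntree
  base <- tree_predictions(model, x)
  err <- (base - y)^2
  mse_base <- colSums(err * oob) / colSums(oob)
  raw <- numeric(ncol(x))
  set.seed(seed)
  for (j in seq_len(ncol(x))) {
    xp <- x
    xp[[j]] <- x[[j]][sample.int(nrow(x))]
    errp <- (tree_predictions(model, xp) - y)^2
    mse_perm <- colSums(errp * oob) / colSums(oob)
    raw[j] <- mean(mse_perm - mse_base)
  }
  out <- data.frame(variable = colnames(x), raw_inc_mse = raw,
                    pct_inc_mse = 100 * raw / oob_mse(model),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct_inc_mse), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", class(out))
  out
}

#' @export
plot.importance_table <- function(x, ...) {
  graphics::dotchart(rev(x$pct_inc_mse), labels = rev(x$variable),
                     xlab = "% increase in OOB MSE", ...)
  invisible(x)
}

#' Tune the number of split candidates (mtry)
#'
#' Stepwise search starting from `floor(P/3)`: mtry is repeatedly divided
#' (then multiplied) by `step_factor`, and a step is accepted while the OOB
#' MSE improves by more than `improve` relative to the best so far.
#'
#' @param design,response as in [fit_forest()].
#' @param config a [forest_config()]; its `mtry` is ignored.
#' @param step_factor multiplicative step (default 2).
#' @param improve relative OOB-MSE improvement required to accept a step
#'   (default 0.05).
#' @param ntree trees per evaluation forest (default `config$ntree`).
#' @return The selected mtry (integer).
#' @export
tune_mtry <- function(design, response, config = forest_config(mtry = NULL),
                      step_factor = 2, improve = 0.05, ntree = config$ntree) {
  p <- ncol(design)
  if (p < 2) stop("need at least 2 predictors to tune mtry")
  evaluate <- function(m) {
    cfg <- forest_config(ntree = ntree, mtry = m,
                         nodesize = config$nodesize, seed = config$seed)
    oob_mse(fit_forest(design, response, cfg))
  }
  m0 <- max(1L, min(p, floor(p / 3)))
  best_m <- m0
  best_err <- evaluate(m0)
  for (dir in c(-1, 1)) {
    m <- m0
    repeat {
      m_next <- if (dir < 0) as.integer(max(1, floor(m / step_factor)))
                else as.integer(min(p, ceiling(m * step_factor)))
      if (m_next == m) break
      err <- evaluate(m_next)
      if (err < best_err * (1 - improve)) {
        best_err <- err; best_m <- m_next; m <- m_next
      } else break
      if (m_next %in% c(1L, p)) break
    }
  }
  best_m
}

#' Partial dependence of the forest on one predictor
#'
#' For each grid value v, the mean model prediction over the training design
#' with the predictor forced to v everywhere (marginal effect in the sense
#' of Friedman's partial dependence).
#'
#' @param model a `forest_model`.
#' @param predictor predictor name.
#' @param grid_values values at which to evaluate; defaults to 25 quantiles
#'   of the training values.
#' @return Data frame with columns `value` and `yhat` (log scale).
#' @export
partial_dependence <- function(model, predictor, grid_values = NULL) {
  stopifnot(inherits(model, "forest_model"))
  if (!predictor %in% colnames(model$design))
    stop("unknown predictor: ", predictor)
  if (is.null(grid_values))
    grid_values <- unname(sort(unique(
      quantile(model$design[[predictor]], probs = seq(0, 1, length.out = 25),
               type = 7))))
  yhat <- vapply(grid_values, function(v) {
    x <- model$design
    x[[predictor]] <- v
    mean(predict(model$rf, x))
  }, numeric(1))
  data.frame(value = grid_values, yhat = yhat)
}

#' Predict from a fitted forest
#'
#' Mean over all trees. New data must carry exactly the training predictor
#' columns (an `id` column and a `log_tcs` column, if present, are dropped
#' before checking).
#'
#' @param object a `forest_model`.
#' @param newdata data frame of predictors.
#' @param type `"log"` (default) for log-scale predictions or `"response"`
#'   for the exponential back-transform to ng/g (no bias correction:
#'   downstream discretization is rank-based on the log scale).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.forest_model <- function(object, newdata,
                                 type = c("log", "response"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  newdata <- newdata[setdiff(names(newdata), c("id", "log_tcs"))]
  want <- colnames(object$design)
  missing_cols <- setdiff(want, names(newdata))
  extra_cols <- setdiff(names(newdata), want)
  if (length(missing_cols) || length(extra_cols))
    stop("prediction schema mismatch; missing: [",
         paste(missing_cols, collapse = ", "), "], extra: [",
         paste(extra_cols, collapse = ", "), "]")
  p <- unname(predict(object$rf, newdata[want]))
  if (type == "response") exp(p) else p
}
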