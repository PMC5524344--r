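#' Quantile discretization schemes
#'
#' Named low/medium/high threshold schemes on the prediction distribution:
#' scheme A is the tercile split (one third of predictions in each class),
#' scheme B puts 25% in the low and high classes with 50% lumped in the
#' medium class, and scheme C restricts the tails further to 12.5% each.
#'
#' @param name `"A"`, `"B"` or `"C"`; or `"custom"` with explicit
#'   probabilities.
#' @param lower_q,upper_q custom quantile probabilities
#'   (0 < lower < upper < 1).
#' @return An object of class `quantile_scheme`.
#' @export
quantile_scheme <- function(name = c("A", "B", "C", "custom"),
                            lower_q = NULL, upper_q = NULL) {
  name <- match.arg(name)
  probs <- switch(name,
                  A = c(1 / 3, 2 / 3),
                  B = c(0.25, 0.75),
                  C = c(0.125, 0.875),
                  custom = c(lower_q, upper_q))
  if (length(probs) != 2 || !(0 < probs[1] && probs[1] < probs[2] &&
                              probs[2] < 1))
    stop("need 0 < lower_q < upper_q < 1")
  structure(list(name = name, lower_q = probs[1], upper_q = probs[2]),
            class = "quantile_scheme")
}

#' Classify predictions into low/medium/high contamination classes
#'
#' Thresholds are the empirical quantiles (type-7 linear interpolation) of
#' the prediction set at the scheme's probabilities. A value strictly below
#' the lower threshold is `low`, strictly above the upper threshold is
#' `high`, and `medium` otherwise — so ties straddling a threshold all fall
#' to `medium`, which is conservative for hotspot calling. Classification is
#' rank-based, hence invariant to any strictly monotone transform of the
#' predictions (log or raw scale give identical classes).
#'
#' @param predictions numeric predictions (log scale by convention).
#' @param scheme a [quantile_scheme()] or a scheme name.
#' @param ids optional point ids.
#' @return An object of class `hotspot_classification`: a list with
#'   `table` (id, pred_log, class), `scheme` and `thresholds`.
#' @export
classify_hotspots <- function(predictions, scheme = "A", ids = NULL) {
  if (is.character(scheme)) scheme <- quantile_scheme(scheme)
  stopifnot(inherits(scheme, "quantile_scheme"))
  n <- length(predictions)
  if (n < 3) stop("need at least 3 predictions to discretize")
  if (is.null(ids)) ids <- seq_len(n)
  thr <- quantile(predictions, probs = c(scheme$lower_q, scheme$upper_q),
                  type = 7, names = FALSE)
  if (length(unique(predictions)) == 1) {
    warning("all predictions identical; every point classed medium")
    cls <- rep("medium", n)
  } else {
    cls <- ifelse(predictions < thr[1], "low",
                  ifelse(predictions > thr[2], "high", "medium"))
  }
  structure(
    list(table = data.frame(id = ids, pred_log = predictions,
                            class = factor(cls, levels = c("low", "medium",
                                                           "high")),
                            stringsAsFactors = FALSE),
         scheme = scheme, thresholds = thr),
    class = "hotspot_classification")
}

#' @export
print.hotspot_classification <- function(x, ...) {
  cat(sprintf("hotspot_classification (scheme %s): thresholds %.3f / %.3f\n",
              x$scheme$name, x$thresholds[1], x$thresholds[2]))
  print(table(x$table$class))
  invisible(x)
}

#' Per-class summary of a classification
#'
#' Counts, fractions and back-transformed concentration ranges (ng/g) per
#' class.
#'
#' @param classification a `hotspot_classification`.
#' @return Data frame with one row per class (low, medium, high): `class`,
#'   `count`, `fraction`, `min_ngg`, `max_ngg`.
#' @export
class_summary <- function(classification) {
  stopifnot(inherits(classification, "hotspot_classification"))
  tb <- classification$table
  out <- do.call(rbind, lapply(levels(tb$class), function(cl) {
    v <- tb$pred_log[tb$class == cl]
    data.frame(class = cl, count = length(v),
               fraction = length(v) / nrow(tb),
               min_ngg = if (length(v)) exp(min(v)) else NA_real_,
               max_ngg = if (length(v)) exp(max(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Combined classification table across schemes A, B and C
#'
#' @param predictions log-scale predictions.
#' @param ids,easting,northing point metadata.
#' @param schemes scheme names (default A, B, C).
#' @return Data frame `id,easting,northing,pred_log,pred_ngg,class_A,...`.
#' @export
classification_table <- function(predictions, ids, easting, northing,
                                 schemes = c("A", "B", "C")) {
  out <- data.frame(id = ids, easting = easting, northing = northing,
                    pred_log = predictions, pred_ngg = exp(predictions),
                    stringsAsFactors = FALSE)
  for (s in schemes)
    out[[paste0("class_", s)]] <-
      as.character(classify_hotspots(predictions, s, ids)$table$class)
  out
}

#' Write a classification table as GeoJSON points
#'
#' @param ct a data frame from [classification_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_classification_geojson <- function(ct, path) {
  feats <- lapply(seq_len(nrow(ct)), function(i) {
    props <- as.list(ct[i, setdiff(names(ct), c("easting", "northing"))])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(ct$easting[i], ct$northing[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
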