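#' CSO distance summary at a sample location
#'
#' Raw minimum, maximum and mean accumulated cost-distance (m) from a sample
#' location to the direct combined-sewer-overflow outfalls. CSO distances are
#' deliberately neither inverted nor rescaled: no discharge-volume
#' information is assumed for CSOs.
#'
#' @param easting,northing sample coordinates.
#' @param surfaces list of `cost_surface` objects, one per direct CSO.
#' @param id sample id used in error messages.
#' @return Named numeric vector `c(cso_min, cso_max, cso_avg)` in metres.
#' @export
cso_distance_summary <- function(easting, northing, surfaces, id = "<sample>") {
  if (!length(surfaces)) stop("no CSO cost surfaces supplied")
  d <- vapply(surfaces, extract_cost, numeric(1),
              easting = easting, northing = northing)
  reach <- is.finite(d)
  if (!any(reach))
    stop(sprintf("sample '%s' is unreachable from every CSO outfall", id))
  if (!all(reach)) {
    warning(sprintf("sample '%s': %d CSO outfall(s) unreachable, excluded",
                    id, sum(!reach)))
    d <- d[reach]
  }
  c(cso_min = min(d), cso_max = max(d), cso_avg = mean(d))
}

# min-max normalize to [0, 1]; a degenerate spread maps everything to 1
# (the upper rescale bound), so a lone source or tied values take the
# maximal weight rather than an undefined one.
minmax01 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(1, length(x)))
  (x - r[1]) / diff(r)
}

#' Discharge-weighted WWTP proximity scores at a sample location
#'
#' For each wastewater treatment plant *j* at distance `d_j` (accumulated
#' cost, m) with permitted discharge volume `V_j`, the inverse distance
#' `1/d_j` and the volume `V_j` are each min-max normalized among the WWTPs
#' and affinely rescaled to `[1, 2]`; the plant's score is their product,
#' spanning `[1, 4]`. Scores *increase* as a plant gets nearer and larger:
#' the nearest, highest-volume plant attains 4; the farthest, lowest-volume
#' plant attains 1. The summary returned is the min/max/mean over plants.
#'
#' The alternative reading in which the *product* of the two normalized
#' factors is rescaled to `[1, 2]` is available as `variant = "product"`.
#' Both variants are monotone transforms of each other plant-wise at a fixed
#' location, so rank-based tree models are unaffected by the choice.
#'
#' @param easting,northing sample coordinates.
#' @param surfaces list of `cost_surface` objects, one per WWTP.
#' @param volumes numeric vector of permitted discharge volumes (volume/day),
#'   one per surface, all present.
#' @param variant `"factors"` (default, each factor to `[1,2]`, product in
#'   `[1,4]`) or `"product"` (normalized product rescaled to `[1,2]`).
#' @param id sample id used in error messages.
#' @return Named numeric vector `c(wwtp_min, wwtp_max, wwtp_avg)`.
#' @export
wwtp_weighted_summary <- function(easting, northing, surfaces, volumes,
                                  variant = c("factors", "product"),
                                  id = "<sample>") {
  variant <- match.arg(variant)
  if (!length(surfaces)) stop("no WWTP cost surfaces supplied")
  if (length(volumes) != length(surfaces) || any(is.na(volumes)))
    stop("a discharge volume is required for every WWTP")
  d <- vapply(surfaces, extract_cost, numeric(1),
              easting = easting, northing = northing)
  if (!any(is.finite(d)))
    stop(sprintf("sample '%s' is unreachable from every WWTP", id))
  if (!all(is.finite(d))) {
    warning(sprintf("sample '%s': %d WWTP(s) unreachable, excluded",
                    id, sum(!is.finite(d))))
    volumes <- volumes[is.finite(d)]
    d <- d[is.finite(d)]
  }
  # a sample inside the source cell has d = 0; it cannot be nearer than
  # within the cell, so floor at half a cell before inverting
  d <- pmax(d, surfaces[[1]]$grid$cell_size / 2)
  u <- minmax01(1 / d)
  v <- minmax01(volumes)
  s <- if (variant == "factors") (1 + u) * (1 + v) else 1 + minmax01(u * v)
  c(wwtp_min = min(s), wwtp_max = max(s), wwtp_avg = mean(s))
}

#' Assemble the random-forest design table
#'
#' One row per sediment sample: the sediment covariates, the raw CSO
#' cost-distance summaries, the discharge-weighted WWTP proximity summaries,
#' and the planar coordinates; plus `log_tcs`, the natural log of the
#' measured concentration, when concentrations are present. Column order is
#' fixed (see [write_design_csv()]).
#'
#' @param samples data frame with columns `id`, `easting`, `northing`, `toc`,
#'   `sand`, `mud`, `depth`, and optionally `tcs` (ng/g dry sediment, > 0).
#' @param cso_surfaces list of `cost_surface` for the direct CSO outfalls.
#' @param wwtp_surfaces list of `cost_surface` for the WWTPs.
#' @param volumes permitted discharge volumes, one per WWTP surface.
#' @param wwtp_variant passed to [wwtp_weighted_summary()].
#' @return A data frame (the design table).
#' @export
assemble_design <- function(samples, cso_surfaces, wwtp_surfaces, volumes,
                            wwtp_variant = "factors") {
  need <- c("id", "easting", "northing", "toc", "sand", "mud", "depth")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing sample columns: ", paste(miss, collapse = ", "))
  for (v in c("toc", "sand", "mud"))
    if (any(samples[[v]] < 0 | samples[[v]] > 100))
      stop(sprintf("'%s' must lie in [0, 100] %%", v))
  has_tcs <- "tcs" %in% names(samples) && !all(is.na(samples$tcs))
  if (has_tcs && any(samples$tcs <= 0))
    stop("non-positive concentration: log transform undefined")
  n <- nrow(samples)
  cso <- matrix(NA_real_, n, 3)
  wwtp <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    cso[i, ] <- cso_distance_summary(samples$easting[i], samples$northing[i],
                                     cso_surfaces, id = samples$id[i])
    wwtp[i, ] <- wwtp_weighted_summary(samples$easting[i], samples$northing[i],
                                       wwtp_surfaces, volumes,
                                       variant = wwtp_variant,
                                       id = samples$id[i])
  }
  out <- data.frame(
    id = samples$id,
    toc = samples$toc, sand = samples$sand, mud = samples$mud,
    depth = samples$depth,
    cso_min = cso[, 1], cso_max = cso[, 2], cso_avg = cso[, 3],
    wwtp_min = wwtp[, 1], wwtp_max = wwtp[, 2], wwtp_avg = wwtp[, 3],
    northing = samples$northing, easting = samples$easting,
    stringsAsFactors = FALSE)
  if (has_tcs) out$log_tcs <- log(samples$tcs)
  out
}

#' Split a design table into predictor matrix and response
#'
#' @param design a design table from [assemble_design()] or
#'   [read_design_csv()].
#' @return List with `x` (data frame of the 12 predictors) and `y` (the
#'   log-concentration response, or `NULL` when absent).
#' @export
design_matrix <- function(design) {
  x <- design[setdiff(design_columns(FALSE), "id")]
  y <- if ("log_tcs" %in% names(design)) design$log_tcs else NULL
  list(x = x, y = y)
}
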