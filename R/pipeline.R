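# timestamped, stage-tagged log line
log_stage <- function(stage, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Validate pipeline input tables against the grid
#'
#' Schema, bounds and plausibility checks on a sample table (and optionally
#' sources) before any modelling. Issues are returned, not thrown, and are
#' split into errors (which [run_pipeline()] refuses to proceed past) and
#' warnings.
#'
#' @param samples sample data frame.
#' @param grid optional [estuary_grid()] for coordinate-range checks.
#' @param sources optional sources data frame.
#' @param require_response demand a usable `tcs` column.
#' @return Data frame with columns `severity` (`"error"`/`"warning"`) and
#'   `message`; zero rows when everything passes.
#' @export
validate_inputs <- function(samples, grid = NULL, sources = NULL,
                            require_response = FALSE) {
  issues <- data.frame(severity = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  add <- function(sev, msg) {
    issues[nrow(issues) + 1L, ] <<- list(sev, msg)
  }
  need <- c("id", "easting", "northing", "toc", "sand", "mud", "depth")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    add("error", paste("missing sample columns:", paste(miss, collapse = ", ")))
    return(issues)
  }
  for (v in c("toc", "sand", "mud")) {
    bad <- which(samples[[v]] < 0 | samples[[v]] > 100)
    if (length(bad))
      add("error", sprintf("'%s' outside [0, 100]%% for row(s) %s", v,
                           paste(head(bad, 5), collapse = ", ")))
  }
  over <- which(samples$sand + samples$mud > 100 + 1e-6)
  if (length(over))
    add("warning", sprintf("sand + mud > 100%% for row(s) %s",
                           paste(head(over, 5), collapse = ", ")))
  if ("tcs" %in% names(samples)) {
    bad <- which(!is.na(samples$tcs) & samples$tcs <= 0)
    if (length(bad))
      add("error", sprintf("non-positive concentration for row(s) %s",
                           paste(head(bad, 5), collapse = ", ")))
  } else if (require_response) {
    add("error", "no `tcs` response column in sample table")
  }
  if (!is.null(grid)) {
    xmax <- grid$xll + grid$n_cols * grid$cell_size
    ymax <- grid$yll + grid$n_rows * grid$cell_size
    out <- which(samples$easting < grid$xll | samples$easting > xmax |
                 samples$northing < grid$yll | samples$northing > ymax)
    if (length(out))
      add("error", sprintf("sample(s) outside raster bounds: row(s) %s",
                           paste(head(out, 5), collapse = ", ")))
  }
  if (!is.null(sources)) {
    res <- try(source_points(as.data.frame(sources)), silent = TRUE)
    if (inherits(res, "try-error"))
      add("error", paste("source table:",
                         attr(res, "condition")$message))
  }
  issues
}

#' Run the full analysis pipeline
#'
#' Orchestrates cost surfaces, feature assembly, optional mtry tuning, the
#' full-model forest fit, three-step variable selection, the parsimonious
#' refit, prediction and quantile discretization, writing artifacts and a
#' machine-readable run summary to `out_dir`. Identical `config` and seed
#' yield an identical summary. The single `seed` is fanned out to fixed
#' per-stage seeds so stages are individually reproducible.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{seed}{integer, required.}
#'     \item{simulate}{optional list of [generator_config()] overrides; when
#'       present the inputs are simulated.}
#'     \item{inputs}{otherwise, paths: `grid` (Esri ASCII water mask),
#'       `sources` (CSV/GeoJSON), `samples` (CSV), optional
#'       `prediction_samples` (CSV of points without concentrations).}
#'     \item{forest}{`ntree`, `mtry` (`NULL`/"tune" to tune), `nodesize`.}
#'     \item{selection}{`n_forests`, `n_rep`, `ntree`.}
#'     \item{schemes}{quantile schemes, default `c("A","B","C")`.}
#'     \item{wwtp_variant}{`"factors"` (default) or `"product"`.}
#'     \item{write_surfaces}{write per-source cost surfaces (default TRUE).}
#'   }
#' @param out_dir output directory.
#' @return The run summary (a list), invisibly; also written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config, out_dir = "estuaryRF-run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must supply a seed")
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schemes <- config$schemes %||% c("A", "B", "C")
  wwtp_variant <- config$wwtp_variant %||% "factors"
  fcfg <- config$forest %||% list()
  scfg <- config$selection %||% list()

  # ---- inputs -------------------------------------------------------------
  pred_samples <- NULL
  if (!is.null(config$simulate)) {
    log_stage("inputs", "simulating synthetic estuary")
    inp <- run_stage("inputs", {
      gcfg <- do.call(generator_config,
                      c(list(seed = seed), config$simulate))
      est <- generate_estuary(gcfg)
      fields <- generate_fields(est$grid, gcfg)
      samples <- generate_samples(est$grid, est$sources, fields, gcfg)
      list(grid = est$grid, sources = est$sources, samples = samples)
    })
  } else {
    log_stage("inputs", "reading inputs")
    inp <- run_stage("inputs", {
      paths <- config$inputs
      if (is.null(paths)) stop("config needs either `simulate` or `inputs`")
      g <- read_estuary_grid(paths$grid)
      s <- read_sources(paths$sources)
      smp <- read.csv(paths$samples, stringsAsFactors = FALSE)
      if (!is.null(paths$prediction_samples))
        pred_samples <- read.csv(paths$prediction_samples,
                                 stringsAsFactors = FALSE)
      list(grid = g, sources = s, samples = smp)
    })
  }
  issues <- validate_inputs(inp$samples, inp$grid, inp$sources,
                            require_response = TRUE)
  for (i in seq_len(nrow(issues)))
    log_stage("validate", issues$severity[i], ": ", issues$message[i])
  if (any(issues$severity == "error"))
    stop("pipeline stage 'validate' failed: ",
         paste(issues$message[issues$severity == "error"], collapse = "; "))

  # ---- cost surfaces ------------------------------------------------------
  log_stage("cost", "computing accumulated cost surfaces")
  surf <- run_stage("cost", {
    cso <- inp$sources[inp$sources$kind == "CSO" & inp$sources$direct, ,
                       drop = FALSE]
    wwtp <- inp$sources[inp$sources$kind == "WWTP", , drop = FALSE]
    if (!nrow(cso)) stop("no direct CSO sources")
    if (!nrow(wwtp)) stop("no WWTP sources")
    if (any(is.na(wwtp$discharge_volume)))
      stop("WWTP sources need discharge volumes")
    list(cso = cost_surfaces(inp$grid, cso),
         wwtp = cost_surfaces(inp$grid, wwtp),
         volumes = wwtp$discharge_volume)
  })
  if (isTRUE(config$write_surfaces %||% TRUE)) {
    for (s in c(surf$cso, surf$wwtp))
      write_esri_ascii(s, file.path(out_dir,
                                    paste0("cost_", s$source_id, ".asc")))
  }

  # ---- features -----------------------------------------------------------
  log_stage("features", "assembling design table")
  design <- run_stage("features", {
    d <- assemble_design(inp$samples, surf$cso, surf$wwtp, surf$volumes,
                         wwtp_variant = wwtp_variant)
    write_design_csv(d, file.path(out_dir, "design.csv"))
    d
  })
  dm <- design_matrix(design)

  # ---- tune ---------------------------------------------------------------
  mtry <- fcfg$mtry %||% 9
  ntree <- fcfg$ntree %||% 4000
  nodesize <- fcfg$nodesize %||% 1
  if (identical(mtry, "tune")) {
    log_stage("tune", "tuning mtry")
    mtry <- run_stage("tune", tune_mtry(
      dm$x, dm$y, forest_config(ntree = ntree, mtry = NULL,
                                nodesize = nodesize,
                                seed = derive_seed(seed, 11)),
      ntree = min(ntree, 1000)))
    log_stage("tune", "selected mtry = ", mtry)
  }

  # ---- fit full model -----------------------------------------------------
  log_stage("fit", "fitting full forest")
  full <- run_stage("fit", fit_forest(
    dm$x, dm$y, forest_config(ntree = ntree, mtry = mtry,
                              nodesize = nodesize,
                              seed = derive_seed(seed, 12))))
  imp <- permutation_importance(full)
  write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)
  write_forest_dump(full, file.path(out_dir, "forest_full.jsonl"))

  # ---- variable selection -------------------------------------------------
  log_stage("select", "three-step variable selection")
  sel <- run_stage("select", var_select(
    dm$x, dm$y,
    forest_config(ntree = ntree, mtry = NULL, nodesize = nodesize,
                  seed = derive_seed(seed, 13)),
    n_forests = scfg$n_forests %||% 25,
    n_rep = scfg$n_rep %||% 10,
    ntree = scfg$ntree %||% 1000))
  write_selection_report(sel, out_dir)

  # ---- parsimonious refit -------------------------------------------------
  log_stage("refit", "refitting prediction model: ",
            paste(sel$prediction_set, collapse = ", "))
  pred_model <- run_stage("refit", {
    vars <- if (length(sel$prediction_set)) sel$prediction_set
            else colnames(dm$x)
    fit_forest(dm$x[vars], dm$y,
               forest_config(ntree = ntree,
                             mtry = min(length(vars),
                                        max(1L, floor(length(vars) / 3))),
                             nodesize = nodesize,
                             seed = derive_seed(seed, 14)))
  })

  # ---- predict ------------------------------------------------------------
  log_stage("predict", "predicting")
  pred <- run_stage("predict", {
    if (!is.null(pred_samples)) {
      pd <- assemble_design(pred_samples, surf$cso, surf$wwtp, surf$volumes,
                            wwtp_variant = wwtp_variant)
      list(ids = pd$id, easting = pd$easting, northing = pd$northing,
           log = predict(pred_model, pd[colnames(pred_model$design)]))
    } else {
      list(ids = design$id, easting = design$easting,
           northing = design$northing,
           log = predict(pred_model, dm$x[colnames(pred_model$design)]))
    }
  })

  # ---- discretize ---------------------------------------------------------
  log_stage("classify", "quantile discretization: ",
            paste(schemes, collapse = ", "))
  ct <- run_stage("classify", {
    ct <- classification_table(pred$log, pred$ids, pred$easting,
                               pred$northing, schemes = schemes)
    write.csv(ct, file.path(out_dir, "classification.csv"),
              row.names = FALSE)
    ct
  })
  class_counts <- lapply(setNames(schemes, schemes), function(s)
    as.list(table(ct[[paste0("class_", s)]])[c("low", "medium", "high")]))

  summary <- list(
    seed = seed,
    config = config,
    n = nrow(design),
    mtry = mtry,
    pct_var_explained_full = pct_var_explained(full),
    oob_mse_full = oob_mse(full),
    importance = setNames(imp$pct_inc_mse, imp$variable),
    selected = list(ranked = sel$ranked_vars,
                    retained = sel$retained_threshold,
                    interpretation = sel$interpretation_set,
                    prediction = sel$prediction_set),
    pct_var_explained_prediction = pct_var_explained(pred_model),
    oob_mse_prediction = oob_mse(pred_model),
    class_counts = class_counts)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", "summary written to ", file.path(out_dir, "summary.json"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
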