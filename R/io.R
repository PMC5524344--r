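#' Read an Esri ASCII grid
#'
#' Minimal reader for the Esri ASCII raster interchange format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed by
#' rows of values, northernmost row first).
#'
#' @param path file path.
#' @return A list with `values` (numeric matrix, row 1 = north), `xll`, `yll`,
#'   `cell_size`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("malformed Esri ASCII header: missing ", k)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("Esri ASCII body has wrong number of values")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cell_size = hdr$cellsize, nodata = hdr$nodata_value)
}

#' Write an Esri ASCII grid
#'
#' @param values numeric matrix (row 1 = north) or an [estuary_grid()] (whose
#'   water mask is written as 1 with land as NODATA) or a `cost_surface`
#'   (land and unreachable cells written as NODATA).
#' @param path file path.
#' @param xll,yll,cell_size georeferencing, taken from the object when it
#'   carries them.
#' @param nodata NODATA sentinel value written for `NA`/non-finite cells.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(values, path, xll = 0, yll = 0, cell_size = 1,
                             nodata = -9999) {
  if (inherits(values, "estuary_grid")) {
    g <- values
    m <- matrix(NA_real_, g$n_rows, g$n_cols)
    m[g$water] <- 1
    xll <- g$xll; yll <- g$yll; cell_size <- g$cell_size
  } else if (inherits(values, "cost_surface")) {
    g <- values$grid
    m <- values$cost
    xll <- g$xll; yll <- g$yll; cell_size <- g$cell_size
  } else m <- values
  m[!is.finite(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)), con)
  write.table(format(m, trim = TRUE, scientific = FALSE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an estuary grid from an Esri ASCII water mask
#'
#' Cells with a finite, non-zero value are water; NODATA (and zero) cells are
#' land.
#'
#' @param path Esri ASCII file.
#' @return An [estuary_grid()].
#' @export
read_estuary_grid <- function(path) {
  r <- read_esri_ascii(path)
  water <- !is.na(r$values) & r$values != 0
  estuary_grid(water, r$cell_size, xll = r$xll, yll = r$yll)
}

#' Read point sources from CSV or GeoJSON
#'
#' CSV files must carry columns `id,kind,easting,northing` and optionally
#' `discharge_volume,direct`. GeoJSON point features use the same names as
#' feature properties, with coordinates taken from the geometry.
#'
#' @param path file path (`.csv`, `.json` or `.geojson`).
#' @return A [source_points()] data frame.
#' @export
read_sources <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else if (ext %in% c("json", "geojson")) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    feats <- gj$features
    df <- do.call(rbind, lapply(feats, function(f) {
      p <- f$properties
      data.frame(
        id = p$id, kind = p$kind,
        easting = f$geometry$coordinates[[1]],
        northing = f$geometry$coordinates[[2]],
        discharge_volume = if (is.null(p$discharge_volume)) NA_real_
                           else as.numeric(p$discharge_volume),
        direct = if (is.null(p$direct)) TRUE else isTRUE(p$direct),
        stringsAsFactors = FALSE)
    }))
  } else stop("unsupported source file type: ", ext)
  source_points(df)
}

# canonical design-table column order
design_columns <- function(with_response = TRUE) {
  c("id", "toc", "sand", "mud", "depth",
    "cso_min", "cso_max", "cso_avg",
    "wwtp_min", "wwtp_max", "wwtp_avg",
    "northing", "easting", if (with_response) "log_tcs")
}

#' Write / read a design table CSV
#'
#' The on-disk header is fixed to
#' `id,toc,sand,mud,depth,cso_min,cso_max,cso_avg,wwtp_min,wwtp_max,wwtp_avg,northing,easting[,log_tcs]`.
#' Doubles are written at full precision (`%.17g`) so a write/read round
#' trip reproduces the table bit-identically.
#'
#' @param design a design table from [assemble_design()].
#' @param path file path.
#' @return `path` invisibly (`write_design_csv`); the design data frame
#'   (`read_design_csv`).
#' @export
write_design_csv <- function(design, path) {
  cols <- design_columns(with_response = "log_tcs" %in% names(design))
  stopifnot(all(cols %in% names(design)))
  out <- design[cols]
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param column_map optional named character vector mapping on-disk column
#'   names to canonical names (e.g. `c(TOC = "toc", CSO_min = "cso_min")`),
#'   for supplementary-style tables whose headers differ.
#' @export
read_design_csv <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  cols <- design_columns(with_response = "log_tcs" %in% names(df))
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("design table missing columns: ",
                         paste(miss, collapse = ", "))
  df[cols]
}

#' Dump a fitted forest as JSON lines
#'
#' Writes one JSON object per tree: arrays of split variable (0 for leaves),
#' split threshold, left/right child indices (0 for leaves) and node
#' prediction, in the node ordering used by the underlying ensemble. The dump
#' is for inspection and cross-language reloading, not for refitting.
#'
#' @param model a `forest_model` from [fit_forest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_forest_dump <- function(model, path) {
  stopifnot(inherits(model, "forest_model"))
  con <- file(path, "w")
  on.exit(close(con))
  vars <- colnames(model$design)
  for (k in seq_len(model$config$ntree)) {
    tr <- randomForest::getTree(model$rf, k = k, labelVar = FALSE)
    obj <- list(tree = k,
                split_var = vars[ifelse(tr[, "split var"] > 0,
                                        tr[, "split var"], NA)],
                split_point = unname(tr[, "split point"]),
                left = unname(tr[, "left daughter"]),
                right = unname(tr[, "right daughter"]),
                prediction = unname(tr[, "prediction"]))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}
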