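#' Rasterized estuary domain
#'
#' An `estuary_grid` is the spatial substrate for all cost-distance work: a
#' regular planar lattice (UTM-like coordinates, metres) in which each cell is
#' either traversable water or impenetrable land. Row 1 is the northern edge;
#' columns increase eastward. Georeferencing follows the Esri ASCII grid
#' convention of a lower-left corner origin.
#'
#' @param water logical matrix, `TRUE` for water cells (row 1 = north edge).
#' @param cell_size cell edge length in metres (> 0).
#' @param xll,yll easting/northing of the lower-left corner of the grid.
#' @return An object of class `estuary_grid`.
#' @seealso [rasterize_domain()], [accumulate_cost()]
#' @export
estuary_grid <- function(water, cell_size, xll = 0, yll = 0) {
  if (!is.matrix(water) || !is.logical(water))
    stop("`water` must be a logical matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (!any(water)) stop("domain contains no water cells")
  structure(
    list(n_rows = nrow(water), n_cols = ncol(water),
         cell_size = cell_size, xll = xll, yll = yll, water = water),
    class = "estuary_grid"
  )
}

#' @export
print.estuary_grid <- function(x, ...) {
  cat(sprintf("estuary_grid: %d x %d cells of %g m (%d water, %d land)\n",
              x$n_rows, x$n_cols, x$cell_size, sum(x$water), sum(!x$water)))
  invisible(x)
}

#' Rasterize a water region onto a regular grid
#'
#' Builds an [estuary_grid()] covering the bounding box of a water region.
#' A cell is water iff its *centre* lies inside the region (point-in-polygon
#' test on cell centres). The region may be given either as a polygon (or a
#' set of loops) or directly as a logical mask.
#'
#' @param region either a two-column matrix/data.frame of polygon vertices
#'   (easting, northing; several loops may be separated by `NA` rows, e.g. two
#'   disjoint water bodies), or a logical matrix used as the water mask
#'   directly.
#' @param cell_size cell edge length in metres.
#' @param xll,yll grid origin when `region` is a mask; ignored for polygons
#'   (the snapped bounding box is used).
#' @return An `estuary_grid`.
#' @export
rasterize_domain <- function(region, cell_size, xll = 0, yll = 0) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (is.logical(region) && is.matrix(region))
    return(estuary_grid(region, cell_size, xll, yll))
  region <- as.matrix(region)
  if (ncol(region) != 2) stop("polygon must have two columns (easting, northing)")
  ok <- stats::complete.cases(region)
  if (!any(ok)) stop("empty water region")
  xr <- range(region[ok, 1]); yr <- range(region[ok, 2])
  if (diff(xr) <= 0 || diff(yr) <= 0) stop("empty water region")
  n_cols <- max(1L, ceiling((xr[2] - xr[1]) / cell_size - 1e-9))
  n_rows <- max(1L, ceiling((yr[2] - yr[1]) / cell_size - 1e-9))
  cx <- xr[1] + (seq_len(n_cols) - 0.5) * cell_size
  cy <- yr[1] + (n_rows - seq_len(n_rows) + 0.5) * cell_size  # row 1 = north
  centers <- cbind(rep(cx, each = n_rows), rep(cy, times = n_cols))
  inside <- mgcv::in.out(region, centers)
  water <- matrix(inside, nrow = n_rows, ncol = n_cols)
  if (!any(water)) stop("empty water region: no cell centre falls in the polygon")
  estuary_grid(water, cell_size, xll = xr[1], yll = yr[1])
}

# point -> (row, col); boundary points on the outer north/east edge are
# clamped into the adjacent cell so that grid corners are usable.
point_to_cell <- function(grid, easting, northing) {
  col <- floor((easting - grid$xll) / grid$cell_size) + 1
  row_s <- floor((northing - grid$yll) / grid$cell_size) + 1  # from south
  col[easting == grid$xll + grid$n_cols * grid$cell_size] <- grid$n_cols
  row_s[northing == grid$yll + grid$n_rows * grid$cell_size] <- grid$n_rows
  row <- grid$n_rows - row_s + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  if (any(bad))
    stop(sprintf("%d point(s) fall outside the grid bounds", sum(bad)))
  cbind(row = row, col = col)
}

cell_center <- function(grid, row, col) {
  cbind(easting  = grid$xll + (col - 0.5) * grid$cell_size,
        northing = grid$yll + (grid$n_rows - row + 0.5) * grid$cell_size)
}

#' Point-source table constructor/validator
#'
#' Validates a data frame of discharge locations (WWTP and CSO outfalls).
#' Required columns: `id`, `kind` (`"WWTP"` or `"CSO"`), `easting`,
#' `northing`; optional: `discharge_volume` (volume/day; required downstream
#' for WWTP weighting), `direct` (logical, defaults to `TRUE`).
#'
#' @param df data frame of sources.
#' @return The validated data frame with class `source_points` prepended.
#' @export
source_points <- function(df) {
  need <- c("id", "kind", "easting", "northing")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing source columns: ", paste(miss, collapse = ", "))
  if (!all(df$kind %in% c("WWTP", "CSO")))
    stop('source `kind` must be "WWTP" or "CSO"')
  if (anyDuplicated(df$id)) stop("source ids must be unique")
  if (is.null(df$discharge_volume)) df$discharge_volume <- NA_real_
  if (is.null(df$direct)) df$direct <- TRUE
  if (any(!is.na(df$discharge_volume) & df$discharge_volume < 0))
    stop("discharge_volume must be >= 0")
  class(df) <- c("source_points", class(df))
  df
}

# Neighbourhood offsets and geometric distance factors. 8 = rook + diagonal;
# 16 additionally allows knight's moves (factor sqrt(5)).
neighborhood_offsets <- function(neighborhood) {
  rook <- cbind(dr = c(0, 1), dc = c(1, 0), f = 1)
  diag <- cbind(dr = c(1, 1), dc = c(1, -1), f = sqrt(2))
  if (neighborhood == 8) return(rbind(rook, diag))
  if (neighborhood == 16) {
    knight <- cbind(dr = c(1, 1, 2, 2), dc = c(2, -2, 1, -1), f = sqrt(5))
    return(rbind(rook, diag, knight))
  }
  stop("`neighborhood` must be 8 or 16")
}

# Weighted adjacency graph over water cells. Vertex i corresponds to the
# i-th water cell in column-major order; edge weight = mean of the two cell
# traversal costs (cell_size each) times the geometric factor.
water_graph <- function(grid, neighborhood = 8) {
  offs <- neighborhood_offsets(neighborhood)
  nr <- grid$n_rows; nc <- grid$n_cols
  vid <- matrix(NA_integer_, nr, nc)
  vid[grid$water] <- seq_len(sum(grid$water))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, "dr"]; dc <- offs[k, "dc"]; f <- offs[k, "f"]
    if (max(1, 1 - dr) > min(nr, nr - dr) ||
        max(1, 1 - dc) > min(nc, nc - dc)) next
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- vid[r1, c1, drop = FALSE]
    b <- vid[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      from <- c(from, a[ok]); to <- c(to, b[ok])
      w <- c(w, rep(grid$cell_size * f, sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = sum(grid$water), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  list(graph = g, vid = vid)
}

# Snap a point to the nearest water cell within `tol` cells (Euclidean, in
# cell units). Errors (naming `id`) when no water cell is close enough.
snap_to_water <- function(grid, easting, northing, id = "<point>", tol = 5) {
  rc <- point_to_cell(grid, easting, northing)
  if (grid$water[rc[1, "row"], rc[1, "col"]]) return(rc)
  wc <- which(grid$water, arr.ind = TRUE)
  d2 <- (wc[, 1] - rc[1, "row"])^2 + (wc[, 2] - rc[1, "col"])^2
  j <- which.min(d2)
  if (d2[j] > tol^2)
    stop(sprintf("source '%s' does not snap to a water cell within %g cells", id, tol))
  cbind(row = wc[j, 1], col = wc[j, 2])
}

#' Accumulated least-cost distance surfaces from point sources
#'
#' Computes, for each source, the accumulated cost ("effective distance", m)
#' of the least-cost path through water from the source outfall to every
#' water cell, with land acting as an impenetrable barrier. Each cell carries
#' a traversal cost equal to its edge length (15 m at the default
#' resolution); the cost of moving between adjacent cells is the mean of the
#' two cell costs times the geometric distance factor (1 for rook moves,
#' sqrt(2) for diagonal moves, sqrt(5) for knight's moves under the
#' 16-neighbourhood). Sources on land are snapped to the nearest water cell
#' within `snap_tol` cells.
#'
#' @param grid an [estuary_grid()].
#' @param sources a [source_points()] data frame (or any data frame with
#'   `id`, `easting`, `northing`).
#' @param neighborhood 8 (default) or 16.
#' @param snap_tol snapping tolerance in cells.
#' @return A named list (by source id) of `cost_surface` objects, each with
#'   elements `source_id`, `grid`, and `cost`: an `n_rows x n_cols` matrix of
#'   accumulated costs in metres. Land cells are `NA`; water cells
#'   unreachable from the source are `Inf`.
#' @export
cost_surfaces <- function(grid, sources, neighborhood = 8, snap_tol = 5) {
  stopifnot(inherits(grid, "estuary_grid"))
  wg <- water_graph(grid, neighborhood)
  vsrc <- integer(nrow(sources))
  for (i in seq_len(nrow(sources))) {
    rc <- snap_to_water(grid, sources$easting[i], sources$northing[i],
                        id = sources$id[i], tol = snap_tol)
    vsrc[i] <- wg$vid[rc[1, "row"], rc[1, "col"]]
  }
  d <- igraph::distances(wg$graph, v = vsrc, algorithm = "dijkstra")
  out <- vector("list", nrow(sources))
  for (i in seq_len(nrow(sources))) {
    cost <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    cost[grid$water] <- d[i, ]
    out[[i]] <- structure(
      list(source_id = sources$id[i], grid = grid, cost = cost),
      class = "cost_surface")
  }
  names(out) <- sources$id
  out
}

#' @rdname cost_surfaces
#' @param source a single-row source data frame (or list with `id`,
#'   `easting`, `northing`).
#' @return `accumulate_cost()` returns a single `cost_surface`.
#' @export
accumulate_cost <- function(grid, source, neighborhood = 8, snap_tol = 5) {
  src <- as.data.frame(source[c("id", "easting", "northing")])
  cost_surfaces(grid, src, neighborhood = neighborhood, snap_tol = snap_tol)[[1]]
}

#' @export
print.cost_surface <- function(x, ...) {
  finite <- x$cost[is.finite(x$cost)]
  cat(sprintf("cost_surface '%s': %d reachable cells, range %.1f - %.1f m\n",
              x$source_id, length(finite),
              if (length(finite)) min(finite) else NA,
              if (length(finite)) max(finite) else NA))
  invisible(x)
}

#' Extract accumulated cost at point locations
#'
#' Looks up the accumulated cost of the cell containing each point. Points on
#' land or on water cells unreachable from the source return `Inf` (the
#' unreachable sentinel); points outside the grid bounds are an error.
#'
#' @param surface a `cost_surface` from [accumulate_cost()].
#' @param easting,northing point coordinates (vectorized).
#' @return Numeric vector of accumulated costs in metres.
#' @export
extract_cost <- function(surface, easting, northing) {
  stopifnot(inherits(surface, "cost_surface"))
  rc <- point_to_cell(surface$grid, easting, northing)
  val <- surface$cost[cbind(rc[, "row"], rc[, "col"])]
  val[is.na(val)] <- Inf
  val
}
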