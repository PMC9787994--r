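#' Canopy height grid
#'
#' A lightweight raster container for canopy height models (CHM): a numeric
#' matrix of heights (metres above ground) plus a cell resolution and a map
#' origin. Rows run north to south, columns west to east, so `values[1, 1]`
#' is the upper-left (north-west) cell. Missing cells are `NA`.
#'
#' @param values Numeric matrix of canopy heights (m); `NA` marks missing
#'   cells. Heights must be non-negative where present.
#' @param resolution Cell edge length in metres (single positive number).
#' @param origin Map coordinates `c(x, y)` of the grid's upper-left corner.
#' @return An object of class `canopy_grid`.
#' @examples
#' g <- canopy_grid(matrix(10, 4, 4), resolution = 0.5)
#' top_canopy_height(g)
#' @export
canopy_grid <- function(values, resolution, origin = c(0, 0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number (metres)")
  if (any(values < 0, na.rm = TRUE))
    stop("canopy heights must be non-negative or NA")
  structure(
    list(values = values, resolution = as.numeric(resolution),
         origin = as.numeric(origin)),
    class = "canopy_grid"
  )
}

#' @export
print.canopy_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<canopy_grid> %d x %d cells at %g m (%.1f x %.1f m)\n",
              nrow(v), ncol(v), x$resolution,
              nrow(v) * x$resolution, ncol(v) * x$resolution))
  cat(sprintf("  height: mean %.2f m, max %.2f m, %d missing cell(s)\n",
              mean(v, na.rm = TRUE), suppressWarnings(max(v, na.rm = TRUE)),
              sum(is.na(v))))
  invisible(x)
}

# x/y map coordinates of every cell centre, in matrix (row-major by column) order
grid_cell_centres <- function(grid) {
  v <- grid$values
  res <- grid$resolution
  xs <- grid$origin[1] + (seq_len(ncol(v)) - 0.5) * res
  ys <- grid$origin[2] - (seq_len(nrow(v)) - 0.5) * res
  list(x = matrix(xs, nrow(v), ncol(v), byrow = TRUE),
       y = matrix(ys, nrow(v), ncol(v)))
}

#' Rasterize height-normalized returns into a canopy height model
#'
#' Each cell takes the maximum return height among the returns falling in it
#' (a simplified CHM; pit-free interpolation is out of scope). Cells without
#' returns are filled with the value of the nearest populated cell within a
#' 3-cell radius (Euclidean distance between cell centres), and with 0 beyond
#' that radius.
#'
#' @param points Data frame with columns `x`, `y`, `height` (height-normalized
#'   returns, ground at ~0 m).
#' @param footprint Numeric vector `c(xmin, xmax, ymin, ymax)` delimiting the
#'   grid extent in map units.
#' @param resolution Cell size in metres (default 0.5).
#' @return A [canopy_grid].
#' @export
rasterize_chm <- function(points, footprint, resolution = 0.5) {
  stopifnot(length(footprint) == 4L)
  xmin <- footprint[1]; xmax <- footprint[2]
  ymin <- footprint[3]; ymax <- footprint[4]
  if (xmax <= xmin || ymax <= ymin) stop("degenerate footprint")
  nc <- max(1L, as.integer(ceiling((xmax - xmin) / resolution - 1e-9)))
  nr <- max(1L, as.integer(ceiling((ymax - ymin) / resolution - 1e-9)))
  v <- matrix(NA_real_, nr, nc)

  inside <- points$x >= xmin & points$x < xmax & points$y > ymin & points$y <= ymax
  pts <- points[inside, , drop = FALSE]
  if (nrow(pts) == 0L) {
    warning("no returns inside footprint; returning all-zero grid")
    v[] <- 0
    return(canopy_grid(v, resolution, origin = c(xmin, ymax)))
  }
  col <- pmin(nc, as.integer(floor((pts$x - xmin) / resolution)) + 1L)
  row <- pmin(nr, as.integer(floor((ymax - pts$y) / resolution)) + 1L)
  idx <- (col - 1L) * nr + row
  mx <- tapply(pts$height, idx, max)
  v[as.integer(names(mx))] <- as.numeric(mx)

  v <- fill_nearest(v, max_radius = 3L, fallback = 0)
  canopy_grid(v, resolution, origin = c(xmin, ymax))
}

# Nearest-neighbour fill of NA cells within max_radius cells; `fallback` beyond.
fill_nearest <- function(v, max_radius = 3L, fallback = 0) {
  nas <- which(is.na(v), arr.ind = TRUE)
  if (nrow(nas) == 0L) return(v)
  nr <- nrow(v); nc <- ncol(v)
  # candidate offsets sorted by distance between cell centres
  off <- expand.grid(dr = -max_radius:max_radius, dc = -max_radius:max_radius)
  off$d2 <- off$dr^2 + off$dc^2
  off <- off[off$d2 > 0 & off$d2 <= max_radius^2, ]
  off <- off[order(off$d2), ]
  out <- v
  for (i in seq_len(nrow(nas))) {
    r <- nas[i, 1]; c <- nas[i, 2]
    val <- fallback
    for (j in seq_len(nrow(off))) {
      rr <- r + off$dr[j]; cc <- c + off$dc[j]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && !is.na(v[rr, cc])) {
        val <- v[rr, cc]
        break
      }
    }
    out[r, c] <- val
  }
  out
}

#' Aggregate a canopy height model to a coarser resolution
#'
#' Each coarse cell is the arithmetic mean of its constituent fine cells,
#' ignoring missing values (the way multi-resolution CHM stacks are built
#' before structural metrics are extracted). The target resolution must be an
#' integer multiple of the source resolution; partial blocks at the east/south
#' margins are averaged over the cells available.
#'
#' @param grid A [canopy_grid].
#' @param target_resolution Target cell size in metres, `>=` the source
#'   resolution and an integral multiple of it.
#' @return A [canopy_grid] at `target_resolution`.
#' @examples
#' g <- canopy_grid(matrix(c(1, 3, 2, 4), 2, 2), resolution = 0.5)
#' aggregate_chm(g, 1)$values # 2.5
#' @export
aggregate_chm <- function(grid, target_resolution) {
  stopifnot(inherits(grid, "canopy_grid"))
  f <- target_resolution / grid$resolution
  if (f < 1 - 1e-9) stop("target resolution must be >= source resolution")
  if (abs(f - round(f)) > 1e-9)
    stop(sprintf("target/source resolution ratio (%g) must be an integer", f))
  f <- as.integer(round(f))
  if (f == 1L) return(grid)
  v <- grid$values
  nr2 <- ceiling(nrow(v) / f) * f
  nc2 <- ceiling(ncol(v) / f) * f
  if (nr2 != nrow(v) || nc2 != ncol(v)) {
    pad <- matrix(NA_real_, nr2, nc2)
    pad[seq_len(nrow(v)), seq_len(ncol(v))] <- v
    v <- pad
  }
  ri <- (seq_len(nrow(v)) - 1L) %/% f
  ci <- (seq_len(ncol(v)) - 1L) %/% f
  sums <- rowsum(t(rowsum(ifelse(is.na(v), 0, v), ri)), ci)
  cnts <- rowsum(t(rowsum((!is.na(v)) + 0, ri)), ci)
  m <- t(sums / ifelse(cnts == 0, NA, cnts))
  canopy_grid(m, target_resolution, origin = grid$origin)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange for canopy height models. `NODATA` cells map to
#' `NA`. Only square cells are supported.
#'
#' @param grid A [canopy_grid].
#' @param path File path.
#' @param nodata Sentinel written for missing cells.
#' @return `write_esri_ascii()` returns `path` invisibly; `read_esri_ascii()`
#'   returns a [canopy_grid].
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "canopy_grid"))
  v <- grid$values
  yll <- grid$origin[2] - nrow(v) * grid$resolution
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", grid$resolution),
    sprintf("NODATA_value %g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    if (length(ln) != 1L) stop(sprintf("malformed ESRI ASCII header: missing '%s'", key))
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  nums <- scan(text = paste(lines[-(1:6)], collapse = " "), quiet = TRUE)
  if (length(nums) != nr * nc) stop("ESRI ASCII body does not match header dimensions")
  v <- matrix(nums, nr, nc, byrow = TRUE)
  v[v == nodata] <- NA_real_
  canopy_grid(v, cs, origin = c(xll, yll + nr * cs))
}

#' Clip spatial objects to a compartment polygon
#'
#' Retains grid cells, returns, or profile columns whose centres fall inside
#' the polygon (on-edge centres count as inside), the operation used to
#' restrict structural data to the surveyed part of each compartment. The
#' clipped area in hectares is attached as attribute `"area_ha"`, and areas
#' under `flag_below_ha` are flagged for downstream exclusion via attribute
#' `"below_min_area"`.
#'
#' @param x A [canopy_grid], a point data frame (`x`, `y`, `height`), or a
#'   [pad_profile].
#' @param polygon Data frame (or matrix) of polygon vertices with columns
#'   `x`, `y`; closed implicitly.
#' @param flag_below_ha Area threshold (ha) below which the result is flagged
#'   (default 0.05 ha, the survey-area exclusion rule).
#' @return Object of the same class, reduced to the polygon; cells outside
#'   become `NA`.
#' @export
clip_to_compartment <- function(x, polygon, flag_below_ha = 0.05) {
  UseMethod("clip_to_compartment")
}

poly_xy <- function(polygon) {
  p <- as.data.frame(polygon)
  if (!all(c("x", "y") %in% names(p))) names(p)[1:2] <- c("x", "y")
  p
}

#' @export
clip_to_compartment.canopy_grid <- function(x, polygon, flag_below_ha = 0.05) {
  p <- poly_xy(polygon)
  cc <- grid_cell_centres(x)
  inside <- sp::point.in.polygon(as.vector(cc$x), as.vector(cc$y), p$x, p$y) > 0
  v <- x$values
  v[!matrix(inside, nrow(v), ncol(v))] <- NA_real_
  if (!any(inside)) warning("polygon does not intersect grid; empty clip")
  out <- canopy_grid(v, x$resolution, x$origin)
  area_ha <- sum(inside) * x$resolution^2 / 1e4
  attr(out, "area_ha") <- area_ha
  attr(out, "below_min_area") <- area_ha < flag_below_ha
  out
}

#' @export
clip_to_compartment.data.frame <- function(x, polygon, flag_below_ha = 0.05) {
  p <- poly_xy(polygon)
  inside <- sp::point.in.polygon(x$x, x$y, p$x, p$y) > 0
  if (!any(inside)) warning("polygon contains no returns; empty clip")
  out <- x[inside, , drop = FALSE]
  # shoelace polygon area for points, which carry no cell footprint
  n <- nrow(p)
  j <- c(2:n, 1L)
  area_ha <- abs(sum(p$x * p$y[j] - p$x[j] * p$y)) / 2 / 1e4
  attr(out, "area_ha") <- area_ha
  attr(out, "below_min_area") <- area_ha < flag_below_ha
  out
}
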