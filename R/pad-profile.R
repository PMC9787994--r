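#' Vertical plant-area density profile (MacArthur-Horn)
#'
#' Estimates a plant-area density (PAD) profile from height-normalized LiDAR
#' returns by the MacArthur-Horn attenuation method. Returns are binned into
#' vertical layers of `bin` metres within horizontal columns of
#' `column_size` metres. Writing \eqn{N_{\le}(z)} for the number of returns in
#' a column at height \eqn{\le z} and \eqn{\Delta z} for the bin width, the
#' density of bin \eqn{[z, z+\Delta z)} is
#' \deqn{PAD = \log(N_{\le}(z+\Delta z) / \max(N_{\le}(z), 1)) / (k \Delta z),}
#' i.e. the log ratio of cumulative returns across the layer, scaled by the
#' extinction coefficient `k`. Bins with no returns at or below their top get
#' 0 (the profile is finite and non-negative by construction), and bins above
#' the highest return are 0 because the cumulative count has saturated.
#'
#' The estimator is a ratio of counts, so its expectation does not depend on
#' point density, and `k` rescales all densities uniformly (it cancels in
#' evenness-type summaries).
#'
#' @param points Data frame of returns with columns `x`, `y`, `height` (m,
#'   `>= 0`).
#' @param footprint `c(xmin, xmax, ymin, ymax)` extent defining the column
#'   grid; defaults to the bounding box of the points.
#' @param column_size Horizontal column edge (m), default 10.
#' @param bin Vertical bin width (m), default 1.
#' @param k Extinction coefficient (default 1; relative units).
#' @param max_height Top of the profile (m); defaults to the highest return
#'   rounded up to a whole bin.
#' @return An object of class `pad_profile`: a list with `pad` (bins x
#'   columns matrix), `bin_edges`, `columns` (data frame of column centres,
#'   return counts and a `missing` flag for empty columns), `column_size`
#'   and `k`.
#' @examples
#' pts <- data.frame(x = runif(100, 0, 10), y = runif(100, 0, 10),
#'                   height = c(rep(0, 50), runif(50, 5, 6)))
#' p <- estimate_pad_profile(pts, c(0, 10, 0, 10))
#' pad_mean(p)[6] # ~ log(2) in bin [5,6)
#' @export
estimate_pad_profile <- function(points, footprint = NULL, column_size = 10,
                                 bin = 1, k = 1, max_height = NULL) {
  if (any(points$height < 0, na.rm = TRUE)) stop("return heights must be >= 0")
  if (is.null(footprint)) {
    if (nrow(points) == 0L) stop("empty point set with no footprint")
    footprint <- c(min(points$x), max(points$x) + 1e-9,
                   min(points$y), max(points$y) + 1e-9)
  }
  xmin <- footprint[1]; xmax <- footprint[2]
  ymin <- footprint[3]; ymax <- footprint[4]
  ncx <- max(1L, as.integer(ceiling((xmax - xmin) / column_size - 1e-9)))
  ncy <- max(1L, as.integer(ceiling((ymax - ymin) / column_size - 1e-9)))
  if (is.null(max_height)) {
    top <- if (nrow(points)) max(points$height) else 0
    max_height <- max(bin, ceiling(top / bin) * bin)
  }
  nbins <- as.integer(round(max_height / bin))
  edges <- seq(0, by = bin, length.out = nbins + 1L)

  cols <- expand.grid(ix = seq_len(ncx), iy = seq_len(ncy))
  cols$x <- xmin + (cols$ix - 0.5) * column_size
  cols$y <- ymin + (cols$iy - 0.5) * column_size
  pad <- matrix(0, nbins, nrow(cols))

  inside <- points$x >= xmin & points$x < xmax & points$y >= ymin & points$y < ymax
  pts <- points[inside, , drop = FALSE]
  ci <- integer(0)
  if (nrow(pts)) {
    ix <- pmin(ncx, as.integer(floor((pts$x - xmin) / column_size)) + 1L)
    iy <- pmin(ncy, as.integer(floor((pts$y - ymin) / column_size)) + 1L)
    ci <- (iy - 1L) * ncx + ix
  }
  n_returns <- tabulate(ci, nbins = nrow(cols))
  for (j in which(n_returns > 0L)) {
    h <- pts$height[ci == j]
    # cumulative returns at height <= edge, for every bin edge
    nb <- vapply(edges, function(z) sum(h <= z + 1e-12), integer(1))
    hi <- nb[-1L]
    lo <- nb[-length(nb)]
    val <- ifelse(hi == 0L, 0, log(hi / pmax(lo, 1L)) / (k * bin))
    pad[, j] <- val
  }
  cols$n_returns <- n_returns
  cols$missing <- n_returns == 0L
  if (any(cols$missing))
    warning(sprintf("%d empty column(s) flagged missing", sum(cols$missing)))
  structure(
    list(pad = pad, bin_edges = edges,
         columns = cols[, c("x", "y", "n_returns", "missing")],
         column_size = column_size, k = k),
    class = "pad_profile"
  )
}

#' @export
print.pad_profile <- function(x, ...) {
  cat(sprintf("<pad_profile> %d vertical bin(s) x %d column(s) (%g m columns, %g m bins)\n",
              nrow(x$pad), ncol(x$pad), x$column_size, diff(x$bin_edges[1:2])))
  if (any(x$columns$missing))
    cat(sprintf("  %d column(s) missing (no returns)\n", sum(x$columns$missing)))
  invisible(x)
}

#' Compartment-mean PAD profile
#'
#' Mean plant-area density of each vertical segment across the profile's
#' non-missing columns, the per-compartment summary the vertical structural
#' metrics operate on.
#'
#' @param profile A [pad_profile] or a plain numeric vector (returned as is).
#' @return Numeric vector of per-bin mean PAD values.
#' @export
pad_mean <- function(profile) {
  if (is.numeric(profile)) return(profile)
  stopifnot(inherits(profile, "pad_profile"))
  keep <- !profile$columns$missing
  if (!any(keep)) return(rep(NA_real_, nrow(profile$pad)))
  rowMeans(profile$pad[, keep, drop = FALSE])
}

#' @export
clip_to_compartment.pad_profile <- function(x, polygon, flag_below_ha = 0.05) {
  p <- poly_xy(polygon)
  inside <- sp::point.in.polygon(x$columns$x, x$columns$y, p$x, p$y) > 0
  if (!any(inside)) warning("polygon contains no profile columns; empty clip")
  out <- x
  out$pad <- x$pad[, inside, drop = FALSE]
  out$columns <- x$columns[inside, , drop = FALSE]
  area_ha <- sum(inside) * x$column_size^2 / 1e4
  attr(out, "area_ha") <- area_ha
  attr(out, "below_min_area") <- area_ha < flag_below_ha
  out
}
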