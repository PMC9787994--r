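#' Simulate a canopy height grid for one compartment
#'
#' Canopy heights are drawn cell-wise from a Gaussian with the age class's
#' mean and SD, clipped at zero, on a square patch of `config$patch_edge_m`
#' metres at the configured grid resolution. Canopy gaps are then carved as
#' small near-zero discs (radius 1-2 cells) until the age class's target gap
#' fraction of cells is reached, which also gives the gap pattern spatial
#' structure that Moran's I can detect.
#'
#' @param age_class Detailed age-class label (or a one-row compartment data
#'   frame with an `age_class` column).
#' @param config A [landscape_config].
#' @param origin Map origin of the patch (upper-left corner).
#' @return A [canopy_grid].
#' @export
generate_canopy <- function(age_class, config = landscape_config(),
                            origin = c(0, 0)) {
  if (is.data.frame(age_class)) age_class <- age_class$age_class[1]
  hb <- config$height_by_age[[age_class]]
  if (is.null(hb)) stop(sprintf("no height parameters for age class '%s'", age_class))
  gp <- config$gap_prob_by_age[[age_class]]
  res <- config$grid_resolution
  side <- max(2L, as.integer(round(config$patch_edge_m / res)))
  v <- matrix(pmax(stats::rnorm(side * side, hb[1], hb[2]), 0), side, side)

  ncell <- side * side
  target <- round(gp * ncell)
  if (target > 0) {
    is_gap <- matrix(FALSE, side, side)
    guard <- 0L
    while (sum(is_gap) < target && guard < 10L * ncell) {
      guard <- guard + 1L
      r0 <- sample.int(side, 1L); c0 <- sample.int(side, 1L)
      rad <- sample(1:2, 1L)
      rr <- max(1L, r0 - rad):min(side, r0 + rad)
      cc <- max(1L, c0 - rad):min(side, c0 + rad)
      disc <- outer((rr - r0)^2, (cc - c0)^2, "+") <= rad^2
      sub <- is_gap[rr, cc, drop = FALSE]
      sub[disc] <- TRUE
      is_gap[rr, cc] <- sub
    }
    v[is_gap] <- stats::runif(sum(is_gap), 0, 0.15)
  }
  canopy_grid(v, res, origin = origin)
}

#' Simulate LiDAR returns over a canopy grid
#'
#' Draws a homogeneous Poisson number of returns over the grid footprint at
#' the given density, positions them uniformly, and sets each return height
#' to the canopy height of its cell plus small Gaussian noise (clipped at
#' zero). A configurable fraction of returns are ground returns near height
#' zero, which controls how hard the plant-area profile is to estimate.
#'
#' @param canopy A [canopy_grid].
#' @param point_density Returns per square metre (must be positive).
#' @param ground_fraction Fraction of returns forced to ground (default 0).
#' @param noise_sd SD of the height perturbation (m).
#' @return Data frame with columns `x`, `y`, `height`.
#' @export
simulate_lidar_returns <- function(canopy, point_density,
                                   ground_fraction = 0, noise_sd = 0.1) {
  stopifnot(inherits(canopy, "canopy_grid"))
  if (!is.numeric(point_density) || point_density <= 0)
    stop("point_density must be positive")
  if (ground_fraction < 0 || ground_fraction > 1)
    stop("ground_fraction must lie in [0, 1]")
  v <- canopy$values
  res <- canopy$resolution
  w <- ncol(v) * res
  h <- nrow(v) * res
  if (length(v) == 0L || w <= 0 || h <= 0)
    return(data.frame(x = numeric(0), y = numeric(0), height = numeric(0)))
  n <- stats::rpois(1L, point_density * w * h)
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), height = numeric(0)))
  x <- canopy$origin[1] + stats::runif(n, 0, w)
  y <- canopy$origin[2] - stats::runif(n, 0, h)
  col <- pmin(ncol(v), as.integer(floor((x - canopy$origin[1]) / res)) + 1L)
  row <- pmin(nrow(v), as.integer(floor((canopy$origin[2] - y) / res)) + 1L)
  base <- v[cbind(row, col)]
  base[is.na(base)] <- 0
  height <- pmax(base + stats::rnorm(n, 0, noise_sd), 0)
  grd <- stats::runif(n) < ground_fraction
  height[grd] <- abs(stats::rnorm(sum(grd), 0, 0.02))
  data.frame(x = x, y = y, height = height)
}
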