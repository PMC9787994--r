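#' Top canopy height
#'
#' Mean canopy height model pixel value over the compartment (m).
#'
#' @param grid A [canopy_grid].
#' @return Mean height in metres.
#' @export
top_canopy_height <- function(grid) {
  stopifnot(inherits(grid, "canopy_grid"))
  v <- grid$values
  if (all(is.na(v))) stop("top_canopy_height undefined: all cells missing")
  mean(v, na.rm = TRUE)
}

#' Gap fraction
#'
#' Proportion of pixels strictly below two-thirds of the compartment's mean
#' top canopy height. An all-zero grid has threshold 0 and therefore gap
#' fraction 0 (strict inequality; documented convention).
#'
#' @param grid A [canopy_grid].
#' @return Fraction in \[0, 1\].
#' @export
gap_fraction <- function(grid) {
  stopifnot(inherits(grid, "canopy_grid"))
  v <- grid$values
  if (all(is.na(v))) stop("gap_fraction undefined: all cells missing")
  thr <- (2 / 3) * mean(v, na.rm = TRUE)
  mean(v < thr, na.rm = TRUE)
}

#' Moran's I spatial autocorrelation (horizontal heterogeneity)
#'
#' Moran's I of all grid pixel values under binary rook (4-neighbour)
#' contiguity weights:
#' \deqn{I = (n/W) \sum_i \sum_j w_{ij}(x_i-\bar x)(x_j-\bar x) / \sum_i (x_i-\bar x)^2}
#' with \eqn{W = \sum w_{ij}}. Pairs involving a missing cell are excluded
#' from both the weight total and the cross-product. A constant grid has no
#' defined autocorrelation and returns `NA` with a warning. Under random
#' permutation of cell values the expected value is \eqn{-1/(n-1)}.
#'
#' @param grid A [canopy_grid] or a plain numeric matrix.
#' @return Moran's I (unitless), or `NA` if the values have zero variance.
#' @examples
#' morans_i(matrix(c(1, 0, 0, 1), 2, 2)) # rook checkerboard: -1
#' @export
morans_i <- function(grid) {
  v <- if (inherits(grid, "canopy_grid")) grid$values else as.matrix(grid)
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 2L) stop("Moran's I needs at least two non-missing cells")
  xbar <- mean(v[ok])
  d <- v - xbar
  ss <- sum(d[ok]^2)
  if (ss <= .Machine$double.eps * n) {
    warning("Moran's I undefined on a constant grid; returning NA")
    return(NA_real_)
  }
  cross <- 0
  npair <- 0L
  if (ncol(v) > 1L) { # east-west neighbours
    a <- d[, -ncol(v), drop = FALSE]; b <- d[, -1L, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    cross <- cross + sum((a * b)[keep])
    npair <- npair + sum(keep)
  }
  if (nrow(v) > 1L) { # north-south neighbours
    a <- d[-nrow(v), , drop = FALSE]; b <- d[-1L, , drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    cross <- cross + sum((a * b)[keep])
    npair <- npair + sum(keep)
  }
  if (npair == 0L) stop("no contiguous cell pairs; Moran's I undefined")
  # W = 2 * npair (symmetric weights); cross counted once per unordered pair
  (n / (2 * npair)) * (2 * cross) / ss
}

#' Vertical evenness (Pielou's J of the PAD profile)
#'
#' Shannon entropy of the plant-area distribution across vertical segments,
#' divided by the log of the number of segments up to the highest vegetated
#' bin: \eqn{J = -\sum_{p_i>0} p_i \log p_i / \log m}. Zero bins inside the
#' canopy count towards \eqn{m} but contribute nothing to the entropy.
#'
#' @param profile A [pad_profile] or a numeric vector of per-bin PAD values
#'   (compartment means).
#' @return Evenness in \[0, 1\]; 0 when all plant area sits in a single
#'   vegetated segment (minimal evenness), `NA` if the profile is all zero.
#' @examples
#' vertical_evenness(c(2, 1, 1)) # ~0.946
#' @export
vertical_evenness <- function(profile) {
  pad <- pad_mean(profile)
  if (all(is.na(pad)) || all(pad <= 0, na.rm = TRUE)) {
    warning("vertical_evenness undefined on an empty profile; returning NA")
    return(NA_real_)
  }
  pad[is.na(pad)] <- 0
  m <- max(which(pad > 0))
  if (m < 2L) return(0) # all mass in one segment: minimal evenness

  p <- pad[seq_len(m)] / sum(pad[seq_len(m)])
  h <- -sum(p[p > 0] * log(p[p > 0]))
  h / log(m)
}

#' Shrub density
#'
#' Sum of plant-area density over vertical segments above 1 m and below 5 m,
#' i.e. 1-m bins \[1,2), \[2,3), \[3,4), \[4,5): bins must lie entirely
#' within the shrub layer (a bin touching 5 m from above is excluded).
#'
#' @inheritParams vertical_evenness
#' @param bin_edges Bin edges if `profile` is a plain vector (default
#'   integer 1-m bins from ground).
#' @return Summed PAD (relative units).
#' @export
shrub_density <- function(profile, bin_edges = NULL) {
  pad <- pad_mean(profile)
  if (is.null(bin_edges))
    bin_edges <- if (inherits(profile, "pad_profile")) profile$bin_edges else
      seq(0, by = 1, length.out = length(pad) + 1L)
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1L]
  sel <- lo >= 1 - 1e-9 & hi <= 5 + 1e-9
  sum(pad[sel], na.rm = TRUE)
}

#' Canopy density
#'
#' Sum of plant-area density over the vertical segments lying entirely within
#' the top third of the canopy. To absorb within-stand variability the top of
#' the canopy is taken as mean top canopy height + 2 standard deviations of
#' the pixel heights; the window is \[(2/3) top, top\] and only bins entirely
#' inside it qualify.
#'
#' @inheritParams shrub_density
#' @param grid The compartment's [canopy_grid] (same stand as `profile`).
#' @return Summed PAD (relative units); 0 with a warning if the canopy top
#'   is not positive.
#' @export
canopy_density <- function(profile, grid, bin_edges = NULL) {
  stopifnot(inherits(grid, "canopy_grid"))
  pad <- pad_mean(profile)
  if (is.null(bin_edges))
    bin_edges <- if (inherits(profile, "pad_profile")) profile$bin_edges else
      seq(0, by = 1, length.out = length(pad) + 1L)
  v <- grid$values
  top <- mean(v, na.rm = TRUE) + 2 * stats::sd(v[!is.na(v)])
  if (!is.finite(top) || top <= 0) {
    warning("canopy top <= 0; canopy_density set to 0")
    return(0)
  }
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1L]
  sel <- lo >= (2 / 3) * top - 1e-9 & hi <= top + 1e-9
  sum(pad[sel], na.rm = TRUE)
}

#' All structural metrics for one compartment
#'
#' Computes the six structural metrics from a fine-resolution canopy height
#' model and a PAD profile. Top canopy height, gap fraction and horizontal
#' heterogeneity (Moran's I) are computed at every requested resolution by
#' mean-aggregating the CHM; vertical evenness, shrub density and canopy
#' density come from the PAD profile (one resolution).
#'
#' @param grid A [canopy_grid] at the finest resolution.
#' @param profile A [pad_profile] for the same compartment.
#' @param resolutions Numeric resolutions (m) at which the CHM metrics are
#'   extracted; must be integral multiples of the grid resolution.
#' @return One-row data frame with columns `tch_r<res>`, `gf_r<res>`,
#'   `hh_r<res>` for each resolution plus `ve`, `sd_shrub`, `cd`.
#' @export
structural_metrics <- function(grid, profile, resolutions = c(0.5, 2, 5, 10)) {
  stopifnot(inherits(grid, "canopy_grid"))
  out <- list()
  for (r in resolutions) {
    g <- aggregate_chm(grid, r)
    lab <- format(r, trim = TRUE)
    out[[paste0("tch_r", lab)]] <- top_canopy_height(g)
    out[[paste0("gf_r", lab)]] <- gap_fraction(g)
    out[[paste0("hh_r", lab)]] <- suppressWarnings(morans_i(g))
  }
  out$ve <- suppressWarnings(vertical_evenness(profile))
  out$sd_shrub <- shrub_density(profile)
  out$cd <- canopy_density(profile, grid)
  as.data.frame(out)
}
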