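#' Taxonomic diversity: species richness and Shannon diversity
#'
#' Richness counts species with strictly positive abundance (fractional,
#' detectability-corrected abundances are allowed); Shannon diversity is
#' \eqn{H' = -\sum p_i \log p_i} in natural-log units (nats), computed with
#' `vegan::diversity()`. An all-zero community has richness 0 and undefined
#' Shannon diversity (`NA`).
#'
#' @param x Abundance vector, or a communities x species matrix.
#' @return Data frame with columns `richness` and `shannon` (one row per
#'   community).
#' @examples
#' taxonomic_diversity(c(4, 1)) # H' ~ 0.5004
#' @export
taxonomic_diversity <- function(x) {
  if (is.vector(x)) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  rich <- rowSums(x > 0)
  sh <- vegan::diversity(x, index = "shannon")
  sh[rich == 0] <- NA_real_
  data.frame(richness = as.integer(rich), shannon = as.numeric(sh),
             row.names = rownames(x))
}

#' Gower dissimilarity over a mixed trait table
#'
#' Per-trait distance: continuous traits contribute `|difference| / range`,
#' categorical traits 0/1; the Gower dissimilarity is the unweighted mean
#' over traits with both values non-missing. Continuous traits with zero
#' range carry no information and are dropped with a warning.
#'
#' @param traits Data frame of trait values, one row per species (row names
#'   or a `species_id` column identify species). Numeric columns are treated
#'   as continuous, everything else as categorical.
#' @return A `dist` object of pairwise Gower dissimilarities.
#' @export
gower_distance <- function(traits) {
  tr <- as.data.frame(traits)
  if ("species_id" %in% names(tr)) {
    rownames(tr) <- tr$species_id
    tr$species_id <- NULL
  }
  n <- nrow(tr)
  if (n < 2L) stop("Gower distance needs at least two species")
  num <- numeric(n * (n - 1) / 2)
  cnt <- numeric(length(num))
  used <- 0L
  for (cl in names(tr)) {
    v <- tr[[cl]]
    if (is.numeric(v)) {
      rng <- diff(range(v, na.rm = TRUE))
      if (!is.finite(rng) || rng <= 0) {
        warning(sprintf("trait '%s' has zero range and was dropped", cl))
        next
      }
      dd <- as.vector(stats::dist(v / rng, method = "manhattan"))
      ok <- !is.na(dd)
    } else {
      v <- as.character(v)
      pair <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE) # dist order
      dd <- as.numeric(v[pair[, 1]] != v[pair[, 2]])
      ok <- !is.na(v[pair[, 1]]) & !is.na(v[pair[, 2]])
    }
    dd[!ok] <- 0
    num <- num + dd
    cnt <- cnt + ok
    used <- used + 1L
  }
  if (used == 0L) stop("no usable traits")
  if (any(cnt == 0)) stop("some species pairs share no non-missing trait")
  d <- num / cnt
  structure(d, Size = n, Labels = rownames(tr), Diag = FALSE, Upper = FALSE,
            method = "gower", class = "dist")
}

#' Principal-coordinates trait space
#'
#' Embeds a species dissimilarity into a low-dimensional Euclidean trait
#' space by classical principal-coordinates analysis. If negative
#' eigenvalues arise (the dissimilarity is not Euclidean), the square-root
#' transform of the dissimilarities is applied and the embedding recomputed.
#' The number of retained axes is `m = max(1, min(max_axes, s_min - 1))`,
#' where `s_min` is the smallest community richness (functional richness
#' needs more species than axes in every community). The quality of the
#' reduced space is the share of retained positive eigenvalues in all
#' positive eigenvalues (an R-squared-like ratio).
#'
#' @param d A `dist` of species dissimilarities (e.g. [gower_distance]).
#' @param max_axes Maximum number of ordination axes (default 4).
#' @param s_min Smallest community species richness, if communities are
#'   known; `NULL` caps axes by `max_axes` alone.
#' @return List of class `trait_space`: `coords` (species x m), `m`,
#'   `quality`, `correction` ("none" or "sqrt"), `eig`.
#' @export
build_trait_space <- function(d, max_axes = 4, s_min = NULL) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < 2L) stop("trait space needs at least two species")
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # eigenvalue screen below handles that case explicitly
  embed <- function(dd) suppressWarnings(stats::cmdscale(dd, k = n - 1L, eig = TRUE))
  fit <- embed(d)
  correction <- "none"
  tol <- max(abs(fit$eig)) * 1e-8
  if (any(fit$eig < -tol)) {
    fit <- embed(sqrt(d))
    correction <- "sqrt"
  }
  pos <- fit$eig > tol
  m <- min(max_axes, n - 1L, max(1L, sum(pos)))
  if (!is.null(s_min)) m <- min(m, max(1L, s_min - 1L))
  m <- max(1L, as.integer(m))
  coords <- fit$points[, seq_len(m), drop = FALSE]
  rownames(coords) <- attr(d, "Labels")
  quality <- sum(fit$eig[pos][seq_len(min(m, sum(pos)))]) / sum(fit$eig[pos])
  structure(list(coords = coords, m = m, quality = quality,
                 correction = correction, eig = fit$eig),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("<trait_space> %d species on %d axes; quality %.3f; correction: %s\n",
              nrow(x$coords), x$m, x$quality, x$correction))
  invisible(x)
}

space_coords <- function(space) {
  if (inherits(space, "trait_space")) space$coords else as.matrix(space)
}

# reorder an abundance vector to the trait-space species order
align_abundances <- function(space, abundances) {
  co <- space_coords(space)
  if (!is.null(names(abundances)) && !is.null(rownames(co))) {
    if (!all(rownames(co) %in% names(abundances)))
      stop("abundance vector does not cover all trait-space species")
    abundances <- abundances[rownames(co)]
  }
  if (length(abundances) != nrow(co))
    stop("abundance vector does not match trait space species")
  abundances
}

#' Functional richness (FRic)
#'
#' Convex-hull volume of the species present in a community, in the
#' m-dimensional trait space: the range of trait combinations the community
#' occupies. Undefined (`NA`, with a warning) when the number of species
#' present does not exceed the dimensionality or the configuration is
#' degenerate (e.g. collinear).
#'
#' @param space A [build_trait_space] object (or coordinate matrix).
#' @param abundances Abundance vector over the space's species.
#' @return Hull volume in trait-space units, or `NA`.
#' @export
functional_richness <- function(space, abundances) {
  co <- space_coords(space)
  pres <- which(align_abundances(space, abundances) > 0)
  m <- ncol(co)
  if (length(pres) <= m) {
    warning(sprintf("FRic undefined: %d species present in a %d-D space",
                    length(pres), m))
    return(NA_real_)
  }
  hull <- convex_hull_volume(co[pres, , drop = FALSE])
  if (hull$degenerate) {
    warning("FRic undefined: degenerate species configuration")
    return(NA_real_)
  }
  hull$volume
}

#' Functional evenness (FEve)
#'
#' Regularity of the abundance distribution along the minimum spanning tree
#' of the species present. For each MST branch l joining species i and j,
#' the abundance-weighted branch length is
#' \eqn{EW_l = dist(i,j)/(w_i + w_j)} with relative abundances w; the partial
#' weights \eqn{PEW_l = EW_l / \sum EW} are compared against the perfectly
#' even value 1/(S-1):
#' \deqn{FEve = (\sum_l \min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1)).}
#' The MST is computed with `vegan::spantree()`. Needs at least three
#' species present.
#'
#' @inheritParams functional_richness
#' @return FEve in \[0, 1\], or `NA` when fewer than 3 species are present.
#' @examples
#' sp <- matrix(c(0, 1, 3), ncol = 1)
#' functional_evenness(sp, c(1, 1, 1)) # 2/3
#' @export
functional_evenness <- function(space, abundances) {
  co <- space_coords(space)
  abundances <- align_abundances(space, abundances)
  pres <- which(abundances > 0)
  s <- length(pres)
  if (s < 3L) {
    warning("FEve undefined with fewer than 3 species present")
    return(NA_real_)
  }
  ab <- abundances[pres]
  w <- ab / sum(ab)
  dd <- stats::dist(co[pres, , drop = FALSE])
  tree <- vegan::spantree(dd)
  i <- 2:s
  j <- tree$kid
  ew <- tree$dist / (w[i] + w[j])
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional divergence (FDiv)
#'
#' How abundance is distributed relative to the centre of the occupied trait
#' space. With G the centroid of the convex-hull vertices of the species
#' present, \eqn{d_i} each species' distance to G and \eqn{\bar d} their
#' unweighted mean, the abundance-weighted deviations
#' \eqn{\Delta d = \sum w_i (d_i - \bar d)} and
#' \eqn{\Delta|d| = \sum w_i |d_i - \bar d|} give
#' \deqn{FDiv = (\Delta d + \bar d) / (\Delta|d| + \bar d).}
#'
#' @inheritParams functional_richness
#' @return FDiv in \[0, 1\], or `NA` (fewer than 3 species, degenerate hull,
#'   or all species at one point).
#' @export
functional_divergence <- function(space, abundances) {
  co <- space_coords(space)
  abundances <- align_abundances(space, abundances)
  pres <- which(abundances > 0)
  s <- length(pres)
  if (s < 3L) {
    warning("FDiv undefined with fewer than 3 species present")
    return(NA_real_)
  }
  pts <- co[pres, , drop = FALSE]
  hull <- convex_hull_volume(pts)
  if (hull$degenerate && ncol(pts) > 1L) {
    warning("FDiv undefined: degenerate species configuration")
    return(NA_real_)
  }
  vidx <- if (ncol(pts) == 1L) c(which.min(pts), which.max(pts)) else hull$vertices
  G <- colMeans(pts[vidx, , drop = FALSE])
  di <- sqrt(rowSums(sweep(pts, 2L, G)^2))
  dbar <- mean(di)
  if (dbar <= .Machine$double.eps) {
    warning("FDiv undefined: all species at a single point")
    return(NA_real_)
  }
  ab <- abundances[pres]
  w <- ab / sum(ab)
  dd <- sum(w * (di - dbar))
  dabs <- sum(w * abs(di - dbar))
  (dd + dbar) / (dabs + dbar)
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean distance of species to the abundance-weighted
#' centroid of the community in trait space. Defined for any non-empty
#' community; a single species gives 0.
#'
#' @inheritParams functional_richness
#' @return FDis (trait-space distance units), or `NA` for an empty
#'   community.
#' @examples
#' sp <- matrix(c(0, 1), ncol = 1)
#' functional_dispersion(sp, c(3, 1)) # 0.375
#' @export
functional_dispersion <- function(space, abundances) {
  co <- space_coords(space)
  abundances <- align_abundances(space, abundances)
  pres <- which(abundances > 0)
  if (length(pres) == 0L) return(NA_real_)
  pts <- co[pres, , drop = FALSE]
  ab <- abundances[pres]
  w <- ab / sum(ab)
  ctr <- colSums(pts * w)
  sum(w * sqrt(rowSums(sweep(pts, 2L, ctr)^2)))
}

#' Shapiro-Wilk check and Box-Cox normalisation of a diversity metric
#'
#' Tests normality of the metric's values across analysis rows
#' (Shapiro-Wilk); values that pass at level `alpha` are returned untouched.
#' Otherwise a Box-Cox power transform is applied with lambda chosen by
#' maximising the profile log-likelihood (via `MASS::boxcox()`) over the
#' grid \[-2, 2\] in steps of 0.01.
#'
#' @param values Numeric vector (at least 3 finite values; strictly positive
#'   — after adding `shift` — if a transform is required).
#' @param alpha Significance level of the normality test (default 0.05).
#' @param shift Constant added to the values before the power transform
#'   (default 0). A non-zero shift is recorded in the result; it is the
#'   documented way to transform metrics whose support includes zero.
#' @return List of class `metric_transform`: `values` (possibly
#'   transformed), `lambda` (`NA` if untransformed), `shift`, `shapiro_p`,
#'   `transformed`.
#' @export
normalize_metric <- function(values, alpha = 0.05, shift = 0) {
  v <- values[is.finite(values)]
  if (length(v) < 3L) stop("need at least 3 finite values")
  p <- stats::shapiro.test(v)$p.value
  if (p >= alpha) {
    out <- list(values = values, lambda = NA_real_, shift = 0,
                shapiro_p = p, transformed = FALSE)
    return(structure(out, class = "metric_transform"))
  }
  if (any(v + shift <= 0))
    stop("Box-Cox requires strictly positive values; supply a documented ",
         "`shift` before transforming")
  bc <- MASS::boxcox((v + shift) ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  x <- values + shift
  tv <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  structure(list(values = tv, lambda = lambda, shift = shift,
                 shapiro_p = p, transformed = TRUE),
            class = "metric_transform")
}

#' Six diversity metrics per community
#'
#' Computes species richness, Shannon diversity and the four functional
#' metrics for each community (group) in an abundance matrix, building the
#' shared Gower/PCoA trait space from the trait table.
#'
#' @param abundance Communities x species abundance matrix
#'   (detectability-corrected).
#' @param traits Trait table matching the species columns.
#' @param max_axes Maximum ordination axes for the trait space (default 4).
#' @return List of class `diversity_profile`: `metrics` (data frame with
#'   `richness`, `shannon`, `fric`, `feve`, `fdiv`, `fdis` per community)
#'   and `space` (the [build_trait_space] used).
#' @export
community_diversity <- function(abundance, traits, max_axes = 4) {
  abundance <- as.matrix(abundance)
  tx <- taxonomic_diversity(abundance)
  tr <- as.data.frame(traits)
  if ("species_id" %in% names(tr)) rownames(tr) <- tr$species_id
  miss <- setdiff(colnames(abundance), rownames(tr))
  if (length(miss))
    stop("no trait values for species: ", paste(miss, collapse = ", "))
  # species never observed in any community carry no abundance column and
  # are excluded from the trait space
  tr <- tr[rownames(tr) %in% colnames(abundance), , drop = FALSE]
  d <- gower_distance(tr)
  if (!is.null(attr(d, "Labels")))
    abundance <- abundance[, attr(d, "Labels"), drop = FALSE]
  pos <- tx$richness > 0
  s_min <- if (any(pos)) min(tx$richness[pos]) else NULL
  space <- build_trait_space(d, max_axes = max_axes, s_min = s_min)
  f <- t(vapply(seq_len(nrow(abundance)), function(i) {
    ab <- abundance[i, ]
    suppressWarnings(c(
      fric = functional_richness(space, ab),
      feve = functional_evenness(space, ab),
      fdiv = functional_divergence(space, ab),
      fdis = functional_dispersion(space, ab)))
  }, numeric(4)))
  metrics <- cbind(tx, as.data.frame(f))
  rownames(metrics) <- rownames(abundance)
  structure(list(metrics = metrics, space = space),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("<diversity_profile> %d communities; trait space: %d axes, quality %.3f\n",
              nrow(x$metrics), x$space$m, x$space$quality))
  print(utils::head(round(x$metrics, 4), 10))
  invisible(x)
}
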