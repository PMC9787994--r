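# d-dimensional convex hull volume by the incremental beneath-beyond
# algorithm. Intended for the small point sets of community trait spaces
# (tens of species, up to ~6 axes). Returns the hull volume and the indices
# of the hull vertices; degenerate (affinely dependent) inputs are reported
# rather than inflated.

#' Convex hull volume of a point set
#'
#' Exact volume (area in 2-D, length in 1-D) of the convex hull of `points`,
#' with the indices of the hull vertices. A configuration that does not span
#' the full dimensionality (collinear/coplanar points) is degenerate: the
#' volume is returned as `NA` with `degenerate = TRUE`.
#'
#' @param points Numeric matrix, one row per point.
#' @param tol Relative tolerance for the "beyond facet" test.
#' @return List with `volume`, `vertices` (row indices), `degenerate`.
#' @examples
#' convex_hull_volume(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))$volume # 1
#' @export
convex_hull_volume <- function(points, tol = 1e-10) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (n == 0L) return(list(volume = NA_real_, vertices = integer(0), degenerate = TRUE))
  if (d == 1L) {
    v <- max(x) - min(x)
    return(list(volume = v, vertices = c(which.min(x), which.max(x)),
                degenerate = v <= 0))
  }
  scale <- max(abs(x), 1)
  eps <- tol * scale^1 * d

  # initial simplex: greedily pick d+1 points maximising affine span
  simp <- which.max(x[, 1])
  for (k in seq_len(d)) {
    base <- x[simp, , drop = FALSE]
    # distance of every point from the affine hull of `simp`
    A <- sweep(x, 2L, base[1, ])
    if (k > 1L) {
      B <- A[simp[-1L], , drop = FALSE]
      qb <- qr(t(B))
      Q <- qr.Q(qb)[, seq_len(qr(t(B))$rank), drop = FALSE]
      resid <- A - A %*% Q %*% t(Q)
    } else resid <- A
    dist <- sqrt(rowSums(resid^2))
    cand <- which.max(dist)
    if (dist[cand] <= eps)
      return(list(volume = NA_real_, vertices = sort(unique(simp)), degenerate = TRUE))
    simp <- c(simp, cand)
  }

  centre <- colMeans(x[simp, , drop = FALSE]) # stays interior throughout

  facet_of <- function(idx) {
    # outward-oriented hyperplane through the d points `idx`
    V <- x[idx, , drop = FALSE]
    M <- sweep(V[-1L, , drop = FALSE], 2L, V[1L, ])
    nv <- qr.Q(qr(t(M)), complete = TRUE)[, d]
    off <- sum(nv * V[1L, ])
    if (sum(nv * centre) > off) { nv <- -nv; off <- -off }
    list(idx = idx, normal = nv, offset = off)
  }

  combs <- utils::combn(d + 1L, d)
  facets <- lapply(seq_len(ncol(combs)), function(j) facet_of(simp[combs[, j]]))

  for (p in setdiff(seq_len(n), simp)) {
    above <- vapply(facets, function(f) sum(f$normal * x[p, ]) - f$offset,
                    numeric(1))
    vis <- above > eps
    if (!any(vis)) next
    # horizon ridges: (d-1)-subsets appearing exactly once among visible facets
    ridges <- list()
    counts <- integer(0)
    for (f in facets[vis]) {
      for (drop_i in seq_len(d)) {
        r <- sort(f$idx[-drop_i])
        key <- paste(r, collapse = ",")
        if (is.null(ridges[[key]])) { ridges[[key]] <- r; counts[key] <- 1L }
        else counts[key] <- counts[key] + 1L
      }
    }
    horizon <- ridges[names(counts)[counts == 1L]]
    facets <- facets[!vis]
    for (r in horizon) facets[[length(facets) + 1L]] <- facet_of(c(r, p))
  }

  vol <- 0
  verts <- integer(0)
  for (f in facets) {
    V <- sweep(x[f$idx, , drop = FALSE], 2L, centre)
    vol <- vol + abs(det(V)) / factorial(d)
    verts <- c(verts, f$idx)
  }
  list(volume = vol, vertices = sort(unique(verts)), degenerate = FALSE)
}
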