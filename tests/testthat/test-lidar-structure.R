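test_that("rasterization takes the per-cell maximum and fills gaps by nearest neighbour", {
  # single return: its cell gets the height, neighbours within 3 cells copy it
  pts <- data.frame(x = 1.25, y = 9.75, height = 10)
  g <- rasterize_chm(pts, c(0, 10, 0, 10), resolution = 0.5)
  expect_equal(g$values[1, 3], 10)
  expect_equal(g$values[1, 4], 10) # nearest-neighbour fill
  expect_equal(g$values[20, 20], 0) # beyond the 3-cell radius

  # uniform 12-m canopy
  set.seed(1)
  pts <- data.frame(x = runif(4000, 0, 10), y = runif(4000, 0, 10), height = 12)
  g <- rasterize_chm(pts, c(0, 10, 0, 10), 0.5)
  expect_true(all(g$values == 12))

  # two strata: cellwise max against a direct per-cell oracle
  set.seed(2)
  pts <- data.frame(x = runif(6000, 0, 10), y = runif(6000, 0, 10))
  pts$height <- ifelse(pts$x < 5, 0, 12)
  g <- rasterize_chm(pts, c(0, 10, 0, 10), 0.5)
  oracle <- matrix(NA_real_, 20, 20)
  ci <- floor(pts$x / 0.5) + 1
  ri <- floor((10 - pts$y) / 0.5) + 1
  for (i in seq_len(nrow(pts))) {
    oracle[ri[i], ci[i]] <- max(oracle[ri[i], ci[i]], pts$height[i], na.rm = TRUE)
  }
  filled <- !is.na(oracle)
  expect_equal(g$values[filled], oracle[filled])

  expect_warning(rasterize_chm(pts[0, ], c(0, 10, 0, 10), 0.5), "no returns")
})

test_that("CHM aggregation is a block mean that preserves the global mean", {
  g <- canopy_grid(matrix(7, 4, 4), 0.5)
  a <- aggregate_chm(g, 2)
  expect_equal(dim(a$values), c(1L, 1L))
  expect_equal(a$values[1, 1], 7)

  g2 <- canopy_grid(matrix(c(1, 3, 2, 4), 2, 2), 0.5) # column-major
  expect_equal(aggregate_chm(g2, 1)$values[1, 1], 2.5)

  set.seed(3)
  g3 <- canopy_grid(matrix(runif(400, 0, 20), 20, 20), 0.5)
  for (r in c(1, 2, 5, 10)) {
    expect_equal(mean(aggregate_chm(g3, r)$values), mean(g3$values),
                 tolerance = 1e-12)
  }
  expect_error(aggregate_chm(g3, 0.7), "integer")
  expect_error(aggregate_chm(g3, 0.25), ">= source")
})

test_that("MacArthur-Horn PAD estimator matches its closed form and laws", {
  set.seed(4)
  pts <- data.frame(x = runif(100, 0, 10), y = runif(100, 0, 10),
                    height = c(rep(0, 50), runif(50, 5.05, 5.95)))
  p <- estimate_pad_profile(pts, c(0, 10, 0, 10))
  prof <- pad_mean(p)
  expect_equal(prof[6], log(2), tolerance = 1e-12)
  expect_equal(prof[-6], rep(0, length(prof) - 1))

  # all returns at ground: all-zero profile
  g0 <- data.frame(x = runif(50, 0, 10), y = runif(50, 0, 10), height = 0)
  p0 <- estimate_pad_profile(g0, c(0, 10, 0, 10), max_height = 5)
  expect_true(all(pad_mean(p0) == 0))

  # ratio estimator: expected PAD invariant to point density (Monte-Carlo)
  column_pad <- function(n, seed) {
    set.seed(seed)
    h <- ifelse(runif(n) < 0.4, 0, runif(n, 7, 8))
    pts <- data.frame(x = runif(n, 0, 10), y = runif(n, 0, 10), height = h)
    sum(pad_mean(estimate_pad_profile(pts, c(0, 10, 0, 10), max_height = 10)))
  }
  lo <- vapply(1:40, function(s) column_pad(200, s), numeric(1))
  hi <- vapply(1:40, function(s) column_pad(400, 100 + s), numeric(1))
  se <- sqrt(var(lo) / 40 + var(hi) / 40)
  expect_lt(abs(mean(lo) - mean(hi)), 3 * se)

  expect_warning(
    estimate_pad_profile(data.frame(x = 1, y = 1, height = 2),
                         c(0, 20, 0, 20), column_size = 10),
    "empty column")
})

test_that("top canopy height is the mean pixel value", {
  expect_equal(top_canopy_height(canopy_grid(matrix(10, 3, 3), 2)), 10)
  expect_equal(top_canopy_height(canopy_grid(matrix(c(0, 10, 20, 30), 2, 2), 2)), 15)
  g <- canopy_grid(matrix(NA_real_, 2, 2), 2)
  expect_error(top_canopy_height(g), "missing")
})

test_that("gap fraction counts pixels strictly below two-thirds of the mean", {
  expect_equal(gap_fraction(canopy_grid(matrix(8, 4, 4), 0.5)), 0)
  half <- canopy_grid(matrix(c(rep(12, 8), rep(0, 8)), 4, 4), 0.5)
  expect_equal(gap_fraction(half), 0.5)
  expect_equal(gap_fraction(canopy_grid(matrix(0, 4, 4), 0.5)), 0)
})

test_that("Moran's I matches closed forms, the permutation null, and ape", {
  expect_equal(morans_i(matrix(c(1, 0, 0, 1), 2, 2)), -1)
  expect_warning(i0 <- morans_i(matrix(5, 3, 3)), "constant")
  expect_true(is.na(i0))

  # permutation null expectation -1/(n-1)
  set.seed(6)
  v <- matrix(rnorm(64), 8, 8)
  perms <- vapply(1:1000, function(i) {
    morans_i(matrix(sample(v), 8, 8))
  }, numeric(1))
  n <- 64
  expect_lt(abs(mean(perms) + 1 / (n - 1)), 4 * sd(perms) / sqrt(1000))

  # independent implementation: dense weight-matrix double sum
  set.seed(7)
  m <- matrix(rnorm(30), 5, 6)
  W <- rook_weights(5, 6)
  z <- as.vector(m) - mean(m)
  oracle <- (length(z) / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
  expect_equal(morans_i(m), oracle, tolerance = 1e-10)
})

test_that("vertical evenness is Pielou's J over vegetated segments", {
  expect_equal(vertical_evenness(rep(0.3, 6)), 1)
  expect_equal(vertical_evenness(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)) / log(3))
  expect_equal(vertical_evenness(c(0, 0, 1)), 0) # single nonzero bin, m = 3
  expect_true(is.na(suppressWarnings(vertical_evenness(c(0, 0, 0)))))
})

test_that("shrub and canopy density sum the correct PAD windows", {
  expect_equal(shrub_density(rep(0.1, 10)), 0.4)
  expect_equal(shrub_density(rep(0, 10)), 0)
  only56 <- c(rep(0, 5), 1, rep(0, 4)) # mass only in [5,6)
  expect_equal(shrub_density(only56), 0)

  # grid with sample mean 12 and sample SD exactly 1.5 -> top 15, window [10, 15]
  n <- 100
  dev <- 1.5 * sqrt((n - 1) / n)
  v <- matrix(c(rep(12 - dev, 50), rep(12 + dev, 50)), 10, 10)
  g <- canopy_grid(v, 0.5)
  expect_equal(mean(v), 12)
  expect_equal(sd(v), 1.5)
  expect_equal(canopy_density(rep(0.1, 20), g), 0.5)
  expect_equal(canopy_density(rep(0, 20), g), 0)

  # top = 14 -> window [9.33, 14]: four whole bins qualify
  dev2 <- 1 * sqrt((n - 1) / n)
  g2 <- canopy_grid(matrix(c(rep(12 - dev2, 50), rep(12 + dev2, 50)), 10, 10), 0.5)
  expect_equal(canopy_density(rep(0.1, 20), g2), 0.4)

  zero <- canopy_grid(matrix(0, 5, 5), 0.5)
  expect_warning(cd0 <- canopy_density(rep(0.1, 5), zero), "canopy top")
  expect_equal(cd0, 0)
})

test_that("clipping keeps centre-inside cells and reports the area", {
  g <- canopy_grid(matrix(5, 10, 10), 1, origin = c(0, 10))
  whole <- data.frame(x = c(-1, 11, 11, -1), y = c(-1, -1, 11, 11))
  cl <- clip_to_compartment(g, whole)
  expect_equal(cl$values, g$values)
  expect_equal(attr(cl, "area_ha"), 0.01)

  halfp <- data.frame(x = c(-1, 5, 5, -1), y = c(-1, -1, 11, 11))
  cl2 <- clip_to_compartment(g, halfp)
  expect_equal(sum(!is.na(cl2$values)) / 100, 0.5, tolerance = 0.1)

  tiny <- data.frame(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2))
  cl3 <- clip_to_compartment(g, tiny)
  expect_true(attr(cl3, "below_min_area")) # 4 cells = 0.0004 ha < 0.05 ha

  pts <- data.frame(x = runif(100, 0, 10), y = runif(100, 0, 10), height = 1)
  clp <- clip_to_compartment(pts, halfp)
  expect_true(all(clp$x <= 5))
})

test_that("ESRI ASCII raster round-trips losslessly", {
  set.seed(8)
  v <- matrix(round(runif(24, 0, 30), 3), 4, 6)
  v[2, 3] <- NA
  g <- canopy_grid(v, 0.5, origin = c(100, 250))
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(g, f)
  g2 <- read_esri_ascii(f)
  expect_equal(g2$values, g$values)
  expect_equal(g2$resolution, g$resolution)
  expect_equal(g2$origin, g$origin)
  unlink(f)
})
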