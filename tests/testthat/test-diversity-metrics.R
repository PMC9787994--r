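test_that("taxonomic diversity matches closed forms", {
  u <- taxonomic_diversity(rep(1, 10))
  expect_equal(u$richness, 10L)
  expect_equal(u$shannon, log(10))

  expect_equal(taxonomic_diversity(c(4, 1))$shannon,
               -(0.8 * log(0.8) + 0.2 * log(0.2)))
  expect_equal(taxonomic_diversity(5)$shannon, 0)
  z <- taxonomic_diversity(c(0, 0))
  expect_equal(z$richness, 0L)
  expect_true(is.na(z$shannon))
})

test_that("Gower distance handles mixed traits per definition", {
  tr <- data.frame(mass = c(1, 1), diet = c("a", "a"))
  expect_equal(as.vector(suppressWarnings(gower_distance(tr))), 0)

  tr2 <- data.frame(mass = c(1, 3))
  expect_equal(as.vector(gower_distance(tr2)), 1)
  tr3 <- data.frame(mass = c(1, 3), diet = c("a", "a"))
  expect_equal(as.vector(gower_distance(tr3)), 0.5)
  tr4 <- data.frame(mass = c(1, 3), diet = c("a", "b"))
  expect_equal(as.vector(gower_distance(tr4)), 1)

  expect_warning(gower_distance(data.frame(mass = c(2, 2), diet = c("a", "b"))),
                 "zero range")

  # cross-check against cluster::daisy on a mixed random table
  skip_if_not_installed("cluster")
  set.seed(11)
  tr5 <- data.frame(mass = rlnorm(12), wing = runif(12),
                    diet = factor(sample(letters[1:3], 12, replace = TRUE)),
                    nest = factor(sample(letters[1:2], 12, replace = TRUE)))
  expect_equal(as.vector(gower_distance(tr5)),
               as.vector(cluster::daisy(tr5, metric = "gower")),
               tolerance = 1e-10)
})

test_that("PCoA trait space is exact on Euclidean input and reports quality", {
  set.seed(12)
  pts <- matrix(rnorm(20), 10, 2)
  d <- dist(pts)
  ts <- build_trait_space(d, max_axes = 2)
  expect_equal(as.vector(dist(ts$coords)), as.vector(d), tolerance = 1e-8)
  expect_equal(ts$correction, "none")

  # three pairwise-equidistant species: equilateral triangle, quality 1
  d3 <- structure(rep(1, 3), Size = 3L, Labels = c("a", "b", "c"),
                  class = "dist")
  ts3 <- build_trait_space(d3, max_axes = 2)
  expect_equal(as.vector(dist(ts3$coords)), rep(1, 3), tolerance = 1e-8)
  expect_equal(ts3$quality, 1)

  # m = 1: quality equals the leading positive-eigenvalue share
  ts1 <- build_trait_space(d, max_axes = 1)
  ev <- suppressWarnings(cmdscale(d, k = 9, eig = TRUE))$eig
  pos <- ev[ev > max(ev) * 1e-8]
  expect_equal(ts1$quality, pos[1] / sum(pos), tolerance = 1e-8)
})

test_that("square-root correction is applied for non-Euclidean dissimilarities", {
  # two incompatible midpoints: not embeddable in any Euclidean space
  d <- structure(c(2, 1, 1, 1, 1, 2), Size = 4L,
                 Labels = letters[1:4], class = "dist")
  ts <- build_trait_space(d, max_axes = 3)
  expect_equal(ts$correction, "sqrt")
})

test_that("functional richness is the trait-space hull volume", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  rownames(sq) <- letters[1:4]
  expect_equal(functional_richness(sq, rep(1, 4)), 1)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(functional_richness(tri, rep(1, 3)), 0.5)
  expect_true(is.na(suppressWarnings(
    functional_richness(sq, c(1, 1, 0, 0))))) # 2 species in 2-D
  colin <- rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))
  expect_true(is.na(suppressWarnings(functional_richness(colin, rep(1, 4)))))

  # monotonicity: adding a species outside the hull never decreases FRic
  set.seed(13)
  for (i in 1:20) {
    pts <- matrix(rnorm(14), 7, 2)
    ab <- c(rep(1, 6), 0)
    v1 <- suppressWarnings(functional_richness(pts, ab))
    v2 <- suppressWarnings(functional_richness(pts, rep(1, 7)))
    if (!is.na(v1) && !is.na(v2)) expect_gte(v2, v1 - 1e-12)
  }
})

test_that("functional evenness follows the MST formula", {
  even3 <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(functional_evenness(even3, rep(1, 3)), 1)
  expect_equal(functional_evenness(matrix(c(0, 1, 3), ncol = 1), rep(1, 3)),
               2 / 3)
  # abundance skew on regular geometry lowers evenness
  expect_lt(functional_evenness(even3, c(100, 1, 1)), 1)
  expect_true(is.na(suppressWarnings(functional_evenness(even3, c(1, 1, 0)))))
})

test_that("functional divergence matches hand computations", {
  th <- 2 * pi * (0:4) / 5
  poly <- cbind(cos(th), sin(th))
  expect_equal(functional_divergence(poly, rep(1, 5)), 1)

  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  G <- colMeans(tri)
  di <- sqrt(rowSums(sweep(tri, 2, G)^2))
  dbar <- mean(di)
  expected <- (0 + dbar) / (mean(abs(di - dbar)) + dbar)
  expect_equal(functional_divergence(tri, rep(1, 3)), expected)
  expect_equal(expected, 0.843, tolerance = 1e-3)

  # shifting abundance onto hull-distant species increases FDiv
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, 0.1), c(0.5, 2))
  lo <- functional_divergence(pts, c(1, 1, 5, 1))
  hi <- functional_divergence(pts, c(1, 1, 1, 5))
  expect_gt(hi, lo)
})

test_that("functional dispersion is the weighted centroid distance", {
  two <- matrix(c(0, 2), ncol = 1)
  expect_equal(functional_dispersion(two, c(1, 1)), 1) # d/2 with d = 2
  expect_equal(functional_dispersion(matrix(c(0, 1), ncol = 1), c(3, 1)), 0.375)
  expect_equal(functional_dispersion(matrix(0, 1, 1), 1), 0)

  # rigid-motion invariance and linear scaling
  set.seed(14)
  pts <- matrix(rnorm(16), 8, 2)
  ab <- runif(8)
  f0 <- functional_dispersion(pts, ab)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(functional_dispersion(pts %*% R + 5, ab), f0, tolerance = 1e-12)
  expect_equal(functional_dispersion(pts * 3, ab), 3 * f0, tolerance = 1e-12)
})

test_that("diversity metric invariants hold on random communities", {
  set.seed(15)
  for (i in 1:15) {
    s <- sample(4:12, 1)
    pts <- matrix(rnorm(2 * s), s, 2)
    ab <- rgamma(s, 1.5)
    feve <- suppressWarnings(functional_evenness(pts, ab))
    fdiv <- suppressWarnings(functional_divergence(pts, ab))
    if (!is.na(feve)) expect_true(feve >= 0 && feve <= 1)
    if (!is.na(fdiv)) expect_true(fdiv >= 0 && fdiv <= 1)
    # abundance-scale invariance: doubling abundances changes nothing
    tx <- taxonomic_diversity(ab)
    tx2 <- taxonomic_diversity(2 * ab)
    expect_equal(tx$shannon, tx2$shannon)
    expect_equal(suppressWarnings(functional_richness(pts, 2 * ab)),
                 suppressWarnings(functional_richness(pts, ab)))
    expect_equal(suppressWarnings(functional_evenness(pts, 2 * ab)), feve)
    expect_equal(suppressWarnings(functional_divergence(pts, 2 * ab)), fdiv)
    expect_equal(functional_dispersion(pts, 2 * ab),
                 functional_dispersion(pts, ab))
    # H' <= ln S, equality only for uniform abundances
    expect_lte(tx$shannon, log(tx$richness) + 1e-12)
  }
  expect_equal(taxonomic_diversity(rep(2, 7))$shannon, log(7))
})

test_that("normality check and Box-Cox transform behave as specified", {
  set.seed(16)
  x <- rnorm(100, 10, 1)
  tr <- normalize_metric(x)
  expect_false(tr$transformed)
  expect_identical(tr$values, x)

  y <- exp(rnorm(200))
  tr2 <- normalize_metric(y)
  expect_true(tr2$transformed)
  expect_lt(abs(tr2$lambda), 0.25)

  # lambda = 1 is a pure shift: check the transform arithmetic directly
  tr3 <- normalize_metric(y)
  lam <- tr3$lambda
  manual <- if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
  expect_equal(tr3$values, manual)

  expect_error(normalize_metric(c(y[1:50], 0, -1)), "positive")
  expect_error(normalize_metric(c(1, 2)), "3 finite")
})

test_that("community-level wrapper produces the six metrics per group", {
  set.seed(17)
  pool <- make_species_pool(15, seed = 17)
  ab <- matrix(rpois(6 * 15, 3), 6, 15,
               dimnames = list(paste0("G", 1:6), pool$species$species_id))
  dv <- community_diversity(ab, pool$species[, c("species_id", "body_mass_g",
                                                 "migratory", "nest_site",
                                                 "diet", "foraging_strata")])
  expect_setequal(names(dv$metrics),
                  c("richness", "shannon", "fric", "feve", "fdiv", "fdis"))
  expect_equal(nrow(dv$metrics), 6L)
  expect_true(dv$space$quality > 0 && dv$space$quality <= 1)
  # single-species pool degrades gracefully at the metric level
  one <- matrix(c(2), 1, 1, dimnames = list("G1", "solo"))
  expect_equal(taxonomic_diversity(one)$richness, 1L)
})
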