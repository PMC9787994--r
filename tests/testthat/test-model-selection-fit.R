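test_that("pairwise association maps mixed variable types onto [0, 1]", {
  set.seed(30)
  n <- 60
  num <- c(1, 2, 3, 7, 8, 9)
  df <- data.frame(x = num, g = rep(c("A", "B"), each = 3))
  gr <- pairwise_association(df, threshold = 0.7)
  expect_equal(diag(gr$matrix), c(x = 1, g = 1))
  expect_gt(gr$matrix["x", "g"], 0.9) # well-separated groups
  expect_equal(nrow(gr$edges), 1L)

  # independent variables: low association, no edge
  big <- data.frame(a = rnorm(1000), b = rnorm(1000),
                    f = sample(letters[1:3], 1000, replace = TRUE))
  gr2 <- pairwise_association(big, 0.7)
  off <- gr2$matrix[upper.tri(gr2$matrix)]
  expect_true(all(off < 0.2))
  expect_equal(nrow(gr2$edges), 0L)

  # correlation ratio agrees with one-way ANOVA algebra
  set.seed(31)
  y <- rnorm(90) + rep(c(0, 1, 3), each = 30)
  f <- rep(c("a", "b", "c"), each = 30)
  gr3 <- pairwise_association(data.frame(y = y, f = f), 0.7)
  r2 <- summary(lm(y ~ f))$r.squared
  expect_equal(unname(gr3$matrix["y", "f"]), sqrt(r2), tolerance = 1e-10)

  expect_error(pairwise_association(data.frame(a = rep(1, 5), b = rnorm(5))),
               "zero variance")
})

test_that("final-variable selection maximises independent effects subject to edges", {
  # spec example: edge A-B, I = {A: .4, B: .35, C: .1} -> {A, C}
  hp <- structure(data.frame(variable = c("A", "B", "C"),
                             independent = c(0.4, 0.35, 0.1),
                             joint = c(0, 0, 0),
                             percent_independent = c(47, 41, 12)),
                  r2_full = 0.85, k = 3L, n = 30L,
                  class = c("hp_result", "data.frame"))
  m <- diag(1, 3); dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  m["A", "B"] <- m["B", "A"] <- 0.9
  gr <- structure(list(matrix = m,
                       edges = data.frame(a = "A", b = "B", association = 0.9),
                       threshold = 0.7), class = "collinearity_graph")
  sel <- select_final_variables(hp, gr, forced = character(0))
  expect_setequal(as.character(sel), c("A", "C"))
  expect_equal(attr(sel, "total_independent"), 0.5)

  # no edges: everything selected
  m0 <- diag(1, 3); dimnames(m0) <- dimnames(m)
  gr0 <- structure(list(matrix = m0, edges = gr$edges[0, ], threshold = 0.7),
                   class = "collinearity_graph")
  expect_setequal(as.character(select_final_variables(hp, gr0,
                                                      forced = character(0))),
                  c("A", "B", "C"))

  # mutually collinear forced variables are rejected
  expect_error(select_final_variables(hp, gr, forced = c("A", "B")),
               "collinear")
})

test_that("selection agrees with an independently coded brute force", {
  set.seed(32)
  for (i in 1:25) {
    k <- sample(3:7, 1)
    vars <- paste0("v", seq_len(k))
    I <- round(runif(k, -0.05, 0.5), 3)
    hp <- structure(data.frame(variable = vars, independent = I,
                               joint = 0 * I,
                               percent_independent = 100 * I / sum(I)),
                    r2_full = sum(I), k = k, n = 40L,
                    class = c("hp_result", "data.frame"))
    m <- diag(1, k); dimnames(m) <- list(vars, vars)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (runif(1) < 0.25) m[a, b] <- m[b, a] <- runif(1, 0.75, 0.95)
    }
    idx <- which(upper.tri(m) & m > 0.7, arr.ind = TRUE)
    edges <- data.frame(a = vars[idx[, 1]], b = vars[idx[, 2]],
                        association = m[idx])
    gr <- structure(list(matrix = m, edges = edges, threshold = 0.7),
                    class = "collinearity_graph")
    forced <- vars[1]
    got <- tryCatch(select_final_variables(hp, gr, forced = forced),
                    error = function(e) NULL)
    want <- select_vars_bruteforce(setNames(I, vars), edges, forced)
    if (is.null(got)) {
      expect_null(want)
    } else {
      expect_setequal(as.character(got), want)
    }
  }
})

test_that("OLS fit recovers dummy-coding algebra and known coefficients", {
  df <- data.frame(y = c(1, 2, 3, 10, 11, 12, 20, 22, 24),
                   g = rep(c("Mixed", "Mature", "Thicket/pole"), each = 3))
  fit <- fit_diversity_model(df, "y", "g", baselines = c(g = "Mixed"))
  co <- coef(fit)
  expect_equal(unname(co["(Intercept)"]), 2) # baseline group mean
  expect_equal(unname(co["gMature"]), 11 - 2)
  expect_equal(unname(co["gThicket/pole"]), 22 - 2)

  # small dataset against the normal-equations oracle
  set.seed(33)
  d2 <- data.frame(y = rnorm(20), a = rnorm(20), b = rnorm(20))
  f2 <- fit_diversity_model(d2, "y", c("a", "b"))
  X <- as.matrix(d2[c("a", "b")])
  beta <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), d2$y))
  expect_equal(unname(coef(f2)), as.vector(beta), tolerance = 1e-10)

  # zero-noise response: exact recovery
  d3 <- data.frame(a = rnorm(15), b = rnorm(15))
  d3$y <- 2 + 3 * d3$a - 1.5 * d3$b
  f3 <- fit_diversity_model(d3, "y", c("a", "b"))
  expect_equal(unname(coef(f3)), c(2, 3, -1.5), tolerance = 1e-10)

  # duplicated factor information is reported as aliased, not silently kept
  d4 <- data.frame(y = rnorm(12),
                   age = rep(c("Mixed", "Mature", "Not applicable"), 4),
                   mgmt = rep(c("Conifer", "Conifer", "Open/other"), 4))
  f4 <- fit_diversity_model(d4, "y", c("age", "mgmt"),
                            baselines = c(age = "Mixed", mgmt = "Conifer"))
  expect_gt(length(f4$aliased), 0L)
})

test_that("type-2 ANOVA equals sequential ANOVA on balanced orthogonal designs", {
  set.seed(34)
  d <- expand.grid(f1 = c("a", "b"), f2 = c("u", "v", "w"), rep = 1:10)
  d$y <- rnorm(nrow(d)) + (d$f1 == "a") * 0.8 + (d$f2 == "w") * 0.5
  fit <- fit_diversity_model(d, "y", c("f1", "f2"),
                             baselines = c(f1 = "a", f2 = "u"))
  t2 <- anova_type2(fit)
  seq_tab <- anova(fit$lm)
  expect_equal(t2$sum_sq, seq_tab$`Sum Sq`[1:2], tolerance = 1e-8)
  expect_equal(t2$p_value, seq_tab$`Pr(>F)`[1:2], tolerance = 1e-8)

  # order invariance
  fit_rev <- fit_diversity_model(d, "y", c("f2", "f1"),
                                 baselines = c(f1 = "a", f2 = "u"))
  t2r <- anova_type2(fit_rev)
  expect_equal(t2$sum_sq, t2r$sum_sq[match(t2$term, t2r$term)],
               tolerance = 1e-10)

  # unbalanced data: cross-check against car::Anova type 2
  skip_if_not_installed("car")
  set.seed(35)
  d2 <- data.frame(f1 = sample(c("a", "b"), 40, replace = TRUE),
                   x = rnorm(40))
  d2$y <- rnorm(40) + (d2$f1 == "b") + 0.5 * d2$x
  fitu <- fit_diversity_model(d2, "y", c("f1", "x"), baselines = c(f1 = "a"))
  t2u <- anova_type2(fitu)
  ca <- car::Anova(fitu$lm, type = 2)
  expect_equal(t2u$sum_sq, ca$`Sum Sq`[1:2], tolerance = 1e-8)
  expect_equal(t2u$p_value, ca$`Pr(>F)`[1:2], tolerance = 1e-8)
})

test_that("residual diagnostics guard, calibrate and detect", {
  small <- fit_diversity_model(data.frame(y = rnorm(4), x = rnorm(4)),
                               "y", "x")
  dg <- residual_diagnostics(small)
  expect_match(dg$note, "insufficient")

  # well-specified model: rarely flagged
  set.seed(36)
  ok <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    d <- data.frame(x = rnorm(100))
    d$y <- 1 + d$x + rnorm(100)
    dgn <- residual_diagnostics(fit_diversity_model(d, "y", "x"))
    !any(dgn$flags)
  }, logical(1))
  expect_gte(mean(ok), 0.85)

  # variance growing with the mean: heteroscedasticity flagged
  het <- vapply(1:40, function(s) {
    set.seed(2000 + s)
    d <- data.frame(x = runif(150, 1, 5))
    d$y <- d$x + rnorm(150, sd = 0.3 * d$x^1.5)
    dgn <- residual_diagnostics(fit_diversity_model(d, "y", "x"))
    unname(dgn$flags["heteroscedastic"])
  }, logical(1))
  expect_gte(mean(het), 0.8)
})
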