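# Independent oracles, coded separately from the package implementations.

# Hierarchical partitioning via the Shapley-value weighting: the independent
# effect of variable j is the weighted sum of R2 increments over all subsets
# S not containing j, with weight |S|! (k-|S|-1)! / k!. Algebraically equal
# to the level-averaging form but computed by a different route.
hp_shapley_oracle <- function(r2_table) {
  vars <- attr(r2_table, "vars")
  k <- attr(r2_table, "k")
  r2 <- unname(r2_table)
  sapply(seq_len(k), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    total <- 0
    for (m in 0:(2L^k - 1L)) {
      if (bitwAnd(m, bit) != 0L) next
      s <- sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) > 0L)
      w <- factorial(s) * factorial(k - s - 1L) / factorial(k)
      total <- total + w * (r2[m + bit + 1L] - r2[m + 1L])
    }
    total
  })
}

# R2 of an OLS fit computed through the normal equations with a pseudo
# inverse (independent of .lm.fit / lm).
r2_normal_equations <- function(y, X) {
  X <- cbind(1, X)
  beta <- MASS::ginv(crossprod(X)) %*% crossprod(X, y)
  res <- y - X %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# Brute-force final-variable selection: enumerate subsets with expand.grid,
# drop infeasible ones by explicit edge lookup, take max total independent
# effect with the smaller-then-lexicographic tie rule.
select_vars_bruteforce <- function(ind_effects, edges, forced) {
  vars <- names(ind_effects)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(vars))))
  colnames(grid) <- vars
  has_edge <- function(sel) {
    s <- vars[sel]
    if (nrow(edges) == 0L) return(FALSE)
    any(edges$a %in% s & edges$b %in% s)
  }
  best <- NULL; best_score <- -Inf
  for (i in seq_len(nrow(grid))) {
    sel <- grid[i, ]
    if (!all(sel[forced])) next
    if (!any(sel)) next
    if (has_edge(sel)) next
    score <- sum(ind_effects[sel])
    sub <- vars[sel]
    if (score > best_score + 1e-12) {
      best <- sub; best_score <- score
    } else if (abs(score - best_score) <= 1e-12 && !is.null(best)) {
      if (length(sub) < length(best) ||
          (length(sub) == length(best) &&
           paste(sub, collapse = ",") < paste(best, collapse = ","))) {
        best <- sub
      }
    }
  }
  best
}

# Dense rook-contiguity weight matrix for a grid, for cross-checking
# Moran's I against ape::Moran.I.
rook_weights <- function(nr, nc) {
  n <- nr * nc
  W <- matrix(0, n, n)
  id <- function(r, c) (c - 1L) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r > 1L) W[id(r, c), id(r - 1L, c)] <- 1
    if (r < nr) W[id(r, c), id(r + 1L, c)] <- 1
    if (c > 1L) W[id(r, c), id(r, c - 1L)] <- 1
    if (c < nc) W[id(r, c), id(r, c + 1L)] <- 1
  }
  W
}

# random mixed predictor table for partitioning fuzz tests
random_predictors <- function(n, k, n_factors = 0) {
  df <- as.data.frame(replicate(k - n_factors, rnorm(n)))
  names(df) <- paste0("x", seq_len(k - n_factors))
  if (n_factors > 0) {
    for (i in seq_len(n_factors))
      df[[paste0("f", i)]] <- sample(letters[1:3], n, replace = TRUE)
  }
  df
}
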