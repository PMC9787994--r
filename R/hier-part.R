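# Hierarchical partitioning of OLS R-squared across predictors, and its use
# to pick the raster resolution at which each structural variable carries
# the most independent explanatory power.

# Dummy-code a predictor into its design block; a factor enters or leaves a
# model atomically as its whole dummy block.
predictor_block <- function(v) {
  if (is.numeric(v)) return(matrix(as.numeric(v), ncol = 1L))
  f <- factor(v)
  if (nlevels(f) < 2L) stop("categorical predictor with a single level")
  stats::model.matrix(~f)[, -1L, drop = FALSE]
}

#' OLS R-squared for every predictor subset
#'
#' Fits ordinary least squares (with intercept) for all `2^k` subsets of the
#' `k` predictors and records the coefficient of determination of each, the
#' exhaustive model set hierarchical partitioning averages over. Following
#' standard practice the number of variables is capped at nine. Categorical
#' predictors are dummy-coded and enter subsets as whole blocks.
#' Rank-deficient subsets (aliased columns) are fitted by pivoted
#' least squares and flagged with a warning.
#'
#' @param response Numeric response vector.
#' @param predictors Data frame of predictors (numeric or categorical),
#'   `k <= 9` columns.
#' @return Named numeric vector of class `subset_r2`, indexed by the
#'   comma-separated predictor names of each subset (empty subset `""` has
#'   R-squared 0); attributes `vars`, `k`, `n`.
#' @export
fit_all_subsets_r2 <- function(response, predictors) {
  y <- as.numeric(response)
  predictors <- as.data.frame(predictors)
  ok <- stats::complete.cases(predictors) & is.finite(y)
  if (!all(ok)) {
    y <- y[ok]
    predictors <- predictors[ok, , drop = FALSE]
  }
  k <- ncol(predictors)
  if (k < 1L) stop("need at least one predictor")
  if (k > 9L)
    stop(sprintf("%d predictors given; hierarchical partitioning is limited to nine variables", k))
  vars <- names(predictors)
  blocks <- lapply(predictors, predictor_block)
  p_max <- 1L + sum(vapply(blocks, ncol, integer(1)))
  n <- length(y)
  if (n <= p_max)
    stop(sprintf("only %d rows for up to %d parameters", n, p_max))
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("response has zero variance")

  nsub <- 2L^k
  r2 <- numeric(nsub)
  names(r2) <- vapply(0:(nsub - 1L), function(mask) {
    paste(vars[bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) > 0L], collapse = ",")
  }, character(1))
  aliased <- FALSE
  one <- matrix(1, n, 1L)
  for (mask in 1:(nsub - 1L)) {
    sel <- bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) > 0L
    X <- cbind(one, do.call(cbind, blocks[sel]))
    fit <- stats::.lm.fit(X, y)
    if (fit$rank < ncol(X)) aliased <- TRUE
    r2[mask + 1L] <- 1 - sum(fit$residuals^2) / tss
  }
  if (aliased)
    warning("aliased (rank-deficient) predictor subsets fitted by pivoted least squares")
  structure(r2, vars = vars, k = k, n = n, class = "subset_r2")
}

subset_mask_names <- function(vars, masks) {
  k <- length(vars)
  vapply(masks, function(mask) {
    paste(vars[bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) > 0L], collapse = ",")
  }, character(1))
}

#' Hierarchical partitioning of R-squared
#'
#' Decomposes the full-model goodness of fit into per-variable independent
#' and joint contributions by averaging, for each variable j, the R-squared
#' increment of adding j over all models without it — first within each
#' model size (hierarchy level), then across the k levels:
#' \deqn{I_j = k^{-1} \sum_{h=0}^{k-1} \mathrm{mean}_{|S|=h,\, j \notin S}
#'   \left[R^2(S \cup j) - R^2(S)\right],}
#' with the joint contribution \eqn{J_j = R^2(\{j\}) - I_j}. The
#' contributions satisfy \eqn{\sum_j I_j = R^2(full)} exactly; negative
#' independent effects (suppression) are reported, never clipped.
#'
#' @param table A [fit_all_subsets_r2] result (complete over all subsets).
#' @return Data frame of class `hp_result`: `variable`, `independent`,
#'   `joint`, `percent_independent`; attributes `r2_full`, `k`, `n`.
#' @examples
#' df <- data.frame(x1 = c(0, 1, 2, 3), x2 = c(0, 1, 1, 2))
#' hierarchical_partition(fit_all_subsets_r2(c(0, 1, 2, 3) + 0.1, df))
#' @export
hierarchical_partition <- function(table) {
  if (!inherits(table, "subset_r2")) stop("`table` must come from fit_all_subsets_r2()")
  vars <- attr(table, "vars")
  k <- attr(table, "k")
  if (length(table) != 2L^k) stop("incomplete subset table")
  r2 <- unname(table)
  I <- numeric(k)
  for (j in seq_len(k)) {
    bit <- bitwShiftL(1L, j - 1L)
    masks <- 0:(2L^k - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    size <- vapply(without, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) > 0L),
                   numeric(1))
    inc <- r2[without + bit + 1L] - r2[without + 1L]
    I[j] <- mean(tapply(inc, size, mean))
  }
  single <- r2[bitwShiftL(1L, seq_len(k) - 1L) + 1L]
  J <- single - I
  out <- data.frame(variable = vars, independent = I, joint = J,
                    percent_independent = 100 * I / sum(I),
                    stringsAsFactors = FALSE)
  structure(out, r2_full = r2[2L^k], k = k, n = attr(table, "n"),
            class = c("hp_result", "data.frame"))
}

#' @export
print.hp_result <- function(x, ...) {
  cat(sprintf("Hierarchical partitioning (k = %d, n = %d, full-model R2 = %.4f)\n",
              attr(x, "k"), attr(x, "n"), attr(x, "r2_full")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

# columns of `predictors` matching a multi-resolution variable stem,
# e.g. "tch" -> tch_r0.5, tch_r2, tch_r5, tch_r10
multires_columns <- function(predictors, stem) {
  grep(paste0("^", stem, "_r"), names(predictors), value = TRUE)
}

#' Choose the best raster resolution for a structural variable
#'
#' Scale optimization: for each candidate resolution of the focal variable,
#' runs the hierarchical partitioning with the focal variable at that
#' resolution — other multi-resolution variables held at a reference
#' resolution (default the coarsest) — and picks the resolution giving the
#' focal variable the highest percentage of independent effects. Ties break
#' to the coarser resolution.
#'
#' @param response Numeric response (a diversity metric across groups).
#' @param predictors Data frame holding multi-resolution variables as
#'   columns named `<stem>_r<resolution>` plus any single-resolution
#'   variables.
#' @param focal Stem of the focal multi-resolution variable (e.g. `"gf"`).
#' @param multires Stems of all multi-resolution variables present.
#' @param reference Reference resolution label for non-focal
#'   multi-resolution variables (default the coarsest available).
#' @return List of class `resolution_choice`: `resolution` (chosen label),
#'   `percent_independent` (named over candidates), `focal`.
#' @export
select_resolution <- function(response, predictors, focal,
                              multires = c("tch", "gf", "hh"),
                              reference = NULL) {
  cols_focal <- multires_columns(predictors, focal)
  if (length(cols_focal) == 0L) stop(sprintf("no columns found for focal stem '%s'", focal))
  res_of <- function(cl, stem) sub(paste0("^", stem, "_r"), "", cl)
  cand <- res_of(cols_focal, focal)
  ord <- order(as.numeric(cand))
  cand <- cand[ord]; cols_focal <- cols_focal[ord]

  other <- setdiff(multires, focal)
  keep_single <- setdiff(names(predictors),
                         unlist(lapply(multires, multires_columns,
                                       predictors = predictors)))
  pick_ref <- function(stem) {
    cls <- multires_columns(predictors, stem)
    if (length(cls) == 0L) return(character(0))
    rr <- res_of(cls, stem)
    lab <- if (is.null(reference)) rr[which.max(as.numeric(rr))] else reference
    cls[rr == lab]
  }
  base_cols <- c(unlist(lapply(other, pick_ref)), keep_single)

  pct <- stats::setNames(numeric(length(cand)), cand)
  for (i in seq_along(cand)) {
    cols <- c(cols_focal[i], base_cols)
    df <- predictors[, cols, drop = FALSE]
    names(df)[1] <- focal
    hp <- hierarchical_partition(fit_all_subsets_r2(response, df))
    pct[i] <- hp$percent_independent[hp$variable == focal]
  }
  best <- max(pct)
  chosen <- cand[pct >= best - 1e-12]
  chosen <- chosen[which.max(as.numeric(chosen))] # ties -> coarser
  structure(list(resolution = chosen, percent_independent = pct,
                 focal = focal), class = "resolution_choice")
}

#' @export
print.resolution_choice <- function(x, ...) {
  cat(sprintf("<resolution_choice> '%s' -> %s m (%%I: %s)\n", x$focal,
              x$resolution,
              paste(sprintf("%s m = %.1f", names(x$percent_independent),
                            x$percent_independent), collapse = ", ")))
  invisible(x)
}
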