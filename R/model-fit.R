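#' Fit the final linear model for a diversity metric
#'
#' Ordinary least squares of a (possibly Box-Cox transformed) diversity
#' metric on the selected variables, with categorical baselines releveled to
#' the stated reference categories (age class "Mixed", management type
#' "Conifer"). Aliased dummy columns — notably the open/other category,
#' which appears identically in both the age-class and management factors
#' and cannot be estimated twice in one model — are detected and dropped,
#' with an explicit aliasing report.
#'
#' @param data Data frame of analysis rows (groups).
#' @param response Name of the response column.
#' @param variables Character vector of predictor columns.
#' @param baselines Named character vector mapping factor columns to their
#'   reference level (default `c(age_simple = "Mixed", management_simple =
#'   "Conifer")`, applied where present).
#' @return Object of class `diversity_lm`: the underlying `lm` plus the
#'   aliasing report, response/variable names and baselines.
#' @export
fit_diversity_model <- function(data, response, variables,
                                baselines = c(age_simple = "Mixed",
                                              management_simple = "Conifer")) {
  data <- as.data.frame(data)
  miss <- setdiff(c(response, variables), names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  for (v in variables) {
    if (!is.numeric(data[[v]])) {
      data[[v]] <- factor(data[[v]])
      if (v %in% names(baselines) && baselines[[v]] %in% levels(data[[v]]))
        data[[v]] <- stats::relevel(data[[v]], ref = baselines[[v]])
    }
  }
  fml <- stats::reformulate(sprintf("`%s`", variables),
                            response = sprintf("`%s`", response))
  fit <- stats::lm(fml, data = data)
  co <- stats::coef(fit)
  aliased <- names(co)[is.na(co)]
  p <- sum(!is.na(co))
  if (fit$df.residual <= 0)
    stop("no residual degrees of freedom after dummy coding")
  if (stats::var(stats::fitted(fit)) == 0 && length(variables))
    warning("predictors explain no variance")
  structure(list(lm = fit, response = response, variables = variables,
                 aliased = aliased, baselines = baselines, data = data),
            class = "diversity_lm")
}

#' @export
print.diversity_lm <- function(x, ...) {
  cat(sprintf("Linear model for %s ~ %s\n", x$response,
              paste(x$variables, collapse = " + ")))
  s <- summary(x$lm)
  cat(sprintf("  R2 = %.3f, adjusted R2 = %.3f, n = %d\n",
              s$r.squared, s$adj.r.squared, length(stats::fitted(x$lm))))
  if (length(x$aliased))
    cat("  aliased (dropped) coefficients:", paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.diversity_lm <- function(object, ...) {
  out <- list(lm_summary = summary(object$lm),
              anova = anova_type2(object),
              aliased = object$aliased,
              response = object$response)
  class(out) <- "summary.diversity_lm"
  out
}

#' @export
print.summary.diversity_lm <- function(x, ...) {
  print(x$lm_summary)
  cat("Type-2 ANOVA\n")
  print(x$anova)
  if (length(x$aliased))
    cat("Aliased coefficients dropped:", paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.diversity_lm <- function(object, ...) stats::coef(object$lm)

#' @export
predict.diversity_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.diversity_lm <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.diversity_lm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(stats::fitted(x$lm), stats::residuals(x$lm),
       xlab = "Fitted", ylab = "Residuals",
       main = sprintf("%s: residuals", x$response), ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(stats::residuals(x$lm), main = "Normal Q-Q")
  stats::qqline(stats::residuals(x$lm))
  invisible(x)
}

#' Type-2 ANOVA table
#'
#' Tests each term after adjusting for all other terms (order-invariant for
#' main-effects models): for every term, the sum of squares is the increase
#' in residual sum of squares when that term alone is removed from the full
#' model, tested by F against the full model's residual mean square. A
#' model with a single term is compared against the intercept-only model.
#'
#' @param fit A [fit_diversity_model] object or a plain `lm` (main effects
#'   only).
#' @return Data frame: `term`, `sum_sq`, `df`, `f_value`, `p_value`, with
#'   residual SS/df as attributes.
#' @export
anova_type2 <- function(fit) {
  lmfit <- if (inherits(fit, "diversity_lm")) fit$lm else fit
  stopifnot(inherits(lmfit, "lm"))
  tl <- attr(stats::terms(lmfit), "term.labels")
  if (any(grepl(":", tl, fixed = TRUE)))
    stop("type-2 table implemented for main-effects models only")
  rss_full <- sum(stats::residuals(lmfit)^2)
  df_res <- lmfit$df.residual
  mse <- rss_full / df_res
  rows <- lapply(tl, function(tm) {
    red <- stats::update(lmfit, stats::as.formula(paste(". ~ . -", tm)),
                         data = stats::model.frame(lmfit))
    ss <- sum(stats::residuals(red)^2) - rss_full
    df <- red$df.residual - lmfit$df.residual
    if (df == 0L) # term fully aliased with the others
      return(data.frame(term = tm, sum_sq = 0, df = 0L, f_value = NA_real_,
                        p_value = NA_real_))
    f <- (ss / df) / mse
    data.frame(term = tm, sum_sq = ss, df = df, f_value = f,
               p_value = stats::pf(f, df, df_res, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  attr(out, "rss") <- rss_full
  attr(out, "df_residual") <- df_res
  out
}

#' Residual diagnostics for a fitted model
#'
#' Advisory residual checks: Shapiro-Wilk normality of residuals,
#' Breusch-Pagan heteroscedasticity (via `lmtest::bptest()`), and leverage
#' flags (hat values above twice the mean leverage). With fewer than 5
#' observations no test is run.
#'
#' @param fit A [fit_diversity_model] object or `lm`.
#' @param alpha Flagging level (default 0.05).
#' @return List of class `lm_diagnostics` with `shapiro_p`, `bp_p`,
#'   `high_leverage` (indices), `flags`, or a note when data are
#'   insufficient.
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  lmfit <- if (inherits(fit, "diversity_lm")) fit$lm else fit
  r <- stats::residuals(lmfit)
  n <- length(r)
  if (n < 5L)
    return(structure(list(note = "insufficient data for residual diagnostics",
                          n = n), class = "lm_diagnostics"))
  sw <- stats::shapiro.test(r)$p.value
  bp <- unname(as.numeric(lmtest::bptest(lmfit)$p.value))
  h <- stats::hatvalues(lmfit)
  lev <- which(h > 2 * mean(h))
  structure(list(shapiro_p = sw, bp_p = as.numeric(bp), high_leverage = lev,
                 flags = c(non_normal = sw < alpha,
                           heteroscedastic = bp < alpha),
                 n = n), class = "lm_diagnostics")
}

#' @export
print.lm_diagnostics <- function(x, ...) {
  if (!is.null(x$note)) {
    cat("<lm_diagnostics>", x$note, sprintf("(n = %d)\n", x$n))
    return(invisible(x))
  }
  cat(sprintf("<lm_diagnostics> Shapiro-Wilk p = %.3f; Breusch-Pagan p = %.3f; %d high-leverage point(s)\n",
              x$shapiro_p, x$bp_p, length(x$high_leverage)))
  if (any(x$flags)) cat("  flagged:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  invisible(x)
}
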