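# Collinearity screening and selection of the independent variable subset
# carrying the greatest total independent effects.

#' Pairwise association matrix and collinearity graph
#'
#' Builds a symmetric association matrix in \[0, 1\] over mixed-type
#' variables so a single collinearity threshold applies to all pairs:
#' continuous-continuous pairs use the absolute Pearson correlation,
#' continuous-categorical pairs the correlation ratio (square root of the
#' one-way between-group R-squared), and categorical-categorical pairs
#' Cramer's V. Pairs exceeding the threshold (conventionally |0.7|) become
#' edges of the collinearity graph.
#'
#' @param data Data frame of variables (numeric or categorical).
#' @param threshold Collinearity threshold (default 0.7).
#' @return List of class `collinearity_graph`: `matrix` (association),
#'   `edges` (data frame `a`, `b`, `association`), `threshold`.
#' @export
pairwise_association <- function(data, threshold = 0.7) {
  data <- as.data.frame(data)
  k <- ncol(data)
  if (k < 2L) stop("need at least two variables")
  isnum <- vapply(data, is.numeric, logical(1))
  for (cl in names(data)[isnum])
    if (stats::var(data[[cl]], na.rm = TRUE) <= 0)
      stop(sprintf("variable '%s' has zero variance", cl))
  for (cl in names(data)[!isnum])
    if (length(unique(stats::na.omit(data[[cl]]))) < 2L)
      stop(sprintf("variable '%s' has a single level", cl))

  corr_ratio <- function(num, cat) {
    g <- factor(cat)
    gm <- tapply(num, g, mean)
    ssb <- sum(tapply(num, g, length) * (gm - mean(num))^2)
    sst <- sum((num - mean(num))^2)
    sqrt(ssb / sst)
  }
  cramers_v <- function(a, b) {
    tab <- table(a, b)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
    mn <- min(nrow(tab), ncol(tab)) - 1L
    if (mn < 1L) return(0)
    sqrt(as.numeric(chi) / (sum(tab) * mn))
  }
  m <- diag(1, k)
  dimnames(m) <- list(names(data), names(data))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- data[[i]]; b <- data[[j]]
    v <- if (isnum[i] && isnum[j]) abs(stats::cor(a, b, use = "complete.obs"))
    else if (isnum[i]) corr_ratio(a, b)
    else if (isnum[j]) corr_ratio(b, a)
    else cramers_v(a, b)
    m[i, j] <- m[j, i] <- v
  }
  idx <- which(upper.tri(m) & m > threshold, arr.ind = TRUE)
  edges <- data.frame(a = rownames(m)[idx[, 1]], b = colnames(m)[idx[, 2]],
                      association = m[idx], stringsAsFactors = FALSE)
  structure(list(matrix = m, edges = edges, threshold = threshold),
            class = "collinearity_graph")
}

#' @export
print.collinearity_graph <- function(x, ...) {
  cat(sprintf("<collinearity_graph> %d variable(s), threshold %.2f, %d collinear pair(s)\n",
              ncol(x$matrix), x$threshold, nrow(x$edges)))
  if (nrow(x$edges))
    print(transform(x$edges, association = round(association, 3)),
          row.names = FALSE)
  invisible(x)
}

#' Select the final independent variable subset
#'
#' Exhaustively searches all predictor subsets containing the forced
#' variables, keeps those with no collinear pair inside (no edge of the
#' collinearity graph), and returns the feasible subset maximising the sum
#' of independent effects from the hierarchical partitioning. Ties break to
#' the smaller subset, then lexicographically. Log total area is forced
#' into every final model as a confounder control.
#'
#' @param hp A [hierarchical_partition] result.
#' @param graph A [pairwise_association] graph over the same variables.
#' @param forced Variables that must be in the subset (default
#'   `"log_total_area"` when present).
#' @return Character vector of selected variables, with attributes
#'   `total_independent` and `n_feasible`.
#' @export
select_final_variables <- function(hp, graph, forced = NULL) {
  stopifnot(inherits(hp, "hp_result"), inherits(graph, "collinearity_graph"))
  vars <- hp$variable
  if (!all(vars %in% rownames(graph$matrix)))
    stop("collinearity graph does not cover all partitioned variables")
  if (is.null(forced)) forced <- intersect("log_total_area", vars)
  if (!all(forced %in% vars)) stop("forced variable(s) not among candidates")
  adj <- graph$matrix[vars, vars, drop = FALSE] > graph$threshold
  diag(adj) <- FALSE
  fidx <- match(forced, vars)
  if (length(fidx) > 1L && any(adj[fidx, fidx]))
    stop("forced variables are mutually collinear")

  k <- length(vars)
  best <- NULL; best_score <- -Inf; n_feasible <- 0L
  I <- hp$independent
  for (mask in 0:(2L^k - 1L)) {
    sel <- bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) > 0L
    if (!all(sel[fidx])) next
    if (!any(sel)) next
    sub <- which(sel)
    if (any(adj[sub, sub])) next
    n_feasible <- n_feasible + 1L
    score <- sum(I[sel])
    better <- score > best_score + 1e-12 ||
      (abs(score - best_score) <= 1e-12 && !is.null(best) &&
         (length(sub) < length(best) ||
            (length(sub) == length(best) &&
               paste(vars[sub], collapse = ",") < paste(vars[best], collapse = ","))))
    if (is.null(best) || better) {
      best <- sub; best_score <- score
    }
  }
  if (is.null(best)) stop("no feasible subset (forced variables collinear?)")
  structure(vars[best], total_independent = best_score,
            n_feasible = n_feasible)
}
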