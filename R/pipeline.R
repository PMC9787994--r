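#' Pipeline configuration
#'
#' Collects the analysis constants in one place: raster resolutions for the
#' multi-resolution structural metrics, the collinearity threshold, group
#' filters, the hierarchical-partitioning variable cap, the normality test
#' level, and the synthetic generator settings.
#'
#' @param n_compartments Compartments in the synthetic landscape.
#' @param resolutions CHM resolutions in metres, ascending (default
#'   0.5, 2, 5, 10).
#' @param collinearity_threshold Association threshold for the collinearity
#'   graph (default 0.7).
#' @param min_members,min_area_ha Group filters (defaults 10 and 0.05 ha).
#' @param max_vars Hierarchical-partitioning variable cap (default 9).
#' @param alpha Shapiro-Wilk level for Box-Cox normalisation (default 0.05).
#' @param n_species Synthetic species pool size (default 48).
#' @param seed Global seed.
#' @param landscape Optional [landscape_config] overriding the defaults.
#' @param trait_config Optional species-pool overrides (see
#'   [make_species_pool]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_compartments = 1000,
                            resolutions = c(0.5, 2, 5, 10),
                            collinearity_threshold = 0.7,
                            min_members = 10, min_area_ha = 0.05,
                            max_vars = 9, alpha = 0.05,
                            n_species = 48, seed = 1L,
                            landscape = NULL, trait_config = list()) {
  if (is.unsorted(resolutions)) stop("resolutions must be ascending")
  if (collinearity_threshold <= 0 || min_members <= 0 || min_area_ha <= 0 ||
      max_vars <= 0 || alpha <= 0)
    stop("thresholds must be positive")
  if (is.null(landscape))
    landscape <- landscape_config(n_compartments = n_compartments, seed = seed)
  structure(list(n_compartments = n_compartments, resolutions = resolutions,
                 collinearity_threshold = collinearity_threshold,
                 min_members = min_members, min_area_ha = min_area_ha,
                 max_vars = max_vars, alpha = alpha, n_species = n_species,
                 seed = as.integer(seed), landscape = landscape,
                 trait_config = trait_config),
            class = "pipeline_config")
}

#' Structural metrics for every compartment of a synthetic landscape
#'
#' Generates each compartment's canopy patch and LiDAR returns from its age
#' class and immediately measures the six structural metrics at the
#' configured resolutions, so only the metric rows are kept in memory. The
#' landscape truth is never consulted: the metrics come from the simulated
#' LiDAR data alone.
#'
#' @param landscape A `synthetic_landscape`.
#' @param resolutions CHM resolutions (m).
#' @return Data frame of per-compartment structural metrics keyed by
#'   `compartment_id`.
#' @export
simulate_structural_metrics <- function(landscape,
                                        resolutions = c(0.5, 2, 5, 10)) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  cfg <- landscape$config
  comp <- landscape$compartments
  set.seed(cfg$seed + 1L)
  rows <- vector("list", nrow(comp))
  for (i in seq_len(nrow(comp))) {
    g <- generate_canopy(comp$age_class[i], cfg)
    pts <- simulate_lidar_returns(g, cfg$point_density, cfg$ground_fraction)
    prof <- suppressWarnings(estimate_pad_profile(
      pts, footprint = c(0, cfg$patch_edge_m, -cfg$patch_edge_m, 0),
      column_size = min(10, cfg$patch_edge_m)))
    rows[[i]] <- suppressWarnings(structural_metrics(g, prof, resolutions))
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(compartment_id = comp$compartment_id,
                   stringsAsFactors = FALSE), out)
}

#' Run the full forest-structure / bird-diversity analysis
#'
#' End-to-end pipeline on a synthetic landscape: simulate compartments,
#' canopy structure and the two-visit bird survey; extract structural
#' metrics; assemble detectability-corrected communities over
#' management/age groups; compute the six diversity metrics and Box-Cox
#' normalise them; pick the best resolution for each multi-resolution
#' structural variable by hierarchical partitioning; run the final
#' nine-variable partitioning; screen collinearity and select the
#' independent subset with the greatest total independent effects (log
#' total area always forced in); and fit the final linear model with a
#' type-2 ANOVA and residual diagnostics for each diversity metric.
#'
#' @param config A [pipeline_config].
#' @param out_dir Optional directory: per-stage CSV outputs and a JSON run
#'   manifest are written there.
#' @return Object of class `forest_bird_analysis`; see
#'   [summary.forest_bird_analysis()].
#' @export
run_forest_bird_analysis <- function(config = pipeline_config(),
                                     out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  land <- stage("simulate", generate_landscape(config$landscape))
  pool <- stage("simulate", make_species_pool(config$n_species,
                                              config$trait_config,
                                              seed = config$seed))
  birds <- stage("simulate", simulate_bird_counts(land, pool,
                                                  seed = config$seed + 2L))
  metrics <- stage("structure",
                   simulate_structural_metrics(land, config$resolutions))
  asm <- stage("assemble",
               assemble_groups(land$compartments, birds$survey,
                               birds$detectability, metrics,
                               min_members = config$min_members,
                               min_area_ha = config$min_area_ha))
  divp <- stage("diversity",
                community_diversity(asm$abundance, birds$traits))

  gt <- merge(asm$groups$groups[c("group_id", "management_simple",
                                  "age_simple", "n_members",
                                  "total_area_ha")],
              asm$covariates, by = "group_id", sort = TRUE)
  stopifnot(identical(gt$group_id, rownames(divp$metrics)))

  metric_names <- c("richness", "shannon", "fric", "feve", "fdiv", "fdis")
  multires <- c("tch", "gf", "hh")
  single_vars <- c("ve", "sd_shrub", "cd", "management_simple", "age_simple",
                   "log_total_area")
  transforms <- list(); choices <- list(); hp_final <- list()
  graphs <- list(); selections <- list(); models <- list()
  anovas <- list(); diagnostics <- list()

  for (mn in metric_names) {
    y_raw <- divp$metrics[[mn]]
    rows_ok <- is.finite(y_raw)
    dat <- gt[rows_ok, , drop = FALSE]
    y_raw <- y_raw[rows_ok]
    sh <- if (min(y_raw) <= 0) 1 - min(y_raw) else 0 # shift to positive support
    tr <- stage("diversity",
                normalize_metric(y_raw, alpha = config$alpha, shift = sh))
    transforms[[mn]] <- tr
    y <- tr$values

    pred_all <- dat[setdiff(names(dat), c("group_id", "n_members",
                                          "total_area_ha"))]
    ch <- lapply(multires, function(st)
      stage("partition", select_resolution(y, pred_all, st,
                                           multires = multires)))
    names(ch) <- multires
    choices[[mn]] <- ch

    sel_cols <- c(vapply(multires, function(st)
      paste0(st, "_r", ch[[st]]$resolution), character(1)), single_vars)
    pred <- pred_all[sel_cols]
    names(pred)[seq_along(multires)] <- multires
    if (ncol(pred) > config$max_vars)
      stop(sprintf("stage 'partition' failed: %d variables exceeds the cap of %d",
                   ncol(pred), config$max_vars))
    hp <- stage("partition",
                hierarchical_partition(
                  suppressWarnings(fit_all_subsets_r2(y, pred))))
    hp_final[[mn]] <- hp

    gr <- stage("fit", pairwise_association(pred,
                                            config$collinearity_threshold))
    graphs[[mn]] <- gr
    sel <- stage("fit", select_final_variables(hp, gr))
    selections[[mn]] <- sel

    dat2 <- cbind(dat, pred, y_transformed = y)
    fit <- stage("fit", fit_diversity_model(dat2, "y_transformed",
                                            as.character(sel)))
    models[[mn]] <- fit
    anovas[[mn]] <- stage("fit", anova_type2(fit))
    diagnostics[[mn]] <- stage("fit", residual_diagnostics(fit))
  }

  res <- structure(list(
    config = config, landscape = land, pool = pool,
    structural_metrics = metrics, groups = asm$groups,
    abundance = asm$abundance, group_table = gt, diversity = divp,
    transforms = transforms, resolution_choices = choices,
    hp = hp_final, collinearity = graphs, selections = selections,
    models = models, anova = anovas, diagnostics = diagnostics),
    class = "forest_bird_analysis")
  if (!is.null(out_dir)) write_analysis_outputs(res, out_dir)
  res
}

#' Rank habitat variables by independent effects
#'
#' For each diversity metric, orders the final-partitioning variables by
#' their percentage of independent effects. The leading variable excluding
#' the (log) total-area confounder is reported separately: it is the
#' headline "most important habitat variable".
#'
#' @param x A `forest_bird_analysis`.
#' @return Data frame: `metric`, `rank`, `variable`, `percent_independent`,
#'   `top_non_area` (logical marker).
#' @export
variable_ranking <- function(x) {
  stopifnot(inherits(x, "forest_bird_analysis"))
  out <- lapply(names(x$hp), function(mn) {
    hp <- x$hp[[mn]]
    ord <- order(-hp$percent_independent)
    df <- data.frame(metric = mn, rank = seq_along(ord),
                     variable = hp$variable[ord],
                     percent_independent = hp$percent_independent[ord],
                     stringsAsFactors = FALSE)
    non_area <- df$variable != "log_total_area"
    df$top_non_area <- FALSE
    df$top_non_area[which(non_area)[1]] <- TRUE
    df
  })
  do.call(rbind, out)
}

#' @export
print.forest_bird_analysis <- function(x, ...) {
  cat(sprintf("<forest_bird_analysis> %d compartments -> %d groups; %d species; seed %d\n",
              nrow(x$landscape$compartments), nrow(x$groups$groups),
              ncol(x$abundance), x$config$seed))
  cat("Diversity metrics modelled:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.forest_bird_analysis <- function(object, ...) {
  rk <- variable_ranking(object)
  tops <- rk[rk$top_non_area, c("metric", "variable", "percent_independent")]
  r2 <- vapply(object$models, function(m) summary(m$lm)$r.squared, numeric(1))
  out <- list(n_groups = nrow(object$groups$groups),
              dropped = object$groups$dropped,
              top_non_area = tops, model_r2 = r2,
              resolution_choices = lapply(object$resolution_choices,
                                          function(ch) vapply(ch, `[[`,
                                                              character(1),
                                                              "resolution")))
  class(out) <- "summary.forest_bird_analysis"
  out
}

#' @export
print.summary.forest_bird_analysis <- function(x, ...) {
  cat(sprintf("Groups analysed: %d (input compartments: %d)\n", x$n_groups,
              x$dropped[["input"]]))
  cat("\nLeading non-area variable by independent effects:\n")
  print(transform(x$top_non_area,
                  percent_independent = round(percent_independent, 1)),
        row.names = FALSE)
  cat("\nFinal model R2:\n")
  print(round(x$model_r2, 3))
  invisible(x)
}

# ---- file interface ---------------------------------------------------

#' Write per-stage pipeline outputs
#'
#' Writes every stage's tabular output as UTF-8 CSV ('.' decimal, header
#' row) plus a JSON run manifest (config, seed, row counts), so any stage
#' can be inspected or re-run in isolation.
#'
#' @param res A `forest_bird_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  wr(res$landscape$compartments, "compartments.csv")
  wr(res$structural_metrics, "structural_metrics.csv")
  wr(res$groups$groups, "groups.csv")
  ab <- data.frame(group_id = rownames(res$abundance), res$abundance,
                   check.names = FALSE)
  wr(ab, "group_abundance.csv")
  dv <- data.frame(group_id = rownames(res$diversity$metrics),
                   res$diversity$metrics, check.names = FALSE)
  wr(dv, "diversity.csv")
  tr <- data.frame(metric = names(res$transforms),
                   lambda = vapply(res$transforms, `[[`, numeric(1), "lambda"),
                   shift = vapply(res$transforms, `[[`, numeric(1), "shift"),
                   shapiro_p = vapply(res$transforms, `[[`, numeric(1),
                                      "shapiro_p"),
                   row.names = NULL)
  wr(tr, "transforms.csv")
  hp <- do.call(rbind, lapply(names(res$hp), function(mn)
    cbind(metric = mn, as.data.frame(res$hp[[mn]]))))
  wr(hp, "hp_results.csv")
  rc <- do.call(rbind, lapply(names(res$resolution_choices), function(mn)
    data.frame(metric = mn, variable = names(res$resolution_choices[[mn]]),
               resolution = vapply(res$resolution_choices[[mn]], `[[`,
                                   character(1), "resolution"))))
  wr(rc, "resolution_choices.csv")
  sel <- do.call(rbind, lapply(names(res$selections), function(mn)
    data.frame(metric = mn, variable = as.character(res$selections[[mn]]))))
  wr(sel, "selected_variables.csv")
  cf <- do.call(rbind, lapply(names(res$models), function(mn) {
    s <- summary(res$models[[mn]]$lm)$coefficients
    data.frame(metric = mn, term = rownames(s), estimate = s[, 1],
               std_error = s[, 2], p_value = s[, 4], row.names = NULL)
  }))
  wr(cf, "model_coefficients.csv")
  an <- do.call(rbind, lapply(names(res$anova), function(mn)
    cbind(metric = mn, res$anova[[mn]])))
  wr(an, "anova.csv")
  manifest <- list(
    package = "forestbirdiv",
    seed = res$config$seed,
    n_compartments = res$config$n_compartments,
    n_groups = nrow(res$groups$groups),
    resolutions = res$config$resolutions,
    thresholds = list(collinearity = res$config$collinearity_threshold,
                      min_members = res$config$min_members,
                      min_area_ha = res$config$min_area_ha,
                      max_vars = res$config$max_vars,
                      alpha = res$config$alpha),
    stage_rows = list(compartments = nrow(res$landscape$compartments),
                      structural_metrics = nrow(res$structural_metrics),
                      groups = nrow(res$groups$groups)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read and validate pipeline input tables
#'
#' Schema-checked CSV readers for the pipeline's exchange tables. Errors
#' name the offending column or record.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compartment_id", "species_id", "visit", "count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("survey file missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(df$compartment_id, df$species_id, df$visit)
  if (anyDuplicated(key))
    stop("duplicate (compartment, species, visit) record: ",
         key[anyDuplicated(key)])
  if (!all(df$visit %in% c(1L, 2L))) stop("column 'visit' must be 1 or 2")
  if (any(df$count < 0)) stop("column 'count' must be non-negative")
  df
}

#' @rdname read_survey_csv
#' @export
read_compartments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compartment_id", "management", "area_ha")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("compartment file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$compartment_id))
    stop("duplicate compartment_id: ",
         df$compartment_id[anyDuplicated(df$compartment_id)])
  if (any(df$area_ha <= 0)) stop("column 'area_ha' must be positive")
  df
}

#' @rdname read_survey_csv
#' @export
read_detectability_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species_id", "detectability")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("detectability file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$detectability <= 0 | df$detectability > 1))
    stop("column 'detectability' must lie in (0, 1]")
  df
}
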