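#' Collapse two survey visits to per-compartment maximum counts
#'
#' The standard two-visit breeding-bird survey reduction: for each
#' (compartment, species) pair take the maximum count over the available
#' visits (species absent from both visits count 0; a species recorded on
#' one visit only keeps that visit's count). Duplicate
#' (compartment, species, visit) records are rejected.
#'
#' @param survey Data frame with columns `compartment_id`, `species_id`,
#'   `visit` (1 or 2) and non-negative integer `count`.
#' @param compartments Optional character vector of compartment ids to
#'   include as (possibly all-zero) rows; defaults to those in the survey.
#' @param species Optional character vector of species ids for the columns.
#' @return Numeric matrix of maximum counts, compartments x species.
#' @export
collapse_visits_max <- function(survey, compartments = NULL, species = NULL) {
  req <- c("compartment_id", "species_id", "visit", "count")
  miss <- setdiff(req, names(survey))
  if (length(miss)) stop("survey is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(survey$visit %in% c(1L, 2L))) stop("visit must be 1 or 2")
  if (any(survey$count < 0)) stop("counts must be non-negative")
  key <- paste(survey$compartment_id, survey$species_id, survey$visit, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (compartment, species, visit) record(s) in survey")
  if (is.null(compartments)) compartments <- sort(unique(survey$compartment_id))
  if (is.null(species)) species <- sort(unique(survey$species_id))
  m <- matrix(0, length(compartments), length(species),
              dimnames = list(compartments, species))
  keep <- survey$compartment_id %in% compartments & survey$species_id %in% species
  s <- survey[keep, , drop = FALSE]
  if (nrow(s)) {
    i <- match(s$compartment_id, compartments)
    j <- match(s$species_id, species)
    mx <- tapply(s$count, list(i, j), max)
    ii <- as.integer(rownames(mx)[row(mx)])
    jj <- as.integer(colnames(mx)[col(mx)])
    ok <- !is.na(mx)
    m[cbind(ii[ok], jj[ok])] <- mx[ok]
  }
  m
}

#' Group compartments by management type and age class
#'
#' Applies the data-reduction rules: compartments whose surveyed area is
#' below `min_area_ha` are dropped first; the remainder are grouped by the
#' unique combination of detailed management type and age class; groups with
#' fewer than `min_members` compartments are dropped (low replication).
#' Each surviving group carries its simplified management/age labels (the
#' analysis covariates), member count, total area and natural-log total
#' area.
#'
#' @param compartments Data frame with `compartment_id`, `management`
#'   (detailed), `age_class` (detailed; or `age_years`), `area_ha`.
#' @param min_members Minimum compartments per group (default 10).
#' @param min_area_ha Minimum surveyed compartment area in ha (default 0.05).
#' @return A list of class `compartment_groups`: `groups` (one row per
#'   group), `membership` (`compartment_id` -> `group_id`), and `dropped`
#'   (tallies of compartments removed by each rule). The conservation audit
#'   `sum(members) + dropped = input rows` always holds.
#' @export
assign_groups <- function(compartments, min_members = 10, min_area_ha = 0.05) {
  req <- c("compartment_id", "management", "area_ha")
  miss <- setdiff(req, names(compartments))
  if (length(miss)) stop("compartments missing column(s): ", paste(miss, collapse = ", "))
  n_in <- nrow(compartments)
  small <- compartments$area_ha < min_area_ha
  kept <- compartments[!small, , drop = FALSE]

  simp <- simplify_categories(kept$management, kept$age_class,
                              age_years = kept$age_years)
  # the database's own age label ("Not applicable" fill applied by the mapper)
  age_detail <- kept$age_class
  if (is.null(age_detail)) age_detail <- rep(NA_character_, nrow(kept))
  age_detail[simp$age_simple == "Not applicable"] <- "Not applicable"
  if (!is.null(kept$age_years)) {
    fill <- is.na(age_detail)
    age_detail[fill] <- age_class_from_years(kept$age_years[fill])
  }

  key <- paste(kept$management, age_detail, sep = " | ")
  tab <- table(key)
  ok_groups <- names(tab)[tab >= min_members]
  in_group <- key %in% ok_groups
  if (!any(in_group))
    stop(sprintf("no group reaches %d compartments; cannot form analysis rows", min_members))

  members <- kept[in_group, , drop = FALSE]
  mkey <- key[in_group]
  gid <- paste0("G", formatC(match(mkey, sort(unique(mkey))), width = 2, flag = "0"))
  first <- !duplicated(mkey)
  ord <- order(mkey[first])
  groups <- data.frame(
    group_id = gid[first][ord],
    management = members$management[first][ord],
    age_class = age_detail[in_group][first][ord],
    stringsAsFactors = FALSE)
  gs <- simplify_categories(groups$management, groups$age_class)
  groups$management_simple <- gs$management_simple
  groups$age_simple <- gs$age_simple
  agg_n <- tapply(rep(1L, length(mkey)), gid, sum)
  agg_a <- tapply(members$area_ha, gid, sum)
  groups$n_members <- as.integer(agg_n[groups$group_id])
  groups$total_area_ha <- as.numeric(agg_a[groups$group_id])
  groups$log_total_area <- log(groups$total_area_ha)

  list(groups = groups,
       membership = data.frame(compartment_id = members$compartment_id,
                               group_id = gid, stringsAsFactors = FALSE),
       dropped = c(below_min_area = sum(small),
                   group_too_small = sum(!in_group),
                   retained = nrow(members),
                   input = n_in)) |>
    structure(class = "compartment_groups")
}

#' @export
print.compartment_groups <- function(x, ...) {
  d <- x$dropped
  cat(sprintf("<compartment_groups> %d group(s) from %d compartment(s) (%d retained; %d under area threshold, %d in undersized groups)\n",
              nrow(x$groups), d[["input"]], d[["retained"]],
              d[["below_min_area"]], d[["group_too_small"]]))
  invisible(x)
}

#' Detectability-corrected group abundance
#'
#' Divides each species' group mean maximum count by its species-specific
#' detectability constant, giving a comparable abundance index across
#' species with different detection probabilities.
#'
#' @param mean_counts Groups x species matrix of mean maximum counts.
#' @param detectability Data frame (`species_id`, `detectability`) or named
#'   vector; constants must lie in (0, 1] and cover every species column.
#' @return Groups x species abundance matrix.
#' @export
detectability_correct <- function(mean_counts, detectability) {
  if (is.data.frame(detectability)) {
    det <- stats::setNames(detectability$detectability, detectability$species_id)
  } else det <- detectability
  sp <- colnames(mean_counts)
  miss <- setdiff(sp, names(det))
  if (length(miss))
    stop("no detectability constant for species: ", paste(miss, collapse = ", "))
  d <- det[sp]
  if (any(d <= 0) || any(d > 1))
    stop("detectability constants must lie in (0, 1]")
  sweep(mean_counts, 2L, d, "/")
}

#' Group-level covariate summaries
#'
#' Unweighted mean of each structural metric over a group's member
#' compartments, plus the natural log of the summed member areas.
#'
#' @param groups A [assign_groups] result.
#' @param metrics Data frame of per-compartment structural metrics keyed by
#'   `compartment_id`.
#' @return Data frame: one row per group with mean metrics and
#'   `log_total_area`.
#' @export
summarize_group_covariates <- function(groups, metrics) {
  stopifnot(inherits(groups, "compartment_groups"))
  mem <- groups$membership
  miss <- setdiff(mem$compartment_id, metrics$compartment_id)
  if (length(miss))
    stop("structural metrics missing for compartment(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  rows <- metrics[match(mem$compartment_id, metrics$compartment_id), , drop = FALSE]
  mcols <- setdiff(names(metrics), "compartment_id")
  bad <- vapply(mcols, function(cl) {
    nas <- is.na(rows[[cl]])
    if (any(nas)) mem$compartment_id[which(nas)[1]] else NA_character_
  }, character(1))
  if (any(!is.na(bad))) {
    w <- which(!is.na(bad))[1]
    stop(sprintf("metric '%s' is missing (NA) for compartment %s",
                 mcols[w], bad[w]))
  }
  agg <- aggregate(rows[mcols], by = list(group_id = mem$group_id), FUN = mean)
  out <- merge(groups$groups[c("group_id", "log_total_area")], agg,
               by = "group_id", sort = TRUE)
  out
}

#' Assemble detectability-corrected communities over compartment groups
#'
#' Convenience wrapper running the whole assembly stage: visit collapse,
#' group formation and filters, group mean maximum counts, detectability
#' correction, and covariate summarisation.
#'
#' @param compartments,survey,detectability,metrics Stage inputs (see the
#'   individual operations).
#' @inheritParams assign_groups
#' @return List with `groups` (a `compartment_groups`), `abundance`
#'   (groups x species detectability-corrected matrix), and `covariates`
#'   (group-level covariate data frame).
#' @export
assemble_groups <- function(compartments, survey, detectability, metrics,
                            min_members = 10, min_area_ha = 0.05) {
  grp <- assign_groups(compartments, min_members, min_area_ha)
  counts <- collapse_visits_max(survey,
                                compartments = grp$membership$compartment_id)
  mean_max <- rowsum(counts[grp$membership$compartment_id, , drop = FALSE],
                     grp$membership$group_id) /
    as.vector(table(grp$membership$group_id)[sort(unique(grp$membership$group_id))])
  abundance <- detectability_correct(mean_max, detectability)
  covar <- summarize_group_covariates(grp, metrics)
  list(groups = grp, abundance = abundance, covariates = covar)
}
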