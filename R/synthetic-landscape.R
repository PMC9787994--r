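#' Synthetic landscape configuration
#'
#' Bundles the parameters of the synthetic plantation generator. Defaults
#' emulate a large lowland conifer plantation: compartments with mean area
#' 2.35 ha (SD 2.53, right-skewed), a predominantly coniferous management
#' mix, age classes from restock to mature plus mixed-age stands, canopy
#' height/gap/shrub structure determined by age class, a 0.5-m canopy grid
#' and LiDAR returns at 24 points/m2.
#'
#' Areas are drawn from a log-normal distribution parameterised by the
#' requested mean and SD (positivity plus right skew: the implied median is
#' below the mean, as observed in real compartment registers). The canopy of
#' each compartment is simulated on a representative square patch of
#' `patch_edge_m` metres; the nominal area in hectares is carried separately
#' and used for grouping and the (log) total-area covariate.
#'
#' @param n_compartments Number of compartments to generate.
#' @param mean_area,area_sd Mean and SD of compartment area (ha).
#' @param management_probs Named probabilities over the detailed management
#'   types (must sum to 1).
#' @param age_probs Named probabilities over the detailed age bands for
#'   treed compartments (must sum to 1).
#' @param height_by_age,gap_prob_by_age,shrub_level_by_age Named lists /
#'   vectors keyed by detailed age band (plus `"Not applicable"`): canopy
#'   height mean and SD (m), target gap fraction, and shrub-layer PAD level.
#' @param grid_resolution Canopy grid cell size (m).
#' @param point_density LiDAR return density (points/m2).
#' @param ground_fraction Fraction of returns that are ground returns.
#' @param patch_edge_m Edge of the simulated canopy patch per compartment (m).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_compartments = 1000,
                             mean_area = 2.35,
                             area_sd = 2.53,
                             management_probs = NULL,
                             age_probs = NULL,
                             height_by_age = NULL,
                             gap_prob_by_age = NULL,
                             shrub_level_by_age = NULL,
                             grid_resolution = 0.5,
                             point_density = 24,
                             ground_fraction = 0.25,
                             patch_edge_m = 20,
                             seed = 1L) {
  if (is.null(management_probs))
    management_probs <- c(
      "Corsican pine monoculture" = 0.35, "Scots pine monoculture" = 0.20,
      "Douglas fir monoculture" = 0.03, "Other conifer monoculture" = 0.05,
      "Birch monoculture" = 0.03, "Other broadleaved monoculture" = 0.07,
      "Mixture (mainly conifer)" = 0.05, "Mixture (mainly broadleaved)" = 0.04,
      "Open" = 0.08, "Open with trees" = 0.03, "Other" = 0.02, "Felled" = 0.05)
  if (is.null(age_probs))
    age_probs <- c(
      "Restock (0-6 years)" = 0.12, "Pre-thicket (7-11 years)" = 0.08,
      "Thicket (12-21 years)" = 0.15, "Pole (22-45 years)" = 0.30,
      "Mature (46+ years)" = 0.25, "Mixed ages" = 0.10)
  if (is.null(height_by_age))
    height_by_age <- list(
      "Restock (0-6 years)" = c(0.8, 0.4), "Pre-thicket (7-11 years)" = c(3, 1),
      "Thicket (12-21 years)" = c(8, 2), "Pole (22-45 years)" = c(12, 2.5),
      "Mature (46+ years)" = c(18, 3), "Mixed ages" = c(12, 6),
      "Not applicable" = c(0.3, 0.2))
  if (is.null(gap_prob_by_age))
    gap_prob_by_age <- c(
      "Restock (0-6 years)" = 0.15, "Pre-thicket (7-11 years)" = 0.12,
      "Thicket (12-21 years)" = 0.05, "Pole (22-45 years)" = 0.08,
      "Mature (46+ years)" = 0.10, "Mixed ages" = 0.20,
      "Not applicable" = 0.50)
  if (is.null(shrub_level_by_age))
    shrub_level_by_age <- c(
      "Restock (0-6 years)" = 0.15, "Pre-thicket (7-11 years)" = 0.50,
      "Thicket (12-21 years)" = 0.30, "Pole (22-45 years)" = 0.15,
      "Mature (46+ years)" = 0.20, "Mixed ages" = 0.40,
      "Not applicable" = 0.10)

  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("%s must be non-negative and sum to 1", what))
  }
  check_probs(management_probs, "management_probs")
  check_probs(age_probs, "age_probs")
  if (mean_area <= 0 || area_sd <= 0) stop("areas must be positive")
  if (point_density <= 0) stop("point_density must be positive")
  if (grid_resolution <= 0) stop("grid_resolution must be positive")

  structure(list(
    n_compartments = as.integer(n_compartments), mean_area = mean_area,
    area_sd = area_sd, management_probs = management_probs,
    age_probs = age_probs, height_by_age = height_by_age,
    gap_prob_by_age = gap_prob_by_age, shrub_level_by_age = shrub_level_by_age,
    grid_resolution = grid_resolution, point_density = point_density,
    ground_fraction = ground_fraction, patch_edge_m = patch_edge_m,
    seed = as.integer(seed)), class = "landscape_config")
}

#' Generate a synthetic compartment table with ground truth
#'
#' Draws `n_compartments` management units: detailed management type and age
#' class (open/other management always carries the "Not applicable" age
#' class), an age in years where the band implies one, and a log-normally
#' distributed area with the configured mean and SD. Alongside the
#' compartment table it emits a `truth` table holding the generative
#' covariates (simplified age class and the age-determined canopy height,
#' shrub level and gap fraction) that the bird simulator consumes; the truth
#' is for validation only and is never read by the analysis pipeline.
#'
#' @param config A [landscape_config].
#' @return A list of class `synthetic_landscape` with elements
#'   `compartments` (data frame: `compartment_id`, `management`, `age_class`,
#'   `age_years`, `area_ha`), `truth` (data frame of true covariates plus
#'   attribute `dominant_driver`), and `config`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  n <- config$n_compartments
  if (n == 0L) {
    comp <- data.frame(compartment_id = character(0), management = character(0),
                       age_class = character(0), age_years = numeric(0),
                       area_ha = numeric(0))
    truth <- data.frame(compartment_id = character(0))
    return(structure(list(compartments = comp, truth = truth, config = config),
                     class = "synthetic_landscape"))
  }

  mgmt <- sample(names(config$management_probs), n, replace = TRUE,
                 prob = config$management_probs)
  open <- management_map[mgmt] == "Open/other"
  age_class <- rep("Not applicable", n)
  age_class[!open] <- sample(names(config$age_probs), sum(!open),
                             replace = TRUE, prob = config$age_probs)
  age_years <- rep(NA_real_, n)
  bands <- list("Restock (0-6 years)" = c(0, 6), "Pre-thicket (7-11 years)" = c(7, 11),
                "Thicket (12-21 years)" = c(12, 21), "Pole (22-45 years)" = c(22, 45),
                "Mature (46+ years)" = c(46, 80))
  for (b in names(bands)) {
    sel <- age_class == b
    if (any(sel))
      age_years[sel] <- round(stats::runif(sum(sel), bands[[b]][1], bands[[b]][2]))
  }

  # log-normal area with the requested arithmetic mean/SD
  sdlog <- sqrt(log(1 + (config$area_sd / config$mean_area)^2))
  meanlog <- log(config$mean_area) - sdlog^2 / 2
  area <- stats::rlnorm(n, meanlog, sdlog)

  comp <- data.frame(
    compartment_id = sprintf("C%05d", seq_len(n)),
    management = mgmt, age_class = age_class, age_years = age_years,
    area_ha = area, stringsAsFactors = FALSE)

  simp <- simplify_categories(mgmt, age_class)
  hb <- config$height_by_age
  truth <- data.frame(
    compartment_id = comp$compartment_id,
    age_simple = simp$age_simple,
    height_true = vapply(age_class, function(a) hb[[a]][1], numeric(1)),
    shrub_true = unname(config$shrub_level_by_age[age_class]),
    gap_true = unname(config$gap_prob_by_age[age_class]),
    stringsAsFactors = FALSE)
  attr(truth, "dominant_driver") <- "age_class"

  structure(list(compartments = comp, truth = truth, config = config),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("<synthetic_landscape> %d compartments, mean area %.2f ha (seed %d)\n",
              nrow(x$compartments),
              if (nrow(x$compartments)) mean(x$compartments$area_ha) else NA_real_,
              x$config$seed))
  invisible(x)
}
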