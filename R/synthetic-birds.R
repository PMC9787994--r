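#' Build a synthetic breeding-bird species pool
#'
#' Draws a pool of species with ecological traits (body mass, migratory
#' status, nest site, diet, foraging strata), a detectability constant, a
#' baseline log abundance, and log-linear response coefficients on habitat
#' covariates. Each species is assigned a preferred simplified age class and
#' receives a positive coefficient (`age_effect`) on that class's indicator,
#' so stand age class is the dominant driver of community composition; small
#' random coefficients on the continuous structural covariates add secondary
#' structure. Trait distributions are tilted by the preferred age class
#' (open/early-stage specialists tend to ground nests and ground foraging,
#' mature-stand specialists to canopy/cavity sites), so communities in
#' different age classes occupy different regions of trait space.
#'
#' These are configurable defaults emulating the richness scale and survey
#' design of a lowland plantation avifauna, not estimates of any real
#' species' parameters.
#'
#' @param n_species Number of species (default 48).
#' @param trait_config Optional list overriding defaults: `age_effect`
#'   (log-scale preference for the preferred age class, default 2),
#'   `struct_coef_sd` (SD of continuous-covariate coefficients, default
#'   0.15), `detectability_range` (default `c(0.3, 0.9)`),
#'   `baseline_mean`/`baseline_sd` (log-abundance, default -2.4 / 1.6,
#'   matching a survey scale of roughly 0.1 birds per species per
#'   compartment with a commonest-to-mean abundance ratio near 8),
#'   `mass_meanlog`/`mass_sdlog` (default log(25) / 0.8).
#' @param seed Integer seed.
#' @return A list of class `species_pool`: `species` (trait and
#'   detectability data frame), `coefficients` (species x covariate matrix
#'   of log-linear effects), and `covariates` (covariate names).
#' @export
make_species_pool <- function(n_species = 48, trait_config = list(), seed = 1L) {
  if (n_species < 1) stop("n_species must be >= 1")
  cfg <- utils::modifyList(list(
    age_effect = 2, struct_coef_sd = 0.15,
    detectability_range = c(0.3, 0.9),
    baseline_mean = -2.4, baseline_sd = 1.6,
    mass_meanlog = log(25), mass_sdlog = 0.8), trait_config)
  set.seed(seed)
  n <- as.integer(n_species)
  ages <- simplified_age_levels
  # successional richness gradient: open/early and mature stages host the
  # most specialists, the intermediate thicket/pole stage the fewest
  pref <- sample(ages, n, replace = TRUE,
                 prob = c(0.25, 0.10, 0.22, 0.15, 0.28))

  tilt <- function(levels, favoured, w = 8) {
    # sample one level with the favoured level upweighted
    vapply(favoured, function(f) {
      p <- rep(1, length(levels)); p[levels == f] <- w
      sample(levels, 1L, prob = p)
    }, character(1))
  }
  nest_fav <- c("Restock/pre-thicket" = "ground", "Thicket/pole" = "shrub",
                "Mature" = "cavity", "Mixed" = "canopy",
                "Not applicable" = "ground")[pref]
  strata_fav <- c("Restock/pre-thicket" = "ground", "Thicket/pole" = "understorey",
                  "Mature" = "canopy", "Mixed" = "canopy",
                  "Not applicable" = "ground")[pref]
  # body size grades along succession: canopy birds of older stands are
  # larger on average than open/scrub specialists
  mass_shift <- c("Not applicable" = -0.3, "Restock/pre-thicket" = -0.15,
                  "Thicket/pole" = 0.1, "Mature" = 0.35, "Mixed" = 0.1)[pref]
  species <- data.frame(
    species_id = sprintf("sp%02d", seq_len(n)),
    body_mass_g = stats::rlnorm(n, cfg$mass_meanlog + mass_shift,
                                cfg$mass_sdlog),
    migratory = sample(c("resident", "short-distance", "long-distance"), n,
                       replace = TRUE, prob = c(0.5, 0.25, 0.25)),
    nest_site = tilt(c("ground", "shrub", "canopy", "cavity"), nest_fav),
    diet = sample(c("invertebrates", "seeds", "omnivore", "vertebrates"), n,
                  replace = TRUE, prob = c(0.5, 0.2, 0.25, 0.05)),
    foraging_strata = tilt(c("ground", "understorey", "canopy", "aerial"),
                           strata_fav),
    detectability = stats::runif(n, cfg$detectability_range[1],
                                 cfg$detectability_range[2]),
    baseline_log_abundance = stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd),
    preferred_age = pref,
    stringsAsFactors = FALSE)

  covariates <- c(paste0("age:", ages), "height_true", "shrub_true", "gap_true")
  coef <- matrix(0, n, length(covariates),
                 dimnames = list(species$species_id, covariates))
  # habitat selection is two-sided: +age_effect in the preferred class and a
  # penalty growing with successional distance elsewhere, so specialists are
  # effectively absent far from their stage; mixed-age stands are a
  # generalist refuge (coefficient 0 for everyone not preferring them)
  pos <- c("Not applicable" = 0, "Restock/pre-thicket" = 1,
           "Thicket/pole" = 2, "Mature" = 3)
  for (a in ages) {
    cv <- paste0("age:", a)
    val <- ifelse(pref == a, cfg$age_effect,
                  ifelse(a == "Mixed" | pref == "Mixed", 0,
                         -cfg$age_effect * pmin(abs(pos[pref] - pos[a]), 2) / 2))
    coef[, cv] <- val
  }
  coef[, c("height_true", "shrub_true", "gap_true")] <-
    stats::rnorm(3 * n, 0, cfg$struct_coef_sd)

  structure(list(species = species, coefficients = coef,
                 covariates = covariates),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("<species_pool> %d species; detectability %.2f-%.2f; covariates: %s\n",
              nrow(x$species), min(x$species$detectability),
              max(x$species$detectability),
              paste(x$covariates, collapse = ", ")))
  invisible(x)
}

# Covariate design matrix implied by the truth table, matching pool covariates
truth_design <- function(truth, covariates) {
  X <- matrix(0, nrow(truth), length(covariates),
              dimnames = list(NULL, covariates))
  for (cv in covariates) {
    if (startsWith(cv, "age:")) {
      lev <- sub("^age:", "", cv)
      X[, cv] <- as.numeric(truth$age_simple == lev)
    } else if (cv %in% names(truth)) {
      X[, cv] <- truth[[cv]]
    } else {
      stop(sprintf("response coefficient names unknown covariate '%s'", cv))
    }
  }
  X
}

#' Simulate a two-visit breeding-bird survey
#'
#' For every species and compartment the true count is Poisson with log mean
#' `baseline + sum(coefficient * covariate)`, covariates taken from the
#' landscape truth table (continuous covariates are standardised across
#' compartments first). Each of the two visits then records a Binomial
#' thinning of the true count with the species' detectability, the
#' generative model under which "maximum of two visits divided by the
#' detectability constant" is a sensible abundance index.
#'
#' @param landscape A `synthetic_landscape` (or its `truth` data frame).
#' @param pool A [make_species_pool] object.
#' @param seed Integer seed.
#' @param keep_zeros Keep zero-count records? Default `FALSE` (survey files
#'   record detections only; downstream code treats absence as zero).
#' @param area_offset Scale expected counts by compartment area relative to
#'   the landscape mean (default `TRUE`): a compartment twice the size
#'   holds twice the birds, which is what makes total group area a genuine
#'   survey-effort control. Set `FALSE` for the pure log-linear law with
#'   every compartment an equal-effort sample.
#' @return A list of class `bird_survey`: `survey` (long data frame:
#'   `compartment_id`, `species_id`, `visit`, `count`), `detectability`
#'   (data frame `species_id`, `detectability`), `traits` (trait table),
#'   and `expected` (true expected counts, species x compartment; part of
#'   the synthetic truth, not a pipeline input).
#' @export
simulate_bird_counts <- function(landscape, pool, seed = 1L,
                                 keep_zeros = FALSE, area_offset = TRUE) {
  is_land <- inherits(landscape, "synthetic_landscape")
  truth <- if (is_land) landscape$truth else landscape
  stopifnot(inherits(pool, "species_pool"))
  set.seed(seed)
  X <- truth_design(truth, pool$covariates)
  cont <- !startsWith(colnames(X), "age:")
  X[, cont] <- scale(X[, cont])
  X[is.nan(X)] <- 0 # zero-variance covariate in tiny landscapes
  eta <- X %*% t(pool$coefficients) # compartments x species
  lambda <- exp(sweep(eta, 2L, pool$species$baseline_log_abundance, "+"))
  if (area_offset && is_land) {
    a <- landscape$compartments$area_ha
    lambda <- lambda * (a / mean(a))
  }

  nc <- nrow(truth); ns <- nrow(pool$species)
  true_count <- matrix(stats::rpois(nc * ns, lambda), nc, ns)
  det <- pool$species$detectability
  v1 <- matrix(stats::rbinom(nc * ns, as.vector(true_count),
                             rep(det, each = nc)), nc, ns)
  v2 <- matrix(stats::rbinom(nc * ns, as.vector(true_count),
                             rep(det, each = nc)), nc, ns)

  long <- data.frame(
    compartment_id = rep(truth$compartment_id, times = 2L * ns),
    species_id = rep(rep(pool$species$species_id, each = nc), times = 2L),
    visit = rep(c(1L, 2L), each = nc * ns),
    count = c(as.vector(v1), as.vector(v2)),
    stringsAsFactors = FALSE)
  if (!keep_zeros) long <- long[long$count > 0, , drop = FALSE]
  rownames(long) <- NULL

  structure(list(
    survey = long,
    detectability = data.frame(species_id = pool$species$species_id,
                               detectability = det, stringsAsFactors = FALSE),
    traits = pool$species[, c("species_id", "body_mass_g", "migratory",
                              "nest_site", "diet", "foraging_strata")],
    expected = t(lambda)), class = "bird_survey")
}

#' @export
print.bird_survey <- function(x, ...) {
  cat(sprintf("<bird_survey> %d detection record(s), %d species, 2 visits\n",
              nrow(x$survey), nrow(x$detectability)))
  invisible(x)
}
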