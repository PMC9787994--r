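# Management-type and age-class vocabulary of the compartment database.
# Detailed categories are what the management records hold; simplified
# categories are the levels used in the statistical analysis.

management_map <- c(
  "Corsican pine monoculture"    = "Conifer",
  "Scots pine monoculture"       = "Conifer",
  "Douglas fir monoculture"      = "Conifer",
  "Other conifer monoculture"    = "Conifer",
  "Birch monoculture"            = "Broadleaved",
  "Other broadleaved monoculture" = "Broadleaved",
  "Mixture (mainly conifer)"     = "Mixture",
  "Mixture (mainly broadleaved)" = "Mixture",
  "Open"                         = "Open/other",
  "Open with trees"              = "Open/other",
  "Other"                        = "Open/other",
  "Felled"                       = "Open/other"
)

age_class_map <- c(
  "Restock (0-6 years)"    = "Restock/pre-thicket",
  "Pre-thicket (7-11 years)" = "Restock/pre-thicket",
  "Thicket (12-21 years)"  = "Thicket/pole",
  "Pole (22-45 years)"     = "Thicket/pole",
  "Mature (46+ years)"     = "Mature",
  "Mixed ages"             = "Mixed",
  "Not applicable"         = "Not applicable"
)

simplified_management_levels <- c("Conifer", "Broadleaved", "Mixture", "Open/other")
simplified_age_levels <- c("Restock/pre-thicket", "Thicket/pole", "Mature",
                           "Mixed", "Not applicable")

#' Age class from stand age
#'
#' Maps the age of the trees (years since planting) to the detailed age-class
#' band used in the management database: restock 0-6, pre-thicket 7-11,
#' thicket 12-21, pole 22-45, mature 46+.
#'
#' @param age_years Numeric vector of stand ages in years.
#' @return Character vector of detailed age-class labels.
#' @export
age_class_from_years <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) stop("stand age cannot be negative")
  cut(age_years,
      breaks = c(-Inf, 6, 11, 21, 45, Inf),
      labels = c("Restock (0-6 years)", "Pre-thicket (7-11 years)",
                 "Thicket (12-21 years)", "Pole (22-45 years)",
                 "Mature (46+ years)"),
      right = TRUE) |> as.character()
}

#' Simplify management and age-class categories
#'
#' Collapses the detailed management-database categories into the simplified
#' analysis levels: the four pine/fir/other conifer monocultures become
#' "Conifer", the broadleaved monocultures "Broadleaved", both mixture types
#' "Mixture", and open/open-with-trees/other/felled become "Open/other" with
#' age class forced to "Not applicable". Detailed age bands collapse to
#' restock/pre-thicket, thicket/pole, mature, and mixed. Stand age in years
#' may be given instead of a detailed age class.
#'
#' @param management Character vector of detailed management types.
#' @param age_class Character vector of detailed age classes (optional if
#'   `age_years` given).
#' @param age_years Numeric vector of stand ages (years), used where
#'   `age_class` is missing.
#' @return Data frame with columns `management_simple` and `age_simple`.
#' @examples
#' simplify_categories("Scots pine monoculture", age_years = 15)
#' simplify_categories("Felled")
#' @export
simplify_categories <- function(management, age_class = NULL, age_years = NULL) {
  management <- as.character(management)
  bad <- setdiff(unique(management), names(management_map))
  if (length(bad))
    stop(sprintf("unknown management type(s): %s\nvalid values: %s",
                 paste(bad, collapse = ", "),
                 paste(names(management_map), collapse = "; ")))
  ms <- unname(management_map[management])

  n <- length(management)
  if (is.null(age_class)) age_class <- rep(NA_character_, n)
  age_class <- as.character(age_class)
  if (!is.null(age_years)) {
    fill <- is.na(age_class) & !is.na(age_years)
    age_class[fill] <- age_class_from_years(age_years[fill])
  }
  # open/other management has no meaningful stand age
  age_class[ms == "Open/other"] <- "Not applicable"
  bad <- setdiff(unique(age_class[!is.na(age_class)]), names(age_class_map))
  if (length(bad))
    stop(sprintf("unknown age class(es): %s\nvalid values: %s",
                 paste(bad, collapse = ", "),
                 paste(names(age_class_map), collapse = "; ")))
  if (anyNA(age_class))
    stop("age class missing for non-open compartment(s); supply `age_class` or `age_years`")
  as <- unname(age_class_map[age_class])
  data.frame(management_simple = ms, age_simple = as, stringsAsFactors = FALSE)
}
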