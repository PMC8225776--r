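# Controlled vocabularies shared across the pipeline. Kept as plain
# character vectors (not factors) so that CSV round-trips are exact.

#' Controlled vocabularies used by the pipeline
#'
#' Accessors for the enumerations the pipeline validates against:
#' Red List categories, taxonomic classes, reporting groups (reptiles and
#' amphibians are pooled as herpetofauna), threat mechanisms, curation
#' evidence cues and severity grades.
#'
#' @return A character vector of allowed tokens.
#' @examples
#' rl_categories()
#' severity_levels()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
rl_categories <- function() c("EX", "EW", "CR", "EN", "VU", "NT", "LC", "DD")

#' @rdname vocabularies
#' @export
taxon_classes <- function() {
  c("reptile", "amphibian", "bird", "mammal", "plant", "invertebrate")
}

#' @rdname vocabularies
#' @export
report_groups <- function() {
  c("plant", "herpetofauna", "bird", "invertebrate", "mammal")
}

#' @rdname vocabularies
#' @export
threat_mechanisms <- function() {
  c("predation", "disturbance", "disease_risk", "competition", "hybridization")
}

#' @rdname vocabularies
#' @export
curation_cues <- function() {
  c("direct_predation", "consumption", "habitat_disturbance", "nest_digging",
    "disease", "competition", "hybridization", "overlap_only",
    "hunting_catalyzed", "domestic_not_free_ranging")
}

#' @rdname vocabularies
#' @export
severity_levels <- function() c("major", "minor", "potential")

#' @rdname vocabularies
#' @export
range_statuses <- function() c("native", "nonnative", "potential", "absent")

# Cues that constitute direct evidence of impact (as opposed to inferred
# range overlap or out-of-scope processes).
direct_impact_cues <- function() {
  c("direct_predation", "consumption", "habitat_disturbance", "nest_digging",
    "disease", "competition", "hybridization")
}

# Cues that alone take a record out of the analysis ("noted but not
# included"): hunting catalyzed by the focal species' presence, and
# domestic animals not described as free-ranging.
exclusion_cues <- function() c("hunting_catalyzed", "domestic_not_free_ranging")

#' Map a taxonomic class to its reporting group
#'
#' Reptiles and amphibians are pooled as \code{"herpetofauna"}; all other
#' classes report under their own name.
#'
#' @param taxon_class Character vector of taxonomic classes
#'   (see [taxon_classes()]).
#' @return Character vector of reporting groups (see [report_groups()]).
#' @examples
#' taxon_group(c("reptile", "plant", "amphibian"))
#' @export
taxon_group <- function(taxon_class) {
  ifelse(taxon_class %in% c("reptile", "amphibian"), "herpetofauna", taxon_class)
}

# Round half away from zero (paper-style percentage rounding, where
# base R's round() would round half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
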