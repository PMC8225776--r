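# Rule engine turning flagged records plus curation evidence into
# per-taxon threat annotations: a severity grade (major / minor /
# potential) and one or more threat mechanisms.

#' Apply manual-review verdicts to the flagged queue
#'
#' Removes false positives and out-of-scope records from the screen
#' output, reproducing the flag-then-curate workflow: records whose
#' curated verdict is `false_positive` are dropped, as are records
#' whose only evidence cues are hunting catalyzed by the focal species
#' or non-free-ranging domestic animals (such threats are noted but not
#' analysed). Everything else is confirmed with its cues and optional
#' stated severity grade.
#'
#' @param flagged Screen results from [screen_corpus()].
#' @param curation Curation tibble from [read_curation()].
#' @param mode `"strict"` (default): a flagged taxon without a curation
#'   entry is an error naming the unreviewed ids. `"lenient"`: such
#'   taxa are dropped with a warning.
#' @return Tibble of confirmed records: `taxon_id`, `cues`
#'   (list-column) and `stated_grade`.
#' @export
apply_review <- function(flagged, curation, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  ids <- flagged$taxon_id
  missing <- setdiff(ids, curation$taxon_id)
  if (length(missing)) {
    if (mode == "strict") {
      stop("unreviewed flagged taxa (no curation entry): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    warning("dropping ", length(missing),
            " flagged taxa without curation entries: ",
            paste(missing, collapse = ", "), call. = FALSE)
    ids <- setdiff(ids, missing)
  }
  cur <- curation[match(ids, curation$taxon_id), ]
  confirmed <- cur$verdict == "confirm"
  # Records whose evidence is exclusively out-of-scope cues are removed.
  out_of_scope <- vapply(cur$cues, function(cs) {
    length(cs) > 0 && all(cs %in% exclusion_cues())
  }, logical(1))
  keep <- confirmed & !out_of_scope
  tibble::tibble(
    taxon_id = cur$taxon_id[keep],
    cues = cur$cues[keep],
    stated_grade = cur$stated_grade[keep]
  )
}

#' Grade the severity of a confirmed threat
#'
#' Severity combines the narrative evidence with the taxon's Red List
#' category, in strict rule order:
#' \enumerate{
#'   \item a curator-stated grade always wins (sufficient narrative
#'     detail overrides any default);
#'   \item evidence consisting solely of range overlap (`overlap_only`)
#'     grades `potential` — the threat was inferred, not documented;
#'   \item EX, EW and CR taxa grade `major` (any threat mention to a
#'     taxon at or past the brink is treated as major);
#'   \item LC taxa grade `minor` by default, as do
#'   \item NT taxa;
#'   \item EN, VU and DD taxa grade `major` when any direct-impact cue
#'     is present, otherwise `potential`.
#' }
#'
#' @param category Red List category (see [rl_categories()]).
#' @param cues Character vector of curation cues for this taxon.
#' @param stated_grade Optional curator-stated grade (`NA` when unset).
#' @return One of `"major"`, `"minor"`, `"potential"`.
#' @examples
#' classify_severity("CR", "habitat_disturbance")        # "major"
#' classify_severity("LC", "direct_predation")           # "minor"
#' classify_severity("EN", "overlap_only")               # "potential"
#' classify_severity("CR", "habitat_disturbance", "minor")
#' @export
classify_severity <- function(category, cues, stated_grade = NA_character_) {
  stopifnot(length(category) == 1, category %in% rl_categories())
  if (!is.na(stated_grade)) {
    stopifnot(stated_grade %in% severity_levels())
    return(stated_grade)
  }
  if (length(cues) > 0 && setequal(cues, "overlap_only")) return("potential")
  if (category %in% c("EX", "EW", "CR")) return("major")
  if (category %in% c("LC", "NT")) return("minor")
  # EN / VU / DD: documented direct impact escalates, otherwise the
  # threat remains potential.
  if (any(cues %in% direct_impact_cues())) "major" else "potential"
}

#' Map evidence cues to threat mechanisms
#'
#' Cues map one-to-one onto mechanisms (direct_predation to predation,
#' habitat_disturbance to disturbance, disease to disease_risk,
#' competition and hybridization to themselves), with two compound
#' rules reflecting the focal species' dual predator/engineer role:
#' consumption of a plant counts as both predation and disturbance
#' (the plant is eaten and the vegetation structure altered), and nest
#' digging for reptiles, amphibians and ground-nesting birds counts as
#' both predation and disturbance (direct mortality plus destruction of
#' the nest site). Evidence that is range overlap only defaults to
#' disturbance. Out-of-scope cues contribute no mechanism.
#'
#' @param taxon_class The taxon's class (see [taxon_classes()]).
#' @param cues Non-empty character vector of curation cues.
#' @return Character vector of mechanisms, a non-empty subset of
#'   [threat_mechanisms()], in canonical order.
#' @examples
#' tag_threat_types("plant", "consumption")     # predation + disturbance
#' tag_threat_types("reptile", "nest_digging")  # predation + disturbance
#' tag_threat_types("mammal", "hybridization")
#' @export
tag_threat_types <- function(taxon_class, cues) {
  stopifnot(length(taxon_class) == 1, taxon_class %in% taxon_classes(),
            length(cues) > 0, all(cues %in% curation_cues()))
  mech <- character(0)
  if ("direct_predation" %in% cues) mech <- c(mech, "predation")
  if ("consumption" %in% cues) {
    mech <- c(mech, "predation",
              if (taxon_class == "plant") "disturbance")
  }
  if ("habitat_disturbance" %in% cues) mech <- c(mech, "disturbance")
  if ("nest_digging" %in% cues) {
    mech <- c(mech,
              if (taxon_class %in% c("reptile", "amphibian", "bird"))
                c("predation", "disturbance")
              else "disturbance")
  }
  if ("disease" %in% cues) mech <- c(mech, "disease_risk")
  if ("competition" %in% cues) mech <- c(mech, "competition")
  if ("hybridization" %in% cues) mech <- c(mech, "hybridization")
  if (length(mech) == 0 && "overlap_only" %in% cues) mech <- "disturbance"
  mech <- intersect(threat_mechanisms(), mech)  # canonical order, unique
  if (length(mech) == 0) {
    stop("no threat mechanism derivable from cues: ",
         paste(cues, collapse = ", "), call. = FALSE)
  }
  mech
}

#' Annotate confirmed records with severity and mechanisms
#'
#' Joins the confirmed review output back to the corpus and applies
#' [classify_severity()] and [tag_threat_types()] per taxon.
#'
#' @param records Validated corpus tibble.
#' @param confirmed Output of [apply_review()].
#' @return Annotation tibble: `taxon_id`, `pig_threatened` (all
#'   `TRUE`), `severity`, `mechanisms` (list-column), `cues`
#'   (list-column).
#' @export
annotate_threats <- function(records, confirmed) {
  idx <- match(confirmed$taxon_id, records$taxon_id)
  if (anyNA(idx)) {
    stop("confirmed taxa missing from corpus: ",
         paste(confirmed$taxon_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    taxon_id = confirmed$taxon_id,
    pig_threatened = TRUE,
    severity = mapply(classify_severity,
                      records$category[idx], confirmed$cues,
                      confirmed$stated_grade),
    mechanisms = mapply(tag_threat_types,
                        records$taxon_class[idx], confirmed$cues,
                        SIMPLIFY = FALSE),
    cues = confirmed$cues
  )
}
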