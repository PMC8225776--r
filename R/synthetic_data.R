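# Seeded generator of Red-List-style corpora with ground truth. The
# generated corpus emulates the statistical structure of a real threat
# screen: mixed taxonomic groups, a minority of narratives mentioning
# the focal species through the keyword forms, distractor tokens that
# trip the wildcard patterns (pigeon, pigment, pigtail, hogweed),
# out-of-scope mentions (hunting catalyzed, penned domestic animals),
# island endemics cross-listed under governing continental units, and
# taxa outside the focal species' range.

#' Simulation configuration
#'
#' Defaults define the study conditions: a plant-heavy group mix, a
#' Red-List-like category marginal, per-group threat rates giving a
#' minority of threatened taxa, the 59/21/20 major/minor/potential
#' severity split, per-class cue profiles dominated by disturbance and
#' predation, a 5% distractor rate among unthreatened narratives, 50%
#' continental cross-listing of island endemics and a 35%
#' island-endemic fraction.
#'
#' @param n_taxa Number of taxa to generate.
#' @param seed Integer seed; one pseudo-random stream drives the whole
#'   corpus.
#' @param group_mix Named probability vector over the six taxonomic
#'   classes.
#' @param category_mix Named probability vector over the eight Red List
#'   categories.
#' @param threat_rate_by_group Named per-class probability that an
#'   in-range taxon is genuinely threatened by the focal species.
#' @param severity_mix Named probability vector (major, minor,
#'   potential) for the ground-truth severity of threatened taxa.
#' @param mechanism_profiles Per-class list with elements `sets` (list
#'   of cue vectors) and `probs`.
#' @param distractor_rate Probability an unthreatened narrative carries
#'   a wildcard-trapping token.
#' @param cross_listing_rate Probability an island endemic also lists
#'   its governing continental unit.
#' @param island_endemic_rate Probability a taxon is an island endemic.
#' @param exclusion_cue_rate Probability a pig-mentioning narrative is
#'   an out-of-scope mention (hunting catalyzed / penned domestic).
#' @param outside_range_rate Probability a non-endemic taxon occurs
#'   only in units where the focal species is absent.
#' @param potential_only_rate Probability a non-endemic taxon occurs
#'   only in potentially-occupied units.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 500,
                       seed = 1,
                       group_mix = c(plant = 0.35, bird = 0.15,
                                     reptile = 0.10, amphibian = 0.10,
                                     mammal = 0.12, invertebrate = 0.18),
                       category_mix = c(EX = 0.01, EW = 0.005, CR = 0.08,
                                        EN = 0.07, VU = 0.10, NT = 0.12,
                                        LC = 0.46, DD = 0.155),
                       threat_rate_by_group = c(plant = 0.20, reptile = 0.18,
                                                amphibian = 0.15, bird = 0.15,
                                                invertebrate = 0.12,
                                                mammal = 0.08),
                       severity_mix = c(major = 0.59, minor = 0.21,
                                        potential = 0.20),
                       mechanism_profiles = default_mechanism_profiles(),
                       distractor_rate = 0.05,
                       cross_listing_rate = 0.5,
                       island_endemic_rate = 0.35,
                       exclusion_cue_rate = 0.02,
                       outside_range_rate = 0.04,
                       potential_only_rate = 0.03) {
  check_prob_vector <- function(x, levels, what) {
    if (!setequal(names(x), levels)) {
      stop("config error: ", what, " must be named over: ",
           paste(levels, collapse = ", "), call. = FALSE)
    }
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      stop("config error: ", what, " must be a probability vector summing to 1",
           call. = FALSE)
    }
  }
  check_prob_vector(group_mix, taxon_classes(), "group_mix")
  check_prob_vector(category_mix, rl_categories(), "category_mix")
  check_prob_vector(severity_mix, severity_levels(), "severity_mix")
  if (!setequal(names(threat_rate_by_group), taxon_classes())) {
    stop("config error: threat_rate_by_group must cover all classes",
         call. = FALSE)
  }
  rates <- c(threat_rate_by_group, distractor_rate, cross_listing_rate,
             island_endemic_rate, exclusion_cue_rate, outside_range_rate,
             potential_only_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("config error: rates must lie in [0, 1]", call. = FALSE)
  }
  for (cls in taxon_classes()) {
    prof <- mechanism_profiles[[cls]]
    if (is.null(prof) || abs(sum(prof$probs) - 1) > 1e-9 ||
        length(prof$sets) != length(prof$probs)) {
      stop("config error: invalid mechanism profile for class ", cls,
           call. = FALSE)
    }
  }
  structure(list(
    n_taxa = n_taxa, seed = as.integer(seed), group_mix = group_mix,
    category_mix = category_mix, threat_rate_by_group = threat_rate_by_group,
    severity_mix = severity_mix, mechanism_profiles = mechanism_profiles,
    distractor_rate = distractor_rate, cross_listing_rate = cross_listing_rate,
    island_endemic_rate = island_endemic_rate,
    exclusion_cue_rate = exclusion_cue_rate,
    outside_range_rate = outside_range_rate,
    potential_only_rate = potential_only_rate
  ), class = "sim_config")
}

#' Default per-class cue profiles
#'
#' Each class draws its evidence-cue set from a small menu weighted so
#' that disturbance and predation dominate (rooting and consumption for
#' plants, nest digging and direct predation for herpetofauna and
#' birds) with rarer disease, competition, hybridization and
#' overlap-only evidence.
#'
#' @return Named list, one profile (`sets`, `probs`) per class.
#' @export
default_mechanism_profiles <- function() {
  herp <- list(
    sets = list("nest_digging", "direct_predation", "habitat_disturbance",
                "overlap_only", "disease"),
    probs = c(0.35, 0.30, 0.15, 0.15, 0.05))
  list(
    plant = list(
      sets = list("consumption", "habitat_disturbance",
                  c("consumption", "competition"), "overlap_only"),
      probs = c(0.55, 0.25, 0.05, 0.15)),
    reptile = herp,
    amphibian = herp,
    bird = list(
      sets = list("nest_digging", "direct_predation", "habitat_disturbance",
                  "overlap_only", "competition"),
      probs = c(0.30, 0.30, 0.20, 0.15, 0.05)),
    mammal = list(
      sets = list("competition", "disease", "hybridization",
                  "direct_predation", "habitat_disturbance", "overlap_only"),
      probs = c(0.25, 0.20, 0.15, 0.20, 0.10, 0.10)),
    invertebrate = list(
      sets = list("direct_predation", "habitat_disturbance", "overlap_only"),
      probs = c(0.40, 0.40, 0.20))
  )
}

# Narrative templates. Threat and out-of-scope templates each embed at
# least one keyword form; benign templates embed none; distractor
# templates trip a wildcard prefix without any literal.
threat_templates <- function() {
  list(
    consumption = c(
      "Browsing and consumption of seedlings by feral pigs suppresses regeneration.",
      "Seedlings and fruit are consumed by wild pigs throughout the range."),
    direct_predation = c(
      "Predation by wild boars on juveniles has been documented.",
      "Feral hogs prey directly upon adults and juveniles."),
    habitat_disturbance = c(
      "Rooting by feral hogs degrades the understory habitat.",
      "Soil disturbance from pig rooting alters habitat structure."),
    nest_digging = c(
      "Nests are dug up by feral pigs during the incubation period.",
      "Wild pigs excavate nesting sites, destroying eggs and hatchlings."),
    disease = c(
      "Disease spillover from wild swine populations is an emerging concern.",
      "Pathogen transmission from feral pigs threatens the remaining population."),
    competition = c(
      "Competition with Sus scrofa for mast resources reduces food availability.",
      "Wild boar compete for forage resources within the range."),
    hybridization = c(
      "Hybridization with wild boar threatens genetic integrity.",
      "Introgression from free-ranging pigs erodes the native gene pool."),
    overlap_only = c(
      "The range overlaps areas where feral pigs are established.",
      "Wild pigs occur throughout the range, although direct impacts are undocumented.")
  )
}

exclusion_templates <- function() {
  list(
    hunting_catalyzed = c(
      "Hunters drawn to the area by wild pigs also take this species opportunistically.",
      "Hunting pressure catalyzed by the presence of feral hogs affects the population."),
    domestic_not_free_ranging = c(
      "Penned domestic pigs occur near the range but are not free-ranging.",
      "Reported threats concern farmed swine kept in enclosures, not free-ranging animals.")
  )
}

benign_templates <- function() {
  c("Habitat loss from agriculture and logging is the principal threat.",
    "Urban expansion and road mortality threaten remaining populations.",
    "Invasive rats and cats depress recruitment at most sites.",
    "Climate-driven drought has reduced breeding success in recent decades.",
    "Collection for the horticultural trade has reduced wild populations.",
    "Wildfire and grazing by goats degrade the remaining habitat.")
}

distractor_templates <- function() {
  c("Predation by peregrine falcons and feral pigeons is reported near cliffs.",
    "Loss of pigment diversity has been noted in isolated populations.",
    "Trapping of pigtail macaques disturbs the forest canopy.",
    "Giant hogweed invasion alters the riparian vegetation.")
}

family_pools <- function() {
  list(
    plant = c("Campanulaceae", "Arecaceae", "Asteraceae", "Orchidaceae",
              "Fagaceae"),
    reptile = c("Scincidae", "Testudinidae", "Gekkonidae"),
    amphibian = c("Myobatrachidae", "Hylidae", "Ranidae"),
    bird = c("Procellariidae", "Rallidae", "Columbidae", "Meliphagidae"),
    mammal = c("Suidae", "Muridae", "Pteropodidae"),
    invertebrate = c("Helicidae", "Achatinellidae", "Carabidae")
  )
}

# Governing continental unit for each island region (none is in the
# focal species' native range, so cross-listing never fabricates
# native-range overlap).
governing_units <- function() {
  c("Polynesia" = "NAM-1", "Micronesia/Melanesia" = "AUS-1",
    "Galapagos" = "SAM-1", "New Zealand" = "AUS-2", "Caribbean" = "NAM-2",
    "Madagascar" = "AFR-3", "Indian Ocean Islands" = "AFR-3",
    "Atlantic Islands" = "CAM-1")
}

#' Generate a synthetic Red-List-style corpus with ground truth
#'
#' Draws a seeded corpus over the shipped 17-region configuration and
#' the default focal-species range map, together with the oracle
#' curation file (confirm with cues for genuine threats, out-of-scope
#' cues for hunting/domestic mentions, false_positive for distractor
#' hits) and a per-taxon ground-truth table. Per taxon the stream is
#' consumed in a fixed order — class, family, category,
#' placement/units, threat flag, out-of-scope flag, cues and severity,
#' narrative — so identical configurations give identical corpora.
#'
#' @param config A [sim_config()].
#' @return Object of class `threat_sim`: list with `records`,
#'   `pig_range`, `region_table`, `curation`, `truth` and `config`.
#'   `truth` has one row per taxon: `threatened`, `severity`,
#'   `mechanisms`, `cues`, `stated_grade`, `regions` (post
#'   cross-listing pruning), `island_endemic`, `in_native`,
#'   `in_nonnative`, `in_potential_only`, `retained`.
#' @export
generate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rt <- default_region_table()
  pr <- default_pig_range()
  islands <- unique(rt$region[rt$system == "island"])
  continents <- unique(rt$region[rt$system == "continental"])
  gov <- governing_units()
  fams <- family_pools()
  t_templ <- threat_templates()
  x_templ <- exclusion_templates()
  benign <- benign_templates()
  distract <- distractor_templates()
  potential_units <- pr$unit[pr$status == "potential"]
  n <- config$n_taxa

  rec <- vector("list", n)
  tru <- vector("list", n)
  cur <- vector("list", n)

  for (i in seq_len(n)) {
    id <- sprintf("T%05d", i)
    cls <- sample(names(config$group_mix), 1, prob = config$group_mix)
    family <- sample(fams[[cls]], 1)
    category <- sample(names(config$category_mix), 1,
                       prob = config$category_mix)

    # Placement: island endemic, out-of-range, potential-only, or
    # ordinary continental occurrence.
    endemic_to <- NA_character_
    if (runif(1) < config$island_endemic_rate) {
      endemic_to <- sample(islands, 1)
      units <- sample(rt$unit[rt$region == endemic_to], 1)
      if (runif(1) < config$cross_listing_rate) {
        units <- c(units, unname(gov[endemic_to]))
      }
    } else {
      v <- runif(1)
      if (v < config$outside_range_rate) {
        units <- sample(pr$unit[pr$status == "absent"], 1)
      } else if (v < config$outside_range_rate + config$potential_only_rate) {
        units <- sample(potential_units, 1)
      } else {
        regions <- sample(continents, sample(1:2, 1))
        units <- unlist(lapply(regions, function(r) {
          sample(rt$unit[rt$region == r], sample(1:2, 1))
        }))
      }
    }
    units <- unique(units)
    status <- pig_status(pr, units)
    eligible <- any(status %in% c("native", "nonnative"))

    mentions_pig <- runif(1) < config$threat_rate_by_group[[cls]] && eligible
    out_of_scope <- mentions_pig && runif(1) < config$exclusion_cue_rate

    threatened <- FALSE
    severity <- NA_character_
    mechanisms <- character(0)
    cues <- character(0)
    stated_grade <- NA_character_
    curation_row <- NULL

    if (mentions_pig && !out_of_scope) {
      threatened <- TRUE
      prof <- config$mechanism_profiles[[cls]]
      cues <- prof$sets[[sample.int(length(prof$sets), 1, prob = prof$probs)]]
      severity <- sample(names(config$severity_mix), 1,
                         prob = config$severity_mix)
      if (!identical(classify_severity(category, cues), severity)) {
        stated_grade <- severity
      }
      mechanisms <- tag_threat_types(cls, cues)
      pool <- t_templ[[cues[1]]]
      narrative <- pool[sample.int(length(pool), 1)]
      curation_row <- list(taxon_id = id, verdict = "confirm",
                           cues = list(cues), stated_grade = stated_grade)
    } else if (out_of_scope) {
      cue <- sample(names(x_templ), 1)
      pool <- x_templ[[cue]]
      narrative <- pool[sample.int(length(pool), 1)]
      cues <- cue
      curation_row <- list(taxon_id = id, verdict = "confirm",
                           cues = list(cue), stated_grade = NA_character_)
    } else {
      narrative <- benign[sample.int(length(benign), 1)]
      if (runif(1) < config$distractor_rate) {
        narrative <- paste(narrative,
                           distract[sample.int(length(distract), 1)])
        curation_row <- list(taxon_id = id, verdict = "false_positive",
                             cues = list(character(0)),
                             stated_grade = NA_character_)
      }
    }

    regions <- if (!is.na(endemic_to)) endemic_to else
      sort(unique(rt$region[match(units, rt$unit)]))
    rec[[i]] <- list(
      taxon_id = id,
      scientific_name = sprintf("Synthetica specimen%05d", i),
      taxon_class = cls, family = family, category = category,
      units = list(units), threats_text = narrative,
      range_text = if (!is.na(endemic_to))
        sprintf("Endemic to %s.", endemic_to)
      else sprintf("Occurs in %s.", paste(units, collapse = ", ")),
      endemic_to = endemic_to
    )
    tru[[i]] <- list(
      taxon_id = id, threatened = threatened, severity = severity,
      mechanisms = list(mechanisms), cues = list(cues),
      stated_grade = stated_grade, regions = list(regions),
      island_endemic = !is.na(endemic_to),
      in_native = any(status == "native"),
      in_nonnative = any(status == "nonnative"),
      in_potential_only = !any(status %in% c("native", "nonnative")) &&
        any(status == "potential")
    )
    cur[[i]] <- curation_row
  }

  records <- if (n > 0) {
    as_corpus(dplyr::bind_rows(lapply(rec, tibble::as_tibble)))
  } else {
    empty_corpus()
  }
  truth <- if (n > 0) {
    dplyr::bind_rows(lapply(tru, tibble::as_tibble))
  } else {
    tibble::tibble(taxon_id = character(0), threatened = logical(0),
                   severity = character(0), mechanisms = list(),
                   cues = list(), stated_grade = character(0),
                   regions = list(), island_endemic = logical(0),
                   in_native = logical(0), in_nonnative = logical(0),
                   in_potential_only = logical(0))
  }
  cur <- cur[!vapply(cur, is.null, logical(1))]
  curation <- if (length(cur) > 0) {
    as_curation(dplyr::bind_rows(lapply(cur, tibble::as_tibble)))
  } else {
    tibble::tibble(taxon_id = character(0), verdict = character(0),
                   cues = list(), stated_grade = character(0))
  }

  # A potential unit is justified when a threatened taxon occurs there;
  # only then do potential-only taxa survive the range exclusion.
  active <- intersect(potential_units,
                      unique(unlist(records$units[truth$threatened])))
  truth$retained <- truth$in_native | truth$in_nonnative |
    (truth$in_potential_only &
       vapply(records$units, function(u) any(u %in% active), logical(1)))

  structure(list(records = records, pig_range = pr, region_table = rt,
                 curation = curation, truth = truth, config = config),
            class = "threat_sim")
}

#' @export
print.threat_sim <- function(x, ...) {
  cat("<threat_sim> ", nrow(x$records), " taxa (seed ", x$config$seed, "), ",
      sum(x$truth$threatened), " ground-truth threatened, ",
      nrow(x$curation), " curation entries\n", sep = "")
  invisible(x)
}

#' Ground-truth summary report for a synthetic corpus
#'
#' Builds the [build_report()] object directly from the generator's
#' ground-truth table — severities, mechanisms, regions, endemism and
#' range flags as generated, bypassing screening, review,
#' classification and geographic resolution. The end-to-end pipeline on
#' the emitted files must reproduce this report exactly (the closure
#' property).
#'
#' @param sim A `threat_sim`.
#' @return A `threat_summary_report`.
#' @export
truth_summary <- function(sim) {
  stopifnot(inherits(sim, "threat_sim"))
  truth <- sim$truth
  keep <- truth$retained
  records <- sim$records[keep, ]
  tr <- truth[keep, ]
  annotations <- tibble::tibble(
    taxon_id = tr$taxon_id[tr$threatened],
    pig_threatened = TRUE,
    severity = tr$severity[tr$threatened],
    mechanisms = tr$mechanisms[tr$threatened],
    cues = tr$cues[tr$threatened]
  )
  resolved <- tibble::tibble(taxon_id = tr$taxon_id, regions = tr$regions)
  sys <- region_systems(sim$region_table)
  stratum <- vapply(seq_len(nrow(tr)), function(i) {
    regs <- tr$regions[[i]]
    systems <- sys$system[match(regs, sys$region)]
    if (length(regs) == 0) "unassigned"
    else if (any(systems == "continental")) "continental"
    else if (tr$island_endemic[i]) "island_endemic"
    else "island_nonendemic"
  }, character(1))
  strata <- tibble::tibble(taxon_id = tr$taxon_id, stratum = stratum)
  overlaps <- tibble::tibble(
    taxon_id = tr$taxon_id, in_native = tr$in_native,
    in_nonnative = tr$in_nonnative, in_potential_only = tr$in_potential_only
  )
  build_report(records, annotations, resolved, sim$region_table,
               overlaps, strata)
}

#' Write a synthetic corpus to disk
#'
#' Emits exactly the CSV dialects the readers consume: `corpus.csv`,
#' `pig_range.csv`, `regions.csv`, `curation.csv` and a `truth.csv`
#' flattening of the ground-truth table.
#'
#' @param sim A `threat_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(sim$records, file.path(dir, "corpus.csv"))
  readr::write_csv(sim$pig_range, file.path(dir, "pig_range.csv"))
  readr::write_csv(sim$region_table, file.path(dir, "regions.csv"))
  cur <- sim$curation
  cur$cues <- join_multi(cur$cues)
  cur$stated_grade[is.na(cur$stated_grade)] <- ""
  readr::write_csv(cur, file.path(dir, "curation.csv"), na = "")
  truth <- sim$truth
  truth$mechanisms <- join_multi(truth$mechanisms)
  truth$cues <- join_multi(truth$cues)
  truth$regions <- join_multi(truth$regions)
  readr::write_csv(truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
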