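analysis_cues <- setdiff(curation_cues(),
                         c("hunting_catalyzed", "domestic_not_free_ranging"))

test_that("review removes false positives and out-of-scope records", {
  flagged <- tibble::tibble(taxon_id = sprintf("T%d", 1:5))
  curation <- as_curation(tibble::tibble(
    taxon_id = sprintf("T%d", 1:5),
    verdict = c("confirm", "false_positive", "confirm", "false_positive",
                "confirm"),
    cues = list("consumption", character(0), "nest_digging", character(0),
                "disease"),
    stated_grade = NA_character_
  ))
  confirmed <- apply_review(flagged, curation)
  expect_equal(confirmed$taxon_id, c("T1", "T3", "T5"))

  # Hunting catalyzed by the focal species, and penned domestic animals,
  # are noted but not analysed.
  curation2 <- as_curation(tibble::tibble(
    taxon_id = c("H1", "H2", "H3", "H4"),
    verdict = "confirm",
    cues = list("hunting_catalyzed", "domestic_not_free_ranging",
                c("hunting_catalyzed", "domestic_not_free_ranging"),
                c("hunting_catalyzed", "consumption")),
    stated_grade = NA_character_
  ))
  confirmed <- apply_review(tibble::tibble(taxon_id = c("H1", "H2", "H3", "H4")),
                            curation2)
  expect_equal(confirmed$taxon_id, "H4")
})

test_that("strict review errors on unreviewed taxa; lenient drops them", {
  flagged <- tibble::tibble(taxon_id = c("T1", "T2"))
  curation <- as_curation(tibble::tibble(
    taxon_id = "T1", verdict = "confirm", cues = list("consumption"),
    stated_grade = NA_character_))
  expect_error(apply_review(flagged, curation, "strict"), "T2")
  expect_warning(out <- apply_review(flagged, curation, "lenient"), "T2")
  expect_equal(out$taxon_id, "T1")
})

test_that("severity follows the stated rule order on quoted cases", {
  expect_equal(classify_severity("CR", "habitat_disturbance"), "major")
  expect_equal(classify_severity("LC", "direct_predation"), "minor")
  expect_equal(classify_severity("EN", "overlap_only"), "potential")
  expect_equal(classify_severity("CR", "habitat_disturbance", "minor"),
               "minor")
  expect_equal(classify_severity("NT", "consumption"), "minor")
  expect_equal(classify_severity("EN", "nest_digging"), "major")
  expect_equal(classify_severity("VU", "overlap_only"), "potential")
  expect_equal(classify_severity("CR", "overlap_only"), "potential")
  expect_equal(classify_severity("EX", "consumption"), "major")
})

test_that("severity matches an independent rule-table oracle exhaustively", {
  oracle_severity <- function(category, cues, stated) {
    if (!is.na(stated)) return(stated)
    if (length(cues) == 1 && cues == "overlap_only") return("potential")
    if (category %in% c("EX", "EW", "CR")) return("major")
    if (category == "LC") return("minor")
    if (category == "NT") return("minor")
    direct <- c("direct_predation", "consumption", "habitat_disturbance",
                "nest_digging", "disease", "competition", "hybridization")
    if (any(cues %in% direct)) "major" else "potential"
  }
  cue_sets <- c(as.list(analysis_cues),
                list(c("overlap_only", "consumption"),
                     c("direct_predation", "disease"),
                     c("overlap_only", "nest_digging", "competition")))
  for (category in rl_categories()) {
    for (cues in cue_sets) {
      for (stated in c(NA_character_, severity_levels())) {
        expect_equal(
          classify_severity(category, cues, stated),
          oracle_severity(category, cues, stated),
          info = sprintf("%s | %s | %s", category,
                         paste(cues, collapse = "+"), stated))
      }
    }
  }
})

test_that("cue-to-mechanism mapping follows the compound rules", {
  expect_setequal(tag_threat_types("plant", "consumption"),
                  c("predation", "disturbance"))
  expect_equal(tag_threat_types("bird", "consumption"), "predation")
  expect_setequal(tag_threat_types("reptile", "nest_digging"),
                  c("predation", "disturbance"))
  expect_setequal(tag_threat_types("amphibian", "nest_digging"),
                  c("predation", "disturbance"))
  expect_setequal(tag_threat_types("bird", "nest_digging"),
                  c("predation", "disturbance"))
  expect_equal(tag_threat_types("mammal", "hybridization"), "hybridization")
  expect_equal(tag_threat_types("mammal", "disease"), "disease_risk")
  expect_equal(tag_threat_types("invertebrate", "overlap_only"),
               "disturbance")
  expect_error(tag_threat_types("plant", "hunting_catalyzed"),
               "no threat mechanism")
})

test_that("mechanism mapping matches an independent oracle over class x cues", {
  oracle_mechanisms <- function(cls, cues) {
    per_cue <- function(cue) {
      switch(cue,
        direct_predation = "predation",
        consumption = if (cls == "plant") c("predation", "disturbance")
                      else "predation",
        habitat_disturbance = "disturbance",
        nest_digging = if (cls %in% c("reptile", "amphibian", "bird"))
                         c("predation", "disturbance") else "disturbance",
        disease = "disease_risk",
        competition = "competition",
        hybridization = "hybridization",
        overlap_only = character(0))
    }
    out <- unique(unlist(lapply(cues, per_cue)))
    if (length(out) == 0 && "overlap_only" %in% cues) out <- "disturbance"
    out
  }
  set.seed(9)
  for (cls in taxon_classes()) {
    for (cue in analysis_cues) {
      expect_setequal(tag_threat_types(cls, cue), oracle_mechanisms(cls, cue))
    }
    for (i in 1:20) {
      cues <- sample(analysis_cues, sample(2:4, 1))
      expect_setequal(tag_threat_types(cls, cues), oracle_mechanisms(cls, cues))
    }
  }
})

test_that("annotation is deterministic and always complete", {
  set.seed(21)
  for (i in 1:50) {
    cls <- sample(taxon_classes(), 1)
    category <- sample(rl_categories(), 1)
    cues <- sample(analysis_cues, sample(1:3, 1))
    stated <- sample(c(NA_character_, severity_levels()), 1)
    records <- make_records("X1", taxon_class = cls, category = category)
    ann1 <- make_annotations(records, cues = cues, stated_grade = stated)
    ann2 <- make_annotations(records, cues = cues, stated_grade = stated)
    expect_identical(ann1, ann2)
    expect_true(ann1$severity %in% severity_levels())
    expect_gte(length(ann1$mechanisms[[1]]), 1)
    expect_true(all(ann1$mechanisms[[1]] %in% threat_mechanisms()))
  }
})
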