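test_that("tallies count once per category/group/severity, once per mechanism", {
  records <- make_records(c("T1", "T2"), taxon_class = "reptile",
                          category = "CR")
  ann <- make_annotations(records, cues = "nest_digging")
  t <- tally(ann, records)
  expect_equal(t$n_threatened, 2)
  expect_equal(unname(t$by_mechanism[c("predation", "disturbance")]), c(2, 2))
  expect_equal(unname(t$by_group[["herpetofauna"]]), 2)
  expect_equal(sum(t$by_mechanism), 4)  # mechanisms exceed taxa

  empty <- tally(ann[0, ], records)
  expect_equal(empty$n_threatened, 0)
  expect_true(all(empty$by_category == 0))
  expect_true(all(empty$by_severity$counts == 0))
})

test_that("concern count equals a brute-force CR+EN filter", {
  expect_equal(concern_count(c(EX = 14, EW = 0, CR = 267, EN = 147, VU = 50,
                               NT = 30, LC = 100, DD = 64)), 414)
  expect_equal(concern_count(c(EX = 0, EW = 0, CR = 0, EN = 0, VU = 0,
                               NT = 0, LC = 0, DD = 0)), 0)
  set.seed(5)
  for (i in 1:20) {
    counts <- stats::setNames(sample(0:500, 8), rl_categories())
    expect_equal(concern_count(counts),
                 sum(counts[names(counts) %in% c("CR", "EN")]))
  }
})

test_that("region proportions equal a brute-force per-region recount", {
  sim <- generate_corpus(sim_config(n_taxa = 250, seed = 31))
  res <- run_pipeline(sim$records, sim$pig_range, sim$region_table,
                      sim$curation)
  props <- res$report$region_props
  expect_true(all(props$proportion >= 0 & props$proportion <= 1))
  expect_true(all(props$n_assessed > 0))
  threatened <- res$annotations$taxon_id
  # Recount each cell independently from the resolved assignments.
  for (i in seq_len(nrow(props))) {
    in_region <- vapply(res$resolved$regions,
                        function(r) props$region[i] %in% r, logical(1))
    sel <- in_region &
      taxon_group(res$retained$taxon_class) == props$group[i]
    if (props$system[i] == "island") {
      sel <- sel & res$strata$stratum == "island_endemic"
    }
    expect_equal(props$n_assessed[i], sum(sel))
    expect_equal(props$n_threatened[i],
                 sum(res$retained$taxon_id[sel] %in% threatened))
  }
})

test_that("island/continental means use the sample SD with n-1 divisor", {
  props <- tibble::tibble(
    region = c("IsleA", "IsleB"), system = "island", group = "bird",
    n_assessed = c(10L, 10L), n_threatened = c(1L, 3L),
    proportion = c(0.1, 0.3))
  s <- island_continental_summary(props, tiny_region_table())
  bird <- s[s$group == "bird", ]
  expect_equal(bird$mean_proportion, 0.2)
  expect_equal(bird$sd_proportion, sqrt(((0.1 - 0.2)^2 + (0.3 - 0.2)^2) / 1),
               tolerance = 1e-12)
  expect_true(bird$sd_defined)

  one <- island_continental_summary(props[1, ], tiny_region_table())
  expect_equal(one$sd_proportion, c(0, 0))
  expect_false(any(one$sd_defined))
  expect_equal(one$mean_proportion, c(0.1, 0.1))

  equal_props <- props
  equal_props$proportion <- c(0.25, 0.25)
  eq <- island_continental_summary(equal_props, tiny_region_table())
  expect_equal(eq$sd_proportion[eq$group == "bird"], 0)
})

test_that("range partition satisfies the inclusion-exclusion identity", {
  overlaps <- tibble::tibble(
    taxon_id = c("A", "B", "C"),
    in_native = c(TRUE, FALSE, TRUE),
    in_nonnative = c(FALSE, TRUE, TRUE),
    in_potential_only = FALSE)
  ann <- tibble::tibble(taxon_id = c("A", "B", "C"), pig_threatened = TRUE)
  p <- range_partition(overlaps, ann)
  expect_equal(p, list(n_native = 2, n_nonnative = 2, n_both = 1))
  expect_equal(range_partition(overlaps, ann[0, ]),
               list(n_native = 0, n_nonnative = 0, n_both = 0))

  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    ov <- tibble::tibble(
      taxon_id = sprintf("R%02d", 1:n),
      in_native = sample(c(TRUE, FALSE), n, replace = TRUE),
      in_nonnative = sample(c(TRUE, FALSE), n, replace = TRUE),
      in_potential_only = FALSE)
    th <- tibble::tibble(taxon_id = sample(ov$taxon_id, sample(0:n, 1)),
                         pig_threatened = TRUE)
    p <- range_partition(ov, th)
    either <- ov$taxon_id %in% th$taxon_id &
      (ov$in_native | ov$in_nonnative)
    expect_equal(p$n_native + p$n_nonnative - p$n_both, sum(either))
  }
})

test_that("comparator profiles apply the published inclusion criteria", {
  records <- make_records(
    sprintf("C%d", 1:6),
    taxon_class = c("reptile", "reptile", "amphibian", "bird", "mammal",
                    "plant"),
    category = c("LC", "CR", "EN", "CR", "NT", "CR"))
  ann <- make_annotations(records, cues = "direct_predation")
  doherty <- comparator_filter(ann, records, "doherty2016")
  expect_equal(unname(doherty$by_class),
               c(1L, 1L, 0L))  # reptile, bird, mammal
  expect_equal(doherty$total, 2)

  plants <- make_records(sprintf("P%d", 1:4), taxon_class = "plant",
                         category = "CR")
  expect_equal(comparator_filter(make_annotations(plants), plants,
                                 "doherty2016")$total, 0)

  strata <- tibble::tibble(taxon_id = records$taxon_id,
                           stratum = "continental")
  medina <- comparator_filter(ann, records, "medina2011_island", strata)
  expect_equal(medina$total, 0)
  strata$stratum[2] <- "island_endemic"
  medina <- comparator_filter(ann, records, "medina2011_island", strata)
  expect_equal(medina$total, 1)
})

test_that("report invariants are enforced on every build", {
  sim <- generate_corpus(sim_config(n_taxa = 150, seed = 13))
  res <- run_pipeline(sim$records, sim$pig_range, sim$region_table,
                      sim$curation)
  expect_s3_class(res$report, "threat_summary_report")
  expect_silent(validate_report(res$report))
  broken <- res$report
  broken$by_group[["plant"]] <- broken$by_group[["plant"]] + 1L
  expect_error(validate_report(broken), "group counts")
})
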