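test_that("region assignment maps units through the table", {
  rt <- tiny_region_table()
  records <- make_records(c("T1", "T2", "T3"),
                          category = c("CR", "CR", "EX"),
                          units = list("ISL-1", c("CON-1", "ISL-2"),
                                       character(0)))
  asg <- assign_regions(records, rt)
  expect_equal(asg$regions[[1]], "Isle")
  expect_equal(asg$regions[[2]], c("Isle", "Mainland"))
  expect_equal(asg$regions[[3]], character(0))

  bad <- make_records("T9", units = list("XX-1"))
  expect_error(assign_regions(bad, rt), "missing from region table: XX-1")
})

test_that("endemic cross-listings collapse to the home region", {
  rt <- tiny_region_table()
  records <- make_records(c("E1", "E2", "E3"),
                          units = list(c("ISL-1", "CON-1"), "CON-1", "ISL-2"),
                          endemic_to = c("Isle", NA, NA))
  resolved <- resolve_endemic_cross_listings(records,
                                             assign_regions(records, rt))
  expect_equal(resolved$regions[[1]], "Isle")
  expect_equal(resolved$regions[[2]], "Mainland")

  bad <- make_records("E9", units = list("CON-1"), endemic_to = "Galapagos")
  expect_error(
    resolve_endemic_cross_listings(bad, assign_regions(bad, rt)),
    "inconsistent record E9")
})

test_that("range overlap matches its definition over all status combinations", {
  pr <- tibble::tibble(unit = c("N", "X", "P", "A"),
                       status = c("native", "nonnative", "potential",
                                  "absent"))
  combos <- unlist(lapply(1:3, function(k) {
    utils::combn(pr$unit, k, simplify = FALSE)
  }), recursive = FALSE)
  records <- make_records(sprintf("T%02d", seq_along(combos)),
                          category = "CR", units = combos)
  ov <- range_overlap(records, pr)
  for (i in seq_along(combos)) {
    s <- pr$status[match(combos[[i]], pr$unit)]
    expect_equal(ov$in_native[i], "native" %in% s)
    expect_equal(ov$in_nonnative[i], "nonnative" %in% s)
    expect_equal(ov$in_potential_only[i],
                 !any(s %in% c("native", "nonnative")) && "potential" %in% s)
  }
  # Potential-only implies neither native nor non-native.
  expect_true(all(!ov$in_potential_only | (!ov$in_native & !ov$in_nonnative)))
})

test_that("potential areas are dropped unless they host a threatened taxon", {
  rt <- tiny_region_table()
  pr <- tiny_pig_range()
  records <- make_records(sprintf("P%d", 1:6),
                          units = c(rep(list("POT-1"), 5), list("CON-1")))
  ann_none <- make_annotations(records[6, ])
  kept <- apply_potential_rule(records, ann_none, pr)
  expect_equal(kept$taxon_id, "P6")
  expect_setequal(attr(kept, "excluded_ids"), sprintf("P%d", 1:5))

  # One threatened taxon in the potential area retains all its taxa.
  ann_one <- make_annotations(records[c(1, 6), ])
  kept <- apply_potential_rule(records, ann_one, pr)
  expect_equal(kept$taxon_id, records$taxon_id)

  # Absent-only taxa are always excluded; no potential units changes nothing.
  records2 <- make_records(c("A1", "C1"), units = list("ABS-1", "CON-2"))
  kept2 <- apply_potential_rule(records2, make_annotations(records2[2, ]), pr)
  expect_equal(kept2$taxon_id, "C1")
})

test_that("island/continental strata partition retained taxa correctly", {
  rt <- tiny_region_table()
  records <- make_records(
    c("I1", "I2", "C1", "M1"),
    units = list("ISL-1", c("ISL-1", "CON-1"), "CON-2", "ISL-2"),
    endemic_to = c("Isle", "Isle", NA, NA))
  resolved <- resolve_endemic_cross_listings(records,
                                             assign_regions(records, rt))
  strata <- island_strata(records, resolved, rt)
  expect_equal(strata$stratum,
               c("island_endemic", "island_endemic", "continental",
                 "island_nonendemic"))

  # Continental co-occurrence demotes a non-endemic to the continental
  # stratum, and every taxon lands in exactly one stratum.
  mixed <- make_records("X1", units = list(c("ISL-1", "CON-1")))
  res <- resolve_endemic_cross_listings(mixed, assign_regions(mixed, rt))
  expect_equal(island_strata(mixed, res, rt)$stratum, "continental")
  expect_true(all(table(strata$taxon_id) == 1))
})

test_that("the shipped default configuration has 17 regions, 8 island", {
  rt <- default_region_table()
  sys <- unique(rt[c("region", "system")])
  expect_equal(nrow(sys), 17)
  expect_equal(sum(sys$system == "island"), 8)
  expect_equal(sum(sys$system == "continental"), 9)
  pr <- default_pig_range()
  expect_setequal(pr$unit, rt$unit)
  expect_true(all(pr$status %in% range_statuses()))
  # The named island regions of the study area are present.
  expect_true(all(c("Polynesia", "Micronesia/Melanesia", "Galapagos",
                    "New Zealand") %in% sys$region[sys$system == "island"]))
})

test_that("shipped configuration files match the in-code defaults", {
  rt <- read_region_table(system.file("extdata", "regions_default.csv",
                                      package = "threatminer"))
  expect_equal(rt, default_region_table())
  pr <- read_pig_range(system.file("extdata", "pig_range_default.csv",
                                   package = "threatminer"))
  expect_equal(pr, default_pig_range())
  kw <- read_keywords(system.file("extdata", "keywords.yml",
                                  package = "threatminer"))
  expect_equal(kw, default_keywords())
})
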