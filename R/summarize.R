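# Results-style descriptive summaries: corpus-level tallies, per-region
# proportions, island vs continental means +/- SD, the native/non-native
# partition, and literature-comparator subsets.

named_count <- function(values, levels) {
  out <- table(factor(values, levels = levels))
  stats::setNames(as.integer(out), levels)
}

#' Corpus-level threat tallies
#'
#' Counts of confirmed threatened taxa by Red List category, reporting
#' group (reptiles + amphibians pooled as herpetofauna), threat
#' mechanism and severity. A taxon contributes once to its category,
#' group and severity, and once per mechanism it carries, so mechanism
#' counts may exceed the number of threatened taxa.
#'
#' @param annotations Annotation tibble from [annotate_threats()].
#' @param records Validated corpus tibble containing the annotated taxa.
#' @return List with `n_threatened`, `by_category`, `by_group`,
#'   `by_mechanism`, and `by_severity` (itself `counts`, `percent`
#'   — raw, of `n_threatened` — and `percent_rounded`, half-up to whole
#'   percent).
#' @export
tally <- function(annotations, records) {
  idx <- match(annotations$taxon_id, records$taxon_id)
  if (anyNA(idx)) {
    stop("annotated taxa missing from corpus: ",
         paste(annotations$taxon_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(annotations)
  by_category <- named_count(records$category[idx], rl_categories())
  by_group <- named_count(taxon_group(records$taxon_class[idx]),
                          report_groups())
  by_mechanism <- named_count(unlist(annotations$mechanisms),
                              threat_mechanisms())
  sev_counts <- named_count(annotations$severity, severity_levels())
  percent <- if (n > 0) 100 * sev_counts / n else sev_counts * 0
  list(
    n_threatened = n,
    by_category = by_category,
    by_group = by_group,
    by_mechanism = by_mechanism,
    by_severity = list(
      counts = sev_counts,
      percent = percent,
      percent_rounded = round_half_up(percent)
    )
  )
}

#' Count of taxa of greatest conservation concern
#'
#' The number of threatened taxa listed as critically endangered or
#' endangered, i.e. `by_category["CR"] + by_category["EN"]`.
#'
#' @param by_category Named count vector from [tally()].
#' @return Integer count.
#' @export
concern_count <- function(by_category) {
  as.integer(by_category[["CR"]] + by_category[["EN"]])
}

#' Per-region, per-group threatened proportions
#'
#' For every (region, reporting group) with at least one assessed
#' taxon, the proportion of taxa threatened by the focal species:
#' threatened / assessed. Island-region denominators and numerators
#' include only island-endemic taxa (the island stratum of
#' [island_strata()]); continental regions include every taxon assigned
#' to them. Cells with zero assessed taxa are omitted.
#'
#' @param records Retained corpus tibble (post range exclusion).
#' @param annotations Annotation tibble restricted to retained taxa.
#' @param resolved Region assignment after
#'   [resolve_endemic_cross_listings()], same taxa as `records`.
#' @param region_table Region tibble.
#' @param strata Stratum tibble from [island_strata()], same taxa.
#' @return Tibble `region`, `system`, `group`, `n_assessed`,
#'   `n_threatened`, `proportion`.
#' @export
region_proportions <- function(records, annotations, resolved, region_table,
                               strata) {
  stopifnot(identical(records$taxon_id, resolved$taxon_id),
            identical(records$taxon_id, strata$taxon_id))
  sys <- region_systems(region_table)
  long <- tibble::tibble(
    taxon_id = rep(records$taxon_id, lengths(resolved$regions)),
    group = rep(taxon_group(records$taxon_class), lengths(resolved$regions)),
    stratum = rep(strata$stratum, lengths(resolved$regions)),
    region = unlist(resolved$regions)
  )
  if (nrow(long) == 0) {
    return(tibble::tibble(region = character(0), system = character(0),
                          group = character(0), n_assessed = integer(0),
                          n_threatened = integer(0), proportion = double(0)))
  }
  long$system <- sys$system[match(long$region, sys$region)]
  # Island comparisons are endemics-only by design.
  long <- long[long$system == "continental" | long$stratum == "island_endemic", ]
  threatened_ids <- annotations$taxon_id[annotations$pig_threatened]
  long$threatened <- long$taxon_id %in% threatened_ids
  out <- long |>
    dplyr::group_by(.data$region, .data$system, .data$group) |>
    dplyr::summarise(n_assessed = dplyr::n(),
                     n_threatened = sum(.data$threatened),
                     .groups = "drop") |>
    dplyr::mutate(proportion = .data$n_threatened / .data$n_assessed) |>
    dplyr::arrange(.data$region, .data$group)
  tibble::as_tibble(out)
}

#' Island vs continental summary of threatened proportions
#'
#' Mean and sample standard deviation (n - 1 divisor) of the per-region
#' threatened proportions, per reporting group and pooled (`"overall"`,
#' each region contributing its all-group proportion), separately for
#' island and continental systems. With a single contributing region
#' the SD is undefined and reported as 0 with `sd_defined = FALSE`.
#'
#' @param region_props Output of [region_proportions()].
#' @param region_table Region tibble.
#' @return Tibble `system`, `group`, `n_regions`, `mean_proportion`,
#'   `sd_proportion`, `sd_defined`, `total_threatened`.
#' @export
island_continental_summary <- function(region_props, region_table) {
  summarise_values <- function(system, group, regions, values, total) {
    n <- length(values)
    s <- if (n >= 2) stats::sd(values) else NA_real_
    tibble::tibble(
      system = system, group = group, n_regions = n,
      mean_proportion = if (n > 0) mean(values) else NA_real_,
      sd_proportion = if (is.na(s)) 0 else s,
      sd_defined = !is.na(s),
      total_threatened = total
    )
  }
  rows <- list()
  for (system in c("island", "continental")) {
    props <- region_props[region_props$system == system, ]
    for (group in report_groups()) {
      gp <- props[props$group == group, ]
      if (nrow(gp) == 0) next
      rows[[length(rows) + 1]] <- summarise_values(
        system, group, gp$region, gp$proportion, sum(gp$n_threatened))
    }
    if (nrow(props) > 0) {
      overall <- props |>
        dplyr::group_by(.data$region) |>
        dplyr::summarise(
          proportion = sum(.data$n_threatened) / sum(.data$n_assessed),
          n_threatened = sum(.data$n_threatened), .groups = "drop")
      rows[[length(rows) + 1]] <- summarise_values(
        system, "overall", overall$region, overall$proportion,
        sum(overall$n_threatened))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(system = character(0), group = character(0),
                          n_regions = integer(0), mean_proportion = double(0),
                          sd_proportion = double(0), sd_defined = logical(0),
                          total_threatened = integer(0)))
  }
  dplyr::bind_rows(rows)
}

#' Native / non-native range partition of threatened taxa
#'
#' @param overlaps Overlap tibble from [range_overlap()].
#' @param annotations Annotation tibble.
#' @return List `n_native`, `n_nonnative`, `n_both`; the identity
#'   `n_native + n_nonnative - n_both` equals the number of unique
#'   threatened taxa overlapping either range.
#' @export
range_partition <- function(overlaps, annotations) {
  ov <- overlaps[overlaps$taxon_id %in%
                   annotations$taxon_id[annotations$pig_threatened], ]
  list(
    n_native = sum(ov$in_native),
    n_nonnative = sum(ov$in_nonnative),
    n_both = sum(ov$in_native & ov$in_nonnative)
  )
}

#' Apply a literature-comparator filter
#'
#' Restricts the threatened set to the inclusion criteria of earlier
#' invasive-predator syntheses so totals are directly comparable:
#' `"doherty2016"` keeps reptiles, birds and mammals whose category is
#' neither LC nor NT (plants, amphibians, invertebrates and
#' least-concern / near-threatened taxa are excluded);
#' `"medina2011_island"` applies the same criteria and additionally
#' keeps only island-endemic taxa.
#'
#' @param annotations Annotation tibble.
#' @param records Corpus tibble containing the annotated taxa.
#' @param profile `"doherty2016"` or `"medina2011_island"`.
#' @param strata Stratum tibble from [island_strata()]; required for
#'   the island profile.
#' @return List with `by_class` (named counts for reptile, bird,
#'   mammal) and `total`.
#' @export
comparator_filter <- function(annotations, records,
                              profile = c("doherty2016", "medina2011_island"),
                              strata = NULL) {
  profile <- match.arg(profile)
  idx <- match(annotations$taxon_id, records$taxon_id)
  keep <- records$taxon_class[idx] %in% c("reptile", "bird", "mammal") &
    !records$category[idx] %in% c("LC", "NT")
  if (profile == "medina2011_island") {
    if (is.null(strata)) {
      stop("the island comparator requires the island/continental strata",
           call. = FALSE)
    }
    sidx <- match(annotations$taxon_id, strata$taxon_id)
    keep <- keep & !is.na(sidx) & strata$stratum[sidx] == "island_endemic"
  }
  by_class <- named_count(records$taxon_class[idx][keep],
                          c("reptile", "bird", "mammal"))
  list(by_class = by_class, total = sum(by_class))
}

#' Assemble the full summary report
#'
#' Bundles every Results-style quantity into one validated object:
#' corpus tallies, concern count, per-region proportions, island vs
#' continental summaries, the native/non-native partition and both
#' comparator profiles.
#'
#' @param records Retained corpus tibble.
#' @param annotations Annotation tibble restricted to retained taxa.
#' @param resolved Resolved region assignment for the retained corpus.
#' @param region_table Region tibble.
#' @param overlaps Overlap tibble for the retained corpus.
#' @param strata Stratum tibble for the retained corpus.
#' @return Object of class `threat_summary_report`.
#' @export
build_report <- function(records, annotations, resolved, region_table,
                         overlaps, strata) {
  t <- tally(annotations, records)
  region_props <- region_proportions(records, annotations, resolved,
                                     region_table, strata)
  report <- structure(list(
    n_threatened = t$n_threatened,
    by_category = t$by_category,
    by_group = t$by_group,
    by_mechanism = t$by_mechanism,
    by_severity = t$by_severity,
    concern_count = concern_count(t$by_category),
    region_props = region_props,
    strata_summary = island_continental_summary(region_props, region_table),
    range_partition = range_partition(overlaps, annotations),
    comparators = list(
      doherty2016 = comparator_filter(annotations, records, "doherty2016"),
      medina2011_island = comparator_filter(annotations, records,
                                            "medina2011_island", strata)
    )
  ), class = "threat_summary_report")
  validate_report(report)
  report
}

#' Assert the internal consistency of a summary report
#'
#' Checks the arithmetic identities every report must satisfy: group
#' and severity counts sum to the threatened total, severity
#' percentages sum to 100 (up to rounding, when the total is
#' positive), all proportions lie in \[0, 1\], and the
#' native + non-native - both identity is non-negative.
#'
#' @param report A `threat_summary_report`.
#' @return `report`, invisibly; errors on any violation.
#' @export
validate_report <- function(report) {
  with(report, {
    if (sum(by_group) != n_threatened) {
      stop("report invariant violated: group counts do not sum to total",
           call. = FALSE)
    }
    if (sum(by_category) != n_threatened) {
      stop("report invariant violated: category counts do not sum to total",
           call. = FALSE)
    }
    if (sum(by_severity$counts) != n_threatened) {
      stop("report invariant violated: severity counts do not sum to total",
           call. = FALSE)
    }
    if (n_threatened > 0 && abs(sum(by_severity$percent) - 100) > 1e-9) {
      stop("report invariant violated: severity percentages do not sum to 100",
           call. = FALSE)
    }
    if (any(region_props$proportion < 0 | region_props$proportion > 1)) {
      stop("report invariant violated: proportion outside [0, 1]",
           call. = FALSE)
    }
    both_ok <- range_partition$n_both <= min(range_partition$n_native,
                                             range_partition$n_nonnative)
    if (!both_ok) {
      stop("report invariant violated: n_both exceeds a marginal count",
           call. = FALSE)
    }
  })
  invisible(report)
}

#' @export
print.threat_summary_report <- function(x, ...) {
  cat("<threat_summary_report>\n")
  cat("  threatened taxa:", x$n_threatened,
      sprintf("(CR+EN: %d)\n", x$concern_count))
  cat("  by group:",
      paste(sprintf("%s %d", names(x$by_group), x$by_group), collapse = ", "),
      "\n")
  cat("  by mechanism:",
      paste(sprintf("%s %d", names(x$by_mechanism), x$by_mechanism),
            collapse = ", "), "\n")
  cat("  severity:",
      paste(sprintf("%s %d (%s%%)", names(x$by_severity$counts),
                    x$by_severity$counts, x$by_severity$percent_rounded),
            collapse = ", "), "\n")
  cat(sprintf("  range partition: native %d, non-native %d, both %d\n",
              x$range_partition$n_native, x$range_partition$n_nonnative,
              x$range_partition$n_both))
  invisible(x)
}

#' Write a summary report to disk
#'
#' Emits the machine-readable report (`report.json`), a human-readable
#' Markdown rendering (`report.md`) and the per-region proportion table
#' (`region_proportions.csv`).
#'
#' @param report A `threat_summary_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(report$region_props,
                   file.path(dir, "region_proportions.csv"))
  md <- c(
    "# Threat summary",
    "",
    sprintf("Threatened taxa: **%d** (CR+EN: %d)", report$n_threatened,
            report$concern_count),
    "",
    "## By severity",
    "",
    "| severity | n | % |",
    "|---|---|---|",
    sprintf("| %s | %d | %d |", names(report$by_severity$counts),
            report$by_severity$counts, report$by_severity$percent_rounded),
    "",
    "## By group",
    "",
    "| group | n |", "|---|---|",
    sprintf("| %s | %d |", names(report$by_group), report$by_group),
    "",
    "## By mechanism",
    "",
    "| mechanism | n |", "|---|---|",
    sprintf("| %s | %d |", names(report$by_mechanism), report$by_mechanism),
    "",
    "## Range partition",
    "",
    sprintf("native: %d, non-native: %d, both: %d",
            report$range_partition$n_native,
            report$range_partition$n_nonnative,
            report$range_partition$n_both),
    ""
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
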