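# Geographic stratification: admin units -> regions, island-endemic
# cross-listing resolution, and overlap with the focal species' native
# and non-native range. All joins are exact on opaque admin-unit codes;
# sub-country units are just additional codes, never a hierarchy.

#' Assign biogeographic regions to corpus records
#'
#' Maps each record's admin units through the region table; the region
#' set of a record is the image of its units. Records with no units
#' (extinct taxa) receive the empty set.
#'
#' @param records Validated corpus tibble.
#' @param region_table Region tibble from [read_region_table()].
#' @return Tibble `taxon_id`, `regions` (list-column of sorted region
#'   ids).
#' @export
assign_regions <- function(records, region_table) {
  unmapped <- setdiff(unique(unlist(records$units)), region_table$unit)
  if (length(unmapped)) {
    stop("configuration error: admin unit(s) missing from region table: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    taxon_id = records$taxon_id,
    regions = lapply(records$units, function(u) {
      sort(unique(region_table$region[match(u, region_table$unit)]))
    })
  )
}

#' Prune island-endemic cross-listings
#'
#' Country-level range data cross-list island endemics under the
#' continental country that governs the island, inflating continental
#' tallies. When a record carries a structured `endemic_to` region, its
#' region set collapses to that single region; an `endemic_to` region
#' that is not among the assigned regions is an inconsistent record and
#' errors.
#'
#' @param records Validated corpus tibble.
#' @param assignment Region assignment from [assign_regions()].
#' @return The assignment tibble with endemic records pruned.
#' @export
resolve_endemic_cross_listings <- function(records, assignment) {
  stopifnot(identical(records$taxon_id, assignment$taxon_id))
  endemic <- which(!is.na(records$endemic_to))
  for (i in endemic) {
    home <- records$endemic_to[i]
    if (!home %in% assignment$regions[[i]]) {
      stop(sprintf(
        "inconsistent record %s: endemic_to '%s' not among assigned regions [%s]",
        records$taxon_id[i], home,
        paste(assignment$regions[[i]], collapse = ", ")), call. = FALSE)
    }
    assignment$regions[[i]] <- home
  }
  assignment
}

#' Overlap of each taxon with the focal species' range
#'
#' @param records Validated corpus tibble.
#' @param pig_range Range tibble from [read_pig_range()]; units missing
#'   from it are treated as absent.
#' @return Tibble `taxon_id`, `in_native`, `in_nonnative`,
#'   `in_potential_only`. A taxon is `in_potential_only` when it shares
#'   no native or non-native unit with the focal species but occurs in
#'   at least one unit where the species potentially occurs.
#' @export
range_overlap <- function(records, pig_range) {
  status <- lapply(records$units, pig_status, pig_range = pig_range)
  in_native <- vapply(status, function(s) any(s == "native"), logical(1))
  in_nonnative <- vapply(status, function(s) any(s == "nonnative"), logical(1))
  has_potential <- vapply(status, function(s) any(s == "potential"), logical(1))
  tibble::tibble(
    taxon_id = records$taxon_id,
    in_native = in_native,
    in_nonnative = in_nonnative,
    in_potential_only = !in_native & !in_nonnative & has_potential
  )
}

#' Exclude taxa outside the focal species' realised range
#'
#' Taxa overlapping the native or non-native range are always retained.
#' Taxa retained only through potentially-occupied units are kept only
#' if at least one of their potential units hosts a confirmed
#' threatened taxon (otherwise the whole potential area is dropped);
#' one pass suffices because removals cannot create new threatened
#' taxa. Taxa exclusively outside all three range classes are excluded.
#'
#' @param records Validated corpus tibble.
#' @param annotations Annotation tibble from [annotate_threats()].
#' @param pig_range Range tibble.
#' @return The retained corpus (subset of `records`, order preserved),
#'   with the excluded ids in attribute `"excluded_ids"`.
#' @export
apply_potential_rule <- function(records, annotations, pig_range) {
  ov <- range_overlap(records, pig_range)
  threatened <- records$taxon_id %in%
    annotations$taxon_id[annotations$pig_threatened]
  potential_units <- pig_range$unit[pig_range$status == "potential"]
  # Potential units justified by at least one confirmed threatened taxon.
  active <- unique(unlist(records$units[threatened]))
  active <- intersect(potential_units, active)
  keep <- ov$in_native | ov$in_nonnative |
    (ov$in_potential_only &
       vapply(records$units, function(u) any(u %in% active), logical(1)))
  retained <- records[keep, , drop = FALSE]
  attr(retained, "excluded_ids") <- records$taxon_id[!keep]
  retained
}

#' Partition taxa into island-endemic and continental strata
#'
#' A taxon whose resolved regions include any continental region
#' belongs to the continental stratum (continental co-occurrence always
#' demotes). A taxon endemic to an island region, all of whose resolved
#' regions are islands, is an island endemic. Island taxa without a
#' structured endemism claim fall in neither stratum (they are counted
#' in corpus-level tallies but not in the island/continental
#' comparison), and unit-less records are unassigned.
#'
#' @param records Validated corpus tibble.
#' @param resolved Region assignment after
#'   [resolve_endemic_cross_listings()].
#' @param region_table Region tibble.
#' @return Tibble `taxon_id`, `stratum` with values `island_endemic`,
#'   `continental`, `island_nonendemic` or `unassigned`.
#' @export
island_strata <- function(records, resolved, region_table) {
  stopifnot(identical(records$taxon_id, resolved$taxon_id))
  sys <- region_systems(region_table)
  stratum <- vapply(seq_len(nrow(records)), function(i) {
    regs <- resolved$regions[[i]]
    if (length(regs) == 0) return("unassigned")
    systems <- sys$system[match(regs, sys$region)]
    if (any(systems == "continental")) return("continental")
    if (!is.na(records$endemic_to[i])) "island_endemic" else "island_nonendemic"
  }, character(1))
  tibble::tibble(taxon_id = records$taxon_id, stratum = stratum)
}

#' The default 17-region table
#'
#' A shipped configuration of 17 biogeographic regions — 8 island
#' systems (Polynesia, Micronesia/Melanesia, Galapagos, New Zealand,
#' Caribbean, Madagascar, Indian Ocean Islands, Atlantic Islands) and
#' 9 continental systems (Europe, North America, Central America,
#' South America, Africa, Mainland Asia, Southeast Asia, Middle East,
#' Australia) — each with three synthetic admin-unit codes. Real
#' analyses supply their own unit-to-region table with the same code
#' set as their corpus; this default exists so the synthetic generator
#' and examples run out of the box.
#'
#' @return Region tibble (`unit`, `region`, `system`), 51 rows.
#' @export
default_region_table <- function() {
  island <- c("Polynesia", "Micronesia/Melanesia", "Galapagos",
              "New Zealand", "Caribbean", "Madagascar",
              "Indian Ocean Islands", "Atlantic Islands")
  continental <- c("Europe", "North America", "Central America",
                   "South America", "Africa", "Mainland Asia",
                   "Southeast Asia", "Middle East", "Australia")
  code <- c("POL", "MIC", "GAL", "NZL", "CAR", "MDG", "IOI", "ATL",
            "EUR", "NAM", "CAM", "SAM", "AFR", "ASI", "SEA", "MDE", "AUS")
  region <- c(island, continental)
  tibble::tibble(
    unit = paste0(rep(code, each = 3), "-", 1:3),
    region = rep(region, each = 3),
    system = rep(c("island", "continental"), c(8L, 9L) * 3L)
  )
}

#' The default focal-species range map for the shipped regions
#'
#' Range statuses over the units of [default_region_table()],
#' emulating a Eurasian native range with broad non-native
#' establishment: native across Europe, Mainland/Southeast Asia, the
#' Middle East and one North African unit; non-native across the
#' Americas, Australia and most island regions; a few units flagged as
#' potential occurrence or absent.
#'
#' @return Range tibble (`unit`, `status`).
#' @export
default_pig_range <- function() {
  rt <- default_region_table()
  status <- rep("nonnative", nrow(rt))
  native_regions <- c("Europe", "Mainland Asia", "Southeast Asia",
                      "Middle East")
  status[rt$region %in% native_regions] <- "native"
  status[rt$unit == "AFR-1"] <- "native"     # North Africa
  status[rt$unit == "AFR-2"] <- "potential"
  status[rt$unit == "AFR-3"] <- "absent"
  status[rt$unit == "IOI-3"] <- "potential"
  status[rt$unit == "ATL-3"] <- "absent"
  status[rt$unit == "CAM-3"] <- "absent"
  tibble::tibble(unit = rt$unit, status = status)
}
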