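# Readers/writers for the four tabular inputs and the annotated outputs.
# All tables are plain tibbles; multi-valued fields (admin units, cues,
# mechanisms) are list-columns in memory and semicolon-joined on disk.

empty_corpus <- function() {
  tibble::tibble(taxon_id = character(0), scientific_name = character(0),
                 taxon_class = character(0), family = character(0),
                 category = character(0), units = list(),
                 threats_text = character(0), range_text = character(0),
                 endemic_to = character(0))
}

corpus_columns <- function() {
  c("taxon_id", "scientific_name", "taxon_class", "family", "category",
    "units", "threats_text", "range_text", "endemic_to")
}

read_table_chr <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE)
}

split_multi <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    out <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    out[nzchar(out)]
  })
}

join_multi <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

#' Read a Red-List-style taxon corpus
#'
#' Parses one record per taxon: identifier, scientific name, taxonomic
#' class, family, Red List category, occurrence admin units
#' (semicolon-joined in CSV), the free-text threat narrative, the
#' free-text range description, and an optional structured endemism
#' field naming the single region the taxon is endemic to.
#'
#' @param path Path to a CSV (UTF-8, header row, quoted fields may
#'   contain commas/newlines) or a JSON array of objects with the same
#'   field names.
#' @param format `"csv"` (default) or `"json"`.
#' @return A tibble with columns `taxon_id`, `scientific_name`,
#'   `taxon_class`, `family`, `category`, `units` (list-column of
#'   character), `threats_text`, `range_text`, `endemic_to`
#'   (`NA` when unset). Row order is preserved.
#' @details Validation errors identify the offending column, row or
#'   identifier: a missing mandatory column, a duplicated `taxon_id`, a
#'   category or class outside the controlled vocabulary, or a non-EX
#'   taxon with no admin units all abort the read.
#' @seealso [write_corpus()], [rl_categories()], [taxon_classes()]
#' @export
read_corpus <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- read_table_chr(path)
  } else {
    df <- tibble::as_tibble(jsonlite::fromJSON(path))
    for (col in intersect(names(df), c("taxon_id", "scientific_name",
                                       "taxon_class", "family", "category",
                                       "threats_text", "range_text",
                                       "endemic_to"))) {
      df[[col]] <- as.character(df[[col]])
    }
  }
  required <- setdiff(corpus_columns(), "endemic_to")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("corpus schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"endemic_to" %in% names(df)) df$endemic_to <- NA_character_
  as_corpus(df)
}

#' Validate an in-memory corpus tibble
#'
#' Coerces a data frame with corpus columns into the validated form
#' returned by [read_corpus()] (units split into a list-column, blank
#' `endemic_to` mapped to `NA`) and enforces the corpus invariants.
#'
#' @param df Data frame with the corpus columns; `units` may be a
#'   semicolon-joined character column or a list-column.
#' @return A validated corpus tibble.
#' @export
as_corpus <- function(df) {
  df <- tibble::as_tibble(df)
  if (!is.list(df$units)) df$units <- split_multi(df$units)
  for (col in c("threats_text", "range_text")) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  df$endemic_to[!is.na(df$endemic_to) & !nzchar(df$endemic_to)] <- NA_character_

  dup <- unique(df$taxon_id[duplicated(df$taxon_id)])
  if (length(dup)) {
    stop("duplicate taxon_id in corpus: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$category %in% rl_categories())
  if (length(bad)) {
    stop(sprintf("validation error: unknown category '%s' (row %d)",
                 df$category[bad[1]], bad[1]), call. = FALSE)
  }
  bad <- which(!df$taxon_class %in% taxon_classes())
  if (length(bad)) {
    stop(sprintf("validation error: unknown taxon_class '%s' (row %d)",
                 df$taxon_class[bad[1]], bad[1]), call. = FALSE)
  }
  no_units <- lengths(df$units) == 0
  bad <- which(no_units & df$category != "EX")
  if (length(bad)) {
    stop("validation error: empty units for non-extinct taxa: ",
         paste(df$taxon_id[bad], collapse = ", "), call. = FALSE)
  }
  df[corpus_columns()]
}

#' Write a corpus to CSV
#'
#' Inverse of [read_corpus()]: `units` is semicolon-joined and an unset
#' `endemic_to` is written as the empty string, so
#' `read_corpus(write_corpus(x, f))` reproduces every field exactly.
#'
#' @param corpus Validated corpus tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  out <- corpus
  out$units <- join_multi(out$units)
  out$endemic_to[is.na(out$endemic_to)] <- ""
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read the focal-species range table
#'
#' Two-column CSV `unit,status` mapping each admin unit to the focal
#' species' range status there: `native`, `nonnative`, `potential`
#' (described as potentially occurring) or `absent`. Units missing from
#' the table are treated as `absent` downstream.
#'
#' @param path CSV path; a zero-byte file yields an empty map.
#' @return Tibble with character columns `unit` and `status`.
#' @export
read_pig_range <- function(path) {
  if (!file.exists(path)) stop("range file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(tibble::tibble(unit = character(0), status = character(0)))
  }
  df <- read_table_chr(path)
  missing <- setdiff(c("unit", "status"), names(df))
  if (length(missing)) {
    stop("range schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(df$unit[duplicated(df$unit)])
  if (length(dup)) {
    stop("conflicting or duplicate status for unit(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$status %in% range_statuses())
  if (length(bad)) {
    stop(sprintf("validation error: unknown range status '%s' (unit %s)",
                 df$status[bad[1]], df$unit[bad[1]]), call. = FALSE)
  }
  df[c("unit", "status")]
}

# Vectorised status lookup; units absent from the map are "absent".
pig_status <- function(pig_range, units) {
  idx <- match(units, pig_range$unit)
  out <- pig_range$status[idx]
  out[is.na(idx)] <- "absent"
  out
}

#' Read the region table
#'
#' CSV `unit,region,system` assigning each admin unit to one of the
#' biogeographic regions (17 in the default configuration) and each
#' region to an `island` or `continental` system. Every region must
#' carry exactly one system class.
#'
#' @param path CSV path.
#' @return Tibble with character columns `unit`, `region`, `system`.
#' @seealso [default_region_table()]
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path, call. = FALSE)
  df <- read_table_chr(path)
  missing <- setdiff(c("unit", "region", "system"), names(df))
  if (length(missing)) {
    stop("region schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(df$unit[duplicated(df$unit)])
  if (length(dup)) {
    stop("duplicate region assignment for unit(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$system %in% c("island", "continental"))
  if (length(bad)) {
    stop(sprintf("validation error: unknown system '%s' (region %s)",
                 df$system[bad[1]], df$region[bad[1]]), call. = FALSE)
  }
  sys <- unique(df[c("region", "system")])
  dup_region <- unique(sys$region[duplicated(sys$region)])
  if (length(dup_region)) {
    stop("region mapped to both island and continental: ",
         paste(dup_region, collapse = ", "), call. = FALSE)
  }
  df[c("unit", "region", "system")]
}

# One row per region with its system class.
region_systems <- function(region_table) {
  unique(region_table[c("region", "system")])
}

#' Read a curation file
#'
#' The structured stand-in for two-reviewer manual reading of flagged
#' narratives: per taxon a verdict (`confirm` or `false_positive`), the
#' evidence cues the reviewers recorded (semicolon-joined), and an
#' optional stated severity grade that overrides the category-based
#' default. Cues and grade of a `false_positive` entry are ignored.
#'
#' @param path CSV path with columns
#'   `taxon_id,verdict,cues,stated_grade`.
#' @return Tibble with `taxon_id`, `verdict`, `cues` (list-column) and
#'   `stated_grade` (`NA` when unset).
#' @seealso [curation_cues()], [apply_review()]
#' @export
read_curation <- function(path) {
  if (!file.exists(path)) stop("curation file not found: ", path, call. = FALSE)
  df <- read_table_chr(path)
  missing <- setdiff(c("taxon_id", "verdict", "cues", "stated_grade"), names(df))
  if (length(missing)) {
    stop("curation schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as_curation(df)
}

#' @rdname read_curation
#' @param df Data frame with curation columns; `cues` may be
#'   semicolon-joined character or a list-column.
#' @export
as_curation <- function(df) {
  df <- tibble::as_tibble(df)
  if (!is.list(df$cues)) df$cues <- split_multi(df$cues)
  df$stated_grade[!is.na(df$stated_grade) & !nzchar(df$stated_grade)] <-
    NA_character_
  dup <- unique(df$taxon_id[duplicated(df$taxon_id)])
  if (length(dup)) {
    stop("duplicate curation entry for: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$verdict %in% c("confirm", "false_positive"))
  if (length(bad)) {
    stop(sprintf("validation error: unknown verdict '%s' (taxon %s)",
                 df$verdict[bad[1]], df$taxon_id[bad[1]]), call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(df$cues)), curation_cues())
  if (length(unknown)) {
    stop("validation error: unknown cue token(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(df$stated_grade) &
                 !df$stated_grade %in% severity_levels())
  if (length(bad)) {
    stop(sprintf("validation error: unknown stated_grade '%s' (taxon %s)",
                 df$stated_grade[bad[1]], df$taxon_id[bad[1]]), call. = FALSE)
  }
  # False-positive verdicts carry no usable evidence downstream.
  fp <- df$verdict == "false_positive"
  df$cues[fp] <- list(character(0))
  df$stated_grade[fp] <- NA_character_
  df[c("taxon_id", "verdict", "cues", "stated_grade")]
}

#' Write per-taxon threat annotations to CSV
#'
#' @param annotations Annotation tibble from [annotate_threats()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations
  out$mechanisms <- join_multi(out$mechanisms)
  out$cues <- join_multi(out$cues)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write the manual-review queue to CSV
#'
#' One row per flagged taxon with the matched tokens, the patterns they
#' matched, and whether every hit came from a wildcard prefix only
#' (the classic false-positive signature, e.g. "pigeon").
#'
#' @param screen Screen results from [screen_corpus()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_review_queue <- function(screen, path) {
  out <- tibble::tibble(
    taxon_id = screen$taxon_id,
    tokens = vapply(screen$hits, function(h) paste(h$token, collapse = ";"),
                    character(1)),
    patterns = vapply(screen$hits, function(h)
      paste(unique(unlist(h$patterns)), collapse = ";"), character(1)),
    prefix_only = screen$prefix_only
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
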