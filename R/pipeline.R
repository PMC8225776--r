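# Orchestration: screen -> review -> classify -> geography -> summary,
# with a file-based front end that writes stage outputs and a manifest.

#' Run the full threat-assessment pipeline in memory
#'
#' Composes the pipeline stages: keyword screen over threat narratives,
#' curated review (false-positive and out-of-scope removal), severity
#' and mechanism classification, region assignment with island-endemic
#' cross-listing pruning, range-overlap exclusion (including the
#' potential-occurrence rule), stratification, and the summary report.
#'
#' @param records Validated corpus tibble.
#' @param pig_range Range tibble from [read_pig_range()].
#' @param region_table Region tibble from [read_region_table()].
#' @param curation Curation tibble from [read_curation()].
#' @param keywords A `keyword_set`; defaults to the wild-pig patterns.
#' @param mode Review mode, `"strict"` or `"lenient"`
#'   (see [apply_review()]).
#' @return List with `report` (a `threat_summary_report`), `screen`,
#'   `annotations` (retained taxa only), `retained` corpus, `resolved`
#'   regions, `overlaps`, `strata`, and `manifest` (stage counts:
#'   `n_records`, `n_flagged`, `n_confirmed`, `n_threatened_retained`,
#'   `n_retained`).
#' @export
run_pipeline <- function(records, pig_range, region_table, curation,
                         keywords = default_keywords(),
                         mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  screen <- screen_corpus(records, keywords)
  confirmed <- apply_review(screen, curation, mode)
  annotations <- annotate_threats(records, confirmed)

  retained <- apply_potential_rule(records, annotations, pig_range)
  annotations <- annotations[annotations$taxon_id %in% retained$taxon_id, ]

  assignment <- assign_regions(retained, region_table)
  resolved <- resolve_endemic_cross_listings(retained, assignment)
  overlaps <- range_overlap(retained, pig_range)
  strata <- island_strata(retained, resolved, region_table)

  report <- build_report(retained, annotations, resolved, region_table,
                         overlaps, strata)
  manifest <- list(
    n_records = nrow(records),
    n_flagged = nrow(screen),
    n_confirmed = nrow(confirmed),
    n_threatened_retained = nrow(annotations),
    n_retained = nrow(retained)
  )
  list(report = report, screen = screen, annotations = annotations,
       retained = retained, resolved = resolved, overlaps = overlaps,
       strata = strata, manifest = manifest)
}

#' Run the pipeline from files and write all outputs
#'
#' File front end over [run_pipeline()]: reads the corpus, range,
#' region and curation tables, runs every stage, and writes the
#' annotated corpus, review queue, overlap table, report
#' (JSON + Markdown + per-region CSV) and a manifest with input MD5
#' hashes and stage counts. Outputs carry no timestamps, so rerunning
#' on identical inputs is byte-identical.
#'
#' @param corpus,pig_range,regions,curation Input file paths.
#' @param out_dir Output directory (created if needed).
#' @param keywords Optional YAML keyword file (see [read_keywords()]);
#'   `NULL` uses the default wild-pig patterns.
#' @param mode Review mode, `"strict"` or `"lenient"`.
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_all <- function(corpus, pig_range, regions, curation, out_dir,
                    keywords = NULL, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  kw <- if (is.null(keywords)) default_keywords() else read_keywords(keywords)
  inputs <- c(corpus = corpus, pig_range = pig_range, regions = regions,
              curation = curation)
  res <- run_pipeline(
    records = read_corpus(corpus),
    pig_range = read_pig_range(pig_range),
    region_table = read_region_table(regions),
    curation = read_curation(curation),
    keywords = kw, mode = mode
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_review_queue(res$screen, file.path(out_dir, "review_queue.csv"))
  write_annotations(res$annotations, file.path(out_dir, "annotations.csv"))
  readr::write_csv(res$overlaps, file.path(out_dir, "range_overlap.csv"))
  write_report(res$report, out_dir)
  manifest <- c(
    list(input_md5 = as.list(tools::md5sum(inputs))),
    res$manifest
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
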