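# Independent oracles and fixture builders shared across test files.

# Brute-force keyword oracle: one full-text regex scan per pattern,
# with word boundaries expressed as lookarounds, never touching the
# package tokenizer. Returns flagged/prefix_only plus hit offsets.
oracle_match <- function(text, kw) {
  find <- function(pat) {
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  lit <- sort(unique(unlist(lapply(kw$literals, function(p) {
    find(paste0("(?i)(?<![[:alpha:]])", p, "(?![[:alpha:]])"))
  }))))
  pre <- sort(unique(unlist(lapply(kw$prefixes, function(p) {
    find(paste0("(?i)(?<![[:alpha:]])", p, "[[:alpha:]]*"))
  }))))
  offsets <- sort(union(lit, pre))
  list(flagged = length(offsets) > 0,
       prefix_only = length(offsets) > 0 && length(lit) == 0,
       offsets = offsets)
}

# Random text over a vocabulary rich in near-keywords and separators.
random_text <- function(n_words) {
  vocab <- c("pig", "pigs", "Piglet", "pigeon", "pigment", "boar", "Boards",
             "boardwalk", "hog", "hogs", "hogweed", "swine", "Sus", "scrofa",
             "domesticus", "suspect", "goat", "rat", "cat", "habitat",
             "loss", "nest", "predation", "fire", "the", "and", "warthog")
  sep <- c(" ", ", ", "-", " (", ") ", ". ", "; ", " 3 ")
  if (n_words == 0) return("")
  words <- sample(vocab, n_words, replace = TRUE)
  paste0(paste(words, sample(sep, n_words, replace = TRUE), collapse = ""),
         "end")
}

# Minimal single-region world used by hand-built fixtures.
tiny_region_table <- function() {
  tibble::tibble(
    unit = c("ISL-1", "ISL-2", "CON-1", "CON-2", "POT-1", "ABS-1"),
    region = c("Isle", "Isle", "Mainland", "Mainland", "Mainland", "Nowhere"),
    system = c("island", "island", "continental", "continental",
               "continental", "continental")
  )
}

tiny_pig_range <- function() {
  tibble::tibble(
    unit = c("ISL-1", "ISL-2", "CON-1", "CON-2", "POT-1"),
    status = c("nonnative", "nonnative", "native", "nonnative", "potential")
  )
}

# Hand-built corpus rows with sensible defaults.
make_records <- function(taxon_id, taxon_class = "plant", category = "CR",
                         units = list("CON-1"), threats_text = "",
                         endemic_to = NA_character_, family = "Testaceae") {
  threatminer::as_corpus(tibble::tibble(
    taxon_id = taxon_id,
    scientific_name = paste("Testus", taxon_id),
    taxon_class = taxon_class, family = family, category = category,
    units = units, threats_text = threats_text, range_text = "",
    endemic_to = endemic_to
  ))
}

make_annotations <- function(records, cues = "consumption",
                             stated_grade = NA_character_) {
  confirmed <- tibble::tibble(
    taxon_id = records$taxon_id,
    cues = rep(list(cues), nrow(records)),
    stated_grade = rep(stated_grade, length.out = nrow(records))
  )
  annotate_threats(records, confirmed)
}
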