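# Wildcard keyword screen over threat narratives. The matcher is
# deliberately permissive (a trailing-* pattern matches any letter
# suffix, so pig* catches pigeon): over-matching followed by manual
# curation is the design, and nothing is auto-excluded at screen time.

#' Build a keyword set
#'
#' A keyword set holds lower-cased literal tokens and prefix stems
#' (from trailing-`*` wildcard patterns). A token hits when it equals a
#' literal or begins with a stem; matching is case-insensitive.
#'
#' @param literals Character vector of literal tokens.
#' @param prefixes Character vector of stems; `"pig"` here means the
#'   pattern `pig*`.
#' @return An object of class `keyword_set`.
#' @seealso [default_keywords()], [match_keywords()]
#' @export
keyword_set <- function(literals, prefixes = character(0)) {
  literals <- unique(tolower(literals))
  prefixes <- unique(tolower(prefixes))
  if (length(literals) + length(prefixes) == 0) {
    stop("keyword set must contain at least one pattern", call. = FALSE)
  }
  if (!all(grepl("^[a-z]+$", c(literals, prefixes)))) {
    stop("keyword patterns must be purely alphabetic tokens", call. = FALSE)
  }
  structure(list(literals = literals, prefixes = prefixes),
            class = "keyword_set")
}

#' The default wild-pig keyword set
#'
#' The 13 search patterns used to flag pig mentions in threat
#' narratives: literals pig, pigs, domesticus, sus, scrofa, boar,
#' boars, hog, hogs, swine and wildcards pig*, boar*, hog*.
#'
#' @return A `keyword_set`.
#' @export
default_keywords <- function() {
  keyword_set(
    literals = c("pig", "pigs", "domesticus", "sus", "scrofa",
                 "boar", "boars", "hog", "hogs", "swine"),
    prefixes = c("pig", "boar", "hog")
  )
}

#' Read a keyword set from YAML
#'
#' @param path YAML file with top-level keys `literals` and `prefixes`
#'   (lists of tokens; a trailing `*` on a prefix entry is tolerated and
#'   stripped).
#' @return A `keyword_set`.
#' @export
read_keywords <- function(path) {
  cfg <- yaml::read_yaml(path)
  keyword_set(
    literals = as.character(cfg$literals %||% character(0)),
    prefixes = sub("\\*$", "", as.character(cfg$prefixes %||% character(0)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.keyword_set <- function(x, ...) {
  cat("<keyword_set> ", length(x$literals), " literals, ",
      length(x$prefixes), " wildcard prefixes\n", sep = "")
  cat("  literals:", paste(x$literals, collapse = ", "), "\n")
  cat("  wildcards:", paste(paste0(x$prefixes, "*"), collapse = ", "), "\n")
  invisible(x)
}

#' Tokenize free text into word tokens with offsets
#'
#' Tokens are maximal runs of letters, lower-cased; digits, hyphens,
#' parentheses and all other punctuation act as separators. Offsets
#' index the first character of each token in the original text
#' (1-based).
#'
#' @param text A single character string (empty or `NA` allowed).
#' @return Tibble with columns `token` and `offset`.
#' @examples
#' tokenize("Rooting by feral pigs (Sus scrofa).")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  empty <- tibble::tibble(token = character(0), offset = integer(0))
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[[:alpha:]]+", text)[[1]]
  if (m[1] == -1L) return(empty)
  tibble::tibble(
    token = tolower(substring(text, m, m + attr(m, "match.length") - 1L)),
    offset = as.integer(m)
  )
}

#' Match a keyword set against one narrative
#'
#' A token hits iff it equals a literal pattern or begins with a
#' wildcard stem; all matching patterns are recorded per hit.
#' `prefix_only` is `TRUE` when the text is flagged but every hit
#' matched only through a wildcard (no literal), the signature of
#' likely false positives such as "pigeon" under `pig*`.
#'
#' @param text A single character string.
#' @param kw A `keyword_set`.
#' @return A list with `hits` (tibble `token`, `offset`, `patterns`
#'   list-column, `via_literal`), `flagged` and `prefix_only`.
#' @examples
#' match_keywords("pigeon predation is severe", default_keywords())$prefix_only
#' @export
match_keywords <- function(text, kw = default_keywords()) {
  stopifnot(inherits(kw, "keyword_set"))
  tok <- tokenize(text)
  pats <- lapply(tok$token, function(t) {
    lit <- kw$literals[kw$literals == t]
    pre <- kw$prefixes[startsWith(t, kw$prefixes)]
    c(lit, if (length(pre)) paste0(pre, "*"))
  })
  via_literal <- vapply(tok$token, function(t) t %in% kw$literals, logical(1),
                        USE.NAMES = FALSE)
  hit <- lengths(pats) > 0
  hits <- tok[hit, , drop = FALSE]
  hits$patterns <- pats[hit]
  hits$via_literal <- via_literal[hit]
  flagged <- nrow(hits) > 0
  list(
    hits = hits,
    flagged = flagged,
    prefix_only = flagged && !any(hits$via_literal)
  )
}

#' Screen a corpus and build the manual-review queue
#'
#' Runs [match_keywords()] over each record's threat narrative
#' (`threats_text` only; range descriptions are not screened) and
#' returns one row per flagged record. Unflagged records take no
#' further part in the threat analysis; the flagged set is the queue
#' handed to manual review.
#'
#' @param records Validated corpus tibble from [read_corpus()].
#' @param kw A `keyword_set`; defaults to the wild-pig patterns.
#' @return Tibble with `taxon_id`, `hits` (list-column of hit tibbles),
#'   `n_hits` and `prefix_only`, one row per flagged record, in corpus
#'   order.
#' @export
screen_corpus <- function(records, kw = default_keywords()) {
  res <- lapply(records$threats_text, match_keywords, kw = kw)
  flagged <- vapply(res, `[[`, logical(1), "flagged")
  tibble::tibble(
    taxon_id = records$taxon_id[flagged],
    hits = lapply(res[flagged], `[[`, "hits"),
    n_hits = vapply(res[flagged], function(r) nrow(r$hits), integer(1)),
    prefix_only = vapply(res[flagged], `[[`, logical(1), "prefix_only")
  )
}
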