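#' Read DOI-to-DOI citation pairs
#'
#' Reads a citation dump and returns normalized, deduplicated directed
#' citation records. Two dialects are supported: `"coci"`, the OpenCitations
#' COCI CSV export (header row with columns such as `oci`, `citing`,
#' `cited`, `creation`, `timespan`; only `citing` and `cited` are consumed),
#' and `"minimal"`, a two-column `citing,cited` CSV with header.
#'
#' DOIs are case-insensitive, so both endpoints are lowercased and trimmed
#' before comparison. Self-citations (citing == cited after normalization)
#' are dropped, as are duplicate (citing, cited) pairs: all downstream
#' networks are simple digraphs. The number of rows dropped by each rule is
#' reported via `message()` and attached as the `"dropped"` attribute.
#'
#' @param path Path to the CSV file.
#' @param dialect `"coci"` or `"minimal"`.
#' @return A data.frame with character columns `citing` and `cited`, one row
#'   per retained citation, with attribute `dropped` = c(self, duplicate).
#' @export
read_citations <- function(path, dialect = c("coci", "minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("citation file not found: ", path)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  for (col in c("citing", "cited")) {
    if (!col %in% names(raw)) {
      stop("citation file ", path, " is missing required column '", col, "'")
    }
  }
  citing <- normalize_doi(raw[["citing"]])
  cited <- normalize_doi(raw[["cited"]])
  bad <- is.na(citing) | is.na(cited) | citing == "" | cited == ""
  if (any(bad)) {
    warning(sum(bad), " unreadable citation row(s) skipped")
    citing <- citing[!bad]
    cited <- cited[!bad]
  }
  self <- citing == cited
  citing <- citing[!self]
  cited <- cited[!self]
  dup <- duplicated(paste(citing, cited, sep = "\r"))
  out <- data.frame(citing = citing[!dup], cited = cited[!dup],
                    stringsAsFactors = FALSE)
  n_self <- sum(self)
  n_dup <- sum(dup)
  if (n_self + n_dup > 0) {
    message("read_citations: dropped ", n_self, " self-citation(s) and ",
            n_dup, " duplicate pair(s)")
  }
  attr(out, "dropped") <- c(self = n_self, duplicate = n_dup)
  out
}

#' Write citations in the canonical two-column form
#'
#' @param citations Data.frame with `citing` and `cited` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_citations <- function(citations, path) {
  utils::write.csv(citations[, c("citing", "cited")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

normalize_doi <- function(x) {
  tolower(trimws(x))
}

#' Read the article metadata sidecar
#'
#' The citation dump carries no article attributes, so eligibility (language
#' and publication type) and field tags come from a tab-separated sidecar
#' with columns `doi`, `headings` (pipe-separated heading IDs, possibly
#' empty), `journal`, `language`, `pub_type`. Later rows for the same DOI
#' override earlier ones (with a warning).
#'
#' @param path Path to the TSV file.
#' @return A data.frame keyed by `doi` with a list-column `headings` of
#'   character vectors plus `journal`, `language`, `pub_type`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop("metadata file not found: ", path)
  }
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
  needed <- c("doi", "headings", "journal", "language", "pub_type")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("metadata file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$doi <- normalize_doi(raw$doi)
  dup <- duplicated(raw$doi, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate metadata row(s) overridden by later rows")
    raw <- raw[!dup, , drop = FALSE]
  }
  headings <- lapply(raw$headings, parse_heading_list)
  out <- data.frame(doi = raw$doi, journal = raw$journal,
                    language = raw$language, pub_type = raw$pub_type,
                    stringsAsFactors = FALSE)
  out$headings <- headings
  rownames(out) <- out$doi
  out
}

parse_heading_list <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(character(0))
  }
  parts <- trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) character(0) else unique(parts)
}

#' Assemble a citation corpus
#'
#' Bundles deduplicated citations with per-article metadata. Every DOI that
#' appears in a retained citation gets a metadata entry; DOIs absent from
#' the sidecar receive a sentinel entry (no headings, journal `"unknown"`,
#' empty language/type) so they remain in the corpus but can never enter a
#' field network.
#'
#' @param citations Data.frame from [read_citations()].
#' @param articles Data.frame from [read_metadata()] (may cover only part of
#'   the cited DOIs).
#' @return An object of class `citation_corpus` with elements `citations`
#'   and `articles`.
#' @export
citation_corpus <- function(citations, articles = NULL) {
  stopifnot(is.data.frame(citations),
            all(c("citing", "cited") %in% names(citations)))
  if (is.null(articles)) {
    articles <- data.frame(doi = character(0), journal = character(0),
                           language = character(0), pub_type = character(0),
                           stringsAsFactors = FALSE)
    articles$headings <- list()
  }
  referenced <- unique(c(citations$citing, citations$cited))
  missing <- setdiff(referenced, articles$doi)
  if (length(missing) > 0) {
    filler <- data.frame(doi = missing, journal = "unknown",
                         language = "", pub_type = "",
                         stringsAsFactors = FALSE)
    filler$headings <- rep(list(character(0)), length(missing))
    articles <- rbind(articles, filler)
  }
  rownames(articles) <- articles$doi
  structure(list(citations = citations, articles = articles),
            class = "citation_corpus")
}

#' @export
print.citation_corpus <- function(x, ...) {
  cat("citation_corpus:", nrow(x$citations), "citations,",
      nrow(x$articles), "articles,",
      length(eligible_articles(x)), "eligible\n")
  invisible(x)
}

#' English journal articles eligible for network construction
#'
#' Network construction is restricted to journal articles written in
#' English; this returns their DOIs.
#'
#' @param corpus A `citation_corpus`.
#' @param language Eligible language code (default `"en"`).
#' @param pub_type Eligible publication type (default `"journal-article"`).
#' @return Character vector of eligible DOIs.
#' @export
eligible_articles <- function(corpus, language = "en",
                              pub_type = "journal-article") {
  stopifnot(inherits(corpus, "citation_corpus"))
  a <- corpus$articles
  a$doi[a$language == language & a$pub_type == pub_type]
}

#' Summarize a corpus as JSON
#'
#' @param corpus A `citation_corpus`.
#' @param path Optional path; when given the summary is written as JSON.
#' @return A list with citation/article/eligible counts (invisibly when
#'   `path` is given).
#' @export
corpus_summary <- function(corpus, path = NULL) {
  s <- list(n_citations = nrow(corpus$citations),
            n_articles = nrow(corpus$articles),
            n_eligible = length(eligible_articles(corpus)),
            n_journals = length(unique(corpus$articles$journal)))
  if (!is.null(path)) {
    jsonlite::write_json(s, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(s))
  }
  s
}

# DOIs (eligible ones only) tagged with each heading, as a named list.
heading_index <- function(corpus, eligible = eligible_articles(corpus)) {
  a <- corpus$articles[corpus$articles$doi %in% eligible, , drop = FALSE]
  n_tags <- lengths(a$headings)
  if (sum(n_tags) == 0) {
    return(list())
  }
  split(rep(a$doi, n_tags), unlist(a$headings))
}
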