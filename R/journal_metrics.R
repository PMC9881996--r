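#' Field-specific journal scores
#'
#' Scores each journal within one field as the median PageRank of the
#' field's articles published in that journal (even counts use the midpoint
#' of the two central values). Journals with fewer than `min_articles`
#' field articles are excluded; the rest are ranked by score descending,
#' ties broken lexicographically by journal ID.
#'
#' @param pr `pagerank_vector` of one field's network.
#' @param corpus The `citation_corpus` supplying journal assignments.
#' @param min_articles Minimum articles a journal needs in the field.
#' @return Data.frame with columns `journal`, `field`, `score`,
#'   `n_articles`, `rank` (1 = highest median).
#' @export
journal_scores <- function(pr, corpus, min_articles = 1) {
  dois <- names(pr)
  journals <- corpus$articles[dois, "journal"]
  med <- tapply(as.numeric(pr), journals, stats::median)
  n <- tapply(as.numeric(pr), journals, length)
  keep <- n >= min_articles
  out <- data.frame(journal = names(med)[keep],
                    field = attr(pr, "scope"),
                    score = as.numeric(med[keep]),
                    n_articles = as.integer(n[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$journal), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' How often each journal tops a field's ranking
#'
#' @param scores_per_field Named list (by field) of [journal_scores()]
#'   tables.
#' @return Named integer vector: for each journal appearing at rank 1 in at
#'   least one field, the number of fields it tops. Counts sum to the
#'   number of fields with a nonempty ranking.
#' @export
top_journal_frequency <- function(scores_per_field) {
  stopifnot(length(scores_per_field) >= 1)
  tops <- vapply(scores_per_field, function(s) {
    if (nrow(s) == 0) NA_character_ else s$journal[s$rank == 1]
  }, character(1))
  tops <- tops[!is.na(tops)]
  counts <- table(tops)
  stats::setNames(as.integer(counts), names(counts))
}

#' Number of fields publishing in each journal
#'
#' Restricted to journals with at least `min_total` articles across all
#' field networks, counts for each journal the number of fields in which
#' it has at least one article.
#'
#' @param corpus The `citation_corpus`.
#' @param field_networks Named list (by field) of single-field
#'   `citation_network`s.
#' @param min_total Dataset-wide minimum article count per journal
#'   (default 50).
#' @return Named integer vector, journal -> number of fields.
#' @export
fields_per_journal <- function(corpus, field_networks, min_total = 50) {
  per_field <- lapply(field_networks, function(net) {
    dois <- network_nodes(net)
    unique(corpus$articles[dois, "journal"])
  })
  all_dois <- unique(unlist(lapply(field_networks, network_nodes)))
  totals <- table(corpus$articles[all_dois, "journal"])
  eligible_journals <- names(totals)[totals >= min_total]
  counts <- table(unlist(per_field))
  counts <- counts[names(counts) %in% eligible_journals]
  stats::setNames(as.integer(counts), names(counts))
}
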