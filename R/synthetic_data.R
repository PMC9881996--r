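#' Generate a synthetic citation corpus
#'
#' Emulates the statistical structure the pipeline assumes at toy scale:
#' articles tagged with one or two of `n_fields` subject headings, journals
#' with Zipf-distributed sizes, and a sequential citation process with
#' preferential attachment (heavy-tailed in-degree), cross-field citations,
#' and optional planted field-favored articles. Citations only point
#' backward in generation order, mimicking publication time-ordering, so
#' the graph is acyclic with realistic dangling structure and can contain
#' no self-citations.
#'
#' Each article draws `Poisson(lambda)` references among earlier articles;
#' a reference stays within the citing article's field(s) with probability
#' `1 - cross_field_rate`, and targets are chosen with probability
#' proportional to `(in_degree + 1)^gamma`. A planted article's selection
#' weight is multiplied by its boost only when the citing article belongs
#' to the planted article's favored field; planted articles are tagged with
#' both their favored field and a second field so they appear in affinity
#' tables.
#'
#' @param n_fields Number of fields (default 2).
#' @param n_per_field Articles whose primary tag is each field
#'   (default 400).
#' @param overlap_fraction Probability an article carries a second field
#'   tag (default 0.2).
#' @param n_journals Number of journals (default 20), sizes Zipf with
#'   exponent `zipf_exponent` (default 1.2).
#' @param gamma Preferential-attachment strength (default 1).
#' @param lambda Mean references per article to earlier in-corpus articles
#'   (default 5).
#' @param cross_field_rate Probability a reference ignores field membership
#'   (default 0.1).
#' @param planted Optional data.frame with columns `doi`, `field`, `boost`
#'   (boost > 1), e.g. from [synthetic_planted()].
#' @param zipf_exponent Zipf exponent for journal sizes.
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   arguments.
#' @return A `citation_corpus`; field heading IDs are available through
#'   [synthetic_field_ids()].
#' @export
generate_corpus <- function(n_fields = 2, n_per_field = 400,
                            overlap_fraction = 0.2, n_journals = 20,
                            gamma = 1, lambda = 5, cross_field_rate = 0.1,
                            planted = NULL, zipf_exponent = 1.2,
                            seed = 1) {
  stopifnot(n_fields >= 1, overlap_fraction >= 0, overlap_fraction <= 1,
            cross_field_rate >= 0, cross_field_rate <= 1,
            lambda > 0, gamma >= 0)
  if (!is.null(planted)) {
    stopifnot(all(c("doi", "field", "boost") %in% names(planted)),
              all(planted$boost > 1))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(seed)

  total <- n_fields * n_per_field
  fields <- synthetic_field_ids(n_fields)
  if (total == 0) {
    return(citation_corpus(data.frame(citing = character(0),
                                      cited = character(0))))
  }
  dois <- synthetic_dois(total)
  primary <- rep_len(seq_len(n_fields), total)
  headings <- lapply(seq_len(total), function(i) fields[primary[i]])
  if (n_fields > 1 && overlap_fraction > 0) {
    dual <- stats::runif(total) < overlap_fraction
    for (i in which(dual)) {
      others <- setdiff(seq_len(n_fields), primary[i])
      second <- if (length(others) == 1) others else sample(others, 1)
      headings[[i]] <- c(headings[[i]], fields[second])
    }
  }

  plant_boost <- rep(1, total)
  plant_field <- rep(NA_character_, total)
  if (!is.null(planted) && nrow(planted) > 0) {
    idx <- match(planted$doi, dois)
    if (anyNA(idx)) {
      stop("planted DOI(s) not part of the generated corpus")
    }
    plant_boost[idx] <- planted$boost
    plant_field[idx] <- planted$field
    for (k in seq_along(idx)) {
      i <- idx[k]
      fav <- planted$field[k]
      other <- setdiff(fields, fav)
      second <- if (length(other) == 0) character(0) else other[1]
      headings[[i]] <- unique(c(fav, second))
    }
  }

  journal_prob <- seq_len(n_journals)^(-zipf_exponent)
  journals <- sprintf("J%03d", sample(n_journals, total, replace = TRUE,
                                      prob = journal_prob))

  in_deg <- rep(0L, total)
  field_sets <- lapply(headings, unique)
  # article x field membership, for fast within-field candidate masks
  field_mat <- matrix(FALSE, total, n_fields)
  for (i in seq_len(total)) {
    field_mat[i, match(field_sets[[i]], fields)] <- TRUE
  }
  citing_out <- vector("list", total)
  for (i in seq_len(total)[-1]) {
    k <- stats::rpois(1, lambda)
    if (k == 0) next
    prior <- seq_len(i - 1)
    fidx <- which(field_mat[i, ])
    same_field <- rowSums(field_mat[prior, fidx, drop = FALSE]) > 0
    targets <- integer(0)
    for (draw in seq_len(k)) {
      cand <- if (stats::runif(1) < cross_field_rate) prior else
        prior[same_field]
      cand <- setdiff(cand, targets)
      if (length(cand) == 0) next
      w <- (in_deg[cand] + 1)^gamma
      boosted <- !is.na(plant_field[cand]) &
        plant_field[cand] %in% field_sets[[i]]
      w[boosted] <- w[boosted] * plant_boost[cand][boosted]
      j <- if (length(cand) == 1) cand else sample(cand, 1, prob = w)
      targets <- c(targets, j)
      in_deg[j] <- in_deg[j] + 1L
    }
    citing_out[[i]] <- targets
  }

  n_cites <- lengths(citing_out)
  citations <- data.frame(
    citing = rep(dois, n_cites),
    cited = dois[unlist(citing_out)],
    stringsAsFactors = FALSE)

  articles <- data.frame(doi = dois, journal = journals,
                         language = "en", pub_type = "journal-article",
                         stringsAsFactors = FALSE)
  articles$headings <- headings
  citation_corpus(citations, articles)
}

#' Heading IDs used by the synthetic generator
#'
#' @param n_fields Number of fields.
#' @return Character vector like `"H01.001"`, `"H01.002"`, ...
#' @export
synthetic_field_ids <- function(n_fields) {
  sprintf("H01.%03d", seq_len(n_fields))
}

synthetic_dois <- function(n) {
  sprintf("10.5555/art%05d", seq_len(n))
}

#' Pick planted field-favored articles for a synthetic corpus
#'
#' Selects `n` early-generation articles whose primary tag is field
#' `field_index` and marks them as favored there with the given boost.
#' Early articles are used so the planted preference acts over the whole
#' citation process.
#'
#' @param n Number of planted articles (default 10).
#' @param field_index Index of the favored field (default 1).
#' @param boost Selection-weight multiplier, > 1 (default 3).
#' @param n_fields,n_per_field Must match the [generate_corpus()] call.
#' @return Data.frame with columns `doi`, `field`, `boost`.
#' @export
synthetic_planted <- function(n = 10, field_index = 1, boost = 3,
                              n_fields = 2, n_per_field = 400) {
  stopifnot(boost > 1, n <= n_per_field, field_index <= n_fields)
  total <- n_fields * n_per_field
  primary <- rep_len(seq_len(n_fields), total)
  idx <- which(primary == field_index)[seq_len(n)]
  data.frame(doi = synthetic_dois(total)[idx],
             field = synthetic_field_ids(n_fields)[field_index],
             boost = boost, stringsAsFactors = FALSE)
}

#' Generate a heading hierarchy matching a synthetic corpus
#'
#' Emits a two-level hierarchy — a root with the corpus's field headings as
#' children, plus a small decoy heading — constructed so that
#' [select_fields()] at any threshold between 1 and the per-field article
#' count recovers exactly the corpus's fields. A single-field corpus yields
#' a single-heading tree (a root with one qualifying child would be
#' selected itself under the descent rule).
#'
#' @param n_fields Number of fields in the corpus.
#' @param root Root heading ID (default `"H01"`).
#' @param decoy Add an empty decoy child heading (default TRUE).
#' @return A `mesh_tree` (unannotated; run [annotate_counts()]).
#' @export
generate_tree <- function(n_fields, root = "H01", decoy = TRUE) {
  stopifnot(n_fields >= 1)
  fields <- synthetic_field_ids(n_fields)
  if (n_fields == 1) {
    return(mesh_tree(id = fields, name = "synthetic field 1", parent = ""))
  }
  ids <- c(root, fields)
  names_ <- c("natural science disciplines",
              sprintf("synthetic field %d", seq_len(n_fields)))
  parents <- c("", rep(root, n_fields))
  if (decoy) {
    ids <- c(ids, paste0(root, ".999"))
    names_ <- c(names_, "decoy heading")
    parents <- c(parents, root)
  }
  mesh_tree(id = ids, name = names_, parent = parents)
}

#' Write synthetic inputs in the pipeline's on-disk formats
#'
#' Writes the corpus and tree in exactly the formats the package's readers
#' consume — a minimal two-column citation CSV, the metadata TSV, and the
#' heading-triple CSV — so the pipeline can be exercised end to end through
#' its real input path.
#'
#' @param corpus A `citation_corpus`.
#' @param tree A `mesh_tree`.
#' @param dir Output directory (created if needed).
#' @return Named list of the three file paths, invisibly.
#' @export
write_synthetic_inputs <- function(corpus, tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  citations_path <- file.path(dir, "citations.csv")
  metadata_path <- file.path(dir, "metadata.tsv")
  tree_path <- file.path(dir, "tree.csv")
  write_citations(corpus$citations, citations_path)
  meta <- data.frame(doi = corpus$articles$doi,
                     headings = vapply(corpus$articles$headings,
                                       paste, character(1), collapse = "|"),
                     journal = corpus$articles$journal,
                     language = corpus$articles$language,
                     pub_type = corpus$articles$pub_type)
  utils::write.table(meta, metadata_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(
    data.frame(id = tree$id, name = tree$name, parent = tree$parent),
    tree_path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(list(citations = citations_path, metadata = metadata_path,
                 tree = tree_path))
}
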