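#' Pipeline configuration
#'
#' Collects the tunable parameters of a field-pair run with the pipeline's
#' defaults: 100 shuffled replicates, 3 successful swaps per edge, damping
#' 0.85, a 5% missingness ceiling, at least 1000 shared articles for a
#' pair to be analyzed, and journal thresholds of 50 articles dataset-wide
#' and 25 per field pair. Every value can be overridden, either directly or
#' from a JSON/YAML file via [read_pipeline_config()].
#'
#' @param threshold Field-selection DOI cutoff (default 10000).
#' @param n_replicates Shuffled replicates per field pair (default 100).
#' @param swaps_per_edge Successful swaps per edge (default 3).
#' @param damping PageRank damping factor (default 0.85).
#' @param max_missingness Missingness ceiling (default 0.05).
#' @param min_shared_articles Minimum shared eligible articles for a pair
#'   (default 1000).
#' @param journal_min_total Dataset-wide journal threshold (default 50).
#' @param journal_min_pair Per-field-pair journal threshold (default 25).
#' @param seed Master seed; all pipeline randomness derives from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = 10000, n_replicates = 100,
                            swaps_per_edge = 3, damping = 0.85,
                            max_missingness = 0.05,
                            min_shared_articles = 1000,
                            journal_min_total = 50, journal_min_pair = 25,
                            seed = 0) {
  structure(list(threshold = threshold, n_replicates = n_replicates,
                 swaps_per_edge = swaps_per_edge, damping = damping,
                 max_missingness = max_missingness,
                 min_shared_articles = min_shared_articles,
                 journal_min_total = journal_min_total,
                 journal_min_pair = journal_min_pair, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are an error; missing keys fall back to the defaults of
#' [pipeline_config()].
#'
#' @param path Path to a `.json`, `.yml`, or `.yaml` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  values <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, values)
}

#' Run the full analysis for one field pair
#'
#' Executes the whole field-pair pipeline: build the combined two-field
#' network, generate the degree-preserving shuffle ensemble, split every
#' replicate back into the two single-field networks, compute PageRanks,
#' convert them to permutation percentiles, filter unstable articles by
#' missingness, derive per-article affinities, and score journals per
#' field. Fully deterministic given `config$seed`.
#'
#' Pairs sharing fewer than `config$min_shared_articles` eligible articles
#' are skipped with a notice (return value `NULL`).
#'
#' @param corpus A `citation_corpus`.
#' @param fieldA,fieldB Distinct heading IDs.
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, all tables are written as
#'   TSV under `outdir/<fieldA>__<fieldB>/` together with a JSON manifest.
#' @return A list with `percentiles` (named list of two filtered
#'   `percentile_table`s), `affinity`, `journals` (named list of two
#'   journal score tables), `pageranks`, `networks`, and
#'   `pearson_r` (correlation of the two fields' true PageRanks over
#'   shared articles, `NA` if undefined) — or `NULL` if the pair was
#'   skipped.
#' @export
run_field_pair <- function(corpus, fieldA, fieldB,
                           config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(corpus, "citation_corpus"))
  eligible <- eligible_articles(corpus)
  shared <- intersect(field_members(corpus, fieldA, eligible),
                      field_members(corpus, fieldB, eligible))
  if (length(shared) < config$min_shared_articles) {
    message("run_field_pair: ", fieldA, " / ", fieldB, " share ",
            length(shared), " articles (< ", config$min_shared_articles,
            "); skipped")
    return(NULL)
  }

  pair_net <- build_pair_network(corpus, fieldA, fieldB, eligible)
  nets <- list(build_field_network(corpus, fieldA, eligible),
               build_field_network(corpus, fieldB, eligible))
  names(nets) <- c(fieldA, fieldB)

  ensemble <- make_ensemble(pair_net, n = config$n_replicates,
                            base_seed = config$seed,
                            swaps_per_edge = config$swaps_per_edge)

  prs <- lapply(nets, pagerank, damping = config$damping)
  tables <- lapply(names(nets), function(f) {
    null_prs <- lapply(ensemble$replicates, function(rep_net) {
      split <- split_to_field(rep_net, nets[[f]])
      if (network_size(split) == 0) {
        # an entirely emptied replicate still counts toward missingness
        stats::setNames(numeric(0), character(0))
      } else {
        pagerank(split, damping = config$damping)
      }
    })
    filter_missingness(percentile_scores(prs[[f]], null_prs),
                       max_missing = config$max_missingness)
  })
  names(tables) <- names(nets)

  aff <- affinity(tables[[fieldA]], tables[[fieldB]])
  journals <- lapply(prs, journal_scores, corpus = corpus,
                     min_articles = config$journal_min_pair)
  r <- tryCatch(field_correlation(prs[[fieldA]], prs[[fieldB]]),
                error = function(e) NA_real_)

  result <- list(percentiles = tables, affinity = aff, journals = journals,
                 pageranks = prs,
                 networks = c(list(pair = pair_net), nets),
                 pearson_r = r)
  if (!is.null(outdir)) {
    pair_dir <- file.path(outdir, paste(fieldA, fieldB, sep = "__"))
    dir.create(pair_dir, showWarnings = FALSE, recursive = TRUE)
    for (f in names(tables)) {
      write_table_tsv(tables[[f]],
                      file.path(pair_dir, paste0("percentiles_", f, ".tsv")))
      write_table_tsv(journals[[f]],
                      file.path(pair_dir, paste0("journals_", f, ".tsv")))
    }
    write_table_tsv(aff, file.path(pair_dir, "affinity.tsv"))
    jsonlite::write_json(
      list(fieldA = fieldA, fieldB = fieldB, seed = config$seed,
           n_replicates = config$n_replicates,
           swaps_per_edge = config$swaps_per_edge,
           pearson_r = r, n_shared = length(shared)),
      file.path(pair_dir, "manifest.json"), auto_unbox = TRUE)
  }
  result
}
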