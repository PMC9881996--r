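#' PageRank of a citation network
#'
#' Power iteration on the citing-to-cited direction, so PageRank mass
#' accumulates on cited (influential) articles. Mass from dangling nodes
#' (articles citing nothing inside the network) is redistributed uniformly
#' at each iteration. Iteration stops when the L1 change drops below
#' `tol * |nodes|`; the defaults (damping 0.85, tol 1e-6, 100 iterations)
#' are the conventional default parameters for citation-scale PageRank.
#'
#' @param net A nonempty `citation_network`.
#' @param damping Damping factor in (0, 1).
#' @param tol Per-node L1 convergence tolerance.
#' @param max_iter Maximum iterations; non-convergence is an error carrying
#'   the residual.
#' @return A `pagerank_vector`: named numeric vector summing to 1, with
#'   attributes `damping` and `scope`.
#' @export
pagerank <- function(net, damping = 0.85, tol = 1e-6, max_iter = 100) {
  stopifnot(damping > 0, damping < 1)
  if (network_size(net) == 0) {
    stop("pagerank: empty network")
  }
  nodes <- network_nodes(net)
  n <- length(nodes)
  from <- match(net$citing, nodes)
  to <- match(net$cited, nodes)
  out_deg <- tabulate(from, nbins = n)
  dangling <- out_deg == 0
  # column-stochastic transition restricted to non-dangling columns
  P <- Matrix::sparseMatrix(i = to, j = from, x = 1 / out_deg[from],
                            dims = c(n, n))
  x <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    x_new <- (1 - damping) / n +
      damping * (as.numeric(P %*% x) + sum(x[dangling]) / n)
    err <- sum(abs(x_new - x))
    x <- x_new
    if (err < tol * n) {
      return(pagerank_vector(stats::setNames(x, nodes), damping, net$scope))
    }
  }
  stop("pagerank failed to converge in ", max_iter,
       " iterations (residual ", format(err), ")")
}

pagerank_vector <- function(scores, damping, scope) {
  structure(scores, damping = damping, scope = scope,
            class = c("pagerank_vector", "numeric"))
}

#' @export
print.pagerank_vector <- function(x, ...) {
  cat("pagerank_vector [", attr(x, "scope"), "]: ", length(x),
      " articles, damping ", attr(x, "damping"), "\n", sep = "")
  print(unclass(utils::head(sort(x, decreasing = TRUE), 5)))
  invisible(x)
}

#' Permutation percentiles of true PageRanks against a null ensemble
#'
#' For each article of the true network, records the percent of shuffled
#' replicates in which the article's PageRank is strictly lower than its
#' true value: 100 means the article beat every replicate (far above its
#' degree-expected importance), 0 means it trailed every one. Ties count as
#' not-lower. Articles can drop out of a shuffled split when shuffling
#' removes all their within-field edges; by default the percentile
#' denominator counts only replicates where the article is present, and
#' the fraction of replicates it is absent from is reported as
#' `missingness` (filtered downstream). With
#' `count_missing_as_not_lower = TRUE` the denominator is always the full
#' replicate count.
#'
#' @param true_pr `pagerank_vector` of the true (unshuffled) field network.
#' @param ensemble_prs List of `pagerank_vector`s, one per shuffled
#'   replicate split to the same field.
#' @param count_missing_as_not_lower Treat absent replicates as not-lower
#'   instead of excluding them from the denominator.
#' @return A `percentile_table`: data.frame with columns `doi`, `field`,
#'   `pagerank`, `percentile` (NaN for articles absent from every
#'   replicate), `missingness`, `n_replicates`.
#' @export
percentile_scores <- function(true_pr, ensemble_prs,
                              count_missing_as_not_lower = FALSE) {
  if (length(ensemble_prs) == 0) {
    stop("percentile_scores: empty ensemble")
  }
  dois <- names(true_pr)
  n_rep <- length(ensemble_prs)
  vals <- vapply(ensemble_prs,
                 function(p) unname(unclass(p)[dois]),
                 numeric(length(dois)))
  vals <- matrix(vals, nrow = length(dois))
  truth <- as.numeric(true_pr)
  present <- !is.na(vals)
  n_present <- rowSums(present)
  n_lower <- rowSums(vals < truth, na.rm = TRUE)
  denom <- if (count_missing_as_not_lower) rep(n_rep, length(dois)) else
    n_present
  out <- data.frame(doi = dois,
                    field = attr(true_pr, "scope"),
                    pagerank = truth,
                    percentile = 100 * n_lower / denom,
                    missingness = 1 - n_present / n_rep,
                    n_replicates = n_rep,
                    stringsAsFactors = FALSE)
  class(out) <- c("percentile_table", "data.frame")
  out
}

#' Drop articles with unstable null PageRanks
#'
#' Removes articles missing from more than `max_missing` of the shuffled
#' replicates (strictly more than; exactly at the threshold is kept).
#'
#' @param table A `percentile_table`.
#' @param max_missing Maximum tolerated missingness fraction (default 0.05).
#' @return The filtered `percentile_table`.
#' @export
filter_missingness <- function(table, max_missing = 0.05) {
  keep <- table$missingness <= max_missing
  if (any(!keep)) {
    message("filter_missingness: removed ", sum(!keep), " of ",
            nrow(table), " article(s)")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Field-specific affinity of shared articles
#'
#' For every article present in both fields' percentile tables, the
#' difference `percentileA - percentileB` measures field-specific
#' preference: +100 means far above degree-expected importance in field A
#' and far below in field B.
#'
#' @param tableA,tableB Filtered `percentile_table`s of the two fields.
#' @return Data.frame with columns `doi`, `fieldA`, `fieldB`,
#'   `percentileA`, `percentileB`, `difference`, sorted by `|difference|`
#'   descending (ties by DOI).
#' @export
affinity <- function(tableA, tableB) {
  shared <- intersect(tableA$doi, tableB$doi)
  if (length(shared) == 0) {
    warning("affinity: no shared articles between the two fields")
  }
  ia <- match(shared, tableA$doi)
  ib <- match(shared, tableB$doi)
  out <- data.frame(doi = shared,
                    fieldA = tableA$field[ia],
                    fieldB = tableB$field[ib],
                    percentileA = tableA$percentile[ia],
                    percentileB = tableB$percentile[ib],
                    stringsAsFactors = FALSE)
  out$difference <- out$percentileA - out$percentileB
  out <- out[order(-abs(out$difference), out$doi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation of two fields' PageRanks
#'
#' Product-moment correlation over the articles shared by the two vectors.
#'
#' @param prA,prB `pagerank_vector`s of two fields.
#' @return Pearson r.
#' @export
field_correlation <- function(prA, prB) {
  shared <- intersect(names(prA), names(prB))
  if (length(shared) < 2) {
    stop("field_correlation: fewer than 2 shared articles")
  }
  x <- as.numeric(unclass(prA)[shared])
  y <- as.numeric(unclass(prB)[shared])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("field_correlation: zero variance on shared articles")
  }
  stats::cor(x, y)
}

#' Empirical cumulative distribution points
#'
#' @param values Nonempty numeric vector (e.g. a field's PageRanks).
#' @return Data.frame of the ECDF's jump points: sorted unique `value` and
#'   `fraction` = share of observations at or below it.
#' @export
ecdf_points <- function(values) {
  stopifnot(length(values) > 0)
  v <- sort(unique(values))
  data.frame(value = v,
             fraction = vapply(v, function(q) mean(values <= q), numeric(1)))
}

#' Write a percentile or affinity table as TSV
#'
#' @param table A data.frame (`percentile_table` or affinity rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
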