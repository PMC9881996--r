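# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written down a different road than the
# package code it checks: dense matrices instead of sparse iteration,
# exhaustive enumeration instead of sampling.

# --- dense PageRank oracle ------------------------------------------------
# Builds the full Google matrix explicitly and power-iterates it.
dense_pagerank_oracle <- function(net, damping = 0.85, tol = 1e-6,
                                  max_iter = 100) {
  nodes <- sort(unique(c(net$citing, net$cited)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(net$citing, net$cited)] <- 1
  out_deg <- rowSums(A)
  P <- A / ifelse(out_deg == 0, 1, out_deg)
  P[out_deg == 0, ] <- 1 / n          # dangling mass spread uniformly
  G <- damping * t(P) + (1 - damping) / n
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    x_new <- as.numeric(G %*% x)
    if (sum(abs(x_new - x)) < tol * n) {
      return(stats::setNames(x_new, nodes))
    }
    x <- x_new
  }
  stats::setNames(x, nodes)
}

# --- exhaustive enumeration of degree-fixed simple digraphs ---------------
# All 0/1 adjacency matrices with zero diagonal and the given out- (row)
# and in- (column) degree sums, found row by row.
enum_degree_fixed_digraphs <- function(out_deg, in_deg) {
  n <- length(out_deg)
  results <- list()
  combos_of <- function(slots, k) {
    if (k == 0) return(list(integer(0)))
    if (length(slots) < k) return(list())
    if (length(slots) == k) return(list(slots))
    lapply(asplit(utils::combn(length(slots), k), 2),
           function(ii) slots[ii])
  }
  recurse <- function(row, col_remaining, mat) {
    if (row > n) {
      results[[length(results) + 1L]] <<- mat
      return(invisible(NULL))
    }
    slots <- setdiff(which(col_remaining > 0), row)
    for (cc in combos_of(slots, out_deg[row])) {
      cr <- col_remaining
      cr[cc] <- cr[cc] - 1L
      m2 <- mat
      m2[row, cc] <- 1L
      recurse(row + 1L, cr, m2)
    }
  }
  recurse(1L, as.integer(in_deg), matrix(0L, n, n))
  results
}

adjacency_key <- function(mat) {
  n <- nrow(mat)
  e <- which(mat == 1L, arr.ind = TRUE)
  paste(sort((e[, 1] - 1) * n + e[, 2]), collapse = ",")
}

network_key <- function(net, nodes) {
  i <- match(net$citing, nodes)
  j <- match(net$cited, nodes)
  paste(sort((i - 1) * length(nodes) + j), collapse = ",")
}

# --- degree bookkeeping ---------------------------------------------------
degree_vectors <- function(net) {
  nodes <- sort(unique(c(net$citing, net$cited)))
  list(out = table(factor(net$citing, levels = nodes)),
       `in` = table(factor(net$cited, levels = nodes)))
}

# --- random fixtures ------------------------------------------------------
# Simple random digraph as a citation_network (uses the current RNG).
random_digraph <- function(n, m) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample(nrow(pairs), min(m, nrow(pairs))), ]
  citation_network(paste0("n", pick$from), paste0("n", pick$to),
                   scope = "random")
}

# Small corpus from explicit rows; headings given as "A|B" strings.
make_toy_corpus <- function(citing, cited, doi, headings,
                            journal = NULL, language = "en",
                            pub_type = "journal-article") {
  articles <- data.frame(
    doi = doi,
    journal = if (is.null(journal)) rep("J1", length(doi)) else journal,
    language = rep_len(language, length(doi)),
    pub_type = rep_len(pub_type, length(doi)),
    stringsAsFactors = FALSE)
  articles$headings <- lapply(strsplit(headings, "|", fixed = TRUE),
                              function(h) h[nzchar(h)])
  citation_corpus(data.frame(citing = citing, cited = cited,
                             stringsAsFactors = FALSE), articles)
}

# Bare percentile-machinery input: a named score vector with a field scope.
make_pr <- function(scores, scope = "F") {
  fieldrank:::pagerank_vector(scores, damping = 0.85, scope = scope)
}

# The frozen toy digraph for sampling checks: its entire 33-member
# degree-fixed space is connected under the three-edge swap (verified by
# breadth-first search over the move graph when the fixture was chosen).
uniformity_toy_graph <- function() {
  edges <- rbind(c(3, 5), c(5, 3), c(2, 1), c(3, 2), c(4, 1), c(5, 4),
                 c(2, 4))
  citation_network(as.character(edges[, 1]), as.character(edges[, 2]),
                   scope = "toy")
}
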