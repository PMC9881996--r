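test_that("PageRank is exactly uniform on a directed 3-cycle", {
  net <- citation_network(c("a", "b", "c"), c("b", "c", "a"))
  pr <- pagerank(net)
  expect_equal(as.numeric(pr), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("PageRank matches the dense power-iteration oracle", {
  # the two-node dangling case, tightly converged on both routes
  single <- citation_network("a", "b")
  pr <- pagerank(single, tol = 1e-14, max_iter = 1000)
  oracle <- dense_pagerank_oracle(single, tol = 1e-14, max_iter = 1000)
  expect_equal(as.numeric(pr[names(oracle)]), as.numeric(oracle),
               tolerance = 1e-10)

  set.seed(23)
  for (rep in 1:8) {
    net <- random_digraph(10, sample(15:30, 1))
    pr <- pagerank(net)
    oracle <- dense_pagerank_oracle(net)
    expect_equal(as.numeric(pr[names(oracle)]), as.numeric(oracle),
                 tolerance = 1e-8)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_true(all(pr > 0))
  }
})

test_that("PageRank agrees with the igraph implementation", {
  set.seed(31)
  net <- random_digraph(12, 30)
  pr <- pagerank(net, tol = 1e-13, max_iter = 2000)
  ig <- igraph::page_rank(as_igraph(net), damping = 0.85)$vector
  expect_equal(as.numeric(pr[names(ig)]), as.numeric(ig),
               tolerance = 1e-8)
})

test_that("PageRank reports non-convergence with its residual", {
  set.seed(2)
  net <- random_digraph(10, 25)
  expect_error(pagerank(net, max_iter = 1, tol = 1e-12), "converge")
  expect_error(pagerank(citation_network(character(0), character(0))),
               "empty")
})

test_that("percentiles count strictly-lower replicates", {
  truth <- make_pr(c(hi = 0.5, mid = 0.25, lo = 0.01, tied = 0.2))
  reps <- lapply(c(0.1, 0.2, 0.3, 0.4), function(v) {
    make_pr(c(hi = v / 2, mid = v, lo = v, tied = 0.2))
  })
  tab <- percentile_scores(truth, reps)
  p <- stats::setNames(tab$percentile, tab$doi)
  expect_equal(p[["hi"]], 100)    # above every replicate
  expect_equal(p[["lo"]], 0)      # below every replicate
  expect_equal(p[["mid"]], 50)    # {0.1,0.2,0.3,0.4} vs 0.25
  expect_equal(p[["tied"]], 0)    # exact ties are not lower
  expect_equal(tab$field, rep("F", 4))
  expect_error(percentile_scores(truth, list()), "empty")
})

test_that("missingness conditions the percentile denominator", {
  truth <- make_pr(c(a = 0.5, gone = 0.2))
  present <- make_pr(c(a = 0.1, gone = 0.1))
  absent <- make_pr(c(a = 0.1))
  tab <- percentile_scores(truth, list(present, present, absent, absent))
  row_a <- tab[tab$doi == "a", ]
  row_g <- tab[tab$doi == "gone", ]
  expect_equal(row_a$missingness, 0)
  expect_equal(row_g$missingness, 0.5)
  expect_equal(row_g$percentile, 100)   # 2 lower of 2 present
  strict <- percentile_scores(truth, list(present, present, absent, absent),
                              count_missing_as_not_lower = TRUE)
  expect_equal(strict[strict$doi == "gone", "percentile"], 50)

  never <- percentile_scores(make_pr(c(x = 1)), list(make_pr(c(y = 1))))
  expect_equal(never$missingness, 1)
  expect_true(is.nan(never$percentile))
})

test_that("raising a true PageRank never lowers its percentile", {
  set.seed(77)
  reps <- lapply(1:30, function(i) make_pr(c(a = stats::runif(1))))
  grid <- seq(0, 1, length.out = 21)
  pct <- vapply(grid, function(v) {
    percentile_scores(make_pr(c(a = v)), reps)$percentile
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("the missingness filter is strict at its boundary", {
  tab <- data.frame(doi = c("a", "b", "c"), field = "F",
                    pagerank = 0.1, percentile = 50,
                    missingness = c(0.06, 0.05, 0),
                    n_replicates = 100)
  class(tab) <- c("percentile_table", "data.frame")
  kept <- suppressMessages(filter_missingness(tab, max_missing = 0.05))
  expect_setequal(kept$doi, c("b", "c"))
})

test_that("affinity is the percentile difference, ordered by magnitude", {
  ta <- data.frame(doi = c("p", "q", "r", "s"), field = "A",
                   pagerank = 0.1,
                   percentile = c(100, 50, 0, 70),
                   missingness = 0, n_replicates = 100)
  tb <- data.frame(doi = c("p", "q", "r", "z"), field = "B",
                   pagerank = 0.1,
                   percentile = c(4, 50, 100, 10),
                   missingness = 0, n_replicates = 100)
  aff <- affinity(ta, tb)
  expect_setequal(aff$doi, c("p", "q", "r"))
  expect_equal(aff$difference[aff$doi == "p"], 96)
  expect_equal(aff$difference[aff$doi == "q"], 0)
  expect_equal(aff$difference[aff$doi == "r"], -100)
  expect_equal(aff$doi, c("r", "p", "q"))  # |-100| > |96| > |0|
  expect_true(all(abs(aff$difference) <= 100))
  expect_warning(affinity(ta[0, ], tb), "no shared")
})

test_that("field correlation reproduces the product-moment formula", {
  prA <- make_pr(c(a = 0.1, b = 0.2, c = 0.4, d = 0.05, e = 0.25), "A")
  prB <- make_pr(c(a = 0.3, b = 0.1, c = 0.35, d = 0.15, e = 0.1), "B")
  x <- as.numeric(prA)
  y <- as.numeric(prB)
  hand <- (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(field_correlation(prA, prB), hand, tolerance = 1e-12)
  expect_equal(field_correlation(prA, prA), 1)
  neg <- make_pr(stats::setNames(0.5 - x, names(prA)), "B")
  expect_equal(field_correlation(prA, neg), -1)
  expect_error(field_correlation(make_pr(c(a = 1)), make_pr(c(a = 1))),
               "fewer than 2")
  flat <- make_pr(c(a = 0.5, b = 0.5), "B")
  expect_error(field_correlation(flat, prA), "variance")
})

test_that("percentiles of a single article are calibrated across
           independent ensembles", {
  # Within one ensemble, articles' percentiles co-move (PageRank mass is
  # conserved, so one replicate shifting mass toward hubs moves every
  # other article's rank together). The per-article marginal, however,
  # must be uniform: here the rank of a designated "true" draw among 20
  # null draws is collected over 40 independent ensembles and checked
  # against the discrete uniform.
  corpus <- generate_corpus(n_per_field = 60, seed = 3)
  pair <- build_pair_network(corpus, "H01.001", "H01.002")
  target <- sort(network_nodes(pair))[25]
  ranks <- vapply(1:40, function(j) {
    prs <- lapply(1:21, function(i) {
      pagerank(shuffle_network(pair, seed = 5000 * j + i))
    })
    tab <- percentile_scores(prs[[1]], prs[-1])
    tab$percentile[tab$doi == target] * 20 / 100
  }, numeric(1))
  bins <- cut(ranks, breaks = c(-0.5, 4.5, 9.5, 15.5, 20.5))
  p <- stats::chisq.test(table(bins), p = c(5, 5, 6, 5) / 21)$p.value
  expect_gt(p, 0.01)
})

test_that("ECDF points agree with a sort-and-count oracle", {
  expect_equal(ecdf_points(1), data.frame(value = 1, fraction = 1))
  expect_equal(ecdf_points(c(2, 1)),
               data.frame(value = c(1, 2), fraction = c(0.5, 1)))
  set.seed(13)
  v <- stats::runif(10)
  pts <- ecdf_points(v)
  for (k in seq_len(nrow(pts))) {
    expect_equal(pts$fraction[k], sum(sort(v) <= pts$value[k]) / 10)
  }
})
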