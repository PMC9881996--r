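# Closed-form restatement of the recursive descent rule: a heading is
# selected iff it qualifies, has at most one qualifying child, and every
# ancestor both qualifies and has at least two qualifying children.
select_fields_oracle <- function(tree, threshold) {
  counts <- stats::setNames(tree$count, tree$id)
  parent <- stats::setNames(tree$parent, tree$id)
  qual_children <- function(id) {
    kids <- tree$id[tree$parent == id]
    sum(counts[kids] >= threshold)
  }
  ancestors <- function(id) {
    out <- character(0)
    p <- parent[[id]]
    while (nzchar(p)) {
      out <- c(out, p)
      p <- parent[[p]]
    }
    out
  }
  keep <- vapply(tree$id, function(id) {
    counts[[id]] >= threshold &&
      qual_children(id) < 2 &&
      all(vapply(ancestors(id), function(a) {
        counts[[a]] >= threshold && qual_children(a) >= 2
      }, logical(1)))
  }, logical(1))
  tree$id[keep]
}

random_tree_with_counts <- function(n, max_count = 40) {
  parent <- c("", if (n > 1)
    paste0("h", vapply(seq_len(n - 1) + 1, function(i) sample(i - 1, 1),
                       numeric(1))))
  tr <- mesh_tree(id = paste0("h", seq_len(n)), parent = parent)
  tr$count <- sample(0:max_count, n, replace = TRUE)
  tr
}

test_that("heading counts follow set-union semantics", {
  corpus <- make_toy_corpus(
    citing = "d1", cited = "d2",
    doi = c("d1", "d2", "d3", "d4", "d5", "d6"),
    headings = c("P.a", "P.a", "P.b", "P.b|P", "P.b", "X"))
  tree <- mesh_tree(id = c("P", "P.a", "P.b"), parent = c("", "P", "P"))
  ann <- suppressMessages(annotate_counts(tree, corpus, explode = TRUE))
  counts <- stats::setNames(ann$count, ann$id)
  expect_equal(counts[["P.a"]], 2)
  expect_equal(counts[["P.b"]], 3)
  # d4 is tagged with both P and P.b but contributes once to P
  expect_equal(counts[["P"]], 5)
  flat <- suppressMessages(annotate_counts(tree, corpus, explode = FALSE))
  expect_equal(stats::setNames(flat$count, flat$id)[["P"]], 1)
})

test_that("only eligible articles are counted", {
  corpus <- make_toy_corpus(
    citing = "d1", cited = "d2", doi = c("d1", "d2", "d3"),
    headings = c("P", "P", "P"),
    language = c("en", "en", "fr"))
  tree <- mesh_tree(id = "P", parent = "")
  expect_equal(annotate_counts(tree, corpus)$count, 2)
})

test_that("threshold rule selects the documented examples", {
  # boundary: exactly at the cutoff still qualifies
  single <- mesh_tree(id = "h1", parent = "")
  single$count <- 10000
  expect_equal(select_fields(single, 10000)$id, "h1")
  expect_equal(nrow(select_fields(single, 10001)), 0)

  # two qualifying children replace the root
  tr <- mesh_tree(id = c("root", "c1", "c2", "c3"),
                  parent = c("", "root", "root", "root"))
  tr$count <- c(30000, 12000, 11000, 2000)
  expect_equal(select_fields(tr, 10000)$id, c("c1", "c2"))

  # exactly one qualifying child is not "multiple": the root is kept
  tr2 <- mesh_tree(id = c("root", "c1", "c2"),
                   parent = c("", "root", "root"))
  tr2$count <- c(25000, 12000, 4000)
  expect_equal(select_fields(tr2, 10000)$id, "root")

  empty <- mesh_tree(id = character(0), parent = character(0))
  expect_equal(nrow(select_fields(empty, 10)), 0)
})

test_that("selection matches the closed-form oracle on random trees", {
  set.seed(41)
  for (rep in 1:40) {
    tr <- random_tree_with_counts(sample(2:30, 1))
    threshold <- sample(1:30, 1)
    got <- select_fields(tr, threshold)
    expect_setequal(got$id, select_fields_oracle(tr, threshold))
    # depth-first pre-order
    pre <- fieldrank:::tree_preorder(tr)
    expect_equal(got$id, pre[pre %in% got$id])
    # every selected heading qualifies
    expect_true(all(got$count >= threshold))
    # antichain: no selected heading is an ancestor of another
    parent <- stats::setNames(tr$parent, tr$id)
    for (id in got$id) {
      p <- parent[[id]]
      while (nzchar(p)) {
        expect_false(p %in% got$id)
        p <- parent[[p]]
      }
    }
  }
})

test_that("field sets round-trip through TSV and enumerate pairs", {
  tr <- mesh_tree(id = c("root", "c1", "c2"), parent = c("", "root", "root"))
  tr$count <- c(300, 150, 120)
  fs <- select_fields(tr, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_field_set(fs, path)
  back <- utils::read.delim(path)
  expect_equal(back$field_id, fs$id)
  expect_equal(nrow(field_pairs(fs)), choose(nrow(fs), 2))
})

test_that("tree files read back with parents intact", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,parent", "H01,root,", "H01.1,child,H01"), path)
  tr <- read_mesh_tree(path)
  expect_equal(fieldrank:::tree_roots(tr), "H01")
  expect_equal(fieldrank:::tree_children(tr, "H01"), "H01.1")
  expect_error(mesh_tree(id = c("a", "a"), parent = c("", "")), "unique")
})
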