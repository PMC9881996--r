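#' Read a subject-heading hierarchy from a flat triple export
#'
#' Headings come as a CSV of `(id, name, parent)` triples; roots have an
#' empty `parent`. IDs are dotted strings in the MeSH style (e.g.
#' `"H01.158"`), unique within the file.
#'
#' @param path CSV path with columns `id`, `name`, `parent`.
#' @return A `mesh_tree`: data.frame with columns `id`, `name`, `parent`
#'   and a `count` column initialized to `NA` until [annotate_counts()].
#' @export
read_mesh_tree <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  needed <- c("id", "name", "parent")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("tree file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  mesh_tree(raw$id, raw$name, raw$parent)
}

#' Construct a heading hierarchy
#'
#' @param id Character vector of unique heading IDs.
#' @param name Display names (defaults to the IDs).
#' @param parent Parent heading IDs; `""` or `NA` marks a root.
#' @return A `mesh_tree` data.frame.
#' @export
mesh_tree <- function(id, name = id, parent) {
  parent[is.na(parent)] <- ""
  if (anyDuplicated(id)) {
    stop("heading IDs must be unique")
  }
  unknown <- setdiff(parent[nzchar(parent)], id)
  if (length(unknown) > 0) {
    stop("parent heading(s) not present in tree: ",
         paste(unknown, collapse = ", "))
  }
  out <- data.frame(id = id, name = name, parent = parent,
                    count = rep(NA_real_, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("mesh_tree", "data.frame")
  out
}

tree_children <- function(tree, id) {
  tree$id[tree$parent == id]
}

tree_roots <- function(tree) {
  tree$id[!nzchar(tree$parent)]
}

# Depth-first pre-order over the whole forest, children in file order.
tree_preorder <- function(tree) {
  out <- character(0)
  visit <- function(id) {
    out[[length(out) + 1L]] <<- id
    for (ch in tree_children(tree, id)) visit(ch)
  }
  for (r in tree_roots(tree)) visit(r)
  out
}

#' Annotate heading article counts from a corpus
#'
#' Sets each heading's `count` to the number of *eligible* corpus articles
#' tagged with that heading — or, with `explode = TRUE` (the default and
#' standard practice for hierarchical subject vocabularies), tagged with the
#' heading or any of its descendants. Counts are set-union based: an article
#' tagged with both a heading and its child counts once toward the parent.
#'
#' @param tree A `mesh_tree`.
#' @param corpus A `citation_corpus`.
#' @param explode Include descendant annotations in each heading's count.
#' @return The tree with `count` filled in.
#' @export
annotate_counts <- function(tree, corpus, explode = TRUE) {
  stopifnot(inherits(tree, "mesh_tree"), inherits(corpus, "citation_corpus"))
  idx <- heading_index(corpus)
  stray <- setdiff(names(idx), tree$id)
  if (length(stray) > 0) {
    message("annotate_counts: ", length(stray),
            " heading(s) in metadata absent from the tree (ignored): ",
            paste(utils::head(stray, 5), collapse = ", "))
  }
  direct <- function(id) {
    if (id %in% names(idx)) idx[[id]] else character(0)
  }
  counts <- stats::setNames(numeric(nrow(tree)), tree$id)
  gather <- function(id) {
    dois <- direct(id)
    for (ch in tree_children(tree, id)) {
      dois <- union(dois, gather(ch))
    }
    counts[[id]] <<- length(dois)
    dois
  }
  if (explode) {
    for (r in tree_roots(tree)) gather(r)
  } else {
    counts[tree$id] <- vapply(tree$id, function(id) length(direct(id)),
                              numeric(1))
  }
  tree$count <- unname(counts[tree$id])
  tree
}

#' Select a balanced field set from an annotated hierarchy
#'
#' Recursive threshold rule, applied depth-first from each root: a heading
#' whose count is below the threshold contributes nothing from its subtree;
#' a heading with two or more children that themselves meet the threshold is
#' skipped in favor of recursing into every child; otherwise the heading is
#' selected and descent stops. The result is an antichain (no selected
#' heading is an ancestor of another), returned in depth-first pre-order.
#'
#' A heading with exactly one qualifying child is itself selected — the
#' literal reading of requiring *multiple* qualifying children to descend.
#'
#' @param tree A count-annotated `mesh_tree`.
#' @param threshold Minimum article count for a heading to qualify.
#' @return A `field_set`: data.frame with columns `id`, `name`, `count`,
#'   with the threshold attached as attribute `"threshold"`.
#' @export
select_fields <- function(tree, threshold) {
  stopifnot(inherits(tree, "mesh_tree"), threshold > 0)
  if (nrow(tree) > 0 && anyNA(tree$count)) {
    stop("tree has no counts; run annotate_counts() first")
  }
  counts <- stats::setNames(tree$count, tree$id)
  selected <- character(0)
  visit <- function(id) {
    if (counts[[id]] < threshold) {
      return(invisible(NULL))
    }
    kids <- tree_children(tree, id)
    qualifying <- sum(counts[kids] >= threshold)
    if (qualifying >= 2) {
      for (ch in kids) visit(ch)
    } else {
      selected[[length(selected) + 1L]] <<- id
    }
    invisible(NULL)
  }
  for (r in tree_roots(tree)) visit(r)
  out <- tree[match(selected, tree$id), c("id", "name", "count"),
              drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("field_set", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Write a field set as TSV
#'
#' @param fields A `field_set`.
#' @param path Output path (columns `field_id`, `name`, `count`).
#' @return `path`, invisibly.
#' @export
write_field_set <- function(fields, path) {
  out <- data.frame(field_id = fields$id, name = fields$name,
                    count = fields$count)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' All unordered pairs of a field set
#'
#' @param fields A `field_set` or character vector of field IDs.
#' @return Data.frame with columns `fieldA`, `fieldB`, one row per
#'   unordered pair (A before B in input order).
#' @export
field_pairs <- function(fields) {
  ids <- if (is.data.frame(fields)) fields$id else as.character(fields)
  if (length(ids) < 2) {
    return(data.frame(fieldA = character(0), fieldB = character(0)))
  }
  pairs <- utils::combn(ids, 2)
  data.frame(fieldA = pairs[1, ], fieldB = pairs[2, ],
             stringsAsFactors = FALSE)
}
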