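#' Construct a citation network
#'
#' A citation network is a simple directed graph whose edges run from the
#' citing article to the cited article. Networks are edge-induced: the node
#' set is exactly the set of edge endpoints, so no isolated nodes exist.
#'
#' @param citing,cited Character vectors of equal length (edge list).
#' @param scope Label for the network's field or field-pair scope.
#' @return A `citation_network` with elements `citing`, `cited`, `scope`.
#' @export
citation_network <- function(citing, cited, scope = NA_character_) {
  citing <- as.character(citing)
  cited <- as.character(cited)
  stopifnot(length(citing) == length(cited))
  if (any(citing == cited)) {
    stop("citation network must not contain self-loops")
  }
  if (anyDuplicated(paste(citing, cited, sep = "\r"))) {
    stop("citation network must not contain duplicate edges")
  }
  structure(list(citing = citing, cited = cited, scope = scope),
            class = "citation_network")
}

#' @export
print.citation_network <- function(x, ...) {
  cat("citation_network [", x$scope, "]: ", length(network_nodes(x)),
      " nodes, ", length(x$citing), " edges\n", sep = "")
  invisible(x)
}

#' Nodes of a citation network
#'
#' @param net A `citation_network`.
#' @return Character vector of DOIs incident to at least one edge.
#' @export
network_nodes <- function(net) {
  unique(c(net$citing, net$cited))
}

#' Number of edges of a citation network
#' @param net A `citation_network`.
#' @return Integer edge count.
#' @export
network_size <- function(net) {
  length(net$citing)
}

edge_keys <- function(net) {
  paste(net$citing, net$cited, sep = "\r")
}

#' Build the citation network of a single field
#'
#' Keeps exactly those citations whose two endpoints are both eligible
#' (English journal articles) and both tagged with the field's heading.
#'
#' @param corpus A `citation_corpus`.
#' @param field Heading ID of the field.
#' @param eligible Optional precomputed eligible DOI vector.
#' @return A `citation_network` scoped to `field`.
#' @export
build_field_network <- function(corpus, field,
                                eligible = eligible_articles(corpus)) {
  members <- field_members(corpus, field, eligible)
  keep <- corpus$citations$citing %in% members &
    corpus$citations$cited %in% members
  citation_network(corpus$citations$citing[keep],
                   corpus$citations$cited[keep], scope = field)
}

# Eligible DOIs tagged with a heading; errors on unknown headings.
field_members <- function(corpus, field, eligible = eligible_articles(corpus)) {
  idx <- heading_index(corpus, eligible)
  all_tagged <- unique(unlist(corpus$articles$headings))
  if (!field %in% all_tagged) {
    stop("unknown field heading: ", field)
  }
  if (field %in% names(idx)) idx[[field]] else character(0)
}

#' Build the combined citation network of a field pair
#'
#' Keeps citations whose endpoints are eligible and each tagged with either
#' field of the pair — including citations that cross from one field to the
#' other, which is the point of the combined network.
#'
#' @param corpus A `citation_corpus`.
#' @param fieldA,fieldB Distinct heading IDs.
#' @param eligible Optional precomputed eligible DOI vector.
#' @return A `citation_network` scoped `"<fieldA>__<fieldB>"`.
#' @export
build_pair_network <- function(corpus, fieldA, fieldB,
                               eligible = eligible_articles(corpus)) {
  if (identical(fieldA, fieldB)) {
    stop("field pair must consist of two distinct fields")
  }
  members <- union(field_members(corpus, fieldA, eligible),
                   field_members(corpus, fieldB, eligible))
  keep <- corpus$citations$citing %in% members &
    corpus$citations$cited %in% members
  citation_network(corpus$citations$citing[keep],
                   corpus$citations$cited[keep],
                   scope = paste(fieldA, fieldB, sep = "__"))
}

#' Reduce a (possibly shuffled) pair network to one field
#'
#' Keeps the edges of `pair_net` whose two endpoints are nodes of the true
#' single-field network, then drops nodes left without edges. After
#' shuffling, articles can lose all their within-field edges and disappear
#' from the split — that absence is the "missingness" tracked downstream.
#'
#' @param pair_net A field-pair `citation_network` (true or shuffled).
#' @param field_net The true single-field network defining the node set.
#' @return A `citation_network` scoped to `field_net$scope`.
#' @export
split_to_field <- function(pair_net, field_net) {
  keep_nodes <- network_nodes(field_net)
  keep <- pair_net$citing %in% keep_nodes & pair_net$cited %in% keep_nodes
  citation_network(pair_net$citing[keep], pair_net$cited[keep],
                   scope = field_net$scope)
}

#' Convert a citation network to an igraph object
#'
#' @param net A `citation_network`.
#' @return A directed `igraph` graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$citing, to = net$cited), directed = TRUE)
}

#' Write a network as an edge list or GraphML
#'
#' The CSV form is a two-column `citing,cited` edge list; scope is recorded
#' in a JSON sidecar `<path>.json`.
#'
#' @param net A `citation_network`.
#' @param path Output path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(data.frame(citing = net$citing, cited = net$cited),
                     path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(scope = net$scope,
                              n_nodes = length(network_nodes(net)),
                              n_edges = network_size(net)),
                         paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_network()] (CSV form)
#'
#' @param path Edge-list CSV path.
#' @return A `citation_network`; scope restored from the JSON sidecar when
#'   present.
#' @export
read_network <- function(path) {
  edges <- utils::read.csv(path, colClasses = "character")
  scope <- NA_character_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    scope <- jsonlite::read_json(sidecar)$scope
  }
  citation_network(edges$citing, edges$cited, scope = scope)
}
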