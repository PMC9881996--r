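#' One attempted three-edge swap
#'
#' Attempts a single degree-preserving move on the network: a directed
#' 3-path `a -> b -> c -> d` is drawn (uniform edge, then uniform out-edges)
#' and rewired to `a -> c`, `c -> b`, `b -> d`. The move is rejected — the
#' graph is returned unchanged — if any replacement edge would be a
#' self-loop or already exists. In- and out-degrees of every node are
#' unchanged either way. Uses R's RNG (seed with [set.seed()]).
#'
#' @param net A simple directed `citation_network` with at least 3 edges.
#' @return The network after the attempt, with attribute `"accepted"`.
#' @export
three_edge_swap <- function(net) {
  if (network_size(net) < 3) {
    warning("three_edge_swap: fewer than 3 edges; no-op")
    attr(net, "accepted") <- FALSE
    return(net)
  }
  shuffled <- run_swap_kernel(net, target_swaps = 1, max_attempts = 1)
  attr(shuffled, "accepted") <- attr(shuffled, "swaps") == 1
  shuffled
}

run_swap_kernel <- function(net, target_swaps, max_attempts) {
  nodes <- network_nodes(net)
  from <- match(net$citing, nodes) - 1L
  to <- match(net$cited, nodes) - 1L
  res <- swap_kernel_cpp(from, to, length(nodes), target_swaps, max_attempts)
  out <- citation_network(nodes[res$from + 1L], nodes[res$to + 1L],
                          scope = net$scope)
  attr(out, "swaps") <- res$swaps
  attr(out, "attempts") <- res$attempts
  out
}

#' Degree-preserving shuffle of a citation network
#'
#' Performs `ceiling(swaps_per_edge * |E|)` *successful* three-edge swaps
#' (rejected proposals are retried), bounded by
#' `max_attempt_factor * target` attempts in total. Every node keeps its
#' exact in- and out-degree, the graph stays simple, and the result is
#' deterministic given `seed`.
#'
#' The `count` argument fixes the stopping rule. `"swaps"` (the default)
#' stops after the target number of *accepted* moves — the convention of
#' published shuffling implementations, and what "swaps per edge" means in
#' the pipeline. `"attempts"` stops after the target number of *proposals*,
#' accepted or not. The distinction matters only on very small graphs: the
#' proposal kernel is symmetric, so the attempt-counted (lazy) chain has
#' an exactly uniform stationary distribution over the reachable
#' degree-fixed graphs, whereas conditioning on acceptance tilts the
#' stationary law toward states with fewer rejected proposals. On citation
#' networks of realistic size the acceptance rate is near constant across
#' states and the two rules agree in practice.
#'
#' @param net A simple directed `citation_network`.
#' @param swaps_per_edge Successful swaps (or attempts, see `count`) per
#'   edge (default 3).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   preserved.
#' @param max_attempt_factor Attempt budget as a multiple of the swap
#'   target (default 100); exhaustion returns the current graph with a
#'   warning and `attr(, "swaps") < target`. Ignored for
#'   `count = "attempts"`.
#' @param count Whether the target counts accepted swaps (`"swaps"`,
#'   default) or proposals (`"attempts"`).
#' @return A shuffled `citation_network` with attributes `swaps`,
#'   `attempts`, and `target_swaps`.
#' @export
shuffle_network <- function(net, swaps_per_edge = 3, seed = NULL,
                            max_attempt_factor = 100,
                            count = c("swaps", "attempts")) {
  count <- match.arg(count)
  stopifnot(swaps_per_edge > 0, max_attempt_factor >= 1)
  if (network_size(net) < 3) {
    warning("shuffle_network: fewer than 3 edges; returning input unchanged")
    attr(net, "swaps") <- 0
    attr(net, "attempts") <- 0
    attr(net, "target_swaps") <- 0
    return(net)
  }
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old_seed), add = TRUE)
    set.seed(seed)
  }
  target <- ceiling(swaps_per_edge * network_size(net))
  if (count == "attempts") {
    out <- run_swap_kernel(net, Inf, target)
  } else {
    out <- run_swap_kernel(net, target, max_attempt_factor * target)
    if (attr(out, "swaps") < target) {
      warning("shuffle_network: attempt budget exhausted after ",
              attr(out, "swaps"), "/", target, " swaps")
    }
  }
  attr(out, "target_swaps") <- target
  out
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Generate a null ensemble of shuffled networks
#'
#' Shuffles a field-pair network `n` times, each replicate with its own
#' seed (`base_seed + i`), giving the degree-preserving background
#' ensemble the permutation percentiles are computed against.
#'
#' @param pair_net A field-pair `citation_network`.
#' @param n Number of replicates (default 100).
#' @param base_seed Integer; replicate `i` uses seed `base_seed + i`.
#' @param swaps_per_edge,max_attempt_factor Passed to [shuffle_network()].
#' @return A `shuffle_ensemble`: list with `source`, `replicates` (list of
#'   `n` networks), and `seeds`.
#' @export
make_ensemble <- function(pair_net, n = 100, base_seed = 0,
                          swaps_per_edge = 3, max_attempt_factor = 100) {
  stopifnot(n >= 1)
  seeds <- base_seed + seq_len(n)
  replicates <- lapply(seeds, function(s) {
    shuffle_network(pair_net, swaps_per_edge = swaps_per_edge, seed = s,
                    max_attempt_factor = max_attempt_factor)
  })
  structure(list(source = pair_net, replicates = replicates, seeds = seeds),
            class = "shuffle_ensemble")
}

#' @export
print.shuffle_ensemble <- function(x, ...) {
  cat("shuffle_ensemble [", x$source$scope, "]: ",
      length(x$replicates), " replicates of ",
      network_size(x$source), " edges\n", sep = "")
  invisible(x)
}

#' Persist an ensemble as edge lists plus a manifest
#'
#' Writes one `replicate_<i>.csv` edge list per replicate and a
#' `manifest.json` recording scope, seeds, and swap/attempt counts.
#'
#' @param ensemble A `shuffle_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$replicates)) {
    write_citations(
      data.frame(citing = ensemble$replicates[[i]]$citing,
                 cited = ensemble$replicates[[i]]$cited),
      file.path(dir, sprintf("replicate_%03d.csv", i)))
  }
  manifest <- list(
    scope = ensemble$source$scope,
    n_replicates = length(ensemble$replicates),
    seeds = ensemble$seeds,
    swaps = vapply(ensemble$replicates,
                   function(r) attr(r, "swaps"), numeric(1)),
    attempts = vapply(ensemble$replicates,
                      function(r) attr(r, "attempts"), numeric(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
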