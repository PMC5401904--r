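#' Specify a cluster wiring topology
#'
#' Describes how the neurons of a simulated cluster are wired. Four families
#' are available: `scale_free` (preferential attachment), `random`
#' (Erdos-Renyi), `small_world` (Watts-Strogatz ring rewiring) and `complete`.
#' Scale-free / small-world wiring is the working hypothesis for healthy
#' cultured networks; dense random wiring models networks that have lost
#' synaptic partner selectivity. The hypothesis is configurable, not baked in.
#'
#' @param n_neurons Number of neurons (>= 2; typical imaged clusters hold
#'   9-25 cells).
#' @param kind One of `"scale_free"`, `"random"`, `"small_world"`,
#'   `"complete"`.
#' @param attachment_m Edges added per new node for `scale_free`
#'   (must be < `n_neurons`).
#' @param edge_prob Edge probability for `random`.
#' @param rewire_beta Rewiring probability for `small_world`.
#' @param ring_degree Even base ring degree for `small_world`.
#' @param seed Integer seed; identical specs yield identical graphs.
#'
#' @return A `topology_spec` list.
#' @export
topology_spec <- function(n_neurons,
                          kind = c("scale_free", "random", "small_world",
                                   "complete"),
                          attachment_m = 2L,
                          edge_prob = 0.5,
                          rewire_beta = 0.1,
                          ring_degree = 4L,
                          seed = 1L) {
  kind <- match.arg(kind)
  assert_scalar_number(n_neurons, "n_neurons", lower = 2, integer = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  if (kind == "scale_free") {
    assert_scalar_number(attachment_m, "attachment_m", lower = 1,
                         integer = TRUE)
    if (attachment_m >= n_neurons) {
      abort("`attachment_m` must be smaller than `n_neurons`.")
    }
  }
  if (kind == "random") assert_probability(edge_prob, "edge_prob")
  if (kind == "small_world") {
    assert_probability(rewire_beta, "rewire_beta")
    assert_scalar_number(ring_degree, "ring_degree", lower = 2,
                         integer = TRUE)
    if (ring_degree %% 2 != 0) abort("`ring_degree` must be even.")
  }
  structure(
    list(n_neurons = as.integer(n_neurons), kind = kind,
         attachment_m = as.integer(attachment_m), edge_prob = edge_prob,
         rewire_beta = rewire_beta, ring_degree = as.integer(ring_degree),
         seed = as.integer(seed)),
    class = "topology_spec"
  )
}

#' Build a cluster adjacency matrix from a topology spec
#'
#' @param spec A [topology_spec()].
#'
#' @return A symmetric binary `n x n` matrix with zero diagonal. The spec is
#'   attached as attribute `"spec"`.
#' @examples
#' adj <- build_topology(topology_spec(10, "random", edge_prob = 0.3, seed = 1))
#' sum(adj) / 2  # number of edges
#' @export
build_topology <- function(spec) {
  if (!inherits(spec, "topology_spec")) {
    abort("`spec` must be created by `topology_spec()`.")
  }
  n <- spec$n_neurons
  g <- withr::with_seed(spec$seed, switch(
    spec$kind,
    scale_free = igraph::sample_pa(n, power = 1, m = spec$attachment_m,
                                   directed = FALSE),
    random = igraph::sample_gnp(n, p = spec$edge_prob),
    small_world = igraph::simplify(igraph::sample_smallworld(
      1, n, spec$ring_degree %/% 2, spec$rewire_beta)),
    complete = igraph::make_full_graph(n)
  ))
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj <- pmin(adj, 1)
  diag(adj) <- 0
  storage.mode(adj) <- "integer"
  dimnames(adj) <- NULL
  attr(adj, "spec") <- spec
  adj
}
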