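directed_roles <- function(network) {
  produced <- character(); consumed <- character()
  for (r in network$reactions) {
    consumed <- c(consumed, r$reactants)
    produced <- c(produced, r$products)
    if (r$reversible) {
      consumed <- c(consumed, r$products)
      produced <- c(produced, r$reactants)
    }
  }
  list(produced = unique(produced), consumed = unique(consumed))
}

#' Dead-end and orphan metabolites
#'
#' A dead-end metabolite is produced by at least one reaction direction but
#' consumed by none; an orphan is consumed but never produced. Both
#' participants of a reversible reaction count in both roles, so a compound
#' touching any reversible reaction is neither. High dead-end/orphan
#' fractions are an indirect sign of a poorly connected draft reconstruction.
#'
#' @param network A `metabolic_network`.
#' @return Sorted character vector of compound ids.
#' @examples
#' net <- metabolic_network("toy", list(reaction("r1", "a", "b")))
#' dead_end_metabolites(net)  # "b"
#' orphan_metabolites(net)    # "a"
#' @export
dead_end_metabolites <- function(network) {
  roles <- directed_roles(network)
  sort(setdiff(roles$produced, roles$consumed))
}

#' @rdname dead_end_metabolites
#' @export
orphan_metabolites <- function(network) {
  roles <- directed_roles(network)
  sort(setdiff(roles$consumed, roles$produced))
}

#' Default currency-metabolite list
#'
#' The 23 ubiquitous cofactors and inorganic compounds conventionally removed
#' before graph-connectivity analysis (water, proton, ATP, ADP, 3'-5'-ADP,
#' AMP, NADP, NADPH, NAD, NADH, FAD, UDP, GTP, GDP, molecular oxygen,
#' inorganic phosphate, diphosphate, carbon dioxide, ammonia, hydrogen
#' peroxide, coenzyme A, and the generic H2 acceptor/donor pair). Matching
#' against compound ids is by exact string on either the English name or the
#' MetaCyc-style id, so networks in either namespace work out of the box;
#' pass your own table for other namespaces.
#'
#' @return A 23-row `data.frame` with columns `name` and `id`.
#' @export
ubiquitous_metabolites <- function() {
  data.frame(
    name = c("water", "proton", "ATP", "ADP", "3-5-ADP", "AMP", "NADP",
             "NADPH", "NAD", "NADH", "FAD", "UDP", "GTP", "GDP",
             "oxygen molecule", "inorganic phosphate", "diphosphate",
             "carbon dioxide", "ammonia", "hydrogen peroxide", "coenzyme A",
             "H2-acceptor", "H2-donor"),
    id = c("WATER", "PROTON", "ATP", "ADP", "3-5-ADP", "AMP", "NADP",
           "NADPH", "NAD", "NADH", "FAD", "UDP", "GTP", "GDP",
           "OXYGEN-MOLECULE", "Pi", "PPI", "CARBON-DIOXIDE", "AMMONIA",
           "HYDROGEN-PEROXIDE", "CO-A", "Acceptor", "Donor-H2"),
    stringsAsFactors = FALSE
  )
}

ubiquitous_ids <- function(ubiquitous) {
  if (is.data.frame(ubiquitous)) unique(c(ubiquitous$name, ubiquitous$id))
  else unique(as.character(ubiquitous))
}

#' Directed metabolite graph
#'
#' One node per non-ubiquitous compound; an edge u -> v for every reaction
#' direction having u among its substrates and v among its products
#' (reversible reactions contribute both directions). Parallel edges are
#' collapsed. Reactions whose participants are all ubiquitous contribute
#' nothing.
#'
#' @param network A `metabolic_network`.
#' @param ubiquitous Currency metabolites to drop: a `data.frame` as returned
#'   by [ubiquitous_metabolites()] (matched on both columns) or a character
#'   vector of ids.
#' @return An [igraph::igraph] directed graph.
#' @export
metabolite_graph <- function(network, ubiquitous = ubiquitous_metabolites()) {
  drop <- ubiquitous_ids(ubiquitous)
  nodes <- setdiff(compounds(network), drop)
  from <- character(); to <- character()
  for (r in network$reactions) {
    s <- setdiff(r$reactants, drop); p <- setdiff(r$products, drop)
    if (length(s) && length(p)) {
      grid <- expand.grid(s, p, stringsAsFactors = FALSE)
      from <- c(from, grid[[1]]); to <- c(to, grid[[2]])
      if (r$reversible) { from <- c(from, grid[[2]]); to <- c(to, grid[[1]]) }
    }
  }
  edges <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

#' Largest strongly connected component ratio
#'
#' Size of the largest strongly connected component of the directed
#' metabolite graph divided by its node count, a proxy for overall network
#' connectivity. By default both numerator and denominator are taken after
#' ubiquitous-metabolite removal; `denominator = "pre"` divides by the full
#' compound count of the network instead.
#'
#' @inheritParams metabolite_graph
#' @param denominator `"post"` (node count after removal, default) or
#'   `"pre"` (all network compounds).
#' @return A fraction in `[0, 1]`; 0 for an empty graph.
#' @export
scc_ratio <- function(network, ubiquitous = ubiquitous_metabolites(),
                      denominator = c("post", "pre")) {
  denominator <- match.arg(denominator)
  g <- metabolite_graph(network, ubiquitous)
  if (igraph::vcount(g) == 0L) return(0)
  comp <- igraph::components(g, mode = "strong")
  denom <- if (denominator == "post") igraph::vcount(g)
           else length(compounds(network))
  if (denom == 0L) return(0)
  max(comp$csize) / denom
}

#' Indirect quality metrics of a draft network
#'
#' Bundles the dead-end and orphan counts (with percentages over all network
#' compounds, the shared pre-removal denominator) and the largest-SCC ratio
#' after currency-metabolite removal.
#'
#' @inheritParams scc_ratio
#' @return An object of class `quality_metrics`: a list with `n_deadend`,
#'   `pct_deadend`, `n_orphan`, `pct_orphan`, `scc_ratio`,
#'   `n_compounds_after_removal`, and the id sets `deadend_ids`/`orphan_ids`.
#' @export
network_quality <- function(network, ubiquitous = ubiquitous_metabolites(),
                            denominator = c("post", "pre")) {
  denominator <- match.arg(denominator)
  cpds <- compounds(network)
  de <- dead_end_metabolites(network)
  or <- orphan_metabolites(network)
  g <- metabolite_graph(network, ubiquitous)
  pct <- function(n) if (length(cpds) == 0L) 0 else 100 * n / length(cpds)
  structure(
    list(n_deadend = length(de), pct_deadend = pct(length(de)),
         n_orphan = length(or), pct_orphan = pct(length(or)),
         scc_ratio = scc_ratio(network, ubiquitous, denominator),
         n_compounds_after_removal = igraph::vcount(g),
         deadend_ids = de, orphan_ids = or),
    class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("<quality_metrics> dead-ends %d (%.1f%%), orphans %d (%.1f%%), SCC ratio %.3f\n",
              x$n_deadend, x$pct_deadend, x$n_orphan, x$pct_orphan,
              x$scc_ratio))
  invisible(x)
}
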