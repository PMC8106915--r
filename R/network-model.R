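#' Create a stoichiometry-free reaction
#'
#' A reaction records which compounds it consumes and produces, whether it is
#' reversible, and its supporting annotation (gene associations and EC
#' numbers). Stoichiometric coefficients and kinetics are deliberately not
#' represented: all downstream producibility reasoning uses the qualitative
#' network-expansion semantics, for which only compound identities and
#' directionality matter.
#'
#' @param id Reaction identifier, a nonempty string.
#' @param reactants,products Character vectors of compound ids. Duplicates are
#'   dropped; a compound may appear on both sides. At least one participant is
#'   required overall.
#' @param reversible Logical flag; a reversible reaction may fire in either
#'   direction during scope computation.
#' @param genes Character vector of supporting gene ids (possibly empty).
#'   Boolean gene-association logic is not modelled, only the gene set.
#' @param ec Character vector of EC numbers, possibly partial (e.g.
#'   `"1.1.-.-"`).
#' @return An object of class `ss_reaction`.
#' @examples
#' reaction("r1", "glc", "g6p", genes = "hexA", ec = "2.7.1.1")
#' @export
reaction <- function(id, reactants, products, reversible = FALSE,
                     genes = character(), ec = character()) {
  id <- as.character(id)
  if (length(id) != 1L || is.na(id) || !nzchar(id))
    stopf("reaction id must be a single nonempty string")
  reactants <- sorted_unique(reactants[!is.na(reactants) & nzchar(reactants)])
  products <- sorted_unique(products[!is.na(products) & nzchar(products)])
  if (length(reactants) + length(products) == 0L)
    stopf("reaction '%s' has no participants", id)
  structure(
    list(id = id, reactants = reactants, products = products,
         reversible = isTRUE(reversible),
         genes = sorted_unique(genes[nzchar(genes)]),
         ec = sorted_unique(ec[nzchar(ec)])),
    class = "ss_reaction"
  )
}

#' @export
print.ss_reaction <- function(x, ...) {
  arrow <- if (x$reversible) "<=>" else "-->"
  cat(sprintf("<reaction %s> %s %s %s\n", x$id,
              paste(x$reactants, collapse = " + "), arrow,
              paste(x$products, collapse = " + ")))
  if (length(x$genes)) cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  if (length(x$ec)) cat("  ec:", paste(x$ec, collapse = ", "), "\n")
  invisible(x)
}

#' Create a metabolic network
#'
#' A network is a set of [reaction()]s with a strain label and, optionally,
#' the label of the annotation pipeline it was derived from. The compound set
#' is always derived from the reactions, never stored independently, so it can
#' never dangle.
#'
#' @param id Strain label.
#' @param reactions List of `ss_reaction` objects with unique ids.
#' @param pipeline Optional annotation-pipeline label.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(id, reactions, pipeline = NA_character_) {
  if (inherits(reactions, "ss_reaction")) reactions <- list(reactions)
  ok <- vapply(reactions, inherits, logical(1), what = "ss_reaction")
  if (!all(ok)) stopf("all elements of 'reactions' must be ss_reaction objects")
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stopf("duplicate reaction id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  reactions <- reactions[order(ids)]
  names(reactions) <- sort(ids)
  structure(list(id = as.character(id), pipeline = as.character(pipeline),
                 reactions = reactions),
            class = "metabolic_network")
}

#' Compound set of a network
#'
#' @param network A `metabolic_network`.
#' @return Sorted character vector: the union of all reactants and products.
#' @export
compounds <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  sorted_unique(unlist(lapply(network$reactions,
                              function(r) c(r$reactants, r$products)),
                       use.names = FALSE))
}

reaction_ids <- function(network) names(network$reactions)

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network %s%s> %d reactions, %d compounds\n",
              x$id,
              if (is.na(x$pipeline)) "" else paste0(" [", x$pipeline, "]"),
              length(x$reactions), length(compounds(x))))
  invisible(x)
}

#' Keep only gene-supported reactions
#'
#' Draft reconstructions contain spontaneous or gap-filled reactions without
#' genetic support; analyses of annotation robustness work on the
#' gene-associated subnetwork, so reactions with an empty gene set are
#' discarded and the compound set shrinks accordingly.
#'
#' @param network A `metabolic_network`.
#' @return A `metabolic_network` containing exactly the reactions with a
#'   nonempty gene set. An all-empty result is allowed but raises a warning.
#' @export
filter_gene_associated <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  keep <- vapply(network$reactions, function(r) length(r$genes) > 0L,
                 logical(1))
  if (!any(keep))
    warning(sprintf("network '%s': no reaction has a gene association",
                    network$id), call. = FALSE)
  metabolic_network(network$id, unname(network$reactions[keep]),
                    network$pipeline)
}

#' Merge metabolic networks by reaction id
#'
#' Reactions are unioned by id: a reaction present in several inputs is kept
#' once, marked reversible if reversible in any input, with gene and EC sets
#' unioned. Two inputs using the same id for different chemistry signal
#' inconsistent sources and raise an error.
#'
#' @param networks Nonempty list of `metabolic_network` objects.
#' @param id,pipeline Labels for the merged network; default to the first
#'   input's strain id and the pipeline label `"merged"`.
#' @return A `metabolic_network`.
#' @export
merge_networks <- function(networks, id = NULL, pipeline = "merged") {
  if (inherits(networks, "metabolic_network")) networks <- list(networks)
  if (length(networks) == 0L) stopf("'networks' must be a nonempty list")
  pool <- list()
  for (net in networks) {
    stopifnot(inherits(net, "metabolic_network"))
    for (r in net$reactions) {
      prev <- pool[[r$id]]
      if (is.null(prev)) {
        pool[[r$id]] <- r
      } else {
        if (!setequal(prev$reactants, r$reactants) ||
            !setequal(prev$products, r$products))
          stopf("reaction '%s' has conflicting participant sets across inputs",
                r$id)
        pool[[r$id]] <- reaction(r$id, r$reactants, r$products,
                                 reversible = prev$reversible || r$reversible,
                                 genes = c(prev$genes, r$genes),
                                 ec = c(prev$ec, r$ec))
      }
    }
  }
  metabolic_network(id %||% networks[[1]]$id, unname(pool), pipeline)
}

instance_label <- function(network) {
  if (is.na(network$pipeline)) network$id
  else paste(network$id, network$pipeline, sep = "|")
}

#' Reaction presence/absence matrix
#'
#' Builds the instances-by-reactions boolean matrix underlying all
#' dissimilarity-based comparisons: one row per (strain, pipeline) instance,
#' one column per reaction id observed in any instance.
#'
#' @param networks Nonempty list of `metabolic_network` objects with distinct
#'   (strain, pipeline) labels.
#' @return A logical matrix with instance labels as rownames,
#'   lexicographically sorted reaction ids as colnames, and a `data.frame`
#'   attribute `"instances"` holding the strain and pipeline of each row.
#' @export
reaction_presence_matrix <- function(networks) {
  if (inherits(networks, "metabolic_network")) networks <- list(networks)
  if (length(networks) == 0L) stopf("'networks' must be a nonempty list")
  labels <- vapply(networks, instance_label, character(1))
  if (anyDuplicated(labels))
    stopf("duplicate (strain, pipeline) instance label(s): %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  cols <- sorted_unique(unlist(lapply(networks, reaction_ids),
                               use.names = FALSE))
  m <- matrix(FALSE, length(networks), length(cols),
              dimnames = list(labels, cols))
  for (i in seq_along(networks))
    m[i, reaction_ids(networks[[i]])] <- TRUE
  attr(m, "instances") <- data.frame(
    strain = vapply(networks, `[[`, character(1), "id"),
    pipeline = vapply(networks, `[[`, character(1), "pipeline"),
    row.names = labels
  )
  m
}
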