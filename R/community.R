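community_result <- function(min_size, communities, targets, truncated = FALSE) {
  communities <- lapply(communities, sort)
  structure(
    list(min_size = as.integer(min_size),
         communities = communities,
         union = sorted_unique(unlist(communities, use.names = FALSE)),
         targets_checked = sorted_unique(targets),
         truncated = isTRUE(truncated)),
    class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("<community_result> min size %d; %d optimal communit%s%s; union of %d strains; %d targets\n",
              x$min_size, length(x$communities),
              if (length(x$communities) == 1L) "y" else "ies",
              if (x$truncated) " (list truncated)" else "",
              length(x$union), length(x$targets_checked)))
  invisible(x)
}

# Precompiled coverage oracle over host + symbiont rule sets: covers(sel)
# runs the scope fixpoint with only the selected strains' rules enabled;
# emits_ok(sel) is a cheap sound necessary condition (every target no host
# rule can emit must be a product of some selected strain's rules).
make_cover_oracle <- function(host, symbionts, seeds, targets) {
  nm <- symbiont_names(symbionts)
  ord <- order(nm)
  symbionts <- symbionts[ord]; nm <- nm[ord]
  n <- length(symbionts)
  eng <- scope_engine(c(list(host), symbionts),
                      extra_compounds = c(seeds, targets))
  seed_idx <- match(sorted_unique(seeds), eng$comp)
  target_idx <- match(sorted_unique(targets), eng$comp)
  host_on <- eng$owner == 1L
  strain_rules <- lapply(seq_len(n), function(j) eng$owner == j + 1L)
  rule_prods_targets <- function(mask) {
    idx <- unique(unlist(eng$prods[mask], use.names = FALSE))
    target_idx %in% idx
  }
  host_emits <- rule_prods_targets(host_on) | (target_idx %in% seed_idx)
  strain_emits <- vapply(strain_rules, rule_prods_targets,
                         logical(length(target_idx)))
  if (length(target_idx) == 1L)
    strain_emits <- matrix(strain_emits, nrow = 1L)
  hard <- which(!host_emits)
  list(
    nm = nm, n = n, eng = eng, hard = hard,
    producible_targets = function(sel) {
      on <- host_on
      for (j in sel) on <- on | strain_rules[[j]]
      scope_fixpoint(eng, seed_idx, on)$prod_flag[target_idx]
    },
    covers = function(sel) {
      on <- host_on
      for (j in sel) on <- on | strain_rules[[j]]
      fx <- scope_fixpoint(eng, seed_idx, on)
      all(fx$prod_flag[target_idx])
    },
    emits_ok = function(sel) {
      if (length(hard) == 0L) return(TRUE)
      if (length(sel) == 0L) return(FALSE)
      ok <- if (length(sel) == 1L) strain_emits[hard, sel]
            else rowSums(strain_emits[hard, sel, drop = FALSE]) > 0
      all(ok)
    })
}

community_search <- function(host, symbionts, seeds, targets,
                             enumerate, cap) {
  stopifnot(inherits(host, "metabolic_network"))
  if (inherits(symbionts, "metabolic_network")) symbionts <- list(symbionts)
  targets <- sorted_unique(targets)
  if (length(targets) == 0L)
    return(community_result(0L, list(character(0)), targets))
  nm0 <- symbiont_names(symbionts)
  if (anyDuplicated(nm0))
    stopf("duplicate symbiont strain id(s): %s",
          paste(unique(nm0[duplicated(nm0)]), collapse = ", "))
  orc <- make_cover_oracle(host, symbionts, seeds, targets)
  nm <- orc$nm; n <- orc$n
  got_full <- orc$producible_targets(seq_len(n))
  if (!all(got_full))
    stopf("target(s) not producible even by the full community: %s",
          paste(targets[!got_full], collapse = ", "))

  # Greedy upper bound: repeatedly add the strain unlocking the most
  # still-missing targets (ties broken lexicographically by strain id).
  greedy <- integer(0)
  got <- orc$producible_targets(greedy)
  while (!all(got)) {
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% greedy) return(-1L)
      sum(orc$producible_targets(c(greedy, j)) & !got)
    }, integer(1))
    best <- which.max(gain)  # first index on ties = lexicographic by id
    if (gain[best] <= 0L)
      best <- which(gain == 0L & !(seq_len(n) %in% greedy))[1]
    greedy <- c(greedy, best)
    got <- orc$producible_targets(greedy)
  }
  ub <- length(greedy)

  for (k in 0:ub) {
    found <- list()
    union_acc <- character(0)
    n_found <- 0L
    combos <- if (k == 0L) matrix(integer(0), nrow = 0L, ncol = 1L)
              else utils::combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      sel <- combos[, ci]
      if (!orc$emits_ok(sel)) next
      if (orc$covers(sel)) {
        n_found <- n_found + 1L
        union_acc <- unique(c(union_acc, nm[sel]))
        if (n_found <= cap) found[[n_found]] <- nm[sel]
        if (!enumerate) break
      }
    }
    if (n_found > 0L) {
      res <- community_result(k, found, targets, truncated = n_found > cap)
      if (enumerate && n_found > cap) res$union <- sort(union_acc)
      return(res)
    }
  }
  stopf("internal error: greedy cover of size %d not confirmed", ub)
}

#' Minimum-cardinality symbiont community covering a target set
#'
#' Finds the smallest number of symbionts whose pooled reactions, together
#' with the host and the medium, make every target compound producible
#' ("soup" semantics, no exchange costs). Optimality is proved by exhaustive
#' search in increasing community size, bounded above by a greedy cover;
#' every candidate is verified by the scope fixpoint itself, and subsets that
#' cannot even emit some required target as a reaction product are pruned.
#' One witness is returned, the lexicographically first by sorted strain ids,
#' so runs are reproducible.
#'
#' @param host Host `metabolic_network`.
#' @param symbionts Named list of symbiont networks.
#' @param seeds Seed compound ids (culture medium).
#' @param targets Target compound ids; must be achievable by the full
#'   community, otherwise an error lists the unproducible targets. An empty
#'   target set yields a community of size 0.
#' @param cap Maximum number of optimal communities stored when enumerating;
#'   beyond it the list is truncated (flagged) but the union still covers all
#'   optima.
#' @return A `community_result` with elements `min_size`, `communities`
#'   (list of strain-id sets), `union`, `targets_checked` and `truncated`.
#' @seealso [enumerate_minimal_communities()] for all optima,
#'   [added_value()] for the canonical target set.
#' @export
minimal_community <- function(host, symbionts, seeds, targets, cap = 10000L) {
  community_search(host, symbionts, seeds, targets,
                   enumerate = FALSE, cap = cap)
}

#' Enumerate all minimum-size communities and their union
#'
#' Same optimum as [minimal_community()], but lists every community of
#' minimum size that covers the targets, plus the union of all of them (the
#' set of strains appearing in at least one optimal community).
#'
#' @inheritParams minimal_community
#' @return A `community_result` whose `communities` holds all optima (up to
#'   `cap`; the `union` is computed over all optima regardless).
#' @export
enumerate_minimal_communities <- function(host, symbionts, seeds, targets,
                                          cap = 10000L) {
  community_search(host, symbionts, seeds, targets,
                   enumerate = TRUE, cap = cap)
}

#' Score a fixed community against another pipeline's networks
#'
#' Takes a community selected on one annotation pipeline's networks and
#' evaluates it on another pipeline's reconstruction of the same strains:
#' the count of host metabolites newly producible when the fixed community's
#' other-pipeline networks are pooled with that pipeline's host. This is the
#' interchangeability comparison between pipelines.
#'
#' @param community Character vector of strain ids (may be empty, yielding 0).
#' @param host Host network from the target pipeline.
#' @param symbionts Named list of the target pipeline's symbiont networks;
#'   every community strain must be present.
#' @param seeds Seed compound ids.
#' @param host_restrict Restrict to host compounds, as in [added_value()].
#' @return Integer count of newly producible (target-type) compounds.
#' @export
cross_pipeline_scope <- function(community, host, symbionts, seeds,
                                 host_restrict = TRUE) {
  if (inherits(symbionts, "metabolic_network")) symbionts <- list(symbionts)
  nm <- symbiont_names(symbionts)
  missing <- setdiff(community, nm)
  if (length(missing))
    stopf("strain(s) absent from target collection: %s",
          paste(missing, collapse = ", "))
  length(added_value(host, symbionts[match(community, nm)], seeds,
                     host_restrict = host_restrict))
}
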