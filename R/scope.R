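#' @keywords internal
#' Precompile a pooled reaction set into directed rules for fast repeated
#' scope evaluation. A reversible reaction becomes two directed rules; an
#' irreversible one a single forward rule. `owner` tags each rule with the
#' index of the network it came from so subsets of networks can be switched
#' on and off without rebuilding.
scope_engine <- function(networks, extra_compounds = character()) {
  if (inherits(networks, "metabolic_network")) networks <- list(networks)
  subs <- list(); prods <- list(); rxn <- character(); owner <- integer()
  add_rule <- function(s, p, id, o) {
    subs[[length(subs) + 1L]] <<- s
    prods[[length(prods) + 1L]] <<- p
    rxn[length(rxn) + 1L] <<- id
    owner[length(owner) + 1L] <<- o
  }
  all_cpds <- character()
  for (i in seq_along(networks)) {
    for (r in networks[[i]]$reactions)
      all_cpds <- c(all_cpds, r$reactants, r$products)
  }
  comp <- sorted_unique(c(all_cpds, extra_compounds))
  for (i in seq_along(networks)) {
    for (r in networks[[i]]$reactions) {
      s <- match(r$reactants, comp); p <- match(r$products, comp)
      add_rule(s, p, r$id, i)
      if (r$reversible) add_rule(p, s, r$id, i)
    }
  }
  needs <- vector("list", length(comp))
  for (k in seq_along(subs))
    for (cc in subs[[k]]) needs[[cc]] <- c(needs[[cc]], k)
  list(comp = comp, subs = subs, prods = prods, rxn = rxn, owner = owner,
       needs = needs, n_networks = length(networks))
}

# Worklist fixpoint over precompiled rules. A rule fires once all of its
# distinct substrates are producible; all of its products then become
# producible. Iterations count expansion waves that added >= 1 compound.
scope_fixpoint <- function(eng, seed_idx, rule_on = NULL) {
  nr <- length(eng$subs)
  on <- if (is.null(rule_on)) rep(TRUE, nr) else rule_on
  prod_flag <- logical(length(eng$comp))
  if (length(seed_idx)) prod_flag[seed_idx] <- TRUE
  unmet <- integer(nr)
  for (k in seq_len(nr))
    unmet[k] <- sum(!prod_flag[eng$subs[[k]]])
  fired <- logical(nr)
  n_iter <- 0L
  repeat {
    ready <- which(on & !fired & unmet == 0L)
    if (length(ready) == 0L) break
    fired[ready] <- TRUE
    newc <- unique(unlist(eng$prods[ready], use.names = FALSE))
    newc <- newc[!prod_flag[newc]]
    if (length(newc) == 0L) break
    prod_flag[newc] <- TRUE
    n_iter <- n_iter + 1L
    for (cc in newc) {
      rs <- eng$needs[[cc]]
      if (length(rs)) unmet[rs] <- unmet[rs] - 1L
    }
  }
  list(prod_flag = prod_flag, n_iterations = n_iter, fired = fired)
}

#' Producible compounds from seed compounds (network expansion)
#'
#' Computes the scope: the least fixpoint obtained by starting from the seed
#' compounds (culture medium) and repeatedly firing any reaction, in either
#' direction if reversible, whose substrates for that direction are all
#' already producible. Stoichiometry, kinetics and organism abundances play
#' no role. The result is independent of reaction order; a compound that is
#' both substrate and product of the same direction cannot self-activate.
#'
#' @param networks A `metabolic_network` or list of them (reactions are
#'   pooled). An empty list is allowed and yields the seeds themselves.
#' @param seeds Nonempty character vector of seed compound ids. Seeds absent
#'   from the networks are retained in the result.
#' @return An object of class `scope_result`: a list with `producible`
#'   (sorted compound ids, always containing the seeds), `n_iterations`
#'   (number of expansion waves that added a compound) and `active_reactions`
#'   (ids of reactions that fired in at least one direction).
#' @examples
#' net <- metabolic_network("toy", list(
#'   reaction("r1", "s", "a", genes = "g1"),
#'   reaction("r2", c("a", "b"), "c", genes = "g2")))
#' compute_scope(net, "s")$producible   # c is blocked: b is not producible
#' @export
compute_scope <- function(networks, seeds) {
  if (inherits(networks, "metabolic_network")) networks <- list(networks)
  seeds <- sorted_unique(seeds)
  if (length(seeds) == 0L) stopf("'seeds' must be nonempty")
  eng <- scope_engine(networks, extra_compounds = seeds)
  fx <- scope_fixpoint(eng, match(seeds, eng$comp))
  structure(
    list(producible = sorted_unique(c(seeds, eng$comp[fx$prod_flag])),
         n_iterations = fx$n_iterations,
         active_reactions = sorted_unique(eng$rxn[fx$fired])),
    class = "scope_result")
}

#' @export
print.scope_result <- function(x, ...) {
  cat(sprintf("<scope_result> %d producible compounds, %d active reactions, %d iterations\n",
              length(x$producible), length(x$active_reactions),
              x$n_iterations))
  invisible(x)
}

#' Host metabolites unlocked by symbiotic cooperation (added value)
#'
#' Pools the symbiont reactions with the host ("soup" semantics: no exchange
#' bookkeeping) and returns the host metabolites that the combined system can
#' produce from the medium but the host alone cannot. This set is the target
#' set for minimal community selection.
#'
#' @param host Host `metabolic_network`.
#' @param symbionts List of symbiont networks (may be empty).
#' @param seeds Seed compound ids.
#' @param host_restrict If `TRUE` (default) the result is restricted to
#'   compounds of the host network; `FALSE` returns every newly producible
#'   compound, for sensitivity analyses.
#' @return Sorted character vector of newly producible compound ids, disjoint
#'   from the host-alone scope.
#' @export
added_value <- function(host, symbionts, seeds, host_restrict = TRUE) {
  stopifnot(inherits(host, "metabolic_network"))
  if (inherits(symbionts, "metabolic_network")) symbionts <- list(symbionts)
  full <- compute_scope(c(list(host), symbionts), seeds)$producible
  alone <- compute_scope(list(host), seeds)$producible
  base <- if (host_restrict) intersect(full, compounds(host)) else full
  sort(setdiff(base, alone))
}

symbiont_names <- function(symbionts) {
  nm <- names(symbionts)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(symbionts, `[[`, character(1), "id")
  nm
}

#' Scope of the host plus a chosen symbiont community
#'
#' @param host Host network.
#' @param symbionts Named list of available symbiont networks (names default
#'   to their strain ids).
#' @param community Character vector of strain ids selecting the community
#'   members; must all be available.
#' @param seeds Seed compound ids.
#' @return A `scope_result` for the host merged with exactly the community
#'   members.
#' @export
community_scope <- function(host, symbionts, community, seeds) {
  if (inherits(symbionts, "metabolic_network")) symbionts <- list(symbionts)
  nm <- symbiont_names(symbionts)
  missing <- setdiff(community, nm)
  if (length(missing))
    stopf("unknown community member(s): %s", paste(missing, collapse = ", "))
  compute_scope(c(list(host), symbionts[match(community, nm)]), seeds)
}
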