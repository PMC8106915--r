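# Independent brute-force oracles and random-instance builders used across
# the suite. Deliberately naive: they re-derive every result from first
# principles and share no code with the implementation paths they check.

# Repeat-until-stable network expansion over plain character sets.
naive_scope <- function(networks, seeds) {
  if (inherits(networks, "metabolic_network")) networks <- list(networks)
  rxns <- do.call(c, c(lapply(networks, function(n) unname(n$reactions)),
                       list(list())))
  prod <- unique(as.character(seeds))
  repeat {
    added <- FALSE
    for (r in rxns) {
      if (all(r$reactants %in% prod) && !all(r$products %in% prod)) {
        prod <- union(prod, r$products); added <- TRUE
      }
      if (r$reversible && all(r$products %in% prod) &&
          !all(r$reactants %in% prod)) {
        prod <- union(prod, r$reactants); added <- TRUE
      }
    }
    if (!added) break
  }
  sort(prod)
}

# Random stoichiometry-free network over a bounded compound pool.
random_network <- function(id = "N", n_rxn = 10, n_cpd = 12,
                           rev_prob = 0.1, gene_prob = 1, pipeline = NA) {
  cpds <- sprintf("m%02d", seq_len(n_cpd))
  rxns <- lapply(seq_len(n_rxn), function(i) {
    nr <- sample(1:3, 1); np <- sample(1:3, 1)
    reaction(sprintf("%s_r%03d", id, i),
             sample(cpds, nr), sample(cpds, np),
             reversible = runif(1) < rev_prob,
             genes = if (runif(1) < gene_prob)
               sprintf("g_%s_%d", id, i) else character(),
             ec = sprintf("%d.%d.1.1", sample(1:7, 1), sample(1:9, 1)))
  })
  metabolic_network(id, rxns, pipeline)
}

# Random host + symbionts + achievable targets for community-selection
# oracles. Targets are sampled from the full community's added value, so the
# precondition always holds; synergy arises through shared intermediates.
random_mincom_instance <- function(seed, max_symbionts = 10) {
  set.seed(seed)
  n_sym <- sample(3:max_symbionts, 1)
  pool <- c(sprintf("m%02d", 1:10), sprintf("t%d", 1:4))
  seeds <- c("s1", "s2")
  make_net <- function(id, n_rxn) {
    rxns <- lapply(seq_len(n_rxn), function(i) {
      subs <- sample(c(seeds, pool), sample(1:2, 1))
      prods <- sample(pool, sample(1:2, 1))
      reaction(sprintf("%s_r%d", id, i), subs, prods,
               reversible = runif(1) < 0.1,
               genes = sprintf("g_%s_%d", id, i))
    })
    metabolic_network(id, rxns)
  }
  host <- make_net("host", sample(2:4, 1))
  symbionts <- lapply(seq_len(n_sym), function(j)
    make_net(sprintf("S%02d", j), sample(2:5, 1)))
  names(symbionts) <- vapply(symbionts, `[[`, character(1), "id")
  av <- added_value(host, symbionts, seeds)
  targets <- if (length(av) == 0) character(0)
             else sample(av, sample(seq_len(min(4, length(av))), 1))
  list(host = host, symbionts = symbionts, seeds = seeds,
       targets = sort(targets))
}

# Exhaustive minimum-cover enumeration via naive_scope.
oracle_mincom <- function(host, symbionts, seeds, targets) {
  nm <- sort(names(symbionts))
  if (length(targets) == 0)
    return(list(min_size = 0L, communities = list(character(0)),
                union = character(0)))
  for (k in 0:length(nm)) {
    hits <- list()
    combos <- if (k == 0) matrix(character(0), nrow = 0, ncol = 1)
              else combn(nm, k)
    for (ci in seq_len(ncol(combos))) {
      sel <- combos[, ci]
      prod <- naive_scope(c(list(host), unname(symbionts[sel])), seeds)
      if (all(targets %in% prod)) hits[[length(hits) + 1L]] <- sort(sel)
    }
    if (length(hits))
      return(list(min_size = k, communities = hits,
                  union = sort(unique(unlist(hits)))))
  }
  stop("oracle: targets unachievable")
}

# All permutations of seq_len(n) (n small), one per row.
all_index_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_index_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# ANOSIM R and exact permutation p by full enumeration, from first
# principles (independent rank bookkeeping).
oracle_anosim_exact <- function(dm, groups) {
  dm <- as.matrix(dm); n <- nrow(dm)
  lt <- lower.tri(dm)
  r <- rank(dm[lt]); ii <- row(dm)[lt]; jj <- col(dm)[lt]
  M <- n * (n - 1) / 2
  R_of <- function(g) {
    w <- g[ii] == g[jj]
    (mean(r[!w]) - mean(r[w])) / (M / 2)
  }
  obs <- R_of(groups)
  perms <- all_index_permutations(n)
  Rs <- apply(perms, 1, function(p) R_of(groups[p]))
  list(R = obs, p = mean(Rs >= obs - 1e-12), n_arrangements = nrow(perms))
}

# One-sided binomial upper tail by explicit term-by-term summation.
direct_binom_tail <- function(x, size, prob) {
  if (x > size) return(0)
  ks <- max(0, x):size
  sum(choose(size, ks) * prob^ks * (1 - prob)^(size - ks))
}

# Largest-SCC size via Warshall pairwise reachability.
oracle_largest_scc <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0L)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n))
    reach <- reach | outer(reach[, k], reach[k, ], "&")
  mutual <- reach & t(reach)
  comp <- apply(mutual, 1, function(z) paste(which(z), collapse = ","))
  max(table(comp))
}

flatten_observed <- function(inst)
  unlist(unname(lapply(inst$observed, function(x) x)), recursive = FALSE)

small_test_config <- function(seed = 1, ...) {
  generator_config(n_phyla = 2, strains_per_phylum = 2, n_pathways = 12,
                   pathway_length = 3, host_pathway_count = 3,
                   host_own_pathway_count = 2, rng_seed = seed, ...)
}
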