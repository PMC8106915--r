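EC_CATEGORIES <- c("1.1", "1.2", "1.6", "1.11", "2.1", "2.3", "2.6", "2.7",
                   "3.1", "3.2", "3.5", "4.1", "4.2", "5.1", "5.3", "5.4",
                   "6.1", "6.3", "6.4", "7.1")

#' Annotation-pipeline observation profile
#'
#' Describes how one simulated annotation pipeline observes a true network:
#' each true reaction is detected with probability `sensitivity`, and a
#' Poisson(`fp_rate`) number of spurious reactions is drawn from the
#' pipeline's private decoy pool (its exclusive false-positive repertoire,
#' of size `exclusive_pool_size`).
#'
#' @param name Pipeline label.
#' @param sensitivity Detection probability per true reaction, in (0, 1].
#' @param fp_rate Expected number of pipeline-specific false reactions per
#'   strain (>= 0).
#' @param exclusive_pool_size Size of the pipeline's private decoy pool.
#' @return An object of class `pipeline_profile`.
#' @export
pipeline_profile <- function(name, sensitivity, fp_rate,
                             exclusive_pool_size = 8L) {
  if (!(sensitivity > 0 && sensitivity <= 1))
    stopf("sensitivity must be in (0, 1]")
  if (fp_rate < 0) stopf("fp_rate must be >= 0")
  structure(list(name = as.character(name), sensitivity = sensitivity,
                 fp_rate = fp_rate,
                 exclusive_pool_size = as.integer(exclusive_pool_size)),
            class = "pipeline_profile")
}

#' Default set of five simulated pipelines
#'
#' Five profiles spanning sensitivities 0.90-0.98 and false-positive rates
#' 2-8 per strain, emulating annotation tools that differ both in how much of
#' the true reactome they recover and in how many tool-specific spurious
#' reactions they introduce.
#'
#' @return List of five [pipeline_profile()] objects.
#' @export
default_pipeline_profiles <- function() {
  nm <- c("alpha", "beta", "gamma", "delta", "epsilon")
  sens <- c(0.98, 0.96, 0.94, 0.92, 0.90)
  fp <- c(2, 3, 5, 6, 8)
  out <- Map(pipeline_profile, nm, sens, fp)
  names(out) <- nm
  out
}

#' Configuration of the synthetic-data generator
#'
#' Defines the study design the generator emulates: `n_phyla *
#' strains_per_phylum` bacterial strains whose reaction content is driven by
#' phylum-level core pathways plus a small private repertoire, observed
#' through several imperfect annotation pipelines, together with a host that
#' depends on bacterial pathway products.
#'
#' @param n_phyla Number of phyla (default 4).
#' @param strains_per_phylum Strains per phylum (default 5).
#' @param n_pathways Number of linear pathways in the reaction universe.
#' @param pathway_length Reactions per pathway chain.
#' @param phylum_core_fraction Fraction of pathways forming each phylum's
#'   core, shared by all its strains.
#' @param strain_private_fraction Fraction of universe reactions each strain
#'   additionally carries as private repertoire.
#' @param pipelines List of [pipeline_profile()]s (>= 2).
#' @param host_pathway_count Number of bacterial pathways whose terminal
#'   products the host consumes (these define the planted targets).
#' @param host_own_pathway_count Number of universe pathways the host itself
#'   carries (its autonomous metabolism).
#' @param cross_link_prob Probability that a pathway starts from an earlier
#'   pathway's terminal compound instead of a fresh medium compound.
#' @param reversible_frac Fraction of reversible chain steps.
#' @param coupled_sampling If `TRUE`, one uniform draw per (strain, reaction)
#'   is shared across pipelines, so a more sensitive pipeline's observed
#'   network nests a less sensitive one's (used for monotonicity checks);
#'   default `FALSE` samples pipelines independently.
#' @param rng_seed Master seed; every internal stream is derived from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_phyla = 4L, strains_per_phylum = 5L,
                             n_pathways = 40L, pathway_length = 5L,
                             phylum_core_fraction = 0.35,
                             strain_private_fraction = 0.05,
                             pipelines = default_pipeline_profiles(),
                             host_pathway_count = 6L,
                             host_own_pathway_count = 3L,
                             cross_link_prob = 0.2,
                             reversible_frac = 0.1,
                             coupled_sampling = FALSE,
                             rng_seed = 1L) {
  fracs <- c(phylum_core_fraction, strain_private_fraction,
             cross_link_prob, reversible_frac)
  if (any(fracs < 0 | fracs > 1)) stopf("all fractions must be in [0, 1]")
  if (length(pipelines) < 2L) stopf("need at least 2 pipeline profiles")
  if (any(c(n_phyla, strains_per_phylum, n_pathways, pathway_length,
            host_pathway_count) < 1L))
    stopf("all counts must be >= 1")
  nm <- vapply(pipelines, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stopf("pipeline names must be unique")
  names(pipelines) <- nm
  structure(list(n_phyla = as.integer(n_phyla),
                 strains_per_phylum = as.integer(strains_per_phylum),
                 n_pathways = as.integer(n_pathways),
                 pathway_length = as.integer(pathway_length),
                 phylum_core_fraction = phylum_core_fraction,
                 strain_private_fraction = strain_private_fraction,
                 pipelines = pipelines,
                 host_pathway_count = as.integer(host_pathway_count),
                 host_own_pathway_count = as.integer(host_own_pathway_count),
                 cross_link_prob = cross_link_prob,
                 reversible_frac = reversible_frac,
                 coupled_sampling = isTRUE(coupled_sampling),
                 rng_seed = as.integer(rng_seed)),
            class = "generator_config")
}

#' Generate the reaction universe
#'
#' Pathways are linear compound chains `C_w_0 -> C_w_1 -> ... -> C_w_L`, one
#' reaction per step, with a fraction of reversible steps. A pathway may be
#' cross-linked: its chain then starts at an earlier pathway's terminal
#' compound rather than a fresh initial compound, so running it requires the
#' upstream pathway. Every reaction belongs to exactly one pathway, carries a
#' canonical gene id and a synthetic EC number drawn from a fixed 20-category
#' list.
#'
#' @param config A [generator_config()].
#' @param seed Master seed (defaults to the config's).
#' @return An object of class `ss_universe`: `reactions` (named list),
#'   `pathway_map` (pathway -> reaction ids), `ec_category` (reaction ->
#'   category), `sources`, `terminals` and `cross_linked` per pathway.
#' @export
generate_universe <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "generator_config"))
  W <- config$n_pathways; L <- config$pathway_length
  withr::with_seed(stream_seed(seed, "universe"), {
    reactions <- list()
    pathway_map <- list()
    ec_category <- character()
    sources <- terminals <- character(W)
    cross_linked <- logical(W)
    for (w in seq_len(W)) {
      own_src <- sprintf("C%02d_0", w)
      if (w > 1 && stats::runif(1) < config$cross_link_prob) {
        src <- terminals[sample.int(w - 1L, 1L)]
        cross_linked[w] <- TRUE
      } else {
        src <- own_src
      }
      sources[w] <- src
      prev <- src
      ids <- character(L)
      for (s in seq_len(L)) {
        cpd <- sprintf("C%02d_%d", w, s)
        rid <- sprintf("R%02d_%02d", w, s)
        cat_ <- sample(EC_CATEGORIES, 1L)
        reactions[[rid]] <- reaction(
          rid, prev, cpd,
          reversible = stats::runif(1) < config$reversible_frac,
          genes = paste0("g_", rid),
          ec = sprintf("%s.1.%d", cat_, s))
        ec_category[rid] <- cat_
        ids[s] <- rid
        prev <- cpd
      }
      terminals[w] <- prev
      pathway_map[[sprintf("pw%02d", w)]] <- ids
    }
    structure(list(reactions = reactions, pathway_map = pathway_map,
                   ec_category = ec_category, sources = sources,
                   terminals = terminals, cross_linked = cross_linked),
              class = "ss_universe")
  })
}

#' Generate true strain networks with phylum structure
#'
#' Each phylum owns a core pathway subset (a `phylum_core_fraction` share of
#' all pathways, sampled per phylum) shared by all its strains; each strain
#' additionally carries a private sample of the remaining universe reactions.
#' This makes within-phylum reaction content much more similar than
#' between-phylum content, the structure the downstream ordination and
#' ANOSIM analyses are meant to recover.
#'
#' @inheritParams generate_universe
#' @param universe An `ss_universe`.
#' @return A list with `networks` (named list of `metabolic_network`),
#'   `phylum` (named character: strain -> phylum) and `core_pathways`
#'   (per-phylum pathway indices).
#' @export
generate_strains <- function(universe, config, seed = config$rng_seed) {
  stopifnot(inherits(universe, "ss_universe"))
  W <- config$n_pathways
  all_rxn <- names(universe$reactions)
  n_core <- max(1L, round(config$phylum_core_fraction * W))
  n_priv <- round(config$strain_private_fraction * length(all_rxn))
  withr::with_seed(stream_seed(seed, "strains"), {
    networks <- list(); phylum <- character()
    core_pathways <- list()
    for (p in seq_len(config$n_phyla)) {
      ph <- sprintf("P%d", p)
      core <- sort(sample.int(W, n_core))
      core_pathways[[ph]] <- core
      core_rxn <- unlist(universe$pathway_map[core], use.names = FALSE)
      for (s in seq_len(config$strains_per_phylum)) {
        id <- sprintf("%sS%02d", ph, s)
        priv <- sample(setdiff(all_rxn, core_rxn),
                       min(n_priv, length(all_rxn) - length(core_rxn)))
        ids <- sorted_unique(c(core_rxn, priv))
        networks[[id]] <- metabolic_network(id, universe$reactions[ids])
        phylum[id] <- ph
      }
    }
    list(networks = networks, phylum = phylum,
         core_pathways = core_pathways)
  })
}

make_decoy_pool <- function(profile, real_compounds, seed) {
  withr::with_seed(stream_seed(seed, "pool", profile$name), {
    lapply(seq_len(profile$exclusive_pool_size), function(j) {
      rid <- sprintf("D_%s_%02d", profile$name, j)
      reaction(rid,
               sample(real_compounds, 1L),
               sprintf("X_%s_%02d", profile$name, j),
               reversible = FALSE,
               genes = paste0("g_", rid),
               ec = sprintf("%s.9.%d", sample(EC_CATEGORIES, 1L), j))
    })
  })
}

#' Simulate imperfect pipeline observations of true networks
#'
#' Independently per (strain, pipeline): each true reaction is kept with the
#' pipeline's sensitivity, and a Poisson(`fp_rate`) number of decoy reactions
#' is added from the pipeline's exclusive pool. Decoys attach a fresh,
#' pipeline-private compound to a real compound, so false positives inflate
#' network size and dead-end counts without opening shortcuts to targets.
#' One RNG stream per (strain, pipeline) is derived from the master seed, so
#' results are reproducible and adding a pipeline never perturbs the others.
#' Under `coupled = TRUE` a single uniform per (strain, reaction) is shared
#' across pipelines, making observed networks nested by sensitivity when
#' false positives are off.
#'
#' @param true_networks Named list of true strain networks.
#' @param profiles Named list of [pipeline_profile()]s.
#' @param seed Master seed.
#' @param coupled Use coupled sampling (see above).
#' @return Named list: pipeline -> named list of observed
#'   `metabolic_network`s, with the decoy pools in attribute
#'   `"decoy_pools"`.
#' @export
simulate_pipeline_annotations <- function(true_networks, profiles, seed,
                                          coupled = FALSE) {
  real_cpds <- sorted_unique(unlist(lapply(true_networks, compounds),
                                    use.names = FALSE))
  pools <- lapply(profiles, make_decoy_pool, real_compounds = real_cpds,
                  seed = seed)
  names(pools) <- vapply(profiles, `[[`, character(1), "name")
  coupled_u <- NULL
  if (coupled) {
    coupled_u <- lapply(names(true_networks), function(st) {
      rids <- reaction_ids(true_networks[[st]])
      withr::with_seed(stream_seed(seed, "coupled", st),
                       stats::setNames(stats::runif(length(rids)), rids))
    })
    names(coupled_u) <- names(true_networks)
  }
  observed <- lapply(profiles, function(pr) {
    nets <- lapply(names(true_networks), function(st) {
      tn <- true_networks[[st]]
      rids <- reaction_ids(tn)
      withr::with_seed(stream_seed(seed, "obs", st, pr$name), {
        keep <- if (coupled) coupled_u[[st]][rids] < pr$sensitivity
                else stats::runif(length(rids)) < pr$sensitivity
        k <- min(pr$exclusive_pool_size, stats::rpois(1L, pr$fp_rate))
        decoys <- if (k > 0) sample(pools[[pr$name]], k) else list()
        metabolic_network(st, c(unname(tn$reactions[keep]), decoys),
                          pipeline = pr$name)
      })
    })
    names(nets) <- names(true_networks)
    nets
  })
  names(observed) <- names(pools)
  attr(observed, "decoy_pools") <- pools
  observed
}

#' Generate the host network, medium and planted targets
#'
#' The host consumes the terminal compounds of `host_pathway_count` bacterial
#' pathways it cannot run itself (turning each into a host-internal
#' metabolite), and autonomously carries a few other pathways. The medium
#' (seeds) consists of every pathway's genuinely initial compound (the
#' sources that no universe reaction produces). The planted targets, the
#' consumed terminals plus the corresponding host-internal products, are
#' verified at generation time: none is producible by the host alone, and
#' all are producible when all true strain networks are pooled with the host.
#'
#' @inheritParams generate_strains
#' @param strains Output of [generate_strains()], used to pick target
#'   pathways actually carried by a strain and to verify producibility.
#' @return A list with `host`, `seeds`, `targets`, `target_pathways` and
#'   `host_own_pathways`.
#' @export
generate_host_and_seeds <- function(universe, config, strains,
                                    seed = config$rng_seed) {
  stopifnot(inherits(universe, "ss_universe"))
  W <- config$n_pathways
  carried <- vapply(seq_len(W), function(w) {
    ids <- universe$pathway_map[[w]]
    any(vapply(strains$networks,
               function(nt) all(ids %in% reaction_ids(nt)), logical(1)))
  }, logical(1))
  eligible <- which(!universe$cross_linked & carried)
  if (length(eligible) < config$host_pathway_count)
    stopf("only %d eligible target pathways for host_pathway_count = %d",
          length(eligible), config$host_pathway_count)
  withr::with_seed(stream_seed(seed, "host"), {
    tgt <- sort(resample(eligible, config$host_pathway_count))
    own_pool <- setdiff(which(!universe$cross_linked), tgt)
    own <- sort(resample(own_pool,
                       min(config$host_own_pathway_count, length(own_pool))))
    host_rxns <- c(
      unname(universe$reactions[unlist(universe$pathway_map[own],
                                       use.names = FALSE)]),
      lapply(tgt, function(w)
        reaction(sprintf("H_R%02d", w), universe$terminals[w],
                 sprintf("H_MET%02d", w),
                 genes = sprintf("g_H_R%02d", w)))
    )
    host <- metabolic_network("host", host_rxns, pipeline = NA_character_)
    produced <- unique(unlist(lapply(universe$reactions, `[[`, "products"),
                              use.names = FALSE))
    seeds <- sorted_unique(setdiff(universe$sources, produced))
    targets <- sort(c(universe$terminals[tgt], sprintf("H_MET%02d", tgt)))
    alone <- compute_scope(host, seeds)$producible
    if (any(targets %in% alone))
      stopf("generation-time check failed: host alone produces planted targets")
    av <- added_value(host, unname(strains$networks), seeds)
    if (!all(targets %in% av))
      stopf("generation-time check failed: targets %s not in added value",
            paste(setdiff(targets, av), collapse = ", "))
    list(host = host, seeds = seeds, targets = targets,
         target_pathways = tgt, host_own_pathways = own)
  })
}

#' Generate a complete synthetic study instance
#'
#' Runs the whole generator: universe, phylum-structured true strain
#' networks, host + medium + verified targets, and per-pipeline observed
#' networks. Identical config and seed give identical instances.
#'
#' @param config A [generator_config()].
#' @param seed Master seed (defaults to the config's `rng_seed`).
#' @return An object of class `synthetic_instance` with elements `universe`,
#'   `true_networks`, `phylum`, `observed` (pipeline -> strain -> network),
#'   `host`, `seeds`, `planted` (`targets`, optional `community`, group
#'   labels) and `config`.
#' @export
generate_instance <- function(config = generator_config(),
                              seed = config$rng_seed) {
  universe <- generate_universe(config, seed)
  strains <- generate_strains(universe, config, seed)
  hs <- generate_host_and_seeds(universe, config, strains, seed)
  observed <- simulate_pipeline_annotations(strains$networks,
                                            config$pipelines, seed,
                                            coupled = config$coupled_sampling)
  structure(list(universe = universe,
                 true_networks = strains$networks,
                 phylum = strains$phylum,
                 observed = observed,
                 host = hs$host, seeds = hs$seeds,
                 planted = list(targets = hs$targets, community = NULL,
                                target_pathways = hs$target_pathways,
                                groups = strains$phylum),
                 config = config),
            class = "synthetic_instance")
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf("<synthetic_instance> %d strains in %d phyla, %d pipelines, %d planted targets%s\n",
              length(x$true_networks), x$config$n_phyla,
              length(x$observed), length(x$planted$targets),
              if (is.null(x$planted$community)) ""
              else sprintf(", planted community of %d",
                           length(x$planted$community))))
  invisible(x)
}

#' Plant a unique minimal community of known size
#'
#' Builds a synthetic instance in which exactly `k` designated strains (and
#' no smaller set) cover the planted targets: each designated strain is the
#' exclusive carrier of one indispensable target pathway, which is removed
#' from every other strain. When the total number of strains is at most
#' `verify_max_n`, uniqueness of the optimum is verified by exhaustive
#' enumeration over all strain subsets of size `<= k` before the instance is
#' returned.
#'
#' @param config A [generator_config()]; needs at least `k` eligible target
#'   pathways and `k` strains.
#' @param k Planted minimal community size.
#' @param seed Master seed.
#' @param verify_max_n Exhaustively verify uniqueness when the strain count
#'   does not exceed this (default 12).
#' @return A `synthetic_instance` whose `planted$community` holds the
#'   designated strain ids.
#' @export
plant_minimal_community <- function(config = generator_config(), k,
                                    seed = config$rng_seed,
                                    verify_max_n = 12L) {
  universe <- generate_universe(config, seed)
  strains <- generate_strains(universe, config, seed)
  n <- length(strains$networks)
  if (k > n) stopf("k = %d exceeds the number of strains (%d)", k, n)
  eligible <- which(!universe$cross_linked)
  if (length(eligible) < k + config$host_own_pathway_count)
    stopf("not enough non-cross-linked pathways to plant k = %d", k)
  withr::with_seed(stream_seed(seed, "plant"), {
    tgt <- sort(resample(eligible, k))
    designated <- sort(sample(names(strains$networks), k))
    tgt_rxn_by_pw <- universe$pathway_map[tgt]
    all_tgt_rxn <- unlist(tgt_rxn_by_pw, use.names = FALSE)
    # strip target pathways everywhere, then give pathway i to designated i
    networks <- lapply(strains$networks, function(nt) {
      keep <- setdiff(reaction_ids(nt), all_tgt_rxn)
      metabolic_network(nt$id, universe$reactions[keep])
    })
    for (i in seq_len(k)) {
      st <- designated[i]
      ids <- sorted_unique(c(reaction_ids(networks[[st]]),
                             tgt_rxn_by_pw[[i]]))
      networks[[st]] <- metabolic_network(st, universe$reactions[ids])
    }
    own_pool <- setdiff(eligible, tgt)
    own <- sort(resample(own_pool,
                       min(config$host_own_pathway_count, length(own_pool))))
    host_rxns <- c(
      unname(universe$reactions[unlist(universe$pathway_map[own],
                                       use.names = FALSE)]),
      lapply(tgt, function(w)
        reaction(sprintf("H_R%02d", w), universe$terminals[w],
                 sprintf("H_MET%02d", w),
                 genes = sprintf("g_H_R%02d", w)))
    )
    host <- metabolic_network("host", host_rxns)
    produced <- unique(unlist(lapply(universe$reactions, `[[`, "products"),
                              use.names = FALSE))
    seeds <- sorted_unique(setdiff(universe$sources, produced))
    targets <- sort(c(universe$terminals[tgt], sprintf("H_MET%02d", tgt)))

    orc <- make_cover_oracle(host, networks, seeds, targets)
    des_idx <- match(designated, orc$nm)
    if (!orc$covers(des_idx))
      stopf("planting failed: designated community does not cover targets")
    if (n <= verify_max_n) {
      # exhaustive uniqueness proof over all subsets of size <= k; subsets
      # that cannot emit every required target are refuted without a fixpoint
      for (size in seq_len(k)) {
        combos <- utils::combn(n, size)
        for (ci in seq_len(ncol(combos))) {
          sel <- combos[, ci]
          if (!orc$emits_ok(sel)) next
          if (!orc$covers(sel)) next
          if (size < k)
            stopf("planting failed: sub-optimal cover of size %d exists", size)
          if (!setequal(orc$nm[sel], designated))
            stopf("planting failed: optimum is not unique")
        }
      }
    }
    observed <- simulate_pipeline_annotations(networks, config$pipelines,
                                              seed,
                                              coupled = config$coupled_sampling)
    structure(list(universe = universe, true_networks = networks,
                   phylum = strains$phylum, observed = observed,
                   host = host, seeds = seeds,
                   planted = list(targets = targets,
                                  community = designated,
                                  target_pathways = tgt,
                                  groups = strains$phylum),
                   config = config),
              class = "synthetic_instance")
  })
}
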