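test_that("the universe has one reaction per chain step, one pathway each", {
  cfg <- generator_config(n_pathways = 3, pathway_length = 4, rng_seed = 3)
  uni <- generate_universe(cfg)
  expect_length(uni$reactions, 12)
  expect_length(uni$pathway_map, 3)
  expect_true(all(lengths(uni$pathway_map) == 4))
  expect_identical(sort(unlist(uni$pathway_map, use.names = FALSE)),
                   sort(names(uni$reactions)))   # exactly one pathway each
  expect_true(all(names(uni$ec_category) == names(uni$reactions)))
})

test_that("seeding a pathway's source makes its whole chain producible", {
  cfg <- generator_config(n_pathways = 8, pathway_length = 5, rng_seed = 9)
  uni <- generate_universe(cfg)
  for (w in seq_along(uni$pathway_map)) {
    net <- metabolic_network("pw", uni$reactions[uni$pathway_map[[w]]])
    sc <- compute_scope(net, uni$sources[w])$producible
    expect_true(all(compounds(net) %in% sc))
  }
})

test_that("degenerate strain settings collapse phyla to identical networks", {
  cfg <- generator_config(n_phyla = 2, strains_per_phylum = 3,
                          n_pathways = 10, pathway_length = 3,
                          phylum_core_fraction = 1,
                          strain_private_fraction = 0, rng_seed = 4)
  uni <- generate_universe(cfg)
  st <- generate_strains(uni, cfg)
  for (ph in unique(st$phylum)) {
    ids <- names(st$phylum)[st$phylum == ph]
    sets <- lapply(st$networks[ids], function(n) names(n$reactions))
    expect_true(all(vapply(sets, identical, logical(1), y = sets[[1]])))
  }
})

test_that("within-phylum repertoires are more similar than between", {
  mean_within <- mean_between <- numeric(0)
  for (rep in 1:5) {
    cfg <- generator_config(rng_seed = 600 + rep)
    st <- generate_strains(generate_universe(cfg), cfg)
    pm <- reaction_presence_matrix(unname(st$networks))
    d <- bray_curtis_matrix(pm)
    ph <- st$phylum[rownames(pm)]
    same <- outer(ph, ph, "==")[lower.tri(d)]
    dv <- d[lower.tri(d)]
    mean_within <- c(mean_within, mean(dv[same]))
    mean_between <- c(mean_between, mean(dv[!same]))
  }
  expect_true(all(mean_within < mean_between))
})

test_that("noiseless observation reproduces the true networks exactly", {
  pls <- Map(pipeline_profile, c("a1", "a2", "a3"),
             sensitivity = 1, fp_rate = 0)
  cfg <- small_test_config(seed = 21, pipelines = pls)
  inst <- generate_instance(cfg)
  for (p in names(inst$observed))
    for (st in names(inst$true_networks))
      expect_identical(names(inst$observed[[p]][[st]]$reactions),
                       names(inst$true_networks[[st]]$reactions))
  # cross-pipeline dissimilarity of the same strain collapses to 0
  pm <- reaction_presence_matrix(flatten_observed(inst))
  d <- bray_curtis_matrix(pm)
  idf <- attr(pm, "instances")
  for (st in names(inst$true_networks)) {
    rows <- which(idf$strain == st)
    expect_true(all(d[rows, rows] == 0))
  }
})

test_that("observed networks stay inside true union decoy-pool reactions", {
  cfg <- small_test_config(seed = 31)
  inst <- generate_instance(cfg)
  pools <- attr(inst$observed, "decoy_pools")
  for (p in names(inst$observed)) {
    pool_ids <- vapply(pools[[p]], `[[`, character(1), "id")
    for (st in names(inst$true_networks)) {
      obs <- names(inst$observed[[p]][[st]]$reactions)
      allowed <- c(names(inst$true_networks[[st]]$reactions), pool_ids)
      expect_true(all(obs %in% allowed))
    }
  }
})

test_that("decoys surface as pipeline-exclusive UpSet singletons", {
  cfg <- small_test_config(seed = 41)
  inst <- generate_instance(cfg)
  sets <- lapply(inst$observed, function(nets)
    unique(unlist(lapply(nets, function(n) names(n$reactions)))))
  spec <- pipeline_specific_reactions(sets)
  for (p in names(sets)) {
    observed_decoys <- grep("^D_", sets[[p]], value = TRUE)
    expect_true(all(observed_decoys %in% spec[[p]]))
  }
})

test_that("coupled sampling nests networks by sensitivity when fp = 0", {
  pls <- Map(pipeline_profile, c("lo", "hi"),
             sensitivity = c(0.7, 0.95), fp_rate = 0)
  cfg <- small_test_config(seed = 51, pipelines = pls,
                           coupled_sampling = TRUE)
  inst <- generate_instance(cfg)
  for (st in names(inst$true_networks)) {
    lo <- names(inst$observed$lo[[st]]$reactions)
    hi <- names(inst$observed$hi[[st]]$reactions)
    expect_true(all(lo %in% hi))
    sc_lo <- compute_scope(inst$observed$lo[[st]], inst$seeds)$producible
    sc_hi <- compute_scope(inst$observed$hi[[st]], inst$seeds)$producible
    expect_true(all(sc_lo %in% sc_hi))
  }
})

test_that("planted targets hinge on symbiotic cooperation", {
  cfg <- generator_config(rng_seed = 61)
  inst <- generate_instance(cfg)
  alone <- compute_scope(inst$host, inst$seeds)$producible
  expect_length(intersect(inst$planted$targets, alone), 0)
  av <- added_value(inst$host, unname(inst$true_networks), inst$seeds)
  expect_true(all(inst$planted$targets %in% av))
})

test_that("removing a target pathway's only phylum removes the target", {
  cfg <- generator_config(strain_private_fraction = 0, rng_seed = 71)
  uni <- generate_universe(cfg)
  st <- generate_strains(uni, cfg)
  hs <- generate_host_and_seeds(uni, cfg, st)
  carriers <- lapply(hs$target_pathways, function(w) {
    ids <- uni$pathway_map[[w]]
    unique(st$phylum[vapply(st$networks, function(nt)
      all(ids %in% names(nt$reactions)), logical(1))])
  })
  solo <- which(lengths(carriers) == 1)
  skip_if(length(solo) == 0, "no single-phylum target pathway in this draw")
  w <- hs$target_pathways[solo[1]]
  ph <- carriers[[solo[1]]]
  keep <- st$networks[st$phylum != ph]
  av <- added_value(hs$host, unname(keep), hs$seeds)
  expect_false(uni$terminals[w] %in% av)
})

test_that("planted minimal communities are unique and recoverable", {
  cfg <- generator_config(n_phyla = 4, strains_per_phylum = 3,
                          n_pathways = 25, pathway_length = 4,
                          host_pathway_count = 6, rng_seed = 81)
  inst <- plant_minimal_community(cfg, k = 3, seed = 81)
  expect_length(inst$planted$community, 3)
  # independent exhaustive confirmation via the naive oracle
  want <- oracle_mincom(inst$host, inst$true_networks, inst$seeds,
                        inst$planted$targets)
  expect_identical(want$min_size, 3L)
  expect_length(want$communities, 1)
  expect_identical(want$communities[[1]], inst$planted$community)
})

test_that("identical config and seed give byte-identical SBML output", {
  cfg <- small_test_config(seed = 91)
  a <- generate_instance(cfg)
  b <- generate_instance(cfg)
  f1 <- withr::local_tempfile(fileext = ".sbml")
  f2 <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(a$observed[[1]][[1]], f1)
  write_sbml(b$observed[[1]][[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(names(a$true_networks), names(b$true_networks))
  expect_identical(a$planted$targets, b$planted$targets)
})
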