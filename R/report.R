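ec_category_of <- function(rxn) {
  if (length(rxn$ec) == 0L) return(NA_character_)
  sub("^([0-9]+\\.[0-9n-]+).*", "\\1", rxn$ec[1])
}

pooled_reaction_sets <- function(collections) {
  lapply(collections, function(nets)
    sorted_unique(unlist(lapply(nets, reaction_ids), use.names = FALSE)))
}

#' Run the full cross-pipeline robustness analysis
#'
#' Orchestrates the whole analysis on a synthetic instance: per pipeline
#' (plus one extra collection merging each strain's networks across all
#' pipelines) it filters to gene-supported reactions, computes the host's
#' added-value target set, enumerates all minimum-size communities and their
#' union, and summarizes network-quality metrics; across pipelines it builds
#' the reaction presence/absence matrix, Bray-Curtis dissimilarities, ANOSIM
#' for phylum and for pipeline, an NMDS embedding, exclusive-intersection
#' counts, pipeline-specific reactions with pathway specificity, EC-category
#' over-representation, per-strain deviations from the cross-pipeline mean
#' with ANOVA/Tukey, and the interchangeability matrix (the first witness
#' community of each pipeline scored against every other pipeline's
#' networks).
#'
#' @param instance A `synthetic_instance` from [generate_instance()] (>= 2
#'   pipelines).
#' @param permutations ANOSIM permutations (default 999).
#' @param seed Integer seed for the permutation and NMDS streams.
#' @param cap Enumeration cap passed to [enumerate_minimal_communities()].
#' @param nmds_starts Random starts for the NMDS embedding.
#' @return An object of class `report_bundle`; see
#'   [write_report_bundle()] for its on-disk form.
#' @export
run_full_analysis <- function(instance, permutations = 999, seed = 1L,
                              cap = 10000L, nmds_starts = 10L) {
  stopifnot(inherits(instance, "synthetic_instance"))
  pipelines <- names(instance$observed)
  if (length(pipelines) < 2L) stopf("need at least 2 pipelines")
  host <- filter_gene_associated(instance$host)
  seeds <- instance$seeds
  obs_f <- lapply(instance$observed, function(nets)
    lapply(nets, filter_gene_associated))
  strains <- names(instance$true_networks)
  merged <- lapply(strains, function(st)
    merge_networks(lapply(obs_f, `[[`, st), id = st, pipeline = "merged"))
  names(merged) <- strains
  collections <- c(obs_f, list(merged = merged))

  per_pipeline <- lapply(names(collections), function(p) {
    nets <- collections[[p]]
    targets <- added_value(host, unname(nets), seeds)
    cr <- enumerate_minimal_communities(host, nets, seeds, targets, cap = cap)
    qual <- lapply(nets, network_quality)
    list(pipeline = p,
         targets = targets,
         scope_size = length(targets),
         community = cr,
         quality = data.frame(
           strain = names(nets),
           pct_deadend = vapply(qual, `[[`, numeric(1), "pct_deadend"),
           pct_orphan = vapply(qual, `[[`, numeric(1), "pct_orphan"),
           scc_ratio = vapply(qual, `[[`, numeric(1), "scc_ratio"),
           n_deadend = vapply(qual, `[[`, integer(1), "n_deadend"),
           n_orphan = vapply(qual, `[[`, integer(1), "n_orphan"),
           n_compounds = vapply(nets, function(x) length(compounds(x)),
                                integer(1)),
           row.names = NULL, stringsAsFactors = FALSE))
  })
  names(per_pipeline) <- names(collections)

  summary_df <- data.frame(
    pipeline = names(collections),
    scope_size = vapply(per_pipeline, `[[`, integer(1), "scope_size"),
    min_community_size = vapply(per_pipeline,
                                function(x) x$community$min_size, integer(1)),
    n_optimal_communities = vapply(per_pipeline,
                                   function(x) length(x$community$communities),
                                   integer(1)),
    union_size = vapply(per_pipeline,
                        function(x) length(x$community$union), integer(1)),
    mean_pct_deadend = vapply(per_pipeline,
                              function(x) mean(x$quality$pct_deadend),
                              numeric(1)),
    mean_pct_orphan = vapply(per_pipeline,
                             function(x) mean(x$quality$pct_orphan),
                             numeric(1)),
    mean_scc_ratio = vapply(per_pipeline,
                            function(x) mean(x$quality$scc_ratio),
                            numeric(1)),
    pooled_pct_deadend = vapply(per_pipeline, function(x)
      100 * sum(x$quality$n_deadend) / sum(x$quality$n_compounds),
      numeric(1)),
    pooled_pct_orphan = vapply(per_pipeline, function(x)
      100 * sum(x$quality$n_orphan) / sum(x$quality$n_compounds),
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  membership <- vapply(per_pipeline, function(x)
    strains %in% x$community$union, logical(length(strains)))
  rownames(membership) <- strains

  flat <- unlist(unname(lapply(pipelines, function(p) obs_f[[p]])),
                 recursive = FALSE)
  presence <- reaction_presence_matrix(flat)
  inst_df <- attr(presence, "instances")
  d <- bray_curtis_matrix(presence)
  anosim_phylum <- anosim(d, instance$phylum[inst_df$strain],
                          permutations = permutations,
                          seed = stream_seed(seed, "anosim", "phylum"),
                          group_factor = "phylum")
  anosim_pipeline <- anosim(d, inst_df$pipeline,
                            permutations = permutations,
                            seed = stream_seed(seed, "anosim", "pipeline"),
                            group_factor = "pipeline")
  embedding <- nmds(d, k = 2, n_starts = nmds_starts,
                    seed = stream_seed(seed, "nmds"))

  sets <- pooled_reaction_sets(obs_f)
  upset <- upset_exclusive_counts(sets)
  specific <- pipeline_specific_reactions(sets)
  pw_spec <- lapply(pipelines, function(p)
    pathway_specificity(specific[[p]], instance$universe$pathway_map))
  names(pw_spec) <- pipelines

  cats <- sorted_unique(stats::na.omit(unlist(
    lapply(flat, function(nt) vapply(nt$reactions, ec_category_of, "")),
    use.names = FALSE)))
  ec_counts <- vapply(pipelines, function(p) {
    tab <- table(factor(unlist(lapply(obs_f[[p]], function(nt)
      vapply(nt$reactions, ec_category_of, "")), use.names = FALSE),
      levels = cats))
    as.integer(tab)
  }, integer(length(cats)))
  rownames(ec_counts) <- cats
  enrichment <- ec_overrepresentation(ec_counts)

  rxn_counts <- vapply(pipelines, function(p)
    vapply(obs_f[[p]], function(nt) length(nt$reactions), integer(1)),
    integer(length(strains)))
  rownames(rxn_counts) <- strains
  deviations <- deviation_from_mean(rxn_counts)
  tukey <- anova_tukey(rxn_counts)

  inter <- matrix(NA_integer_, length(collections), length(collections),
                  dimnames = list(names(collections), names(collections)))
  for (p in names(collections)) {
    comm <- per_pipeline[[p]]$community$communities[[1]]
    for (q in names(collections))
      inter[p, q] <- cross_pipeline_scope(comm, host, collections[[q]],
                                          seeds)
  }

  structure(
    list(summary = summary_df,
         per_pipeline = per_pipeline,
         union_membership = membership,
         presence = presence,
         dist = d,
         anosim = list(phylum = anosim_phylum, pipeline = anosim_pipeline),
         nmds = embedding,
         upset = upset,
         specific_reactions = specific,
         pathway_specificity = pw_spec,
         ec_counts = ec_counts,
         enrichment = enrichment,
         reaction_counts = rxn_counts,
         deviations = deviations,
         tukey = tukey,
         interchangeability = inter,
         manifest = list(seed = seed, permutations = permutations,
                         cap = cap, nmds_starts = nmds_starts,
                         pipelines = pipelines,
                         n_strains = length(strains),
                         rng_seed = instance$config$rng_seed,
                         package_version =
                           as.character(utils::packageVersion("symbioscope")))),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  print(x$summary[, c("pipeline", "scope_size", "min_community_size",
                      "union_size")], row.names = FALSE)
  cat(sprintf("ANOSIM: phylum R = %.3f (p = %.4g), pipeline R = %.3f (p = %.4g)\n",
              x$anosim$phylum$R, x$anosim$phylum$p_value,
              x$anosim$pipeline$R, x$anosim$pipeline$p_value))
  invisible(x)
}

#' Write a report bundle to a directory of TSV/JSON files
#'
#' Emits `summary.tsv`, `table2_analog.tsv` (strain-by-pipeline union
#' membership), `quality.tsv`, `fig1_deviations.tsv`, `fig2_nmds.tsv`,
#' `fig3_upset.tsv`, `interchangeability.tsv`, `enrichment.tsv`,
#' `distmatrix.tsv`, `specific_reactions.tsv`, `anosim.json` and
#' `manifest.json`. Reruns with the same instance and seed are byte
#' identical.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(bundle$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$union_membership * 1L,
                     file.path(dir, "table2_analog.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  qual <- do.call(rbind, lapply(names(bundle$per_pipeline), function(p)
    cbind(pipeline = p, bundle$per_pipeline[[p]]$quality)))
  utils::write.table(qual, file.path(dir, "quality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(round(bundle$deviations, 6),
                     file.path(dir, "fig1_deviations.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(round(bundle$nmds$coords, 6),
                     file.path(dir, "fig2_nmds.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(data.frame(combo = names(bundle$upset),
                                count = as.integer(bundle$upset)),
                     file.path(dir, "fig3_upset.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$interchangeability,
                     file.path(dir, "interchangeability.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(bundle$enrichment, file.path(dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(bundle$dist, 8),
                     file.path(dir, "distmatrix.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  spec_df <- do.call(rbind, lapply(names(bundle$specific_reactions),
    function(p) {
      ids <- bundle$specific_reactions[[p]]
      if (length(ids) == 0L) return(NULL)
      data.frame(pipeline = p, reaction_id = ids, stringsAsFactors = FALSE)
    }))
  if (is.null(spec_df))
    spec_df <- data.frame(pipeline = character(), reaction_id = character())
  utils::write.table(spec_df, file.path(dir, "specific_reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(phylum = list(R = bundle$anosim$phylum$R,
                       p_value = bundle$anosim$phylum$p_value,
                       n_permutations = bundle$anosim$phylum$n_permutations),
         pipeline = list(R = bundle$anosim$pipeline$R,
                         p_value = bundle$anosim$pipeline$p_value,
                         n_permutations =
                           bundle$anosim$pipeline$n_permutations)),
    file.path(dir, "anosim.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
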