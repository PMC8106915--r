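membership_signatures <- function(sets) {
  if (length(sets) < 2L) stopf("need at least 2 pipelines")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("'sets' must be a named list (pipeline labels)")
  universe <- sorted_unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L)
    memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, names(sets)))
  list(universe = universe, memb = memb)
}

#' Exclusive intersection counts (UpSet cells)
#'
#' For every nonempty subset S of pipelines, the number of reactions present
#' in exactly the pipelines of S (where "present in a pipeline" means found
#' in at least one of that pipeline's networks, i.e. `sets` holds the pooled
#' reaction set per pipeline). The cells partition the union of all sets.
#'
#' @param sets Named list (>= 2 entries) of reaction-id character vectors,
#'   one per pipeline.
#' @return Named integer vector over all nonempty pipeline subsets, names
#'   joined with `"&"` in the input pipeline order, ordered by subset size.
#' @export
upset_exclusive_counts <- function(sets) {
  ms <- membership_signatures(sets)
  nm <- names(sets); P <- length(sets)
  sig <- apply(ms$memb, 1, function(z) paste(nm[z], collapse = "&"))
  tab <- table(sig)
  combos <- unlist(lapply(seq_len(P), function(s)
    utils::combn(nm, s, paste, collapse = "&")), use.names = FALSE)
  counts <- integer(length(combos))
  names(counts) <- combos
  hit <- intersect(names(tab), combos)
  counts[hit] <- as.integer(tab[hit])
  counts
}

#' Reactions exclusive to one pipeline
#'
#' The singleton cells of [upset_exclusive_counts()] as id sets: for each
#' pipeline, the reactions found under it and no other pipeline.
#'
#' @inheritParams upset_exclusive_counts
#' @return Named list (one entry per pipeline) of sorted reaction-id vectors.
#' @export
pipeline_specific_reactions <- function(sets) {
  ms <- membership_signatures(sets)
  only <- rowSums(ms$memb) == 1L
  out <- lapply(names(sets), function(p)
    sort(ms$universe[only & ms$memb[, p]]))
  names(out) <- names(sets)
  out
}

#' Pathway specificity of a reaction set
#'
#' For each pathway, the fraction of its reactions belonging to a given
#' (typically pipeline-specific) reaction set; pathways with a fraction above
#' the threshold are flagged as dominated by that set.
#'
#' @param specific Character vector of reaction ids.
#' @param pathway_map Named list mapping pathway id to its (nonempty)
#'   reaction-id set.
#' @param threshold Flagging threshold on the fraction (default 0.5).
#' @return A `data.frame` with columns `pathway`, `n_specific`, `n_total`,
#'   `fraction`, `flagged`, sorted by decreasing fraction.
#' @export
pathway_specificity <- function(specific, pathway_map, threshold = 0.5) {
  if (length(pathway_map) == 0L)
    return(data.frame(pathway = character(), n_specific = integer(),
                      n_total = integer(), fraction = numeric(),
                      flagged = logical()))
  sizes <- lengths(pathway_map)
  if (any(sizes == 0L)) stopf("pathway_map contains empty pathway(s)")
  n_spec <- vapply(pathway_map, function(rs)
    length(intersect(specific, rs)), integer(1))
  out <- data.frame(pathway = names(pathway_map),
                    n_specific = n_spec, n_total = as.integer(sizes),
                    fraction = n_spec / sizes,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$flagged <- out$fraction > threshold
  out[order(-out$fraction, out$pathway), , drop = FALSE]
}

#' EC-category over-representation across pipelines
#'
#' Tests, per EC category, whether one pipeline predicted more entries than
#' expected if all pipelines were equally likely to contribute: with
#' `N_c` the category's row total over the `P` pipelines, the raw p-value is
#' the one-sided exact binomial tail `P(X >= n) , X ~ Binomial(N_c, 1/P)`,
#' Bonferroni-adjusted over all (category, pipeline) pairs tested. The
#' percentage over-representation compares the pipeline's count to the mean
#' of the other pipelines; it is `Inf` when the category was predicted by
#' this pipeline only.
#'
#' @param counts Nonnegative integer matrix, EC categories in rows (named),
#'   pipelines in columns (named, >= 2). All-zero categories are skipped.
#' @return A `data.frame` of class `enrichment_table` with columns
#'   `pipeline`, `ec_category`, `observed`, `pct_over`, `p_raw`,
#'   `p_adjusted`, sorted by adjusted p-value.
#' @export
ec_overrepresentation <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stopf("need counts for at least 2 pipelines")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("'counts' must be nonnegative integers")
  P <- ncol(counts)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  m <- nrow(counts) * P
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    N <- sum(counts[i, ])
    do.call(rbind, lapply(seq_len(P), function(p) {
      n <- counts[i, p]
      other_mean <- mean(counts[i, -p])
      pct <- if (other_mean == 0) {
        if (n > 0) Inf else NA_real_
      } else 100 * (n / other_mean - 1)
      data.frame(pipeline = colnames(counts)[p],
                 ec_category = rownames(counts)[i],
                 observed = as.integer(n),
                 pct_over = pct,
                 p_raw = stats::pbinom(n - 1, N, 1 / P, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }))
  rows$p_adjusted <- pmin(1, rows$p_raw * m)
  rows <- rows[order(rows$p_adjusted, rows$pipeline, rows$ec_category), ,
               drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("enrichment_table", "data.frame")
  rows
}

#' Per-genome deviation from the cross-pipeline mean
#'
#' For each genome (row) and pipeline (column),
#' `100 * (x - mean_over_pipelines) / mean_over_pipelines`. Genomes whose
#' cross-pipeline mean is zero cannot be normalized; they are dropped with a
#' warning and recorded in the `"excluded"` attribute.
#'
#' @param values Numeric genomes-by-pipelines matrix, every genome measured
#'   under every pipeline.
#' @return Matrix of percent deviations (rows sum to ~0 per genome).
#' @export
deviation_from_mean <- function(values) {
  values <- as.matrix(values)
  rm_ <- rowMeans(values)
  bad <- !is.finite(rm_) | rm_ == 0
  if (any(bad)) {
    warning(sprintf("%d genome(s) with zero cross-pipeline mean excluded",
                    sum(bad)), call. = FALSE)
  }
  out <- 100 * sweep(values[!bad, , drop = FALSE], 1, rm_[!bad], "-") /
    rm_[!bad]
  attr(out, "excluded") <- rownames(values)[bad]
  out
}

#' One-way ANOVA with Tukey HSD across pipelines
#'
#' Treats each genome as a replicate of each pipeline and asks whether the
#' pipelines differ in the metric at hand, with Tukey's honestly significant
#' difference test for the pairwise contrasts.
#'
#' @inheritParams deviation_from_mean
#' @return A list with `anova_p` (the F-test p-value) and `tukey`, a
#'   `data.frame` of pairwise comparisons with adjusted p-values.
#' @export
anova_tukey <- function(values) {
  values <- as.matrix(values)
  long <- data.frame(
    value = as.vector(values),
    pipeline = factor(rep(colnames(values), each = nrow(values))))
  fit <- stats::aov(value ~ pipeline, data = long)
  tk <- stats::TukeyHSD(fit)$pipeline
  list(anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adjusted = tk[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE))
}
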