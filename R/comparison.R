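#' Bray-Curtis dissimilarity on presence/absence rows
#'
#' For boolean repertoires this is the Sorensen dissimilarity
#' `1 - 2|A n B| / (|A| + |B|)`: 0 for identical nonempty rows, 1 for
#' disjoint ones, and defined as 0 when both rows are empty.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return A dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b))
    stopf("presence rows differ in length (%d vs %d)", length(a), length(b))
  a <- as.logical(a); b <- as.logical(b)
  den <- sum(a) + sum(b)
  if (den == 0L) return(0)
  1 - 2 * sum(a & b) / den
}

#' Bray-Curtis dissimilarity matrix of a presence matrix
#'
#' @param presence Logical instances-by-reactions matrix, e.g. from
#'   [reaction_presence_matrix()].
#' @return A symmetric numeric matrix of dissimilarities in `[0, 1]` with the
#'   instance labels as dimnames.
#' @export
bray_curtis_matrix <- function(presence) {
  a <- matrix(as.numeric(presence), nrow(presence), ncol(presence))
  inter <- tcrossprod(a)
  sizes <- rowSums(a)
  den <- outer(sizes, sizes, "+")
  d <- 1 - 2 * inter / den
  d[den == 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(presence), rownames(presence))
  d
}

multiset_permutations <- function(x) {
  out <- list()
  recurse <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in unique(remaining)) {
      idx <- which(remaining == v)[1]
      recurse(c(prefix, v), remaining[-idx])
    }
  }
  recurse(x[0], x)
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. All `n(n-1)/2` dissimilarities are
#' ranked with mid-ranks for ties and
#' `R = (mean between-group rank - mean within-group rank) / (M/2)`,
#' `M = n(n-1)/2` (Clarke's statistic, in `[-1, 1]`). Significance is
#' assessed by permuting group labels; the reported p-value is
#' `(1 + #(permuted R >= observed R)) / (1 + permutations)`, so p = 0 is
#' never reported. With `exact = TRUE` all distinct label arrangements are
#' enumerated instead and the p-value is the exact proportion (including the
#' identity) with `R >= observed`.
#'
#' @param d Symmetric dissimilarity matrix or `dist` object.
#' @param groups Group label per instance; at least 2 groups, each of size
#'   at least 2.
#' @param permutations Number of random label permutations (default 9999).
#' @param seed Optional integer seed making the permutation stream
#'   reproducible.
#' @param exact Enumerate all distinct label arrangements (only sensible for
#'   small n).
#' @return An object of class `anosim_result` with `R`, `p_value`,
#'   `n_permutations` and `group_factor`.
#' @export
anosim <- function(d, groups, permutations = 9999, seed = NULL,
                   exact = FALSE, group_factor = deparse(substitute(groups))) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n)
    stopf("'groups' must have one label per instance (%d vs %d)",
          length(groups), n)
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("ANOSIM needs at least 2 groups")
  if (any(sizes < 2L))
    stopf("every group needs >= 2 instances (offending: %s)",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  lt <- lower.tri(dm)
  pi_ <- row(dm)[lt]; pj <- col(dm)[lt]
  r <- rank(dm[lt])
  M <- n * (n - 1) / 2
  R_of <- function(g) {
    w <- g[pi_] == g[pj]
    (mean(r[!w]) - mean(r[w])) / (M / 2)
  }
  obs <- R_of(groups)
  eps <- 1e-12
  if (exact) {
    arrangements <- multiset_permutations(groups)
    allR <- vapply(arrangements, R_of, numeric(1))
    p <- mean(allR >= obs - eps)
    nperm <- length(arrangements)
  } else {
    permute_once <- function() R_of(sample(groups))
    permR <- if (is.null(seed)) {
      replicate(permutations, permute_once())
    } else {
      withr::with_seed(seed, replicate(permutations, permute_once()))
    }
    p <- (1 + sum(permR >= obs - eps)) / (1 + permutations)
    nperm <- permutations
  }
  structure(list(R = obs, p_value = p, n_permutations = nperm,
                 group_factor = group_factor),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<anosim> %s: R = %.3f, p = %.4g (%d permutations)\n",
              x$group_factor, x$R, x$p_value, x$n_permutations))
  invisible(x)
}
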