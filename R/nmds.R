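#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimizing Kruskal's
#' stress-1, `sqrt(sum((d_ij - dhat_ij)^2) / sum(d_ij^2))`, where `dhat` is
#' the isotonic (monotone) regression of the configuration distances on the
#' dissimilarity order. Each start alternates an isotonic fit with a Guttman
#' (stress-majorization) configuration update, guarded by step halving so the
#' recorded stress trace is non-increasing; the best of `n_starts`
#' initializations is returned (a classical-scaling start followed by random
#' starts). The embedding is centred and rotated to its principal axes;
#' rigid rotations and translations leave stress unchanged.
#'
#' @param d Symmetric dissimilarity matrix or `dist` object; must not be all
#'   zero, and needs at least `k + 1` points.
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of initial configurations (default 20).
#' @param max_iter Maximum iterations per start (default 300).
#' @param tol Relative stress-improvement threshold declaring convergence
#'   (default 1e-6).
#' @param seed Optional integer seed; given the same seed the result is
#'   deterministic.
#' @return An object of class `nmds_result`: `coords` (n x k matrix),
#'   `stress`, `stress_trace` (per accepted iteration, non-increasing),
#'   `converged`, `seed`, `n_starts`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 300, tol = 1e-6,
                 seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < k + 1) stopf("NMDS needs at least k + 1 = %d points", k + 1)
  lt <- lower.tri(dm)
  dv <- dm[lt]
  if (all(dv == 0)) stopf("degenerate input: all dissimilarities are zero")
  ord <- order(dv)

  stress_and_dhat <- function(D) {
    fit <- stats::isoreg(D[ord])$yf
    dhat <- numeric(length(D)); dhat[ord] <- fit
    den <- sum(D^2)
    s <- if (den == 0) Inf else sqrt(sum((D - dhat)^2) / den)
    list(stress = s, dhat = dhat)
  }

  run_start <- function(X) {
    D <- as.vector(stats::dist(X))
    sd_ <- stress_and_dhat(D)
    s <- sd_$stress; dhat <- sd_$dhat
    trace <- s
    converged <- FALSE
    dh_m <- matrix(0, n, n); dm_tmp <- matrix(0, n, n)
    for (iter in seq_len(max_iter)) {
      # Guttman transform toward the current monotone targets
      dh_m[lt] <- dhat; dh_m <- dh_m + t(dh_m)
      dm_tmp[lt] <- D; dm_tmp <- dm_tmp + t(dm_tmp)
      ratio <- ifelse(dm_tmp > 0, dh_m / dm_tmp, 0)
      B <- -ratio; diag(B) <- rowSums(ratio)
      Xup <- B %*% X / n
      step <- 1; accepted <- FALSE
      for (h in 1:8) {
        Xc <- X + step * (Xup - X)
        Dc <- as.vector(stats::dist(Xc))
        sdc <- stress_and_dhat(Dc)
        if (sdc$stress <= s + 1e-15) { accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) break
      improve <- s - sdc$stress
      X <- Xc; D <- Dc; s <- sdc$stress; dhat <- sdc$dhat
      trace <- c(trace, s)
      dh_m[] <- 0; dm_tmp[] <- 0
      if (improve <= tol * max(s, 1e-12)) { converged <- TRUE; break }
      if (s < 1e-12) { converged <- TRUE; break }
    }
    list(X = X, stress = s, trace = trace, converged = converged)
  }

  do_fit <- function() {
    starts <- vector("list", n_starts)
    cmd <- tryCatch(stats::cmdscale(dm, k = k), error = function(e) NULL)
    if (!is.null(cmd) && ncol(cmd) > 0) {
      if (ncol(cmd) < k)
        cmd <- cbind(cmd, matrix(0, n, k - ncol(cmd)))
      starts[[1]] <- cmd
    } else {
      starts[[1]] <- matrix(stats::rnorm(n * k, sd = stats::median(dv)), n, k)
    }
    if (n_starts > 1)
      for (i in 2:n_starts)
        starts[[i]] <- matrix(stats::rnorm(n * k, sd = stats::median(dv)),
                              n, k)
    best <- NULL
    for (X0 in starts) {
      res <- run_start(X0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    best
  }
  best <- if (is.null(seed)) do_fit() else withr::with_seed(seed, do_fit())

  X <- scale(best$X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  X <- X %*% sv$v
  flip <- apply(X, 2, function(col) {
    i <- which.max(abs(col)); if (col[i] < 0) -1 else 1
  })
  X <- sweep(X, 2, flip, "*")
  rownames(X) <- rownames(dm)
  colnames(X) <- paste0("NMDS", seq_len(k))
  structure(list(coords = X, stress = best$stress,
                 stress_trace = best$trace, converged = best$converged,
                 seed = seed, n_starts = n_starts, k = k),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds> k = %d, stress = %.5f, converged: %s (%d starts)\n",
              x$k, x$stress, x$converged, x$n_starts))
  invisible(x)
}
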