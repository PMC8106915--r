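test_that("Bray-Curtis closed form behaves at the boundary cases", {
  expect_equal(bray_curtis(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(bray_curtis(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # A = {r1,r2,r3}, B = {r2,r3,r4}: 1 - 4/6
  expect_equal(bray_curtis(c(1, 1, 1, 0), c(0, 1, 1, 1)), 1 / 3)
  expect_equal(bray_curtis(logical(4), logical(4)), 0)
  expect_error(bray_curtis(c(1, 0), c(1, 0, 1)), "length")
})

test_that("Bray-Curtis matrix agrees with vegan's binary implementation", {
  withr::local_seed(88)
  pm <- matrix(runif(20 * 30) < 0.4, 20, 30,
               dimnames = list(sprintf("i%02d", 1:20), NULL))
  d <- bray_curtis_matrix(pm)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  dv <- vegan::vegdist(pm * 1, method = "bray", binary = TRUE)
  expect_equal(d[lower.tri(d)], as.vector(dv), tolerance = 1e-12)
})

test_that("ANOSIM reaches R = 1 under complete group separation", {
  n <- 8
  d <- matrix(0.9, n, n)
  d[1:4, 1:4] <- 0.1; d[5:8, 5:8] <- 0.1
  diag(d) <- 0
  res <- anosim(d, rep(c("g1", "g2"), each = 4), permutations = 199,
                seed = 1)
  expect_equal(res$R, 1)
  expect_lte(res$p_value, 0.05)
})

test_that("exact ANOSIM matches full permutation enumeration", {
  withr::local_seed(6)
  d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  groups <- rep(c("a", "b"), each = 3)
  got <- anosim(d, groups, exact = TRUE)
  want <- oracle_anosim_exact(d, groups)
  expect_equal(got$R, want$R, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
})

test_that("ANOSIM statistic matches vegan on a fixed dataset", {
  withr::local_seed(9)
  pm <- matrix(runif(16 * 25) < 0.5, 16, 25)
  d <- bray_curtis_matrix(pm)
  groups <- rep(c("w", "x", "y", "z"), each = 4)
  ours <- anosim(d, groups, permutations = 99, seed = 3)
  theirs <- vegan::anosim(as.dist(d), groups, permutations = 99)
  expect_equal(ours$R, unname(theirs$statistic), tolerance = 1e-12)
})

test_that("ANOSIM validates its grouping and honours the p convention", {
  d <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  expect_error(anosim(d, c("a", "a", "a", "b", "b")[c(1, 2, 3, 4, 4)],
                      permutations = 9),
               NA)
  expect_error(anosim(d, rep("a", 5)), "2 groups")
  expect_error(anosim(d, c("a", "a", "b", "b", "c")), "c")
  res <- anosim(d, c("a", "a", "a", "b", "b"), permutations = 99, seed = 1)
  expect_gte(res$p_value, 1 / 100)   # +1 convention: p is never 0
})

test_that("ANOSIM R is centred on zero under a random-label null", {
  withr::local_seed(123)
  Rs <- replicate(100, {
    d <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    anosim(d, sample(rep(c("a", "b"), each = 5)), permutations = 2,
           seed = 1)$R
  })
  expect_lt(abs(mean(Rs)), 0.05)
})

test_that("UpSet exclusive cells partition the reaction universe", {
  sets <- list(p1 = c("a", "b", "c"), p2 = c("b", "c", "d"),
               p3 = c("c", "e"))
  cells <- upset_exclusive_counts(sets)
  expect_identical(sum(cells), 5L)               # |union|
  expect_identical(unname(cells["p1"]), 1L)      # {a}
  expect_identical(unname(cells["p1&p2&p3"]), 1L) # {c}
  # identical sets: everything in the full-intersection cell
  same <- upset_exclusive_counts(list(p1 = c("a", "b"), p2 = c("a", "b"),
                                      p3 = c("a", "b")))
  expect_identical(unname(same["p1&p2&p3"]), 2L)
  expect_identical(sum(same), 2L)
  # pairwise disjoint: only singletons populated
  disj <- upset_exclusive_counts(list(p1 = "a", p2 = "b", p3 = "c"))
  expect_identical(unname(disj[c("p1", "p2", "p3")]), c(1L, 1L, 1L))
  expect_identical(sum(disj), 3L)
  withr::local_seed(44)
  for (i in 1:10) {
    rnd <- lapply(1:4, function(j) sample(letters, sample(3:15, 1)))
    names(rnd) <- paste0("q", 1:4)
    expect_identical(sum(upset_exclusive_counts(rnd)),
                     length(unique(unlist(rnd))))
  }
})

test_that("pipeline-specific reactions are the singleton cells", {
  sets <- list(p1 = c("a", "b", "c"), p2 = c("b", "c", "d"),
               p3 = c("c", "e"))
  spec <- pipeline_specific_reactions(sets)
  expect_identical(spec$p1, "a")
  expect_identical(spec$p2, "d")
  expect_identical(spec$p3, "e")
  cells <- upset_exclusive_counts(sets)
  expect_identical(lengths(spec)[names(sets)],
                   setNames(as.integer(cells[names(sets)]), names(sets)))
})

test_that("pathway specificity flags pathways above the 50% threshold", {
  pmap <- list(pwA = c("r1", "r2", "r3", "r4"), pwB = c("r5", "r6"))
  out <- pathway_specificity(c("r1", "r2", "r3"), pmap)
  rowA <- out[out$pathway == "pwA", ]
  expect_equal(rowA$fraction, 0.75)
  expect_true(rowA$flagged)
  rowB <- out[out$pathway == "pwB", ]
  expect_equal(rowB$fraction, 0)
  expect_false(rowB$flagged)
  withr::local_seed(71)
  for (i in 1:10) {
    pmap <- split(sample(paste0("r", 1:40)), rep(1:8, each = 5))
    spec <- sample(paste0("r", 1:40), 12)
    out <- pathway_specificity(spec, pmap)
    brute <- names(pmap)[vapply(pmap, function(rs)
      mean(rs %in% spec) > 0.5, logical(1))]
    expect_setequal(out$pathway[out$flagged], brute)
  }
})

test_that("EC over-representation reproduces the closed-form cases", {
  counts <- rbind(cat1 = c(30, 10, 10, 10, 10),
                  cat2 = c(10, 10, 10, 10, 10),
                  cat3 = c(7, 0, 0, 0, 0),
                  cat4 = c(0, 0, 0, 0, 0))
  colnames(counts) <- paste0("p", 1:5)
  out <- ec_overrepresentation(counts)
  expect_false("cat4" %in% out$ec_category)          # empty row skipped
  r1 <- out[out$ec_category == "cat1" & out$pipeline == "p1", ]
  expect_equal(r1$pct_over, 200)
  expect_equal(r1$p_raw, direct_binom_tail(30, 70, 0.2), tolerance = 1e-12)
  expect_equal(r1$p_adjusted, min(1, r1$p_raw * 3 * 5))
  sym <- out[out$ec_category == "cat2", ]
  expect_true(all(sym$pct_over == 0))
  expect_true(all(sym$p_raw > 0.5))
  inf_row <- out[out$ec_category == "cat3" & out$pipeline == "p1", ]
  expect_identical(inf_row$pct_over, Inf)
  expect_error(ec_overrepresentation(counts[, 1, drop = FALSE]), "2")
})

test_that("binomial tails agree with direct summation to 1e-12", {
  withr::local_seed(52)
  for (i in 1:50) {
    N <- sample(1:200, 1); x <- sample(0:N, 1); P <- sample(2:6, 1)
    expect_equal(pbinom(x - 1, N, 1 / P, lower.tail = FALSE),
                 direct_binom_tail(x, N, 1 / P), tolerance = 1e-12)
  }
})

test_that("deviations from the cross-pipeline mean are exact percentages", {
  vals <- rbind(g1 = c(110, 90), g2 = c(100, 100), g3 = c(0, 0))
  colnames(vals) <- c("p1", "p2")
  expect_warning(dev <- deviation_from_mean(vals), "zero")
  expect_equal(unname(dev["g1", ]), c(10, -10))
  expect_equal(unname(dev["g2", ]), c(0, 0))
  expect_identical(attr(dev, "excluded"), "g3")
})

test_that("Tukey p-values match the studentized-range closed form", {
  withr::local_seed(303)
  k <- 4; n <- 12
  vals <- matrix(rnorm(n * k, mean = rep(c(10, 10.5, 11, 10.2), each = n)),
                 n, k, dimnames = list(NULL, paste0("p", 1:k)))
  res <- anova_tukey(vals)
  long <- data.frame(value = as.vector(vals),
                     pipeline = factor(rep(colnames(vals), each = n)))
  fit <- aov(value ~ pipeline, data = long)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfres <- summary(fit)[[1]]["Residuals", "Df"]
  means <- colMeans(vals)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    q <- abs(means[j] - means[i]) / sqrt(mse / n)
    p_ref <- unname(ptukey(q, k, dfres, lower.tail = FALSE))
    cmp <- paste0("p", j, "-p", i)
    expect_equal(res$tukey$p_adjusted[res$tukey$comparison == cmp],
                 p_ref, tolerance = 1e-8)
  }
  expect_lt(res$anova_p, 1)
})
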