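make_counts <- function(n_s, n_a, seed = 1, lambda = 60) {
  set.seed(seed)
  m <- matrix(rpois(n_s * n_a, lambda), n_s, n_a,
              dimnames = list(sprintf("s%02d", 1:n_s),
                              sprintf("a%03d", 1:n_a)))
  storage.mode(m) <- "integer"
  m
}

test_that("filter_min_counts drops low samples first, then low ASVs", {
  m <- make_counts(6, 5, seed = 61, lambda = 100)
  m["s01", ] <- c(99L, 0L, 0L, 0L, 0L)    # sample total 99 -> dropped
  m["s02", ] <- c(50L, 50L, 0L, 0L, 0L)   # total 100 -> kept
  m[, "a005"] <- 0L                       # all-zero ASV -> dropped
  f <- filter_min_counts(m, 100)
  expect_false("s01" %in% rownames(f))
  expect_true("s02" %in% rownames(f))
  expect_false("a005" %in% colnames(f))
  expect_equal(attr(f, "dropped_samples"), "s01")
  # idempotent
  f2 <- filter_min_counts(f, 100)
  expect_equal(f2, f, ignore_attr = TRUE)
  expect_error(filter_min_counts(m * 0L, 100), "all samples")
})

test_that("rarefy conserves depth exactly and is seed-deterministic", {
  m <- make_counts(8, 30, seed = 62)
  depth <- min(rowSums(m))
  r1 <- rarefy(m, seed = 7)
  r2 <- rarefy(m, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(rowSums(r1) == depth))
  expect_true(all(r1 <= m))
  # depth equal to a sample's total leaves that sample unchanged
  i <- which.min(rowSums(m))
  expect_equal(r1[i, ], m[i, ])
  expect_error(rarefy(m, depth = max(rowSums(m)) + 1), "exceeds")
})

test_that("rarefied counts have the hypergeometric mean", {
  m <- matrix(c(600L, 300L, 100L), 1, 3,
              dimnames = list("s1", c("a", "b", "c")))
  depth <- 200
  draws <- vapply(seq_len(500), function(s)
    rarefy(m, depth = depth, seed = s)[1, ], numeric(3))
  exp_mean <- depth * m[1, ] / sum(m)
  se <- sqrt(apply(draws, 1, var) / 500)
  expect_true(all(abs(rowMeans(draws) - exp_mean) < 3 * se))
})

test_that("shannon matches closed forms", {
  expect_equal(shannon(c(10, 10, 10, 10)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(as.numeric(shannon(c(0, 0))), 0)
  expect_true(attr(shannon(c(0, 0)), "zero_sample"))
  # [1,1,2]: -2*(1/4 log 1/4) - 1/2 log 1/2
  expect_equal(shannon(c(1, 1, 2)), -2 * 0.25 * log(0.25) - 0.5 * log(0.5),
               tolerance = 1e-12)
  expect_error(shannon(c(-1, 2)), "negative")
})

test_that("shannon agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(63)
  for (k in 1:20) {
    v <- rpois(15, 5)
    expect_equal(as.numeric(shannon(v)),
                 as.numeric(vegan::diversity(matrix(v, 1), index = "shannon")),
                 tolerance = 1e-10)
  }
})

test_that("subset_shannon restricts to the taxon and bounds by richness", {
  m <- make_counts(10, 12, seed = 64)
  tax <- setNames(sprintf("d__B;p__P;c__C;o__O;f__F%d;g__G%d;s__",
                          rep(1:2, each = 6), rep(1:4, 3)), colnames(m))
  h_all <- subset_shannon(m, tax, "c", "C")
  expect_equal(unname(h_all), unname(apply(m, 1, function(r)
    as.numeric(shannon(r)))))
  h_f1 <- subset_shannon(m, tax, "f", "F1")
  expect_true(all(h_f1 <= log(6) + 1e-12))
  # zero-subset sample gets H = 0
  m2 <- m
  m2[1, 1:6] <- 0L
  expect_equal(unname(subset_shannon(m2, tax, "f", "F1")[1]), 0)
  expect_error(subset_shannon(m, tax, "f", "Nope"), "no ASV")
})

test_that("greedy_cluster honors the identity threshold", {
  s100 <- paste(rep("A", 50), collapse = "")
  set.seed(65)
  base <- random_seq(100)
  variant <- base
  substr(variant, 10, 10) <- if (substr(base, 10, 10) == "A") "C" else "A"
  seqs <- c(x1 = base, x2 = variant, x3 = random_seq(100))
  ab <- c(x1 = 100, x2 = 10, x3 = 50)
  cl97 <- greedy_cluster(seqs, ab, 0.97)
  expect_equal(unname(cl97$map["x2"]), "x1")       # identity 0.99 >= 0.97
  cl100 <- greedy_cluster(seqs, ab, 1.0)
  expect_equal(length(cl100$centroids), 3)         # identity partition
  expect_equal(unname(cl100$map), names(cl100$map))
  # ties in abundance broken lexicographically; identical sequences merge
  seqs2 <- c(b = base, a = base)
  cl <- greedy_cluster(seqs2, c(a = 5, b = 5), 1.0)
  expect_equal(unname(cl$map[c("a", "b")]), c("a", "a"))
  # collapse sums member counts on centroid columns in original order
  m <- make_counts(4, 3, seed = 66)
  colnames(m) <- c("x1", "x2", "x3")
  cc <- collapse_counts(m, cl97)
  expect_equal(colnames(cc), c("x1", "x3"))
  expect_equal(cc[, "x1"], m[, "x1"] + m[, "x2"])
})

test_that("cluster count is monotone non-increasing in threshold", {
  set.seed(67)
  base <- random_seq(80)
  seqs <- setNames(c(base, vapply(1:7, function(i)
    evolve_k80(base, runif(1, 0.01, 0.3), seed = 200 + i), character(1))),
    paste0("q", 1:8))
  ab <- setNames(rexp(8, 0.01), names(seqs))
  ncl <- vapply(c(1, 0.97, 0.9, 0.85), function(t)
    length(greedy_cluster(seqs, ab, t)$centroids), numeric(1))
  expect_true(all(diff(ncl) <= 0))
})

test_that("fit_hurdle flags degenerate designs instead of erroring", {
  coh <- simulate_diversity_cohort(cohort_spec(n_samples = 60, a0 = 10,
                                               a1 = 0, seed = 68))
  f <- fit_hurdle(coh$shannon, coh$metadata)
  expect_false(f$estimable[f$model == "glm.bin"])   # no zeros
  expect_true(f$estimable[f$model == "glm.cont"])
  # all-zero diversity: neither model estimable
  h0 <- setNames(rep(0, 60), coh$metadata$sample_id)
  f0 <- fit_hurdle(h0, coh$metadata)
  expect_false(any(f0$estimable))
  expect_error(fit_hurdle(coh$shannon[1:5], coh$metadata), "10 samples")
})

test_that("hurdle null calibration: no BMI effect, nonzero city effect", {
  reps <- 200
  p_bin <- p_cont <- numeric(reps)
  beta <- numeric(reps)
  for (r in seq_len(reps)) {
    coh <- simulate_diversity_cohort(cohort_spec(
      n_samples = 250, a0 = 1, a1 = 0, b0 = 1, b1 = 0,
      city_levels = c("A", "B"), city_effects_bin = c(0, 0.5),
      city_effects_cont = c(0, 0.3), seed = 3000 + r))
    f <- fit_hurdle(coh$shannon, coh$metadata)
    p_bin[r] <- f$p[f$model == "glm.bin"]
    p_cont[r] <- f$p[f$model == "glm.cont"]
    beta[r] <- f$beta_bmi[f$model == "glm.cont"]
  }
  # BMI coefficient centered on zero within 2 Monte-Carlo SE
  expect_lt(abs(mean(beta)), 2 * sd(beta) / sqrt(reps))
  # type-I near nominal (loose 3-SE band at 200 replicates)
  for (p in list(p_bin, p_cont)) {
    expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
  }
})

test_that("adjust_fdr equals the brute-force BH oracle", {
  expect_equal(as.numeric(adjust_fdr(c(0.01, 0.02, 0.03, 0.5))),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(as.numeric(adjust_fdr(0.3)), 0.3)
  set.seed(69)
  for (k in seq_len(200)) {
    p <- runif(sample(1:40, 1))
    expect_equal(as.numeric(adjust_fdr(p)), oracle_bh(p))
  }
  p <- runif(30)
  g <- sample(c("x", "y"), 30, replace = TRUE)
  adj <- adjust_fdr(p, groups = g)
  expect_equal(as.numeric(adj[g == "x"]), oracle_bh(p[g == "x"]))
  expect_true(all(adj >= p))
  expect_equal(attr(adjust_fdr(c(0.01, 0.5), alpha = 0.2), "significant"),
               c(TRUE, FALSE))
  expect_error(adjust_fdr(c(0.5, 1.2)), "outside")
})

test_that("sensitivity at threshold 1 reproduces the unclustered fits", {
  coh <- simulate_count_cohort(n_samples = 50, n_asvs = 40,
                               dispersion = 0.3, seed = 70)
  set.seed(71)
  seqs <- setNames(vapply(seq_len(40), function(i) random_seq(90),
                          character(1)), colnames(coh$counts))
  base <- diversity_analysis(coh$counts, coh$taxonomy, coh$metadata,
                             marker = "m", seed = 5)
  sens <- sensitivity_suite(coh$counts, coh$taxonomy, seqs, coh$metadata,
                            thresholds = 1, marker = "m", seed = 5)
  expect_identical(sens[["1"]]$fits, base)
  expect_equal(sens[["1"]]$n_clusters, 40)
})

test_that("collapsing a taxon to one cluster kills its diversity signal", {
  coh <- simulate_count_cohort(n_samples = 50, n_asvs = 12,
                               dispersion = 0.3, seed = 72)
  # all ASVs same genus; all sequences tiny variants of one base sequence
  tax <- setNames(rep("d__B;p__P;c__C;o__O;f__F;g__G;s__", 12),
                  colnames(coh$counts))
  set.seed(73)
  base <- random_seq(100)
  seqs <- setNames(vapply(1:12, function(i) {
    v <- base; substr(v, i, i) <- "A"; v
  }, character(1)), colnames(coh$counts))
  sens <- sensitivity_suite(coh$counts, tax, seqs, coh$metadata,
                            thresholds = 0.85,
                            taxa = data.frame(rank = "g", name = "G"),
                            marker = "m", seed = 5)
  res <- sens[["0.85"]]$fits
  expect_equal(sens[["0.85"]]$n_clusters, 1)
  # single cluster -> H = 0 everywhere -> neither model estimable
  expect_false(any(res$estimable))
})
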