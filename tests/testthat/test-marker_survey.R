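test_that("align_pair reproduces the toy single-gap alignment", {
  al <- align_pair("ACGT", "AGT")
  expect_equal(al$score, -2)
  expect_equal(al$a, "ACGT")
  expect_equal(al$b, "A-GT")
  al2 <- align_pair("ACGT", "ACGT")
  expect_equal(al2$score, 4)
  expect_false(grepl("-", paste0(al2$a, al2$b)))
})

test_that("align_pair score equals the brute-force Gotoh oracle", {
  set.seed(21)
  for (k in seq_len(50)) {
    a <- random_seq(sample(5:30, 1))
    b <- random_seq(sample(5:30, 1))
    expect_equal(align_pair(a, b)$score, oracle_global_score(a, b),
                 info = paste(a, b))
  }
})

test_that("compute_k80 matches the closed form and flags saturation", {
  # P = 0.1, Q = 0.05 on 100 sites
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  d <- compute_k80(a, b)
  expect_equal(d$P, 0.1)
  expect_equal(d$Q, 0.05)
  expect_equal(d$d_k80, oracle_k80(0.1, 0.05), tolerance = 1e-12)
  expect_equal(d$p_identity, 0.85)
  expect_false(d$saturated)

  # saturation boundary: 1 - 2P - Q = 0 at P = 0.4, Q = 0.2
  b2 <- paste(c(rep("G", 40), rep("C", 20), rep("A", 40)), collapse = "")
  d2 <- compute_k80(a, b2)
  expect_true(d2$saturated)
  expect_true(is.na(d2$d_k80))
  expect_equal(d2$p_identity, 0.4)

  expect_error(compute_k80("----", "ACGT"), "no comparable")
})

test_that("compute_k80 excludes gap/ambiguity columns and is symmetric", {
  a <- "AC-GTNAC"
  b <- "ACTG-TGC"
  d <- compute_k80(a, b)
  # comparable columns: A/A C/C T/T (wait) -> positions 1,2,7(A/G ts),8(C/C)
  expect_equal(d$n_sites, 5)
  d_rev <- compute_k80(b, a)
  expect_equal(d$d_k80, d_rev$d_k80)
  expect_equal(d$P, d_rev$P)
})

test_that("d_k80 is invariant under the joint A<->G, C<->T relabeling", {
  set.seed(22)
  a <- random_seq(300)
  b <- evolve_k80(a, 0.2, seed = 23)
  d1 <- compute_k80(a, b)
  d2 <- compute_k80(chartr("AGCT", "GATC", a), chartr("AGCT", "GATC", b))
  expect_equal(d1$d_k80, d2$d_k80)
  expect_equal(d1$P, d2$P)
  expect_equal(d1$Q, d2$Q)
})

test_that("compute_k80 agrees with the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(24)
  a <- random_seq(1000)
  b <- evolve_k80(a, 0.12, seed = 25)
  d <- compute_k80(a, b)
  mat <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
  ref <- ape::dist.dna(ape::as.DNAbin(mat), model = "K80")
  expect_equal(d$d_k80, as.numeric(ref), tolerance = 1e-10)
})

test_that("trim_alignment_columns slices rows identically", {
  msa <- c(r1 = "ACGTACGTAC", r2 = "ACGT--GTAC")
  expect_identical(trim_alignment_columns(msa, 1, 10), msa)
  tr <- trim_alignment_columns(msa, 3, 7)
  expect_equal(unname(nchar(tr)), c(5, 5))
  expect_equal(tr[["r2"]], "GT--G")
  expect_error(trim_alignment_columns(msa, 0, 5), "out of range")
  expect_error(trim_alignment_columns(msa, 3, 11), "out of range")
  # distances after trimming use only the retained columns
  d <- compute_k80(tr[["r1"]], tr[["r2"]])
  expect_equal(d$n_sites, 3)
})

test_that("locate_marker finds embedded loci at truth coordinates", {
  # exact embedded query: coordinates must match the truth table exactly
  sim <- simulate_marker_genomes(3, 0, list(marker_spec("m", 400, 1)),
                                 background_length = 2000, seed = 26)
  for (i in 1:3) {
    h <- locate_marker(sim$genomes$sequence[i], sim$ancestors[["m"]],
                       genome_id = sim$genomes$id[i], marker_name = "m")
    tr <- sim$truth[sim$truth$genome_id == sim$genomes$id[i], ]
    expect_equal(nrow(h), 1L)
    expect_equal(h$start, tr$start)
    expect_equal(h$end, tr$end)
    expect_equal(h$strand, tr$strand)
  }
  # diverged locus: still one hit, within a few bp of the truth (local
  # alignment may trim mismatching locus ends)
  sim2 <- simulate_marker_genomes(3, 0.02, list(marker_spec("m", 400, 1)),
                                  background_length = 2000, seed = 31)
  for (i in 1:3) {
    h <- locate_marker(sim2$genomes$sequence[i], sim2$ancestors[["m"]],
                       genome_id = sim2$genomes$id[i], marker_name = "m")
    tr <- sim2$truth[sim2$truth$genome_id == sim2$genomes$id[i], ]
    expect_equal(nrow(h), 1L)
    expect_lte(abs(h$start - tr$start), 5)
    expect_lte(abs(h$end - tr$end), 5)
    expect_equal(h$strand, tr$strand)
  }
  # absent query on random background
  none <- locate_marker(random_dna(3000, seed = 27), random_dna(300, seed = 28),
                        min_identity = 0.9)
  expect_equal(nrow(none), 0L)
})

test_that("locate_marker reports duplicated loci as two copies", {
  set.seed(29)
  marker <- random_seq(300)
  g <- paste0(random_seq(800), marker, random_seq(700), marker,
              random_seq(500))
  h <- locate_marker(g, marker, genome_id = "dup")
  expect_equal(nrow(h), 2L)
  expect_equal(sort(h$start), c(800, 1800))
  expect_equal(single_copy_fraction(h, "dup"), 0)
})

test_that("locate_marker protein mode finds a CDS via its translation", {
  fam <- simulate_orthologue_family(n_rows = 2, n_codons = 100, seed = 30)
  cds <- fam$cds[[1]]
  set.seed(31)
  g <- paste0(random_seq(900), cds, random_seq(600))
  h <- locate_marker(g, fam$protein_msa[[1]], is_protein = TRUE,
                     min_identity = 0.9, min_coverage = 0.9)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 900)
  expect_equal(h$end, 900 + nchar(cds))
  expect_equal(h$strand, "+")
  # and on the reverse strand
  h2 <- locate_marker(revcomp(g), fam$protein_msa[[1]], is_protein = TRUE,
                      min_identity = 0.9, min_coverage = 0.9)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$end - h2$start, nchar(cds))
})

test_that("single_copy_fraction counts exactly-one-hit genomes", {
  hits <- data.frame(genome_id = c("g1", "g2", "g2"))
  expect_equal(single_copy_fraction(hits, c("g1", "g2")), 0.5)
  expect_equal(single_copy_fraction(hits, c("g1", "g2", "g3")), 1 / 3)
  expect_equal(single_copy_fraction(hits[0, , drop = FALSE], "g1"), 0)
  expect_error(single_copy_fraction(hits, character(0)), "empty")
})

test_that("compare_markers matches the least-squares oracle", {
  set.seed(32)
  n <- 20
  ids <- sprintf("g%02d", 1:8)
  pairs <- t(combn(ids, 2))[1:n, ]
  x <- runif(n, 0.7, 1)
  y <- 0.3 + 0.6 * x + rnorm(n, 0, 0.02)
  dx <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2], p_identity = x,
                   d_k80 = NA, stringsAsFactors = FALSE)
  dy <- data.frame(id_a = pairs[, 2], id_b = pairs[, 1], p_identity = y,
                   d_k80 = NA, stringsAsFactors = FALSE)
  cmp <- compare_markers(dx, dy)
  # closed-form normal equations
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_o <- mean(y) - slope_o * mean(x)
  expect_equal(cmp$slope, slope_o, tolerance = 1e-10)
  expect_equal(cmp$intercept, int_o, tolerance = 1e-10)
  expect_equal(cmp$n_pairs, n)

  # identity regression
  dy2 <- dx
  # exact y = x data: lm warns about a perfect fit, which is the point
  cmp2 <- suppressWarnings(compare_markers(dx, dy2))
  expect_equal(cmp2$slope, 1, tolerance = 1e-10)
  expect_equal(cmp2$intercept, 0, tolerance = 1e-10)
  expect_equal(cmp2$r2, 1, tolerance = 1e-10)
  expect_equal(map_identity(cmp2, 0.97), 0.97)

  expect_error(compare_markers(dx[1:2, ], dy[1:2, ]), "insufficient")
})

test_that("map_identity is linear, clipped, and needs a fit", {
  cmp <- structure(list(slope = 2, intercept = -1), class = "marker_comparison")
  expect_equal(map_identity(cmp, 0.97), 0.94)
  expect_equal(map_identity(cmp, 2), 1)
  expect_equal(map_identity(cmp, -1), 0)
  xs <- seq(0.6, 0.9, by = 0.05)
  expect_true(all(diff(map_identity(cmp, xs)) >= 0))
  expect_error(map_identity(list(), 0.9), "not a fitted")
})
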