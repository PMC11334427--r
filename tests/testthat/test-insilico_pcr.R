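test_that("iupac_match implements the subset rule", {
  expect_true(iupac_match("Y", "C"))
  expect_true(iupac_match("Y", "T"))
  expect_false(iupac_match("Y", "G"))
  for (x in c("A", "C", "G", "T", "R", "Y", "N", "H"))
    expect_true(iupac_match("N", x))
  expect_false(iupac_match("A", "N"))  # genome ambiguity not covered
  expect_false(iupac_match("Y", "N"))
  expect_true(iupac_match("H", "W"))   # {A,T} subset of {A,C,T}
  expect_error(iupac_match("Z", "A"), "invalid")
})

test_that("count_mismatches counts subset-rule failures", {
  p <- published_primers()$dnaK$fwd
  site <- realize_primer_site(p$iupac, 0L)
  expect_equal(count_mismatches(p, site), 0L)
  set.seed(41)
  site2 <- realize_primer_site(p$iupac, 2L)
  expect_equal(count_mismatches(p, site2), 2L)
  expect_error(count_mismatches(p, "ACGT"), "length")
})

test_that("subset-rule counting equals brute-force min Hamming over expansions", {
  # all four published primers have degeneracy <= 256
  prs <- published_primers()
  primers <- c(prs$dnaK$fwd$iupac, prs$dnaK$rev$iupac,
               prs$gyrB$fwd$iupac, prs$gyrB$rev$iupac)
  expect_true(all(vapply(primers, iupac_degeneracy, numeric(1)) <= 256))
  set.seed(42)
  for (p in primers) {
    for (k in seq_len(25)) {
      w <- random_seq(nchar(p))
      expect_equal(count_mismatches(p, w), oracle_min_hamming(p, w),
                   info = paste(p, w))
    }
  }
})

test_that("find_amplicons respects the length window and strand symmetry", {
  pp <- published_primers()$dnaK
  sim <- simulate_marker_genomes(
    2, 0, list(marker_spec("fast", 130, 3)), background_length = 1200,
    primer_pairs = list(fast = list(fwd = pp$fwd$iupac, rev = pp$rev$iupac,
                                    mismatches_fwd = 0L,
                                    mismatches_rev = 0L)),
    seed = 43)
  g <- sim$genomes$sequence[1]
  tr <- sim$truth[1, ]
  hits <- find_amplicons(g, pp$fwd, pp$rev, 75, 150, 6, genome_id = "t1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_length, 130L)
  expect_equal(hits$mismatches_fwd + hits$mismatches_rev, 0L)
  expect_equal(hits$fwd_start, tr$start)
  expect_equal(hits$rev_end, tr$end)
  expect_equal(hits$orientation, tr$strand)

  # reverse complement of the genome: mirrored orientation, same lengths
  hits_rc <- find_amplicons(revcomp(g), pp$fwd, pp$rev, 75, 150, 6)
  expect_equal(hits_rc$product_length, hits$product_length)
  expect_equal(sort(c(hits$orientation, hits_rc$orientation)), c("+", "-"))
  expect_equal(hits_rc$mismatches_fwd, hits$mismatches_fwd)

  # length filter: too-long product excluded
  expect_equal(nrow(find_amplicons(g, pp$fwd, pp$rev, 75, 129, 6)), 0L)
  expect_equal(nrow(find_amplicons(g, pp$fwd, pp$rev, 131, 150, 6)), 0L)

  # inner-span convention differs by the two primer footprints
  inner <- find_amplicons(g, pp$fwd, pp$rev, 75, 150, 6, span = "inner")
  expect_equal(inner$product_length, 130L - 21L - 21L)
})

test_that("hit reported iff injected mismatches <= max_mismatch", {
  pp <- published_primers()$dnaK
  mm <- c(0L, 1L, 3L, 5L, 6L, 7L)
  sim <- simulate_marker_genomes(
    length(mm), 0, list(marker_spec("fast", 130, 3)),
    background_length = 1500,
    primer_pairs = list(fast = list(fwd = pp$fwd$iupac, rev = pp$rev$iupac,
                                    mismatches_fwd = mm,
                                    mismatches_rev = 0L)),
    seed = 44)
  for (i in seq_along(mm)) {
    h <- find_amplicons(sim$genomes$sequence[i], pp$fwd, pp$rev,
                        75, 150, 6)
    if (mm[i] <= 6L) {
      expect_equal(nrow(h), 1L, info = paste("mm =", mm[i]))
      expect_equal(h$mismatches_fwd, mm[i])
    } else {
      expect_equal(nrow(h), 0L, info = paste("mm =", mm[i]))
    }
  }
})

test_that("coverage is monotone in mismatch allowance and window width", {
  pp <- published_primers()$dnaK
  mm_f <- c(0L, 2L, 4L, 7L, 8L, 0L, 1L, 9L)
  sim <- simulate_marker_genomes(
    8, 0, list(marker_spec("fast", 130, 3)), background_length = 1000,
    primer_pairs = list(fast = list(fwd = pp$fwd$iupac, rev = pp$rev$iupac,
                                    mismatches_fwd = mm_f,
                                    mismatches_rev = 0L)),
    seed = 45)
  cov_at <- function(mm, lo = 75, hi = 150) {
    taxonomic_coverage(sim$genomes, pp$fwd, pp$rev, lo, hi, mm)$coverage
  }
  covs <- vapply(c(0L, 2L, 4L, 6L, 8L), cov_at, numeric(1))
  expect_true(all(diff(covs) >= 0))
  expect_equal(cov_at(6L), 5 / 8)          # mm <= 6 for 5 of 8 taxa
  expect_equal(cov_at(6L, 131, 150), 0)    # window excludes the product
  expect_error(taxonomic_coverage(sim$genomes[0, ], pp$fwd, pp$rev,
                                  75, 150), "empty")
})

test_that("taxonomic coverage groups by (order, family)", {
  pp <- published_primers()$dnaK
  tax <- c(rep("d__B;p__P;c__C;o__O1;f__F1;g__;s__", 4),
           rep("d__B;p__P;c__C;o__O1;f__F2;g__;s__", 2))
  sim <- simulate_marker_genomes(
    6, 0, list(marker_spec("fast", 130, 3)), background_length = 800,
    primer_pairs = list(fast = list(fwd = pp$fwd$iupac, rev = pp$rev$iupac,
                                    mismatches_fwd = c(0L, 0L, 0L, 7L, 0L, 7L),
                                    mismatches_rev = 0L)),
    taxonomy = tax, seed = 46)
  cov <- taxonomic_coverage(sim$genomes, pp$fwd, pp$rev, 75, 150, 6)
  f1 <- cov[cov$family == "F1", ]
  f2 <- cov[cov$family == "F2", ]
  expect_equal(f1$n_species, 4)
  expect_equal(f1$n_hit, 3)
  expect_equal(f1$coverage, 0.75)
  expect_equal(f2$coverage, 0.5)
  expect_equal(f1$order, "O1")
})

test_that("extract_inner_region returns the sequence strictly between primers", {
  pp <- published_primers()$dnaK
  set.seed(47)
  fwd_site <- realize_primer_site(pp$fwd$iupac, 0L)
  rev_site <- realize_primer_site(pp$rev$iupac, 0L)
  read <- paste0(fwd_site, "CCGGAA", revcomp(rev_site))
  expect_equal(extract_inner_region(read, pp$fwd, pp$rev, 6), "CCGGAA")
  # missing reverse site -> unmatched
  read2 <- paste0(fwd_site, "CCGGAA", random_seq(21))
  expect_true(is.na(extract_inner_region(read2, pp$fwd, pp$rev, 0)))
  # the simulated dnaK-like locus yields the 88 bp inner fragment
  sim <- simulate_marker_genomes(
    2, 0, list(marker_spec("fast", 130, 3)), background_length = 200,
    primer_pairs = list(fast = list(fwd = pp$fwd$iupac, rev = pp$rev$iupac,
                                    mismatches_fwd = 0L,
                                    mismatches_rev = 0L)),
    seed = 48)
  inner <- extract_inner_region(sim$marker_seqs$fast[[1]], pp$fwd, pp$rev, 6)
  expect_equal(nchar(inner), 88L)
})
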