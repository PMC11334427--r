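# Synthetic-data generators. Every downstream stage is exercised on data
# whose truth is known: marker loci evolved under K80 at per-marker relative
# rates, primer sites with exactly controlled mismatch counts, and cohorts
# whose per-taxon Shannon diversity follows the hurdle structure
# (Bernoulli presence x Gamma positive part) the statistical stage fits.

#' Random DNA sequence
#'
#' @param n Length in bp.
#' @param seed Optional RNG seed.
#' @return A single ACGT string.
#' @export
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Evolve a sequence under the Kimura (1980) model
#'
#' Each site evolves independently under the K80 transition-probability
#' matrix at branch length `distance` (expected substitutions/site) with
#' transition/transversion rate ratio `kappa`. With d the branch length and
#' k = kappa, the per-site probabilities are
#' `P(transition) = 1/4 + 1/4 exp(-4d/(k+2)) - 1/2 exp(-2d(k+1)/(k+2))` and
#' `P(each transversion) = 1/4 - 1/4 exp(-4d/(k+2))`.
#'
#' @param ancestor ACGT string.
#' @param distance Branch length, substitutions/site, >= 0.
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param seed Optional RNG seed.
#' @return Evolved sequence of the same length.
#' @export
evolve_k80 <- function(ancestor, distance, kappa = 2, seed = NULL) {
  if (!is.finite(distance) || distance < 0) stop("distance must be >= 0")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  ancestor <- normalize_sequence(ancestor)
  if (grepl("[^ACGT]", ancestor)) stop("ancestor must be over A,C,G,T")
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(ancestor)
  if (n == 0L) return(ancestor)
  e1 <- exp(-4 * distance / (kappa + 2))
  e2 <- exp(-2 * distance * (kappa + 1) / (kappa + 2))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2      # transition
  p_tv <- 0.25 - 0.25 * e1                 # each of the two transversions
  u <- stats::runif(n)
  base <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  ts <- strsplit(chartr("ACGT", "GTAC", ancestor), "", fixed = TRUE)[[1]]
  tv1 <- strsplit(chartr("ACGT", "CACA", ancestor), "", fixed = TRUE)[[1]]
  tv2 <- strsplit(chartr("ACGT", "TGTG", ancestor), "", fixed = TRUE)[[1]]
  out <- base
  out[u < p_ts] <- ts[u < p_ts]
  sel <- u >= p_ts & u < p_ts + p_tv
  out[sel] <- tv1[sel]
  sel <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  out[sel] <- tv2[sel]
  paste(out, collapse = "")
}

#' Marker specification for genome simulation
#'
#' @param name Marker name.
#' @param length Marker length in bp (>= 60).
#' @param rate_multiplier Relative substitution rate vs the slowest marker
#'   (the 16S-like marker is the reference at 1).
#' @param kappa Transition/transversion rate ratio.
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(name, length = 1000L, rate_multiplier = 1,
                        kappa = 2) {
  stopifnot(length >= 60, rate_multiplier >= 0, kappa > 0)
  structure(list(name = name, length = as.integer(length),
                 rate_multiplier = rate_multiplier, kappa = kappa),
            class = "marker_spec")
}

# realize one concrete primer site from a degenerate primer, optionally
# injecting exactly n_mismatch mismatches at non-degenerate positions (so
# the injected count equals the realized mismatch count under the subset
# matching rule).
realize_primer_site <- function(iupac, n_mismatch = 0L) {
  iupac <- normalize_sequence(iupac)
  codes <- strsplit(iupac, "", fixed = TRUE)[[1]]
  site <- vapply(IUPAC_SETS[codes], function(s)
    if (length(s) == 1L) s else sample(s, 1L), character(1))
  if (n_mismatch > 0L) {
    concrete <- which(lengths(IUPAC_SETS[codes]) == 1L)
    if (length(concrete) < n_mismatch) {
      stop("not enough non-degenerate positions to inject ", n_mismatch,
           " mismatches")
    }
    pos <- sample(concrete, n_mismatch)
    for (i in pos) {
      site[i] <- sample(setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[codes[i]]][1]), 1L)
    }
  }
  paste(site, collapse = "")
}

#' Simulate genomes carrying single-copy marker loci
#'
#' Each genome carries exactly one copy of each marker (random strand) at
#' recorded coordinates, embedded in independent random background. Marker i
#' of taxon t is evolved from a shared ancestor to distance
#' `divergences[t] * rate_multiplier[i]`, so a pair of taxa sits at distance
#' `(divergences[t1] + divergences[t2]) * rate_multiplier[i]` in
#' expectation. When `primer_pairs` is given, the marker locus is built as
#' `fwd site + evolved inner + revcomp(rev site)` with the requested number
#' of mismatches injected at non-degenerate primer positions; primer sites
#' themselves are not further mutated, so the injected counts are exact.
#'
#' @param n_taxa Number of genomes (>= 2).
#' @param divergences Per-taxon distance from the shared ancestor
#'   (recycled; substitutions/site).
#' @param specs List of [marker_spec()] objects.
#' @param background_length Background bp per genome.
#' @param primer_pairs Optional named list, one entry per marker name, each
#'   `list(fwd=, rev=, mismatches_fwd=, mismatches_rev=)` where the mismatch
#'   entries are per-taxon integer vectors (recycled).
#' @param taxonomy Optional character vector of taxonomy labels per taxon.
#' @param seed RNG seed.
#' @return List with `genomes` (data.frame id, sequence, taxonomy),
#'   `truth` (data.frame of marker coordinates, 0-based half-open, strand,
#'   injected mismatches), `ancestors` (named vector of ancestral marker
#'   inner sequences) and `marker_seqs` (list marker -> named vector of the
#'   realized locus sequence per taxon, forward orientation of the locus).
#' @export
simulate_marker_genomes <- function(n_taxa, divergences, specs,
                                    background_length = 4000L,
                                    primer_pairs = NULL,
                                    taxonomy = NULL, seed = 1L) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (any(divergences < 0)) stop("divergences must be >= 0")
  if (inherits(specs, "marker_spec")) specs <- list(specs)
  divergences <- rep_len(divergences, n_taxa)
  set.seed(seed)
  marker_names <- vapply(specs, `[[`, character(1), "name")
  names(specs) <- marker_names

  # ancestral inner sequences
  ancestors <- stats::setNames(vapply(specs, function(sp) {
    inner_len <- sp$length
    if (!is.null(primer_pairs[[sp$name]])) {
      pp <- primer_pairs[[sp$name]]
      inner_len <- sp$length - nchar(pp$fwd) - nchar(pp$rev)
      if (inner_len < 1L) stop("marker '", sp$name,
                               "' shorter than its primer footprints")
    }
    random_dna(inner_len)
  }, character(1)), marker_names)

  ids <- sprintf("taxon%02d", seq_len(n_taxa))
  if (is.null(taxonomy)) {
    taxonomy <- sprintf(
      "d__Bacteria;p__Bacillota_A;c__Clostridia;o__SimOrder;f__SimFamily;g__SimGenus;s__SimGenus sp%02d",
      seq_len(n_taxa))
  }
  taxonomy <- rep_len(taxonomy, n_taxa)

  genomes <- character(n_taxa)
  truth <- list()
  marker_seqs <- stats::setNames(
    lapply(marker_names, function(m) stats::setNames(character(n_taxa), ids)),
    marker_names)

  for (t in seq_len(n_taxa)) {
    loci <- character(length(specs))
    meta <- vector("list", length(specs))
    for (k in seq_along(specs)) {
      sp <- specs[[k]]
      d <- divergences[t] * sp$rate_multiplier
      inner <- evolve_k80(ancestors[[sp$name]], d, sp$kappa)
      mm_f <- mm_r <- NA_integer_
      if (!is.null(primer_pairs[[sp$name]])) {
        pp <- primer_pairs[[sp$name]]
        mm_f <- rep_len(as.integer(pp$mismatches_fwd %||% 0L), n_taxa)[t]
        mm_r <- rep_len(as.integer(pp$mismatches_rev %||% 0L), n_taxa)[t]
        locus <- paste0(realize_primer_site(pp$fwd, mm_f), inner,
                        revcomp(realize_primer_site(pp$rev, mm_r)))
      } else {
        locus <- inner
      }
      loci[k] <- locus
      meta[[k]] <- list(marker = sp$name, mm_f = mm_f, mm_r = mm_r)
      marker_seqs[[sp$name]][t] <- locus
    }
    # place loci in background without overlap
    n_slots <- length(loci) + 1L
    bg_part <- pmax(1L, as.integer(background_length / n_slots))
    strands <- sample(c("+", "-"), length(loci), replace = TRUE)
    pieces <- character(0)
    pos <- 0L
    for (k in seq_along(loci)) {
      bg <- random_dna(bg_part)
      placed <- if (strands[k] == "+") loci[k] else revcomp(loci[k])
      pieces <- c(pieces, bg, placed)
      start <- pos + nchar(bg)
      end <- start + nchar(loci[k])
      truth[[length(truth) + 1L]] <- data.frame(
        genome_id = ids[t], marker = meta[[k]]$marker,
        start = start, end = end, strand = strands[k],
        mismatches_fwd = meta[[k]]$mm_f, mismatches_rev = meta[[k]]$mm_r,
        divergence = divergences[t], stringsAsFactors = FALSE)
      pos <- end
    }
    pieces <- c(pieces, random_dna(bg_part))
    genomes[t] <- paste(pieces, collapse = "")
  }

  list(genomes = data.frame(id = ids, sequence = genomes,
                            taxonomy = taxonomy, stringsAsFactors = FALSE),
       truth = do.call(rbind, truth),
       ancestors = ancestors,
       marker_seqs = marker_seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort specification for the hurdle diversity generator
#'
#' Defaults are the generator's stated world: BMI uniform on \[18.5, 40\]
#' (spanning the lean/overweight/obese strata), five city levels with modest
#' baseline offsets, logit presence intercept `a0 = 6` and slope
#' `a1 = -0.165` (per BMI unit), log-scale positive-part intercept `b0 = 1`
#' and slope `b1 = -0.017`, Gamma shape 3.
#'
#' @param n_samples Cohort size.
#' @param bmi_range BMI interval (kg/m^2).
#' @param city_levels City factor levels; samples are balanced across them.
#' @param a0,a1 Presence-model intercept and BMI slope (logit scale).
#' @param b0,b1 Positive-part intercept and BMI slope (log scale).
#' @param gamma_shape Gamma shape of the positive part (> 0).
#' @param city_effects_bin,city_effects_cont Per-city offsets added to the
#'   two linear predictors (recycled over `city_levels`).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 114L,
                        bmi_range = c(18.5, 40),
                        city_levels = c("Bogota", "Medellin", "Cali",
                                        "Barranquilla", "Bucaramanga"),
                        a0 = 6, a1 = -0.165,
                        b0 = 1, b1 = -0.017,
                        gamma_shape = 3,
                        city_effects_bin = c(0, 0.3, -0.3, 0.15, -0.15),
                        city_effects_cont = c(0, 0.1, -0.1, 0.05, -0.05),
                        seed = 1L) {
  stopifnot(n_samples >= 1, gamma_shape > 0, length(bmi_range) == 2,
            bmi_range[1] < bmi_range[2])
  structure(list(
    n_samples = as.integer(n_samples), bmi_range = bmi_range,
    city_levels = city_levels, a0 = a0, a1 = a1, b0 = b0, b1 = b1,
    gamma_shape = gamma_shape,
    city_effects_bin = rep_len(city_effects_bin, length(city_levels)),
    city_effects_cont = rep_len(city_effects_cont, length(city_levels)),
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Simulate a cohort with hurdle-structured Shannon diversity
#'
#' Presence `z_i ~ Bernoulli(plogis(a0 + a1 bmi_i + city offset))`; given
#' presence, `H_i ~ Gamma(shape, mean = exp(b0 + b1 bmi_i + city offset))`;
#' `H_i = 0` otherwise. BMI is uniform over `bmi_range`; cities balanced.
#'
#' @param spec A [cohort_spec()].
#' @return List with `metadata` (sample_id, bmi, bmi_category, city, sex,
#'   age) and `shannon` (named numeric, nats).
#' @export
simulate_diversity_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  bmi <- stats::runif(n, spec$bmi_range[1], spec$bmi_range[2])
  city <- rep_len(spec$city_levels, n)[sample.int(n)]
  ci <- match(city, spec$city_levels)
  eta_bin <- spec$a0 + spec$a1 * bmi + spec$city_effects_bin[ci]
  z <- stats::rbinom(n, 1L, stats::plogis(eta_bin))
  mu <- exp(spec$b0 + spec$b1 * bmi + spec$city_effects_cont[ci])
  h <- ifelse(z == 1L,
              stats::rgamma(n, shape = spec$gamma_shape,
                            rate = spec$gamma_shape / mu),
              0)
  metadata <- data.frame(
    sample_id = ids, bmi = bmi, bmi_category = classify_bmi(bmi),
    city = city,
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = sample(18:62, n, replace = TRUE),
    stringsAsFactors = FALSE)
  list(metadata = metadata, shannon = stats::setNames(h, ids))
}

#' Simulate an ASV count cohort with known fold changes
#'
#' Counts are negative-binomial around per-category means. Each ASV j has a
#' base relative abundance (log-normal) and a fold change `fold_changes[j]`
#' interpreted as obese-vs-lean ratio; overweight samples sit at the
#' geometric midpoint. When `richness_slope < 0` the expected number of
#' non-zero ASVs per sample decreases with BMI (presence thinning on the
#' logit scale per BMI unit).
#'
#' @param n_samples,n_asvs Dimensions.
#' @param richness_slope Per-BMI-unit logit slope of ASV presence (0 = all
#'   ASVs present in all samples).
#' @param fold_changes Numeric vector (recycled to `n_asvs`): obese/lean
#'   mean ratio per ASV.
#' @param lib_meanlog,lib_sdlog Log-normal library-size parameters.
#' @param dispersion NB dispersion (`1/size`).
#' @param taxonomy Optional taxonomy labels per ASV.
#' @param seed RNG seed.
#' @return List with `counts` (samples x ASVs integer matrix), `metadata`,
#'   `taxonomy` (named character) and `truth` (data.frame asv_id,
#'   fold_change).
#' @export
simulate_count_cohort <- function(n_samples = 60L, n_asvs = 200L,
                                  richness_slope = 0,
                                  fold_changes = 1,
                                  lib_meanlog = log(2e4), lib_sdlog = 0.3,
                                  dispersion = 0.5,
                                  taxonomy = NULL, seed = 1L) {
  if (n_asvs < 2L) stop("n_asvs must be >= 2")
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n_samples))
  asvs <- sprintf("ASV%04d", seq_len(n_asvs))
  fold_changes <- rep_len(fold_changes, n_asvs)
  bmi <- stats::runif(n_samples, 18.5, 40)
  cat3 <- classify_bmi(bmi)
  x <- c(lean = 0, overweight = 0.5, obese = 1)[cat3]
  base_p <- stats::rlnorm(n_asvs, meanlog = 0, sdlog = 1)
  base_p <- base_p / sum(base_p)
  lib <- stats::rlnorm(n_samples, lib_meanlog, lib_sdlog)
  mu <- outer(rep(1, n_samples), base_p) *
    exp(outer(x, log(fold_changes))) * lib
  if (richness_slope != 0) {
    p_pres <- stats::plogis(stats::qlogis(0.9) +
                              richness_slope * (bmi - mean(bmi)))
    pres <- matrix(stats::rbinom(n_samples * n_asvs, 1L,
                                 rep(p_pres, n_asvs)),
                   n_samples, n_asvs)
    mu <- mu * pres
  }
  counts <- matrix(stats::rnbinom(n_samples * n_asvs, mu = as.vector(mu),
                                  size = 1 / dispersion),
                   n_samples, n_asvs, dimnames = list(ids, asvs))
  storage.mode(counts) <- "integer"
  if (is.null(taxonomy)) {
    taxonomy <- sprintf(
      "d__Bacteria;p__Bacillota_A;c__Clostridia;o__SimOrder;f__SimFamily;g__Genus%02d;s__",
      (seq_len(n_asvs) - 1L) %% 8L + 1L)
  }
  metadata <- data.frame(
    sample_id = ids, bmi = bmi, bmi_category = cat3,
    city = rep_len(c("Bogota", "Medellin", "Cali", "Barranquilla",
                     "Bucaramanga"), n_samples)[sample.int(n_samples)],
    sex = sample(c("female", "male"), n_samples, replace = TRUE),
    age = sample(18:62, n_samples, replace = TRUE),
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata,
       taxonomy = stats::setNames(rep_len(taxonomy, n_asvs), asvs),
       truth = data.frame(asv_id = asvs, fold_change = fold_changes,
                          stringsAsFactors = FALSE))
}

#' Simulate an orthologue CDS family with designated conserved windows
#'
#' Builds a gap-free family of same-length CDSs from a random ancestor:
#' positions inside each conserved window vary only within the window's
#' IUPAC pattern (so the minimal-code consensus of the family reproduces
#' the pattern), all other positions mutate independently with probability
#' `p_var`. In-frame stop codons are repaired outside the windows, and the
#' window patterns are checked to admit no stop codon. The translated rows
#' form a gap-free protein "alignment", mirroring an orthologue set aligned
#' without indels.
#'
#' @param n_rows Number of orthologues.
#' @param n_codons CDS length in codons.
#' @param conserved List of `list(start, iupac)` with `start` a 1-based
#'   nucleotide position and `iupac` the window's allowed-variation
#'   pattern.
#' @param p_var Per-position substitution probability outside windows.
#' @param seed RNG seed.
#' @return List: `cds` (named vector), `protein_msa` (named, gap-free),
#'   `truth` (data.frame start, iupac).
#' @export
simulate_orthologue_family <- function(n_rows = 12L, n_codons = 120L,
                                       conserved = list(), p_var = 0.25,
                                       seed = 1L) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  len <- 3L * n_codons
  in_window <- rep(FALSE, len)
  for (w in conserved) {
    iu <- normalize_sequence(w$iupac)
    idx <- w$start:(w$start + nchar(iu) - 1L)
    if (max(idx) > len) stop("conserved window out of range")
    in_window[idx] <- TRUE
    # codons fully covered by the window must be stop-free in every
    # realization (partially covered codons are repaired via their free
    # positions below)
    first_codon <- (w$start - 1L) %/% 3L
    last_codon <- (idx[length(idx)] - 1L) %/% 3L
    for (cd in first_codon:last_codon) {
      cols <- (3L * cd + 1L):(3L * cd + 3L)
      if (!all(cols >= w$start & cols <= idx[length(idx)])) next
      sets <- lapply(cols, function(p)
        IUPAC_SETS[[substr(iu, p - w$start + 1L, p - w$start + 1L)]])
      combos <- expand.grid(sets, stringsAsFactors = FALSE)
      codons <- apply(combos, 1, paste, collapse = "")
      if (any(codons %in% stops)) {
        stop("conserved window pattern admits a stop codon")
      }
    }
  }
  draw_base <- function() sample(c("A", "C", "G", "T"), 1L)
  draw_windows <- function(v) {
    for (w in conserved) {
      iu <- normalize_sequence(w$iupac)
      for (k in seq_len(nchar(iu))) {
        s <- IUPAC_SETS[[substr(iu, k, k)]]
        v[w$start + k - 1L] <- if (length(s) == 1L) s else sample(s, 1L)
      }
    }
    v
  }
  ancestor <- draw_windows(strsplit(random_dna(len), "", fixed = TRUE)[[1]])
  fix_stops <- function(v) {
    for (cd in seq_len(n_codons)) {
      cols <- (3L * cd - 2L):(3L * cd)
      if (paste(v[cols], collapse = "") %in% stops) {
        free <- cols[!in_window[cols]]
        if (!length(free)) stop("conserved window admits a stop codon")
        repeat {
          v[free[1]] <- draw_base()
          if (!paste(v[cols], collapse = "") %in% stops) break
        }
      }
    }
    v
  }
  ancestor <- fix_stops(ancestor)
  rows <- stats::setNames(vector("character", n_rows),
                          sprintf("orth%02d", seq_len(n_rows)))
  for (r in seq_len(n_rows)) {
    v <- ancestor
    mut <- !in_window & stats::runif(len) < p_var
    v[mut] <- vapply(seq_len(sum(mut)), function(i) draw_base(),
                     character(1))
    v <- fix_stops(draw_windows(v))
    rows[r] <- paste(v, collapse = "")
  }
  truth <- if (length(conserved)) {
    data.frame(start = vapply(conserved, `[[`, numeric(1), "start"),
               iupac = vapply(conserved, function(w)
                 normalize_sequence(w$iupac), character(1)),
               stringsAsFactors = FALSE)
  } else data.frame(start = numeric(0), iupac = character(0))
  list(cds = rows,
       protein_msa = vapply(rows, translate_cds, character(1)),
       truth = truth)
}
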