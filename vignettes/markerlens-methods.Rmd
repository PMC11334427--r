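---
title: "markerlens: models, synthetic worlds, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{markerlens: models, synthetic worlds, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`markerlens` packages the methodology for studying fine-grained
gut-microbiome diversity with fast-evolving single-copy marker genes
(*dnaK*, *gyrB*) as alternatives to the 16S rRNA gene. This vignette is
the package's own account of the science it implements: the models and
their assumptions, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical
decisions a maintainer would want written down. It states no empirical
result that the test suite does not itself compute.

## 1. Sequence distances: the K80 model

Pairwise marker divergence is measured with the Kimura (1980)
two-parameter model. Over the aligned, ungapped, unambiguous columns of a
pair, let `P` be the proportion differing by a transition (A↔G, C↔T) and
`Q` by a transversion; then

    d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)   substitutions/site.

Assumptions: sites evolve independently under a stationary, reversible
process with equal base frequencies and a single
transition/transversion ratio; no rate variation among sites. These are
the assumptions of the upstream literature this mirrors, not claims about
real loci.

Numerical choices:

* Columns with a gap or IUPAC ambiguity code in either sequence are
  excluded from `n_sites`; `p_identity = 1 - P - Q` is therefore a
  gap-excluded identity. The source analyses plot "sequence identity"
  without defining gap treatment; gap exclusion is the choice least
  sensitive to alignment end effects.
* When `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the log is undefined: the pair
  is *saturated*. It is retained with identity only (`d_k80 = NA`,
  `saturated = TRUE`) rather than dropped or clamped, so downstream joins
  can count such pairs.
* A large-sample standard error (the standard delta-method expression in
  `c1 = 1/(1-2P-Q)`, `c2 = 1/(1-2Q)`, `c3 = (c1+c2)/2`) is attached to
  every estimate; the simulator-consistency tests consume it.

`evolve_k80()` simulates the same process forward, parameterized directly
by branch length (expected substitutions/site), not rate × time, so the
quantity simulated is exactly the quantity the estimator recovers. Its
transition probabilities are the closed forms
`P(t) = 1/4 + 1/4 e1 - 1/2 e2`, `Q(t)/2 = 1/4 - 1/4 e1` with
`e1 = exp(-4d/(k+2))`, `e2 = exp(-2d(k+1)/(k+2))`; the test suite checks
the realized site process against these within Monte-Carlo error.

## 2. Cross-marker regression

`compare_markers()` inner-joins pairwise identities of two markers on the
unordered genome-pair key and fits ordinary least squares of the y-marker
identity on the x-marker identity. Two caveats are deliberate mirrors of
the field's practice and are recorded in the result object: pairs sharing
a genome are not independent, and the regression is run on p-identity by
default (a flag switches to `1 - d` model-corrected values; the upstream
figure's axis convention is ambiguous). `map_identity()` linearly maps an
identity threshold through the fit, clipped to [0, 1] — the operation
behind statements like "97% on 16S corresponds to ~84% on *dnaK*".

A design note on the consistency test: a star cohort in which every taxon
sits at the *same* distance from the ancestor gives pairwise identities
that vary only by noise, so r² would be meaningless. The acceptance
fixture therefore spreads per-taxon divergences over [0.005, 0.045]
(pairwise mean 0.05 on the slow marker) — the stated "divergence 0.05"
world with the spread needed for a regression to exist.

## 3. Marker location

`locate_marker()` is a deliberately simple surrogate for BLASTn/tBLASTn:
repeated local alignment (Biostrings) of the query against both strands
(nucleotide mode) or against all six reading-frame translations under
BLOSUM62 (protein mode), with accepted hits masked and the scan repeated
to find additional copies. Hits must reach `min_identity` 0.5 over
`min_coverage` 0.5 of the query — permissive thresholds chosen for recall
(the upstream search ran with no e-value cutoff); copy number is the
count of surviving non-overlapping hits, which feeds
`single_copy_fraction()`. BLAST statistics (bit scores, e-values) are a
non-goal. One behavioral consequence worth knowing: at nonzero divergence
a local alignment may trim mismatching locus ends, so hit coordinates can
differ from the simulated truth by a few bp; the tests assert exactness
only for exact embedded queries.

## 4. In-silico PCR

Degenerate-primer matching uses a conservative *subset rule*: a genome
position matches a primer code only if the genome code's base set is a
subset of the primer's. An `N` in the genome therefore never silently
matches a concrete primer base, while a fully degenerate primer position
matches anything. For windows over concrete bases this rule provably
equals the minimum Hamming distance over the primer's full expansion (the
test oracle enumerates expansions up to degeneracy 256, which covers all
four published primers).

`find_amplicons()` scans both orientations, requires each primer to pass
`max_mismatch` (default 6, read as *per primer* — the upstream "up to six
mismatches for both primers" is ambiguous; the per-primer reading is the
one under which its coverage numbers are reproducible at all), counts
mismatches uniformly along the primer (no 3'-anchor rule, matching
ipcress's flat allowance), and reports hits whose **outer 5'→5' span**
falls in the product window (defaults 75–150 bp dnaK, 800–1100 bp gyrB).
The outer-span convention is forced by arithmetic: the gyrB window
(800–1100) can only contain the ~600 bp insert plus primer footprints if
footprints count; a `span = "inner"` flag provides the other convention.
All alternative hits are reported — a random background can legitimately
carry a 6-mismatch site, and suppressing it would misrepresent what a
primer pair would amplify.

`extract_inner_region()` mirrors the read-processing step that trims
primer footprints from merged amplicon reads: leftmost acceptable forward
site, rightmost acceptable reverse site, sequence strictly between. On
the dnaK pair the simulated locus yields an 88 bp inner fragment — the
coordinate arithmetic (154 − 66) behind the "~90 bp" fragment the primer
names imply.

## 5. Primer design

The design path starts from a protein orthologue alignment plus the
source CDSs (orthologue retrieval is out of scope).
`back_translate()` rebuilds the codon alignment (amino acid → source
codon, `-` → `---`) and validates every row (CDS length 3× the ungapped
protein; translation must match — errors name the row).
`consensus_degenerate()` uses the *minimal covering code* per column
rather than frequency thresholding, because that is the rule that
reproduces fully degenerate published primers; a `min_freq` flag can
exclude rare variants, in which case window conservation (fraction of
rows matched with zero mismatches) becomes informative.
`primer_metrics()` reports degeneracy (product of code-set sizes),
expected %GC, and Wallace-rule Tm `2(A+T) + 4(G+C)` on expected counts —
the paper names no Tm formula, and Wallace is the standard for ≤ 25-mers
while remaining well-defined for degenerate codes via expectation.
`scan_windows()` (default window 21 bp, the published primer length)
enumerates gap-free windows under a degeneracy cap; `select_pairs()`
filters ordered pairs by outer product span, |ΔTm| and |ΔGC|, and sorts
by combined degeneracy. The design-consistency property — every selected
pair, pushed through `find_amplicons()` on the ungapped source CDSs,
amplifies at least the conserved fraction of rows with zero mismatches —
is the acceptance check tying this module to the PCR module.

## 6. The diversity–phenotype stage

Order of operations is fixed as **filter → rarefy → subset → Shannon**:
samples then ASVs with totals below 100 are dropped (strict `< 100`,
matching the stated exclusion), the whole table is rarefied once to the
global minimum depth, and per-taxon Shannon indices (natural log) are
computed on the column subset. The upstream text does not say whether
subsetting preceded rarefaction; rarefying the whole table once keeps all
taxa on a common depth and is the default, with per-subset rarefaction
available. One rarefaction draw per seed (no averaging), as upstream.

The association model is a two-part hurdle, fit by `stats::glm` (IRLS,
epsilon 1e-8, ≤ 100 iterations):

* `glm.bin`: 1{H > 0} ~ BMI + city, binomial, logit link. Taxa absent
  from a sample contribute structural zeros, which is why zeros are
  modelled separately rather than log-shifted.
* `glm.cont`: H ~ BMI + city on the H > 0 subset, Gamma, log link,
  dispersion from Pearson residuals (the default of the GLM software the
  source used).

The reported p is a normal-approximation Wald test of the BMI
coefficient. Degenerate designs are *flagged*, not errored: all-zero or
all-positive presence makes `glm.bin` non-estimable; fewer positive
samples than parameters + 2 makes `glm.cont` non-estimable;
quasi-separation (non-convergence, |beta| > 50, or fitted probabilities
within 1e-10 of 0/1) clears the `converged` flag. BH-FDR is applied
within (marker × rank × model) — upstream reports family-level and
genus-level FDRs separately, and pooling across ranks would change the
adjustment — with significance at FDR < 0.20.

`greedy_cluster()` (abundance-ordered, ties lexicographic; first centroid
at or above the threshold wins) uses alignment-length identity — gap
columns count against identity — so that at threshold 1.0 distinct
sequences always form the identity partition and the sensitivity suite's
`t = 1` run reproduces the unclustered fits byte-identically. (The
gap-excluded identity used for K80 would merge indel-only variants at
t = 1.) Collapsed tables keep centroid columns in original order for the
same reason.

## 7. Differential abundance

Size factors are the median-of-ratios: reference ASVs are those with
all-positive counts, `g_j` their geometric means, and
`s_i = median_j(c_ij / g_j)`. When no ASV is all-positive the function
errors, advising the zero-skipping pseudo-reference fallback
(`fallback = TRUE`); an error rather than a silent fallback because the
two estimators are not interchangeable on sparse tables. Size factors
are defined only up to a common scale — properties are asserted on
ratios.

The test is a plain per-ASV negative-binomial GLM with log link and
`offset(log s_i)` on the BMI-category factor, dispersion per ASV by
maximum likelihood (`MASS::glm.nb`), Wald test on the contrast
coefficient, BH-FDR within contrast, three pairwise contrasts
(lean–obese, lean–overweight, overweight–obese). **Deviation, by
design:** no dispersion shrinkage, no LFC shrinkage, no Cook's/independent
filtering — the DESeq2 refinements matter for ranking real, noisy data,
but the upstream ASV lists are external-data results that are not
reproduction targets here, and the plain estimator is the honest null for
calibration tests (type-I fraction and Wald-p uniformity are asserted in
the suite). The output header records the deviation. City was not added
to the abundance design because the upstream design formula is unstated;
the contrast-on-category model is the minimal reading.

## 8. The synthetic world

Generator defaults are fixed once and are the conditions the tests run
under; they are not tuned against outcomes.

* **Marker genomes**: independent random background per taxon (so
  location tests cannot be rescued by shared background), exactly one
  locus per marker on a random strand, coordinates and strand in a truth
  table. Markers evolve from a shared ancestor at
  `divergence × rate_multiplier`; the 16S-like reference rate is 1.
  Primer sites are concrete realizations of the degenerate primer with
  mismatches injected only at non-degenerate positions, and are not
  further mutated — injected counts are therefore *exact* realized
  counts, making the ≤ 6-mismatch threshold exactly testable.
* **Diversity cohorts**: BMI ~ U[18.5, 40] (spanning the lean /
  overweight / obese strata above the underweight exclusion), five city
  levels mirroring the cohort design with modest baseline offsets (±0.3
  logit, ±0.1 log), presence logit `6 - 0.165·BMI`, positive part
  `exp(1 - 0.017·BMI)` with Gamma shape 3. The slopes are the published
  effect sizes used as simulation truths; intercepts were chosen once so
  that both model parts are informative across the BMI range (presence
  ~95% at BMI 18.5 falling to ~35% at 40). n = 114 by default (the
  cohort's size); recovery tests use n = 2000 as stated.
* **Count cohorts**: log-normal base abundances and library sizes
  (meanlog log 2e4, sdlog 0.3), NB dispersion 0.5, fold changes applied
  as obese/lean ratios with overweight at the geometric midpoint,
  optional presence thinning for a richness–BMI trend.

What the generators do **not** emulate: sequencing error and chimeras,
taxonomic misclassification, compositionality constraints, indel
evolution, rate variation among sites, phylogenetic correlation beyond
the star tree, and covariate confounding other than the city offsets. A
green test therefore establishes that the estimators recover the stated
generative truth — not that the upstream biological findings are correct.

## 9. Known limitations

* `locate_marker` is not BLAST: no seeding heuristics, no e-values; on
  large genomes it is O(query × genome) per strand. Fine for the
  synthetic scale it serves.
* The hurdle model treats rarefied Shannon values as Gamma-distributed;
  real Shannon indices are bounded by log richness and the Gamma is an
  approximation adopted from the upstream analysis, not defended here.
* OLS on pairwise identities ignores pair non-independence (shared
  genomes); slopes are descriptive.
* The NB test's plain dispersion estimate is anti-conservative for very
  small groups; the suite calibrates it at n = 60 per the stated world.
* Config files are flat YAML with a fixed schema; unknown keys are
  usage errors by design (silent typos in analysis configs are worse).
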