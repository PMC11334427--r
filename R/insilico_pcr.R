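# In-silico PCR: degenerate-primer matching under the subset rule, amplicon
# calling under mismatch and product-length constraints, per-family
# taxonomic coverage, and inner-region extraction.

#' Construct a degenerate primer
#'
#' @param name Primer name.
#' @param iupac IUPAC nucleotide string (5'->3').
#' @return A `degenerate_primer` list with `name`, `iupac`, `degeneracy`.
#' @export
degenerate_primer <- function(name, iupac) {
  iupac <- normalize_sequence(iupac)
  structure(list(name = name, iupac = iupac,
                 degeneracy = iupac_degeneracy(iupac)),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("%s: %s (degeneracy %d)\n", x$name, x$iupac, x$degeneracy))
  invisible(x)
}

#' The published primer pairs
#'
#' The dnaK pair (F_Ru_45_65 / R_Ru_154_174) and the gyrB pair
#' (F_La_334_354 / R_La_816_836), as used for the taxonomic-coverage
#' analysis, plus the 16S V4 pair (F515/R806).
#'
#' @return Named list of lists with `fwd` and `rev` [degenerate_primer()]s
#'   and the default product-length window.
#' @export
published_primers <- function() {
  list(
    dnaK = list(fwd = degenerate_primer("F_Ru_45_65", "YGTNGCNGTNATGGARGGCGG"),
                rev = degenerate_primer("R_Ru_154_174", "NGCCTGNCKYTTTGCVACCTG"),
                window = c(75L, 150L)),
    gyrB = list(fwd = degenerate_primer("F_La_334_354", "GGHGGAGGATAYAAGGTATCC"),
                rev = degenerate_primer("R_La_816_836", "TRTANGAATCRTTRTGCTGC"),
                window = c(800L, 1100L)),
    rrn16S = list(fwd = degenerate_primer("F515", "GTGCCAGCMGCCGCGGTAA"),
                  rev = degenerate_primer("R806", "GGACTACHVGGGTWTCTAAT"),
                  window = c(200L, 300L)))
}

.primer_iupac <- function(p) {
  if (inherits(p, "degenerate_primer")) p$iupac else normalize_sequence(p)
}

#' Count primer-window mismatches under the subset rule
#'
#' @param primer A [degenerate_primer()] or IUPAC string.
#' @param window Genome window of the same length.
#' @return Number of positions failing [iupac_match()].
#' @export
count_mismatches <- function(primer, window) {
  p <- .primer_iupac(primer)
  w <- normalize_sequence(window)
  if (nchar(p) != nchar(w)) {
    stop("window length ", nchar(w), " != primer length ", nchar(p))
  }
  pv <- strsplit(p, "", fixed = TRUE)[[1]]
  wv <- strsplit(w, "", fixed = TRUE)[[1]]
  sum(!.iupac_compat[cbind(pv, wv)])
}

# mismatch count for every start offset of `primer` along `seq_str`
# (0-based offsets 0 .. G-L). O(G*L) vectorized over offsets.
mismatch_profile <- function(primer, seq_str) {
  p <- strsplit(.primer_iupac(primer), "", fixed = TRUE)[[1]]
  s <- strsplit(seq_str, "", fixed = TRUE)[[1]]
  L <- length(p); G <- length(s)
  if (G < L) return(integer(0))
  n_off <- G - L + 1L
  mm <- integer(n_off)
  idx <- seq_len(n_off)
  for (j in seq_len(L)) {
    mm <- mm + !.iupac_compat[cbind(p[j], s[idx + j - 1L])]
  }
  mm
}

#' Find amplicons of a degenerate primer pair in a genome
#'
#' Scans both orientations: the forward primer is matched on a strand and
#' the reverse complement of the reverse primer downstream on the same
#' strand. A hit is reported when each primer has at most `max_mismatch`
#' mismatches (per primer, counted uniformly along its length) and the
#' product length lies in `[min_len, max_len]`. Product length is the outer
#' 5'->5' span including both primer footprints (set `span = "inner"` for
#' the insert-only convention). Overlapping alternative hits are all
#' reported, sorted by `fwd_start`.
#'
#' @param genome_seq Genome nucleotide string.
#' @param fwd,rev [degenerate_primer()]s or IUPAC strings (both 5'->3' as
#'   synthesized).
#' @param min_len,max_len Product-length window in bp.
#' @param max_mismatch Per-primer mismatch allowance (default 6).
#' @param genome_id Id carried into the result.
#' @param span `"outer"` (default) or `"inner"` length convention.
#' @return Data frame: genome_id, fwd_start, rev_end (0-based half-open
#'   outer span on the forward strand), product_length, mismatches_fwd,
#'   mismatches_rev, orientation (`+` if the forward primer sits on the
#'   forward strand).
#' @export
find_amplicons <- function(genome_seq, fwd, rev, min_len, max_len,
                           max_mismatch = 6L, genome_id = "genome",
                           span = c("outer", "inner")) {
  span <- match.arg(span)
  if (min_len > max_len) stop("min_len > max_len")
  genome_seq <- normalize_sequence(genome_seq)
  f <- .primer_iupac(fwd)
  r <- .primer_iupac(rev)
  G <- nchar(genome_seq)
  Lf <- nchar(f); Lr <- nchar(r)
  if (Lf >= G || Lr >= G) return(.empty_amplicons())
  scan_one <- function(subj, orientation) {
    fp <- mismatch_profile(f, subj)
    rp <- mismatch_profile(revcomp(r), subj)
    fi <- which(fp <= max_mismatch)        # 1-based offsets
    ri <- which(rp <= max_mismatch)
    if (!length(fi) || !length(ri)) return(NULL)
    out <- list()
    for (i in fi) {
      j <- ri[ri >= i + Lf]                # rev site fully downstream
      if (!length(j)) next
      outer_len <- (j + Lr - 1L) - (i - 1L)
      plen <- if (span == "outer") outer_len else outer_len - Lf - Lr
      ok <- plen >= min_len & plen <= max_len
      if (!any(ok)) next
      j <- j[ok]; plen <- plen[ok]; olen <- outer_len[ok]
      # forward-strand outer span
      if (orientation == "+") {
        fs <- rep(i - 1L, length(j)); re <- (j + Lr - 1L)
      } else {
        fs <- G - (j + Lr - 1L); re <- rep(G - (i - 1L), length(j))
      }
      out[[length(out) + 1L]] <- data.frame(
        genome_id = genome_id, fwd_start = fs, rev_end = re,
        product_length = plen,
        mismatches_fwd = fp[i], mismatches_rev = rp[j],
        orientation = orientation, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  res <- rbind(scan_one(genome_seq, "+"),
               scan_one(revcomp(genome_seq), "-"))
  if (is.null(res)) return(.empty_amplicons())
  res[order(res$fwd_start, res$rev_end), , drop = FALSE]
}

.empty_amplicons <- function() {
  data.frame(genome_id = character(0), fwd_start = integer(0),
             rev_end = integer(0), product_length = integer(0),
             mismatches_fwd = integer(0), mismatches_rev = integer(0),
             orientation = character(0), stringsAsFactors = FALSE)
}

#' Taxonomic coverage of a primer pair
#'
#' For a set of species-representative genomes, the fraction of species per
#' (order, family) with at least one predicted amplicon.
#'
#' @param genomes Data frame with columns `id`, `sequence`, `taxonomy`
#'   (GTDB-style labels).
#' @param fwd,rev Primers.
#' @param min_len,max_len,max_mismatch Passed to [find_amplicons()].
#' @return Data frame (order, family, n_species, n_hit, coverage), sorted
#'   by n_hit decreasing. Coverage is exact (rounded only at presentation).
#' @export
taxonomic_coverage <- function(genomes, fwd, rev, min_len, max_len,
                               max_mismatch = 6L) {
  if (nrow(genomes) == 0L) stop("empty genome set")
  hit <- vapply(seq_len(nrow(genomes)), function(i) {
    nrow(find_amplicons(genomes$sequence[i], fwd, rev, min_len, max_len,
                        max_mismatch, genome_id = genomes$id[i])) > 0L
  }, logical(1))
  ord <- taxonomy_rank(genomes$taxonomy, "o")
  fam <- taxonomy_rank(genomes$taxonomy, "f")
  agg <- stats::aggregate(hit, by = list(order = ord, family = fam),
                          FUN = function(z) c(n = length(z), h = sum(z)))
  out <- data.frame(order = agg$order, family = agg$family,
                    n_species = agg$x[, "n"], n_hit = agg$x[, "h"],
                    stringsAsFactors = FALSE)
  out$coverage <- out$n_hit / out$n_species
  out[order(-out$n_hit, out$family), , drop = FALSE]
}

#' Extract the inner sequence between primer sites on a read
#'
#' Locates the forward primer (leftmost occurrence within the mismatch
#' allowance) and the reverse complement of the reverse primer (rightmost
#' occurrence starting at or after the forward site's end) and returns the
#' sequence strictly between them; `NA` when either primer is not found.
#'
#' @param read Amplicon-oriented sequence (forward primer near the 5' end).
#' @param fwd,rev Primers (5'->3' as synthesized).
#' @param max_mismatch Per-primer mismatch allowance.
#' @return Inner sequence, or `NA_character_` for an unmatched read.
#' @export
extract_inner_region <- function(read, fwd, rev, max_mismatch = 6L) {
  read <- normalize_sequence(read)
  f <- .primer_iupac(fwd)
  r <- revcomp(.primer_iupac(rev))
  fp <- mismatch_profile(f, read)
  rp <- mismatch_profile(r, read)
  fi <- which(fp <= max_mismatch)
  if (!length(fi)) return(NA_character_)
  i <- fi[1]
  ri <- which(rp <= max_mismatch)
  ri <- ri[ri >= i + nchar(f)]
  if (!length(ri)) return(NA_character_)
  j <- ri[length(ri)]
  substr(read, i + nchar(f), j - 1L)
}
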