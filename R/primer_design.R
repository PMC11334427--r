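# Codon-aware primer design: back-translation of a protein orthologue
# alignment onto source CDSs, minimal-code degenerate consensus, conserved
# window scanning, and primer-pair selection with matched %GC and Tm.

GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

translate_cds <- function(cds) {
  cds <- normalize_sequence(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- GENETIC_CODE_TABLE[codons]
  if (anyNA(aa)) stop("untranslatable codon: ",
                      codons[which(is.na(aa))[1]])
  paste(aa, collapse = "")
}

#' Back-translate a protein alignment onto its source CDSs
#'
#' Each amino acid is replaced by its source codon; protein gaps become
#' `---`, so the codon alignment keeps the protein alignment's structure
#' (width exactly 3x). Each row is validated: the CDS must be 3x the
#' ungapped protein length and translate to it under the standard code.
#'
#' @param protein_msa Named character vector of aligned amino-acid rows
#'   (gaps as `-`), all the same width.
#' @param cds_map Named character vector of CDS nucleotide sequences keyed
#'   by row id.
#' @return Named character vector: the codon alignment.
#' @export
back_translate <- function(protein_msa, cds_map) {
  ids <- names(protein_msa)
  if (is.null(ids)) stop("protein_msa must be named")
  if (length(unique(nchar(protein_msa))) != 1L) {
    stop("protein alignment rows have unequal widths")
  }
  out <- stats::setNames(character(length(ids)), ids)
  for (id in ids) {
    row <- toupper(protein_msa[[id]])
    if (!id %in% names(cds_map)) stop("no CDS for row '", id, "'")
    cds <- normalize_sequence(cds_map[[id]])
    ungapped <- gsub("-", "", row, fixed = TRUE)
    if (nchar(cds) != 3L * nchar(ungapped)) {
      stop("row '", id, "': CDS length ", nchar(cds),
           " != 3 x ungapped protein length ", nchar(ungapped))
    }
    if (translate_cds(cds) != ungapped) {
      stop("row '", id, "': CDS does not translate to the protein row")
    }
    chars <- strsplit(row, "", fixed = TRUE)[[1]]
    codons <- character(length(chars))
    ci <- 0L
    for (k in seq_along(chars)) {
      if (chars[k] == "-") {
        codons[k] <- "---"
      } else {
        codons[k] <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
        ci <- ci + 1L
      }
    }
    out[id] <- paste(codons, collapse = "")
  }
  out
}

#' Minimal-code degenerate consensus of an alignment slice
#'
#' Per column, the smallest IUPAC code covering all observed bases with
#' frequency above `min_freq` (default 0: cover every observed base, which
#' reproduces fully degenerate published-primer style consensi). A column
#' containing a gap in any row invalidates the window.
#'
#' @param rows Character vector of equal-length nucleotide strings (one
#'   window per row).
#' @param min_freq Minimum base frequency to be covered (0 = cover all).
#' @return IUPAC consensus string, or `NA_character_` when the slice
#'   contains a gap (window-invalid signal).
#' @export
consensus_degenerate <- function(rows, min_freq = 0) {
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("rows have unequal widths")
  mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  if (any(mat == "-")) return(NA_character_)
  codes <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[, j]) / nrow(mat)
    bases <- names(tab)[tab > min_freq]
    if (length(bases) == 0L) bases <- names(tab)[which.max(tab)]
    iupac_code_for(bases)
  }, character(1))
  paste(codes, collapse = "")
}

#' Degeneracy, %GC and melting temperature of a degenerate primer
#'
#' GC fraction is the mean over positions of the expected GC content of
#' each code (`|set n {G,C}| / |set|`). Tm uses the Wallace rule
#' `2(A+T) + 4(G+C)` on expected counts — standard for short (<= 25 bp)
#' oligos and well-defined for degenerate codes via expectation.
#'
#' @param iupac IUPAC string, length >= 10.
#' @return List: `degeneracy`, `gc_fraction`, `tm` (degrees C).
#' @export
primer_metrics <- function(iupac) {
  iupac <- normalize_sequence(iupac)
  if (nchar(iupac) < 10L) stop("primer shorter than 10 bp")
  sets <- IUPAC_SETS[strsplit(iupac, "", fixed = TRUE)[[1]]]
  gc_pos <- vapply(sets, function(s)
    length(intersect(s, c("G", "C"))) / length(s), numeric(1))
  e_gc <- sum(gc_pos)
  e_at <- length(sets) - e_gc
  list(degeneracy = prod(lengths(sets)),
       gc_fraction = mean(gc_pos),
       tm = 2 * e_at + 4 * e_gc)
}

#' Scan a codon alignment for conserved primer windows
#'
#' Every gap-free window of `window_len` columns whose minimal-code
#' consensus has degeneracy at most `max_degeneracy` and whose conservation
#' (fraction of rows matching the consensus with zero mismatches) is at
#' least `min_conservation`. Sorted by (degeneracy asc, conservation desc,
#' start_col asc).
#'
#' @param codon_aln Named character vector (from [back_translate()] or any
#'   equal-width nucleotide alignment).
#' @param window_len Window length in bp (default 21, the published primer
#'   length).
#' @param max_degeneracy Maximum consensus degeneracy.
#' @param min_conservation Minimum fraction of rows matched exactly.
#' @param min_freq Passed to [consensus_degenerate()].
#' @return Data frame of candidates: start_col (0-based alignment column),
#'   iupac, degeneracy, gc_fraction, tm, conservation.
#' @export
scan_windows <- function(codon_aln, window_len = 21L, max_degeneracy = 256L,
                         min_conservation = 0.9, min_freq = 0) {
  w <- unique(nchar(codon_aln))
  if (length(w) != 1L) stop("alignment rows have unequal widths")
  if (window_len > w) stop("window longer than alignment")
  res <- list()
  for (s in seq_len(w - window_len + 1L)) {
    slice <- substr(codon_aln, s, s + window_len - 1L)
    cons <- consensus_degenerate(slice, min_freq = min_freq)
    if (is.na(cons)) next
    deg <- iupac_degeneracy(cons)
    if (deg > max_degeneracy) next
    conserv <- mean(vapply(slice, function(row)
      count_mismatches(cons, row) == 0L, logical(1)))
    if (conserv < min_conservation) next
    met <- primer_metrics(cons)
    res[[length(res) + 1L]] <- data.frame(
      start_col = s - 1L, iupac = cons, degeneracy = deg,
      gc_fraction = met$gc_fraction, tm = met$tm, conservation = conserv,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(start_col = integer(0), iupac = character(0),
                      degeneracy = integer(0), gc_fraction = numeric(0),
                      tm = numeric(0), conservation = numeric(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$degeneracy, -out$conservation, out$start_col), ,
      drop = FALSE]
}

#' Select primer pairs with matched Tm and %GC
#'
#' All ordered candidate pairs whose predicted outer product length
#' (`rev.start - fwd.start + window_len`) falls in `product_range`, with
#' non-overlapping windows, `|dTm| <= max_dTm` and `|dGC| <= max_dGC`. The
#' reverse primer is reported as the reverse complement of its consensus
#' (5'->3' as synthesized). Sorted by combined degeneracy.
#'
#' @param candidates Data frame from [scan_windows()].
#' @param product_range Length-2 bp interval for the outer product span.
#' @param max_dTm Maximum Tm difference (degrees C).
#' @param max_dGC Maximum GC-fraction difference.
#' @return Data frame: fwd_start_col, rev_start_col, fwd_iupac, rev_iupac
#'   (synthesized orientation), product_length, degeneracy_fwd,
#'   degeneracy_rev, degeneracy_pair, tm_fwd, tm_rev, gc_fwd, gc_rev.
#' @export
select_pairs <- function(candidates, product_range, max_dTm = 5,
                         max_dGC = 0.15) {
  if (nrow(candidates) < 2L) return(.empty_pairs())
  wl <- nchar(candidates$iupac[1])
  res <- list()
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_len(nrow(candidates))) {
      f <- candidates[i, ]; r <- candidates[j, ]
      if (r$start_col < f$start_col + wl) next
      # outer span: from fwd-window 5' start to rev-window 3' end
      plen <- (r$start_col + nchar(r$iupac)) - f$start_col
      if (plen < product_range[1] || plen > product_range[2]) next
      if (abs(f$tm - r$tm) > max_dTm) next
      if (abs(f$gc_fraction - r$gc_fraction) > max_dGC) next
      res[[length(res) + 1L]] <- data.frame(
        fwd_start_col = f$start_col, rev_start_col = r$start_col,
        fwd_iupac = f$iupac, rev_iupac = revcomp(r$iupac),
        product_length = plen,
        degeneracy_fwd = f$degeneracy, degeneracy_rev = r$degeneracy,
        degeneracy_pair = f$degeneracy * r$degeneracy,
        tm_fwd = f$tm, tm_rev = r$tm,
        gc_fwd = f$gc_fraction, gc_rev = r$gc_fraction,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(.empty_pairs())
  out <- do.call(rbind, res)
  out[order(out$degeneracy_pair, out$product_length, out$fwd_start_col), ,
      drop = FALSE]
}

.empty_pairs <- function() {
  data.frame(fwd_start_col = integer(0), rev_start_col = integer(0),
             fwd_iupac = character(0), rev_iupac = character(0),
             product_length = integer(0), degeneracy_fwd = integer(0),
             degeneracy_rev = integer(0), degeneracy_pair = integer(0),
             tm_fwd = numeric(0), tm_rev = numeric(0),
             gc_fwd = numeric(0), gc_rev = numeric(0),
             stringsAsFactors = FALSE)
}
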