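# Pairwise alignment and Kimura (1980) two-parameter distances.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment via
#' [Biostrings::pairwiseAlignment()]. Default scoring: match +1,
#' mismatch -1, and a gap of length L costs `gap_open + L * gap_extend`
#' (4 + L by default). Deterministic.
#'
#' @param a,b Nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   given as positive numbers).
#' @return List with `a`, `b` (aligned strings of equal length, gaps as
#'   `-`) and `score`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1,
                       gap_open = 4, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  a <- normalize_sequence(a)
  b <- normalize_sequence(b)
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Kimura (1980) distance for an aligned pair
#'
#' Columns with a gap or ambiguity code in either sequence are excluded.
#' Over the remaining `n_sites` columns, P is the proportion differing by a
#' transition (A<->G, C<->T) and Q by a transversion; then
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` and
#' `p_identity = 1 - P - Q`. When the log arguments are non-positive the
#' pair is *saturated*: it is retained with identity only and `d_k80 = NA`.
#' The large-sample standard error of d is also reported.
#'
#' @param a,b Aligned strings of equal length (gaps as `-`).
#' @param id_a,id_b Optional sequence ids carried through.
#' @return A `pairwise_distance` list: `id_a`, `id_b`, `n_sites`, `P`, `Q`,
#'   `p_identity`, `d_k80`, `d_se`, `saturated`.
#' @export
compute_k80 <- function(a, b, id_a = "a", id_b = "b") {
  a <- normalize_sequence(a, allow_gap = TRUE)
  b <- normalize_sequence(b, allow_gap = TRUE)
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[keep]; bv <- bv[keep]
  n <- length(av)
  if (n == 0L) stop("no comparable (ungapped, unambiguous) columns")
  diff <- av != bv
  is_ts <- diff & ((av == "A" & bv == "G") | (av == "G" & bv == "A") |
                     (av == "C" & bv == "T") | (av == "T" & bv == "C"))
  P <- sum(is_ts) / n
  Q <- sum(diff & !is_ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- w1 <= 0 || w2 <= 0
  if (saturated) {
    d <- NA_real_; se <- NA_real_
  } else {
    d <- -0.5 * log(w1) - 0.25 * log(w2)
    c1 <- 1 / w1
    c2 <- 1 / w2
    c3 <- 0.5 * (c1 + c2)
    se <- sqrt((c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n)
  }
  structure(list(id_a = id_a, id_b = id_b, n_sites = n, P = P, Q = Q,
                 p_identity = 1 - P - Q, d_k80 = d, d_se = se,
                 saturated = saturated),
            class = "pairwise_distance")
}

#' @export
print.pairwise_distance <- function(x, ...) {
  cat(sprintf("%s vs %s: n=%d  P=%.4f  Q=%.4f  identity=%.4f  dK80=%s%s\n",
              x$id_a, x$id_b, x$n_sites, x$P, x$Q, x$p_identity,
              ifelse(x$saturated, "NA", sprintf("%.5f", x$d_k80)),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' Slice an alignment to a column interval
#'
#' All rows are sliced identically; the interval is 1-based inclusive, as
#' in curated-alignment trimming.
#'
#' @param msa Character vector of equal-length aligned strings.
#' @param start_col,end_col 1-based inclusive column interval.
#' @return Character vector of sliced rows (names preserved).
#' @export
trim_alignment_columns <- function(msa, start_col, end_col) {
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop("rows have unequal widths")
  if (start_col < 1L || end_col > w || start_col > end_col) {
    stop("column interval [", start_col, ", ", end_col,
         "] out of range for width ", w)
  }
  stats::setNames(substr(msa, start_col, end_col), names(msa))
}
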