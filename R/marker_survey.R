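# Marker survey: locate marker genes in genomes (nucleotide or protein
# query), per-marker pairwise distances, cross-marker identity regression,
# and single-copy fractions.

#' Locate a marker gene in a genome
#'
#' Local alignment of the query against both strands (nucleotide mode) or
#' against all six reading-frame translations (protein mode, a tBLASTn
#' surrogate). Hits passing the identity and query-coverage thresholds are
#' reported best-score first; overlapping weaker hits are suppressed, so the
#' number of hits is the copy count. Additional copies are found by masking
#' each accepted hit and re-aligning.
#'
#' @param genome_seq Genome nucleotide string.
#' @param query Query sequence (nucleotide, or amino acid when
#'   `is_protein = TRUE`).
#' @param genome_id Id carried into the result.
#' @param marker_name Marker name carried into the result.
#' @param is_protein Scan six-frame translations with a protein query.
#' @param min_identity Minimum alignment identity (matches / aligned
#'   columns), default 0.5 (permissive, recall over precision).
#' @param min_coverage Minimum fraction of the query aligned, default 0.5.
#' @param max_copies Safety cap on the masking iteration.
#' @return Data frame: genome_id, marker, start, end (0-based half-open,
#'   forward strand), strand, score, identity, coverage, sequence (the
#'   extracted nucleotides in the orientation of the hit strand).
#' @export
locate_marker <- function(genome_seq, query, genome_id = "genome",
                          marker_name = "marker", is_protein = FALSE,
                          min_identity = 0.5, min_coverage = 0.5,
                          max_copies = 10L) {
  if (!nzchar(query)) stop("empty query")
  genome_seq <- normalize_sequence(genome_seq)
  glen <- nchar(genome_seq)
  hits <- if (is_protein) {
    .locate_protein(genome_seq, toupper(query), min_identity, min_coverage,
                    max_copies)
  } else {
    .locate_nucleotide(genome_seq, normalize_sequence(query), min_identity,
                       min_coverage, max_copies)
  }
  if (nrow(hits) == 0L) {
    return(data.frame(genome_id = character(0), marker = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      identity = numeric(0), coverage = numeric(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  # suppress overlapping weaker hits (forward-strand intervals)
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) for (j in (i + 1L):nrow(hits)) {
      if (keep[j] && hits$start[j] < hits$end[i] &&
          hits$end[j] > hits$start[i]) keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  seqs <- substr(rep(genome_seq, nrow(hits)), hits$start + 1L, hits$end)
  seqs[hits$strand == "-"] <- revcomp(seqs[hits$strand == "-"])
  out <- data.frame(genome_id = genome_id, marker = marker_name,
                    start = hits$start, end = hits$end,
                    strand = hits$strand, score = hits$score,
                    identity = hits$identity, coverage = hits$coverage,
                    sequence = seqs, stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}

.nuc_local <- function(query, subject) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  Biostrings::pairwiseAlignment(query, subject, substitutionMatrix = sm,
                                gapOpening = 4, gapExtension = 1,
                                type = "local")
}

.aln_stats <- function(pa, qlen) {
  w <- Biostrings::nchar(pa)
  list(identity = Biostrings::nmatch(pa) / w,
       coverage = (Biostrings::end(Biostrings::pattern(pa)) -
                     Biostrings::start(Biostrings::pattern(pa)) + 1L) / qlen,
       score = Biostrings::score(pa),
       s_start = Biostrings::start(Biostrings::subject(pa)),
       s_end = Biostrings::end(Biostrings::subject(pa)))
}

.locate_nucleotide <- function(genome, query, min_id, min_cov, max_copies) {
  glen <- nchar(genome)
  qlen <- nchar(query)
  res <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") genome else revcomp(genome)
    for (k in seq_len(max_copies)) {
      if (nchar(gsub("N", "", subj)) < 8L) break
      pa <- .nuc_local(query, subj)
      st <- .aln_stats(pa, qlen)
      if (st$score <= 0) break
      ok <- st$identity >= min_id && st$coverage >= min_cov
      # mask and continue regardless, so a strong spurious region cannot
      # shadow a weaker true copy
      if (ok) {
        fs <- if (strand == "+") c(st$s_start - 1L, st$s_end)
              else c(glen - st$s_end, glen - st$s_start + 1L)
        res[[length(res) + 1L]] <- data.frame(
          start = fs[1], end = fs[2], strand = strand, score = st$score,
          identity = st$identity, coverage = st$coverage,
          stringsAsFactors = FALSE)
      }
      substr(subj, st$s_start, st$s_end) <-
        strrep("N", st$s_end - st$s_start + 1L)
      if (!ok) break
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               score = numeric(0), identity = numeric(0),
               coverage = numeric(0))
}

.locate_protein <- function(genome, query, min_id, min_cov, max_copies) {
  glen <- nchar(genome)
  qlen <- nchar(query)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sm <- get("BLOSUM62", envir = environment())
  res <- list()
  for (strand in c("+", "-")) {
    g <- if (strand == "+") genome else revcomp(genome)
    for (frame in 0:2) {
      sub_nt <- substring(g, frame + 1L)
      sub_nt <- substr(sub_nt, 1L, 3L * (nchar(sub_nt) %/% 3L))
      if (nchar(sub_nt) < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub_nt), if.fuzzy.codon = "X"))
      aa <- chartr("*", "X", aa)
      for (k in seq_len(max_copies)) {
        if (nchar(gsub("X", "", aa)) < 5L) break
        pa <- Biostrings::pairwiseAlignment(
          query, aa, substitutionMatrix = sm, gapOpening = 10,
          gapExtension = 1, type = "local")
        st <- .aln_stats(pa, qlen)
        if (st$score <= 0) break
        ok <- st$identity >= min_id && st$coverage >= min_cov
        if (ok) {
          nt_start <- frame + 3L * (st$s_start - 1L)       # 0-based on g
          nt_end <- frame + 3L * st$s_end
          fs <- if (strand == "+") c(nt_start, nt_end)
                else c(glen - nt_end, glen - nt_start)
          res[[length(res) + 1L]] <- data.frame(
            start = fs[1], end = fs[2], strand = strand, score = st$score,
            identity = st$identity, coverage = st$coverage,
            stringsAsFactors = FALSE)
        }
        substr(aa, st$s_start, st$s_end) <-
          strrep("X", st$s_end - st$s_start + 1L)
        if (!ok) break
      }
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               score = numeric(0), identity = numeric(0),
               coverage = numeric(0))
}

#' Fraction of genomes carrying a marker as single copy
#'
#' @param hits Data frame as returned by [locate_marker()] (rows pooled
#'   over genomes), or any data frame with a `genome_id` column where each
#'   row is one hit.
#' @param genome_ids Character vector of all surveyed genome ids (genomes
#'   with zero hits count against the fraction).
#' @return Fraction in \[0, 1\] of genomes with exactly one hit.
#' @export
single_copy_fraction <- function(hits, genome_ids) {
  if (length(genome_ids) == 0L) stop("empty genome set")
  counts <- table(factor(hits$genome_id, levels = genome_ids))
  mean(counts == 1L)
}

#' All pairwise K80 distances for one marker
#'
#' @param seqs Named character vector of marker sequences (one per genome).
#' @param align Run [align_pair()] on each pair first; set `FALSE` when the
#'   sequences are already equal-length/aligned (e.g. simulated loci with
#'   no indels).
#' @return Data frame with one row per unordered pair: id_a, id_b, n_sites,
#'   P, Q, p_identity, d_k80, d_se, saturated.
#' @export
marker_pairwise_distances <- function(seqs, align = TRUE) {
  ids <- names(seqs)
  if (is.null(ids) || length(seqs) < 2L) stop("need >= 2 named sequences")
  pairs <- utils::combn(ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (align && nchar(seqs[[i]]) != nchar(seqs[[j]])) {
      al <- align_pair(seqs[[i]], seqs[[j]])
      d <- compute_k80(al$a, al$b, i, j)
    } else if (align) {
      al <- align_pair(seqs[[i]], seqs[[j]])
      d <- compute_k80(al$a, al$b, i, j)
    } else {
      d <- compute_k80(seqs[[i]], seqs[[j]], i, j)
    }
    data.frame(id_a = d$id_a, id_b = d$id_b, n_sites = d$n_sites,
               P = d$P, Q = d$Q, p_identity = d$p_identity,
               d_k80 = d$d_k80, d_se = d$d_se, saturated = d$saturated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Regress one marker's pairwise identities on another's
#'
#' Pairs are inner-joined on the unordered (genome_a, genome_b) key; OLS of
#' the y-marker identity on the x-marker identity. Mirrors the usual
#' scatter-plus-regression comparison of marker conservation; note the OLS
#' ignores non-independence of pairs sharing a genome (recorded in the
#' result).
#'
#' @param dist_x,dist_y Data frames from [marker_pairwise_distances()].
#' @param use `"p_identity"` (default) or `"k80"` (regress `exp(-d)`-style
#'   model-corrected similarity `1 - d` clipped at 0; saturated pairs drop).
#' @param marker_x,marker_y Names carried into the result.
#' @return A `marker_comparison` list: slope, intercept, r2, n_pairs,
#'   n_dropped, marker_x, marker_y, data.
#' @export
compare_markers <- function(dist_x, dist_y, use = c("p_identity", "k80"),
                            marker_x = "x", marker_y = "y") {
  use <- match.arg(use)
  val <- function(d) {
    if (use == "p_identity") d$p_identity else pmax(0, 1 - d$d_k80)
  }
  kx <- pair_key(dist_x$id_a, dist_x$id_b)
  ky <- pair_key(dist_y$id_a, dist_y$id_b)
  shared <- intersect(kx, ky)
  x <- val(dist_x)[match(shared, kx)]
  y <- val(dist_y)[match(shared, ky)]
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- length(union(kx, ky)) - sum(ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("insufficient data: fewer than 3 shared pairs")
  fit <- stats::lm(y ~ x)
  structure(list(marker_x = marker_x, marker_y = marker_y,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared,
                 n_pairs = length(x), n_dropped = n_dropped,
                 note = "OLS on pairwise data; pairs sharing a genome are not independent",
                 data = data.frame(pair = shared[ok], x = x, y = y,
                                   stringsAsFactors = FALSE)),
            class = "marker_comparison")
}

#' @export
print.marker_comparison <- function(x, ...) {
  cat(sprintf("%s identity ~ %s identity: y = %.4f + %.4f x (r2 = %.3f, n = %d pairs)\n",
              x$marker_y, x$marker_x, x$intercept, x$slope, x$r2, x$n_pairs))
  invisible(x)
}

#' Map an identity value through a fitted marker comparison
#'
#' E.g. predict what a 97% identity on the conserved marker corresponds to
#' on a faster marker. Clipped to \[0, 1\].
#'
#' @param comparison A [compare_markers()] result.
#' @param x_identity Identity value(s) on the x marker.
#' @return Predicted identity on the y marker.
#' @export
map_identity <- function(comparison, x_identity) {
  if (!inherits(comparison, "marker_comparison")) {
    stop("not a fitted marker_comparison")
  }
  pmin(1, pmax(0, comparison$intercept + comparison$slope * x_identity))
}
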