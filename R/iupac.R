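# IUPAC nucleotide code machinery shared by the PCR and primer-design stages.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# complement map covering every ambiguity code
.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Reverse-complement a nucleotide string
#'
#' Handles all IUPAC ambiguity codes (e.g. `R` complements to `Y`). Input is
#' upper-cased first; `U` is mapped to `T`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- normalize_sequence(x)
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Normalize a nucleotide string
#'
#' Upper-cases and maps U to T. Errors on characters outside the IUPAC
#' alphabet (gap characters optionally allowed).
#'
#' @param x Character vector.
#' @param allow_gap Allow `-` characters (alignment rows).
#' @return Normalized character vector.
#' @export
normalize_sequence <- function(x, allow_gap = FALSE) {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  alphabet <- c(IUPAC_CODES, if (allow_gap) "-")
  bad <- !grepl(paste0("^[", paste(alphabet, collapse = ""), "]*$"), x)
  if (any(bad)) {
    chars <- setdiff(unique(strsplit(paste(x[bad], collapse = ""), "")[[1]]),
                     alphabet)
    stop("invalid nucleotide character(s): ", paste(chars, collapse = ", "))
  }
  x
}

#' Expand an IUPAC string into all concrete sequences
#'
#' @param iupac IUPAC nucleotide string.
#' @param max_size Guard against combinatorial explosion.
#' @return Character vector of all concrete (ACGT) realizations.
#' @export
iupac_expand <- function(iupac, max_size = 65536L) {
  iupac <- normalize_sequence(iupac)
  sets <- IUPAC_SETS[strsplit(iupac, "", fixed = TRUE)[[1]]]
  n <- prod(lengths(sets))
  if (n > max_size) stop("expansion of size ", n, " exceeds max_size")
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

#' Degeneracy of an IUPAC string
#'
#' Product of the per-position code-set sizes.
#'
#' @param iupac IUPAC nucleotide string.
#' @return Integer degeneracy (>= 1).
#' @export
iupac_degeneracy <- function(iupac) {
  iupac <- normalize_sequence(iupac)
  prod(lengths(IUPAC_SETS[strsplit(iupac, "", fixed = TRUE)[[1]]]))
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector drawn from A, C, G, T.
#' @return Single IUPAC code whose set equals `union(bases)`.
#' @export
iupac_code_for <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be concrete nucleotides (A/C/G/T)")
  }
  if (length(bases) == 0L) stop("empty base set")
  key <- paste(bases, collapse = "")
  hit <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s)
    identical(sort(s), bases), logical(1))]
  if (length(hit) != 1L) stop("no IUPAC code for set ", key)
  hit
}

# 15x15 logical lookup: compat[p, g] is TRUE iff expand(g) is a subset of
# expand(p). Built once at load time; the subset rule is the conservative
# reading of degenerate-primer matching (an N in the genome never silently
# matches a concrete primer base).
.iupac_compat <- local({
  m <- matrix(FALSE, length(IUPAC_CODES), length(IUPAC_CODES),
              dimnames = list(IUPAC_CODES, IUPAC_CODES))
  for (p in IUPAC_CODES) for (g in IUPAC_CODES) {
    m[p, g] <- all(IUPAC_SETS[[g]] %in% IUPAC_SETS[[p]])
  }
  m
})

#' Does a genome base satisfy a primer code?
#'
#' Subset rule: TRUE iff every base the genome code could be is covered by
#' the primer code. `iupac_match("N", x)` is TRUE for every x;
#' `iupac_match("A", "N")` is FALSE.
#'
#' @param primer_code,genome_code Single IUPAC codes (vectorized).
#' @return Logical vector.
#' @export
iupac_match <- function(primer_code, genome_code) {
  primer_code <- toupper(primer_code)
  genome_code <- toupper(genome_code)
  ok <- primer_code %in% IUPAC_CODES & genome_code %in% IUPAC_CODES
  if (!all(ok)) stop("invalid IUPAC code: ",
                     paste(unique(c(primer_code, genome_code)[
                       !c(primer_code, genome_code) %in% IUPAC_CODES]),
                       collapse = ", "))
  .iupac_compat[cbind(primer_code, genome_code)]
}
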