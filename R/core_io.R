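# Readers/writers and shared conventions: FASTA, TSV tables, GTDB-style
# taxonomy strings, BMI categories. All genomic coordinates in this package
# are 0-based half-open on the forward strand; reverse-strand features carry
# forward-strand coordinates plus a strand flag.

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] with normalization:
#' sequences are upper-cased and U is mapped to T. A sequence line appearing
#' before the first header is reported with its line number.
#'
#' @param path Path to a plain (wrapped or unwrapped) FASTA file.
#' @return Named character vector: names are full header lines (without
#'   `>`), values are normalized sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(stats::setNames(character(0), character(0)))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence before first header at line ", first)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_sequence(as.character(set))
  stats::setNames(seqs, names(set))
}

#' Write sequences to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` is the identity
#' on (id, sequence) pairs for normalized sequences.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` for unwrapped.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all records need non-empty names")
  }
  out <- unlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    body <- if (is.finite(width) && nchar(s) > width) {
      substring(s, seq(1, nchar(s), by = width),
                pmin(seq(width, nchar(s) + width - 1, by = width), nchar(s)))
    } else s
    c(paste0(">", names(seqs)[i]), body)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read/write TSV tables with optional provenance header
#'
#' Provenance lines start with `#` and are skipped on read.
#'
#' @param path File path.
#' @return A data.frame (`read_tsv`).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv
#' @param x Data frame to write.
#' @param header_lines Character vector of provenance lines (written with a
#'   leading `# `); may be empty.
#' @export
write_tsv <- function(x, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a count matrix (samples x ASVs) as TSV
#'
#' First column `sample_id`, remaining columns one per ASV.
#'
#' @param path File path.
#' @return Integer matrix with sample rownames and ASV colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  validate_counts(m)
  m
}

#' @rdname read_counts
#' @param counts Count matrix.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs sample rownames and ASV colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated ASV ids")
  if (any(counts < 0)) stop("negative counts")
  invisible(counts)
}

TAX_PREFIXES <- c("d", "p", "c", "o", "f", "g", "s")
TAX_RANKS <- c(d = "domain", p = "phylum", c = "class", o = "order",
               f = "family", g = "genus", s = "species")

#' Parse a GTDB-style taxonomy label
#'
#' Accepts full 7-rank labels (`d__...;p__...;...;s__...`) or partial labels
#' (`c__Clostridia`); missing ranks are filled with empty names. Ranks must
#' appear in canonical order.
#'
#' @param label Taxonomy string.
#' @return A `taxonomy_label`: named character vector of 7 rank names, names
#'   `d p c o f g s`.
#' @export
parse_taxonomy <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  out <- stats::setNames(rep("", 7L), TAX_PREFIXES)
  parts <- strsplit(trimws(label), ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  last <- 0L
  for (p in parts) {
    if (!grepl("^[a-z]__", p)) stop("malformed rank token: '", p, "'")
    prefix <- substr(p, 1, 1)
    idx <- match(prefix, TAX_PREFIXES)
    if (is.na(idx)) stop("unknown rank prefix: '", prefix, "__'")
    if (idx <= last) stop("ranks out of canonical order at '", p, "'")
    out[idx] <- substring(p, 4)
    last <- idx
  }
  structure(out, class = "taxonomy_label")
}

#' Render a taxonomy label back to its string form
#'
#' `parse_taxonomy(render_taxonomy(x))` is the identity; for canonical
#' 7-rank labels `render_taxonomy(parse_taxonomy(s)) == s`.
#'
#' @param x A `taxonomy_label`.
#' @return Canonical 7-rank string.
#' @export
render_taxonomy <- function(x) {
  stopifnot(inherits(x, "taxonomy_label"))
  paste(paste0(TAX_PREFIXES, "__", unclass(x)), collapse = ";")
}

#' @export
print.taxonomy_label <- function(x, ...) {
  cat(render_taxonomy(x), "\n")
  invisible(x)
}

#' Extract one rank's name from taxonomy strings (vectorized)
#'
#' @param labels Character vector of GTDB-style labels.
#' @param rank One of `d p c o f g s` (or the full rank name).
#' @return Character vector of names ("" when absent).
#' @export
taxonomy_rank <- function(labels, rank) {
  rank <- match.arg(rank, c(TAX_PREFIXES, unname(TAX_RANKS)))
  if (nchar(rank) > 1L) rank <- names(TAX_RANKS)[match(rank, TAX_RANKS)]
  pat <- paste0("(^|;)\\s*", rank, "__([^;]*)")
  m <- regmatches(labels, regexpr(pat, labels))
  out <- rep("", length(labels))
  hit <- regexpr(pat, labels) > 0
  out[hit] <- sub(pat, "\\2", m)
  trimws(out)
}

#' Classify BMI into the standard adult categories
#'
#' Half-open intervals: lean `[18.5, 25)`, overweight `[25, 30)`, obese
#' `[30, Inf)`. Values below 18.5 are flagged `underweight-excluded`
#' (such samples are excluded from the cohort by design).
#'
#' @param bmi Numeric vector of BMI values in kg/m^2; must be positive.
#' @return Character vector of categories.
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("BMI must be positive and finite")
  }
  cut_pts <- c(0, 18.5, 25, 30, Inf)
  labs <- c("underweight-excluded", "lean", "overweight", "obese")
  as.character(cut(bmi, cut_pts, labs, right = FALSE))
}

#' Read sample metadata (sample_id, bmi, city, sex, age)
#'
#' Adds the derived `bmi_category` column and (by default) drops
#' underweight samples, mirroring the cohort's exclusion filter.
#'
#' @param path TSV path with at least `sample_id` and `bmi` columns.
#' @param drop_underweight Drop BMI < 18.5 rows.
#' @return Data frame of metadata.
#' @export
read_metadata <- function(path, drop_underweight = TRUE) {
  df <- read_tsv(path)
  if (!all(c("sample_id", "bmi") %in% names(df))) {
    stop("metadata needs sample_id and bmi columns")
  }
  df$bmi_category <- classify_bmi(df$bmi)
  if (drop_underweight) df <- df[df$bmi_category != "underweight-excluded", ]
  df
}
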