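# The diversity-phenotype stage: count filtering, rarefaction, taxon-subset
# Shannon indices, greedy identity clustering, the two-part (hurdle) GLM
# against BMI with a city covariate, and BH-FDR.

#' Drop low-count samples and ASVs
#'
#' Samples with a total below `min_total` are dropped first, then ASVs with
#' a (post-sample-filter) total below `min_total`. Order preserved;
#' idempotent. Dropped ids are attached as attributes `dropped_samples`
#' and `dropped_asvs`.
#'
#' @param counts Samples x ASVs integer matrix.
#' @param min_total Exclusive threshold: totals `< min_total` are dropped
#'   (default 100).
#' @return Filtered matrix with the attributes above.
#' @export
filter_min_counts <- function(counts, min_total = 100L) {
  validate_counts(counts)
  drop_s <- rownames(counts)[rowSums(counts) < min_total]
  m <- counts[!rownames(counts) %in% drop_s, , drop = FALSE]
  if (nrow(m) == 0L) stop("all samples dropped by the count filter")
  drop_a <- colnames(m)[colSums(m) < min_total]
  m <- m[, !colnames(m) %in% drop_a, drop = FALSE]
  attr(m, "dropped_samples") <- drop_s
  attr(m, "dropped_asvs") <- drop_a
  m
}

#' Rarefy a count table to a common depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads
#' (the global minimum sample sum by default), normalizing read counts
#' before diversity comparison. Deterministic given `seed`.
#'
#' @param counts Samples x ASVs integer matrix.
#' @param depth Target depth; must not exceed any sample sum.
#' @param seed RNG seed.
#' @return Rarefied integer matrix; every row sums to `depth`.
#' @export
rarefy <- function(counts, depth = min(rowSums(counts)), seed = 1L) {
  validate_counts(counts)
  if (any(rowSums(counts) < depth)) {
    stop("depth ", depth, " exceeds some sample's total")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- counts
  for (i in seq_len(nrow(counts))) {
    pool <- rep.int(seq_len(ncol(counts)), counts[i, ])
    pick <- sample(pool, depth)
    out[i, ] <- tabulate(pick, nbins = ncol(counts))
  }
  storage.mode(out) <- "integer"
  out
}

#' Shannon diversity index (nats)
#'
#' `H = -sum p_i log p_i` over positive entries. Zero when at most one
#' entry is positive; an all-zero vector returns 0 with attribute
#' `zero_sample = TRUE`.
#'
#' @param counts Non-negative numeric vector.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot == 0) return(structure(0, zero_sample = TRUE))
  p <- counts[counts > 0] / tot
  if (length(p) <= 1L) return(0)
  -sum(p * log(p))
}

#' Per-sample Shannon index for a taxon subset
#'
#' Restricts the table to ASVs whose taxonomy matches `name` at `rank`;
#' samples with no counts in the subset get H = 0 (these feed the binary
#' part of the hurdle model).
#'
#' @param counts Samples x ASVs matrix.
#' @param taxonomy Named character vector of GTDB-style labels per ASV.
#' @param rank Rank prefix or name (e.g. `"f"` or `"family"`).
#' @param name Taxon name at that rank.
#' @return Named numeric vector of per-sample Shannon indices (nats).
#' @export
subset_shannon <- function(counts, taxonomy, rank, name) {
  validate_counts(counts)
  tax <- taxonomy[colnames(counts)]
  sel <- taxonomy_rank(tax, rank) == name
  if (!any(sel)) stop("no ASV with ", rank, " == '", name, "'")
  sub <- counts[, sel, drop = FALSE]
  h <- apply(sub, 1L, function(r) as.numeric(shannon(r)))
  stats::setNames(h, rownames(counts))
}

#' Greedy centroid clustering of ASV sequences
#'
#' Sequences are processed in decreasing total abundance (ties broken by
#' lexicographic id); each joins the first existing centroid whose
#' global-alignment identity (matches / alignment length, gaps counting
#' against identity) is at least `threshold`, otherwise it founds a new
#' cluster. At `threshold = 1` distinct sequences therefore form the
#' identity partition.
#'
#' @param seqs Named character vector of representative sequences.
#' @param abundances Named numeric vector of total counts per sequence id.
#' @param threshold Identity threshold in (0, 1].
#' @return A `cluster_assignment` list: `threshold`, `map` (named centroid
#'   id per ASV), `centroids` (character vector).
#' @export
greedy_cluster <- function(seqs, abundances, threshold) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ids <- names(seqs)
  if (length(ids) == 0L) {
    return(structure(list(threshold = threshold,
                          map = stats::setNames(character(0), character(0)),
                          centroids = character(0)),
                     class = "cluster_assignment"))
  }
  ord <- ids[order(-abundances[ids], ids)]
  centroids <- character(0)
  map <- stats::setNames(character(length(ids)), ids)
  for (id in ord) {
    assigned <- NA_character_
    for (cid in centroids) {
      if (identical(seqs[[id]], seqs[[cid]])) { assigned <- cid; break }
      if (threshold < 1) {
        al <- align_pair(seqs[[id]], seqs[[cid]])
        n_match <- sum(strsplit(al$a, "")[[1]] == strsplit(al$b, "")[[1]])
        if (n_match / nchar(al$a) >= threshold) { assigned <- cid; break }
      }
    }
    if (is.na(assigned)) {
      centroids <- c(centroids, id)
      assigned <- id
    }
    map[id] <- assigned
  }
  structure(list(threshold = threshold, map = map, centroids = centroids),
            class = "cluster_assignment")
}

#' Collapse a count table by a cluster assignment
#'
#' Member counts are summed per cluster; the collapsed columns are the
#' centroid ids in the original column order.
#'
#' @param counts Samples x ASVs matrix.
#' @param assignment A [greedy_cluster()] result.
#' @return Collapsed samples x clusters matrix.
#' @export
collapse_counts <- function(counts, assignment) {
  validate_counts(counts)
  map <- assignment$map[colnames(counts)]
  cents <- colnames(counts)[colnames(counts) %in% assignment$centroids]
  out <- matrix(0L, nrow(counts), length(cents),
                dimnames = list(rownames(counts), cents))
  for (k in seq_along(cents)) {
    member <- names(map)[map == cents[k]]
    out[, k] <- as.integer(rowSums(counts[, member, drop = FALSE]))
  }
  out
}

#' Two-part (hurdle) GLM of Shannon diversity on BMI
#'
#' Fits (i) `glm.bin`: presence (H > 0) on BMI plus covariates, binomial
#' family with logit link; and (ii) `glm.cont`: H on the H > 0 subset,
#' Gamma family with log link and Pearson dispersion. Both by IRLS
#' (`stats::glm`, epsilon 1e-8, up to 100 iterations). The reported p is a
#' Wald test of the BMI coefficient. Degenerate designs are flagged
#' (`estimable = FALSE`), not errored: all-zero or all-positive H for the
#' binary part; too few positive samples for the continuous part.
#' Quasi-separation is flagged via `converged = FALSE`.
#'
#' @param shannon Named numeric vector of per-sample Shannon indices.
#' @param metadata Data frame with `sample_id`, `bmi` and covariate
#'   columns.
#' @param covariates Covariate column names (default `"city"`).
#' @param taxon,marker Labels carried into the result.
#' @return Data frame of class `hurdle_fit`, two rows (glm.bin, glm.cont):
#'   taxon, marker, model, beta_bmi, se, p, fdr (NA until adjusted), n_obs,
#'   converged, estimable.
#' @export
fit_hurdle <- function(shannon, metadata, covariates = "city",
                       taxon = NA_character_, marker = NA_character_) {
  ids <- intersect(names(shannon), metadata$sample_id)
  if (length(ids) < 10L) stop("need at least 10 samples with metadata")
  df <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  df$H <- as.numeric(shannon[ids])
  if (any(is.na(df$bmi)) ||
      any(vapply(covariates, function(v) any(is.na(df[[v]])), logical(1)))) {
    stop("BMI and covariates must be complete")
  }
  for (v in covariates) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  rhs <- paste(c("bmi", covariates), collapse = " + ")
  n_par <- 2L + sum(vapply(covariates, function(v)
    max(1L, nlevels(df[[v]]) - 1L), integer(1)))

  row <- function(model, beta, se, p, n, conv, est) {
    data.frame(taxon = taxon, marker = marker, model = model,
               beta_bmi = beta, se = se, p = p, fdr = NA_real_,
               n_obs = n, converged = conv, estimable = est,
               stringsAsFactors = FALSE)
  }
  wald <- function(fit, dispersion = NULL) {
    s <- if (is.null(dispersion)) summary(fit) else
      summary(fit, dispersion = dispersion)
    co <- s$coefficients
    beta <- co["bmi", 1]; se <- co["bmi", 2]
    z <- beta / se
    list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)))
  }

  # binary part
  df$pres <- as.integer(df$H > 0)
  if (all(df$pres == 1L) || all(df$pres == 0L)) {
    bin <- row("glm.bin", NA_real_, NA_real_, NA_real_, nrow(df), NA, FALSE)
  } else {
    fit <- suppressWarnings(stats::glm(
      stats::as.formula(paste("pres ~", rhs)), data = df,
      family = stats::binomial("logit"),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
    w <- wald(fit)
    sep <- !fit$converged || abs(w$beta) > 50 ||
      any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
    bin <- row("glm.bin", w$beta, w$se, w$p, nrow(df), !sep, TRUE)
  }

  # continuous part on the positive subset
  pos <- df[df$H > 0, , drop = FALSE]
  if (nrow(pos) < n_par + 2L) {
    cont <- row("glm.cont", NA_real_, NA_real_, NA_real_, nrow(pos), NA, FALSE)
  } else {
    fit <- suppressWarnings(stats::glm(
      stats::as.formula(paste("H ~", rhs)), data = pos,
      family = stats::Gamma(link = "log"),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
    disp <- sum(stats::residuals(fit, type = "pearson")^2) /
      stats::df.residual(fit)
    w <- wald(fit, dispersion = disp)
    cont <- row("glm.cont", w$beta, w$se, w$p, nrow(pos), fit$converged, TRUE)
  }
  out <- rbind(bin, cont)
  class(out) <- c("hurdle_fit", class(out))
  out
}

#' Benjamini-Hochberg FDR adjustment within groups
#'
#' Step-up BH within each level of `groups` (a single family of tests when
#' `NULL`). The result is monotone, at least the raw p, and at most 1. The
#' attribute `significant` flags `fdr < alpha` (default 0.20).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs passed through).
#' @param groups Optional grouping vector (family of tests).
#' @param alpha Significance threshold on the adjusted values.
#' @return Adjusted p-values with attribute `significant`.
#' @export
adjust_fdr <- function(p, groups = NULL, alpha = 0.20) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  out <- rep(NA_real_, length(p))
  if (is.null(groups)) groups <- rep(1L, length(p))
  for (g in unique(groups)) {
    sel <- which(groups == g)
    out[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  attr(out, "significant") <- !is.na(out) & out < alpha
  out
}

#' Hurdle fits for a set of taxa
#'
#' Filter, rarefy (whole table, global minimum depth), then for each
#' requested taxon compute the subset Shannon index and fit the hurdle
#' models; BH-FDR is applied within (marker x rank x model).
#'
#' @param counts Samples x ASVs matrix.
#' @param taxonomy Named taxonomy labels per ASV.
#' @param metadata Metadata data frame.
#' @param taxa Data frame with columns `rank` and `name`; by default all
#'   families and all genera present in `taxonomy`.
#' @param marker Marker label for the output.
#' @param covariates Passed to [fit_hurdle()].
#' @param min_total Count filter threshold.
#' @param rarefy_depth Depth (default global minimum after filtering).
#' @param fdr_alpha Significance threshold on FDR.
#' @param seed Rarefaction seed.
#' @param do_rarefy Set `FALSE` to skip rarefaction (e.g. for pre-rarefied
#'   input).
#' @return Data frame of hurdle fits for all taxa with `fdr` filled in.
#' @export
diversity_analysis <- function(counts, taxonomy, metadata, taxa = NULL,
                               marker = NA_character_, covariates = "city",
                               min_total = 100L, rarefy_depth = NULL,
                               fdr_alpha = 0.20, seed = 1L,
                               do_rarefy = TRUE) {
  m <- filter_min_counts(counts, min_total)
  if (do_rarefy) {
    depth <- if (is.null(rarefy_depth)) min(rowSums(m)) else rarefy_depth
    m <- rarefy(m, depth, seed = seed)
  }
  tax <- taxonomy[colnames(m)]
  if (is.null(taxa)) {
    fams <- setdiff(unique(taxonomy_rank(tax, "f")), "")
    gens <- setdiff(unique(taxonomy_rank(tax, "g")), "")
    taxa <- rbind(
      if (length(fams)) data.frame(rank = "f", name = fams),
      if (length(gens)) data.frame(rank = "g", name = gens))
  }
  fits <- lapply(seq_len(nrow(taxa)), function(i) {
    h <- subset_shannon(m, tax, taxa$rank[i], taxa$name[i])
    fit <- fit_hurdle(h, metadata, covariates = covariates,
                      taxon = taxa$name[i], marker = marker)
    fit$rank <- taxa$rank[i]
    fit
  })
  out <- do.call(rbind, fits)
  grp <- paste(out$marker, out$rank, out$model)
  out$fdr <- as.numeric(adjust_fdr(out$p, groups = grp, alpha = fdr_alpha))
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_alpha
  out
}

#' Clustering-threshold sensitivity analysis
#'
#' For each identity threshold: cluster the representative sequences,
#' collapse the counts (centroid taxonomy), and re-run the full
#' diversity-BMI analysis. Threshold 1 reproduces the unclustered analysis
#' exactly when all representative sequences are distinct.
#'
#' @param counts Samples x ASVs matrix.
#' @param taxonomy Named taxonomy labels per ASV.
#' @param seqs Named representative sequences per ASV.
#' @param metadata Metadata data frame.
#' @param thresholds Identity thresholds (default 1, 0.97, 0.90, 0.85).
#' @param taxa,marker,covariates,fdr_alpha,seed Passed through to
#'   [diversity_analysis()].
#' @return Named list (one element per threshold) of results plus the
#'   cluster count, `list(fits=, n_clusters=)`.
#' @export
sensitivity_suite <- function(counts, taxonomy, seqs, metadata,
                              thresholds = c(1, 0.97, 0.90, 0.85),
                              taxa = NULL, marker = NA_character_,
                              covariates = "city", fdr_alpha = 0.20,
                              seed = 1L) {
  validate_counts(counts)
  out <- list()
  for (t in thresholds) {
    asg <- greedy_cluster(seqs[colnames(counts)],
                          colSums(counts), threshold = t)
    cc <- collapse_counts(counts, asg)
    fits <- diversity_analysis(cc, taxonomy[colnames(cc)], metadata,
                               taxa = taxa, marker = marker,
                               covariates = covariates,
                               fdr_alpha = fdr_alpha, seed = seed)
    out[[format(t)]] <- list(fits = fits, n_clusters = ncol(cc))
  }
  out
}
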