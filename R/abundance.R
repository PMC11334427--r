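# Differential ASV abundance across BMI categories: median-of-ratios size
# factors and a per-ASV negative-binomial Wald test. Deliberately a plain NB
# GLM (no dispersion or fold-change shrinkage) -- a simplified analogue of
# the DESeq2 procedure; see the methods vignette.

#' Median-of-ratios size factors
#'
#' For each ASV j with all-positive counts across samples, g_j is its
#' geometric mean; the size factor of sample i is the median over those
#' reference ASVs of `c_ij / g_j`.
#'
#' @param counts Samples x ASVs matrix.
#' @param fallback When no ASV is positive in every sample, use the
#'   "poscounts"-style pseudo-reference (geometric mean over positive
#'   counts only) instead of erroring.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts, fallback = FALSE) {
  validate_counts(counts)
  allpos <- colSums(counts > 0) == nrow(counts)
  if (!any(allpos)) {
    if (!fallback) {
      stop("no ASV with all-positive counts; rerun with fallback = TRUE ",
           "to use a zero-skipping pseudo-reference")
    }
    logg <- apply(counts, 2L, function(x) mean(log(x[x > 0])))
    ratios <- log(counts)
    ratios[!is.finite(ratios)] <- NA
    ratios <- sweep(ratios, 2L, logg, "-")
    s <- exp(apply(ratios, 1L, stats::median, na.rm = TRUE))
  } else {
    ref <- counts[, allpos, drop = FALSE]
    g <- exp(colMeans(log(ref)))
    s <- apply(sweep(ref, 2L, g, "/"), 1L, stats::median)
  }
  if (any(!is.finite(s) | s <= 0)) stop("non-positive size factor")
  stats::setNames(s, rownames(counts))
}

#' Per-ASV negative-binomial Wald test between two BMI categories
#'
#' For each ASV, a negative-binomial GLM with log link and
#' `offset(log(size_factor))` on the condition factor, dispersion estimated
#' per ASV by maximum likelihood ([MASS::glm.nb()]); Wald test of the
#' contrast coefficient, BH-FDR across the tested ASVs. ASVs with all-zero
#' counts in both contrast levels are excluded with a reason; fits that
#' fail are flagged.
#'
#' @param counts Samples x ASVs matrix.
#' @param sf Size factors (default computed from `counts`).
#' @param condition Factor/character per sample (e.g. `bmi_category`).
#' @param contrast Length-2 character: `c(numerator, denominator)` levels;
#'   the log2 fold change is numerator vs denominator.
#' @return Data frame of class `diff_abundance`: asv_id, base_mean,
#'   log2_fold_change, se, wald_p, fdr, converged, excluded_reason.
#' @export
nb_wald_test <- function(counts, sf = NULL, condition,
                         contrast = c("obese", "lean")) {
  validate_counts(counts)
  condition <- as.character(condition)
  if (length(condition) != nrow(counts)) {
    stop("condition length != number of samples")
  }
  keep <- condition %in% contrast
  counts <- counts[keep, , drop = FALSE]
  condition <- condition[keep]
  if (any(table(condition)[contrast] < 3L) ||
      length(unique(condition)) < 2L) {
    stop("need >= 3 samples in each contrast level")
  }
  if (is.null(sf)) sf <- size_factors(counts, fallback = TRUE)
  sf <- sf[rownames(counts)]
  # reference = denominator, so the condition coefficient is num vs den
  cond <- stats::relevel(factor(condition, levels = contrast), contrast[2])
  off <- log(sf)
  norm <- sweep(counts, 1L, sf, "/")
  rows <- lapply(colnames(counts), function(a) {
    y <- counts[, a]
    base_mean <- mean(norm[, a])
    if (all(y == 0L)) {
      return(data.frame(asv_id = a, base_mean = base_mean,
                        log2_fold_change = NA_real_, se = NA_real_,
                        wald_p = NA_real_, fdr = NA_real_, converged = NA,
                        excluded_reason = "all-zero in both levels",
                        stringsAsFactors = FALSE))
    }
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ cond + offset(off),
                                    control = stats::glm.control(maxit = 100L))),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(asv_id = a, base_mean = base_mean,
                        log2_fold_change = NA_real_, se = NA_real_,
                        wald_p = NA_real_, fdr = NA_real_, converged = FALSE,
                        excluded_reason = "fit failed",
                        stringsAsFactors = FALSE))
    }
    co <- summary(fit)$coefficients
    cname <- paste0("cond", contrast[1])
    beta <- co[cname, 1]; se <- co[cname, 2]
    p <- 2 * stats::pnorm(-abs(beta / se))
    data.frame(asv_id = a, base_mean = base_mean,
               log2_fold_change = beta / log(2), se = se / log(2),
               wald_p = p, fdr = NA_real_,
               converged = isTRUE(fit$converged),
               excluded_reason = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- is.na(out$excluded_reason)
  out$fdr[tested] <- stats::p.adjust(out$wald_p[tested], method = "BH")
  attr(out, "contrast") <- contrast
  attr(out, "note") <- "plain per-ASV NB Wald test; no dispersion/LFC shrinkage"
  class(out) <- c("diff_abundance", class(out))
  out
}

#' All three pairwise BMI-category contrasts
#'
#' Runs [nb_wald_test()] for lean-obese, lean-overweight and
#' overweight-obese, with FDR within each contrast.
#'
#' @param counts Samples x ASVs matrix.
#' @param metadata Data frame with `sample_id` and `bmi_category`.
#' @return Named list of `diff_abundance` data frames.
#' @export
nb_wald_contrasts <- function(counts, metadata) {
  cond <- metadata$bmi_category[match(rownames(counts),
                                      metadata$sample_id)]
  contrasts <- list(obese_vs_lean = c("obese", "lean"),
                    overweight_vs_lean = c("overweight", "lean"),
                    obese_vs_overweight = c("obese", "overweight"))
  lapply(contrasts, function(ct)
    nb_wald_test(counts, condition = cond, contrast = ct))
}
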