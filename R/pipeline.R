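# Orchestration: config loading with schema validation, seed propagation,
# stage-tagged logging to stderr, and an end-to-end demo pipeline on
# synthetic fixtures. Results go only to declared output files; identical
# config + seed gives byte-identical outputs.

.config_schema <- c(
  "seed", "n_taxa", "divergence", "background_length",
  "ssu_length", "fast_length", "fast_rate", "kappa",
  "pcr_min_len", "pcr_max_len", "max_mismatch",
  "n_samples", "n_asvs", "n_da_asvs", "da_fold_change", "richness_slope",
  "dispersion", "min_total", "fdr_alpha",
  "design_n_rows", "design_n_codons", "stages")

#' Read and validate a pipeline configuration
#'
#' Flat YAML key-value file; unknown keys are rejected (usage error).
#'
#' @param path Path to a YAML config file.
#' @return Named list of parameters merged over defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_usage("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_usage("config must be a YAML mapping")
  unknown <- setdiff(names(cfg), .config_schema)
  if (length(unknown)) {
    stop_usage("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(seed = 20240716L,
       n_taxa = 12L, divergence = 0.025, background_length = 3000L,
       ssu_length = 800L, fast_length = 130L, fast_rate = 3, kappa = 2,
       pcr_min_len = 75L, pcr_max_len = 150L, max_mismatch = 6L,
       n_samples = 80L, n_asvs = 120L, n_da_asvs = 10L,
       da_fold_change = 4, richness_slope = -0.08,
       dispersion = 0.5, min_total = 100L, fdr_alpha = 0.20,
       design_n_rows = 10L, design_n_codons = 80L,
       stages = c("simulate", "survey", "pcr", "design", "diversity",
                  "diffabund"))
}

stop_usage <- function(...) {
  stop(structure(class = c("markerlens_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

log_stage <- function(stage, ...) {
  message(sprintf("[markerlens:%s] %s", stage, paste0(...)))
}

.provenance <- function(cfg, extra = character(0)) {
  c(paste0("markerlens ", as.character(utils::packageVersion("markerlens"))),
    paste0("seed=", cfg$seed), extra)
}

#' Run the demo pipeline on synthetic fixtures
#'
#' Stages (in declared order): `simulate` genomes and cohorts; `survey`
#' markers (locate, pairwise K80 distances, cross-marker regression);
#' `pcr` (amplicons and taxonomic coverage with the published dnaK
#' primers); `design` (primer design on a simulated orthologue family);
#' `diversity` (hurdle GLM per taxon); `diffabund` (NB Wald obese vs
#' lean). Every output TSV carries a provenance header; outputs are
#' deterministic for a given config + seed.
#'
#' @param config Path to a YAML config, or a config list.
#' @param out_dir Output directory (created).
#' @param seed Optional seed override.
#' @return Invisibly, `list(status = 0, manifest = <data.frame>)`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_config(config) else
    utils::modifyList(default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name, extra = character(0)) {
    path <- file.path(out_dir, name)
    write_tsv(df, path, header_lines = .provenance(cfg, extra))
    files <<- c(files, path)
    path
  }
  pp <- published_primers()$dnaK

  sim <- NULL
  if (any(c("simulate", "survey", "pcr") %in% cfg$stages)) {
    log_stage("simulate", "genomes: ", cfg$n_taxa, " taxa")
    fams <- rep(c("f__SimFamilyA", "f__SimFamilyB"), length.out = cfg$n_taxa)
    tax <- sprintf(
      "d__Bacteria;p__Bacillota_A;c__Clostridia;o__SimOrder;%s;g__SimGenus;s__sp%02d",
      sub("^f__", "f__", fams), seq_len(cfg$n_taxa))
    sim <- simulate_marker_genomes(
      n_taxa = cfg$n_taxa, divergences = cfg$divergence,
      specs = list(marker_spec("ssu", cfg$ssu_length, 1, cfg$kappa),
                   marker_spec("fast", cfg$fast_length, cfg$fast_rate,
                               cfg$kappa)),
      background_length = cfg$background_length,
      primer_pairs = list(fast = list(fwd = pp$fwd$iupac,
                                      rev = pp$rev$iupac,
                                      mismatches_fwd = 0L,
                                      mismatches_rev = 0L)),
      taxonomy = tax, seed = cfg$seed)
    if ("simulate" %in% cfg$stages) {
      write_fasta(stats::setNames(sim$genomes$sequence, sim$genomes$id),
                  file.path(out_dir, "genomes.fasta"))
      files <- c(files, file.path(out_dir, "genomes.fasta"))
      emit(sim$truth, "genome_truth.tsv")
      emit(sim$genomes[, c("id", "taxonomy")], "genome_taxonomy.tsv")
    }
  }

  if ("survey" %in% cfg$stages) {
    log_stage("survey", "locating markers and computing K80 distances")
    hits <- do.call(rbind, lapply(seq_len(nrow(sim$genomes)), function(i) {
      rbind(locate_marker(sim$genomes$sequence[i], sim$ancestors[["ssu"]],
                          genome_id = sim$genomes$id[i],
                          marker_name = "ssu"),
            locate_marker(sim$genomes$sequence[i], sim$ancestors[["fast"]],
                          genome_id = sim$genomes$id[i],
                          marker_name = "fast"))
    }))
    emit(hits[, c("genome_id", "marker", "start", "end", "strand",
                  "score", "identity", "coverage")], "survey_hits.tsv")
    dist_list <- lapply(c("ssu", "fast"), function(mk) {
      seqs <- sim$marker_seqs[[mk]]
      d <- marker_pairwise_distances(seqs, align = FALSE)
      d$marker <- mk
      d
    })
    emit(do.call(rbind, dist_list), "survey_distances.tsv")
    cmp <- compare_markers(dist_list[[1]], dist_list[[2]],
                           marker_x = "ssu", marker_y = "fast")
    json <- jsonlite::toJSON(
      list(marker_x = cmp$marker_x, marker_y = cmp$marker_y,
           slope = cmp$slope, intercept = cmp$intercept, r2 = cmp$r2,
           n_pairs = cmp$n_pairs, seed = cfg$seed),
      auto_unbox = TRUE, digits = 10)
    writeLines(json, file.path(out_dir, "survey_comparison.json"))
    files <- c(files, file.path(out_dir, "survey_comparison.json"))
  }

  if ("pcr" %in% cfg$stages) {
    log_stage("pcr", "in-silico PCR and taxonomic coverage")
    amp <- do.call(rbind, lapply(seq_len(nrow(sim$genomes)), function(i)
      find_amplicons(sim$genomes$sequence[i], pp$fwd, pp$rev,
                     cfg$pcr_min_len, cfg$pcr_max_len, cfg$max_mismatch,
                     genome_id = sim$genomes$id[i])))
    emit(amp, "amplicons.tsv")
    cov <- taxonomic_coverage(sim$genomes, pp$fwd, pp$rev,
                              cfg$pcr_min_len, cfg$pcr_max_len,
                              cfg$max_mismatch)
    emit(cov, "coverage.tsv",
         extra = sprintf("primers=%s/%s window=[%d,%d] max_mismatch=%d",
                         pp$fwd$name, pp$rev$name, cfg$pcr_min_len,
                         cfg$pcr_max_len, cfg$max_mismatch))
  }

  if ("design" %in% cfg$stages) {
    log_stage("design", "primer design on a simulated orthologue family")
    fam <- simulate_orthologue_family(
      n_rows = cfg$design_n_rows, n_codons = cfg$design_n_codons,
      conserved = list(list(start = 31L, iupac = "GGTGCWGTTATGGARGGYGGT"),
                       list(start = 151L, iupac = "GCNTGYCTTTTTGCTACCTGY")),
      seed = cfg$seed)
    codon_aln <- back_translate(fam$protein_msa, fam$cds)
    cand <- scan_windows(codon_aln, window_len = 21L,
                         max_degeneracy = 256L, min_conservation = 0.9)
    pairs <- select_pairs(cand, product_range = c(cfg$pcr_min_len,
                                                  cfg$pcr_max_len))
    emit(cand, "primer_candidates.tsv")
    emit(pairs, "primer_pairs.tsv")
  }

  cohort <- NULL
  if (any(c("diversity", "diffabund") %in% cfg$stages)) {
    fc <- rep(1, cfg$n_asvs)
    if (cfg$n_da_asvs > 0) fc[seq_len(cfg$n_da_asvs)] <- cfg$da_fold_change
    cohort <- simulate_count_cohort(
      n_samples = cfg$n_samples, n_asvs = cfg$n_asvs,
      richness_slope = cfg$richness_slope, fold_changes = fc,
      dispersion = cfg$dispersion, seed = cfg$seed + 1L)
    if ("simulate" %in% cfg$stages) {
      write_counts(cohort$counts, file.path(out_dir, "counts.tsv"))
      files <- c(files, file.path(out_dir, "counts.tsv"))
      emit(cohort$metadata, "metadata.tsv")
      emit(data.frame(asv_id = names(cohort$taxonomy),
                      taxonomy = unname(cohort$taxonomy)), "asv_taxonomy.tsv")
    }
  }

  if ("diversity" %in% cfg$stages) {
    log_stage("diversity", "hurdle GLM per taxon")
    fits <- diversity_analysis(cohort$counts, cohort$taxonomy,
                               cohort$metadata, marker = "fast",
                               min_total = cfg$min_total,
                               fdr_alpha = cfg$fdr_alpha,
                               seed = cfg$seed + 2L)
    emit(fits, "diversity_fits.tsv",
         extra = sprintf("fdr_alpha=%.2f", cfg$fdr_alpha))
  }

  if ("diffabund" %in% cfg$stages) {
    log_stage("diffabund", "NB Wald test obese vs lean")
    filt <- filter_min_counts(cohort$counts, cfg$min_total)
    res <- nb_wald_test(filt,
                        condition = cohort$metadata$bmi_category[
                          match(rownames(filt),
                                cohort$metadata$sample_id)],
                        contrast = c("obese", "lean"))
    emit(as.data.frame(res), "diffabund_obese_vs_lean.tsv",
         extra = "plain NB Wald test; no dispersion/LFC shrinkage")
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  log_stage("done", length(files), " artifacts in ", out_dir)
  invisible(list(status = 0L, manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `survey`, `pcr-coverage`, `design-primers`,
#' `diversity`, `diffabund`, `pipeline` (all stages). Each runs the
#' corresponding stage(s) of [run_pipeline()].
#' Usage: `markerlens <subcommand> --config cfg.yaml [--seed N] [--out DIR]`.
#' Exit codes: 0 ok, 1 data/stage error, 2 usage error.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  stage_map <- list(
    simulate = "simulate",
    survey = c("simulate", "survey"),
    `pcr-coverage` = c("simulate", "pcr"),
    `design-primers` = "design",
    diversity = c("simulate", "diversity"),
    diffabund = c("simulate", "diffabund"),
    pipeline = default_config()$stages)
  usage <- function() {
    message("usage: markerlens <",
            paste(names(stage_map), collapse = "|"),
            "> [--config cfg.yaml] [--seed N] [--out DIR]")
  }
  status <- tryCatch({
    if (length(args) < 1L || !args[1] %in% names(stage_map)) {
      usage(); stop_usage("unknown or missing subcommand")
    }
    sub <- args[1]
    opts <- list(config = NULL, seed = NULL, out = "markerlens-out")
    rest <- args[-1]
    i <- 1L
    while (i <= length(rest)) {
      key <- sub("^--", "", rest[i])
      if (!key %in% names(opts) || i == length(rest)) {
        stop_usage("bad option: ", rest[i])
      }
      opts[[key]] <- rest[i + 1L]
      i <- i + 2L
    }
    cfg <- if (is.null(opts$config)) default_config() else
      read_config(opts$config)
    cfg$stages <- stage_map[[sub]]
    run_pipeline(cfg, out_dir = opts$out,
                 seed = if (!is.null(opts$seed)) as.integer(opts$seed))
    0L
  },
  markerlens_usage_error = function(e) {
    message("usage error: ", conditionMessage(e)); 2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
  invisible(status)
}
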