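## End-to-end orchestration: synthetic or user data in, per-stage tables and
## a report-style summary out, with deterministic file output.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate the inputs from `sim`) or `"real"`
#'   (read them from `paths`).
#' @param out_dir output directory.
#' @param sim a [sim_config()] (synthetic mode).
#' @param paths named list of input paths for real mode: `genome, gff,
#'   counts, manifest, categories` and one `pileup_<strain>` per strain.
#' @param detect_min,alpha_de,fc_min,epsilon expression thresholds
#'   (see [call_de()]).
#' @param min_run,cov_detect,qual_min,cov_min,dfreq_min variant thresholds
#'   (see [call_snps()]).
#' @param flank nearest-gene flank in bp (see [annotate_effects()]).
#' @param alpha_enrich enrichment threshold (see [enrich()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"), out_dir,
                            sim = sim_config(), paths = list(),
                            detect_min = 0.5, alpha_de = 1e-15, fc_min = 2,
                            epsilon = 0.05, min_run = 11L, cov_detect = 20,
                            qual_min = 0, cov_min = 30, dfreq_min = 40,
                            flank = 1000L, alpha_enrich = 0.05) {
  mode <- match.arg(mode)
  thr <- c(detect_min = detect_min, alpha_de = alpha_de, fc_min = fc_min,
           epsilon = epsilon, min_run = min_run, cov_detect = cov_detect,
           cov_min = cov_min, dfreq_min = dfreq_min, flank = flank,
           alpha_enrich = alpha_enrich)
  if (any(thr <= 0) || qual_min < 0) stopf("thresholds must be positive")
  cfg <- list(mode = mode, out_dir = out_dir, sim = sim, paths = paths,
              detect_min = detect_min, alpha_de = alpha_de, fc_min = fc_min,
              epsilon = epsilon, min_run = as.integer(min_run),
              cov_detect = cov_detect, qual_min = qual_min,
              cov_min = cov_min, dfreq_min = dfreq_min,
              flank = as.integer(flank), alpha_enrich = alpha_enrich)
  if (mode == "real") {
    need <- c("genome", "gff", "counts", "manifest")
    missing <- setdiff(need, names(paths))
    if (length(missing))
      stopf("configuration error: real mode requires paths for %s",
            paste(missing, collapse = ", "))
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent))
      stopf("configuration error: input file not found: %s",
            paste(absent, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

read_tsv <- function(path) utils::read.delim(path, check.names = FALSE,
                                             stringsAsFactors = FALSE)

#' Run the full pipeline
#'
#' Stages run in order: synthetic generation (or input loading), replicate
#' concordance and differential transcription, SNP calling and differential
#' classification, effect annotation, gene-level aggregation, and category
#' enrichment. Every stage's table is written as TSV under `out_dir`
#' together with a plain-text run manifest; re-running an identical
#' configuration reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage record-count logging.
#' @return object of class `pooldiff_result`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a pipeline_config")
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (config$mode == "synthetic") {
    log("stage simulate: generating synthetic dataset (seed %d)", config$sim$seed)
    sim <- simulate_dataset(config$sim, file.path(config$out_dir, "inputs"))
    genome <- sim$genome; models <- sim$models
    counts <- sim$counts; manifest <- sim$manifest
    pileups <- sim$pileups; categories <- sim$categories
  } else {
    sim <- NULL
    genome <- read_genome(config$paths$genome)
    models <- read_gene_models(config$paths$gff)
    counts <- read_tsv(config$paths$counts)
    manifest <- read_tsv(config$paths$manifest)
    pstrain <- grep("^pileup_", names(config$paths), value = TRUE)
    pileups <- lapply(config$paths[pstrain], read_tsv)
    names(pileups) <- sub("^pileup_", "", pstrain)
    categories <- if (!is.null(config$paths$categories))
      read_tsv(config$paths$categories) else NULL
  }
  sus <- unique(manifest$strain[manifest$role == "parental"])
  selected <- setdiff(unique(manifest$strain), sus)

  log("stage expression: %d genes, %d libraries", nrow(counts),
      nrow(manifest))
  rpkm <- compute_rpkm(counts, manifest)
  r2 <- vapply(unique(manifest$strain), function(s) {
    libs <- manifest$library_id[manifest$strain == s]
    if (length(libs) == 2)
      replicate_concordance(rpkm, libs, config$detect_min) else NA_real_
  }, numeric(1))
  de <- call_de(counts, manifest, alpha = config$alpha_de,
                fc_min = config$fc_min, detect_min = config$detect_min,
                epsilon = config$epsilon)
  overlap <- if (length(selected) >= 2)
    overlap_summary(de[de$comparison %in% selected[1:2], ]) else
      overlap_summary(de)
  log("stage expression: %d detected, %d differential calls",
      sum(de$detected[de$comparison == selected[1]]),
      sum(de$call != "NS"))

  log("stage variants: %d pileup sites/strain", nrow(pileups[[1]]))
  snps <- call_snps(pileups, genome, susceptible = sus, selected = selected,
                    min_run = config$min_run, cov_detect = config$cov_detect,
                    qual_min = config$qual_min, cov_min = config$cov_min,
                    dfreq_min = config$dfreq_min)
  log("stage variants: %d SNPs called", nrow(snps))

  effects <- annotate_effects(snps, models, genome, flank = config$flank)
  gene_table <- aggregate_by_gene(effects, de)
  log("stage effects: %d effect rows, %d genes hit", nrow(effects),
      nrow(gene_table))

  enrichment <- NULL; burden <- NULL
  if (!is.null(categories)) {
    names(categories)[1:2] <- c("gene_id", "term")
    universe <- unique(de$gene_id[de$detected])
    de_genes <- intersect(unique(de$gene_id[de$call != "NS"]), universe)
    snp_genes <- intersect(gene_table$gene_id[gene_table$n_differential > 0],
                           universe)
    enrichment <- list(
      de = enrich(de_genes, universe, categories, config$alpha_enrich),
      snp = enrich(snp_genes, universe, categories, config$alpha_enrich))
    names(categories)[2] <- "category"
    burden <- tryCatch(
      burden_compare(effects, categories),
      warning = function(w) { list(table = NULL, p_value = 1) })
    log("stage enrichment: %d + %d terms tested",
        nrow(enrichment$de), nrow(enrichment$snp))
  }

  res <- structure(list(config = config, manifest = manifest,
                        replicate_r2 = r2, de = de, overlap = overlap,
                        snps = snps, effects = effects,
                        gene_table = gene_table, enrichment = enrichment,
                        burden = burden, sim = sim),
                   class = "pooldiff_result")
  res$summary <- summary_table(res)
  write_pipeline_outputs(res)
  res
}

write_pipeline_outputs <- function(res) {
  out <- res$config$out_dir
  wtsv <- function(df, f) utils::write.table(
    df, file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(res$de, "de_results.tsv")
  wtsv(res$snps, "snp_records.tsv")
  wtsv(res$effects, "snp_effects.tsv")
  wtsv(res$gene_table, "gene_table.tsv")
  if (!is.null(res$enrichment)) {
    wtsv(res$enrichment$de, "enrichment_de.tsv")
    wtsv(res$enrichment$snp, "enrichment_snp.tsv")
  }
  qcols <- grep("_qualifies$", names(res$snps), value = TRUE)
  if (length(qcols)) {
    qual <- apply(res$snps[qcols], 1, function(v) any(v %in% TRUE))
    if (any(qual))
      write_vcf(res$snps[qual, , drop = FALSE],
                file.path(out, "differential_snps.vcf"))
  }
  cfg <- res$config
  manifest_lines <- c(
    "pooldiff run manifest",
    sprintf("package_version: %s",
            as.character(utils::packageVersion("pooldiff"))),
    sprintf("mode: %s", cfg$mode),
    if (cfg$mode == "synthetic") sprintf("seed: %d", cfg$sim$seed),
    sprintf("thresholds: detect_min=%g alpha_de=%g fc_min=%g cov_detect=%g cov_min=%g dfreq_min=%g flank=%d alpha_enrich=%g",
            cfg$detect_min, cfg$alpha_de, cfg$fc_min, cfg$cov_detect,
            cfg$cov_min, cfg$dfreq_min, cfg$flank, cfg$alpha_enrich))
  writeLines(manifest_lines, file.path(out, "run_manifest.txt"))
  invisible(res)
}

#' Report-style summary of a pipeline run
#'
#' Per comparison and combined: counts and percentages (one decimal,
#' half-up) of over/under-transcribed transcripts among detected
#' transcripts; SNP totals, qualifying SNPs and affected genes; and the
#' effect-class distribution of differential SNPs (a partition summing to
#' 100 percent up to rounding).
#'
#' @param res a `pooldiff_result`.
#' @return list with `de` (data.frame), `snp` (named vector) and
#'   `effect_classes` (data.frame).
#' @export
summary_table <- function(res) {
  de <- res$de
  comps <- unique(de$comparison)
  rows <- lapply(comps, function(s) {
    xi <- de[de$comparison == s, ]
    n_det <- sum(xi$detected)
    data.frame(comparison = s, detected = n_det,
               over = sum(xi$call == "over"),
               over_pct = pct1(sum(xi$call == "over"), n_det),
               under = sum(xi$call == "under"),
               under_pct = pct1(sum(xi$call == "under"), n_det),
               de_total = sum(xi$call != "NS"),
               de_pct = pct1(sum(xi$call != "NS"), n_det))
  })
  any_gene <- unique(de$gene_id[de$call != "NS"])
  n_det_any <- length(unique(de$gene_id[de$detected]))
  rows <- c(rows, list(data.frame(
    comparison = "any", detected = n_det_any,
    over = NA, over_pct = NA, under = NA, under_pct = NA,
    de_total = length(any_gene), de_pct = pct1(length(any_gene), n_det_any))))
  de_tab <- do.call(rbind, rows)

  qcols <- grep("_qualifies$", names(res$snps), value = TRUE)
  qual <- if (length(qcols))
    apply(res$snps[qcols], 1, function(v) any(v %in% TRUE)) else logical(nrow(res$snps))
  snp_sum <- c(snps_called = nrow(res$snps),
               differential_snps = sum(qual),
               affected_genes = sum(res$gene_table$n_differential > 0))

  eff <- res$effects
  key <- paste(eff$contig, eff$pos)
  qual_eff <- eff[key %in% paste(res$snps$contig[qual], res$snps$pos[qual]) &
                    !duplicated(key), , drop = FALSE]
  cls <- table(factor(qual_eff$effect,
                      c("five_prime_UTR", "synonymous", "non_synonymous",
                        "three_prime_UTR", "other")))
  effect_classes <- data.frame(effect = names(cls), n = as.integer(cls),
                               pct = vapply(as.integer(cls), pct1,
                                            numeric(1), den = sum(cls)))
  list(de = de_tab, snp = snp_sum, effect_classes = effect_classes)
}

#' @export
print.pooldiff_result <- function(x, ...) {
  cat("pooldiff pipeline result\n")
  cat(sprintf("  mode: %s\n", x$config$mode))
  r2 <- x$replicate_r2[!is.na(x$replicate_r2)]
  if (length(r2))
    cat(sprintf("  replicate r^2: %s\n",
                paste(sprintf("%s=%.3f", names(r2), r2), collapse = ", ")))
  print(x$summary$de, row.names = FALSE)
  cat(sprintf("  SNPs: %d called, %d differential, %d genes affected\n",
              x$summary$snp["snps_called"],
              x$summary$snp["differential_snps"],
              x$summary$snp["affected_genes"]))
  invisible(x)
}

#' @export
summary.pooldiff_result <- function(object, ...) object$summary
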