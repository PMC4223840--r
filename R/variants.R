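## SNP calling from per-strain pileup allele counts: homopolymer masking,
## detection filters, pooled allele-frequency estimation, and differential
## classification between each selected strain and the susceptible parent.

#' Mask positions in and next to homopolymer runs
#'
#' Finds every maximal single-base run of length `>= min_run` and returns all
#' positions inside the run plus the single flanking position on each side.
#' The default `min_run = 11` masks runs longer than 10 nucleotides.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character vector.
#' @param min_run minimum run length to mask (`>= 2`).
#' @return data.frame `contig, pos` of masked positions.
#' @export
mask_homopolymers <- function(genome, min_run = 11L) {
  if (min_run < 2) stopf("min_run must be >= 2")
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  out <- lapply(names(genome), function(contig) {
    r <- rle(strsplit(genome[[contig]], "")[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$lengths >= min_run)
    if (!length(keep)) return(NULL)
    pos <- unlist(lapply(keep, function(i)
      max(1L, starts[i] - 1L):min(nchar(genome[[contig]]), ends[i] + 1L)))
    data.frame(contig = contig, pos = pos)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(contig = character(), pos = integer()) else out
}

#' Pooled allele frequency
#'
#' Variant-allele percentage among reference-plus-variant reads,
#' `100 * var / (ref + var)`; other alleles at the site are excluded from the
#' denominator. Reports are rounded to one decimal elsewhere; this returns
#' the unrounded value.
#'
#' @param ref_count,var_count read counts (vectorized).
#' @return frequency in percent.
#' @export
allele_frequency <- function(ref_count, var_count) {
  if (any(ref_count < 0) || any(var_count < 0)) stopf("counts must be non-negative")
  den <- ref_count + var_count
  if (any(den < 1))
    stopf("undefined allele frequency: reference plus variant coverage is zero")
  100 * var_count / den
}

merge_pileups <- function(pileups) {
  strains <- names(pileups)
  need <- c("contig", "pos_1based", "ref_base", DNA_BASES, "site_quality")
  for (s in strains) {
    if (!all(need %in% names(pileups[[s]])))
      stopf("pileup for strain %s lacks required columns", s)
    if (any(!pileups[[s]]$ref_base %in% DNA_BASES))
      stopf("pileup position without valid reference base (strain %s)", s)
  }
  key <- function(df) paste(df$contig, df$pos_1based)
  keys <- Reduce(intersect, lapply(pileups, key))
  merged <- NULL
  for (s in strains) {
    df <- pileups[[s]]
    df <- df[match(keys, key(df)), ]
    if (is.null(merged)) {
      merged <- df[c("contig", "pos_1based", "ref_base")]
      names(merged)[2] <- "pos"
    } else if (any(df$ref_base != merged$ref_base)) {
      stopf("reference base disagrees across strain pileups")
    }
    for (b in DNA_BASES) merged[[paste0(s, "_", b)]] <- df[[b]]
    merged[[paste0(s, "_qual")]] <- df$site_quality
  }
  merged
}

#' Detect candidate SNPs from pileups
#'
#' A site yields a record when it is not masked, its site quality reaches
#' `qual_min` in every strain, at least one strain has total coverage
#' strictly above `cov_detect`, and a non-reference allele is observed. The
#' variant allele is the most frequent non-reference allele summed over
#' strains (ties broken by base order A<C<G<T); remaining non-reference
#' alleles are dropped from the frequency denominator. Per-strain frequency
#' is `NA` (flagged, not zero) where reference-plus-variant coverage is zero.
#'
#' @param pileups named list, strain -> pileup data.frame
#'   (`contig, pos_1based, ref_base, A, C, G, T, site_quality`).
#' @param masked data.frame `contig, pos` from [mask_homopolymers()], or NULL.
#' @param cov_detect per-strain total-coverage detection threshold
#'   (strict `>`, default 20).
#' @param qual_min site-quality floor (default 0, permissive).
#' @return data.frame of class `snp_set`: `contig, pos, ref, var`, then per
#'   strain `<strain>_freq` (percent) and `<strain>_cov` (total coverage).
#' @export
detect_snps <- function(pileups, masked = NULL, cov_detect = 20, qual_min = 0) {
  strains <- names(pileups)
  merged <- merge_pileups(pileups)
  if (!is.null(masked) && nrow(masked)) {
    bad <- paste(merged$contig, merged$pos) %in% paste(masked$contig, masked$pos)
    merged <- merged[!bad, , drop = FALSE]
  }
  if (nrow(merged) == 0)
    return(empty_snp_set(strains))

  counts <- function(s) as.matrix(merged[paste0(s, "_", DNA_BASES)])
  total_cov <- sapply(strains, function(s) rowSums(counts(s)))
  qual <- sapply(strains, function(s) merged[[paste0(s, "_qual")]])
  if (is.null(dim(total_cov))) {  # single row
    total_cov <- matrix(total_cov, nrow = 1, dimnames = list(NULL, strains))
    qual <- matrix(qual, nrow = 1, dimnames = list(NULL, strains))
  }

  pooled <- Reduce(`+`, lapply(strains, counts))
  colnames(pooled) <- DNA_BASES
  ref_idx <- match(merged$ref_base, DNA_BASES)
  nonref <- pooled
  nonref[cbind(seq_len(nrow(pooled)), ref_idx)] <- -1L  # exclude ref from argmax
  var_idx <- max.col(nonref, ties.method = "first")
  has_var <- nonref[cbind(seq_len(nrow(pooled)), var_idx)] > 0

  keep <- has_var &
    apply(total_cov > cov_detect, 1, any) &
    apply(qual >= qual_min, 1, all)
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) return(empty_snp_set(strains))
  ref_idx <- ref_idx[keep]; var_idx <- var_idx[keep]
  total_cov <- total_cov[keep, , drop = FALSE]

  out <- data.frame(contig = merged$contig, pos = merged$pos,
                    ref = merged$ref_base, var = DNA_BASES[var_idx],
                    row.names = NULL)
  for (s in strains) {
    cm <- counts(s)
    refc <- cm[cbind(seq_len(nrow(cm)), ref_idx)]
    varc <- cm[cbind(seq_len(nrow(cm)), var_idx)]
    den <- refc + varc
    freq <- ifelse(den >= 1, 100 * varc / den, NA_real_)
    out[[paste0(s, "_freq")]] <- freq
    out[[paste0(s, "_cov")]] <- total_cov[, s]
  }
  structure(out, class = c("snp_set", "data.frame"), strains = strains)
}

empty_snp_set <- function(strains) {
  out <- data.frame(contig = character(), pos = integer(),
                    ref = character(), var = character())
  for (s in strains) {
    out[[paste0(s, "_freq")]] <- numeric()
    out[[paste0(s, "_cov")]] <- numeric()
  }
  structure(out, class = c("snp_set", "data.frame"), strains = strains)
}

#' Classify differential SNPs between a selected strain and the parent
#'
#' A record qualifies when the summed coverage of the two compared strains
#' at the site reaches `cov_min` and the absolute allele-frequency
#' difference (selected minus susceptible, percentage points) reaches
#' `dfreq_min`. Sites with an undefined frequency in either strain never
#' qualify.
#'
#' @param snps a `snp_set` from [detect_snps()].
#' @param susceptible,selected strain names present in the record columns.
#' @param cov_min summed-coverage threshold (default 30).
#' @param dfreq_min frequency-difference threshold in points (default 40).
#' @return `snps` with added columns `<selected>_delta` and
#'   `<selected>_qualifies`.
#' @export
classify_differential <- function(snps, susceptible, selected,
                                  cov_min = 30, dfreq_min = 40) {
  for (s in c(susceptible, selected))
    if (!paste0(s, "_freq") %in% names(snps))
      stopf("strain %s absent from SNP records", s)
  fs <- snps[[paste0(susceptible, "_freq")]]
  fy <- snps[[paste0(selected, "_freq")]]
  pair_cov <- snps[[paste0(susceptible, "_cov")]] +
    snps[[paste0(selected, "_cov")]]
  delta <- fy - fs
  snps[[paste0(selected, "_delta")]] <- delta
  snps[[paste0(selected, "_qualifies")]] <-
    !is.na(delta) & pair_cov >= cov_min & abs(delta) >= dfreq_min
  snps
}

#' Call and classify SNPs end-to-end
#'
#' Convenience wrapper: homopolymer masking, detection, and differential
#' classification of every selected strain against the susceptible parent.
#'
#' @inheritParams detect_snps
#' @inheritParams classify_differential
#' @param genome reference genome for homopolymer masking (skipped if NULL).
#' @param min_run homopolymer mask threshold (runs `>= min_run`; default 11).
#' @return a `snp_set` with `_delta`/`_qualifies` columns per selected strain.
#' @export
call_snps <- function(pileups, genome = NULL, susceptible, selected,
                      min_run = 11L, cov_detect = 20, qual_min = 0,
                      cov_min = 30, dfreq_min = 40) {
  masked <- if (is.null(genome)) NULL else mask_homopolymers(genome, min_run)
  snps <- detect_snps(pileups, masked, cov_detect, qual_min)
  for (s in selected)
    snps <- classify_differential(snps, susceptible, s, cov_min, dfreq_min)
  snps
}

#' @export
print.snp_set <- function(x, ...) {
  qcols <- grep("_qualifies$", names(x), value = TRUE)
  cat(sprintf("SNP set: %d biallelic substitution(s)\n", nrow(x)))
  for (qc in qcols)
    cat(sprintf("  %s: %d differential\n", sub("_qualifies$", "", qc),
                sum(x[[qc]], na.rm = TRUE)))
  invisible(x)
}

#' Export qualifying SNPs as a minimal VCF 4.2
#'
#' Writes biallelic substitutions with per-strain variant-allele frequency
#' (fraction) and total depth in the INFO field.
#'
#' @param snps a `snp_set` (typically filtered to qualifying records).
#' @param path output file path.
#' @param strains strain names to export; default all in the record.
#' @return (invisibly) the path.
#' @export
write_vcf <- function(snps, path, strains = NULL) {
  if (is.null(strains))
    strains <- sub("_freq$", "", grep("_freq$", names(snps), value = TRUE))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pooldiff",
           sprintf("##INFO=<ID=AF_%s,Number=1,Type=Float,Description=\"Variant allele frequency in %s\">",
                   strains, strains),
           sprintf("##INFO=<ID=DP_%s,Number=1,Type=Integer,Description=\"Total read depth in %s\">",
                   strains, strains),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(snps)), function(i) {
    parts <- unlist(lapply(strains, function(s) {
      f <- snps[[paste0(s, "_freq")]][i]
      c(sprintf("AF_%s=%s", s, ifelse(is.na(f), ".", sprintf("%.4f", f / 100))),
        sprintf("DP_%s=%d", s, as.integer(snps[[paste0(s, "_cov")]][i])))
    }))
    paste(parts, collapse = ";")
  }, character(1))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  snps$contig, snps$pos, snps$ref, snps$var, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
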