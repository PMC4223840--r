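## Genic-context and protein-consequence annotation of SNPs against gene
## models, on either strand, with codon-aware translation via the standard
## genetic code. Minus-strand genes: pileup alleles are reported on the
## forward genome strand and complemented onto the coding strand here.

region_granges <- function(models) {
  mk <- function(get, region) {
    dfs <- lapply(models, function(m) {
      iv <- get(m)
      if (is.null(iv) || nrow(iv) == 0) return(NULL)
      data.frame(contig = m$contig, start = iv$start, end = iv$end,
                 gene_id = m$gene_id, region = region)
    })
    do.call(rbind, dfs)
  }
  df <- rbind(mk(function(m) m$cds, "CDS"),
              mk(function(m) m$utr5, "five_prime_UTR"),
              mk(function(m) m$utr3, "three_prime_UTR"),
              mk(function(m) data.frame(start = m$start, end = m$end), "gene"))
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$region <- df$region
  gr
}

#' Locate SNPs relative to gene models
#'
#' Assigns each SNP its genic region: `five_prime_UTR`, `CDS`,
#' `three_prime_UTR`, or `intron` when inside a gene; `other` with the
#' nearest gene id when within `flank` bp of a gene; `other` with no gene
#' otherwise. A SNP overlapping several genes is assigned to each and
#' flagged `multi_gene`.
#'
#' @param snps data.frame with `contig` and `pos` columns.
#' @param models named list of gene models (see [read_gene_models()]).
#' @param flank distance (bp) within which an intergenic SNP is linked to
#'   its nearest gene (default 1000).
#' @return data.frame `contig, pos, gene_id, region, multi_gene`, one row
#'   per SNP-gene assignment (one row with `gene_id = NA` for intergenic).
#' @export
locate_snps <- function(snps, models, flank = 1000L) {
  contigs <- unique(vapply(models, `[[`, character(1), "contig"))
  unknown <- setdiff(unique(snps$contig), contigs)
  if (length(unknown))
    stopf("SNP on unknown contig: %s", paste(unknown, collapse = ", "))
  gr <- region_granges(models)
  q <- GenomicRanges::GRanges(snps$contig, IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(q, gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  gene_id <- S4Vectors::mcols(gr)$gene_id[sh]
  region <- S4Vectors::mcols(gr)$region[sh]

  prec <- c(CDS = 1L, five_prime_UTR = 2L, three_prime_UTR = 3L, gene = 4L)
  out <- NULL
  for (i in seq_len(nrow(snps))) {
    j <- which(qh == i)
    if (length(j)) {
      genes <- unique(gene_id[j])
      multi <- length(genes) > 1
      for (g in genes) {
        regs <- region[j][gene_id[j] == g]
        best <- regs[which.min(prec[regs])]
        if (best == "gene") best <- "intron"
        out <- rbind(out, data.frame(contig = snps$contig[i], pos = snps$pos[i],
                                     gene_id = g, region = best,
                                     multi_gene = multi))
      }
    } else {
      gg <- gr[S4Vectors::mcols(gr)$region == "gene"]
      near <- GenomicRanges::distanceToNearest(q[i], gg)
      g <- NA_character_
      if (length(near) && S4Vectors::mcols(near)$distance <= flank)
        g <- S4Vectors::mcols(gg)$gene_id[S4Vectors::subjectHits(near)]
      out <- rbind(out, data.frame(contig = snps$contig[i], pos = snps$pos[i],
                                   gene_id = g, region = "other",
                                   multi_gene = FALSE))
    }
  }
  out
}

#' Spliced CDS coordinate of a genomic position
#'
#' 1-based position within the spliced CDS, counted in coding (transcript)
#' orientation: for minus-strand genes the first CDS base is the 3'-most
#' genomic CDS base. The amino-acid index is `ceiling(cds_pos / 3)`.
#'
#' @param pos genomic position (1-based).
#' @param model a gene model.
#' @return list with `cds_pos` and `codon_index`.
#' @export
cds_coordinate <- function(pos, model) {
  gpos <- cds_genomic_positions(model)
  i <- match(pos, gpos)
  if (is.na(i))
    stopf("position %d is not within a CDS interval of %s", pos, model$gene_id)
  list(cds_pos = i, codon_index = as.integer(ceiling(i / 3)))
}

#' Protein-level consequence of a coding SNP
#'
#' Builds the reference codon from the spliced CDS, substitutes the variant
#' base (complemented for minus-strand genes, since pileup alleles are on
#' the forward genome strand), translates both with the standard genetic
#' code, and classifies the change as synonymous or non-synonymous. Stop
#' gain/loss is non-synonymous with `*` as the amino-acid letter. The label
#' follows the `A847S` convention.
#'
#' @param snp one-row data.frame (or list) with `contig, pos, ref, var`,
#'   alleles on the forward genome strand.
#' @param model the gene model whose CDS contains the position.
#' @param genome named [Biostrings::DNAStringSet].
#' @return list `effect, cds_pos, codon_index, ref_aa, alt_aa, label`.
#' @export
consequence <- function(snp, model, genome) {
  genome_base <- as.character(Biostrings::subseq(genome[[model$contig]],
                                                 snp$pos, snp$pos))
  if (genome_base != snp$ref)
    stopf("reference mismatch at %s:%d (genome %s, record %s)",
          snp$contig, snp$pos, genome_base, snp$ref)
  cc <- cds_coordinate(snp$pos, model)
  cds_seq <- extract_spliced_cds(genome, model)
  if (nchar(cds_seq) %% 3 != 0)
    stopf("spliced CDS of %s is not a multiple of 3", model$gene_id)
  ref_codon <- substr(cds_seq, 3L * cc$codon_index - 2L, 3L * cc$codon_index)
  pos_in_codon <- cc$cds_pos - 3L * (cc$codon_index - 1L)
  var_coding <- if (model$strand == "+") snp$var else unname(comp_base(snp$var))
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- var_coding
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon]); alt_aa <- unname(code[alt_codon])
  effect <- if (ref_aa == alt_aa) "synonymous" else "non_synonymous"
  list(effect = effect, cds_pos = cc$cds_pos, codon_index = cc$codon_index,
       ref_aa = ref_aa, alt_aa = alt_aa,
       label = paste0(ref_aa, cc$codon_index, alt_aa))
}

#' Annotate effects for a set of SNPs
#'
#' Runs [locate_snps()] and, for coding positions, [consequence()]. Each SNP
#' receives exactly one effect class from `{five_prime_UTR, synonymous,
#' non_synonymous, three_prime_UTR, other}` (introns and intergenic
#' positions are `other`); the finer region is kept in `region`. A SNP
#' overlapping several genes contributes one row per gene (flagged);
#' synthetic annotations never do.
#'
#' @param snps a `snp_set` (or any data.frame with `contig, pos, ref, var`).
#' @param models named list of gene models.
#' @param genome named [Biostrings::DNAStringSet].
#' @param flank nearest-gene flank for intergenic SNPs (default 1000).
#' @return `snps` joined with `gene_id, region, effect, cds_pos,
#'   codon_index, ref_aa, alt_aa, label, multi_gene`.
#' @export
annotate_effects <- function(snps, models, genome, flank = 1000L) {
  loc <- locate_snps(snps, models, flank)
  key <- paste(snps$contig, snps$pos)
  loc_key <- paste(loc$contig, loc$pos)
  idx <- match(loc_key, key)
  out <- cbind(snps[idx, setdiff(names(snps), c("contig", "pos")),
                    drop = FALSE],
               loc, row.names = NULL)
  out$effect <- ifelse(out$region %in% c("five_prime_UTR", "three_prime_UTR"),
                       out$region, "other")
  out$cds_pos <- NA_integer_; out$codon_index <- NA_integer_
  out$ref_aa <- NA_character_; out$alt_aa <- NA_character_
  out$label <- NA_character_
  coding <- which(out$region == "CDS")
  for (i in coding) {
    cq <- consequence(list(contig = out$contig[i], pos = out$pos[i],
                           ref = out$ref[i], var = out$var[i]),
                      models[[out$gene_id[i]]], genome)
    out$effect[i] <- cq$effect
    out$cds_pos[i] <- cq$cds_pos
    out$codon_index[i] <- cq$codon_index
    out$ref_aa[i] <- cq$ref_aa
    out$alt_aa[i] <- cq$alt_aa
    out$label[i] <- cq$label
  }
  front <- c("contig", "pos", "ref", "var", "gene_id", "region", "effect",
             "cds_pos", "codon_index", "ref_aa", "alt_aa", "label",
             "multi_gene")
  out[c(front, setdiff(names(out), front))]
}

#' Aggregate SNP effects to gene level and join expression calls
#'
#' Per gene: number of SNPs, of differential SNPs (qualifying in any
#' comparison), and of non-synonymous differential SNPs; joined with the
#' gene's differential-transcription calls. The attribute `overlap` counts
#' genes that are both differentially transcribed and hit by a
#' non-synonymous differential SNP.
#'
#' @param effects output of [annotate_effects()] carrying
#'   `<comparison>_qualifies` columns.
#' @param de optional `de_result` from [call_de()].
#' @return data.frame `gene_id, n_snps, n_differential, n_nonsyn_differential`
#'   plus one `de_<comparison>` column per comparison, with attribute
#'   `overlap`.
#' @export
aggregate_by_gene <- function(effects, de = NULL) {
  qcols <- grep("_qualifies$", names(effects), value = TRUE)
  genic <- effects[!is.na(effects$gene_id) & effects$region != "other", ,
                   drop = FALSE]
  qual_any <- if (length(qcols))
    apply(genic[qcols], 1, function(v) any(v %in% TRUE)) else
      rep(FALSE, nrow(genic))
  genes <- sort(unique(genic$gene_id))
  tab <- data.frame(
    gene_id = genes,
    n_snps = as.integer(table(factor(genic$gene_id, genes))),
    n_differential = as.integer(table(factor(genic$gene_id[qual_any], genes))),
    n_nonsyn_differential = as.integer(table(factor(
      genic$gene_id[qual_any & genic$effect == "non_synonymous"], genes))))
  de_any <- character(0)
  if (!is.null(de)) {
    for (s in unique(de$comparison)) {
      di <- de[de$comparison == s, ]
      tab[[paste0("de_", s)]] <- di$call[match(tab$gene_id, di$gene_id)]
    }
    de_any <- unique(de$gene_id[de$call != "NS"])
  }
  overlap <- c(
    genes_with_differential_snps = sum(tab$n_differential > 0),
    genes_with_nonsyn_differential = sum(tab$n_nonsyn_differential > 0),
    genes_de = length(de_any),
    genes_de_and_nonsyn = length(intersect(
      de_any, tab$gene_id[tab$n_nonsyn_differential > 0])))
  structure(tab, overlap = overlap)
}
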