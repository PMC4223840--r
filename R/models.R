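## Gene-model infrastructure shared by the simulator and the effect annotator.
## Models are plain lists (class "gene_model") holding genomic feature
## intervals, 1-based inclusive, exon/CDS/UTR ranges sorted by ascending
## genomic coordinate; transcription order is derived from the strand.

new_gene_model <- function(gene_id, tx_id, contig, strand, start, end,
                           exons, cds, utr5, utr3) {
  m <- list(gene_id = gene_id, tx_id = tx_id, contig = contig,
            strand = strand, start = start, end = end,
            exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
  m$exonic_length <- sum(exons$end - exons$start + 1L)
  m$cds_length <- sum(cds$end - cds$start + 1L)
  class(m) <- "gene_model"
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d (%s), %d exon(s), CDS %d bp\n",
              x$gene_id, x$tx_id, x$contig, x$start, x$end, x$strand,
              nrow(x$exons), x$cds_length))
  invisible(x)
}

## Genomic position of every spliced-CDS base, in transcription order
## (element i is the genome coordinate of CDS base i, 5'->3' on the mRNA).
cds_genomic_positions <- function(model) {
  cds <- model$cds
  if (model$strand == "+") {
    unlist(lapply(order(cds$start), function(i) cds$start[i]:cds$end[i]))
  } else {
    unlist(lapply(order(cds$start, decreasing = TRUE),
                  function(i) cds$end[i]:cds$start[i]))
  }
}

## Intron intervals (genomic ascending); empty data.frame for single-exon genes
intron_intervals <- function(model) {
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  if (nrow(ex) < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

## Spliced CDS sequence (coding strand, 5'->3'), as a character scalar
extract_spliced_cds <- function(genome, model) {
  contig_seq <- genome[[model$contig]]
  cds <- model$cds[order(model$cds$start), , drop = FALSE]
  pieces <- vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(contig_seq, cds$start[i], cds$end[i])),
    character(1))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

## CDS phase per piece, in transcription order, mapped back onto the
## ascending-genomic row order of model$cds
cds_phases <- function(model) {
  cds <- model$cds
  ord <- if (model$strand == "+") order(cds$start) else order(cds$start, decreasing = TRUE)
  len <- cds$end - cds$start + 1L
  phase <- integer(nrow(cds))
  cum <- 0L
  for (i in ord) {
    phase[i] <- (3L - cum %% 3L) %% 3L
    cum <- cum + len[i]
  }
  phase
}

gff_attr <- function(x, key) {
  m <- regmatches(x, regexpr(paste0(key, "=[^;]+"), x))
  ifelse(length(m) == 0, NA_character_, sub(paste0(key, "="), "", m))
}

## Serialize models to GFF3 text (1-based inclusive, ID/Parent attributes)
gff3_text <- function(models, contig_lengths) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(contig_lengths), contig_lengths))
  src <- "pooldiff_sim"
  fmt <- function(contig, type, start, end, strand, phase, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            contig, src, type, start, end, strand, phase, attrs)
  for (m in models) {
    lines <- c(lines,
      fmt(m$contig, "gene", m$start, m$end, m$strand, ".",
          sprintf("ID=%s", m$gene_id)),
      fmt(m$contig, "mRNA", m$start, m$end, m$strand, ".",
          sprintf("ID=%s;Parent=%s", m$tx_id, m$gene_id)))
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    for (i in seq_len(nrow(ex)))
      lines <- c(lines, fmt(m$contig, "exon", ex$start[i], ex$end[i],
                            m$strand, ".",
                            sprintf("ID=%s.exon%d;Parent=%s", m$tx_id, i, m$tx_id)))
    cds <- m$cds[order(m$cds$start), , drop = FALSE]
    ph <- cds_phases(m)[order(m$cds$start)]
    for (i in seq_len(nrow(cds)))
      lines <- c(lines, fmt(m$contig, "CDS", cds$start[i], cds$end[i],
                            m$strand, as.character(ph[i]),
                            sprintf("ID=%s.cds;Parent=%s", m$tx_id, m$tx_id)))
    for (ut in c("utr5", "utr3")) {
      type <- if (ut == "utr5") "five_prime_UTR" else "three_prime_UTR"
      uu <- m[[ut]]
      if (is.null(uu) || nrow(uu) == 0) next
      uu <- uu[order(uu$start), , drop = FALSE]
      for (i in seq_len(nrow(uu)))
        lines <- c(lines, fmt(m$contig, type, uu$start[i], uu$end[i],
                              m$strand, ".",
                              sprintf("ID=%s.%s.%d;Parent=%s", m$tx_id, type, i, m$tx_id)))
    }
  }
  lines
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/UTR features (via [rtracklayer::import]) into the
#' package's gene-model representation. One mRNA per gene is assumed, as in
#' the synthetic annotation; for multi-isoform annotations the first mRNA of
#' each gene is used.
#'
#' @param path path to a GFF3 file with `ID`/`Parent` attributes.
#' @return named list of `gene_model` objects, keyed by `gene_id`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  mrna <- df[df$type == "mRNA", ]
  models <- list()
  for (i in seq_len(nrow(mrna))) {
    tx <- mrna$ID[i]
    gene <- mrna$Parent[i]
    if (gene %in% names(models)) next
    kids <- df[!is.na(df$Parent) & df$Parent == tx, ]
    iv <- function(type) {
      k <- kids[kids$type == type, , drop = FALSE]
      data.frame(start = as.integer(k$start), end = as.integer(k$end))
    }
    models[[gene]] <- new_gene_model(
      gene_id = gene, tx_id = tx,
      contig = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      start = as.integer(mrna$start[i]), end = as.integer(mrna$end[i]),
      exons = iv("exon"), cds = iv("CDS"),
      utr5 = iv("five_prime_UTR"), utr3 = iv("three_prime_UTR"))
  }
  models
}

#' Read a reference genome FASTA
#'
#' @param path FASTA file path.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
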