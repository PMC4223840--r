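## mini fixture: one gene with transcript GGGGGGGGGG + ATG GCT TTA TGG TGA +
## CCCCCCCCCC (protein MALW*), single exon, placed at 11..45 on a 55 bp
## contig, on either strand
mini_gene <- function(strand = "+") {
  tx <- paste0("GGGGGGGGGG", "ATGGCTTTATGGTGA", "CCCCCCCCCC")
  pad <- "ACGTACGTAC"
  locus <- if (strand == "+") tx else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  genome <- Biostrings::DNAStringSet(c(c1 = paste0(pad, locus, pad)))
  iv <- function(s, e) data.frame(start = s, end = e)
  if (strand == "+") {
    utr5 <- iv(11L, 20L); cds <- iv(21L, 35L); utr3 <- iv(36L, 45L)
  } else {
    utr3 <- iv(11L, 20L); cds <- iv(21L, 35L); utr5 <- iv(36L, 45L)
  }
  model <- pooldiff:::new_gene_model("gX", "gX.t1", "c1", strand, 11L, 45L,
                                     exons = iv(11L, 45L), cds = cds,
                                     utr5 = utr5, utr3 = utr3)
  list(genome = genome, model = model)
}

test_that("locate_snps assigns regions by containment and flank distance", {
  fx <- mini_gene("+")
  models <- list(gX = fx$model)
  snps <- data.frame(contig = "c1", pos = c(15L, 25L, 40L, 50L))
  loc <- locate_snps(snps, models, flank = 3L)
  expect_identical(loc$region, c("five_prime_UTR", "CDS", "three_prime_UTR",
                                 "other"))
  expect_identical(loc$gene_id[1], "gX")
  expect_true(is.na(loc$gene_id[4]))                  # > 3 bp from the gene
  loc2 <- locate_snps(snps, models, flank = 1000L)
  expect_identical(loc2$gene_id[4], "gX")             # near-gene "other"
  expect_error(locate_snps(data.frame(contig = "nope", pos = 1L), models),
               "unknown contig")
})

test_that("cds_coordinate maps genomic to spliced coding positions", {
  ## large single-exon plus-strand CDS: position 2539 sits in codon 847
  big <- pooldiff:::new_gene_model(
    "gBig", "gBig.t1", "c1", "+", 1L, 2541L,
    exons = data.frame(start = 1L, end = 2541L),
    cds = data.frame(start = 1L, end = 2541L),
    utr5 = data.frame(start = integer(), end = integer()),
    utr3 = data.frame(start = integer(), end = integer()))
  cc <- cds_coordinate(2539L, big)
  expect_identical(cc$cds_pos, 2539L)
  expect_identical(cc$codon_index, 847L)
  expect_identical(cds_coordinate(1L, big)$codon_index, 1L)
  expect_identical(cds_coordinate(3L, big)$codon_index, 1L)
  expect_identical(cds_coordinate(4L, big)$codon_index, 2L)
  expect_error(cds_coordinate(4000L, big), "not within a CDS")
})

test_that("consequence classifies substitutions on both strands identically", {
  for (strand in c("+", "-")) {
    fx <- mini_gene(strand)
    gpos <- pooldiff:::cds_genomic_positions(fx$model)
    base_at <- function(p)
      as.character(Biostrings::subseq(fx$genome[["c1"]], p, p))
    flip <- function(b) if (strand == "+") b else unname(pooldiff:::comp_base(b))
    ## GCT -> TCT at codon 2 (cds_pos 4): Ala -> Ser, non-synonymous
    p4 <- gpos[4]
    cq <- consequence(list(contig = "c1", pos = p4, ref = base_at(p4),
                           var = flip("T")), fx$model, fx$genome)
    expect_identical(cq$label, "A2S")
    expect_identical(cq$effect, "non_synonymous")
    ## TTA -> TTG at codon 3 third position (cds_pos 9): Leu -> Leu
    p9 <- gpos[9]
    cq <- consequence(list(contig = "c1", pos = p9, ref = base_at(p9),
                           var = flip("G")), fx$model, fx$genome)
    expect_identical(cq$effect, "synonymous")
    expect_identical(cq$label, "L3L")
    ## TGG -> TGA at codon 4 (cds_pos 12): Trp -> stop, non-synonymous "*"
    p12 <- gpos[12]
    cq <- consequence(list(contig = "c1", pos = p12, ref = base_at(p12),
                           var = flip("A")), fx$model, fx$genome)
    expect_identical(cq$label, "W4*")
    expect_identical(cq$effect, "non_synonymous")
    ## reference mismatch is an error
    expect_error(consequence(list(contig = "c1", pos = p4,
                                  ref = flip("T"), var = flip("A")),
                             fx$model, fx$genome),
                 "reference mismatch")
  }
})

test_that("cds_coordinate round-trips through genomic positions", {
  sim <- tiny_sim()
  for (m in sim$models[1:6]) {
    gpos <- pooldiff:::cds_genomic_positions(m)
    probe <- gpos[c(1L, 5L, length(gpos))]
    for (i in seq_along(probe))
      expect_identical(cds_coordinate(probe[i], m)$cds_pos,
                       match(probe[i], gpos))
  }
})

test_that("annotated classes match the generator's intent for every site", {
  sim <- tiny_sim()
  tr <- sim$truth_snps[!sim$truth_snps$in_homopolymer, ]
  snps <- data.frame(contig = tr$contig, pos = tr$pos, ref = tr$ref,
                     var = tr$alt)
  eff <- annotate_effects(snps, sim$models, sim$genome)
  expect_identical(nrow(eff), nrow(tr))               # partition: one row each
  expected <- ifelse(tr$class == "intronic", "other",
                     ifelse(tr$class == "intergenic", "other", tr$class))
  expect_identical(eff$effect, expected)
  genic <- !tr$class %in% "intergenic"
  expect_identical(eff$gene_id[genic], tr$gene_id[genic])
})

test_that("consequences agree with a mutate-and-retranslate oracle", {
  skip_if_not_installed("seqinr")
  sim <- tiny_sim()
  tr <- sim$truth_snps[sim$truth_snps$class %in%
                         c("synonymous", "non_synonymous"), ]
  expect_setequal(unique(tr$strand), c("+", "-"))     # both strands exercised
  snps <- data.frame(contig = tr$contig, pos = tr$pos, ref = tr$ref,
                     var = tr$alt)
  eff <- annotate_effects(snps, sim$models, sim$genome)
  for (i in seq_len(nrow(eff))) {
    oracle <- mutated_protein_diff(sim$genome, sim$models[[eff$gene_id[i]]],
                                   eff$pos[i], eff$var[i])
    if (eff$effect[i] == "synonymous") {
      expect_identical(length(oracle$diff_at), 0L)
    } else {
      expect_identical(oracle$diff_at, eff$codon_index[i])
      expect_identical(substr(oracle$ref_prot, oracle$diff_at, oracle$diff_at),
                       eff$ref_aa[i])
      expect_identical(substr(oracle$mut_prot, oracle$diff_at, oracle$diff_at),
                       eff$alt_aa[i])
    }
  }
})

test_that("gene-level aggregation counts SNP classes and joins DE calls", {
  eff <- data.frame(contig = "c1", pos = 1:3, ref = "A", var = "C",
                    gene_id = "g1", region = "CDS",
                    effect = c("non_synonymous", "synonymous", "synonymous"),
                    sel_qualifies = c(TRUE, TRUE, FALSE))
  de <- data.frame(gene_id = c("g1", "g2"), comparison = "sel",
                   call = c("over", "NS"), detected = TRUE)
  tab <- aggregate_by_gene(eff, de)
  expect_identical(tab$n_snps, 3L)
  expect_identical(tab$n_differential, 2L)
  expect_identical(tab$n_nonsyn_differential, 1L)
  expect_identical(tab$de_sel, "over")
  ov <- attr(tab, "overlap")
  expect_equal(unname(ov["genes_de_and_nonsyn"]), 1)
  ## a gene with no SNPs contributes nothing
  expect_false("g2" %in% tab$gene_id)
})
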