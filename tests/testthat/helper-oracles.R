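## Independent oracles, kept deliberately naive and separate from the
## package's implementations.

## Audic-Claverie posterior predictive by direct product evaluation of the
## factorial formula, rearranged to avoid overflow:
##   p(y|x) = prod_{i=1..y} [ (x+i)/i * n2/(n1+n2) ] * (n1/(n1+n2))^(x+1)
ac_pmf_naive <- function(y, x, n1, n2) {
  p1 <- n1 / (n1 + n2); p2 <- n2 / (n1 + n2)
  f <- p1^(x + 1)
  if (y > 0) for (i in 1:y) f <- f * ((x + i) / i) * p2
  f
}

## one-sided Fisher by full hypergeometric enumeration:
## P(X >= a) over tables with fixed margins
fisher_enum <- function(a, b, c, d) {
  K <- a + c; n <- a + b; N <- a + b + c + d
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= a])
}

## brute-force codon walker used to audit generated CDS (via seqinr, an
## implementation independent of the package's Biostrings path)
translate_walker <- function(cds_chr) {
  paste(seqinr::translate(strsplit(cds_chr, "")[[1]]), collapse = "")
}

## cached small synthetic dataset shared across test files
.fixtures <- new.env(parent = emptyenv())

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(seed = 11L, n_contigs = 2L, contig_length = 60000L,
         n_genes = 24L, n_de_genes = 6L, n_variant_sites = 60L,
         count_mean = 300, count_sdlog = 0.5),
    list(...))
  do.call(sim_config, args)
}

tiny_sim <- function() {
  if (is.null(.fixtures$tiny)) {
    dir <- file.path(tempdir(), "pooldiff-tiny-sim")
    .fixtures$tiny <- simulate_dataset(tiny_config(), dir)
  }
  .fixtures$tiny
}

## mutate-genome / re-extract / re-translate oracle for one coding SNP
mutated_protein_diff <- function(genome, model, pos, alt) {
  contig <- as.character(genome[[model$contig]])
  stopifnot(substr(contig, pos, pos) != alt)
  substr(contig, pos, pos) <- alt
  mut <- Biostrings::DNAStringSet(setNames(contig, model$contig))
  ref_cds <- pooldiff:::extract_spliced_cds(genome, model)
  mut_cds <- pooldiff:::extract_spliced_cds(mut, model)
  ref_prot <- translate_walker(ref_cds)
  mut_prot <- translate_walker(mut_cds)
  diff_at <- which(strsplit(ref_prot, "")[[1]] != strsplit(mut_prot, "")[[1]])
  list(ref_prot = ref_prot, mut_prot = mut_prot, diff_at = diff_at)
}
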