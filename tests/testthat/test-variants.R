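pileup_row <- function(contig, pos, ref, counts, qual = 200) {
  df <- data.frame(contig = contig, pos_1based = pos, ref_base = ref,
                   A = counts[1], C = counts[2], G = counts[3], T = counts[4],
                   site_quality = qual)
  df
}

test_that("homopolymer masking covers runs and single flanks only", {
  g <- c(chr = "ACGTACGTACGT")
  expect_identical(nrow(mask_homopolymers(g, 11)), 0L)
  g2 <- c(chr = paste0("ACGT", strrep("A", 11), "CGTAC"))  # run at 5..15
  m <- mask_homopolymers(g2, 11)
  expect_setequal(m$pos, 4:16)
  ## a run of exactly 10 stays unmasked at the >10 threshold
  g3 <- c(chr = paste0("ACGT", strrep("A", 10), "CGTAC"))
  expect_identical(nrow(mask_homopolymers(g3, 11)), 0L)
  ## run touching the contig start clips the left flank
  g4 <- c(chr = paste0(strrep("T", 12), "ACG"))
  expect_setequal(mask_homopolymers(g4, 11)$pos, 1:13)
  expect_error(mask_homopolymers(g, 1), ">= 2")
})

test_that("allele_frequency is the variant fraction of ref+var reads", {
  expect_equal(allele_frequency(50, 0), 0)
  expect_equal(allele_frequency(50, 50), 50)
  expect_equal(round_half_up(allele_frequency(139, 6), 1), 4.1)
  expect_error(allele_frequency(0, 0), "undefined")
  expect_error(allele_frequency(-1, 5), "non-negative")
})

test_that("detect_snps applies mask, quality and coverage gates", {
  pil <- list(
    sus = rbind(pileup_row("c1", 10, "A", c(50, 0, 0, 0)),    # ref only
                pileup_row("c1", 20, "A", c(25, 25, 0, 0)),   # 50% C
                pileup_row("c1", 30, "G", c(0, 10, 40, 0)),   # 20% C
                pileup_row("c1", 40, "T", c(0, 5, 0, 10), qual = 20),
                pileup_row("c1", 50, "C", c(3, 7, 0, 0))),    # low coverage
    sel = rbind(pileup_row("c1", 10, "A", c(60, 0, 0, 0)),
                pileup_row("c1", 20, "A", c(5, 45, 0, 0)),
                pileup_row("c1", 30, "G", c(0, 30, 20, 0)),
                pileup_row("c1", 40, "T", c(0, 15, 0, 15), qual = 20),
                pileup_row("c1", 50, "C", c(2, 8, 0, 0))))
  snps <- detect_snps(pil, masked = NULL, cov_detect = 20, qual_min = 0)
  expect_setequal(snps$pos, c(20, 30, 40))          # no variant at 10; 50 under-covered
  expect_identical(snps$var[snps$pos == 20], "C")
  expect_equal(snps$sus_freq[snps$pos == 20], 50)
  expect_equal(snps$sel_freq[snps$pos == 20], 90)
  ## quality floor removes the qual-20 site
  snps_q <- detect_snps(pil, masked = NULL, cov_detect = 20, qual_min = 100)
  expect_setequal(snps_q$pos, c(20, 30))
  ## mask precedence: a masked site with 50% variant reads yields no record
  masked <- data.frame(contig = "c1", pos = 20)
  snps_m <- detect_snps(pil, masked = masked, cov_detect = 20)
  expect_false(20 %in% snps_m$pos)
  ## invalid reference base errors
  bad <- pil; bad$sus$ref_base[1] <- "N"
  expect_error(detect_snps(bad), "reference base")
})

test_that("variant allele is the dominant non-reference allele across strains", {
  pil <- list(
    sus = pileup_row("c1", 5, "A", c(40, 8, 2, 0)),
    sel = pileup_row("c1", 5, "A", c(40, 6, 3, 0)))
  snps <- detect_snps(pil)
  expect_identical(snps$var, "C")                  # 14 C vs 5 G pooled
  ## minor third allele excluded from the frequency denominator
  expect_equal(snps$sus_freq, 100 * 8 / 48)
  expect_equal(snps$sus_cov, 50)                   # coverage is all four bases
})

test_that("differential classification matches the published worked example", {
  ## cadherin-like site: susceptible 12.1% of 33 reads; one phenotype at
  ## 58.7% of 63 qualifies (delta 46.6), the other at 43.9% of 57 does not
  snps <- data.frame(contig = "c1", pos = 100, ref = "T", var = "A",
                     sus_freq = 12.1, sus_cov = 33,
                     pN_freq = 43.9, pN_cov = 57,
                     pS_freq = 58.7, pS_cov = 63)
  snps <- classify_differential(snps, "sus", "pS")
  snps <- classify_differential(snps, "sus", "pN")
  expect_true(snps$pS_qualifies)
  expect_equal(snps$pS_delta, 46.6, tolerance = 1e-9)
  expect_false(snps$pN_qualifies)
  expect_equal(snps$pN_delta, 31.8, tolerance = 1e-9)
  ## identical frequencies never qualify
  same <- data.frame(contig = "c1", pos = 1, ref = "A", var = "C",
                     a_freq = 30, a_cov = 100, b_freq = 30, b_cov = 100)
  expect_false(classify_differential(same, "a", "b")$b_qualifies)
  expect_error(classify_differential(same, "a", "missing"), "absent")
})

test_that("classification is label-symmetric and threshold-monotone", {
  set.seed(8)
  n <- 50
  snps <- data.frame(contig = "c1", pos = seq_len(n), ref = "A", var = "G",
                     a_freq = runif(n, 0, 100), a_cov = rpois(n, 40),
                     b_freq = runif(n, 0, 100), b_cov = rpois(n, 40))
  fwd <- classify_differential(snps, "a", "b")
  rev <- classify_differential(snps, "b", "a")
  expect_equal(rev$a_delta, -fwd$b_delta)
  expect_identical(rev$a_qualifies, fwd$b_qualifies)
  for (cm in c(30, 50, 80)) for (dm in c(40, 60)) {
    q1 <- classify_differential(snps, "a", "b", cov_min = cm,
                                dfreq_min = dm)$b_qualifies
    q2 <- classify_differential(snps, "a", "b", cov_min = cm + 20,
                                dfreq_min = dm)$b_qualifies
    q3 <- classify_differential(snps, "a", "b", cov_min = cm,
                                dfreq_min = dm + 15)$b_qualifies
    expect_true(all(q1 | !q2))                      # q2 subset of q1
    expect_true(all(q1 | !q3))
  }
})

test_that("synthetic truth sites above the filters are all recovered", {
  sim <- tiny_sim()
  snps <- call_snps(sim$pileups, sim$genome, susceptible = "susceptible",
                    selected = c("selected_N", "selected_S"))
  tr <- sim$truth_snps
  ## per-site eligibility from the generated pileups themselves
  covs <- sapply(sim$pileups, function(p) rowSums(p[c("A", "C", "G", "T")]))
  has_alt <- Reduce(`|`, lapply(names(sim$pileups), function(s) {
    p <- sim$pileups[[s]]
    cm <- as.matrix(p[c("A", "C", "G", "T")])
    cm[cbind(seq_len(nrow(p)), match(tr$alt, c("A", "C", "G", "T")))] > 0
  }))
  eligible <- !tr$in_homopolymer & apply(covs > 20, 1, any) & has_alt
  key <- function(df, pos_col = "pos") paste(df$contig, df[[pos_col]])
  recovered <- key(tr) %in% key(snps)
  expect_true(all(recovered[eligible]))            # recall = 1 at count level
  expect_false(any(recovered[tr$in_homopolymer]))
  expect_false(any(recovered[tr$low_coverage]))
})

test_that("estimated frequencies are unbiased and track truth", {
  cfg <- sim_config(seed = 23L, n_genes = 60L, n_contigs = 2L,
                    contig_length = 120000L, n_variant_sites = 220L,
                    coverage_mean = 100)
  ref <- generate_reference(cfg)
  pil <- generate_pileups(cfg, ref)
  snps <- call_snps(pil$pileups, ref$genome, susceptible = "susceptible",
                    selected = c("selected_N", "selected_S"))
  tr <- pil$truth_snps
  idx <- match(paste(snps$contig, snps$pos), paste(tr$contig, tr$pos))
  for (f in unique(tr$f_susceptible)) {
    sel <- which(tr$f_susceptible[idx] == f)
    if (length(sel) >= 50)
      expect_lt(abs(mean(snps$susceptible_freq[sel]) - 100 * f), 2)
  }
  keep <- rowSums(cbind(snps$susceptible_cov, snps$selected_N_cov)) >= 30
  r <- cor(snps$selected_N_freq[keep], 100 * tr$f_selected_N[idx][keep])
  expect_gt(r, 0.9)
})

test_that("qualifying records export as valid VCF", {
  skip_if_not_installed("vcfR")
  sim <- tiny_sim()
  snps <- call_snps(sim$pileups, sim$genome, susceptible = "susceptible",
                    selected = c("selected_N", "selected_S"))
  qual <- snps$selected_N_qualifies | snps$selected_S_qualifies
  path <- file.path(tempdir(), "diff.vcf")
  write_vcf(snps[qual, ], path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(v@fix), sum(qual))
  expect_identical(unname(v@fix[1, "REF"]), snps$ref[qual][1])
  expect_identical(unname(v@fix[1, "ALT"]), snps$var[qual][1])
})
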