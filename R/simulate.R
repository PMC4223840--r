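#' Simulation configuration
#'
#' Parameters of the synthetic dataset generator. The defaults emulate the
#' pooled design the pipeline was built for: one susceptible parental strain
#' and two selected phenotypes, each sequenced as two technical cDNA
#' libraries prepared from the same RNA pool, plus pileup allele counts at
#' variant sites whose true pooled allele frequencies differ (or not)
#' between strains.
#'
#' @param seed integer seed; identical configurations produce byte-identical
#'   output files.
#' @param n_contigs,contig_length number and length (bp) of reference contigs.
#' @param n_genes number of genes, spread round-robin over contigs.
#' @param exons_per_gene integer range `c(min,max)` of exons per gene.
#' @param cds_codons range of CDS length in codons (start and stop included).
#' @param utr5_len,utr3_len ranges of UTR lengths (bp).
#' @param intron_len range of intron lengths (bp).
#' @param intergenic_gap range of intergenic gap lengths (bp).
#' @param strand_fraction_minus proportion of genes on the minus strand.
#' @param strains character vector of strain names; the first is the
#'   susceptible parent, the rest are selected phenotypes.
#' @param library_sizes named numeric vector, library id -> total mapped
#'   reads; default two libraries of 1e6 reads per strain.
#' @param count_mean,count_sdlog lognormal parameters of the per-gene
#'   expected read count per library (at 1e6 mapped reads).
#' @param n_de_genes number of genes given a true expression shift in the
#'   selected strains.
#' @param log2fc_values pool of true log2 fold changes for DE genes.
#' @param n_variant_sites number of polymorphic sites to place.
#' @param coverage_mean mean per-strain read coverage at a site (Poisson).
#' @param true_freqs named list, strain -> vector of true alternate-allele
#'   frequencies in `[0,1]`; sites cycle through the vectors, so the defaults
#'   alternate a differential pattern (0.05 vs 0.55, a 50-point shift), a
#'   null pattern, and a downward differential pattern.
#' @param homopolymer_insert_len length of the single-base run inserted in an
#'   intergenic region (must exceed the mask threshold of 10).
#' @param site_quality_range range of the uniform per-site quality score.
#' @param flank bp kept clear of genes when placing intergenic sites.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 4L, contig_length = 150000L,
                       n_genes = 200L,
                       exons_per_gene = c(2L, 4L),
                       cds_codons = c(60L, 180L),
                       utr5_len = c(40L, 150L), utr3_len = c(80L, 300L),
                       intron_len = c(60L, 200L),
                       intergenic_gap = c(300L, 2500L),
                       strand_fraction_minus = 0.5,
                       strains = c("susceptible", "selected_N", "selected_S"),
                       library_sizes = NULL,
                       count_mean = 200, count_sdlog = 1,
                       n_de_genes = 40L, log2fc_values = c(-2, 2),
                       n_variant_sites = 240L, coverage_mean = 100,
                       true_freqs = NULL,
                       homopolymer_insert_len = 14L,
                       site_quality_range = c(150, 500),
                       flank = 1000L) {
  if (is.null(library_sizes)) {
    library_sizes <- rep(1e6, 2L * length(strains))
    names(library_sizes) <- paste(rep(strains, each = 2L), 1:2, sep = "_")
  }
  if (is.null(true_freqs)) {
    sel <- strains[-1]
    true_freqs <- c(list(c(0.05, 0.20, 0.60)),
                    rep(list(c(0.55, 0.20, 0.10)), length(sel)))
    names(true_freqs) <- strains
  }
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              cds_codons = as.integer(cds_codons),
              utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
              intron_len = as.integer(intron_len),
              intergenic_gap = as.integer(intergenic_gap),
              strand_fraction_minus = strand_fraction_minus,
              strains = strains, library_sizes = library_sizes,
              count_mean = count_mean, count_sdlog = count_sdlog,
              n_de_genes = as.integer(n_de_genes),
              log2fc_values = log2fc_values,
              n_variant_sites = as.integer(n_variant_sites),
              coverage_mean = coverage_mean, true_freqs = true_freqs,
              homopolymer_insert_len = as.integer(homopolymer_insert_len),
              site_quality_range = site_quality_range,
              flank = as.integer(flank))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && r[1] >= 1 && r[1] <= r[2]
  if (length(cfg$strains) < 2)
    stopf("need a susceptible strain plus at least one selected strain")
  if (!all(rng_ok(cfg$exons_per_gene), rng_ok(cfg$cds_codons),
           rng_ok(cfg$utr5_len), rng_ok(cfg$utr3_len),
           rng_ok(cfg$intron_len), rng_ok(cfg$intergenic_gap)))
    stopf("malformed range in sim_config (need c(min, max), min >= 1)")
  if (cfg$strand_fraction_minus < 0 || cfg$strand_fraction_minus > 1)
    stopf("strand_fraction_minus must lie in [0, 1]")
  if (any(cfg$library_sizes <= 0)) stopf("library sizes must be positive")
  bad <- vapply(cfg$true_freqs, function(f) any(f < 0 | f > 1), logical(1))
  if (any(bad)) stopf("true allele frequencies must lie in [0, 1]")
  lens <- lengths(cfg$true_freqs)
  if (length(unique(lens)) != 1)
    stopf("true_freqs vectors must have one common length across strains")
  if (!setequal(names(cfg$true_freqs), cfg$strains))
    stopf("true_freqs must name every strain")
  if (cfg$homopolymer_insert_len <= 10)
    stopf("homopolymer_insert_len must exceed 10 to trip the mask")
  invisible(cfg)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

STOP_CODONS <- c("TAA", "TAG", "TGA")

## random CDS: ATG + non-stop codons + one stop codon
make_cds_seq <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  mid <- sample(sense[sense != "ATG"], n_codons - 2L, replace = TRUE)
  paste(c("ATG", mid, sample(STOP_CODONS, 1L)), collapse = "")
}

rc_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## map an interval in unspliced-transcript coordinates to genomic coordinates
tx2genomic <- function(u1, u2, g0, gend, strand) {
  if (strand == "+") c(g0 + u1 - 1L, g0 + u2 - 1L)
  else c(gend - u2 + 1L, gend - u1 + 1L)
}

build_gene <- function(cfg, gene_id, contig, strand, g0) {
  rint <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  u5 <- rint(cfg$utr5_len); u3 <- rint(cfg$utr3_len)
  cds_len <- 3L * rint(cfg$cds_codons)
  L <- u5 + cds_len + u3
  k <- rint(cfg$exons_per_gene)
  cuts <- if (k > 1) sort(sample(seq_len(L - 1L), k - 1L)) else integer(0)
  ex_s <- c(1L, cuts + 1L); ex_e <- c(cuts, L)             # spliced exon bounds
  il <- if (k > 1) vapply(seq_len(k - 1L), function(i) rint(cfg$intron_len),
                          integer(1)) else integer(0)
  off <- c(0L, cumsum(il))                                  # unspliced offsets
  Lg <- L + sum(il)
  gend <- g0 + Lg - 1L

  tx_seq <- paste0(random_dna(u5), make_cds_seq(cds_len %/% 3L), random_dna(u3))
  pieces <- character(0)
  for (j in seq_len(k)) {
    pieces <- c(pieces, substr(tx_seq, ex_s[j], ex_e[j]))
    if (j < k) pieces <- c(pieces, random_dna(il[j]))
  }
  unspliced <- paste(pieces, collapse = "")
  locus_seq <- if (strand == "+") unspliced else rc_chr(unspliced)

  ## genomic sub-intervals of a spliced feature range
  feat_iv <- function(f1, f2) {
    out <- NULL
    for (j in seq_len(k)) {
      a <- max(f1, ex_s[j]); b <- min(f2, ex_e[j])
      if (a > b) next
      g <- tx2genomic(a + off[j], b + off[j], g0, gend, strand)
      out <- rbind(out, g)
    }
    df <- as.data.frame(out); names(df) <- c("start", "end")
    df[order(df$start), , drop = FALSE]
  }
  exons <- feat_iv(1L, L)
  model <- new_gene_model(
    gene_id = gene_id, tx_id = paste0(gene_id, ".t1"),
    contig = contig, strand = strand, start = g0, end = gend,
    exons = exons,
    cds = feat_iv(u5 + 1L, u5 + cds_len),
    utr5 = feat_iv(1L, u5),
    utr3 = feat_iv(u5 + cds_len + 1L, L))
  list(model = model, locus_seq = locus_seq, g0 = g0, gend = gend)
}

#' Generate a synthetic reference genome and gene annotation
#'
#' Builds `n_contigs` random contigs carrying non-overlapping protein-coding
#' genes on both strands (multi-exon, with 5'/3' UTRs, CDS a multiple of 3
#' beginning with ATG and ending with a stop codon), plus one long
#' single-base homopolymer run inserted in an intergenic region of the first
#' contig to exercise the homopolymer mask.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named [Biostrings::DNAStringSet]), `models`
#'   (named list of gene models), `gff` (GFF3 text lines), and `homopolymer`
#'   (data.frame with contig/start/end of the inserted run).
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  margin <- 200L
  contig_names <- sprintf("contig_%02d", seq_len(config$n_contigs))
  contigs <- vapply(contig_names, function(x) random_dna(config$contig_length),
                    character(1))
  strands <- ifelse(stats::runif(config$n_genes) < config$strand_fraction_minus,
                    "-", "+")
  if (length(unique(strands)) == 1 && config$n_genes >= 2)
    strands[2] <- setdiff(c("+", "-"), strands[1])

  models <- list()
  gaps <- data.frame(contig = character(), start = integer(), end = integer())
  for (ci in seq_len(config$n_contigs)) {
    idx <- which((seq_len(config$n_genes) - 1L) %% config$n_contigs == ci - 1L)
    cursor <- 1501L
    gap_from <- 1L
    for (gi in idx) {
      gid <- sprintf("G%04d", gi)
      g <- build_gene(config, gid, contig_names[ci], strands[gi], cursor)
      if (g$gend > config$contig_length - margin)
        stopf("capacity error: gene span exceeds contig space on %s (gene %s ends at %d, contig length %d)",
              contig_names[ci], gid, g$gend, config$contig_length)
      substr(contigs[ci], g$g0, g$gend) <- g$locus_seq
      models[[gid]] <- g$model
      gaps <- rbind(gaps, data.frame(contig = contig_names[ci],
                                     start = gap_from, end = g$g0 - 1L))
      gap_from <- g$gend + 1L
      gap <- sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1L)
      cursor <- g$gend + gap + 1L
    }
    gaps <- rbind(gaps, data.frame(contig = contig_names[ci],
                                   start = gap_from, end = config$contig_length))
  }
  models <- models[order(names(models))]

  ## insert the homopolymer run in the widest intergenic gap of contig 1
  g1 <- gaps[gaps$contig == contig_names[1], ]
  g1 <- g1[which.max(g1$end - g1$start), ]
  hp_len <- config$homopolymer_insert_len
  hp_start <- g1$start + (g1$end - g1$start - hp_len) %/% 2L
  hp_end <- hp_start + hp_len - 1L
  substr(contigs[1], hp_start, hp_end) <- strrep("A", hp_len)
  ## guard against accidental extension of the run by neighbouring As
  if (substr(contigs[1], hp_start - 1L, hp_start - 1L) == "A")
    substr(contigs[1], hp_start - 1L, hp_start - 1L) <- "C"
  if (substr(contigs[1], hp_end + 1L, hp_end + 1L) == "A")
    substr(contigs[1], hp_end + 1L, hp_end + 1L) <- "C"

  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- contig_names
  list(genome = genome, models = models,
       gff = gff3_text(models, stats::setNames(rep(config$contig_length,
                                                   config$n_contigs),
                                               contig_names)),
       homopolymer = data.frame(contig = contig_names[1],
                                start = hp_start, end = hp_end))
}

#' Generate synthetic gene counts for all libraries
#'
#' Draws per-gene expected counts from a lognormal, then Poisson counts per
#' library scaled by library size; a configured number of genes get their
#' rate multiplied by `2^log2fc` in the selected strains. Technical
#' replicates of a strain share one rate, as expected for libraries prepared
#' from the same RNA pool.
#'
#' @param config a [sim_config()].
#' @param models gene models from [generate_reference()], or `NULL` to
#'   synthesize gene ids and exonic lengths without a genome (useful for
#'   expression-only simulations at large gene numbers).
#' @return list with `counts` (data.frame `gene_id, exonic_length_bp,
#'   <library...>`), `manifest` (data.frame `library_id, strain, role, N`)
#'   and `truth_de` (data.frame `gene_id, log2fc, base_mean`).
#' @export
generate_counts <- function(config, models = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  if (is.null(models)) {
    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
    lens <- sample(500:3000, config$n_genes, replace = TRUE)
  } else {
    gene_ids <- names(models)
    lens <- vapply(models, function(m) m$exonic_length, integer(1))
  }
  n <- length(gene_ids)
  base_mean <- stats::rlnorm(n, meanlog = log(config$count_mean),
                             sdlog = config$count_sdlog)
  if (config$n_de_genes > n)
    stopf("n_de_genes (%d) exceeds the number of genes (%d)",
          config$n_de_genes, n)
  de_idx <- sort(sample.int(n, config$n_de_genes))
  l2fc <- if (config$n_de_genes)
    resample(config$log2fc_values, config$n_de_genes, replace = TRUE) else numeric(0)
  fc <- rep(1, n); fc[de_idx] <- 2^l2fc

  libs <- names(config$library_sizes)
  lib_strain <- sub("_[0-9]+$", "", libs)
  if (!all(lib_strain %in% config$strains))
    stopf("library ids must be <strain>_<k> for configured strains")
  counts <- matrix(0L, nrow = n, ncol = length(libs),
                   dimnames = list(gene_ids, libs))
  susceptible <- config$strains[1]
  for (j in seq_along(libs)) {
    scale <- config$library_sizes[j] / 1e6
    rate <- base_mean * scale
    if (lib_strain[j] != susceptible) rate <- rate * fc
    counts[, j] <- stats::rpois(n, rate)
  }
  counts_df <- data.frame(gene_id = gene_ids, exonic_length_bp = lens,
                          counts, check.names = FALSE)
  manifest <- data.frame(
    library_id = libs, strain = lib_strain,
    role = ifelse(lib_strain == susceptible, "parental", "selected"),
    N = as.numeric(config$library_sizes))
  truth_de <- data.frame(gene_id = gene_ids[de_idx], log2fc = l2fc,
                         base_mean = base_mean[de_idx])
  list(counts = counts_df, manifest = manifest, truth_de = truth_de)
}

## ---- variant site placement ------------------------------------------------

## candidate variant positions for one gene, with intended effect class
gene_site_pool <- function(genome, model, max_per_class = 4L,
                           max_codons = 8L) {
  base_at <- function(pos)
    as.character(Biostrings::subseq(genome[[model$contig]], pos, pos))
  pick_iv <- function(iv, class) {
    pos <- unlist(lapply(seq_len(nrow(iv)), function(i) iv$start[i]:iv$end[i]))
    if (!length(pos)) return(NULL)
    pos <- sort(resample(pos, min(max_per_class, length(pos))))
    ref <- vapply(pos, base_at, character(1))
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1))
    data.frame(contig = model$contig, pos = pos, ref = ref, alt = alt,
               class = class, strand = model$strand, gene_id = model$gene_id)
  }
  out <- rbind(pick_iv(model$utr5, "five_prime_UTR"),
               pick_iv(model$utr3, "three_prime_UTR"))
  intr <- intron_intervals(model)
  if (nrow(intr)) out <- rbind(out, pick_iv(intr, "intronic"))

  code <- Biostrings::GENETIC_CODE
  cds_seq <- extract_spliced_cds(genome, model)
  gpos <- cds_genomic_positions(model)
  n_cod <- nchar(cds_seq) %/% 3L
  cods <- resample(2:(n_cod - 1L), min(max_codons, n_cod - 2L))
  for (ci in cods) {
    codon <- substr(cds_seq, 3L * ci - 2L, 3L * ci)
    found <- c(synonymous = FALSE, non_synonymous = FALSE)
    for (p in sample(1:3)) {
      ref_cb <- substr(codon, p, p)           # coding-strand base
      for (ab in sample(setdiff(DNA_BASES, ref_cb))) {
        alt_codon <- codon
        substr(alt_codon, p, p) <- ab
        cls <- if (code[alt_codon] == code[codon]) "synonymous" else "non_synonymous"
        if (found[cls]) next
        found[cls] <- TRUE
        g <- gpos[3L * (ci - 1L) + p]
        if (model$strand == "+") {
          ref_g <- ref_cb; alt_g <- ab
        } else {
          ref_g <- comp_base(ref_cb); alt_g <- comp_base(ab)
        }
        out <- rbind(out, data.frame(contig = model$contig, pos = g,
                                     ref = unname(ref_g), alt = unname(alt_g),
                                     class = cls, strand = model$strand,
                                     gene_id = model$gene_id))
      }
      if (all(found)) break
    }
  }
  out
}

intergenic_pool <- function(genome, models, flank, avoid = NULL,
                            per_contig = 40L) {
  out <- NULL
  for (contig in names(genome)) {
    len <- Biostrings::width(genome[contig])
    mm <- Filter(function(m) m$contig == contig, models)
    if (!length(mm)) next
    sp <- data.frame(start = vapply(mm, `[[`, integer(1), "start"),
                     end = vapply(mm, `[[`, integer(1), "end"))
    sp <- sp[order(sp$start), ]
    bounds <- c(0L, sp$end, len + 1L)
    starts <- c(1L, sp$end + 1L)
    ends <- c(sp$start - 1L, len)
    pos <- NULL
    for (i in seq_along(starts)) {
      a <- starts[i] + flank; b <- ends[i] - flank
      if (a <= b) pos <- c(pos, a:b)
    }
    if (!is.null(avoid)) {
      av <- avoid[avoid$contig == contig, ]
      if (nrow(av))
        pos <- setdiff(pos, unlist(lapply(seq_len(nrow(av)), function(i)
          (av$start[i] - 2L):(av$end[i] + 2L))))
    }
    if (!length(pos)) next
    pos <- sort(resample(pos, min(per_contig, length(pos))))
    ref <- vapply(pos, function(p)
      as.character(Biostrings::subseq(genome[[contig]], p, p)), character(1))
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1))
    out <- rbind(out, data.frame(contig = contig, pos = pos, ref = ref,
                                 alt = alt, class = "intergenic",
                                 strand = NA_character_,
                                 gene_id = NA_character_))
  }
  out
}

#' Generate synthetic per-strain pileup allele counts
#'
#' Places variant sites so that every effect class (5'UTR, synonymous,
#' non-synonymous, 3'UTR, intronic, intergenic) occurs on both strand
#' orientations, plus one site inside the inserted homopolymer run and one
#' site with coverage forced below the detection threshold. Per strain,
#' coverage is Poisson around `coverage_mean` and the alternate-allele count
#' is binomial at the site's true frequency.
#'
#' @param config a [sim_config()].
#' @param reference output of [generate_reference()] for the same config.
#' @return list with `pileups` (named list strain -> data.frame
#'   `contig, pos_1based, ref_base, A, C, G, T, site_quality`) and
#'   `truth_snps` (data.frame of placed sites with true per-strain
#'   frequencies, intended class/strand/gene, and flags).
#' @export
generate_pileups <- function(config, reference) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  genome <- reference$genome
  models <- reference$models

  pool <- do.call(rbind, lapply(models, function(m)
    gene_site_pool(genome, m)))
  pool <- rbind(pool, intergenic_pool(genome, models, config$flank,
                                      avoid = reference$homopolymer))
  pool <- pool[!duplicated(paste(pool$contig, pool$pos)), ]
  rownames(pool) <- NULL

  ## guarantee every class on both strands (intergenic strandless)
  genic <- c("five_prime_UTR", "synonymous", "non_synonymous",
             "three_prime_UTR", "intronic")
  req_idx <- integer(0)
  for (cls in genic) for (st in c("+", "-")) {
    cand <- which(pool$class == cls & pool$strand == st)
    cand <- setdiff(cand, req_idx)
    if (!length(cand))
      stopf("capacity error: no candidate %s site on strand %s; enlarge the simulated genes", cls, st)
    req_idx <- c(req_idx, resample(cand, 1L))
  }
  ig <- setdiff(which(pool$class == "intergenic"), req_idx)
  if (!length(ig)) stopf("capacity error: no intergenic candidate site")
  req_idx <- c(req_idx, resample(ig, 1L))

  n_extra <- config$n_variant_sites - length(req_idx)
  if (n_extra < 0)
    stopf("n_variant_sites (%d) below the %d sites needed for class coverage",
          config$n_variant_sites, length(req_idx))
  rest <- setdiff(seq_len(nrow(pool)), req_idx)
  if (n_extra > length(rest))
    stopf("capacity error: requested %d variant sites but only %d candidate positions",
          config$n_variant_sites, nrow(pool))
  sites <- pool[c(req_idx, resample(rest, n_extra)), ]
  sites$in_homopolymer <- FALSE
  sites$low_coverage <- FALSE

  ## one low-coverage site (flag an ordinary genic site)
  sites$low_coverage[resample(which(sites$class != "intergenic"), 1L)] <- TRUE

  ## one site inside the homopolymer run
  hp <- reference$homopolymer
  hp_pos <- hp$start + (hp$end - hp$start) %/% 2L
  sites <- rbind(sites, data.frame(
    contig = hp$contig, pos = hp_pos, ref = "A",
    alt = sample(c("C", "G", "T"), 1L), class = "intergenic",
    strand = NA_character_, gene_id = NA_character_,
    in_homopolymer = TRUE, low_coverage = FALSE))

  sites <- sites[order(sites$contig, sites$pos), ]
  rownames(sites) <- NULL

  npat <- length(config$true_freqs[[1]])
  pat <- (seq_len(nrow(sites)) - 1L) %% npat + 1L
  for (s in config$strains)
    sites[[paste0("f_", s)]] <- config$true_freqs[[s]][pat]

  qual <- round(stats::runif(nrow(sites), config$site_quality_range[1],
                             config$site_quality_range[2]), 1)
  pileups <- list()
  for (s in config$strains) {
    cov <- stats::rpois(nrow(sites), config$coverage_mean)
    cov[cov == 0] <- 1L
    cov[sites$low_coverage] <- 10L
    altc <- stats::rbinom(nrow(sites), cov, sites[[paste0("f_", s)]])
    mat <- matrix(0L, nrow(sites), 4L, dimnames = list(NULL, DNA_BASES))
    for (b in DNA_BASES) {
      mat[sites$ref == b, b] <- mat[sites$ref == b, b] + (cov - altc)[sites$ref == b]
      mat[sites$alt == b, b] <- mat[sites$alt == b, b] + altc[sites$alt == b]
    }
    pileups[[s]] <- data.frame(contig = sites$contig, pos_1based = sites$pos,
                               ref_base = sites$ref, mat,
                               site_quality = qual, check.names = FALSE)
  }
  list(pileups = pileups, truth_snps = sites)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [generate_reference()], [generate_counts()] and [generate_pileups()]
#' under the configured seed, assigns each gene a functional category, and
#' writes every pipeline input plus the truth tables as plain-text files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) a list with all in-memory objects and a `files`
#'   vector of written paths.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(config)
  cnt <- generate_counts(config, ref$models)
  pil <- generate_pileups(config, ref)

  set.seed(config$seed + 3L)
  cats <- c("Candidate", "Detoxification", "Other enzymes", "Cuticle",
            "Immunity", "Hormones and neurotransmitters signaling",
            "Transcription factors",
            "Intra or extracellular trafficking/chaperonins",
            "Structure", "Unknown")
  w <- c(0.08, 0.08, 0.12, 0.08, 0.08, 0.06, 0.06, 0.08, 0.06, 0.30)
  categories <- data.frame(
    gene_id = cnt$counts$gene_id,
    category = sample(cats, nrow(cnt$counts), replace = TRUE, prob = w))

  p <- function(f) file.path(dir, f)
  files <- c(genome = p("genome.fasta"), gff = p("models.gff3"),
             counts = p("counts.tsv"), manifest = p("manifest.tsv"),
             categories = p("categories.tsv"),
             truth_de = p("truth_de.tsv"), truth_snps = p("truth_snps.tsv"))
  Biostrings::writeXStringSet(ref$genome, files["genome"], width = 70L)
  writeLines(ref$gff, files["gff"])
  wtsv <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(cnt$counts, files["counts"])
  wtsv(cnt$manifest, files["manifest"])
  wtsv(categories, files["categories"])
  wtsv(cnt$truth_de, files["truth_de"])
  wtsv(pil$truth_snps, files["truth_snps"])
  for (s in config$strains) {
    f <- p(sprintf("pileup_%s.tsv", s))
    wtsv(pil$pileups[[s]], f)
    files[paste0("pileup_", s)] <- f
  }
  invisible(list(config = config, genome = ref$genome, models = ref$models,
                 homopolymer = ref$homopolymer, counts = cnt$counts,
                 manifest = cnt$manifest, truth_de = cnt$truth_de,
                 pileups = pil$pileups, truth_snps = pil$truth_snps,
                 categories = categories, files = files))
}
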