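## Expression quantification and differential-transcription calling.
## The two-library count test is the Audic-Claverie posterior predictive:
## under a shared unknown Poisson rate with a flat prior, the probability of
## seeing y counts in library 2 given x in library 1 is
##   p(y|x) = C(x+y, y) * N2^y * N1^(x+1) / (N1+N2)^(x+y+1),
## the negative-binomial mass at y with size x+1 and prob N1/(N1+N2).

#' Audic-Claverie posterior predictive mass
#'
#' Probability of observing `y` counts for a transcript in a library of `n2`
#' total reads, given `x` counts in a library of `n1` total reads, under the
#' null of one shared Poisson rate (flat prior). Computed in log space.
#'
#' @param y,x observed counts (non-negative integers; vectorized).
#' @param n1,n2 total mapped reads of the libraries carrying `x` and `y`.
#' @param log if `TRUE`, return the log probability.
#' @return probability (or log probability) vector.
#' @export
ac_pmf <- function(y, x, n1, n2, log = FALSE) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stopf("library totals must be positive")
  lp <- lchoose(x + y, y) + y * base::log(n2) + (x + 1) * base::log(n1) -
    (x + y + 1) * base::log(n1 + n2)
  if (log) lp else exp(lp)
}

#' Audic-Claverie two-library test
#'
#' Tail probability of the posterior predictive [ac_pmf()]. The two-sided
#' p-value doubles the smaller of the two tails (each including the observed
#' count) and caps at 1. Both tails are accumulated directly in log space, so
#' far-tail p-values keep full relative precision instead of flooring at the
#' double-precision resolution of `1 - P`.
#'
#' @param x count in the reference (susceptible) library pool.
#' @param y count in the comparison (selected) library pool.
#' @param n1,n2 total mapped reads behind `x` and `y`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the rate in library 2 relative to library 1.
#' @return p-value in `[0, 1]`.
#' @export
ac_test <- function(x, y, n1, n2,
                    alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != 1 || length(y) != 1)
    return(vapply(seq_along(x), function(i)
      ac_test(x[i], y[i], n1, n2, alternative), numeric(1)))
  if (x < 0 || y < 0) stopf("counts must be non-negative")
  lp <- ac_pmf(0:y, x, n1, n2, log = TRUE)
  lower <- min(1, exp(logsumexp(lp)))              # P(Y <= y)
  upper <- ac_upper_tail(x, y, n1, n2)             # P(Y >= y)
  switch(alternative,
         two.sided = min(1, 2 * min(lower, upper)),
         less = min(1, lower),
         greater = min(1, upper))
}

## P(Y >= y) by blockwise log-space summation from y upward; the pmf is
## unimodal, so once a block's terms are decreasing and negligible relative
## to the accumulated sum the remainder is bounded by a geometric tail.
ac_upper_tail <- function(x, y, n1, n2, block = 4096L) {
  total <- -Inf
  from <- y
  repeat {
    ys <- from:(from + block - 1L)
    lp <- ac_pmf(ys, x, n1, n2, log = TRUE)
    total <- logsumexp(c(total, lp))
    decreasing <- lp[block] < lp[block - 1L]
    if (decreasing && lp[block] < total - 60) break
    from <- from + block
    if (from > y + 5e6) break  # safety cap; never reached at pipeline depths
  }
  min(1, exp(total))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement
#' (delegates to [stats::p.adjust()]); output order matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

check_counts_manifest <- function(counts, manifest) {
  need <- c("gene_id", "exonic_length_bp")
  if (!all(need %in% names(counts)))
    stopf("counts must have columns gene_id and exonic_length_bp")
  libs <- setdiff(names(counts), need)
  missing <- setdiff(libs, manifest$library_id)
  if (length(missing))
    stopf("library not in manifest: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$library_id))
    stopf("duplicated library_id in manifest")
  if (any(manifest$N <= 0)) stopf("manifest N must be positive")
  if (any(counts$exonic_length_bp < 1)) stopf("exonic_length_bp must be >= 1")
  cm <- as.matrix(counts[libs])
  if (any(cm < 0) || any(cm != round(cm)))
    stopf("counts must be non-negative integers")
  libs
}

#' Per-library RPKM
#'
#' `RPKM = count * 1e9 / (N * exonic_length_bp)`, with `N` the library's
#' total mapped reads from the manifest.
#'
#' @param counts data.frame `gene_id, exonic_length_bp, <library...>`.
#' @param manifest data.frame `library_id, strain, role, N`.
#' @return numeric matrix, genes x libraries.
#' @export
compute_rpkm <- function(counts, manifest) {
  libs <- check_counts_manifest(counts, manifest)
  N <- manifest$N[match(libs, manifest$library_id)]
  m <- as.matrix(counts[libs])
  rpkm <- sweep(m * 1e9 / counts$exonic_length_bp, 2, N, "/")
  rownames(rpkm) <- counts$gene_id
  rpkm
}

#' Strain-level RPKM from pooled technical replicates
#'
#' Pools counts and library totals of each strain's libraries before the
#' RPKM formula, so the result is invariant to how a strain's reads are
#' split across technical replicates.
#'
#' @inheritParams compute_rpkm
#' @return numeric matrix, genes x strains.
#' @export
strain_rpkm <- function(counts, manifest) {
  libs <- check_counts_manifest(counts, manifest)
  manifest <- manifest[match(libs, manifest$library_id), ]
  strains <- unique(manifest$strain)
  m <- as.matrix(counts[libs])
  out <- vapply(strains, function(s) {
    j <- which(manifest$strain == s)
    rowSums(m[, j, drop = FALSE]) * 1e9 /
      (sum(manifest$N[j]) * counts$exonic_length_bp)
  }, numeric(nrow(counts)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(NULL, strains))
  rownames(out) <- counts$gene_id
  out
}

#' Technical-replicate concordance
#'
#' Squared Pearson correlation of two libraries' RPKM vectors, restricted to
#' genes detected (RPKM above `detect_min`) in at least one of the pair.
#' Warns (but does not abort) below the 0.9 concordance expected of
#' technical replicates.
#'
#' @param rpkm matrix from [compute_rpkm()].
#' @param pair character vector of two library ids.
#' @param detect_min detection threshold (RPKM).
#' @return r-squared in `[0, 1]`.
#' @export
replicate_concordance <- function(rpkm, pair, detect_min = 0.5) {
  if (length(pair) != 2 || !all(pair %in% colnames(rpkm)))
    stopf("pair must name two columns of the RPKM matrix")
  a <- rpkm[, pair[1]]; b <- rpkm[, pair[2]]
  keep <- a > detect_min | b > detect_min
  if (sum(keep) < 3)
    stopf("fewer than 3 detected genes in pair (%s, %s); correlation undefined",
          pair[1], pair[2])
  r2 <- stats::cor(a[keep], b[keep])^2
  if (is.na(r2)) stopf("undefined correlation (zero variance) for pair (%s, %s)",
                       pair[1], pair[2])
  if (r2 <= 0.9)
    warning(sprintf("replicate r^2 = %.3f <= 0.9 for pair (%s, %s)",
                    r2, pair[1], pair[2]), call. = FALSE)
  r2
}

#' Call differential transcription against the susceptible parent
#'
#' For each selected strain versus the parental strain: technical replicates
#' are pooled (summed counts, summed totals), transcripts detected above
#' `detect_min` RPKM in at least one strain enter the test, the
#' Audic-Claverie two-sided p-value is BH-adjusted within the comparison
#' across detected transcripts, and a transcript is called over-/
#' under-transcribed when the adjusted p-value passes `alpha` and the fold
#' change passes `fc_min` in either direction. Fold change uses floored RPKM
#' `(rpkm_sel + epsilon) / (rpkm_sus + epsilon)` so transcripts undetected in
#' one strain keep a finite value.
#'
#' @inheritParams compute_rpkm
#' @param alpha adjusted-p-value threshold (default `1e-15`).
#' @param fc_min fold-change threshold (default 2; "under" uses `1/fc_min`).
#' @param detect_min detection threshold in RPKM (default 0.5, strict `>`).
#' @param epsilon RPKM floor used in the fold change (default 0.05).
#' @return data.frame of class `de_result`: `gene_id, comparison, rpkm_sus,
#'   rpkm_sel, fold_change, p_raw, p_adj, call, detected`.
#' @export
call_de <- function(counts, manifest, alpha = 1e-15, fc_min = 2,
                    detect_min = 0.5, epsilon = 0.05) {
  libs <- check_counts_manifest(counts, manifest)
  manifest <- manifest[match(libs, manifest$library_id), ]
  sus <- unique(manifest$strain[manifest$role == "parental"])
  if (length(sus) != 1) stopf("manifest must have exactly one parental strain")
  selected <- setdiff(unique(manifest$strain), sus)
  if (!length(selected)) stopf("manifest has no selected strain")

  m <- as.matrix(counts[libs])
  pooled <- sapply(unique(manifest$strain), function(s)
    rowSums(m[, manifest$strain == s, drop = FALSE]))
  totals <- vapply(unique(manifest$strain), function(s)
    sum(manifest$N[manifest$strain == s]), numeric(1))
  srpkm <- strain_rpkm(counts, manifest)
  detected <- apply(srpkm > detect_min, 1, any)
  if (!any(detected)) {
    warning("no transcript above the detection threshold", call. = FALSE)
    return(structure(data.frame(gene_id = character(), comparison = character(),
                                rpkm_sus = numeric(), rpkm_sel = numeric(),
                                fold_change = numeric(), p_raw = numeric(),
                                p_adj = numeric(), call = character(),
                                detected = logical()),
                     class = c("de_result", "data.frame")))
  }

  out <- NULL
  for (s in selected) {
    x <- pooled[, sus]; y <- pooled[, s]
    p_raw <- rep(NA_real_, nrow(m))
    p_raw[detected] <- vapply(which(detected), function(i)
      ac_test(x[i], y[i], totals[sus], totals[s]), numeric(1))
    p_adj <- rep(NA_real_, nrow(m))
    p_adj[detected] <- bh_adjust(p_raw[detected])
    fc <- (srpkm[, s] + epsilon) / (srpkm[, sus] + epsilon)
    call <- rep("NS", nrow(m))
    sig <- detected & !is.na(p_adj) & p_adj < alpha
    call[sig & fc >= fc_min] <- "over"
    call[sig & fc <= 1 / fc_min] <- "under"
    out <- rbind(out, data.frame(
      gene_id = counts$gene_id, comparison = s,
      rpkm_sus = srpkm[, sus], rpkm_sel = srpkm[, s],
      fold_change = fc, p_raw = p_raw, p_adj = p_adj,
      call = call, detected = detected, row.names = NULL))
  }
  structure(out, class = c("de_result", "data.frame"),
            susceptible = sus, alpha = alpha, fc_min = fc_min,
            detect_min = detect_min)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Differential transcription calls: %d transcripts x %d comparison(s)\n",
              length(unique(x$gene_id)), length(unique(x$comparison))))
  for (s in unique(x$comparison)) {
    xi <- x[x$comparison == s, ]
    cat(sprintf("  %s vs %s: %d detected, %d over, %d under\n",
                s, attr(x, "susceptible") %||% "parent",
                sum(xi$detected), sum(xi$call == "over"),
                sum(xi$call == "under")))
  }
  invisible(x)
}

#' Overlap of differential calls across comparisons
#'
#' Counts genes per Venn cell over two or more comparisons, split by
#' direction concordance: genes called in both comparisons in the same
#' direction (shared-over, shared-under), in opposite directions
#' (shared-discordant), or in only one comparison.
#'
#' @param de a `de_result` from [call_de()].
#' @return for two comparisons, a list with per-comparison totals, shared
#'   counts by direction class, and the shared total; for one comparison, a
#'   degenerate table of its totals.
#' @export
overlap_summary <- function(de) {
  comps <- unique(de$comparison)
  per <- lapply(comps, function(s) {
    xi <- de[de$comparison == s & de$call != "NS", ]
    stats::setNames(xi$call, xi$gene_id)
  })
  names(per) <- comps
  totals <- lapply(per, function(v) c(total = length(v),
                                      over = sum(v == "over"),
                                      under = sum(v == "under")))
  if (length(comps) == 1)
    return(list(comparisons = comps, totals = totals,
                shared = c(total = 0, over = 0, under = 0, discordant = 0)))
  if (length(comps) > 2)
    stopf("overlap_summary supports one or two comparisons")
  g <- intersect(names(per[[1]]), names(per[[2]]))
  shared_over <- sum(per[[1]][g] == "over" & per[[2]][g] == "over")
  shared_under <- sum(per[[1]][g] == "under" & per[[2]][g] == "under")
  discordant <- length(g) - shared_over - shared_under
  list(comparisons = comps, totals = totals,
       shared = c(total = length(g), over = shared_over,
                  under = shared_under, discordant = discordant),
       only = stats::setNames(
         c(length(per[[1]]) - length(g), length(per[[2]]) - length(g)), comps))
}
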