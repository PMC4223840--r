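## Functional-category / GO-term over-representation among gene sets, and
## the non-synonymous burden comparison between candidate and other genes.
## All tests are one-sided Fisher exact tests (hypergeometric upper tail)
## with Benjamini-Hochberg correction across the terms of one selected set.

#' One-sided Fisher exact test on a 2x2 table
#'
#' Upper-tail hypergeometric probability `P(X >= a)` for the table
#' `(a, b; c, d)` with `a` = selected-and-in-term, `b` = selected-not,
#' `c` = unselected-in-term, `d` = unselected-not. A term absent from the
#' universe (degenerate margin) returns `p = 1` with a warning.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return p-value.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stopf("cell counts must be non-negative")
  if (a + c == 0 || a + b + c + d == 0) {
    warning("degenerate margin: term absent from the universe; p = 1",
            call. = FALSE)
    return(1)
  }
  stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
}

#' Term over-representation in a gene set
#'
#' One one-sided Fisher test per term of the map, comparing the selected
#' genes to the rest of the universe, BH-corrected across the tested terms.
#' The universe should be all detected genes.
#'
#' @param selected character vector of selected gene ids (subset of
#'   `universe`).
#' @param universe character vector of background gene ids.
#' @param map data.frame `gene_id, term` (a category map has one term per
#'   gene; a GO map may repeat genes).
#' @param alpha corrected-p-value threshold for the `enriched` flag
#'   (default 0.05).
#' @return data.frame `term, a, b, c, d, p_raw, p_adj, enriched`.
#' @export
enrich <- function(selected, universe, map, alpha = 0.05) {
  stray <- setdiff(selected, universe)
  if (length(stray))
    stopf("selected genes outside the universe: %s",
          paste(utils::head(stray, 5), collapse = ", "))
  if (!all(c("gene_id", "term") %in% names(map))) {
    if (ncol(map) >= 2) names(map)[1:2] <- c("gene_id", "term")
    else stopf("map must have columns gene_id and term")
  }
  if (!length(selected))
    return(data.frame(term = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p_raw = numeric(),
                      p_adj = numeric(), enriched = logical()))
  map <- map[map$gene_id %in% universe, ]
  terms <- sort(unique(map$term))
  n_sel <- length(unique(selected)); n_uni <- length(unique(universe))
  rows <- lapply(terms, function(tm) {
    in_term <- unique(map$gene_id[map$term == tm])
    a <- length(intersect(selected, in_term))
    b <- n_sel - a
    c <- length(in_term) - a
    d <- (n_uni - n_sel) - c
    data.frame(term = tm, a = a, b = b, c = c, d = d,
               p_raw = fisher_one_sided(a, b, c, d))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out$enriched <- out$p_adj < alpha
  out
}

#' Non-synonymous burden: candidate versus other genes
#'
#' Among qualifying (differential) SNPs, tests whether non-synonymous
#' changes are over-represented in candidate genes relative to all other
#' affected genes, with a one-sided Fisher exact test on the 2x2 table
#' rows = candidate/other gene, columns = non-synonymous/other effect.
#'
#' @param effects output of [annotate_effects()] with `_qualifies` columns.
#' @param map data.frame `gene_id, category`; `candidate_label` marks the
#'   candidate category.
#' @param candidate_label category treated as candidates (default
#'   `"Candidate"`).
#' @return list `table` (2x2 matrix) and `p_value`.
#' @export
burden_compare <- function(effects, map, candidate_label = "Candidate") {
  qcols <- grep("_qualifies$", names(effects), value = TRUE)
  if (!length(qcols)) stopf("effects carry no _qualifies columns")
  qual <- apply(effects[qcols], 1, function(v) any(v %in% TRUE))
  eff <- effects[qual & !is.na(effects$gene_id), , drop = FALSE]
  if (!all(c("gene_id", "category") %in% names(map)))
    names(map)[1:2] <- c("gene_id", "category")
  cand <- eff$gene_id %in% map$gene_id[map$category == candidate_label]
  nonsyn <- eff$effect == "non_synonymous"
  tab <- matrix(c(sum(cand & nonsyn), sum(cand & !nonsyn),
                  sum(!cand & nonsyn), sum(!cand & !nonsyn)),
                2, 2, byrow = TRUE,
                dimnames = list(c("candidate", "other_gene"),
                                c("non_synonymous", "other_effect")))
  if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) {
    warning("empty stratum in burden comparison; p = 1", call. = FALSE)
    return(list(table = tab, p_value = 1))
  }
  list(table = tab,
       p_value = fisher_one_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}
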