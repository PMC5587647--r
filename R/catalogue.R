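#' Filter WD40 candidates by repeat count and score
#'
#' A candidate is retained when it has at least `min_repeats` repeat units
#' and a mean repeat score of at least `min_score`. Retained proteins whose
#' mean score lies in the borderline band \[`min_score`, `review_below`) are
#' additionally flagged for manual review; with `strict = TRUE` the flagged
#' set is dropped from `retained` instead.
#'
#' @param proteins list of `wd40_protein`.
#' @param min_repeats,min_score retention thresholds (defaults 6 and 48).
#' @param review_below upper edge of the review band (default 60).
#' @param strict drop review-band proteins from `retained` (default FALSE:
#'   they are retained and flagged).
#' @return list with elements `retained`, `review_flagged`, `rejected`
#'   (each a list of proteins); `review_flagged` is a subset of `retained`
#'   unless `strict`.
#' @export
filter_wd40_candidates <- function(proteins, min_repeats = 6L,
                                   min_score = 48, review_below = 60,
                                   strict = FALSE) {
  mean_score <- vapply(proteins, function(p) mean(p$repeats$score), 0)
  n_rep <- vapply(proteins, function(p) nrow(p$repeats), 0L)
  pass <- n_rep >= min_repeats & mean_score >= min_score
  flag <- pass & mean_score < review_below
  retained <- proteins[if (strict) pass & !flag else pass]
  rs_log("info", "filter_wd40_candidates: ", length(proteins), " in, ",
         length(retained), " retained, ", sum(flag), " review-flagged, ",
         sum(!pass), " rejected")
  list(retained = retained,
       review_flagged = proteins[flag],
       rejected = proteins[!pass])
}

#' Keep the longest protein per gene
#'
#' When one gene maps to multiple proteins in the same organism (isoforms,
#' redundant entries), only the longest sequence is retained; length ties
#' are broken by the lexicographically smallest accession.
#'
#' @param proteins list of `wd40_protein` with `gene_id` and `organism_id`
#'   populated.
#' @return deduplicated list, one protein per (organism_id, gene_id), in
#'   order of first appearance of each gene.
#' @export
dedupe_longest_per_gene <- function(proteins) {
  if (!length(proteins)) return(proteins)
  key <- vapply(proteins, function(p) paste(p$organism_id, p$gene_id,
                                            sep = "\r"), "")
  len <- vapply(proteins, function(p) nchar(p$sequence), 0L)
  acc <- vapply(proteins, function(p) p$accession, "")
  keep <- vapply(split(seq_along(proteins), factor(key, unique(key))),
                 function(idx) {
                   idx[order(-len[idx], acc[idx])][1L]
                 }, 0L)
  rs_log("info", "dedupe_longest_per_gene: ", length(proteins), " in, ",
         length(keep), " kept")
  proteins[sort(keep)]
}

#' WD40 abundance of one proteome
#'
#' @param record one-row proteome record (or vectors recycled from the
#'   columns `n_wd40`, `n_proteins`).
#' @return percentage 100 * n_wd40 / n_proteins.
#' @export
proteome_abundance <- function(record) {
  if (any(record$n_proteins <= 0)) stop("n_proteins must be positive")
  100 * record$n_wd40 / record$n_proteins
}

#' Summarise WD40 abundance for one taxonomic category
#'
#' @param records proteome record data.frame.
#' @param category category to summarise (must be present in `records`).
#' @return one-row data.frame: category, n_proteomes, n_with_wd40,
#'   pct_with_wd40, mean_abundance_pct (unweighted mean over proteomes of
#'   the per-proteome percentage).
#' @export
summarize_category <- function(records, category) {
  r <- records[records$category == category, , drop = FALSE]
  if (!nrow(r)) stop("no proteome records for category ", category)
  data.frame(
    category = category,
    n_proteomes = nrow(r),
    n_with_wd40 = sum(r$n_wd40 > 0L),
    pct_with_wd40 = 100 * sum(r$n_wd40 > 0L) / nrow(r),
    mean_abundance_pct = mean(proteome_abundance(r)),
    stringsAsFactors = FALSE
  )
}

#' Fold change of mean WD40 abundance between two categories
#'
#' @param a,b one-row category summaries from [summarize_category()].
#' @return ratio a / b of the mean abundances.
#' @export
fold_change <- function(a, b) {
  if (b$mean_abundance_pct <= 0) stop("fold change needs a positive denominator")
  a$mean_abundance_pct / b$mean_abundance_pct
}

#' One-sided Wilcoxon rank-sum test
#'
#' Tests whether the values in `a` are stochastically greater (or less)
#' than those in `b`. With a combined sample size of at most `exact_max`
#' and no ties the exact rank-sum null distribution is used; otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param a,b non-empty numeric samples (e.g. per-proteome abundances).
#' @param alternative `"greater"` (a shifted above b) or `"less"`.
#' @param exact_max largest combined sample size for the exact branch
#'   (default 12).
#' @return p-value in (0, 1\].
#' @export
rank_sum_test <- function(a, b, alternative = c("greater", "less"),
                          exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  exact <- (length(a) + length(b)) <= exact_max && !anyDuplicated(c(a, b))
  stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                     correct = TRUE)$p.value
}

#' Empirical distribution table
#'
#' Tabulates counts and fractions either over the distinct observed values
#' (`breaks = NULL`, for discrete data like repeat counts) or over interval
#' bins (numeric `breaks`, for densities in \[0,1\]); empty interval bins
#' are kept.
#'
#' @param values numeric vector; empty input yields an empty table with a
#'   warning.
#' @param breaks `NULL` or a breaks specification as in [cut()] (number of
#'   intervals or boundary vector); intervals are left-closed,
#'   right-open except the last.
#' @return data.frame with columns bin, count, fraction (fractions sum
#'   to 1).
#' @export
distribution_table <- function(values, breaks = NULL) {
  if (!length(values)) {
    warning("distribution_table: no values")
    return(data.frame(bin = character(0), count = integer(0),
                      fraction = numeric(0)))
  }
  if (is.null(breaks)) {
    tab <- table(values)
    out <- data.frame(bin = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
  } else {
    cuts <- cut(values, breaks, include.lowest = TRUE, right = FALSE)
    tab <- table(cuts)
    out <- data.frame(bin = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
  }
  out$fraction <- out$count / sum(out$count)
  out
}
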