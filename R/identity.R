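#' Pairwise repeat identity matrix of a WD40 protein
#'
#' Aligns every unordered pair of repeat units globally and records the
#' pairwise identity (identical pairs / shorter repeat length).
#'
#' @param protein a `wd40_protein` with at least two repeats.
#' @param ... alignment parameters passed to [nw_align()].
#' @return symmetric numeric matrix in \[0,1\], unit diagonal, dimension =
#'   repeat count, dimnames = repeat indices; class `identity_matrix` with
#'   attribute `accession`.
#' @export
repeat_identity_matrix <- function(protein, ...) {
  r <- protein$repeats
  n <- nrow(r)
  if (n < 2L) stop("identity matrix needs >= 2 repeats")
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    alns <- nw_align_many(r$sequence[i], r$sequence[js], ...)
    for (k in seq_along(js)) {
      j <- js[k]
      m[i, j] <- m[j, i] <- pairwise_identity(alns[[k]],
                                              nchar(r$sequence[i]),
                                              nchar(r$sequence[j]))
    }
  }
  dimnames(m) <- list(r$index, r$index)
  structure(m, accession = protein$accession, class = "identity_matrix")
}

#' Internal sequence identity of a WD40 protein
#'
#' The per-protein repetitiveness statistic: the largest threshold X such
#' that some window of 8 contiguous repeats contains at least 6 repeats
#' whose pairwise identities all reach X. Computed in continuous form as
#'
#'   max over windows W of 8 contiguous repeats
#'     max over 6-subsets S of W
#'       min pairwise identity within S
#'
#' For proteins with only 6 or 7 repeats the window constraint is dropped
#' (all repeats form the single window). "Reach" is inclusive: the value v
#' returned satisfies "internal identity at least X" exactly when v >= X.
#'
#' @param m identity matrix from [repeat_identity_matrix()] (any symmetric
#'   matrix with unit diagonal works).
#' @param window window width (default 8) and `subset` clique size
#'   (default 6) of the statistic.
#' @param subset see above.
#' @return the statistic in \[0,1\]; `NA` with attribute `reason` when the
#'   protein has fewer than `subset` repeats (undefined, never 0).
#' @export
internal_identity <- function(m, window = 8L, subset = 6L) {
  n <- nrow(m)
  if (n < subset)
    return(structure(NA_real_, reason = sprintf(
      "undefined: %d repeats < %d required", n, subset)))
  windows <- if (n < window) list(seq_len(n)) else
    lapply(seq_len(n - window + 1L), function(s) s:(s + window - 1L))
  sub_idx <- NULL
  best <- -Inf
  for (w in windows) {
    if (is.null(sub_idx) || length(w) != attr(sub_idx, "k"))
      sub_idx <- structure(combn(length(w), subset, simplify = FALSE),
                           k = length(w))
    mw <- m[w, w, drop = FALSE]
    for (s in sub_idx) {
      ms <- mw[s, s]
      v <- min(ms[upper.tri(ms)])
      if (v > best) best <- v
    }
  }
  best
}

#' Classify repetitiveness from the internal-identity statistic
#'
#' Highly-Repetitive (HR) proteins have internal identity of at least 0.7;
#' Moderately-Repetitive (MR) at least 0.4 but below 0.7; everything lower
#' is "other". Proteins whose statistic is undefined (fewer than 6 repeats)
#' are "undefined".
#'
#' @param v internal identity value(s), possibly `NA`.
#' @param hr,mr class cutoffs (inclusive; defaults 0.7 and 0.4).
#' @return factor with levels HR, MR, other, undefined.
#' @export
classify_repetitiveness <- function(v, hr = 0.7, mr = 0.4) {
  out <- ifelse(is.na(v), "undefined",
         ifelse(v >= hr, "HR", ifelse(v >= mr, "MR", "other")))
  factor(out, levels = c("HR", "MR", "other", "undefined"))
}

#' Internal-identity table for a set of proteins
#'
#' Convenience wrapper: computes the identity matrix, the statistic and the
#' HR/MR label for each protein.
#'
#' @param proteins list of `wd40_protein`.
#' @param ... passed to [nw_align()].
#' @return data.frame with columns accession, repeat_count,
#'   internal_identity, label.
#' @export
internal_identity_table <- function(proteins, ...) {
  rows <- lapply(proteins, function(p) {
    n <- nrow(p$repeats)
    v <- if (n >= 2L) internal_identity(repeat_identity_matrix(p, ...))
         else NA_real_
    data.frame(accession = p$accession, repeat_count = n,
               internal_identity = as.numeric(v),
               label = as.character(classify_repetitiveness(as.numeric(v))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
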