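# cache for modified substitution matrices (X scored 0 against everything)
.align_env <- new.env(parent = emptyenv())

alignment_matrix <- function(name = "BLOSUM62") {
  key <- paste0("mat_", name)
  if (!is.null(.align_env[[key]])) return(.align_env[[key]])
  mat <- get(utils::data(list = name, package = "Biostrings",
                         envir = environment()))
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  .align_env[[key]] <- mat
  mat
}

#' Global (Needleman-Wunsch) alignment of two residue strings
#'
#' Optimal global alignment under a substitution matrix and affine gap
#' penalties (positive-penalty convention: `gap_open` and `gap_extend` are
#' subtracted). The unknown residue X scores 0 against everything.
#'
#' @param a,b non-empty amino-acid strings.
#' @param matrix substitution matrix name from Biostrings (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5).
#' @return object of class `wd_alignment`: list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`, and
#'   `n_identical` (aligned identical residue pairs).
#' @export
#' @examples
#' aln <- nw_align("ACDE", "ADE")
#' aln$aligned_b   # "A-DE"
nw_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                     gap_extend = 0.5) {
  nw_align_many(a, b, matrix = matrix, gap_open = gap_open,
                gap_extend = gap_extend)[[1L]]
}

# vectorised variant: one subject aligned against many patterns in a single
# pairwiseAlignment call; returns a list of wd_alignment
nw_align_many <- function(a, bs, matrix = "BLOSUM62", gap_open = 10,
                          gap_extend = 0.5) {
  if (!nzchar(a) || any(!nzchar(bs))) stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    bs, a, type = "global", substitutionMatrix = alignment_matrix(matrix),
    gapOpening = gap_open, gapExtension = gap_extend)
  scores <- Biostrings::score(pa)
  nm <- Biostrings::nmatch(pa)
  alen <- Biostrings::nchar(pa)
  # gap-free alignments (alignment length equals both input lengths) skip
  # the costly gapped-string extraction
  gapless <- alen == nchar(a) & alen == nchar(bs)
  al_a <- character(length(bs)); al_b <- al_a
  al_a[gapless] <- a
  al_b[gapless] <- bs[gapless]
  if (any(!gapless)) {
    sub <- pa[!gapless]
    al_b[!gapless] <- as.character(Biostrings::alignedPattern(sub))
    al_a[!gapless] <- as.character(Biostrings::alignedSubject(sub))
  }
  lapply(seq_along(bs), function(i)
    structure(list(aligned_a = al_a[i], aligned_b = al_b[i],
                   score = scores[i], n_identical = nm[i]),
              class = "wd_alignment"))
}

#' @export
print.wd_alignment <- function(x, ...) {
  cat("<wd_alignment> score", x$score, "identical", x$n_identical, "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Pairwise identity of an alignment
#'
#' Identical aligned residue pairs divided by the length of the shorter of
#' the two (ungapped) sequences.
#'
#' @param aln a `wd_alignment` (or anything with `n_identical`).
#' @param len_a,len_b ungapped sequence lengths; taken from the alignment's
#'   gapped strings when omitted.
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(aln, len_a = NULL, len_b = NULL) {
  if (is.null(len_a)) len_a <- nchar(gsub("-", "", aln$aligned_a))
  if (is.null(len_b)) len_b <- nchar(gsub("-", "", aln$aligned_b))
  m <- min(len_a, len_b)
  if (m == 0L) stop("pairwise identity undefined for empty sequence")
  aln$n_identical / m
}
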