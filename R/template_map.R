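.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# star multiple alignment of short same-loop segments: all residues are
# mapped onto the coordinates of the longest segment (ties: first); used in
# place of a full progressive MSA, which these few-residue loops do not need
star_align <- function(segs, ...) {
  lens <- nchar(segs)
  if (length(unique(lens)) == 1L) {
    return(do.call(rbind, strsplit(segs, "")))
  }
  ref <- segs[which.max(lens)][1L]
  width <- nchar(ref)
  out <- matrix("-", nrow = length(segs), ncol = width)
  for (i in seq_along(segs)) {
    if (!nchar(segs[i])) next
    if (segs[i] == ref) { out[i, ] <- strsplit(ref, "")[[1L]]; next }
    aln <- nw_align(ref, segs[i], ...)
    ra <- strsplit(aln$aligned_a, "")[[1L]]
    sa <- strsplit(aln$aligned_b, "")[[1L]]
    pos <- cumsum(ra != "-")      # reference coordinate of each column
    keep <- ra != "-" & sa != "-" # insertions vs the reference are dropped
    out[i, pos[keep]] <- sa[keep]
  }
  out
}

# rank alignment columns: non-gap occupancy, then max single-residue
# frequency, then leftmost; returns the kept column indices in original order
rank_loop_columns <- function(colmat, k) {
  occ <- colSums(colmat != "-")
  topfreq <- apply(colmat, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) 0L else max(table(col))
  })
  ord <- order(-occ, -topfreq, seq_len(ncol(colmat)))
  sort(head(ord, k))
}

#' Map the repeats of a protein onto the canonical blade template
#'
#' Strand residues (Sa/Sb/Sc/Sd) are placed positionally, left-anchored in
#' their template blocks, exactly as labelled. Loop residues are aligned
#' across all same-loop segments of the protein's repeats (positional when
#' the segments share one length, otherwise a star alignment around the
#' longest segment using the package's global aligner); the aligned columns
#' are then ranked by conservation (non-gap occupancy, then top residue
#' frequency, then leftmost) and the top 6/5/3/4 sites are kept for
#' Lda/Lab/Lbc/Lcd respectively.
#'
#' @param protein a `wd40_protein` whose repeats carry structural labels.
#' @param template a [wd40_template()].
#' @param ... alignment parameters for the loop star alignment.
#' @return character matrix (class `template_map`) of residues or "-",
#'   one row per repeat, one column per template position (48); attribute
#'   `flagged`: logical per repeat, TRUE when a strand label run was
#'   missing or overflowed its block.
#' @export
map_repeats_to_template <- function(protein, template = wd40_template(),
                                    ...) {
  r <- protein$repeats
  n <- nrow(r)
  L <- max(template$blocks$end)
  tm <- matrix("-", nrow = n, ncol = L,
               dimnames = list(r$index, NULL))
  flagged <- logical(n)
  segs <- lapply(seq_len(n), function(i) {
    tags <- repeat_labels(r$labels[i])
    res <- strsplit(r$sequence[i], "")[[1L]]
    split(res, factor(tags, levels = .blade_order))
  })
  for (bi in seq_len(nrow(template$blocks))) {
    blk <- template$blocks$block[bi]
    s0 <- template$blocks$start[bi]
    e0 <- template$blocks$end[bi]
    width <- e0 - s0 + 1L
    if (blk %in% .strand_labels) {
      for (i in seq_len(n)) {
        res <- segs[[i]][[blk]]
        if (!length(res)) { flagged[i] <- TRUE; next }
        if (length(res) > width) { flagged[i] <- TRUE; res <- res[1:width] }
        tm[i, s0:(s0 + length(res) - 1L)] <- res
      }
    } else {
      loopseq <- vapply(segs, function(s) paste(s[[blk]], collapse = ""), "")
      if (!any(nzchar(loopseq))) next
      colmat <- star_align(loopseq, ...)
      k <- min(template$kept_loop_sites[[blk]], ncol(colmat))
      keep <- rank_loop_columns(colmat, k)
      tm[, s0:(s0 + k - 1L)] <- colmat[, keep, drop = FALSE]
    }
  }
  structure(tm, flagged = flagged, class = c("template_map", "matrix"))
}

#' Call DH[S/T]W tetrads on template-mapped repeats
#'
#' The tetrad is the Asp/His/Ser-or-Thr/Trp hydrogen-bond network of one
#' blade. Each member is called present when the configured template
#' position carries a residue from its allowed set (D; H; S or T; W); a
#' repeat's tetrad is complete when all four are present.
#'
#' @param tm template map matrix from [map_repeats_to_template()].
#' @param sites named integer vector of template positions for D, H, ST, W
#'   (defaults: the [wd40_template()] anchors — the SPDG aspartate on Lab,
#'   the Lda histidine, the final Sb serine site, and the Sc tryptophan at
#'   template position 37).
#' @return data.frame, one row per repeat: site positions, present_D,
#'   present_H, present_ST, present_W, complete.
#' @export
call_tetrad <- function(tm, sites = wd40_template()$tetrad_sites) {
  L <- ncol(tm)
  if (!all(c("D", "H", "ST", "W") %in% names(sites)))
    stop("sites must name positions D, H, ST, W")
  if (any(sites < 1L) || any(sites > L))
    stop("tetrad site outside template (1..", L, ")")
  allowed <- list(D = "D", H = "H", ST = c("S", "T"), W = "W")
  pres <- sapply(c("D", "H", "ST", "W"), function(k)
    tm[, sites[[k]]] %in% allowed[[k]])
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1L,
                                         dimnames = list(NULL, names(allowed)))
  data.frame(repeat_index = rownames(tm) %||% seq_len(nrow(tm)),
             site_D = sites[["D"]], site_H = sites[["H"]],
             site_ST = sites[["ST"]], site_W = sites[["W"]],
             present_D = pres[, "D"], present_H = pres[, "H"],
             present_ST = pres[, "ST"], present_W = pres[, "W"],
             complete = rowSums(pres) == 4L,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tetrad density of a protein
#'
#' Complete tetrads divided by repeat count; one repeat can hold at most
#' one tetrad, so the density lies in \[0,1\].
#'
#' @param calls tetrad call table from [call_tetrad()] (one row per
#'   repeat).
#' @param n_repeats repeat count (defaults to `nrow(calls)`).
#' @return fraction in \[0,1\].
#' @export
tetrad_density <- function(calls, n_repeats = nrow(calls)) {
  if (n_repeats == 0L) stop("tetrad density undefined for zero repeats")
  sum(calls$complete) / n_repeats
}

#' Residue count (logo) matrix from template-mapped repeats
#'
#' @param tm template map matrix, or a list of them (e.g. one per protein)
#'   which are stacked.
#' @return 20 x L integer matrix of residue counts per template position
#'   (gaps not counted), class `logo_matrix`.
#' @export
logo_matrix <- function(tm) {
  if (is.list(tm)) tm <- do.call(rbind, tm)
  counts <- vapply(seq_len(ncol(tm)), function(j)
    vapply(.AA20, function(a) sum(tm[, j] == a), 0L), integer(20L))
  rownames(counts) <- .AA20
  structure(counts, class = c("logo_matrix", "matrix"))
}

#' Per-position information content of a logo matrix
#'
#' Shannon information against the uniform 20-letter background, without
#' small-sample correction: log2(20) minus the entropy of the empirical
#' residue distribution at the position.
#'
#' @param lm logo (count) matrix from [logo_matrix()].
#' @return numeric vector of bits per template position in
#'   \[0, log2(20)\]; `NA` at positions with no residues.
#' @export
information_content <- function(lm) {
  apply(lm, 2L, function(cnt) {
    tot <- sum(cnt)
    if (tot == 0L) return(NA_real_)
    p <- cnt[cnt > 0L] / tot
    log2(20) + sum(p * log2(p))
  })
}
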