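#' Canonical WD40 blade template
#'
#' The package's reference blade for one WD40 sequence repeat. A blade has
#' four antiparallel beta-strands (Sa, Sb, Sc, Sd) connected by loops; the
#' loop preceding Sa (Lda) closes the previous blade. The template keeps the
#' conventional numbers of conserved loop sites: 6 for Lda, 5 for Lab, 3 for
#' Lbc and 4 for Lcd, so every loop block of the template is exactly its
#' kept-site width. Total template length is 48 residues.
#'
#' The template carries a complete DH[S/T]W tetrad: the His on Lda
#' (position 2), the Asp of the SPDG motif on Lab (position 16), the Ser at
#' the final Sb site (position 25) and the Trp at the last Sc site
#' (position 37). These four positions are the defaults used by
#' [call_tetrad()] and can be overridden there.
#'
#' @return A list of class `wd40_template` with elements
#'   `sequence` (48-residue amino-acid string), `labels` (per-residue
#'   structural tags), `blocks` (data.frame of block name, start, end),
#'   `tetrad_sites` (named integer vector D/H/ST/W) and
#'   `kept_loop_sites` (named integer vector for the four loops).
#' @export
#' @examples
#' tpl <- wd40_template()
#' substr(tpl$sequence, 37, 37)  # the Sc tryptophan
wd40_template <- function() {
  blocks <- data.frame(
    block = c("Lda", "Sa", "Lab", "Sb", "Lbc", "Sc", "Lcd", "Sd"),
    len   = c(6L,    7L,   5L,    7L,   3L,    9L,   4L,    7L),
    stringsAsFactors = FALSE
  )
  blocks$end <- cumsum(blocks$len)
  blocks$start <- blocks$end - blocks$len + 1L
  seg <- c(
    Lda = "GHTNSV",
    Sa  = "YVKAVAF",
    Lab = "SPDGS",
    Sb  = "KLLASGS",
    Lbc = "DDN",
    Sc  = "TIKLVDLNW",
    Lcd = "ETGA",
    Sd  = "KLKTFEG"
  )
  structure(list(
    sequence = paste(seg, collapse = ""),
    labels = rep(blocks$block, blocks$len),
    blocks = blocks[, c("block", "start", "end")],
    tetrad_sites = c(D = 16L, H = 2L, ST = 25L, W = 37L),
    kept_loop_sites = c(Lda = 6L, Lab = 5L, Lbc = 3L, Lcd = 4L)
  ), class = "wd40_template")
}

# residue labels in canonical blade order, starting at Lda
.blade_order <- c("Lda", "Sa", "Lab", "Sb", "Lbc", "Sc", "Lcd", "Sd")
.strand_labels <- c("Sa", "Sb", "Sc", "Sd")
.loop_labels <- c("Lda", "Lab", "Lbc", "Lcd")
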