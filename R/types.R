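#' Construct a WD40 protein record
#'
#' The central container of the package: one protein with its ordered repeat
#' annotation and, optionally, its coding sequence. Repeats are held as a
#' data.frame with one row per repeat unit (columns `index`, `start`, `end`,
#' `score`, `sequence`, `labels`); `labels` is a comma-separated string of
#' per-residue structural tags (Sa/Sb/Sc/Sd strands, Lda/Lab/Lbc/Lcd loops),
#' one tag per residue.
#'
#' @param accession protein accession.
#' @param sequence amino-acid sequence (uppercased).
#' @param repeats data.frame of repeat units as described above; rows are
#'   sorted by `start` on construction.
#' @param gene_id,organism_id identifiers used for per-gene deduplication.
#' @param category taxonomic category, one of Animalia, Plantae, Fungi,
#'   Protista, Archaea, Bacteria, Virus, Other.
#' @param cds optional coding sequence; when present its length must be
#'   exactly three times the protein length (stop codon excluded).
#' @return object of class `wd40_protein`.
#' @export
wd40_protein <- function(accession, sequence, repeats,
                         gene_id = accession, organism_id = "unknown",
                         category = "Other", cds = NULL) {
  sequence <- toupper(sequence)
  if (!is.null(cds)) cds <- toupper(cds)
  p <- structure(list(
    accession = as.character(accession),
    gene_id = as.character(gene_id),
    organism_id = as.character(organism_id),
    category = match.arg(category, c("Animalia", "Plantae", "Fungi",
                                     "Protista", "Archaea", "Bacteria",
                                     "Virus", "Other")),
    sequence = sequence,
    repeats = repeats[order(repeats$start), , drop = FALSE],
    cds = cds
  ), class = "wd40_protein")
  rownames(p$repeats) <- NULL
  validate_wd40_protein(p)
  p
}

#' Validate a WD40 protein record
#'
#' Checks the structural invariants: repeat coordinates within the protein,
#' non-overlapping ordered repeats, per-repeat label vectors matching repeat
#' length with tags drawn from the eight strand/loop names in contiguous
#' canonical-order runs, non-negative scores, and CDS length 3x protein
#' length when a CDS is present.
#'
#' @param p a `wd40_protein`.
#' @return `p`, invisibly; stops with an informative error on violation.
#' @export
validate_wd40_protein <- function(p) {
  stopifnot(inherits(p, "wd40_protein"))
  r <- p$repeats
  if (nrow(r) == 0L)
    stop("protein ", p$accession, ": no repeats annotated")
  need <- c("index", "start", "end", "score", "sequence", "labels")
  if (!all(need %in% names(r)))
    stop("protein ", p$accession, ": repeat table missing columns: ",
         paste(setdiff(need, names(r)), collapse = ", "))
  if (any(r$end < r$start))
    stop("protein ", p$accession, ": repeat with end < start")
  if (any(r$start < 1L) || any(r$end > nchar(p$sequence)))
    stop("protein ", p$accession, ": repeat outside protein bounds")
  if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)]))
    stop("protein ", p$accession, ": overlapping repeats")
  if (any(r$score < 0))
    stop("protein ", p$accession, ": negative repeat score")
  for (i in seq_len(nrow(r))) {
    len <- r$end[i] - r$start[i] + 1L
    if (nchar(r$sequence[i]) != len)
      stop("protein ", p$accession, ": repeat ", r$index[i],
           " sequence length != end - start + 1")
    tags <- repeat_labels(r$labels[i])
    if (length(tags) != len)
      stop("protein ", p$accession, ": repeat ", r$index[i],
           " has ", length(tags), " labels for ", len, " residues")
    bad <- setdiff(unique(tags), .blade_order)
    if (length(bad))
      stop("protein ", p$accession, ": unknown label tag(s): ",
           paste(bad, collapse = ", "))
    if (!labels_in_blade_order(tags))
      stop("protein ", p$accession, ": repeat ", r$index[i],
           " labels not in canonical blade order")
  }
  if (!is.null(p$cds) && nchar(p$cds) != 3L * nchar(p$sequence))
    stop("protein ", p$accession, ": cds length must be 3x protein length")
  invisible(p)
}

#' Split a packed label string into per-residue tags
#' @param labels comma-separated tag string (or an already-split vector).
#' @return character vector of tags.
#' @export
repeat_labels <- function(labels) {
  if (length(labels) == 1L && grepl(",", labels, fixed = TRUE))
    return(strsplit(labels, ",", fixed = TRUE)[[1L]])
  if (length(labels) == 1L && labels %in% .blade_order) return(labels)
  if (length(labels) > 1L) return(as.character(labels))
  strsplit(labels, ",", fixed = TRUE)[[1L]]
}

# tags must be contiguous runs following the cyclic blade order; a repeat may
# start mid-cycle (the "Velcro" offset between sequence repeat and blade)
labels_in_blade_order <- function(tags) {
  runs <- rle(tags)$values
  if (anyDuplicated(runs)) return(FALSE)
  pos <- match(runs, .blade_order)
  if (anyNA(pos)) return(FALSE)
  if (length(pos) <= 1L) return(TRUE)
  steps <- diff(pos) %% length(.blade_order)
  all(steps >= 1L) && sum(steps) <= length(.blade_order)
}

#' @export
print.wd40_protein <- function(x, ...) {
  cat("<wd40_protein>", x$accession,
      sprintf("(%s, %s)", x$organism_id, x$category), "\n")
  cat("  length:", nchar(x$sequence), "aa;",
      nrow(x$repeats), "repeats; mean score",
      round(mean(x$repeats$score), 1), "\n")
  if (!is.null(x$cds)) cat("  cds:", nchar(x$cds), "nt\n")
  invisible(x)
}

#' Construct a gene record table
#'
#' @param gene_id,contig,start,end,strand,product vectors of equal length;
#'   coordinates are 1-based inclusive, strand one of "+"/"-".
#' @return data.frame with the six columns, one row per gene.
#' @export
gene_record <- function(gene_id, contig, start, end, strand, product = "") {
  g <- data.frame(gene_id = as.character(gene_id),
                  contig = as.character(contig),
                  start = as.integer(start), end = as.integer(end),
                  strand = as.character(strand),
                  product = as.character(product),
                  stringsAsFactors = FALSE)
  if (any(g$end < g$start)) stop("gene record with end < start")
  if (!all(g$strand %in% c("+", "-"))) stop("unknown strand symbol")
  g
}

#' Construct proteome records
#'
#' @param organism_id,category,n_proteins,n_wd40 vectors of equal length.
#' @return data.frame of proteome records (one organism per row).
#' @export
proteome_record <- function(organism_id, category, n_proteins, n_wd40) {
  r <- data.frame(organism_id = as.character(organism_id),
                  category = as.character(category),
                  n_proteins = as.integer(n_proteins),
                  n_wd40 = as.integer(n_wd40),
                  stringsAsFactors = FALSE)
  if (any(r$n_proteins <= 0L)) stop("n_proteins must be positive")
  if (any(r$n_wd40 < 0L) || any(r$n_wd40 > r$n_proteins))
    stop("need 0 <= n_wd40 <= n_proteins")
  r
}
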