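#' @importFrom utils read.delim write.table head combn
#' @importFrom stats median rbinom rpois runif setNames
NULL

# leveled logging; level "warn" by default so library use stays quiet,
# the CLI switches to "info" to echo filter counts and seeds
.log_levels <- c(debug = 1L, info = 2L, warn = 3L)
rs_log <- function(level, ...) {
  threshold <- getOption("repeatscope.log_level", "warn")
  if (.log_levels[[level]] >= .log_levels[[threshold]])
    message("[", level, "] ", ...)
  invisible(NULL)
}

#' Read a FASTA file
#'
#' Sequences are uppercased and stripped of gaps and whitespace; record
#' order is preserved. An empty file yields an empty vector with a warning.
#'
#' @param path FASTA file (protein or nucleotide).
#' @return named character vector, names = record ids (first whitespace
#'   token of each header), values = sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA (", path, "): ",
                                           conditionMessage(e)))
  seqs <- toupper(gsub("[-.[:space:]]", "", as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("malformed FASTA: empty header in ", path)
  setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector as returned by [read_fasta()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a repeat-annotation table into WD40 protein records
#'
#' The table is the package's WDSP-style TSV dialect: one row per repeat
#' unit with columns `accession`, `repeat_index`, `start`, `end`, `score`,
#' `labels` (comma-separated per-residue structural tags) and optionally
#' `sequence` (the repeat's residues), `gene_id`, `organism_id`,
#' `category`. Coordinates are 1-based inclusive residue positions.
#'
#' @param path TSV file as above (with header).
#' @param fasta optional FASTA of full protein sequences; when given, repeat
#'   sequences are taken from it by coordinate and the full sequence is
#'   attached. Without it a minimal sequence is reconstructed from the
#'   repeat rows (inter-repeat residues set to X).
#' @return list of [wd40_protein()] objects (no CDS), repeats sorted by
#'   start, all invariants enforced.
#' @export
read_repeat_table <- function(path, fasta = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "repeat_index", "start", "end", "score", "labels")
  if (!all(need %in% names(tab)))
    stop("repeat table must have columns: ", paste(need, collapse = ", "))
  seqs <- if (!is.null(fasta)) read_fasta(fasta) else NULL
  out <- lapply(split(tab, tab$accession), function(rows) {
    acc <- rows$accession[1L]
    if (!is.null(seqs)) {
      if (!acc %in% names(seqs))
        stop("accession ", acc, " missing from FASTA")
      full <- seqs[[acc]]
      rseq <- substr(rep(full, nrow(rows)), rows$start, rows$end)
    } else if ("sequence" %in% names(rows)) {
      rseq <- rows$sequence
      full <- paste(rep("X", max(rows$end)), collapse = "")
      for (i in seq_len(nrow(rows)))
        substr(full, rows$start[i], rows$end[i]) <- rseq[i]
    } else stop("repeat table needs a sequence column or a FASTA")
    wd40_protein(
      accession = acc, sequence = full,
      repeats = data.frame(index = rows$repeat_index, start = rows$start,
                           end = rows$end, score = rows$score,
                           sequence = rseq, labels = rows$labels,
                           stringsAsFactors = FALSE),
      gene_id = if ("gene_id" %in% names(rows)) rows$gene_id[1L] else acc,
      organism_id = if ("organism_id" %in% names(rows))
        rows$organism_id[1L] else "unknown",
      category = if ("category" %in% names(rows)) rows$category[1L] else "Other"
    )
  })
  rs_log("info", "read_repeat_table: ", length(out), " proteins, ",
         nrow(tab), " repeat rows from ", path)
  out[order(names(out))]
}

#' Write WD40 protein repeat annotations as TSV
#'
#' Inverse of [read_repeat_table()] (with the `sequence` column included).
#'
#' @param proteins list of `wd40_protein`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(proteins, path) {
  rows <- do.call(rbind, lapply(proteins, function(p) {
    cbind(accession = p$accession, p$repeats[, c("index", "start", "end",
                                                 "score", "sequence",
                                                 "labels")],
          gene_id = p$gene_id, organism_id = p$organism_id,
          category = p$category)
  }))
  names(rows)[names(rows) == "index"] <- "repeat_index"
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' @param path GFF3 file or TSV with header columns `gene_id`, `contig`,
#'   `start`, `end`, `strand`, `product`.
#' @param format `"gff3"` or `"tsv"`.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @param product_attr GFF3 attribute carrying the functional annotation
#'   (default `"product"`; falls back to `"Name"`, then empty).
#' @return gene record data.frame (see [gene_record()]); coordinates stay
#'   1-based inclusive as in GFF3.
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3"),
                            feature_type = "gene", product_attr = "product") {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr, stringsAsFactors = FALSE)
    df <- df[as.character(df$type) %in% feature_type, , drop = FALSE]
    pick <- function(col) if (col %in% names(df))
      as.character(df[[col]]) else rep(NA_character_, nrow(df))
    ids <- pick("ID")
    if (all(is.na(ids))) ids <- paste0("gene", seq_len(nrow(df)))
    prod <- pick(product_attr)
    prod[is.na(prod)] <- pick("Name")[is.na(prod)]
    prod[is.na(prod)] <- ""
    strand <- as.character(df$strand)
    if (any(!strand %in% c("+", "-")))
      stop("unknown strand symbol in ", path)
    return(gene_record(ids, as.character(df$seqnames),
                       df$start, df$end, strand, prod))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "start", "end", "strand", "product")
  if (!all(need %in% names(tab)))
    stop("gene TSV must have columns: ", paste(need, collapse = ", "))
  gene_record(tab$gene_id, tab$contig, tab$start, tab$end, tab$strand,
              tab$product)
}

#' Read a proteome summary table
#'
#' @param path TSV with header columns `organism_id`, `category`,
#'   `n_proteins`, `n_wd40`.
#' @return proteome record data.frame (see [proteome_record()]).
#' @export
read_proteome_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  proteome_record(tab$organism_id, tab$category, tab$n_proteins, tab$n_wd40)
}

#' Write a results table as TSV
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
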