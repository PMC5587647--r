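#' Cluster genes into same-strand neighbourhoods
#'
#' Operon-proxy clustering: consecutive genes on the same contig and strand
#' belong to one cluster when the intergenic distance between them —
#' `next$start - prev$end - 1`, the bases strictly between the two genes —
#' is below `max_gap`. Overlapping genes (negative gap) therefore cluster.
#' Every gene is assigned to exactly one cluster; isolated genes form
#' size-1 clusters. Cluster ids are deterministic, derived from the
#' leftmost member.
#'
#' @param genes gene record data.frame (see [gene_record()]).
#' @param max_gap maximum intergenic distance in bases, exclusive
#'   (default 300: a 299-bp gap joins, a 300-bp gap splits).
#' @param gap_convention `"between"` (default, as above) or
#'   `"start_to_end"` (`next$start - prev$end`).
#' @return the gene table sorted by contig/strand/start with a `cluster_id`
#'   column added.
#' @export
cluster_genes <- function(genes, max_gap = 300L,
                          gap_convention = c("between", "start_to_end")) {
  gap_convention <- match.arg(gap_convention)
  off <- if (gap_convention == "between") 1L else 0L
  g <- genes[order(genes$contig, genes$strand, genes$start), , drop = FALSE]
  key <- paste(g$contig, g$strand, sep = "\r")
  cluster_id <- character(nrow(g))
  for (k in unique(key)) {
    idx <- which(key == k)
    gap <- g$start[idx][-1L] - g$end[idx][-length(idx)] - off
    grp <- cumsum(c(TRUE, gap >= max_gap))
    first <- idx[!duplicated(grp)]
    cluster_id[idx] <- paste0(g$contig[first], g$strand[first],
                              ":", g$start[first])[grp]
  }
  g$cluster_id <- cluster_id
  rownames(g) <- NULL
  rs_log("info", "cluster_genes: ", nrow(g), " genes -> ",
         length(unique(cluster_id)), " clusters")
  g
}

#' Bidirectional best hits between two proteomes
#'
#' For each protein of one proteome the best partner in the other is found
#' by global alignment score (ties broken by higher identity, then by
#' lexicographically smaller id); a pair is reported only when the two
#' proteins are each other's best hits.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences (names = ids), as from [read_fasta()].
#' @param ... alignment parameters for [nw_align()].
#' @return data.frame with columns id_a, id_b, score, identity; zero rows
#'   when no pair is mutual.
#' @export
bbh_pairs <- function(proteome_a, proteome_b, ...) {
  if (!length(proteome_a) || !length(proteome_b))
    stop("both proteomes must be non-empty")
  score <- matrix(0, length(proteome_a), length(proteome_b),
                  dimnames = list(names(proteome_a), names(proteome_b)))
  ident <- score
  for (i in seq_along(proteome_a)) {
    alns <- nw_align_many(proteome_a[[i]], unname(proteome_b), ...)
    for (j in seq_along(proteome_b)) {
      score[i, j] <- alns[[j]]$score
      ident[i, j] <- pairwise_identity(alns[[j]], nchar(proteome_a[[i]]),
                                       nchar(proteome_b[[j]]))
    }
  }
  best_of <- function(s, id_names, ids) {
    # index of best partner for one row/column of scores
    cand <- which(s == max(s))
    cand <- cand[order(-ids[cand], id_names[cand])]
    cand[1L]
  }
  na <- length(proteome_a); nb <- length(proteome_b)
  best_b <- vapply(seq_len(na), function(i)
    best_of(score[i, ], colnames(score), ident[i, ]), 0L)
  best_a <- vapply(seq_len(nb), function(j)
    best_of(score[, j], rownames(score), ident[, j]), 0L)
  keep <- which(best_a[best_b] == seq_len(na))
  out <- data.frame(
    id_a = rownames(score)[keep],
    id_b = colnames(score)[best_b[keep]],
    score = score[cbind(keep, best_b[keep])],
    identity = ident[cbind(keep, best_b[keep])],
    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Match conserved gene neighbourhoods across two genomes
#'
#' Two clusters form a conserved pair when (i) they contain a
#' bidirectional-best-hit pair of WD40 genes, and (ii) every other member
#' of the smaller cluster has a BBH partner with identity at least
#' `min_identity` inside the other cluster. WD40-containing clusters with
#' no such partner are reported as lineage/species-specific.
#'
#' @param clusters_a,clusters_b clustered gene tables from
#'   [cluster_genes()] (gene ids must match the protein ids used for
#'   `pairs`).
#' @param pairs BBH table from [bbh_pairs()] computed between the two
#'   genomes' proteins.
#' @param wd40_ids character vector of gene ids annotated as WD40 genes.
#' @param min_identity minimum BBH identity for neighbour conservation
#'   (default 0.3).
#' @return list with `matches` (data.frame: cluster_a, cluster_b, wd40_a,
#'   wd40_b, n_support) and `specific_a`, `specific_b` (cluster ids of
#'   unmatched WD40-containing clusters).
#' @export
match_conserved_clusters <- function(clusters_a, clusters_b, pairs,
                                     wd40_ids, min_identity = 0.3) {
  cl_of <- function(clusters) setNames(clusters$cluster_id, clusters$gene_id)
  ca <- cl_of(clusters_a); cb <- cl_of(clusters_b)
  ok <- pairs[pairs$identity >= min_identity, , drop = FALSE]
  seeds <- pairs[pairs$id_a %in% wd40_ids & pairs$id_b %in% wd40_ids, ,
                 drop = FALSE]
  rows <- list()
  for (s in seq_len(nrow(seeds))) {
    wa <- seeds$id_a[s]; wb <- seeds$id_b[s]
    if (!wa %in% names(ca) || !wb %in% names(cb)) next
    mem_a <- clusters_a$gene_id[clusters_a$cluster_id == ca[[wa]]]
    mem_b <- clusters_b$gene_id[clusters_b$cluster_id == cb[[wb]]]
    if (length(mem_a) <= length(mem_b)) {
      small <- setdiff(mem_a, wa); other <- mem_b
      covered <- vapply(small, function(g) any(
        ok$id_a == g & ok$id_b %in% other), TRUE)
    } else {
      small <- setdiff(mem_b, wb); other <- mem_a
      covered <- vapply(small, function(g) any(
        ok$id_b == g & ok$id_a %in% other), TRUE)
    }
    if (all(covered))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_a = ca[[wa]], cluster_b = cb[[wb]], wd40_a = wa,
        wd40_b = wb, n_support = length(small), stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_a = character(0), cluster_b = character(0),
               wd40_a = character(0), wd40_b = character(0),
               n_support = integer(0), stringsAsFactors = FALSE)
  wd_cl_a <- unique(ca[names(ca) %in% wd40_ids])
  wd_cl_b <- unique(cb[names(cb) %in% wd40_ids])
  list(matches = matches,
       specific_a = setdiff(wd_cl_a, matches$cluster_a),
       specific_b = setdiff(wd_cl_b, matches$cluster_b))
}

#' Annotation term frequencies across cluster members
#'
#' Counts product annotation phrases over all genes of the given clusters,
#' after removing uninformative stoplist phrases (matched case-insensitively
#' against the trimmed product string).
#'
#' @param clusters clustered gene table (any gene table with a `product`
#'   column works).
#' @param stoplist phrases to drop (default "hypothetical protein",
#'   "WD40 repeat", and close variants).
#' @return data.frame (phrase, count) sorted by descending count, ties
#'   lexicographic.
#' @export
term_frequencies <- function(clusters,
                             stoplist = c("hypothetical protein",
                                          "WD40 repeat",
                                          "WD40 repeat protein",
                                          "WD-40 repeat protein",
                                          "uncharacterized protein", "")) {
  prod <- trimws(clusters$product)
  prod <- prod[!tolower(prod) %in% tolower(stoplist)]
  if (!length(prod))
    return(data.frame(phrase = character(0), count = integer(0)))
  tab <- table(prod)
  out <- data.frame(phrase = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$phrase), , drop = FALSE]
  rownames(out) <- NULL
  out
}
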