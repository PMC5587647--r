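# In-code fixtures and independent oracles shared across test files.

tpl <- wd40_template()

rand_prot <- function(len)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")

# a protein whose repeats are explicit sequences on the canonical template
make_protein <- function(seqs, scores = rep(90, length(seqs)),
                         accession = "P1", gene_id = accession,
                         organism_id = "org1", labels = NULL) {
  if (!length(seqs))
    return(wd40_protein(accession, "", data.frame(
      index = integer(0), start = integer(0), end = integer(0),
      score = numeric(0), sequence = character(0), labels = character(0)),
      gene_id = gene_id, organism_id = organism_id))
  lens <- nchar(seqs)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  if (is.null(labels))
    labels <- vapply(lens, function(l)
      paste(rep("Sa", l), collapse = ","), "")
  wd40_protein(
    accession = accession, sequence = paste(seqs, collapse = ""),
    repeats = data.frame(index = seq_along(seqs), start = starts,
                         end = starts + lens - 1L, score = scores,
                         sequence = seqs, labels = labels,
                         stringsAsFactors = FALSE),
    gene_id = gene_id, organism_id = organism_id)
}

# symmetric identity matrix with given off-diagonal entries (row-major upper)
sym_matrix <- function(n, upper) {
  m <- diag(1, n)
  m[upper.tri(m)] <- upper
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

random_identity_matrix <- function(n) sym_matrix(n, runif(n * (n - 1) / 2))

# --- independent oracle: internal identity -------------------------------
# enumerates every 6-subset of all repeats whose index span fits in a
# window of 8 (no constraint for 6-7 repeats) -- a different decomposition
# from the windowed implementation
oracle_internal_identity <- function(m, window = 8L, subset = 6L) {
  n <- nrow(m)
  if (n < subset) return(NA_real_)
  best <- -Inf
  for (s in utils::combn(n, subset, simplify = FALSE)) {
    if (n > 7L && (max(s) - min(s)) > (window - 1L)) next
    ms <- m[s, s]
    v <- min(ms[upper.tri(ms)])
    if (v > best) best <- v
  }
  best
}

# --- independent oracle: NG86 on tiny codon alignments -------------------
# direct site/path enumeration written against Biostrings' code table only
oracle_ng86 <- function(codons_a, codons_b, code = "1") {
  gc <- Biostrings::getGeneticCode(as.character(code))
  nts <- c("A", "C", "G", "T")
  syn_sites_one <- function(codon) {
    s <- 0
    for (p in 1:3) {
      nsyn <- 0; ntot <- 0
      for (x in nts) {
        if (x == substr(codon, p, p)) next
        mut <- codon
        substr(mut, p, p) <- x
        if (gc[[mut]] == "*") next
        ntot <- ntot + 1
        if (gc[[mut]] == gc[[codon]]) nsyn <- nsyn + 1
      }
      if (ntot > 0) s <- s + nsyn / ntot
    }
    s
  }
  path_counts <- function(ca, cb) {
    dp <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(dp)) return(c(0, 0))
    perms <- if (length(dp) == 1) list(dp) else {
      idx <- seq_along(dp)
      all_p <- if (length(dp) == 2) list(idx, rev(idx)) else {
        out <- list()
        for (i in 1:3) for (j in setdiff(1:3, i))
          out[[length(out) + 1]] <- c(i, j, setdiff(1:3, c(i, j)))
        out
      }
      lapply(all_p, function(o) dp[o])
    }
    res <- list()
    for (path in perms) {
      cur <- ca; syn <- 0; non <- 0; blocked <- FALSE
      for (p in path) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (gc[[nxt]] == "*") { blocked <- TRUE; break }
        if (gc[[cur]] == gc[[nxt]]) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      if (!blocked) res[[length(res) + 1]] <- c(syn, non)
    }
    if (!length(res)) {
      for (path in perms) {
        cur <- ca; syn <- 0; non <- 0
        for (p in path) {
          nxt <- cur
          substr(nxt, p, p) <- substr(cb, p, p)
          if (gc[[cur]] == gc[[nxt]]) syn <- syn + 1 else non <- non + 1
          cur <- nxt
        }
        res[[length(res) + 1]] <- c(syn, non)
      }
    }
    colMeans(do.call(rbind, res))
  }
  S <- mean(c(sum(vapply(codons_a, syn_sites_one, 0)),
              sum(vapply(codons_b, syn_sites_one, 0))))
  N <- 3 * length(codons_a) - S
  d <- rowSums(vapply(seq_along(codons_a), function(i)
    path_counts(codons_a[i], codons_b[i]), c(0, 0)))
  Sd <- d[[1]]; Nd <- d[[2]]
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (1 - 4 * pS / 3 <= 0 || 1 - 4 * pN / 3 <= 0)
    return(list(S = S, N = N, Sd = Sd, Nd = Nd, status = "saturated",
                dS = NA_real_, dN = NA_real_))
  list(S = S, N = N, Sd = Sd, Nd = Nd, status = "ok",
       dS = -0.75 * log(1 - 4 * pS / 3) + 0,
       dN = -0.75 * log(1 - 4 * pN / 3) + 0)
}

codon_aln <- function(a, b, code = "1")
  structure(list(codons_a = a, codons_b = b,
                 genetic_code = as.character(code)),
            class = "codon_alignment")

# --- independent oracle: one-sided rank-sum p by full enumeration --------
oracle_rank_sum_greater <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals)
  ranks <- rank(vals)
  w_obs <- sum(ranks[seq_along(a)])
  subs <- utils::combn(n, length(a))
  w_all <- apply(subs, 2, function(s) sum(ranks[s]))
  mean(w_all >= w_obs)
}

# --- independent oracle: gene clustering by BFS over the adjacency graph --
oracle_cluster_sizes <- function(genes, max_gap = 300L) {
  comp <- rep(NA_integer_, nrow(genes))
  nxt <- 0L
  for (k in unique(paste(genes$contig, genes$strand))) {
    idx <- which(paste(genes$contig, genes$strand) == k)
    idx <- idx[order(genes$start[idx])]
    adj <- function(i, j) {
      lo <- idx[min(i, j)]; hi <- idx[max(i, j)]
      abs(i - j) == 1 && (genes$start[hi] - genes$end[lo] - 1L) < max_gap
    }
    for (i in seq_along(idx)) {
      if (!is.na(comp[idx[i]])) next
      nxt <- nxt + 1L
      queue <- i
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[idx[cur]])) next
        comp[idx[cur]] <- nxt
        for (j in seq_along(idx))
          if (is.na(comp[idx[j]]) && adj(cur, j)) queue <- c(queue, j)
      }
    }
  }
  sort(as.integer(table(comp)))
}
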