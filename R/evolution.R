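.codon_env <- new.env(parent = emptyenv())
.NT <- c("A", "C", "G", "T")

#' Codon degeneracy and difference tables for a genetic code
#'
#' Precomputes, for one NCBI translation table, the NG86 ingredients: the
#' per-codon synonymous site count (enumerating the nine single-nucleotide
#' neighbours of each position; changes to stop codons are excluded from
#' the denominator) and, for every ordered codon pair, the synonymous and
#' nonsynonymous difference counts averaged over all minimal mutation
#' paths, with paths through stop codons discarded (equal weights over the
#' surviving paths; if every path is blocked, all paths are used).
#'
#' @param code NCBI genetic code id as a string (`"1"` standard, `"11"`
#'   bacterial; any id known to [Biostrings::getGeneticCode()]).
#' @return list with `aa` (named codon -> amino acid, `*` = stop),
#'   `syn_sites` (named numeric, 64 codons), `sd`/`nd` (64 x 64 matrices of
#'   per-pair synonymous / nonsynonymous differences). Cached per code.
#' @export
codon_tables <- function(code = "1") {
  code <- as.character(code)
  if (!is.null(.codon_env[[code]])) return(.codon_env[[code]])
  gc <- Biostrings::getGeneticCode(code)
  codons <- names(gc)
  aa <- setNames(unname(gc), codons)
  neighbours <- function(codon, pos) {
    nt <- strsplit(codon, "")[[1L]]
    vapply(setdiff(.NT, nt[pos]), function(x) {
      nt2 <- nt; nt2[pos] <- x; paste(nt2, collapse = "")
    }, "")
  }
  syn_sites <- vapply(codons, function(cod) {
    if (aa[[cod]] == "*") return(NA_real_)
    sum(vapply(1:3, function(p) {
      nb <- neighbours(cod, p)
      nb <- nb[aa[nb] != "*"]
      if (!length(nb)) return(0)
      sum(aa[nb] == aa[[cod]]) / length(nb)
    }, 0))
  }, 0)
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- sd
  perms <- list(`1` = list(1L), `2` = list(1:2, 2:1),
                `3` = list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                           c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || aa[[codons[i]]] == "*" || aa[[codons[j]]] == "*") next
    a <- strsplit(codons[i], "")[[1L]]
    b <- strsplit(codons[j], "")[[1L]]
    diff_pos <- which(a != b)
    k <- length(diff_pos)
    paths <- lapply(perms[[as.character(k)]], function(ord) diff_pos[ord])
    walk <- function(path) {
      cur <- a; syn <- 0; non <- 0
      for (p in path) {
        nxt <- cur; nxt[p] <- b[p]
        aa1 <- aa[[paste(cur, collapse = "")]]
        aa2 <- aa[[paste(nxt, collapse = "")]]
        if (aa2 == "*") return(NULL)
        if (aa1 == aa2) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      c(syn, non)
    }
    res <- Filter(Negate(is.null), lapply(paths, walk))
    if (!length(res)) {
      # all minimal paths pass a stop; fall back to counting through them
      res <- lapply(paths, function(path) {
        cur <- a; syn <- 0; non <- 0
        for (p in path) {
          nxt <- cur; nxt[p] <- b[p]
          if (aa[[paste(cur, collapse = "")]] ==
              aa[[paste(nxt, collapse = "")]]) syn <- syn + 1
          else non <- non + 1
          cur <- nxt
        }
        c(syn, non)
      })
    }
    m <- colMeans(do.call(rbind, res))
    sd[i, j] <- m[1L]; nd[i, j] <- m[2L]
  }
  .codon_env[[code]] <- list(aa = aa, syn_sites = syn_sites, sd = sd, nd = nd)
  .codon_env[[code]]
}

split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

translate_cds <- function(cds, code = "1") {
  aa <- codon_tables(code)$aa
  cod <- split_codons(cds)
  unknown <- !cod %in% names(aa)
  res <- character(length(cod))
  res[unknown] <- "X"
  res[!unknown] <- aa[cod[!unknown]]
  paste(res, collapse = "")
}

#' Thread a protein alignment onto coding sequences
#'
#' Converts a global amino-acid alignment of two repeat segments into a
#' codon alignment: every aligned residue pair becomes a codon pair and
#' every residue gap becomes a whole-codon gap. The CDSs must be exactly
#' three times the ungapped protein lengths and translate to the aligned
#' residues under the declared genetic code.
#'
#' @param protein_aln `wd_alignment` of the two amino-acid segments.
#' @param cds_a,cds_b in-frame coding sequences of the two segments (no
#'   stop codon).
#' @param code NCBI genetic code id (default `"1"`).
#' @return object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (character vectors, `"---"` for gaps) and `genetic_code`.
#' @export
thread_codon_alignment <- function(protein_aln, cds_a, cds_b, code = "1") {
  ga <- strsplit(protein_aln$aligned_a, "")[[1L]]
  gb <- strsplit(protein_aln$aligned_b, "")[[1L]]
  ua <- ga[ga != "-"]; ub <- gb[gb != "-"]
  if (nchar(cds_a) != 3L * length(ua) || nchar(cds_b) != 3L * length(ub))
    stop("CDS length must be 3x the ungapped protein length")
  if (translate_cds(cds_a, code) != paste(ua, collapse = ""))
    stop("cds_a does not translate to the aligned protein segment")
  if (translate_cds(cds_b, code) != paste(ub, collapse = ""))
    stop("cds_b does not translate to the aligned protein segment")
  coda <- split_codons(cds_a); codb <- split_codons(cds_b)
  out_a <- character(length(ga)); out_b <- out_a
  ia <- 0L; ib <- 0L
  for (k in seq_along(ga)) {
    if (ga[k] == "-") out_a[k] <- "---" else {
      ia <- ia + 1L; out_a[k] <- coda[ia]
    }
    if (gb[k] == "-") out_b[k] <- "---" else {
      ib <- ib + 1L; out_b[k] <- codb[ib]
    }
  }
  structure(list(codons_a = out_a, codons_b = out_b,
                 genetic_code = as.character(code)),
            class = "codon_alignment")
}

#' Nei-Gojobori (NG86) substitution estimates for a codon alignment
#'
#' The counting estimator of synonymous and nonsynonymous divergence:
#' expected site counts S and N are averaged over the two sequences
#' (per-codon synonymous site fractions from the nine single-nucleotide
#' neighbours, stop changes excluded from the denominator); observed
#' differences Sd and Nd are averaged over all minimal mutation paths with
#' stop-traversing paths discarded; proportions pS = Sd/S and pN = Nd/N are
#' corrected for multiple hits with the Jukes-Cantor formula
#' d = -(3/4) log(1 - (4/3) p). When a log argument is non-positive the
#' estimate is saturated: no rates are reported and `status` is
#' `"saturated"` (such pairs are excluded downstream rather than clamped).
#' omega = dN/dS when dS > 0, and absent (`NA`) when dS = 0.
#'
#' @param ca `codon_alignment` from [thread_codon_alignment()] (gapped
#'   codon columns are skipped).
#' @return object of class `ng86_estimate`: list with n_codons, N, S, Nd,
#'   Sd, pN, pS, dN, dS, omega, status (`"ok"` or `"saturated"`).
#' @export
ng86 <- function(ca) {
  tab <- codon_tables(ca$genetic_code)
  keep <- ca$codons_a != "---" & ca$codons_b != "---"
  a <- ca$codons_a[keep]; b <- ca$codons_b[keep]
  valid <- a %in% names(tab$aa) & b %in% names(tab$aa) &
    tab$aa[a] != "*" & tab$aa[b] != "*"
  a <- a[valid]; b <- b[valid]
  if (!length(a)) stop("no ungapped codon pairs to compare")
  S <- (sum(tab$syn_sites[a]) + sum(tab$syn_sites[b])) / 2
  N <- 3 * length(a) - S
  Sd <- sum(tab$sd[cbind(a, b)])
  Nd <- sum(tab$nd[cbind(a, b)])
  # a site class can be empty (e.g. an all-Trp alignment has S = 0); its
  # difference count is then necessarily 0 and the proportion is taken as 0
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  argS <- 1 - 4 * pS / 3; argN <- 1 - 4 * pN / 3
  saturated <- argS <= 0 || argN <= 0
  dS <- if (saturated) NA_real_ else -0.75 * log(argS) + 0
  dN <- if (saturated) NA_real_ else -0.75 * log(argN) + 0
  omega <- if (saturated || dS == 0) NA_real_ else dN / dS
  structure(list(n_codons = length(a), N = N, S = S, Nd = Nd, Sd = Sd,
                 pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
                 status = if (saturated) "saturated" else "ok"),
            class = "ng86_estimate")
}

#' @export
print.ng86_estimate <- function(x, ...) {
  cat("<ng86_estimate>", x$n_codons, "codons; status", x$status, "\n")
  cat(sprintf("  S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n", x$S, x$N, x$Sd, x$Nd))
  if (x$status == "ok")
    cat(sprintf("  dS=%.4f dN=%.4f omega=%s\n", x$dS, x$dN,
                ifelse(is.na(x$omega), "NA", sprintf("%.4f", x$omega))))
  invisible(x)
}

#' NG86 estimates for all repeat pairs of a protein
#'
#' Aligns every unordered pair of repeat units at the protein level,
#' threads the repeat CDS segments (codons i..j of the gene CDS for
#' residues i..j) onto the alignment, and runs [ng86()].
#'
#' @param protein `wd40_protein` with `cds` present; repeats must lie in
#'   one reading frame of the CDS.
#' @param code NCBI genetic code id (default `"11"`, the bacterial table,
#'   matching the prokaryote-focused pipeline).
#' @param ... alignment parameters for [nw_align()].
#' @return data.frame, one row per pair: repeat_i, repeat_j, N, S, Nd, Sd,
#'   dN, dS, omega, status.
#' @export
repeat_pair_estimates <- function(protein, code = "11", ...) {
  if (is.null(protein$cds)) stop("protein ", protein$accession, " has no CDS")
  r <- protein$repeats
  n <- nrow(r)
  if (n < 2L) stop("need >= 2 repeats")
  cds_of <- function(i) substr(protein$cds, 3L * (r$start[i] - 1L) + 1L,
                               3L * r$end[i])
  rows <- list()
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    alns <- nw_align_many(r$sequence[i], r$sequence[js], ...)
    for (k in seq_along(js)) {
      j <- js[k]
      est <- ng86(thread_codon_alignment(alns[[k]], cds_of(i), cds_of(j),
                                         code))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_i = r$index[i], repeat_j = r$index[j], N = est$N, S = est$S,
        Nd = est$Nd, Sd = est$Sd, dN = est$dN, dS = est$dS,
        omega = est$omega, status = est$status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Median repeat-pair dS of a protein
#'
#' Median over the non-saturated pairwise dS values (saturated pairs are
#' excluded, mirroring the treatment of undefined estimates); an even
#' count yields the mean of the middle two.
#'
#' @param estimates per-pair table from [repeat_pair_estimates()] (or any
#'   data.frame with `dS` and `status`).
#' @return median dS, or `NA` with attribute `reason` when every pair is
#'   saturated.
#' @export
median_repeat_ds <- function(estimates) {
  ok <- estimates$status == "ok" & !is.na(estimates$dS)
  if (!any(ok))
    return(structure(NA_real_, reason = "all repeat pairs saturated"))
  median(estimates$dS[ok])
}

#' Purifying-selection subset by median dS
#'
#' Selects proteins whose median repeat-pair dS lies in \[1.0, 2.0) — old
#' enough for reliable rate estimation but below saturation — and reports
#' the median of their per-protein omega values.
#'
#' @param ds_table data.frame with columns `accession`, `median_ds` and
#'   `median_omega` (per-protein medians; see [repeat_pair_estimates()]).
#' @param lower,upper dS bounds (default 1.0 inclusive, 2.0 exclusive).
#' @return list with `subset` (filtered rows) and `median_omega` (`NA`
#'   with a warning when the subset is empty).
#' @export
purifying_subset <- function(ds_table, lower = 1.0, upper = 2.0) {
  sel <- !is.na(ds_table$median_ds) & ds_table$median_ds >= lower &
    ds_table$median_ds < upper
  subset <- ds_table[sel, , drop = FALSE]
  if (!nrow(subset)) {
    warning("purifying_subset: no protein with median dS in [",
            lower, ", ", upper, ")")
    return(list(subset = subset, median_omega = NA_real_))
  }
  list(subset = subset,
       median_omega = median(subset$median_omega, na.rm = TRUE))
}
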