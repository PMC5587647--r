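#' Configuration for the WD40 gene simulator
#'
#' Parameters of the repeat-duplication / codon-divergence model: an
#' ancestral blade is back-translated, duplicated `n_repeats` times, and
#' each copy then evolves independently (a star phylogeny, matching the
#' pairwise statistics computed downstream).
#'
#' @param n_repeats number of repeat units (>= 6).
#' @param template a [wd40_template()] (or a list with `sequence`,
#'   `labels`, `tetrad_sites`).
#' @param t divergence time: expected candidate substitutions per
#'   nucleotide site on each repeat's lineage (>= 0).
#' @param kappa transition/transversion rate ratio (> 0; default 2).
#' @param omega_sim acceptance probability for nonsynonymous changes in
#'   \[0,1\] (synonymous changes are always accepted); values well below 1
#'   emulate purifying selection.
#' @param seed integer RNG seed; the simulator is byte-deterministic under
#'   (config, seed).
#' @param genetic_code NCBI code id (default `"11"`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_repeats = 8L, template = wd40_template(),
                       t = 0.1, kappa = 2, omega_sim = 0.1, seed = 1L,
                       genetic_code = "11") {
  stopifnot(n_repeats >= 6L, t >= 0, kappa > 0,
            omega_sim >= 0, omega_sim <= 1)
  if (grepl("\\*", template$sequence))
    stop("template contains a stop symbol")
  structure(list(n_repeats = as.integer(n_repeats), template = template,
                 t = t, kappa = kappa, omega_sim = omega_sim,
                 seed = as.integer(seed),
                 genetic_code = as.character(genetic_code)),
            class = "sim_config")
}

# transition partner of each nucleotide
.transition <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate one WD40 gene by repeat duplication and codon divergence
#'
#' Builds an ancestral repeat CDS by back-translating the template with a
#' uniform choice among synonymous codons, duplicates it, and evolves each
#' repeat independently: Poisson(t x 3 x codons) candidate point mutations,
#' target nucleotide drawn with transition weight `kappa` against 1 per
#' transversion, mutations creating stop codons rejected, nonsynonymous
#' changes accepted with probability `omega_sim`, synonymous changes always
#' accepted. Repeat boundaries, labels and a synthetic repeat score
#' (100 x positional identity to the template) are attached.
#'
#' @param cfg a [sim_config()].
#' @return list with `protein` (a `wd40_protein` with CDS) and `truth`:
#'   `ancestral_cds`, `mutations` (data.frame: repeat_index, site (1-based
#'   within the repeat CDS), from, to, synonymous), `tetrad_sites`
#'   (template positions), `boundaries` (repeat start/end residues), and
#'   `config`. The truth log is sufficient to recompute every planted
#'   quantity (see [true_pairwise_divergence()]).
#' @export
simulate_wd40_gene <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tab <- codon_tables(cfg$genetic_code)
  aa_to_codons <- split(names(tab$aa), tab$aa)
  tpl_aa <- strsplit(cfg$template$sequence, "")[[1L]]
  if (!all(tpl_aa %in% names(aa_to_codons)))
    stop("template residue not encodable under code ", cfg$genetic_code)
  anc_codons <- vapply(tpl_aa, function(a) {
    cands <- aa_to_codons[[a]]
    cands[sample.int(length(cands), 1L)]
  }, "")
  L <- length(anc_codons)
  mut_rows <- list()
  repeat_cds <- character(cfg$n_repeats)
  for (rep_i in seq_len(cfg$n_repeats)) {
    nt <- strsplit(paste(anc_codons, collapse = ""), "")[[1L]]
    n_cand <- rpois(1L, cfg$t * 3 * L)
    for (m in seq_len(n_cand)) {
      pos <- sample.int(3L * L, 1L)
      from <- nt[pos]
      others <- setdiff(.NT, from)
      w <- ifelse(others == .transition[[from]], cfg$kappa, 1)
      to <- sample(others, 1L, prob = w)
      ci <- (pos - 1L) %/% 3L + 1L
      cod <- nt[(3L * ci - 2L):(3L * ci)]
      newcod <- cod
      newcod[(pos - 1L) %% 3L + 1L] <- to
      aa_old <- tab$aa[[paste(cod, collapse = "")]]
      aa_new <- tab$aa[[paste(newcod, collapse = "")]]
      if (aa_new == "*") next
      syn <- aa_old == aa_new
      if (!syn && runif(1L) > cfg$omega_sim) next
      nt[pos] <- to
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        repeat_index = rep_i, site = pos, from = from, to = to,
        synonymous = syn, stringsAsFactors = FALSE)
    }
    repeat_cds[rep_i] <- paste(nt, collapse = "")
  }
  repeat_aa <- vapply(repeat_cds, translate_cds, "",
                      code = cfg$genetic_code, USE.NAMES = FALSE)
  score <- vapply(repeat_aa, function(s) {
    100 * mean(strsplit(s, "")[[1L]] == tpl_aa)
  }, 0, USE.NAMES = FALSE)
  starts <- (seq_len(cfg$n_repeats) - 1L) * L + 1L
  repeats <- data.frame(
    index = seq_len(cfg$n_repeats), start = starts, end = starts + L - 1L,
    score = score, sequence = repeat_aa,
    labels = paste(cfg$template$labels, collapse = ","),
    stringsAsFactors = FALSE)
  acc <- sprintf("SIM%06d", cfg$seed)
  protein <- wd40_protein(
    accession = acc, sequence = paste(repeat_aa, collapse = ""),
    repeats = repeats, gene_id = acc, organism_id = "synthetic",
    category = "Bacteria", cds = paste(repeat_cds, collapse = ""))
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(repeat_index = integer(0), site = integer(0),
               from = character(0), to = character(0),
               synonymous = logical(0), stringsAsFactors = FALSE)
  list(protein = protein,
       truth = list(ancestral_cds = paste(anc_codons, collapse = ""),
                    mutations = mutations,
                    tetrad_sites = cfg$template$tetrad_sites,
                    boundaries = repeats[, c("index", "start", "end")],
                    config = cfg))
}

#' True pairwise divergence from a simulation truth log
#'
#' Recomputes, without re-running the generator, the planted synonymous and
#' nonsynonymous divergence between every repeat pair: accepted mutations
#' on the two lineages divided by the NG86 synonymous (resp.
#' nonsynonymous) site count of the ancestral repeat.
#'
#' @param truth truth log from [simulate_wd40_gene()].
#' @return list with matrices `syn` and `nonsyn` (n_repeats x n_repeats,
#'   substitutions per site) and scalars `S_anc`, `N_anc`.
#' @export
true_pairwise_divergence <- function(truth) {
  tab <- codon_tables(truth$config$genetic_code)
  anc <- split_codons(truth$ancestral_cds)
  S_anc <- sum(tab$syn_sites[anc])
  N_anc <- 3 * length(anc) - S_anc
  n <- truth$config$n_repeats
  nsyn <- vapply(seq_len(n), function(i)
    sum(truth$mutations$synonymous[truth$mutations$repeat_index == i]), 0)
  nnon <- vapply(seq_len(n), function(i)
    sum(!truth$mutations$synonymous[truth$mutations$repeat_index == i]), 0)
  syn <- outer(nsyn, nsyn, "+") / S_anc
  nonsyn <- outer(nnon, nnon, "+") / N_anc
  diag(syn) <- 0; diag(nonsyn) <- 0
  list(syn = syn, nonsyn = nonsyn, S_anc = S_anc, N_anc = N_anc)
}

#' Simulate proteome collections with set WD40 abundances
#'
#' One proteome per row drawn per the configured category: `n_wd40 ~
#' Binomial(n_proteins, abundance/100)`, or `round(n_proteins x p)` in
#' exact mode. The default configuration reproduces the study conditions
#' of the six cellular taxonomic categories (proteome counts as published;
#' abundances equal to the published per-category means; typical proteome
#' sizes per category).
#'
#' @param config data.frame with columns `category`, `n_proteomes`,
#'   `n_proteins` (proteome size), `abundance_pct`.
#' @param seed integer RNG seed.
#' @param exact deterministic rounding instead of binomial draws.
#' @return proteome record data.frame (see [proteome_record()]).
#' @export
simulate_proteomes <- function(config = default_proteome_config(),
                               seed = 1L, exact = FALSE) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(config)), function(i) {
    n <- config$n_proteomes[i]
    size <- rep(config$n_proteins[i], n)
    p <- config$abundance_pct[i] / 100
    w <- if (exact) round(size * p) else rbinom(n, size, p)
    proteome_record(sprintf("%s_%03d", config$category[i], seq_len(n)),
                    config$category[i], size, w)
  })
  do.call(rbind, rows)
}

#' Default proteome simulation configuration
#'
#' The six cellular categories with their published complete-proteome
#' counts and mean WD40 abundances; proteome sizes are round figures
#' typical of each category.
#'
#' @return config data.frame for [simulate_proteomes()].
#' @export
default_proteome_config <- function() {
  data.frame(
    category = c("Animalia", "Plantae", "Fungi", "Protista",
                 "Archaea", "Bacteria"),
    n_proteomes = c(100L, 27L, 198L, 55L, 134L, 1679L),
    n_proteins = c(15000L, 25000L, 9000L, 12000L, 2400L, 3500L),
    abundance_pct = c(0.98, 0.77, 1.21, 1.08, 0.08, 0.06),
    stringsAsFactors = FALSE)
}

#' Expected pairwise synonymous divergence per unit mutation rate
#'
#' Analytic calibration of the simulator: the expected pairwise synonymous
#' divergence (accepted synonymous substitutions on both lineages per NG86
#' synonymous site of the ancestor) accrued per unit of the simulator's
#' per-nucleotide candidate rate `t`. Computed from the template's amino
#' acids under uniform synonymous codon usage and the kappa-weighted target
#' distribution — no simulation involved. To simulate repeat pairs at a
#' target synonymous divergence `d`, set `t = d / pairwise_syn_rate(...)`.
#'
#' @param template a [wd40_template()] (or list with `sequence`).
#' @param kappa transition/transversion rate ratio.
#' @param genetic_code NCBI code id.
#' @return scalar rate (dimensionless).
#' @export
pairwise_syn_rate <- function(template = wd40_template(), kappa = 2,
                              genetic_code = "11") {
  tab <- codon_tables(genetic_code)
  aa_to_codons <- split(names(tab$aa), tab$aa)
  tpl_aa <- strsplit(template$sequence, "")[[1L]]
  L <- length(tpl_aa)
  q <- function(from, to)
    (if (to == .transition[[from]]) kappa else 1) / (kappa + 2)
  syn_events <- 0; S_exp <- 0
  for (a in tpl_aa) {
    cods <- aa_to_codons[[a]]
    for (cod in cods) {
      w <- 1 / length(cods)
      S_exp <- S_exp + w * tab$syn_sites[[cod]]
      nt <- strsplit(cod, "")[[1L]]
      for (p in 1:3) for (x in setdiff(.NT, nt[p])) {
        mut <- nt; mut[p] <- x
        mutc <- paste(mut, collapse = "")
        if (tab$aa[[mutc]] == a)           # synonymous, always accepted
          syn_events <- syn_events + w * q(nt[p], x) / 3
      }
    }
  }
  # candidates per lineage = t * 3L, each picks a uniform nucleotide, so
  # expected synonymous events per lineage = t * 3 * syn_events; two
  # lineages diverge independently
  2 * 3 * syn_events / S_exp
}

random_protein <- function(len) paste(sample(.AA20, len, TRUE), collapse = "")

#' Simulate a gene table with planted same-strand clusters
#'
#' Lays planted clusters consecutively on their contigs with the requested
#' intragenic gaps and strand, separated from each other and from decoy
#' genes by at least `decoy_gap` bases; decoys may also sit on the
#' opposite strand. Gene lengths are drawn uniformly in
#' \[`len_range[1]`, `len_range[2]`\].
#'
#' @param planted data.frame with columns `contig`, `size`, `gap`,
#'   `strand` — one planted cluster per row.
#' @param n_decoys decoy genes appended per contig.
#' @param decoy_gap minimum separation around/between decoys (default 400,
#'   safely above the clustering threshold).
#' @param len_range gene length range in bases.
#' @param seed integer RNG seed.
#' @param products annotation vocabulary sampled for gene products.
#' @return list with `genes` (gene record data.frame) and `truth`
#'   (data.frame gene_id, planted_cluster; `NA` for decoys).
#' @export
simulate_gene_table <- function(planted, n_decoys = 5L, decoy_gap = 400L,
                                len_range = c(300L, 1500L), seed = 1L,
                                products = c("serine/threonine protein kinase",
                                             "ABC transporter ATP-binding protein",
                                             "two-component sensor histidine kinase",
                                             "glycosyltransferase",
                                             "hypothetical protein")) {
  stopifnot(all(planted$gap >= 0L))
  set.seed(seed)
  genes <- list(); truth <- list()
  gid <- 0L
  for (contig in unique(planted$contig)) {
    pos <- 1L
    pc <- planted[planted$contig == contig, , drop = FALSE]
    for (ci in seq_len(nrow(pc))) {
      lab <- sprintf("%s_cluster%d", contig, ci)
      for (gi in seq_len(pc$size[ci])) {
        len <- sample(len_range[1L]:len_range[2L], 1L)
        gid <- gid + 1L
        id <- sprintf("g%04d", gid)
        genes[[gid]] <- gene_record(id, contig, pos, pos + len - 1L,
                                    pc$strand[ci],
                                    sample(products, 1L))
        truth[[gid]] <- data.frame(gene_id = id, planted_cluster = lab,
                                   stringsAsFactors = FALSE)
        pos <- pos + len + if (gi < pc$size[ci]) pc$gap[ci] else decoy_gap
      }
    }
    for (d in seq_len(n_decoys)) {
      len <- sample(len_range[1L]:len_range[2L], 1L)
      gid <- gid + 1L
      id <- sprintf("g%04d", gid)
      genes[[gid]] <- gene_record(id, contig, pos, pos + len - 1L,
                                  sample(c("+", "-"), 1L),
                                  sample(products, 1L))
      truth[[gid]] <- data.frame(gene_id = id,
                                 planted_cluster = NA_character_,
                                 stringsAsFactors = FALSE)
      pos <- pos + len + decoy_gap
    }
  }
  list(genes = do.call(rbind, genes), truth = do.call(rbind, truth))
}

#' Simulate a pair of genomes sharing one conserved WD40 neighbourhood
#'
#' Plants the same `n_shared`-gene cluster (identical protein sequences,
#' first member the WD40 gene) in two genomes, plus per-genome decoy genes
#' with unrelated random proteins. Handy for exercising [bbh_pairs()] and
#' [match_conserved_clusters()] end to end.
#'
#' @param n_shared size of the shared cluster (>= 2).
#' @param gap intragenic gap inside the planted cluster (default 50).
#' @param n_decoys decoys per genome.
#' @param protein_len length of the simulated proteins.
#' @param seed integer RNG seed.
#' @param disrupt_b if TRUE, one non-WD40 member of genome B's cluster is
#'   replaced by an unrelated sequence (breaks conservation).
#' @return list: `genes_a`, `genes_b` (gene tables), `proteins_a`,
#'   `proteins_b` (named sequence vectors), `wd40_ids`, and
#'   `shared_cluster` truth labels.
#' @export
simulate_genome_pair <- function(n_shared = 3L, gap = 50L, n_decoys = 4L,
                                 protein_len = 120L, seed = 1L,
                                 disrupt_b = FALSE) {
  stopifnot(n_shared >= 2L)
  set.seed(seed)
  shared <- vapply(seq_len(n_shared), function(i) random_protein(protein_len),
                   "")
  build <- function(prefix, disrupt = FALSE) {
    ids <- sprintf("%s_c%02d", prefix, seq_len(n_shared))
    prot <- setNames(shared, ids)
    if (disrupt && n_shared >= 2L) prot[[2L]] <- random_protein(protein_len)
    pos <- 1L
    rows <- list()
    for (i in seq_len(n_shared)) {
      len <- protein_len * 3L
      rows[[i]] <- gene_record(ids[i], paste0(prefix, "_chr"), pos,
                               pos + len - 1L, "+",
                               if (i == 1L) "WD40 repeat protein"
                               else "conserved neighbour")
      pos <- pos + len + gap
    }
    pos <- pos + 1000L
    for (d in seq_len(n_decoys)) {
      id <- sprintf("%s_d%02d", prefix, d)
      prot[[id]] <- random_protein(protein_len)
      len <- protein_len * 3L
      rows[[n_shared + d]] <- gene_record(id, paste0(prefix, "_chr"), pos,
                                          pos + len - 1L, "+",
                                          "hypothetical protein")
      pos <- pos + len + 1000L
    }
    list(genes = do.call(rbind, rows), proteins = prot)
  }
  a <- build("a")
  b <- build("b", disrupt = disrupt_b)
  list(genes_a = a$genes, genes_b = b$genes,
       proteins_a = a$proteins, proteins_b = b$proteins,
       wd40_ids = c("a_c01", "b_c01"),
       shared_cluster = sprintf("%s_c%02d", rep(c("a", "b"), each = n_shared),
                                seq_len(n_shared)))
}
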