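two_genes <- function(gap, strands = c("+", "+")) {
  gene_record(c("g1", "g2"), "c1", c(1L, 1000L + gap + 1L),
              c(1000L, 1500L + gap), strands, "x")
}

test_that("clustering respects the 300-bp boundary and strandedness", {
  g299 <- cluster_genes(two_genes(299))
  expect_equal(length(unique(g299$cluster_id)), 1)
  g300 <- cluster_genes(two_genes(300))
  expect_equal(length(unique(g300$cluster_id)), 2)
  opp <- cluster_genes(two_genes(10, c("+", "-")))
  expect_equal(length(unique(opp$cluster_id)), 2)
  # overlapping genes (negative gap) cluster
  ovl <- gene_record(c("g1", "g2"), "c1", c(1L, 900L), c(1000L, 1800L),
                     "+", "x")
  expect_equal(length(unique(cluster_genes(ovl)$cluster_id)), 1)
  # the start-to-end convention shifts the boundary by one base
  alt <- cluster_genes(two_genes(299), gap_convention = "start_to_end")
  expect_equal(length(unique(alt$cluster_id)), 2)
  alt2 <- cluster_genes(two_genes(298), gap_convention = "start_to_end")
  expect_equal(length(unique(alt2$cluster_id)), 1)
})

test_that("clustering partitions the gene set and matches the BFS oracle", {
  set.seed(77)
  for (rep_i in 1:10) {
    n <- sample(5:15, 1)
    pos <- 1L
    rows <- lapply(seq_len(n), function(i) {
      len <- sample(200:1200, 1)
      gap <- sample(c(0:50, 250:350, 500), 1)
      g <- gene_record(sprintf("g%02d", i), sample(c("c1", "c2"), 1),
                       pos, pos + len - 1L, sample(c("+", "-"), 1), "x")
      pos <<- pos + len + gap
      g
    })
    genes <- do.call(rbind, rows)
    cl <- cluster_genes(genes)
    expect_setequal(cl$gene_id, genes$gene_id)
    expect_equal(sort(as.integer(table(cl$cluster_id))),
                 oracle_cluster_sizes(genes))
  }
})

test_that("planted clusters are recovered exactly, decoys excluded", {
  sim <- simulate_gene_table(
    planted = data.frame(contig = "c1", size = 3L, gap = 50L, strand = "+"),
    n_decoys = 4L, seed = 8)
  cl <- cluster_genes(sim$genes)
  planted_ids <- sim$truth$gene_id[!is.na(sim$truth$planted_cluster)]
  got <- cl$cluster_id[match(planted_ids, cl$gene_id)]
  expect_equal(length(unique(got)), 1)
  # the planted cluster contains nothing else
  expect_setequal(cl$gene_id[cl$cluster_id == got[1]], planted_ids)
  # decoys are singletons
  decoys <- cl[cl$gene_id %in% sim$truth$gene_id[is.na(sim$truth$planted_cluster)], ]
  expect_equal(length(unique(decoys$cluster_id)), nrow(decoys))
})

test_that("BBH pairs are mutual best hits with deterministic ties", {
  pa <- c(a1 = "MKTAYIAKQR", a2 = "WWWWWHHHHH")
  pb <- c(b1 = "MKTAYIAKQR", b2 = "WWWWWHHHHH", b3 = "MKTAYIAKQR")
  pairs <- bbh_pairs(pa, pb)
  # duplicate identical partners: tie broken to lexicographically smaller id
  expect_equal(pairs$id_b[pairs$id_a == "a1"], "b1")
  expect_equal(pairs$id_b[pairs$id_a == "a2"], "b2")
  expect_equal(pairs$identity[pairs$id_a == "a1"], 1)

  # 1x1 proteomes are trivially mutual
  one <- bbh_pairs(c(x = "ACDEFGHIKL"), c(y = "ACDEFGHIKL"))
  expect_equal(nrow(one), 1)

  # symmetry: swapping proteomes swaps roles
  rev_pairs <- bbh_pairs(pb, pa)
  expect_setequal(paste(pairs$id_a, pairs$id_b),
                  paste(rev_pairs$id_b, rev_pairs$id_a))
  expect_error(bbh_pairs(pa, character(0)), "non-empty")
})

test_that("a best hit that is not mutual yields no pair", {
  # a1's best hit is b1, but b1 prefers a2 (constructed 2x2 score table)
  pa <- c(a1 = "MKTAYIAK", a2 = "MKTAYIAKQRLV")
  pb <- c(b1 = "MKTAYIAKQRLV", b2 = "GGGGGGGG")
  pairs <- bbh_pairs(pa, pb)
  expect_false("a1" %in% pairs$id_a)
  expect_true(all(pairs$id_a != "a1"))
})

test_that("conserved neighbourhoods match across genomes, disruption breaks them", {
  sim <- simulate_genome_pair(n_shared = 3, gap = 50, n_decoys = 3, seed = 21)
  cla <- cluster_genes(sim$genes_a)
  clb <- cluster_genes(sim$genes_b)
  pairs <- bbh_pairs(sim$proteins_a, sim$proteins_b)
  res <- match_conserved_clusters(cla, clb, pairs, sim$wd40_ids)
  expect_equal(nrow(res$matches), 1)
  expect_equal(res$matches$wd40_a, "a_c01")
  expect_length(res$specific_a, 0)

  bad <- simulate_genome_pair(n_shared = 3, gap = 50, n_decoys = 3,
                              seed = 21, disrupt_b = TRUE)
  res2 <- match_conserved_clusters(cluster_genes(bad$genes_a),
                                   cluster_genes(bad$genes_b),
                                   bbh_pairs(bad$proteins_a, bad$proteins_b),
                                   bad$wd40_ids)
  expect_equal(nrow(res2$matches), 0)
  expect_gt(length(res2$specific_a), 0)
})

test_that("a smaller cluster fully covered by a larger one still matches", {
  sim <- simulate_genome_pair(n_shared = 3, gap = 50, n_decoys = 2, seed = 33)
  # graft two extra genes onto genome A's cluster only
  extra <- gene_record(c("a_x1", "a_x2"), "a_chr",
                       c(2000L, 2500L) + 0L, c(2300L, 2900L), "+", "x")
  # place them adjacent to the cluster end
  last_end <- max(sim$genes_a$end[1:3])
  extra$start <- c(last_end + 51L, last_end + 500L)
  extra$end <- extra$start + 299L
  genes_a <- rbind(sim$genes_a, extra)
  prot_a <- c(sim$proteins_a, a_x1 = rand_prot(120), a_x2 = rand_prot(120))
  res <- match_conserved_clusters(
    cluster_genes(genes_a), cluster_genes(sim$genes_b),
    bbh_pairs(prot_a, sim$proteins_b), sim$wd40_ids)
  expect_equal(nrow(res$matches), 1)
})

test_that("term frequencies drop stoplist phrases and sort by count", {
  genes <- gene_record(sprintf("g%d", 1:5), "c1",
                       seq(1, by = 2000, length.out = 5),
                       seq(1000, by = 2000, length.out = 5), "+",
                       c("serine/threonine protein kinase",
                         "hypothetical protein",
                         "glycosyltransferase",
                         "glycosyltransferase",
                         "WD40 repeat"))
  tf <- term_frequencies(genes)
  expect_equal(tf$phrase, c("glycosyltransferase",
                            "serine/threonine protein kinase"))
  expect_equal(tf$count, c(2L, 1L))
  expect_equal(nrow(term_frequencies(genes[0, ])), 0)
})
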