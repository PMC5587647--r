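test_that("codon threading converts residue alignments to codon alignments", {
  aln <- nw_align("MKT", "MKT")
  ca <- thread_codon_alignment(aln, "ATGAAAACC", "ATGAAAACG")
  expect_length(ca$codons_a, 3)
  expect_equal(ca$codons_a, c("ATG", "AAA", "ACC"))

  # a protein gap becomes a whole-codon gap at the right columns
  galn <- nw_align("MKT", "MT")
  ca2 <- thread_codon_alignment(galn, "ATGAAAACC", "ATGACC")
  expect_equal(sum(ca2$codons_b == "---"), 1)
  expect_equal(ca2$codons_b[ca2$codons_a == "AAA"], "---")

  expect_error(thread_codon_alignment(aln, "ATGAAA", "ATGAAAACG"), "3x")
  expect_error(thread_codon_alignment(aln, "ATGAAAATT", "ATGAAAACG"),
               "translate")
})

test_that("NG86 reproduces the hand-enumerated glycine example", {
  ca <- codon_aln(c("GGT", "GGT"), c("GGC", "GGT"))
  e <- ng86(ca)
  expect_equal(e$S, 2)
  expect_equal(e$N, 4)
  expect_equal(e$Sd, 1)
  expect_equal(e$Nd, 0)
  expect_equal(e$pS, 0.5)
  expect_equal(e$dS, -0.75 * log(1 / 3))
  expect_equal(round(e$dS, 3), 0.824)
  expect_equal(e$dN, 0)
  expect_equal(e$omega, 0)
  expect_equal(e$status, "ok")
})

test_that("NG86 flags saturated pairs and identical pairs correctly", {
  sat <- ng86(codon_aln("GGT", "GGC"))   # pS = 1 -> log argument < 0
  expect_equal(sat$status, "saturated")
  expect_true(is.na(sat$dS))

  same <- ng86(codon_aln(c("ATG", "AAA"), c("ATG", "AAA")))
  expect_equal(same$Sd, 0)
  expect_equal(same$dS, 0)
  expect_true(is.na(same$omega))   # omega absent when dS = 0
  expect_equal(same$status, "ok")

  expect_error(ng86(codon_aln("---", "ATG")), "no ungapped")
})

test_that("NG86 matches the brute-force site/path oracle on a fixed battery", {
  battery <- list(
    list(a = c("GGT", "GGT"), b = c("GGC", "GGT"), code = "1"),
    list(a = c("ATG", "AAA"), b = c("ATG", "AAA"), code = "1"),
    list(a = "TTT", b = "GGG", code = "1"),            # 3 differences
    list(a = "TGT", b = "TGG", code = "1"),            # near the TGA stop
    list(a = c("CTT", "AGA"), b = c("CTC", "AGG"), code = "1"),
    list(a = c("ATA", "CGA"), b = c("ATG", "CGG"), code = "2"),
    list(a = c("TTA", "CCC", "GAT"), b = c("CTA", "CCG", "GCT"), code = "11"),
    list(a = c("AAA", "CCC", "GGG"), b = c("TTT", "GGG", "CCC"), code = "11"),
    list(a = "GGT", b = "GGC", code = "1")              # saturated path
  )
  for (case in battery) {
    mine <- ng86(codon_aln(case$a, case$b, case$code))
    ref <- oracle_ng86(case$a, case$b, case$code)
    expect_equal(mine$S, ref$S, tolerance = 1e-12)
    expect_equal(mine$N, ref$N, tolerance = 1e-12)
    expect_equal(mine$Sd, ref$Sd, tolerance = 1e-12)
    expect_equal(mine$Nd, ref$Nd, tolerance = 1e-12)
    expect_equal(mine$status, ref$status)
    if (ref$status == "ok") {
      expect_equal(mine$dS, ref$dS, tolerance = 1e-12)
      expect_equal(mine$dN, ref$dN, tolerance = 1e-12)
    }
  }
})

test_that("NG86 is symmetric and conserves sites (N + S = 3 codons)", {
  set.seed(55)
  tabs <- codon_tables("1")
  sense <- names(tabs$aa)[tabs$aa != "*"]
  for (rep_i in 1:20) {
    n <- sample(2:6, 1)
    a <- sample(sense, n, TRUE)
    b <- sample(sense, n, TRUE)
    ea <- ng86(codon_aln(a, b))
    eb <- ng86(codon_aln(b, a))
    expect_equal(ea$N + ea$S, 3 * n, tolerance = 1e-12)
    expect_equal(ea$Sd, eb$Sd, tolerance = 1e-12)
    expect_equal(ea$Nd, eb$Nd, tolerance = 1e-12)
    expect_equal(ea$S, eb$S, tolerance = 1e-12)
  }
})

test_that("genetic code choice changes degeneracy where the tables differ", {
  # vertebrate-mitochondrial AGA is a stop; codon sites differ from table 1
  t1 <- codon_tables("1")
  t2 <- codon_tables("2")
  expect_false(isTRUE(all.equal(t1$syn_sites[["CGA"]],
                                t2$syn_sites[["CGA"]])))
  # tables 1 and 11 share every amino-acid assignment, hence every site count
  t11 <- codon_tables("11")
  expect_equal(t1$syn_sites, t11$syn_sites)
})

test_that("median dS excludes saturated pairs; bounds select the omega subset", {
  est <- data.frame(dS = c(0, 0.824, 0.824), status = "ok")
  expect_equal(median_repeat_ds(est), 0.824)
  est2 <- data.frame(dS = c(0.1, NA, 0.3), status = c("ok", "saturated", "ok"))
  expect_equal(median_repeat_ds(est2), 0.2)
  allsat <- data.frame(dS = NA_real_, status = "saturated")
  v <- median_repeat_ds(allsat)
  expect_true(is.na(v))
  expect_match(attr(v, "reason"), "saturated")

  ds_tab <- data.frame(accession = c("p1", "p2", "p3"),
                       median_ds = c(0.5, 1.2, 2.5),
                       median_omega = c(0.1, 0.19, 0.4))
  ps <- purifying_subset(ds_tab)
  expect_equal(ps$subset$accession, "p2")
  expect_equal(ps$median_omega, 0.19)
  # boundaries: 1.0 in, 2.0 out
  edge <- data.frame(accession = c("lo", "hi"), median_ds = c(1.0, 2.0),
                     median_omega = c(0.2, 0.3))
  expect_equal(purifying_subset(edge)$subset$accession, "lo")
  expect_warning(purifying_subset(ds_tab[1, ]), "no protein")
})

test_that("repeat-pair estimates run off a simulated gene's CDS", {
  g <- simulate_wd40_gene(sim_config(n_repeats = 6, t = 0.15, seed = 12))
  est <- repeat_pair_estimates(g$protein, code = "11")
  expect_equal(nrow(est), choose(6, 2))
  expect_true(all(est$N + est$S == 3 * 48))
  expect_true(all(est$dS[est$status == "ok"] >= 0))
  # identical repeats at t = 0 give median dS exactly 0
  g0 <- simulate_wd40_gene(sim_config(n_repeats = 6, t = 0, seed = 12))
  est0 <- repeat_pair_estimates(g0$protein, code = "11")
  expect_equal(median_repeat_ds(est0), 0)
})
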