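test_that("candidate filter applies repeat-count and score thresholds", {
  mk <- function(n, score, acc) make_protein(rep("ACDEFGHIKL", n),
                                             scores = rep(score, n),
                                             accession = acc)
  ps <- list(mk(7, 65, "hi"),      # clean pass
             mk(5, 100, "few"),    # too few repeats
             mk(6, 47.9, "low"),   # below score threshold
             mk(6, 50, "band"))    # pass, inside review band
  out <- filter_wd40_candidates(ps)
  accs <- function(l) vapply(l, function(p) p$accession, "")
  expect_setequal(accs(out$retained), c("hi", "band"))
  expect_equal(accs(out$review_flagged), "band")
  expect_setequal(accs(out$rejected), c("few", "low"))
  # flagged set is a subset of retained; strict mode drops it
  strict <- filter_wd40_candidates(ps, strict = TRUE)
  expect_equal(accs(strict$retained), "hi")
  # empty input: three empty lists
  empty <- filter_wd40_candidates(list())
  expect_true(all(lengths(empty) == 0))
})

test_that("dedupe keeps the longest isoform per gene, ties to smallest accession", {
  iso1 <- make_protein(rep("ACDEF", 60), accession = "X1", gene_id = "g1")
  iso2 <- make_protein(rep("ACDEFGH", 50), accession = "X2", gene_id = "g1")
  other <- make_protein(rep("ACDEF", 10), accession = "X3", gene_id = "g2")
  out <- dedupe_longest_per_gene(list(iso1, iso2, other))
  expect_setequal(vapply(out, `[[`, "", "accession"), c("X2", "X3"))

  tie_a <- make_protein(rep("ACDEF", 10), accession = "B2", gene_id = "g1")
  tie_b <- make_protein(rep("FGHIK", 10), accession = "A1", gene_id = "g1")
  out <- dedupe_longest_per_gene(list(tie_a, tie_b))
  expect_equal(out[[1]]$accession, "A1")

  # same gene id in different organisms is not a duplicate
  o1 <- make_protein(rep("ACDEF", 10), accession = "Y1", gene_id = "g1",
                     organism_id = "orgA")
  o2 <- make_protein(rep("ACDEF", 10), accession = "Y2", gene_id = "g1",
                     organism_id = "orgB")
  expect_length(dedupe_longest_per_gene(list(o1, o2)), 2)
})

test_that("filter then dedupe is invariant to input order", {
  set.seed(11)
  ps <- lapply(1:12, function(i)
    make_protein(rep("ACDEFGHIKL", sample(5:8, 1)),
                 scores = rep(sample(c(40, 50, 70), 1), 1),
                 accession = sprintf("P%02d", i),
                 gene_id = sprintf("g%d", sample(1:6, 1))))
  run <- function(x) sort(vapply(
    dedupe_longest_per_gene(filter_wd40_candidates(x)$retained),
    `[[`, "", "accession"))
  expect_equal(run(ps), run(rev(ps)))
  expect_equal(run(ps), run(ps[sample(seq_along(ps))]))
})

test_that("abundance, category summaries and fold changes are exact", {
  expect_equal(proteome_abundance(data.frame(n_wd40 = 0, n_proteins = 500)), 0)
  expect_equal(proteome_abundance(data.frame(n_wd40 = 10, n_proteins = 1000)), 1)
  expect_equal(proteome_abundance(data.frame(n_wd40 = 13, n_proteins = 5000)),
               0.26)
  expect_error(proteome_abundance(data.frame(n_wd40 = 1, n_proteins = 0)),
               "positive")

  rec <- proteome_record(sprintf("o%d", 1:4), "Fungi",
                         c(1000, 1000, 2000, 500), c(10, 0, 10, 5))
  s <- summarize_category(rec, "Fungi")
  expect_equal(s$n_proteomes, 4)
  expect_equal(s$n_with_wd40, 3)
  expect_equal(s$pct_with_wd40, 75)
  expect_equal(s$mean_abundance_pct, mean(c(1, 0, 0.5, 1)))
  expect_error(summarize_category(rec, "Plantae"), "no proteome records")

  a <- data.frame(mean_abundance_pct = 1.21)
  b <- data.frame(mean_abundance_pct = 0.98)
  expect_equal(fold_change(a, b), 1.21 / 0.98)
  expect_equal(fold_change(a, a), 1)
  expect_error(fold_change(a, data.frame(mean_abundance_pct = 0)),
               "denominator")
})

test_that("rank-sum exact branch matches analytic small cases", {
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3), "greater"), 0.05)
  expect_equal(rank_sum_test(c(2, 4, 6), c(1, 3, 5), "greater"), 0.35)
  expect_equal(rank_sum_test(7, 5, "greater"), 0.5)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
  # large or tied samples take the corrected normal approximation
  p_tied <- rank_sum_test(c(1, 2, 2), c(2, 3, 4), "less")
  expect_true(p_tied > 0 && p_tied <= 1)
})

test_that("rank-sum exact branch equals full enumeration (n <= 10)", {
  for (n_tot in 4:10) {
    vals <- seq_len(n_tot) * 1.0
    for (n_a in 1:(n_tot - 1)) {
      for (s in utils::combn(n_tot, n_a, simplify = FALSE)) {
        a <- vals[s]; b <- vals[-s]
        expect_equal(rank_sum_test(a, b, "greater"),
                     oracle_rank_sum_greater(a, b),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("distribution_table tabulates counts and interval bins", {
  d <- distribution_table(c(7, 7, 7, 14))
  expect_equal(d$bin, c("7", "14"))
  expect_equal(d$fraction, c(0.75, 0.25))
  expect_warning(d0 <- distribution_table(numeric(0)), "no values")
  expect_equal(nrow(d0), 0)
  d10 <- distribution_table(runif(100), breaks = seq(0, 1, 0.1))
  expect_equal(nrow(d10), 10)
  expect_equal(sum(d10$fraction), 1, tolerance = 1e-12)
})

test_that("summaries of simulated proteomes recover configured abundance", {
  cfgp <- data.frame(category = "Fungi", n_proteomes = 200L,
                     n_proteins = 5000L, abundance_pct = 1)
  rec <- simulate_proteomes(cfgp, seed = 5)
  s <- summarize_category(rec, "Fungi")
  # binomial s.e. of the mean abundance: sqrt(p(1-p)/n)/sqrt(200) * 100
  se <- 100 * sqrt(0.01 * 0.99 / 5000 / 200)
  expect_lt(abs(s$mean_abundance_pct - 1), 3 * se)
  # exact mode is deterministic
  ex <- simulate_proteomes(cfgp, seed = 1, exact = TRUE)
  expect_true(all(ex$n_wd40 == 50L))
  zero <- simulate_proteomes(data.frame(category = "X", n_proteomes = 10L,
                                        n_proteins = 100L,
                                        abundance_pct = 0), seed = 1)
  expect_true(all(zero$n_wd40 == 0L))
})
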