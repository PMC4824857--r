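test_that("QconCAT stock quantification is a linear area-ratio scaling", {
  expect_equal(quantify_qconcat_stock(1e5, 1e5), 21.5)
  expect_equal(quantify_qconcat_stock(1e5, 2e5), 43.0)
  expect_error(quantify_qconcat_stock(0, 1e5), "light_area")
})

test_that("copies-per-cell conversion applies Avogadro over the cell load", {
  expect_equal(peptide_cpc(1, 1e-15, 2e5), 1e-15 * 6.02214e23 / 2e5)
  expect_equal(round(peptide_cpc(1, 1e-15, 2e5)), 3011)
  expect_equal(peptide_cpc(0, 1e-15, 2e5), 0)
  expect_equal(peptide_cpc(2, 1e-15, 2e5), 2 * peptide_cpc(1, 1e-15, 2e5))
  expect_error(peptide_cpc(1, 1e-15, 0), "cells")
})

test_that("robust CV matches the scaled-MAD formula and is scale invariant", {
  expect_equal(robust_cv(c(10, 10, 10)), 0)
  expect_equal(robust_cv(c(8, 10, 12)), 100 * 1.4826 * 2 / 10)
  set.seed(3)
  for (i in 1:20) {
    x <- rlnorm(sample(3:8, 1), 5, 0.4)
    k <- runif(1, 0.01, 100)
    expect_equal(robust_cv(k * x), robust_cv(x), tolerance = 1e-12)
  }
  expect_error(robust_cv(5), "fewer than 2")
})

test_that("spike-level choice constrains ratios to the 10:1 band", {
  mk <- function(labels, amounts, ratios) {
    tibble::tibble(spike_label = rep(labels, each = 2),
                   spike_amount_mol = rep(amounts, each = 2),
                   ratio = rep(ratios, each = 2))
  }
  rows <- mk(c("low", "medium", "high"), c(2e-16, 1.5e-15, 1.5e-14),
             c(15, 2, 0.3))
  ch <- choose_spike_level(rows)
  expect_equal(ch$spike_label, "medium")
  expect_true(ch$in_range)

  single <- mk("low", 2e-16, 0.5)
  expect_equal(choose_spike_level(single)$spike_label, "low")

  out <- mk(c("low", "medium"), c(2e-16, 1.5e-15), c(80, 30))
  cho <- choose_spike_level(out)
  expect_false(cho$in_range)
  expect_equal(cho$spike_label, "medium")  # 30 is nearest the band

  # ties on |log10 ratio| go to the higher spike amount
  tie <- mk(c("low", "high"), c(2e-16, 1.5e-14), c(2, 0.5))
  expect_equal(choose_spike_level(tie)$spike_label, "high")
  expect_error(choose_spike_level(tie[0, ]), "no replicate rows")
})

test_that("QC filter applies the joint 3-of-4 / FDR / S-N rule", {
  qc <- qc_filter(q = rep(0.005, 4), sn = rep(10, 4))
  expect_true(qc$pass)
  expect_equal(qc$n_pass, 4)

  expect_false(qc_filter(q = c(0.005, 0.005, 0.5, 0.5),
                         sn = rep(10, 4))$pass)

  # a replicate passing FDR but failing S/N counts against the rule
  joint <- qc_filter(q = c(0.005, 0.005, 0.005, 0.5),
                     sn = c(10, 10, 4, 10))
  expect_false(joint$pass)
  expect_equal(joint$n_pass, 2)

  # lenient reading: the S/N clause only audits FDR-passing replicates
  lenient <- qc_filter(q = c(0.005, 0.005, 0.005, 0.5),
                       sn = c(10, 10, 4, 10), sn_all_replicates = FALSE)
  expect_false(lenient$pass)
  ok_lenient <- qc_filter(q = c(0.005, 0.005, 0.005, 0.5),
                          sn = c(10, 10, 10, 4),
                          sn_all_replicates = FALSE)
  expect_true(ok_lenient$pass)

  # boundary: q exactly at threshold passes, S/N exactly at 5 fails
  expect_true(qc_filter(rep(0.01, 4), rep(6, 4))$pass)
  expect_false(qc_filter(rep(0.01, 4), rep(5, 4))$pass)
})

test_that("peptide outcomes classify into A, B and C", {
  expect_equal(classify_peptide(TRUE, TRUE), "A")
  expect_equal(classify_peptide(FALSE, TRUE), "B")
  expect_equal(classify_peptide(FALSE, FALSE), "C")
})

test_that("Type B upper limit scales with noise, spike and heavy signal", {
  b <- upper_limit_cpc(heavy_area = 1e5, noise = 100,
                       spike_amount_mol = 1e-15)
  expect_equal(b, (5 * 100 / 1e5) * peptide_cpc(1, 1e-15, 2e5))
  expect_equal(round(b, 1), 15.1)
  expect_equal(upper_limit_cpc(1e5, 200, 1e-15), 2 * b)
  expect_lt(upper_limit_cpc(2e5, 100, 1e-15), b)
  expect_error(upper_limit_cpc(0, 100, 1e-15), "heavy")
})

test_that("sibling reconciliation follows the discrepancy rule", {
  r1 <- reconcile_pair(1000, 800)   # log2 = 0.32: concordant
  expect_equal(r1$cpc, 900)
  expect_equal(r1$rule, "median_of_pair")

  r2 <- reconcile_pair(1000, 400)   # log2 = 1.32: discordant
  expect_equal(r2$cpc, 1000)
  expect_equal(r2$rule, "higher_peptide")

  r3 <- reconcile_pair(500, 500)    # both branches agree at equality
  expect_equal(r3$cpc, 500)
})

test_that("protein aggregation covers every class and conserves the tally", {
  peps <- tibble::tibble(
    protein_group = rep(c("AA1", "AA2", "AB", "AC", "BB", "BC", "CC",
                          "solo"), times = c(2, 2, 2, 2, 2, 2, 2, 1)),
    peptide_id = paste0("p", 1:15),
    type = c("A", "A",  "A", "A",  "A", "B",  "A", "C",  "B", "B",
             "B", "C",  "C", "C",  "A"),
    cpc = c(1000, 800,  1000, 400,  500, 2000,  300, NA,  60, 45,
            80, NA,  NA, NA,  700),
    rcv = c(10, 12,  9, 20,  8, NA,  11, NA,  NA, NA, NA, NA, NA, NA, 13),
    replicate_cpc = list(c(990, 1010, 1000), c(790, 810, 800),
                         NULL, NULL, NULL, NULL, NULL, NULL, NULL, NULL,
                         NULL, NULL, NULL, NULL, NULL)
  )
  prot <- reconcile_and_aggregate(peps)
  expect_equal(nrow(prot), length(unique(peps$protein_group)))

  g <- function(id) prot[prot$protein_group == id, ]
  expect_equal(g("AA1")$class, "AA")
  expect_equal(g("AA1")$cpc, 900)
  expect_equal(g("AA1")$rule, "median_of_pair")
  # pooled rCV recomputed over both peptides' replicate values
  expect_equal(g("AA1")$rcv,
               robust_cv(c(990, 1010, 1000, 790, 810, 800)))
  expect_equal(g("AA2")$cpc, 1000)
  expect_equal(g("AA2")$rule, "higher_peptide")
  expect_equal(g("AA2")$rcv, 9)
  expect_equal(g("AB")$cpc, 500)
  expect_equal(g("AB")$rule, "single_A")
  expect_equal(g("AC")$cpc, 300)
  expect_equal(g("BB")$cpc, 45)   # tighter bound wins
  expect_true(g("BB")$upper_limit)
  expect_equal(g("BC")$class, "BC")
  expect_equal(g("BC")$cpc, 80)
  expect_true(is.na(g("CC")$cpc))
  expect_equal(g("CC")$rule, "none")
  expect_equal(g("solo")$class, "AC")

  # tally conservation across all classes
  expect_equal(sum(table(prot$class)), nrow(prot))
})

test_that("the discrepancy threshold can be recomputed from the data", {
  peps <- tibble::tibble(
    protein_group = rep(c("g1", "g2", "g3"), each = 2),
    peptide_id = paste0("p", 1:6),
    type = "A",
    cpc = c(1000, 900, 500, 5000, 200, 230),
    rcv = 10
  )
  # dataset median |log2 X/Y| is driven by the g2 outlier pair
  prot <- reconcile_and_aggregate(peps, recompute_threshold = TRUE)
  rules <- setNames(prot$rule, prot$protein_group)
  # median |log2 X/Y| = the g3 pair; only g1 falls strictly below it
  expect_equal(rules[["g1"]], "median_of_pair")
  expect_equal(rules[["g2"]], "higher_peptide")
  expect_equal(rules[["g3"]], "higher_peptide")
})

test_that("outcome rates reproduce the assay success arithmetic", {
  pep <- outcome_rates(c(A = 1700, B = 1476, C = 659))
  expect_equal(pep$total, 3835)
  expect_equal(unname(pep$percent), round(100 * c(1700, 1476, 659) / 3835, 1))
  expect_equal(pep$informative_percent, 83)
  prot <- outcome_rates(c(quantified = 1167 + 668, C = 68),
                        informative = "quantified")
  expect_equal(prot$informative_percent, 96)
})
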