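test_that("configuration validates its invariants", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(replicate_cv = -0.1), "replicate_cv")
  bad_spikes <- tibble::tibble(label = "low", min_mol = -1, max_mol = 1)
  expect_error(sim_config(spike_levels = bad_spikes))
})

test_that("identical seeds give byte-identical synthetic data", {
  cfg <- sim_config(n_genes = 40, seed = 77)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_srm(t1, cfg)
  s2 <- simulate_srm(t2, cfg)
  expect_identical(s1$peak_table, s2$peak_table)
  expect_identical(s1$transitions, s2$transitions)
  x1 <- simulate_transcriptome(t1, cfg)
  x2 <- simulate_transcriptome(t2, cfg)
  expect_identical(x1, x2)
  # different seeds differ
  t3 <- simulate_truth(sim_config(n_genes = 40, seed = 78))
  expect_false(identical(t1$protein_cpc, t3$protein_cpc))
})

test_that("truth respects the zero-variance limit and TE identity", {
  cfg <- sim_config(n_genes = 30, te_log10_sd = 0, te_median = 1000,
                    seed = 5)
  tr <- simulate_truth(cfg)
  expect_equal(tr$te, rep(1000, 30), tolerance = 1e-12)
  # TE = protein / mRNA holds exactly in both generation modes
  expect_equal(tr$te, tr$protein_cpc / tr$mrna_cpc, tolerance = 1e-12)
  cfg2 <- sim_config(n_genes = 200, seed = 6,
                     feature_effects = list(main = c(f1 = 0.3),
                                            interaction = c(f2 = 0.3),
                                            r2 = 0.7))
  tr2 <- simulate_truth(cfg2)
  expect_equal(tr2$te, tr2$protein_cpc / tr2$mrna_cpc, tolerance = 1e-12)
  expect_equal(attr(tr2, "total_protein"), sum(tr2$protein_cpc))
})

test_that("empirical median TE converges on the configured median", {
  cfg <- sim_config(n_genes = 2000, seed = 101)
  tr <- simulate_truth(cfg)
  # median of a log-normal: SE of log10 median = 1.2533 * sd / sqrt(n)
  se3 <- 3 * 1.2533 * cfg$te_log10_sd / sqrt(2000)
  expect_lt(abs(log10(median(tr$te) / cfg$te_median)), se3)
})

test_that("the SRM layer emits the full design and forced Type B cases", {
  cfg <- sim_config(n_genes = 12, seed = 8)
  tr <- simulate_truth(cfg)
  sim <- simulate_srm(tr, cfg)
  pt <- sim$peak_table
  # 2 peptides x 3 transitions x (light + heavy + decoy) x reps x spikes
  expect_equal(nrow(pt), 12 * 2 * 3 * 3 * cfg$n_replicates * 3)
  expect_equal(nrow(sim$transitions), 12 * 2 * 3 * 2)
  # heavy/light transition pairs differ only by the label shift
  tl <- sim$transitions
  light <- tl[tl$label_type == "light", ]
  heavy <- tl[tl$label_type == "heavy", ]
  expect_equal(heavy$precursor_mz - light$precursor_mz,
               rep(6.02013 / 2, nrow(light)), tolerance = 1e-9)
  expect_equal(heavy$product_mz - light$product_mz,
               rep(6.02013, nrow(light)), tolerance = 1e-9)

  # a gene far below the LOD yields heavy-only (Type B) peptides
  tiny <- tr
  tiny$protein_cpc[1] <- 1e-3
  sim2 <- simulate_srm(tiny, cfg)
  g1 <- sim2$peak_table[sim2$peak_table$protein_group == tr$gene_id[1] &
                          !sim2$peak_table$is_decoy, ]
  expect_true(all(is.na(g1$area[g1$label == "light"])))
  expect_true(all(g1$area[g1$label == "heavy"] > 0))
})

test_that("spike amounts fall in the configured ranges", {
  cfg <- sim_config(n_genes = 5, seed = 12)
  sim <- simulate_srm(simulate_truth(cfg), cfg)
  amt <- sim$spike_amounts
  lv <- cfg$spike_levels
  for (i in seq_len(nrow(lv))) {
    expect_gte(amt[[lv$label[i]]], lv$min_mol[i])
    expect_lte(amt[[lv$label[i]]], lv$max_mol[i])
  }
})

test_that("noise-free transcriptome rescales back to true mRNA copies", {
  cfg <- sim_config(n_genes = 50, fpkm_noise_cv = 0, seed = 21)
  tr <- simulate_truth(cfg)
  tx <- simulate_transcriptome(tr, cfg)
  back <- fpkm_to_cpc(tx$fpkm, total_mrna = sum(tr$mrna_cpc))
  expect_equal(back$mrna_cpc, tr$mrna_cpc, tolerance = 1e-9)
})

test_that("feature-free generative model shows no spurious feature gain", {
  cfg <- sim_config(n_genes = 600, seed = 31,
                    feature_effects = list(main = c(f1 = 0), r2 = 0.6))
  tr <- simulate_truth(cfg)
  fit <- fit_translation_model(tr$protein_cpc, tr$mrna_cpc,
                               tr[, "f1", drop = FALSE])
  expect_length(fit$terms, 0)
  expect_equal(nrow(fit$trace), 1)
})

test_that("generative r2 is recovered by the fitted model", {
  cfg <- sim_config(n_genes = 1200, seed = 41,
                    feature_effects = list(main = c(f1 = 0.35),
                                           interaction = c(f2 = 0.35),
                                           r2 = 0.70))
  tr <- simulate_truth(cfg)
  fit <- fit_translation_model(tr$protein_cpc, tr$mrna_cpc,
                               tr[, c("f1", "f2")])
  expect_lt(abs(fit$r2 - 0.70), 0.05)
})

test_that("replicate CV calibration: simulated rCVs track the dial", {
  cfg <- sim_config(n_genes = 250, seed = 61)
  sim <- simulate_srm(simulate_truth(cfg), cfg)
  res <- srm_quantify(sim$peak_table, cells_on_column = cfg$cells_on_column)
  med <- median(res$peptides$rcv, na.rm = TRUE)
  expect_lt(abs(med - 100 * cfg$replicate_cv), 0.25 * 100 * cfg$replicate_cv)
})
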