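test_that("FPKM allocation conserves the mRNA budget exactly", {
  expect_equal(fpkm_to_cpc(c(100, 300)), c(15000, 45000))
  expect_equal(fpkm_to_cpc(42), 60000)
  expect_equal(fpkm_to_cpc(c(100, 300), total_mrna = 15000),
               fpkm_to_cpc(c(100, 300)) / 4)
  set.seed(3)
  f <- rlnorm(500, 2, 1.5)
  expect_equal(sum(fpkm_to_cpc(f)), 60000)
  expect_error(fpkm_to_cpc(c(0, 0)), "zero")

  tb <- tibble::tibble(gene_id = c("g1", "g2"), fpkm = c(100, 300))
  expect_equal(fpkm_to_cpc(tb)$mrna_cpc, c(15000, 45000))
})

test_that("translational efficiency ratios and exclusions", {
  prot <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         cpc = c(1000, 4000, 500))
  tx <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       mrna_cpc = c(1, 2, 0))
  te <- translational_efficiency(prot, tx)
  expect_equal(te$te$te, c(1000, 2000))
  expect_equal(te$median_te, 1500)
  expect_equal(te$n_excluded, 1)

  # median over Type A proteins only when types are given
  prot$type <- c("A", "B", "A")
  te2 <- translational_efficiency(prot, tx)
  expect_equal(te2$median_te, 1000)

  # quartering the assumed mRNA pool scales TE by exactly 4
  tx4 <- tx
  tx4$mrna_cpc <- tx$mrna_cpc / 4
  te4 <- translational_efficiency(prot[, 1:2], tx4)
  expect_equal(te4$te$te, 4 * te$te$te)

  expect_error(translational_efficiency(
    prot, tibble::tibble(gene_id = "zz", mrna_cpc = 1)), "shared")
})

test_that("total-proteome extrapolation adds the unmeasured remainder", {
  tot <- extrapolate_total_proteome(54e6, 1035, 44444)
  expect_equal(tot, 54e6 + 1035 * 44444)
  expect_equal(round(tot / 1e8, 2), 1.00)
  expect_equal(extrapolate_total_proteome(54e6, 1035, 0), 54e6)
  expect_gt(extrapolate_total_proteome(54e6, 1100, 44444), tot)
})

test_that("disattenuation matches the worked example and its identities", {
  expect_equal(round(disattenuate(0.72, 0.98, 0.96), 2), 0.74)
  expect_equal(disattenuate(0.5, 1, 1), 0.5)
  expect_warning(r <- disattenuate(0.6, 0.25, 1.0), "clipped")
  expect_equal(r, 1)
  # strictly increasing in r at fixed reliabilities
  expect_gt(disattenuate(0.6, 0.9, 0.9), disattenuate(0.5, 0.9, 0.9))
  expect_error(disattenuate(0.5, 0, 1), "reliabilities")
  expect_error(disattenuate(1.2, 1, 1), "r_observed")
})

test_that("log-log slopes: OLS attenuates, model-II methods do not", {
  # exact line: every method returns the generating slope
  x <- 10^seq(0, 3, length.out = 50)
  sl <- loglog_slopes(x^2, x)
  expect_equal(sl$ols_slope, 2, tolerance = 1e-9)
  expect_equal(sl$rma_slope, 2, tolerance = 1e-9)
  expect_equal(sl$ma_slope, 2, tolerance = 1e-9)

  # bivariate normal limit: OLS -> rho, major axis -> 1
  set.seed(53)
  lx <- rnorm(10000)
  ly <- 0.8 * lx + sqrt(1 - 0.64) * rnorm(10000)
  sl2 <- loglog_slopes(10^(ly + 3), 10^(lx + 1))
  expect_equal(sl2$ols_slope, 0.8, tolerance = 0.02)
  expect_equal(sl2$ma_slope, 1.0, tolerance = 0.02)
  # model-II slope exceeds the attenuated OLS slope
  expect_gt(sl2$rma_slope, sl2$ols_slope)

  # swapping axes inverts the RMA slope but not the OLS slope
  sl_xy <- loglog_slopes(10^(lx + 1), 10^(ly + 3))
  expect_equal(sl_xy$rma_slope, 1 / sl2$rma_slope, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sl_xy$ols_slope, 1 / sl2$ols_slope,
                                tolerance = 1e-3)))

  expect_error(loglog_slopes(c(1, 2), c(1, 2)), "at least 3")
  expect_error(loglog_slopes(c(5, 5, 5), c(1, 2, 3)), "degenerate")
})

test_that("forward selection rejects noise and keeps r2 monotone", {
  set.seed(59)
  n <- 400
  lm10 <- rnorm(n, 1, 0.6)
  y <- 3 + lm10 + rnorm(n, 0, 0.4)
  noise_feat <- data.frame(junk = rnorm(n))
  fit <- fit_translation_model(10^y, 10^lm10, noise_feat)
  expect_length(fit$terms, 0)
  expect_equal(nrow(fit$trace), 1)

  # nested-model monotonicity: the selected model never loses to mRNA-only
  cfg <- sim_config(n_genes = 500, seed = 61,
                    feature_effects = list(main = c(f1 = 0.4),
                                           interaction = c(f2 = 0.3),
                                           r2 = 0.7))
  tr <- simulate_truth(cfg)
  fit2 <- fit_translation_model(tr$protein_cpc, tr$mrna_cpc,
                                tr[, c("f1", "f2")])
  expect_gte(fit2$r2, fit2$trace$r2[1])
  expect_true(all(diff(fit2$trace$r2) >= -1e-12))
  expect_true(all(diff(fit2$trace$adj_r2) > 0))
  # interaction feature enters as an interaction term
  expect_true("f2_x_log10_mrna" %in% fit2$terms)
  expect_true("f1" %in% fit2$terms)

  # collinear candidates are skipped with a note
  feats <- data.frame(f1 = tr$f1, f1_copy = tr$f1 + 1e-9 * rnorm(500))
  fit3 <- fit_translation_model(tr$protein_cpc, tr$mrna_cpc, feats)
  expect_true(any(grepl("f1_copy", fit3$skipped)))
})
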