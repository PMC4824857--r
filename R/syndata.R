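#' Configuration for the synthetic SRM proteome simulator
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the study conditions of a chemostat-grown yeast census: protein
#' abundances log-normal over ~5 orders of magnitude, a median of ~1000
#' proteins per transcript, four biological replicates at ~12% CV, three
#' QconCAT spike levels (low 100-250 amol, medium 1-2 fmol, high 10-20
#' fmol) and the protein equivalent of 200,000 cells on column.
#'
#' @param n_genes Number of simulated genes (>= 1).
#' @param protein_log10_mean,protein_log10_sd Parameters of the log10
#'   protein copies-per-cell distribution.
#' @param te_median Median translational efficiency (proteins per
#'   transcript).
#' @param te_log10_sd SD of log10 translational efficiency.
#' @param n_replicates Biological replicates (>= 2, default 4).
#' @param replicate_cv Biological replicate CV of the light signal
#'   (fraction, default 0.12).
#' @param spike_levels Tibble with columns `label`, `min_mol`, `max_mol`
#'   (spike amount ranges in mol).
#' @param cells_on_column Cell equivalents loaded (default 2e5).
#' @param lod_area Hard limit of detection on light transition areas
#'   (arbitrary intensity units); censored areas produce Type B/C
#'   outcomes.
#' @param noise_area Noise floor used for signal-to-noise (area units).
#' @param dropout_prob Probability that an entire light peak group drops
#'   out (per peptide x replicate x spike).
#' @param response_log10_sd SD of the log10 peptide response factor
#'   (affects light and heavy equally; cancels in the ratio).
#' @param peptide_bias_log2_sd SD of the log2 peptide-specific light/heavy
#'   recovery bias (drives sibling-peptide discrepancies; the default
#'   0.566 makes the median AA sibling |log2 X/Y| approximately 0.54).
#' @param transition_cv Technical CV applied per transition measurement.
#' @param fpkm_noise_cv Multiplicative noise CV on simulated FPKM values.
#' @param feature_te_cors Named vector of target correlations between
#'   numeric gene features and log10 translational efficiency (default
#'   generation mode).
#' @param feature_effects Optional generative translation model: a list
#'   with elements `main` (named coefficients on standard-normal
#'   features), `interaction` (named coefficients on feature x centred
#'   log10 mRNA products), `r2` (target proportion of log10-protein
#'   variance explained by the full predictor set), and optionally
#'   `b_mrna`, `mrna_log10_sd`. When supplied, log10 protein is built
#'   from log10 mRNA and the features and translational efficiency is
#'   derived as protein/mRNA.
#' @param turnover_labels Labels for the half-life bins 0-20, 20-40 and
#'   >40 min (default fast/medium/slow as in turnover-class figures).
#' @param seed Integer seed; identical configs give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       protein_log10_mean = 3.5,
                       protein_log10_sd = 0.8,
                       te_median = 1035,
                       te_log10_sd = 0.5,
                       n_replicates = 4L,
                       replicate_cv = 0.12,
                       spike_levels = default_spike_levels(),
                       cells_on_column = 2e5,
                       lod_area = 250,
                       noise_area = 50,
                       dropout_prob = 0.02,
                       response_log10_sd = 0.3,
                       peptide_bias_log2_sd = 0.566,
                       transition_cv = 0.05,
                       fpkm_noise_cv = 0.1,
                       feature_te_cors = c(tai = 0.6, caf20_rip = -0.5,
                                           pars = 0.45, polya_len = -0.3),
                       feature_effects = NULL,
                       turnover_labels = c("fast", "medium", "slow"),
                       seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) {
    stop("`n_genes` must be >= 1", call. = FALSE)
  }
  if (n_replicates < 2) stop("`n_replicates` must be >= 2", call. = FALSE)
  if (replicate_cv < 0) stop("`replicate_cv` must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(spike_levels),
            all(c("label", "min_mol", "max_mol") %in% names(spike_levels)),
            all(spike_levels$min_mol > 0),
            all(spike_levels$max_mol >= spike_levels$min_mol))
  if (te_median <= 0 || cells_on_column <= 0) {
    stop("`te_median` and `cells_on_column` must be > 0", call. = FALSE)
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      protein_log10_mean = protein_log10_mean,
      protein_log10_sd = protein_log10_sd,
      te_median = te_median,
      te_log10_sd = te_log10_sd,
      n_replicates = as.integer(n_replicates),
      replicate_cv = replicate_cv,
      spike_levels = spike_levels,
      cells_on_column = cells_on_column,
      lod_area = lod_area,
      noise_area = noise_area,
      dropout_prob = dropout_prob,
      response_log10_sd = response_log10_sd,
      peptide_bias_log2_sd = peptide_bias_log2_sd,
      transition_cv = transition_cv,
      fpkm_noise_cv = fpkm_noise_cv,
      feature_te_cors = feature_te_cors,
      feature_effects = feature_effects,
      turnover_labels = turnover_labels,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default QconCAT spike levels
#'
#' Low 100-250 amol, medium 1-2 fmol, high 10-20 fmol on column.
#'
#' @return Tibble with columns `label`, `min_mol`, `max_mol`.
#' @export
default_spike_levels <- function() {
  tibble::tibble(
    label = c("low", "medium", "high"),
    min_mol = c(100e-18, 1e-15, 10e-15),
    max_mol = c(250e-18, 2e-15, 20e-15)
  )
}

# lognormal multiplier with unit mean and the requested CV
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate ground-truth abundances
#'
#' Draws true protein copies per cell, per-gene translational efficiency
#' and the implied mRNA copies per cell, together with gene features used
#' by the translation model. In the default mode log10 protein cpc is
#' normal, log10 TE is normal around the configured median, mRNA is
#' protein/TE, and numeric features are generated with the configured
#' correlations to log10 TE. When `feature_effects` is set, log10 protein
#' is generated from log10 mRNA plus feature main effects and feature x
#' log-mRNA interactions with noise scaled to the target generative r2;
#' TE is then derived, so TE = protein/mRNA holds exactly in both modes.
#'
#' @param config A [sim_config()].
#' @return A tibble (the truth table) with columns `gene_id`,
#'   `protein_cpc`, `mrna_cpc`, `te`, feature columns (`tai`,
#'   `caf20_rip`, `pars`, `polya_len`, `pest`, `turnover_class`, plus any
#'   `feature_effects` features), and attributes `coefficients` (the
#'   generative model, when used) and `total_protein`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("G%05d", seq_len(n))
    fe <- config$feature_effects
    coefs <- NULL

    if (is.null(fe)) {
      log10p <- stats::rnorm(n, config$protein_log10_mean,
                             config$protein_log10_sd)
      log10te <- stats::rnorm(n, log10(config$te_median), config$te_log10_sd)
      log10m <- log10p - log10te
      extra <- NULL
    } else {
      b1 <- if (is.null(fe$b_mrna)) 1 else fe$b_mrna
      m_sd <- if (is.null(fe$mrna_log10_sd)) 0.6 else fe$mrna_log10_sd
      m_mean <- config$protein_log10_mean - log10(config$te_median)
      log10m <- stats::rnorm(n, m_mean, m_sd)
      lm_c <- log10m - mean(log10m)
      feat_names <- union(names(fe$main), names(fe$interaction))
      extra <- stats::setNames(
        lapply(feat_names, function(f) stats::rnorm(n)), feat_names)
      signal <- (config$protein_log10_mean - b1 * m_mean) + b1 * log10m
      for (f in names(fe$main)) signal <- signal + fe$main[[f]] * extra[[f]]
      for (f in names(fe$interaction)) {
        signal <- signal + fe$interaction[[f]] * extra[[f]] * lm_c
      }
      r2 <- if (is.null(fe$r2)) 0.7 else fe$r2
      eps_sd <- sqrt(stats::var(signal) * (1 - r2) / r2)
      log10p <- signal + stats::rnorm(n, 0, eps_sd)
      log10te <- log10p - log10m
      coefs <- list(intercept = config$protein_log10_mean - b1 * m_mean,
                    b_mrna = b1, main = fe$main,
                    interaction = fe$interaction, r2 = r2, noise_sd = eps_sd)
    }

    z_te <- if (stats::sd(log10te) > 0) {
      as.numeric(scale(log10te))
    } else {
      rep(0, n)
    }
    corr_feat <- function(rho) {
      rho * z_te + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    }
    fc <- config$feature_te_cors
    truth <- tibble::tibble(
      gene_id = gene_id,
      protein_cpc = 10^log10p,
      mrna_cpc = 10^log10m,
      te = 10^(log10p - log10m),
      tai = 0.35 + 0.08 * corr_feat(fc[["tai"]]),
      caf20_rip = corr_feat(fc[["caf20_rip"]]),
      pars = corr_feat(fc[["pars"]]),
      polya_len = pmax(10, 30 + 8 * corr_feat(fc[["polya_len"]])),
      pest = stats::rbinom(n, 1, stats::plogis(0.8 * z_te)) == 1L,
      half_life_min = pmin(90, pmax(2, 30 + 12 * z_te + stats::rnorm(n, 0, 8)))
    )
    truth$turnover_class <- cut(truth$half_life_min, c(0, 20, 40, Inf),
                                labels = config$turnover_labels)
    if (!is.null(extra)) {
      for (f in names(extra)) truth[[f]] <- extra[[f]]
    }
    attr(truth, "coefficients") <- coefs
    attr(truth, "total_protein") <- sum(truth$protein_cpc)
    truth
  })
}

# random tryptic-looking peptide sequences (no M/C/K/R/P in the body,
# C-terminal K or R), unique within the call
.random_peptides <- function(n, len_min = 7L, len_max = 14L) {
  body <- strsplit("ADEFGHILNQSTVWY", "")[[1]]
  make <- function(k) {
    len <- sample(len_min:len_max, k, replace = TRUE)
    vapply(len, function(l) {
      paste0(paste(sample(body, l - 1L, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, character(1))
  }
  out <- make(n)
  while (anyDuplicated(out) > 0L) {
    dup <- which(duplicated(out))
    out[dup] <- make(length(dup))
  }
  out
}

#' Simulate an SRM peak-area experiment from ground truth
#'
#' Emits, for every gene, two surrogate peptides x three transitions x
#' light/heavy labels x replicates x spike levels. Light transition areas
#' are proportional to true copies-per-cell times cells on column (in
#' mol), with a per-peptide response factor (shared by both labels), a
#' per-peptide light/heavy recovery bias (driving sibling discrepancies),
#' multiplicative log-normal biological noise per replicate at
#' `replicate_cv`, and per-transition technical noise. Heavy areas are
#' proportional to the spike amount. Light areas below `lod_area` are
#' censored and whole light groups drop out with `dropout_prob`,
#' producing Type B/C outcomes. One noise-only decoy peak group is
#' emitted per target light group.
#'
#' @param truth Truth table from [simulate_truth()].
#' @param config The same [sim_config()].
#' @return List with elements `peak_table` (transition-level tibble ready
#'   for [score_peak_table()]), `transitions` (Skyline-style transition
#'   list with computed m/z), and `peptides` (per-peptide simulation
#'   metadata including the true response factor and bias).
#' @export
simulate_srm <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  req <- c("gene_id", "protein_cpc")
  miss <- setdiff(req, names(truth))
  if (length(miss) > 0L) {
    stop("truth table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(config$seed + 1L, {
    n <- nrow(truth)
    n_pep <- 2L
    n_tr <- 3L
    n_rep <- config$n_replicates
    levels_tbl <- config$spike_levels
    n_spk <- nrow(levels_tbl)
    area_per_fmol <- 1e4

    spike_mol <- stats::runif(n_spk, levels_tbl$min_mol, levels_tbl$max_mol)

    peptides <- tibble::tibble(
      protein_group = rep(truth$gene_id, each = n_pep),
      peptide_id = paste0(rep(truth$gene_id, each = n_pep), "_p",
                          rep(seq_len(n_pep), n)),
      sequence = .random_peptides(n * n_pep),
      response_factor = 10^stats::rnorm(n * n_pep, 0,
                                        config$response_log10_sd),
      bias = 2^stats::rnorm(n * n_pep, 0, config$peptide_bias_log2_sd),
      rt = stats::runif(n * n_pep, 10, 70)
    )
    # per-peptide relative transition intensity pattern
    w <- matrix(stats::rexp(n * n_pep * n_tr), ncol = n_tr)
    w <- w / rowSums(w)

    light_fmol <- truth$protein_cpc * config$cells_on_column /
      .AVOGADRO * 1e15
    bio <- matrix(.ln_noise(n * n_rep, config$replicate_cv), n, n_rep)

    grid <- tidyr::expand_grid(
      pep_idx = seq_len(n * n_pep),
      spike_idx = seq_len(n_spk),
      replicate = seq_len(n_rep),
      transition = seq_len(n_tr)
    )
    gene_idx <- (grid$pep_idx - 1L) %/% n_pep + 1L
    rf <- peptides$response_factor[grid$pep_idx]
    bias <- peptides$bias[grid$pep_idx]
    wt <- w[cbind(grid$pep_idx, grid$transition)]
    bio_f <- bio[cbind(gene_idx, grid$replicate)]
    m <- nrow(grid)

    light_area <- area_per_fmol * rf * bias * light_fmol[gene_idx] *
      bio_f * wt * .ln_noise(m, config$transition_cv)
    heavy_area <- area_per_fmol * rf * spike_mol[grid$spike_idx] * 1e15 *
      wt * .ln_noise(m, config$transition_cv)

    # censoring: hard LOD plus whole-group dropout on the light channel
    light_area[light_area < config$lod_area] <- NA_real_
    grp_key <- (grid$pep_idx - 1L) * n_spk * n_rep +
      (grid$spike_idx - 1L) * n_rep + grid$replicate
    n_grp <- n * n_pep * n_spk * n_rep
    drop_grp <- stats::runif(n_grp) < config$dropout_prob
    light_area[drop_grp[grp_key]] <- NA_real_

    base <- tibble::tibble(
      protein_group = peptides$protein_group[grid$pep_idx],
      peptide_id = peptides$peptide_id[grid$pep_idx],
      replicate = grid$replicate,
      spike_label = levels_tbl$label[grid$spike_idx],
      spike_amount_mol = spike_mol[grid$spike_idx],
      transition = grid$transition,
      noise = config$noise_area
    )
    light_tbl <- dplyr::mutate(base, label = "light", area = light_area,
                               is_decoy = FALSE)
    heavy_tbl <- dplyr::mutate(base, label = "heavy", area = heavy_area,
                               is_decoy = FALSE)
    decoy_tbl <- dplyr::mutate(
      base, label = "light",
      area = exp(stats::rnorm(m, log(config$noise_area), 0.5)),
      is_decoy = TRUE
    )
    peak_table <- dplyr::bind_rows(light_tbl, heavy_tbl, decoy_tbl)

    transitions <- .transition_list(peptides, n_tr)

    list(peak_table = peak_table, transitions = transitions,
         peptides = peptides,
         spike_amounts = stats::setNames(spike_mol, levels_tbl$label))
  })
}

# Skyline-style transition list (y3..y(2+n_tr) at 1+, precursor 2+) for
# light and heavy labels
.transition_list <- function(peptides, n_tr = 3L) {
  combos <- tidyr::expand_grid(
    i = seq_len(nrow(peptides)),
    frag = seq_len(n_tr) + 2L,
    label = c("light", "heavy")
  )
  seqs <- peptides$sequence[combos$i]
  tibble::tibble(
    protein = peptides$protein_group[combos$i],
    peptide_sequence = seqs,
    precursor_mz = mapply(compute_mz, seqs, MoreArgs = list(charge = 2L),
                          label = combos$label, USE.NAMES = FALSE),
    precursor_charge = 2L,
    product_mz = mapply(function(s, k, lab) compute_mz(s, 1L,
                                                       paste0("y", k), lab),
                        seqs, combos$frag, combos$label,
                        USE.NAMES = FALSE),
    fragment_ion = paste0("y", combos$frag),
    fragment_charge = 1L,
    label_type = combos$label,
    expected_rt = peptides$rt[combos$i]
  )
}

#' Simulate a matched transcriptome and gene-feature table
#'
#' FPKM values are proportional to true mRNA copies per cell with
#' multiplicative log-normal noise at `fpkm_noise_cv` and are scaled so
#' the column sums to 1e6 before noise; rescaling them to the true total
#' mRNA therefore reproduces the true copies when the noise is zero. The
#' feature table re-emits the truth table's gene features.
#'
#' @param truth Truth table from [simulate_truth()].
#' @param config The same [sim_config()].
#' @return List with `fpkm` (tibble `gene_id`, `fpkm`) and `features`
#'   (tibble of gene features).
#' @export
simulate_transcriptome <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("gene_id", "mrna_cpc") %in% names(truth))) {
    stop("truth table lacks gene_id/mrna_cpc", call. = FALSE)
  }
  withr::with_seed(config$seed + 2L, {
    n <- nrow(truth)
    fpkm <- truth$mrna_cpc / sum(truth$mrna_cpc) * 1e6 *
      .ln_noise(n, config$fpkm_noise_cv)
    feat_cols <- setdiff(names(truth),
                         c("protein_cpc", "mrna_cpc", "te"))
    list(
      fpkm = tibble::tibble(gene_id = truth$gene_id, fpkm = fpkm),
      features = truth[, feat_cols, drop = FALSE]
    )
  })
}
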