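#' Generate decoy transitions
#'
#' For each target transition a decoy is created that shares the precursor
#' m/z and retention-time window but has its product m/z shifted by a
#' fixed offset. If the shifted product falls within `min_sep` Th of any
#' real product m/z in the assay, the offset is incremented in 1 Th steps
#' until clear, so decoy signals can never be confused with genuine
#' fragment signals.
#'
#' @param transitions Tibble with at least a `product_mz` column; other
#'   columns (precursor m/z, RT, peptide id) are carried through.
#' @param offset Initial product m/z shift (Th, default +11).
#' @param min_sep Minimum separation from any real product (Th).
#' @return The input tibble with shifted `product_mz` and `is_decoy =
#'   TRUE`.
#' @export
generate_decoys <- function(transitions, offset = 11.0, min_sep = 0.5) {
  stopifnot(is.data.frame(transitions), "product_mz" %in% names(transitions))
  if (nrow(transitions) == 0L) stop("at least one target transition needed",
                                    call. = FALSE)
  real <- sort(transitions$product_mz)
  shift_one <- function(mz) {
    off <- offset
    while (min(abs(real - (mz + off))) < min_sep) off <- off + 1.0
    mz + off
  }
  out <- transitions
  out$product_mz <- vapply(transitions$product_mz, shift_one, numeric(1))
  out$is_decoy <- TRUE
  out
}

#' Score a light peak group against its heavy reference
#'
#' Composite evidence score for a candidate light (analyte) peak group
#' given the co-eluting heavy (internal standard) peak group on the same
#' transitions. Sub-scores: Pearson correlation of the per-transition
#' intensity patterns (co-elution/shape agreement, in [-1, 1]); the
#' normalised dot product of the two non-negative intensity patterns
#' (relative-intensity agreement, in [0, 1]); and log10 of the mean light
#' signal-to-noise. The composite is their weighted sum. All three
#' sub-scores are invariant to a uniform positive rescaling of the areas,
#' so so is the score ordering.
#'
#' @param light_areas,heavy_areas Per-transition integrated areas (equal
#'   length, >= 2 transitions for a defined correlation).
#' @param light_sn Per-transition light signal-to-noise.
#' @param weights Numeric length-3 weights for (correlation, dot product,
#'   log S/N).
#' @param sn_floor Floor applied to the mean S/N before the log.
#' @return List: `coelution`, `dotp`, `log_sn`, `score`.
#' @export
score_peak_group <- function(light_areas, heavy_areas, light_sn,
                             weights = c(1, 1, 1), sn_floor = 0.01) {
  if (length(light_areas) != length(heavy_areas)) {
    stop("light and heavy groups must have matching transition counts",
         call. = FALSE)
  }
  l <- ifelse(is.na(light_areas), 0, light_areas)
  h <- ifelse(is.na(heavy_areas), 0, heavy_areas)
  if (stats::sd(l) > 0 && stats::sd(h) > 0) {
    coel <- stats::cor(l, h)
  } else {
    coel <- 0
  }
  denom <- sqrt(sum(l^2) * sum(h^2))
  dotp <- if (denom > 0) sum(l * h) / denom else 0
  msn <- mean(light_sn, na.rm = TRUE)
  if (!is.finite(msn)) msn <- 0
  log_sn <- log10(max(msn, sn_floor))
  score <- weights[1] * coel + weights[2] * dotp + weights[3] * log_sn
  list(coelution = coel, dotp = dotp, log_sn = log_sn, score = score)
}

#' Target-decoy q-values
#'
#' At a score threshold s the false-discovery rate is estimated as the
#' number of decoys scoring at or above s divided by the number of targets
#' scoring at or above s (floored at 1). The q-value of a target is the
#' minimum estimated FDR over all thresholds at or below its score
#' (monotonised), so q-values are non-increasing in score and independent
#' of input order.
#'
#' @param target_scores,decoy_scores Numeric score vectors.
#' @param conservative Add a +1 pseudo-count to the decoy tally (imposes a
#'   1/#targets floor); default off.
#' @return Numeric q-values aligned with `target_scores`.
#' @export
estimate_fdr <- function(target_scores, decoy_scores, conservative = FALSE) {
  if (length(decoy_scores) == 0L) {
    stop("no decoy scores supplied; generate decoy transitions first",
         call. = FALSE)
  }
  stopifnot(length(target_scores) > 0L, !anyNA(target_scores),
            !anyNA(decoy_scores))
  ord <- order(target_scores)            # ascending
  s <- target_scores[ord]
  n_t <- length(s)
  d <- sort(decoy_scores)
  # counts of scores >= each threshold s[i]: total minus strictly-below
  t_ge <- n_t - findInterval(s, s, left.open = TRUE)
  d_ge <- length(d) - findInterval(s, d, left.open = TRUE)
  if (conservative) d_ge <- d_ge + 1
  fdr <- pmin(d_ge / pmax(t_ge, 1), 1)
  q <- cummin(fdr)                       # min over thresholds <= score
  out <- numeric(n_t)
  out[ord] <- q
  out
}

#' Score all peak groups in a simulated or imported peak table
#'
#' Aggregates a transition-level peak table into one peak group per
#' peptide x replicate x spike level, scores every light group (target and
#' decoy) against the corresponding heavy reference with
#' [score_peak_group()] (vectorised), estimates target-decoy q-values with
#' [estimate_fdr()], and returns replicate-level quantification rows.
#'
#' @param peak_table Transition-level tibble with columns
#'   `protein_group`, `peptide_id`, `replicate`, `spike_label`,
#'   `spike_amount_mol`, `transition`, `label` ("light"/"heavy"), `area`,
#'   `noise`, `is_decoy`.
#' @param weights Sub-score weights passed to the composite.
#' @param conservative Passed to [estimate_fdr()].
#' @return Tibble with one row per target peptide x replicate x spike:
#'   `protein_group`, `peptide_id`, `replicate`, `spike_label`,
#'   `spike_amount_mol`, `light_area`, `heavy_area`, `ratio`, `sn`,
#'   `heavy_sn`, `score`, `q`.
#' @export
score_peak_table <- function(peak_table, weights = c(1, 1, 1),
                             conservative = FALSE) {
  req <- c("protein_group", "peptide_id", "replicate", "spike_label",
           "spike_amount_mol", "transition", "label", "area", "noise",
           "is_decoy")
  miss <- setdiff(req, names(peak_table))
  if (length(miss) > 0L) {
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  heavy <- dplyr::filter(peak_table, .data$label == "heavy", !.data$is_decoy)
  light <- dplyr::filter(peak_table, .data$label == "light")
  heavy <- dplyr::select(heavy, "peptide_id", "replicate", "spike_label",
                         "transition", heavy_area_t = "area")
  grp <- dplyr::left_join(
    light, heavy,
    by = c("peptide_id", "replicate", "spike_label", "transition")
  )
  grp <- dplyr::mutate(
    grp,
    l = dplyr::coalesce(.data$area, 0),
    h = dplyr::coalesce(.data$heavy_area_t, 0)
  )

  scored <- dplyr::summarise(
    dplyr::group_by(grp, .data$protein_group, .data$peptide_id,
                    .data$replicate, .data$spike_label,
                    .data$spike_amount_mol, .data$is_decoy),
    n_tr = dplyr::n(),
    light_area = sum(.data$l),
    heavy_area = sum(.data$h),
    sxy = sum(.data$l * .data$h),
    sx = sum(.data$l), sy = sum(.data$h),
    sxx = sum(.data$l^2), syy = sum(.data$h^2),
    sn = mean(.data$l / .data$noise),
    heavy_sn = mean(.data$h / .data$noise),
    noise = mean(.data$noise),
    .groups = "drop"
  )
  n <- scored$n_tr
  vx <- n * scored$sxx - scored$sx^2
  vy <- n * scored$syy - scored$sy^2
  coel <- ifelse(vx > 0 & vy > 0,
                 (n * scored$sxy - scored$sx * scored$sy) / sqrt(vx * vy), 0)
  denom <- sqrt(scored$sxx * scored$syy)
  dotp <- ifelse(denom > 0, scored$sxy / denom, 0)
  log_sn <- log10(pmax(scored$sn, 0.01))
  scored$score <- weights[1] * coel + weights[2] * dotp + weights[3] * log_sn

  q_all <- rep(NA_real_, nrow(scored))
  q_all[!scored$is_decoy] <- estimate_fdr(
    scored$score[!scored$is_decoy], scored$score[scored$is_decoy],
    conservative = conservative
  )
  scored$q <- q_all

  out <- dplyr::filter(scored, !.data$is_decoy)
  out <- dplyr::mutate(
    out,
    ratio = ifelse(.data$light_area > 0 & .data$heavy_area > 0,
                   .data$light_area / .data$heavy_area, NA_real_)
  )
  dplyr::select(out, "protein_group", "peptide_id", "replicate",
                "spike_label", "spike_amount_mol", "light_area",
                "heavy_area", "ratio", "sn", "heavy_sn", "noise",
                "score", "q")
}
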