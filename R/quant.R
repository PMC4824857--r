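#' @keywords internal
.AVOGADRO <- 6.02214e23

#' Quantify a QconCAT stock against a glu-fibrinopeptide standard
#'
#' The stable-isotope-labelled QconCAT stock is quantified by spiking a
#' known amount of light glu-fibrinopeptide B into a digest and comparing
#' the extracted-ion-chromatogram peak areas of the light standard against
#' the heavy glu-fibrinopeptide released from the QconCAT.
#'
#' @param light_area Integrated XIC area of the light standard peptide.
#' @param heavy_area Integrated XIC area of the heavy (QconCAT-derived)
#'   peptide.
#' @param light_spike_pmol Amount of light standard spiked (pmol); default
#'   21.5 pmol (10 ul of a 2.15 pmol/ul solution).
#' @return QconCAT amount in pmol.
#' @examples
#' quantify_qconcat_stock(1e5, 1e5)  # 21.5
#' @export
quantify_qconcat_stock <- function(light_area, heavy_area,
                                   light_spike_pmol = 21.5) {
  if (!is.numeric(light_area) || any(light_area <= 0)) {
    stop("`light_area` must be > 0", call. = FALSE)
  }
  if (any(heavy_area < 0) || any(light_spike_pmol <= 0)) {
    stop("`heavy_area` must be >= 0 and `light_spike_pmol` > 0",
         call. = FALSE)
  }
  (heavy_area / light_area) * light_spike_pmol
}

#' Isotope-dilution copies per cell
#'
#' Converts a light:heavy peak-area ratio into absolute protein copies per
#' cell: the ratio times the spiked amount of heavy standard (mol) gives
#' the moles of analyte on column; multiplying by Avogadro's number and
#' dividing by the number of cell equivalents loaded gives copies per cell.
#'
#' @param ratio Light/heavy area ratio (>= 0).
#' @param spike_amount_mol Heavy standard on column (mol).
#' @param cells_on_column Cell equivalents loaded (default 2e5).
#' @return Copies per cell.
#' @examples
#' peptide_cpc(1, 1e-15, 2e5)  # ~3011 cpc for a 1 fmol spike
#' @export
peptide_cpc <- function(ratio, spike_amount_mol, cells_on_column = 2e5) {
  if (any(cells_on_column <= 0)) stop("`cells_on_column` must be > 0",
                                      call. = FALSE)
  if (any(spike_amount_mol <= 0)) stop("`spike_amount_mol` must be > 0",
                                       call. = FALSE)
  if (any(ratio < 0, na.rm = TRUE)) stop("`ratio` must be >= 0",
                                         call. = FALSE)
  ratio * spike_amount_mol * .AVOGADRO / cells_on_column
}

#' Robust coefficient of variation
#'
#' rCV = 100 x 1.4826 x MAD / median, with
#' MAD = median(|x_i - median(x)|). The 1.4826 factor makes the MAD a
#' consistent estimator of the standard deviation under normality.
#'
#' @param values Numeric vector (>= 2 values, positive median).
#' @return rCV in percent.
#' @examples
#' robust_cv(c(8, 10, 12))  # 29.652
#' @export
robust_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("robust CV is undefined for fewer than 2 values", call. = FALSE)
  }
  med <- stats::median(values)
  if (med <= 0) stop("robust CV requires a positive median", call. = FALSE)
  100 * 1.4826 * stats::median(abs(values - med)) / med
}

#' Choose the spike level best matched to the analyte
#'
#' The assay aims to keep analyte/standard ratios between 10:1 and 1:10.
#' Among spike levels whose median light/heavy ratio falls inside
#' [0.1, 10], the level with median ratio closest to 1 on the log scale is
#' chosen (ties go to the higher spike amount). If no level qualifies, the
#' level whose median ratio is closest to the interval is returned and
#' flagged out-of-range.
#'
#' @param rows Tibble of replicate rows for one peptide with columns
#'   `spike_label`, `spike_amount_mol`, `ratio` (NA allowed).
#' @param lo,hi Acceptable ratio interval.
#' @return List: `spike_label`, `spike_amount_mol`, `median_ratio`,
#'   `in_range`.
#' @export
choose_spike_level <- function(rows, lo = 0.1, hi = 10) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("no replicate rows supplied", call. = FALSE)
  }
  med <- dplyr::summarise(
    dplyr::group_by(rows, .data$spike_label),
    spike_amount_mol = .data$spike_amount_mol[1],
    median_ratio = stats::median(.data$ratio, na.rm = TRUE),
    .groups = "drop"
  )
  med <- med[is.finite(med$median_ratio), , drop = FALSE]
  if (nrow(med) == 0L) {
    stop("no spike level has any finite light/heavy ratio", call. = FALSE)
  }
  ok <- med$median_ratio >= lo & med$median_ratio <= hi
  if (any(ok)) {
    cand <- med[ok, , drop = FALSE]
    ord <- order(abs(log10(cand$median_ratio)), -cand$spike_amount_mol)
    hit <- cand[ord[1L], ]
    in_range <- TRUE
  } else {
    dist <- pmax(lo - med$median_ratio, med$median_ratio - hi, 0)
    ord <- order(dist, -med$spike_amount_mol)
    hit <- med[ord[1L], ]
    in_range <- FALSE
  }
  list(spike_label = hit$spike_label,
       spike_amount_mol = hit$spike_amount_mol,
       median_ratio = hit$median_ratio,
       in_range = in_range)
}

#' Replicate-level quality-control filter
#'
#' A replicate passes when its q-value is at or below `fdr_threshold` and
#' its signal-to-noise exceeds `sn_min`; the peptide passes when at least
#' `min_pass` of `n_reps` replicates pass. Under the default, conservative
#' reading every replicate must satisfy both clauses jointly and a
#' replicate failing S/N counts against the 3-of-4 rule; setting
#' `sn_all_replicates = FALSE` applies the S/N clause only to the
#' replicates that already pass the FDR threshold.
#'
#' @param q,sn Numeric vectors of per-replicate q-values and
#'   signal-to-noise (NA = no measurement).
#' @param fdr_threshold,sn_min QC thresholds (defaults 0.01 and 5).
#' @param min_pass,n_reps Acceptance rule (default 3 of 4).
#' @param sn_all_replicates Interpretation switch, see Details.
#' @return List: `pass` (logical), `passing` (logical per replicate),
#'   `n_pass`.
#' @export
qc_filter <- function(q, sn, fdr_threshold = 0.01, sn_min = 5,
                      min_pass = 3L, n_reps = 4L,
                      sn_all_replicates = TRUE) {
  stopifnot(length(q) == length(sn))
  q_ok <- !is.na(q) & q <= fdr_threshold
  sn_ok <- !is.na(sn) & sn > sn_min
  passing <- if (sn_all_replicates) q_ok & sn_ok else q_ok & sn_ok
  # the two readings differ in whether an S/N failure among otherwise
  # FDR-passing replicates invalidates the peptide outright
  if (sn_all_replicates) {
    pass <- sum(passing) >= min_pass
  } else {
    pass <- sum(q_ok) >= min_pass && all(sn_ok[q_ok])
    passing <- q_ok & sn_ok
  }
  list(pass = pass, passing = passing, n_pass = sum(passing))
}

#' Classify a peptide quantification outcome
#'
#' Type A: both the light analyte and the heavy standard yield acceptable
#' data. Type B: only the heavy standard does, so the peptide defines a
#' conservative upper limit on the analyte. Type C: neither channel gives
#' usable signal.
#'
#' @param light_pass Did the light channel pass QC (the replicate-level
#'   3-of-4 / FDR / S-N rule)?
#' @param heavy_pass Did the heavy standard yield acceptable signal?
#' @return `"A"`, `"B"` or `"C"`.
#' @export
classify_peptide <- function(light_pass, heavy_pass) {
  dplyr::case_when(
    light_pass & heavy_pass ~ "A",
    heavy_pass ~ "B",
    .default = "C"
  )
}

#' Upper-limit copies per cell for a Type B peptide
#'
#' When the analyte is undetected, the largest light signal consistent
#' with non-detection is `sn_min` times the local noise level; the bound is
#' the copies-per-cell value that hypothetical light area would imply
#' given the observed heavy area and spike amount.
#'
#' @param heavy_area Observed heavy-standard area (> 0).
#' @param noise Local noise estimate in area units (> 0).
#' @param spike_amount_mol Heavy spike on column (mol).
#' @param cells_on_column Cell equivalents loaded.
#' @param sn_min Detection S/N threshold (default 5).
#' @return Upper bound in copies per cell (value to report as "< bound").
#' @export
upper_limit_cpc <- function(heavy_area, noise, spike_amount_mol,
                            cells_on_column = 2e5, sn_min = 5) {
  if (any(heavy_area <= 0)) stop("upper limit needs heavy signal",
                                 call. = FALSE)
  if (any(noise <= 0)) stop("`noise` must be > 0", call. = FALSE)
  peptide_cpc((sn_min * noise) / heavy_area, spike_amount_mol,
              cells_on_column)
}

#' Reconcile a sibling-peptide pair (internal rule kernel)
#'
#' For two Type A sibling peptides quantifying the same protein: when the
#' absolute log2 ratio of the two copies-per-cell values is below the
#' discrepancy threshold the protein value is the median (= mean) of the
#' two; otherwise the higher value is used, reasoning that signal loss
#' from the endogenous peptide is the more likely fault.
#'
#' @param x,y Sibling peptide cpc values (> 0).
#' @param threshold_log2 Discrepancy threshold on |log2(x/y)|
#'   (default 0.54).
#' @return List: `cpc`, `rule` ("median_of_pair" or "higher_peptide"),
#'   `log2_ratio`.
#' @export
reconcile_pair <- function(x, y, threshold_log2 = 0.54) {
  stopifnot(is.finite(x), is.finite(y), x > 0, y > 0)
  d <- abs(log2(x / y))
  if (d < threshold_log2) {
    list(cpc = (x + y) / 2, rule = "median_of_pair", log2_ratio = d)
  } else {
    list(cpc = max(x, y), rule = "higher_peptide", log2_ratio = d)
  }
}

#' Aggregate typed peptide quantifications to the protein level
#'
#' Applies the sibling-reconciliation protocol to each protein group:
#' \itemize{
#'   \item AA, concordant (|log2 X/Y| < threshold): cpc = median of the
#'     pair; rCV recomputed over the pooled per-replicate cpc values of
#'     both peptides when available.
#'   \item AA, discordant: cpc and rCV from the higher peptide.
#'   \item AB / AC: cpc and rCV from the single A peptide.
#'   \item BB / BC: upper bound = the smaller (tighter) of the peptide
#'     upper bounds.
#'   \item CC: no value.
#' }
#' A protein with a single measured peptide is classed as if its missing
#' sibling were Type C.
#'
#' @param peptides Tibble with one row per peptide: `protein_group`,
#'   `peptide_id`, `type` ("A"/"B"/"C"), `cpc` (summary value or upper
#'   bound; NA for C), `rcv` (percent, NA allowed), and optionally
#'   `replicate_cpc` (list column of per-replicate cpc values used to
#'   recompute pooled rCVs).
#' @param threshold_log2 AA discrepancy threshold (default 0.54, the
#'   study's median sibling log2 ratio; pass
#'   `recompute_threshold = TRUE` to use the dataset's own median).
#' @param recompute_threshold Recompute the threshold as the median
#'   |log2 X/Y| over this dataset's AA pairs.
#' @return Tibble with one row per protein group: `protein_group`,
#'   `class`, `cpc`, `upper_limit` (logical), `rcv`, `rule`,
#'   `n_peptides`, `log2_ratio` (AA pairs, else NA).
#' @export
reconcile_and_aggregate <- function(peptides, threshold_log2 = 0.54,
                                    recompute_threshold = FALSE) {
  stopifnot(is.data.frame(peptides), nrow(peptides) > 0L,
            all(c("protein_group", "peptide_id", "type", "cpc") %in%
                  names(peptides)))
  if (!"rcv" %in% names(peptides)) peptides$rcv <- NA_real_
  has_reps <- "replicate_cpc" %in% names(peptides)

  if (recompute_threshold) {
    aa <- peptides[peptides$type == "A", , drop = FALSE]
    pairs <- split(aa$cpc, aa$protein_group)
    pairs <- Filter(function(v) length(v) == 2L && all(v > 0), pairs)
    if (length(pairs) > 0L) {
      threshold_log2 <- stats::median(
        vapply(pairs, function(v) abs(log2(v[1] / v[2])), numeric(1))
      )
    }
  }

  one <- function(df) {
    types <- sort(df$type)  # "A" < "B" < "C"
    cls <- paste(c(types, rep("C", max(0L, 2L - length(types))))[1:2],
                 collapse = "")
    a <- df[df$type == "A", , drop = FALSE]
    b <- df[df$type == "B", , drop = FALSE]
    out <- tibble::tibble(class = cls, cpc = NA_real_, upper_limit = FALSE,
                          rcv = NA_real_, rule = "none",
                          n_peptides = nrow(df), log2_ratio = NA_real_)
    if (cls == "AA") {
      rec <- reconcile_pair(a$cpc[1], a$cpc[2], threshold_log2)
      out$cpc <- rec$cpc
      out$rule <- rec$rule
      out$log2_ratio <- rec$log2_ratio
      if (rec$rule == "median_of_pair") {
        pooled <- if (has_reps) unlist(a$replicate_cpc) else a$cpc
        out$rcv <- if (length(pooled) >= 2L) robust_cv(pooled) else NA_real_
      } else {
        out$rcv <- a$rcv[which.max(a$cpc)]
      }
    } else if (nrow(a) == 1L) {           # AB, AC or single-A
      out$cpc <- a$cpc[1]
      out$rcv <- a$rcv[1]
      out$rule <- "single_A"
    } else if (nrow(b) >= 1L) {           # BB, BC or single-B
      out$cpc <- min(b$cpc, na.rm = TRUE)
      out$upper_limit <- TRUE
      out$rule <- "upper_limit"
    }
    out
  }
  res <- dplyr::group_modify(
    dplyr::group_by(peptides, .data$protein_group),
    function(df, key) one(df)
  )
  dplyr::ungroup(res)
}

#' Percentage breakdown of quantification outcomes
#'
#' Turns outcome counts into the percentages used to summarise assay
#' performance: the share of each class and the combined success rate of
#' the informative classes.
#'
#' @param counts Named integer vector of outcome counts (e.g.
#'   `c(A = 1700, B = 1476, C = 659)`).
#' @param informative Names of the classes that yield quantitative
#'   information (default all but `"C"` / classes containing only C).
#' @param digits Rounding for the percentages (default 1).
#' @return List: `percent` (named, same names as `counts`), `total`,
#'   `informative_percent` (rounded to the nearest integer).
#' @export
outcome_rates <- function(counts, informative = setdiff(names(counts), "C"),
                          digits = 1) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  total <- sum(counts)
  pct <- round(100 * counts / total, digits)
  list(percent = pct, total = total,
       informative_percent = round(100 * sum(counts[informative]) / total))
}
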