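#' Convert FPKM to transcript copies per cell
#'
#' Allocates a fixed cellular mRNA budget proportionally to FPKM:
#' cpc_i = fpkm_i / sum(fpkm) x total_mrna. Values are kept fractional;
#' the allocated copies sum to `total_mrna` exactly.
#'
#' @param fpkm Either a numeric vector or a data frame with columns
#'   `gene_id` and `fpkm`.
#' @param total_mrna Total mRNA copies per cell assumed for the whole
#'   table (default 60,000; 15,000 is the older literature figure and
#'   scales every value by 1/4).
#' @return Same shape as the input: a numeric vector of cpc, or the
#'   tibble with an `mrna_cpc` column added.
#' @examples
#' fpkm_to_cpc(c(100, 300))  # 15000 45000
#' @export
fpkm_to_cpc <- function(fpkm, total_mrna = 60000) {
  if (total_mrna <= 0) stop("`total_mrna` must be > 0", call. = FALSE)
  if (is.data.frame(fpkm)) {
    stopifnot(all(c("gene_id", "fpkm") %in% names(fpkm)))
    out <- tibble::as_tibble(fpkm)
    out$mrna_cpc <- fpkm_to_cpc(out$fpkm, total_mrna)
    return(out)
  }
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM must be >= 0", call. = FALSE)
  tot <- sum(fpkm, na.rm = TRUE)
  if (tot <= 0) stop("all FPKM values are zero", call. = FALSE)
  fpkm / tot * total_mrna
}

#' Per-gene translational efficiency
#'
#' TE = protein copies per cell / mRNA copies per cell, the number of
#' protein molecules maintained per transcript at steady state. The
#' summary median is computed over Type A proteins when a `type` column
#' is present (upper limits are not averaged in), otherwise over all
#' matched genes. Genes with zero or missing mRNA are excluded and
#' counted.
#'
#' @param proteins Data frame with `gene_id` and `cpc` (optionally
#'   `type`).
#' @param transcripts Data frame with `gene_id` and `mrna_cpc`.
#' @return List: `te` (tibble `gene_id`, `protein_cpc`, `mrna_cpc`,
#'   `te`), `median_te`, `n_excluded`.
#' @export
translational_efficiency <- function(proteins, transcripts) {
  stopifnot(all(c("gene_id", "cpc") %in% names(proteins)),
            all(c("gene_id", "mrna_cpc") %in% names(transcripts)))
  m <- dplyr::inner_join(
    dplyr::select(proteins, "gene_id", protein_cpc = "cpc",
                  dplyr::any_of("type")),
    dplyr::select(transcripts, "gene_id", "mrna_cpc"),
    by = "gene_id"
  )
  if (nrow(m) == 0L) stop("no genes shared between the two tables",
                          call. = FALSE)
  ok <- is.finite(m$mrna_cpc) & m$mrna_cpc > 0 & is.finite(m$protein_cpc)
  n_excluded <- sum(!ok)
  m <- m[ok, , drop = FALSE]
  m$te <- m$protein_cpc / m$mrna_cpc
  med_src <- if ("type" %in% names(m)) m$te[m$type == "A"] else m$te
  if (length(med_src) == 0L) med_src <- m$te
  list(te = tibble::as_tibble(m), median_te = stats::median(med_src),
       n_excluded = n_excluded)
}

#' Extrapolate the total proteome size
#'
#' Adds, to the summed copies per cell of the measured proteins, an
#' estimate for the unmeasured remainder: the median proteins-per-
#' transcript times the summed mRNA copies of the unmeasured genes.
#'
#' @param measured_cpc_sum Sum of measured protein cpc.
#' @param median_te Median translational efficiency of the measured set.
#' @param unmeasured_mrna_cpc_sum Summed mRNA cpc of unmeasured genes.
#' @return Estimated total protein molecules per cell.
#' @export
extrapolate_total_proteome <- function(measured_cpc_sum, median_te,
                                       unmeasured_mrna_cpc_sum) {
  stopifnot(measured_cpc_sum >= 0, median_te >= 0,
            unmeasured_mrna_cpc_sum >= 0)
  measured_cpc_sum + median_te * unmeasured_mrna_cpc_sum
}

#' Correct a correlation for attenuation by measurement error
#'
#' Spearman's classical disattenuation: the observed correlation is
#' divided by the geometric mean of the two measurement reliabilities
#' (e.g. between-replicate repeatability). Corrected values beyond 1 in
#' magnitude are clipped with a warning.
#'
#' @param r_observed Observed correlation in [-1, 1].
#' @param reliability_x,reliability_y Reliabilities in (0, 1].
#' @return Corrected correlation.
#' @examples
#' disattenuate(0.72, 0.98, 0.96)  # 0.742...
#' @export
disattenuate <- function(r_observed, reliability_x, reliability_y) {
  if (any(reliability_x <= 0) || any(reliability_y <= 0) ||
      any(reliability_x > 1) || any(reliability_y > 1)) {
    stop("reliabilities must lie in (0, 1]", call. = FALSE)
  }
  if (any(abs(r_observed) > 1)) {
    stop("`r_observed` must lie in [-1, 1]", call. = FALSE)
  }
  r <- r_observed / sqrt(reliability_x * reliability_y)
  if (any(abs(r) > 1)) {
    warning("corrected correlation exceeds 1 in magnitude; clipped")
    r <- pmin(pmax(r, -1), 1)
  }
  r
}

#' Log-log slopes between proteome and transcriptome
#'
#' Fits log10 protein on log10 mRNA by ordinary least squares and by two
#' symmetric model-II methods: the major axis (first principal axis of
#' the covariance) and the Ranged Major Axis, in which both variables
#' are first ranged to [0, 1] by (v - min) / (max - min), the major-axis
#' slope is computed on the ranged values, and the slope is
#' back-transformed by the ratio of the ranges. Model-II slopes are
#' appropriate when both axes carry measurement error; for imperfectly
#' correlated data they exceed the attenuated OLS slope in magnitude.
#'
#' @param protein_cpc,mrna_cpc Paired positive abundances (>= 3 pairs
#'   after removing non-positive values).
#' @return List: `n`, `ols_slope`, `ols_intercept`, `ma_slope`,
#'   `ma_intercept`, `rma_slope`, `rma_intercept` (all on the log10
#'   scale).
#' @export
loglog_slopes <- function(protein_cpc, mrna_cpc) {
  stopifnot(length(protein_cpc) == length(mrna_cpc))
  ok <- is.finite(protein_cpc) & is.finite(mrna_cpc) &
    protein_cpc > 0 & mrna_cpc > 0
  y <- log10(protein_cpc[ok])
  x <- log10(mrna_cpc[ok])
  if (length(x) < 3L) stop("need at least 3 positive pairs", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("degenerate range: one variable is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ols <- unname(stats::coef(fit))

  ma_slope_of <- function(u, v) {
    suu <- stats::var(u); svv <- stats::var(v); suv <- stats::cov(u, v)
    if (suv == 0) {
      stop("zero covariance: major-axis slope undefined", call. = FALSE)
    }
    (svv - suu + sqrt((svv - suu)^2 + 4 * suv^2)) / (2 * suv)
  }
  b_ma <- ma_slope_of(x, y)

  rx <- diff(range(x)); ry <- diff(range(y))
  u <- (x - min(x)) / rx
  v <- (y - min(y)) / ry
  b_rma <- ma_slope_of(u, v) * ry / rx

  list(
    n = length(x),
    ols_slope = ols[2], ols_intercept = ols[1],
    ma_slope = b_ma, ma_intercept = mean(y) - b_ma * mean(x),
    rma_slope = b_rma, rma_intercept = mean(y) - b_rma * mean(x)
  )
}

#' Forward-selected multivariate translation model
#'
#' Models log10 protein copies per cell as a function of log10 mRNA
#' copies per cell (always included) plus gene features. Each candidate
#' feature is tried both as a main effect and as an interaction with
#' centred log10 mRNA (both variables centred before multiplication). At
#' every step the candidate term giving the largest adjusted r2 is
#' accepted if its partial F-test p-value is below `p_enter`; selection
#' stops when no candidate qualifies or `max_terms` terms have been
#' added. Ties and ordering are deterministic (alphabetical by term
#' name). Candidates nearly collinear (|r| > `collinear_r`) with an
#' already-included column are skipped with a note. Genes with a missing
#' value in any column are dropped listwise.
#'
#' @param protein_cpc,mrna_cpc Positive abundance vectors (same genes,
#'   same order).
#' @param features Data frame of numeric/logical candidate features
#'   (same rows).
#' @param max_terms Maximum number of feature terms added (default 7).
#' @param p_enter Partial F-test entry threshold (default 0.01).
#' @param collinear_r Collinearity guard on candidate columns.
#' @return Object of class `translation_fit`: `terms` (selected term
#'   labels), `coefficients` (tibble with estimates and standard
#'   errors), `r2`, `adj_r2`, `spearman` (predicted vs observed),
#'   `trace` (tibble: step, term, r2, adj_r2, p), `n`, `skipped`
#'   (collinear candidates), and `model` (the final `lm`).
#' @export
fit_translation_model <- function(protein_cpc, mrna_cpc, features,
                                  max_terms = 7L, p_enter = 0.01,
                                  collinear_r = 0.99) {
  stopifnot(length(protein_cpc) == length(mrna_cpc),
            is.data.frame(features),
            nrow(features) == length(protein_cpc))
  ok <- is.finite(protein_cpc) & is.finite(mrna_cpc) &
    protein_cpc > 0 & mrna_cpc > 0 &
    stats::complete.cases(features)
  y <- log10(protein_cpc[ok])
  lm10 <- log10(mrna_cpc[ok])
  fx <- features[ok, , drop = FALSE]
  n <- length(y)
  numcols <- vapply(fx, function(col) is.numeric(col) || is.logical(col),
                    logical(1))
  fx <- fx[, numcols, drop = FALSE]
  fx[] <- lapply(fx, as.numeric)
  if (n < 10L * ncol(fx)) {
    warning("fewer than 10 observations per candidate feature")
  }

  lm_c <- lm10 - mean(lm10)
  cand <- list(log10_mrna = lm10)
  for (f in names(fx)) {
    fc <- fx[[f]] - mean(fx[[f]])
    cand[[f]] <- fx[[f]]
    cand[[paste0(f, "_x_log10_mrna")]] <- fc * lm_c
  }
  cand <- cand[order(names(cand))]

  included <- "log10_mrna"
  dat <- data.frame(y = y, check.names = FALSE)
  dat[["log10_mrna"]] <- lm10
  fit <- stats::lm(y ~ ., data = dat)
  base_sum <- summary(fit)
  trace <- tibble::tibble(step = 0L, term = "log10_mrna",
                          r2 = base_sum$r.squared,
                          adj_r2 = base_sum$adj.r.squared,
                          p = NA_real_)
  skipped <- character(0)
  step <- 0L

  repeat {
    if (step >= max_terms) break
    pool <- setdiff(names(cand), included)
    if (length(pool) == 0L) break
    best <- NULL
    for (term in pool) {
      col <- cand[[term]]
      if (stats::sd(col) == 0) next
      cmax <- max(abs(stats::cor(col, as.data.frame(dat[included]))))
      if (cmax > collinear_r) {
        skipped <- union(skipped, term)
        next
      }
      dat2 <- dat
      dat2[[term]] <- col
      fit2 <- stats::lm(y ~ ., data = dat2)
      adj <- summary(fit2)$adj.r.squared
      if (is.null(best) || adj > best$adj) {
        best <- list(term = term, fit = fit2, dat = dat2, adj = adj)
      }
    }
    if (is.null(best)) break
    pcmp <- stats::anova(fit, best$fit)
    pval <- pcmp[["Pr(>F)"]][2]
    if (!is.finite(pval) || pval >= p_enter) break
    step <- step + 1L
    fit <- best$fit
    dat <- best$dat
    included <- c(included, best$term)
    s <- summary(fit)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, term = best$term, r2 = s$r.squared,
      adj_r2 = s$adj.r.squared, p = pval
    ))
  }

  s <- summary(fit)
  coefs <- tibble::tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "Estimate"],
    std_error = s$coefficients[, "Std. Error"],
    p_value = s$coefficients[, "Pr(>|t|)"]
  )
  structure(
    list(
      terms = setdiff(included, "log10_mrna"),
      coefficients = coefs,
      r2 = s$r.squared,
      adj_r2 = s$adj.r.squared,
      spearman = stats::cor(stats::fitted(fit), y, method = "spearman"),
      trace = trace,
      n = n,
      skipped = skipped,
      model = fit
    ),
    class = "translation_fit"
  )
}

#' @export
print.translation_fit <- function(x, ...) {
  cat("Translation model:", x$n, "genes; log10_mrna +",
      length(x$terms), "selected term(s)\n")
  if (length(x$terms) > 0L) cat("  terms:", paste(x$terms, collapse = ", "),
                                "\n")
  cat(sprintf("  r2 = %.3f (adjusted %.3f), Spearman %.3f\n",
              x$r2, x$adj_r2, x$spearman))
  invisible(x)
}
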