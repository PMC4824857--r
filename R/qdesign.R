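#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) for the 20 standard amino-acid
#' residues (i.e. the mass each residue contributes inside a peptide chain;
#' add one water for the intact peptide).
#'
#' @return Named numeric vector of length 20.
#' @export
residue_masses <- function() {
  c(
    A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
    C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
    H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
    M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
    T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
  )
}

.MASS_PROTON <- 1.007276
.MASS_WATER <- 18.010565
# mass shift of a [13C6] label on a C-terminal K or R
.SHIFT_13C6 <- 6.02013

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(residue_masses()))
  if (length(bad) > 0L) {
    stop("illegal residue character(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  sequence
}

#' Monoisotopic m/z of a peptide precursor or fragment ion
#'
#' Computes the monoisotopic m/z of a protonated peptide ion. Precursor m/z
#' is (sum of residue masses + water + z protons) / z. A y\eqn{_k} fragment
#' retains the C-terminal water; a b\eqn{_k} fragment does not. A heavy
#' stable-isotope label is modelled as a fixed mass shift added to the
#' neutral mass (default +6.02013 Da, a [13C6] label on the C-terminal K/R).
#'
#' @param sequence Peptide sequence (one-letter amino-acid codes).
#' @param charge Positive integer charge state.
#' @param ion `"precursor"` (default), or a fragment spec such as `"y7"` or
#'   `"b2"`.
#' @param label `"light"` or `"heavy"`.
#' @param label_shift Mass added to the neutral ion when `label = "heavy"`
#'   (Da). For fragment ions the shift is applied only to ions containing
#'   the labelled C-terminal residue (y ions); b ions are unshifted.
#' @return m/z in Thomson.
#' @examples
#' compute_mz("EGVNDNEEGFFSAR", 2)            # glu-fibrinopeptide B, [M+2H]2+
#' compute_mz("EGVNDNEEGFFSAR", 2, label = "heavy")
#' @export
compute_mz <- function(sequence, charge, ion = "precursor",
                       label = c("light", "heavy"),
                       label_shift = .SHIFT_13C6) {
  sequence <- .check_sequence(sequence)
  label <- match.arg(label)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    stop("`charge` must be a positive integer", call. = FALSE)
  }
  masses <- residue_masses()
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  shift <- if (label == "heavy") label_shift else 0

  if (identical(ion, "precursor")) {
    neutral <- sum(masses[aa]) + .MASS_WATER + shift
  } else {
    m <- regmatches(ion, regexec("^([yb])([0-9]+)$", ion))[[1]]
    if (length(m) != 3L) {
      stop("`ion` must be \"precursor\" or like \"y7\"/\"b2\"", call. = FALSE)
    }
    type <- m[2]
    k <- as.integer(m[3])
    if (k < 1L || k >= n) {
      stop("fragment index ", k, " out of range for a ", n, "-residue peptide",
           call. = FALSE)
    }
    if (type == "y") {
      neutral <- sum(masses[aa[(n - k + 1L):n]]) + .MASS_WATER + shift
    } else {
      # b ions exclude the labelled C-terminal residue
      neutral <- sum(masses[aa[1:k]])
    }
  }
  (neutral + charge * .MASS_PROTON) / charge
}

#' Monoisotopic mass of a peptide or protein
#'
#' @param sequence Amino-acid sequence.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence) {
  sequence <- .check_sequence(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(residue_masses()[aa]) + .MASS_WATER
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein after K or R except when the next residue is P,
#' producing fully tryptic peptides that tile the protein exactly. Flanking
#' residues are recorded (`"-"` at protein termini).
#'
#' @param sequence Protein sequence.
#' @param protein_id Identifier copied into the result.
#' @return A tibble with columns `protein_id`, `sequence`, `start`, `end`
#'   (1-based inclusive), `n_flank`, `c_flank`, `length`.
#' @examples
#' digest_tryptic("MKRAPK")$sequence  # "MK" "R" "APK"
#' @export
digest_tryptic <- function(sequence, protein_id = NA_character_) {
  sequence <- .check_sequence(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  # cleavage after position i when aa[i] is K/R and aa[i+1] is not P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  ends <- sort(unique(c(cut_after, n)))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  tibble::tibble(
    protein_id = protein_id,
    sequence = vapply(seq_along(starts), function(i) {
      paste(aa[starts[i]:ends[i]], collapse = "")
    }, character(1)),
    start = starts,
    end = ends,
    n_flank = ifelse(starts == 1L, "-", aa[pmax(starts - 1L, 1L)]),
    c_flank = ifelse(ends == n, "-", aa[pmin(ends + 1L, n)]),
    length = ends - starts + 1L
  )
}

#' Rule table for missed-cleavage risk
#'
#' Versioned, explicit penalty rules for the heuristic cleavage-risk score.
#' Penalties are additive per cleavage site and the total is clamped to
#' [0, 1]; a proline immediately after a required K/R site makes the site
#' uncleavable (penalty 1).
#'
#' @return A tibble with columns `rule`, `penalty`, `description`.
#' @export
cleavage_rules <- function() {
  tibble::tibble(
    rule = c("proline_block", "acidic_adjacent", "dibasic"),
    penalty = c(1.0, 0.3, 0.2),
    description = c(
      "K/R cleavage site followed by proline (uncleavable)",
      "D or E immediately before or after the cleavage K/R",
      "second basic residue (K/R) adjacent to the cleavage K/R"
    )
  )
}

# risk contribution of one cleavage site. `before`, `site`, `after` are the
# residue before the cleavage K/R, the K/R itself, and the residue following
# the cut ("-" or NA when unknown/terminus).
.site_risk <- function(before, site, after, rules) {
  pen <- stats::setNames(rules$penalty, rules$rule)
  if (is.na(site) || !site %in% c("K", "R")) return(0)
  risk <- 0
  if (!is.na(after) && after == "P") risk <- risk + pen[["proline_block"]]
  if (!is.na(before) && before %in% c("D", "E")) {
    risk <- risk + pen[["acidic_adjacent"]]
  }
  if (!is.na(after) && after %in% c("D", "E")) {
    risk <- risk + pen[["acidic_adjacent"]]
  }
  if ((!is.na(before) && before %in% c("K", "R")) ||
      (!is.na(after) && after %in% c("K", "R"))) {
    risk <- risk + pen[["dibasic"]]
  }
  unname(risk)
}

#' Heuristic missed-cleavage risk of a tryptic peptide
#'
#' Rule-based stand-in for a trained missed-cleavage predictor: additive
#' penalties (see [cleavage_rules()]) are evaluated at the two cleavage
#' sites a fully tryptic peptide requires (its N-terminal junction, where
#' the preceding flank residue is the cleaved K/R, and its own C-terminal
#' K/R), then clamped to [0, 1]. Adding a firing rule never lowers the
#' score.
#'
#' @param sequence Peptide sequence.
#' @param n_flank Residue preceding the peptide (`"-"` for protein
#'   N-terminus).
#' @param c_flank Residue following the peptide (`"-"` for protein
#'   C-terminus).
#' @param rules Rule table, see [cleavage_rules()].
#' @return Risk score in [0, 1].
#' @export
cleavage_risk <- function(sequence, n_flank = "-", c_flank = "-",
                          rules = cleavage_rules()) {
  sequence <- .check_sequence(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  term <- function(x) if (is.na(x) || x == "-") NA_character_ else x
  # N-side junction: cleavage residue is the flank (K/R); residue before it
  # is outside the recorded context.
  risk <- .site_risk(NA_character_, term(n_flank), aa[1], rules)
  # C-side junction: peptide's own terminal residue, if K/R (internal
  # peptides); penultimate residue and the C flank are its context.
  before <- if (n >= 2L) aa[n - 1L] else term(n_flank)
  risk <- risk + .site_risk(before, aa[n], term(c_flank), rules)
  min(max(risk, 0), 1)
}

#' Select quantotypic surrogate peptides
#'
#' Filters tryptic peptide candidates to those suitable as quantification
#' surrogates and ranks them, returning the best `n_select` per protein.
#' Hard filters: length within bounds and sequence unique in the digested
#' proteome. Soft filter: no methionine (oxidation) or cysteine (alkylation
#' variability) -- relaxed with a warning flag when a protein would
#' otherwise have no surrogates. Remaining candidates are ranked by
#' cleavage risk, then by closeness to the preferred length, then
#' alphabetically for determinism.
#'
#' @param candidates Tibble from [digest_tryptic()] (one or more proteins),
#'   with a `protein_id` column.
#' @param proteome_digest Tibble of the full proteome digest used for
#'   uniqueness testing (defaults to `candidates`).
#' @param len_min,len_max Length bounds (residues).
#' @param len_pref Preferred length used as ranking tie-break.
#' @param n_select Number of surrogates per protein.
#' @param group_shared If `TRUE`, peptides shared between proteins are kept
#'   and the sharing proteins are reported as a group id; if `FALSE`
#'   (default) shared peptides are excluded from all parents.
#' @param rules Cleavage-risk rule table.
#' @return Tibble of selected peptides with columns of `candidates` plus
#'   `cleavage_risk`, `has_met_cys`, `flagged` (soft filter relaxed) and
#'   `rank`.
#' @export
select_quantotypic <- function(candidates, proteome_digest = candidates,
                               len_min = 7L, len_max = 25L, len_pref = 10L,
                               n_select = 2L, group_shared = FALSE,
                               rules = cleavage_rules()) {
  stopifnot(is.data.frame(candidates), "protein_id" %in% names(candidates))
  seq_parents <- tapply(proteome_digest$protein_id, proteome_digest$sequence,
                        function(x) sort(unique(x)), simplify = FALSE)
  n_parents <- lengths(seq_parents)

  cand <- dplyr::mutate(
    candidates,
    cleavage_risk = mapply(cleavage_risk, .data$sequence, .data$n_flank,
                           .data$c_flank, MoreArgs = list(rules = rules)),
    has_met_cys = grepl("[MC]", .data$sequence),
    n_parents = as.integer(n_parents[.data$sequence])
  )
  cand <- dplyr::filter(cand, .data$length >= len_min, .data$length <= len_max)
  if (group_shared) {
    cand <- dplyr::mutate(
      cand,
      protein_group = vapply(seq_parents[.data$sequence], paste,
                             character(1), collapse = ";")
    )
  } else {
    cand <- dplyr::filter(cand, .data$n_parents == 1L)
    cand$protein_group <- cand$protein_id
  }

  pick <- function(df) {
    clean <- df[!df$has_met_cys, , drop = FALSE]
    use <- if (nrow(clean) > 0L) clean else df
    use$flagged <- use$has_met_cys
    ord <- order(use$cleavage_risk, abs(use$length - len_pref), use$sequence)
    out <- use[utils::head(ord, n_select), , drop = FALSE]
    # top up with flagged peptides when clean ones are too few
    if (nrow(out) < n_select && nrow(clean) > 0L && nrow(df) > nrow(clean)) {
      rest <- df[df$has_met_cys, , drop = FALSE]
      rest$flagged <- TRUE
      ord2 <- order(rest$cleavage_risk, abs(rest$length - len_pref),
                    rest$sequence)
      out <- rbind(out, rest[utils::head(ord2, n_select - nrow(out)), ,
                             drop = FALSE])
    }
    out$rank <- seq_len(nrow(out))
    out
  }
  sel <- dplyr::group_modify(dplyr::group_by(cand, .data$protein_id),
                             function(df, key) pick(df))
  dplyr::ungroup(sel)
}

#' Assemble a QconCAT from selected peptides
#'
#' Orders the surrogate peptides to minimise the summed missed-cleavage
#' risk at the junctions between consecutive peptides, then concatenates
#' them with no spacers. For small designs (<= `exhaustive_max` peptides)
#' all orderings are enumerated; otherwise a multi-start greedy search is
#' used and the identity ordering is always included as a candidate, so the
#' returned ordering never scores worse than the input order.
#'
#' @param peptides Character vector of peptide sequences (or a tibble with
#'   a `sequence` column).
#' @param exhaustive_max Maximum number of peptides for exhaustive ordering.
#' @param rules Cleavage-risk rule table.
#' @return List of class `qconcat_design`: `peptides` (ordered), `sequence`
#'   (concatenation), `mass` (monoisotopic, Da), `junction_risks`,
#'   `total_junction_risk`, `n_peptides`.
#' @export
assemble_qconcat <- function(peptides, exhaustive_max = 6L,
                             rules = cleavage_rules()) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- vapply(peptides, .check_sequence, character(1), USE.NAMES = FALSE)
  n <- length(peptides)
  if (n < 1L) stop("at least one peptide is required", call. = FALSE)

  junction <- function(a, b) {
    aa_a <- strsplit(a, "", fixed = TRUE)[[1]]
    la <- length(aa_a)
    before <- if (la >= 2L) aa_a[la - 1L] else NA_character_
    .site_risk(before, aa_a[la], substr(b, 1L, 1L), rules)
  }
  jr <- outer(seq_len(n), seq_len(n),
              Vectorize(function(i, j) junction(peptides[i], peptides[j])))

  path_cost <- function(ord) {
    if (length(ord) < 2L) return(0)
    sum(jr[cbind(utils::head(ord, -1L), ord[-1L])])
  }

  if (n <= exhaustive_max) {
    perms <- .permutations(n)
    costs <- apply(perms, 1L, path_cost)
    best <- perms[which.min(costs), ]
  } else {
    greedy_from <- function(start) {
      ord <- start
      left <- setdiff(seq_len(n), start)
      while (length(left) > 0L) {
        nxt <- left[which.min(jr[ord[length(ord)], left])]
        ord <- c(ord, nxt)
        left <- setdiff(left, nxt)
      }
      ord
    }
    cands <- c(lapply(seq_len(n), greedy_from), list(seq_len(n)))
    costs <- vapply(cands, path_cost, numeric(1))
    best <- cands[[which.min(costs)]]
  }

  ordered <- peptides[best]
  concat <- paste(ordered, collapse = "")
  risks <- if (n >= 2L) {
    jr[cbind(utils::head(best, -1L), best[-1L])]
  } else {
    numeric(0)
  }
  structure(
    list(
      peptides = ordered,
      sequence = concat,
      mass = peptide_mass(concat),
      junction_risks = risks,
      total_junction_risk = sum(risks),
      n_peptides = n
    ),
    class = "qconcat_design"
  )
}

#' @export
print.qconcat_design <- function(x, ...) {
  cat("QconCAT design:", x$n_peptides, "peptides,",
      nchar(x$sequence), "residues,",
      sprintf("%.3f Da,", x$mass),
      sprintf("total junction risk %.2f\n", x$total_junction_risk))
  invisible(x)
}

# all permutations of 1..n as rows (n small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1L))
  }))
}

#' Select SRM transitions for a peptide
#'
#' Two-stage selection: candidates are first tiered (tier 1: y ions with
#' product m/z above the precursor m/z; tier 2: everything else) and ranked
#' within tier by intensity (descending), taking the top `n_first`.
#' Those are then re-ranked by signal-to-background (descending) and the
#' top `n_final` retained. All ties break deterministically by fragment
#' index ascending.
#'
#' @param candidates Tibble with columns `ion_type` ("y"/"b"), `index`,
#'   `product_mz`, `intensity`, `s2b` (signal-to-background).
#' @param precursor_mz Precursor m/z (Th).
#' @param n_first,n_final Sizes of the two selection stages.
#' @return List with `usable` (logical), `six` (stage-1 tibble) and `three`
#'   (final tibble); `three` is always a subset of `six`.
#' @export
select_transitions <- function(candidates, precursor_mz, n_first = 6L,
                               n_final = 3L) {
  req <- c("ion_type", "index", "product_mz", "intensity", "s2b")
  miss <- setdiff(req, names(candidates))
  if (length(miss) > 0L) {
    stop("candidate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(candidates) < n_final) {
    return(list(usable = FALSE, six = candidates[0, ], three = candidates[0, ]))
  }
  tier <- ifelse(candidates$ion_type == "y" &
                   candidates$product_mz > precursor_mz, 1L, 2L)
  ord1 <- order(tier, -candidates$intensity, candidates$index)
  six <- candidates[utils::head(ord1, n_first), , drop = FALSE]
  ord2 <- order(-six$s2b, six$index)
  three <- six[utils::head(ord2, n_final), , drop = FALSE]
  list(usable = TRUE, six = six, three = three)
}

#' Feasibility of a time-scheduled SRM method
#'
#' Cycle time is the chromatographic peak width divided by the data points
#' required per peak. At any moment the instrument must cycle through every
#' transition whose retention-time window covers that moment; the schedule
#' is feasible when the maximum concurrency times the minimum dwell fits in
#' one cycle. Defaults (15 s peaks, 12 points, 40 ms dwell, 3 min windows)
#' give a capacity of floor(1.25 / 0.040) = 31 concurrent transitions.
#'
#' @param rt Numeric vector of expected retention times (min), one per
#'   transition.
#' @param window_min Scheduling window width (min).
#' @param peak_width_s Chromatographic peak width (s).
#' @param points_per_peak Required data points per peak.
#' @param min_dwell_s Minimum dwell time per transition (s).
#' @return List of class `srm_schedule`: `cycle_time_s`, `capacity`,
#'   `max_concurrency`, `feasible`, `concurrency` (per transition).
#' @export
schedule_srm <- function(rt, window_min = 3, peak_width_s = 15,
                         points_per_peak = 12, min_dwell_s = 0.040) {
  cycle <- peak_width_s / points_per_peak
  capacity <- floor(cycle / min_dwell_s)
  if (length(rt) == 0L) {
    return(structure(list(cycle_time_s = cycle, capacity = capacity,
                          max_concurrency = 0L, feasible = TRUE,
                          concurrency = integer(0)),
                     class = "srm_schedule"))
  }
  stopifnot(is.numeric(rt), !anyNA(rt))
  half <- window_min / 2
  conc <- vapply(rt, function(t) sum(abs(rt - t) <= half), integer(1))
  structure(
    list(cycle_time_s = cycle, capacity = capacity,
         max_concurrency = max(conc), feasible = max(conc) <= capacity,
         concurrency = conc),
    class = "srm_schedule"
  )
}

#' @export
print.srm_schedule <- function(x, ...) {
  cat("SRM schedule: cycle", x$cycle_time_s, "s, capacity", x$capacity,
      "concurrent transitions, max concurrency", x$max_concurrency,
      if (x$feasible) "-> feasible\n" else "-> INFEASIBLE\n")
  invisible(x)
}
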