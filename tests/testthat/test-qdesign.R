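test_that("tryptic digestion cleaves after K/R, suppresses proline, tiles", {
  expect_equal(digest_tryptic("MKRAPK")$sequence, c("MK", "R", "APK"))
  expect_equal(digest_tryptic("AKPR")$sequence, "AKPR")

  # fuzz: peptides tile arbitrary proteins exactly and flanks are correct
  set.seed(7)
  for (i in 1:25) {
    prot <- random_peptide(sample(10:120, 1))
    d <- digest_tryptic(prot, "X")
    expect_identical(paste(d$sequence, collapse = ""), prot)
    expect_identical(substr(prot, d$start[1], d$end[1]), d$sequence[1])
    expect_identical(d$n_flank[1], "-")
    expect_identical(d$c_flank[nrow(d)], "-")
    if (nrow(d) > 1) {
      last_chars <- substr(d$sequence, nchar(d$sequence), nchar(d$sequence))
      expect_identical(d$n_flank[-1], last_chars[-nrow(d)])
      expect_identical(d$c_flank[-nrow(d)], substr(d$sequence, 1, 1)[-1])
    }
  }
  expect_error(digest_tryptic("MKZ"), "illegal residue")
})

test_that("cleavage risk follows the rule table and is monotone", {
  # plain junctions fire nothing
  expect_equal(cleavage_risk("AGTLSAK", n_flank = "K", c_flank = "A"), 0)
  # proline after a needed site is uncleavable
  expect_equal(cleavage_risk("AGTLSAK", n_flank = "K", c_flank = "P"), 1)
  # acidic residue before the C-terminal site raises the score
  risk_d <- cleavage_risk("AGTLSDK", n_flank = "K", c_flank = "A")
  risk_a <- cleavage_risk("AGTLSAK", n_flank = "K", c_flank = "A")
  expect_gt(risk_d, risk_a)
  # adding a second firing rule never lowers the score
  risk_dd <- cleavage_risk("AGTLSDK", n_flank = "K", c_flank = "E")
  expect_gte(risk_dd, risk_d)
  # clamped to [0, 1]
  expect_lte(cleavage_risk("DKDKDK", n_flank = "R", c_flank = "P"), 1)
})

test_that("quantotypic selection enforces hard filters and falls back", {
  proteome <- tibble::tibble(
    protein_id = c("P1", "P2"),
    sequence = c(
      paste0("MAGTLSEQWNNK", "AGLYHTTVLDNR", "SHAREDPEPK", "AMTTLCVVK"),
      paste0("MQQVTLNNALSK", "SHAREDPEPK", "TTYLGGHHNR")
    )
  )
  digests <- dplyr::bind_rows(lapply(seq_len(nrow(proteome)), function(i) {
    digest_tryptic(proteome$sequence[i], proteome$protein_id[i])
  }))
  sel <- select_quantotypic(digests, digests)
  # shared peptide excluded from both parents
  expect_false("SHAREDPEPK" %in% sel$sequence)
  # selected peptides pass the hard filters
  expect_true(all(sel$length >= 7 & sel$length <= 25))
  expect_true(all(sel$n_parents == 1))
  # Met/Cys peptides only appear flagged
  expect_true(all(!grepl("[MC]", sel$sequence[!sel$flagged])))

  # a protein whose only legal peptides contain Met is not lost
  met_only <- digest_tryptic(paste0("GMTTLSVVNK", "AMLLSTGHNR"), "PM")
  selm <- select_quantotypic(met_only, met_only)
  expect_equal(nrow(selm), 2L)
  expect_true(all(selm$flagged))
})

test_that("quantotypic filter audit holds on a random proteome", {
  set.seed(11)
  proteome <- tibble::tibble(
    protein_id = sprintf("P%03d", 1:60),
    sequence = vapply(1:60, function(i) random_peptide(sample(60:200, 1)),
                      character(1))
  )
  digests <- dplyr::bind_rows(lapply(seq_len(nrow(proteome)), function(i) {
    digest_tryptic(proteome$sequence[i], proteome$protein_id[i])
  }))
  sel <- select_quantotypic(digests, digests)
  counts <- table(digests$sequence)
  # brute-force audit of every hard filter
  expect_true(all(sel$length >= 7 & sel$length <= 25))
  expect_true(all(counts[sel$sequence] == 1))
  expect_true(all(table(sel$protein_id) <= 2))
  # ranking respects cleavage risk among unflagged picks within a protein
  for (p in unique(sel$protein_id)) {
    s <- sel[sel$protein_id == p, ]
    if (nrow(s) == 2 && !any(s$flagged)) {
      expect_lte(s$cleavage_risk[s$rank == 1], s$cleavage_risk[s$rank == 2])
    }
  }
})

test_that("QconCAT assembly minimises junction risk and conserves mass", {
  single <- assemble_qconcat("AGTLSAK")
  expect_equal(single$sequence, "AGTLSAK")
  expect_equal(single$total_junction_risk, 0)

  junction_cost <- function(a, b) {
    proteocensus:::.site_risk(substr(a, nchar(a) - 1, nchar(a) - 1),
                              substr(a, nchar(a), nchar(a)),
                              substr(b, 1, 1), cleavage_rules())
  }
  path_cost <- function(peps, ord) {
    sum(vapply(seq_len(length(ord) - 1), function(i) {
      junction_cost(peps[ord[i]], peps[ord[i + 1]])
    }, numeric(1)))
  }

  peps <- c("AGTLSDK", "PLLSTGR", "AGTVVNK")  # P start punishes one order
  des <- assemble_qconcat(peps)
  expect_lte(des$total_junction_risk, path_cost(peps, 1:3))

  # exhaustive optimum equals an independent brute-force enumeration
  set.seed(5)
  peps2 <- vapply(1:5, function(i) random_peptide(sample(6:10, 1)),
                  character(1))
  peps2 <- paste0(substr(peps2, 1, nchar(peps2) - 1), "K")
  des2 <- assemble_qconcat(peps2)
  perms <- proteocensus:::.permutations(5)
  brute <- min(apply(perms, 1, function(ord) path_cost(peps2, ord)))
  expect_equal(des2$total_junction_risk, brute)

  # greedy path (large-n branch) also never beats nor misses the identity
  des3 <- assemble_qconcat(peps2, exhaustive_max = 2)
  expect_lte(des3$total_junction_risk, path_cost(peps2, 1:5))
  expect_gte(des3$total_junction_risk, brute)

  # mass additivity: concatenation mass = sum of residues + one water
  expect_equal(des$mass,
               sum(vapply(des$peptides, peptide_mass, numeric(1))) -
                 (length(des$peptides) - 1) * 18.010565,
               tolerance = 1e-9)
})

test_that("m/z computation matches the elemental-composition oracle", {
  # printed internal-standard value: glu-fibrinopeptide B at 2+
  expect_equal(round(compute_mz("EGVNDNEEGFFSAR", 2), 1), 785.8)
  # heavy/light precursor difference = label shift / charge
  expect_equal(compute_mz("EGVNDNEEGFFSAR", 2, label = "heavy") -
                 compute_mz("EGVNDNEEGFFSAR", 2),
               6.02013 / 2, tolerance = 1e-9)
  # single glycine at 1+
  expect_equal(compute_mz("G", 1), 76.0393, tolerance = 1e-4)

  set.seed(13)
  for (i in 1:200) {
    pep <- random_peptide(sample(5:25, 1))
    z <- sample(1:3, 1)
    expect_equal(compute_mz(pep, z), oracle_peptide_mz(pep, z),
                 tolerance = 1e-3)
  }

  # charge-state identity: 2 * (m/z at 2+) - 2 proton = (m/z at 1+) - proton
  for (pep in c("AGTLSAK", "EGVNDNEEGFFSAR")) {
    expect_equal(2 * compute_mz(pep, 2) - 2 * 1.007276,
                 compute_mz(pep, 1) - 1.007276, tolerance = 1e-9)
  }

  # y/b fragment bookkeeping: y_k + b_(n-k) = precursor neutral + 2 protons
  pep <- "AGTLSVNDK"
  n <- nchar(pep)
  for (k in 1:(n - 1)) {
    expect_equal(compute_mz(pep, 1, paste0("y", k)) +
                   compute_mz(pep, 1, paste0("b", n - k)),
                 peptide_mass(pep) + 2 * 1.007276, tolerance = 1e-9)
  }
  expect_error(compute_mz("AGK", 1, "y5"), "out of range")
})

test_that("transition selection tiers, tie-breaks and nests correctly", {
  cand <- tibble::tibble(
    ion_type = c("y", "y", rep("b", 4), rep("y", 4)),
    index = 1:10,
    product_mz = c(900, 850, rep(400, 4), rep(500, 4)),
    intensity = rep(100, 10),
    s2b = c(5, 8, rep(3, 8))
  )
  sel <- select_transitions(cand, precursor_mz = 600)
  # both above-precursor y ions occupy ranks 1-2 of the six
  expect_setequal(sel$six$index[1:2], c(1L, 2L))
  # equal intensities tie-break by fragment index ascending
  expect_equal(sel$six$index[3:6], 3:6)
  # the trio is a subset of the six, led by signal-to-background
  expect_true(all(sel$three$index %in% sel$six$index))
  expect_equal(sel$three$index[1], 2L)

  set.seed(17)
  for (i in 1:50) {
    k <- sample(3:12, 1)
    cand2 <- tibble::tibble(
      ion_type = sample(c("y", "b"), k, replace = TRUE),
      index = seq_len(k),
      product_mz = runif(k, 200, 1200),
      intensity = runif(k, 1, 1000),
      s2b = runif(k, 1, 50)
    )
    s2 <- select_transitions(cand2, precursor_mz = 700)
    expect_true(all(s2$three$index %in% s2$six$index))
  }
  expect_false(select_transitions(cand[1:2, ], 600)$usable)
})

test_that("SRM scheduling applies the cycle-time capacity bound", {
  s31 <- schedule_srm(rep(30, 31))
  expect_equal(s31$cycle_time_s, 1.25)
  expect_equal(s31$capacity, 31)
  expect_true(s31$feasible)
  expect_false(schedule_srm(rep(30, 32))$feasible)
  # spreading transitions beyond the window restores feasibility
  expect_true(schedule_srm(c(rep(10, 20), rep(20, 20)))$feasible)
  empty <- schedule_srm(numeric(0))
  expect_true(empty$feasible)
  expect_length(empty$concurrency, 0)
})
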