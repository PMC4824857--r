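# Independent elemental-composition mass oracle: residue formulas times
# element monoisotopic masses, a different route than the residue table
# used by the package.
element_masses <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                    O = 15.9949146221, S = 31.97207069)

# residue formulas (C, H, N, O, S) inside a peptide chain
residue_formulas <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)

oracle_residue_mass <- function(aa) {
  f <- residue_formulas[[aa]]
  sum(f * element_masses[c("C", "H", "N", "O", "S")])
}

oracle_peptide_mz <- function(sequence, charge) {
  aa <- strsplit(sequence, "")[[1]]
  water <- 2 * element_masses[["H"]] + element_masses[["O"]]
  proton <- 1.007276
  neutral <- sum(vapply(aa, oracle_residue_mass, numeric(1))) + water
  (neutral + charge * proton) / charge
}

random_peptide <- function(len) {
  paste(sample(names(residue_formulas), len, replace = TRUE),
        collapse = "")
}
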