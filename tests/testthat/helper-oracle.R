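# Independent oracles and shared fixtures for the test suite.

# circular angle separation, written independently of the package internals
oracle_angle_sep <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

# brute-force beta-turn matcher: enumerates every type and every choice of
# the single angle allowed the relaxed tolerance
oracle_turn_table <- data.frame(
  type = c("I", "I'", "II", "II'", "VIII", "VIa1", "VIa2", "VIb"),
  phi1 = c(-60,   60,  -60,   60,  -60,  -60, -120, -135),
  psi1 = c(-30,   30,  120, -120,  -30,  120,  120,  135),
  phi2 = c(-90,   90,   80,  -80, -120,  -90,  -60,  -75),
  psi2 = c(  0,    0,    0,    0,  120,    0,    0,  160),
  cis  = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

oracle_classify <- function(phi1, psi1, phi2, psi2, cis = FALSE,
                            strict = 30, relaxed = 45) {
  angles <- c(phi1, psi1, phi2, psi2)
  for (pass in c("strict", "relaxed")) {
    for (r in seq_len(nrow(oracle_turn_table))) {
      if (oracle_turn_table$cis[r] && !cis) next
      canon <- as.numeric(oracle_turn_table[r, c("phi1", "psi1", "phi2", "psi2")])
      d <- oracle_angle_sep(angles, canon)
      if (pass == "strict" && all(d <= strict))
        return(list(type = oracle_turn_table$type[r], relaxed = FALSE))
      if (pass == "relaxed") {
        for (j in 1:4) {
          lim <- rep(strict, 4); lim[j] <- relaxed
          if (all(d <= lim) && d[j] > strict)
            return(list(type = oracle_turn_table$type[r], relaxed = TRUE))
        }
      }
    }
  }
  list(type = "IV", relaxed = FALSE)
}

# phi/psi printed for the cleavage-site-region turn (author numbering 83-86)
csr_table1 <- data.frame(
  resno = 83:86,
  resname = c("GLU", "GLY", "ALA", "ALA"),
  phi = c(-62.5, -58.86, 79.02, -68.97),
  psi = c(145.65, 126.78, -24.45, 136.73))

# synthetic reconstruction of the turn region (residues 82-87): printed
# torsions at 83-86, extended flanks, ideal covalent geometry
build_csr_reconstruction <- function() {
  build_peptide(
    resname = c("ALA", csr_table1$resname, "ALA"),
    phi = c(-120, csr_table1$phi, -120),
    psi = c(120, csr_table1$psi, 120),
    omega = 180, start_resno = 82L)
}
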