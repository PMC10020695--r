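# standard peptide internal geometry used by build_peptide
peptide_geometry <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7, ca_c_o = 120.8)

#' Simulation settings for cleavage time courses
#'
#' Bundles the parameters of a simulated inhibitor titration experiment:
#' the uninhibited first-order rate constant `k0`, the effectiveness `phi`
#' of the inhibitor, the protein concentration, the inhibitor
#' concentration series, the aliquot schedule, and the noise level. The
#' defaults mirror a RecA-mediated cleavage titration: protein at the
#' molarity of 15 micrograms in a 100 microliter reaction, a two-fold
#' inhibitor dilution series from 1 mM down to 62.5 uM plus a control, and
#' 5-minute aliquots over 25 minutes.
#'
#' @param k0 Uninhibited rate constant, per minute.
#' @param phi Inhibitor effectiveness (molar ratio halving the rate).
#' @param lexa0 Protein concentration, micromolar.
#' @param inhibitor_concs Inhibitor concentrations, micromolar (include 0
#'   for the control).
#' @param times Aliquot times in minutes (must include 0).
#' @param noise_sd Additive Gaussian noise SD on the fraction scale.
#' @param intensity0 Band intensity of the t = 0 aliquot (arbitrary units).
#' @param seed Integer seed.
#' @param noise_model `"additive"` (Gaussian on the fraction scale, clipped
#'   at 0) or `"lognormal"` (multiplicative, same log-SD).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(k0 = 0.1, phi = 43.422,
                              lexa0 = molar_concentration(15, 100, LEXA_MW),
                              inhibitor_concs = c(1000, 500, 250, 125, 62.5, 0),
                              times = seq(0, 25, by = 5),
                              noise_sd = 0.03, intensity0 = 1000, seed = 1,
                              noise_model = c("additive", "lognormal")) {
  stopifnot(k0 >= 0, phi > 0, lexa0 > 0, noise_sd >= 0, intensity0 > 0,
            0 %in% times, !is.unsorted(times, strictly = TRUE))
  structure(list(k0 = k0, phi = phi, lexa0 = lexa0,
                 inhibitor_concs = inhibitor_concs, times = times,
                 noise_sd = noise_sd, intensity0 = intensity0,
                 seed = as.integer(seed),
                 noise_model = match.arg(noise_model)),
            class = "simulation_config")
}

#' Simulate cleavage time courses under the effectiveness model
#'
#' For each inhibitor concentration, the condition's rate constant is
#' k_i = k0 / (1 + ratio / phi) with ratio = conc / lexa0, the true
#' fraction remaining is exp(-k_i t), and observed fractions add Gaussian
#' noise (SD `noise_sd`) clipped at 0 -- except the t = 0 point, which is
#' the normalization anchor and stays noise-free. Fractions are
#' re-expressed as band intensities through `intensity0`. Deterministic
#' for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @return List of `timecourse` objects, one per inhibitor concentration.
#' @export
simulate_cleavage_series <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  lapply(config$inhibitor_concs, function(conc) {
    ratio <- conc / config$lexa0
    k_i <- effectiveness_model(ratio, config$k0, config$phi)
    truth <- exp(-k_i * config$times)
    obs <- if (config$noise_model == "additive") {
      pmax(0, truth + stats::rnorm(length(truth), 0, config$noise_sd))
    } else {
      truth * exp(stats::rnorm(length(truth), 0, config$noise_sd))
    }
    obs[config$times == 0] <- truth[config$times == 0] # anchor noise-free
    timecourse(times = config$times,
               intensities = obs * config$intensity0,
               inhibitor_conc = conc, lexa0 = config$lexa0,
               label = sprintf("I%g", conc))
  })
}

#' Build a peptide backbone from prescribed torsions
#'
#' Sequential internal-to-Cartesian construction: each backbone atom is
#' placed from the previous three using fixed standard bond lengths and
#' angles (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 angstroms; N-CA-C
#' 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees) and the prescribed phi, psi
#' and omega torsions. The carbonyl oxygen is placed in the peptide plane
#' anti to the next amide nitrogen. Recomputing torsions on the built
#' chain reproduces the prescription to numerical precision.
#'
#' `phi[1]`, `omega[1]` and `psi[n]` do not position any atom placed from
#' a preceding residue but `psi[n]` still orients the final carbonyl
#' oxygen.
#'
#' @param resname 3-letter residue codes (length n >= 2), or a single
#'   integer n for a poly-alanine.
#' @param phi,psi,omega Torsions in degrees; recycled to length n
#'   (`omega` defaults to all-trans 180).
#' @param chain_id Chain identifier for the result (default "A").
#' @param start_resno First residue number (default 1).
#' @return A [backbone_chain].
#' @examples
#' ch <- build_peptide(6, phi = -120, psi = 120)  # extended hexapeptide
#' compute_torsions(ch)
#' @export
build_peptide <- function(resname, phi, psi, omega = 180, chain_id = "A",
                          start_resno = 1L) {
  if (is.numeric(resname) && length(resname) == 1)
    resname <- rep("ALA", resname)
  n <- length(resname)
  stopifnot(n >= 2)
  phi <- wrap_angle(rep_len(as.numeric(phi), n))
  psi <- wrap_angle(rep_len(as.numeric(psi), n))
  omega <- wrap_angle(rep_len(as.numeric(omega), n))
  g <- peptide_geometry
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- g$n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_internal(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                             g$c_n, g$ca_c_n, psi[i - 1])
    CA[i, ] <- place_internal(CA[i - 1, ], C[i - 1, ], N[i, ],
                              g$n_ca, g$c_n_ca, omega[i])
    C[i, ] <- place_internal(C[i - 1, ], N[i, ], CA[i, ],
                             g$ca_c, g$n_ca_c, phi[i])
  }
  for (i in seq_len(n))
    O[i, ] <- place_internal(N[i, ], CA[i, ], C[i, ],
                             g$c_o, g$ca_c_o, psi[i] + 180)
  backbone_chain(chain_id = chain_id,
                 resno = seq(start_resno, length.out = n),
                 resname = resname, n = N, ca = CA, c = C, o = O,
                 source_label = "built from torsions (synthetic)")
}

# place atom d such that |c-d| = bond, angle(b,c,d) = angle and
# dihedral(a,b,c,d) = torsion (degrees)
place_internal <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- cross3(ab, bc)
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-9) stop("degenerate torsion placement: collinear reference atoms")
  nrm <- nrm / nn
  m <- cross3(nrm, bc)
  c + bond * (-cos(ang) * bc + cos(tor) * sin(ang) * m + sin(tor) * sin(ang) * nrm)
}

#' Build the standard peptide with an ideal type-II turn
#'
#' Convenience fixture: an extended chain (phi = -120, psi = 120) with the
#' canonical type-II central torsions (-60, 120) and (80, 0) at the two
#' residues following `turn_i`, so that [detect_turns()] finds exactly one
#' type-II turn with residue i at that position.
#'
#' @param n_res Total residues (default 8).
#' @param turn_i Position of turn residue i (default 3).
#' @param glycine_i2 Use glycine at i+2 (common in type-II turns)?
#' @return A [backbone_chain].
#' @export
build_type2_turn_peptide <- function(n_res = 8, turn_i = 3, glycine_i2 = TRUE) {
  stopifnot(n_res >= 4, turn_i >= 1, turn_i + 3 <= n_res)
  phi <- rep(-120, n_res); psi <- rep(120, n_res)
  phi[turn_i + 1] <- -60; psi[turn_i + 1] <- 120
  phi[turn_i + 2] <- 80;  psi[turn_i + 2] <- 0
  resname <- rep("ALA", n_res)
  if (glycine_i2) resname[turn_i + 2] <- "GLY"
  build_peptide(resname, phi, psi)
}

#' Deterministic toy compound-screen table
#'
#' Generates a compound table with columns `id`, `library`,
#' `docking_score` (seeded uniform), `selected` and `active`, for
#' exercising [summarize_screen()] without real screening data. The top
#' `n_selected` scorers per library are marked selected; compounds named
#' in `active_ids` are marked active (and selected).
#'
#' @param n_per_library Named integer vector: compounds docked per library.
#' @param n_selected Integer vector (recycled over libraries): how many
#'   top-scoring compounds are selected per library.
#' @param active_ids Character ids of active compounds (must exist).
#' @param seed Integer seed.
#' @return data.frame with one row per compound.
#' @export
make_toy_screen_table <- function(n_per_library, n_selected = 0,
                                  active_ids = character(), seed = 1) {
  if (is.null(names(n_per_library)))
    names(n_per_library) <- paste0("lib", seq_along(n_per_library))
  n_selected <- rep_len(as.integer(n_selected), length(n_per_library))
  stopifnot(all(n_selected <= n_per_library))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  tabs <- mapply(function(lib, n, nsel) {
    if (n == 0) return(NULL)
    id <- sprintf("%s-%06d", lib, seq_len(n))
    score <- stats::runif(n, -10, 0) # more negative = better
    selected <- rank(score, ties.method = "first") <= nsel
    data.frame(id = id, library = lib, docking_score = score,
               selected = selected, active = FALSE, stringsAsFactors = FALSE)
  }, names(n_per_library), n_per_library, n_selected, SIMPLIFY = FALSE)
  tab <- do.call(rbind, tabs)
  if (is.null(tab))
    return(data.frame(id = character(0), library = character(0),
                      docking_score = numeric(0), selected = logical(0),
                      active = logical(0), stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  if (length(active_ids)) {
    miss <- setdiff(active_ids, tab$id)
    if (length(miss)) stop("make_toy_screen_table: unknown active id(s): ",
                           paste(miss, collapse = ", "))
    hit <- tab$id %in% active_ids
    tab$active[hit] <- TRUE
    tab$selected[hit] <- TRUE
    # keep per-library selected counts: forcing an unselected active
    # compound in bumps the worst-scoring selected inactive one out
    for (lib in unique(tab$library[hit])) {
      nsel <- n_selected[match(lib, names(n_per_library))]
      in_lib <- tab$library == lib
      excess <- sum(tab$selected[in_lib]) - nsel
      if (excess > 0) {
        cand <- which(in_lib & tab$selected & !tab$active)
        cand <- cand[order(tab$docking_score[cand], decreasing = TRUE)]
        tab$selected[utils::head(cand, excess)] <- FALSE
      }
    }
  }
  tab
}
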