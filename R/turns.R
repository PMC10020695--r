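#' Canonical beta-turn type table
#'
#' The eight named beta-turn types with their canonical central torsions
#' (phi, psi of residues i+1 and i+2, degrees), following the established
#' literature convention; type IV is the implicit catch-all for windows
#' matching none of them. The VI types additionally require a cis peptide
#' bond into residue i+2. A window matches a type when all four angles are
#' within `strict_tol` of the canonical values, with at most one angle
#' allowed out to `relaxed_tol` (circular differences throughout).
#'
#' Rows may be appended through `extra` (e.g. newer clustering-derived turn
#' nomenclatures): a data.frame with columns `type`, `phi1`, `psi1`,
#' `phi2`, `psi2` and optionally `cis`; appended rows are tried after the
#' built-in ones in the order given.
#'
#' @param strict_tol Strict tolerance in degrees (default 30).
#' @param relaxed_tol Relaxed tolerance, applicable to at most one of the
#'   four angles (default 45).
#' @param extra Optional extension rows (see Details).
#' @return A data.frame of class `turn_type_table` with attributes
#'   `strict_tol` and `relaxed_tol`.
#' @export
turn_type_table <- function(strict_tol = 30, relaxed_tol = 45, extra = NULL) {
  stopifnot(strict_tol > 0, relaxed_tol >= strict_tol)
  tab <- data.frame(
    type = c("I", "I'", "II", "II'", "VIII", "VIa1", "VIa2", "VIb"),
    phi1 = c(-60,   60,  -60,   60,  -60,  -60, -120, -135),
    psi1 = c(-30,   30,  120, -120,  -30,  120,  120,  135),
    phi2 = c(-90,   90,   80,  -80, -120,  -90,  -60,  -75),
    psi2 = c(  0,    0,    0,    0,  120,    0,    0,  160),
    cis  = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("type", "phi1", "psi1", "phi2", "psi2") %in% names(extra)))
    if (is.null(extra$cis)) extra$cis <- FALSE
    tab <- rbind(tab, extra[, names(tab)])
  }
  attr(tab, "strict_tol") <- strict_tol
  attr(tab, "relaxed_tol") <- relaxed_tol
  class(tab) <- c("turn_type_table", "data.frame")
  tab
}

#' Classify a beta-turn from its central torsions
#'
#' Assigns the turn type of a 4-residue window from the phi/psi angles of
#' its two central residues. Types are tried in fixed table order; an
#' all-strict match is preferred over a match that needs the relaxed
#' tolerance on one angle; cis-requiring types are only eligible when
#' `omega2_cis` is `TRUE`. Windows matching no canonical type are "IV".
#'
#' @param phi1,psi1 Torsions of residue i+1, degrees.
#' @param phi2,psi2 Torsions of residue i+2, degrees.
#' @param omega2_cis Is the peptide bond into residue i+2 cis (omega within
#'   30 degrees of 0)?
#' @param table A [turn_type_table()].
#' @return List with elements `type` (character) and `relaxed` (logical;
#'   `TRUE` when the match needed the relaxed tolerance on one angle).
#' @examples
#' classify_turn(-58.86, 126.78, 79.02, -24.45)  # the LexA CSR turn: type II
#' @export
classify_turn <- function(phi1, psi1, phi2, psi2, omega2_cis = FALSE,
                          table = turn_type_table()) {
  angles <- c(phi1, psi1, phi2, psi2)
  if (anyNA(angles) || !all(is.finite(angles)))
    stop("classify_turn: all four angles must be defined; exclude terminal windows")
  strict <- attr(table, "strict_tol")
  relaxed <- attr(table, "relaxed_tol")
  eligible <- !table$cis | isTRUE(omega2_cis)
  devs <- function(row) {
    c(angle_sep(phi1, table$phi1[row]), angle_sep(psi1, table$psi1[row]),
      angle_sep(phi2, table$phi2[row]), angle_sep(psi2, table$psi2[row]))
  }
  # pass 1: all four angles strict
  for (r in which(eligible)) {
    if (all(devs(r) <= strict))
      return(list(type = table$type[r], relaxed = FALSE))
  }
  # pass 2: one angle allowed out to the relaxed tolerance
  for (r in which(eligible)) {
    d <- devs(r)
    if (sum(d > strict) == 1L && all(d <= relaxed))
      return(list(type = table$type[r], relaxed = TRUE))
  }
  list(type = "IV", relaxed = FALSE)
}

#' Detect beta-turns in a backbone chain
#'
#' Scans every 4-residue window of consecutively bonded residues and
#' reports those whose CA(i)-CA(i+3) distance is at most `ca_cutoff`
#' (the classical detection criterion) and whose central torsions are
#' defined. Each reported window is classified with [classify_turn()] and
#' annotated with its hydrogen-bond geometry ([turn_hbond()]). Overlapping
#' turns are all reported. With `exclude_helical`, windows whose two
#' central residues both fall in the alpha-helical region
#' (phi in \[-100, -30\], psi in \[-80, -5\]) are dropped.
#'
#' @param chain A [backbone_chain].
#' @param ca_cutoff CA(i)-CA(i+3) detection cutoff in angstroms
#'   (default 7.0).
#' @param exclude_helical Drop helical windows? Default `FALSE`.
#' @param table A [turn_type_table()].
#' @param place_hydrogen Construct the amide hydrogen of residue i+3 to
#'   measure the O(i)...H(i+3) distance? Default `TRUE`.
#' @return A data.frame (possibly 0-row) with one row per detected turn:
#'   `i_resno`, `sequence` (hyphenated 3-letter codes of i..i+3), `phi1`,
#'   `psi1`, `phi2`, `psi2`, `omega2_cis`, `ca_dist`, `o_n_dist`,
#'   `o_h_dist`, `type`, `relaxed`.
#' @export
detect_turns <- function(chain, ca_cutoff = 7.0, exclude_helical = FALSE,
                         table = turn_type_table(), place_hydrogen = TRUE) {
  stopifnot(inherits(chain, "backbone_chain"))
  nres <- length(chain)
  out <- list()
  if (nres >= 4 && any(chain$bonded)) {
    tors <- compute_torsions(chain)
    for (i in seq_len(nres - 3L)) {
      if (!all(chain$bonded[i:(i + 2L)])) next
      ca_d <- atom_distance(chain$ca[i, ], chain$ca[i + 3L, ])
      if (ca_d > ca_cutoff) next
      phi1 <- tors$phi[i + 1L]; psi1 <- tors$psi[i + 1L]
      phi2 <- tors$phi[i + 2L]; psi2 <- tors$psi[i + 2L]
      if (anyNA(c(phi1, psi1, phi2, psi2))) next
      if (exclude_helical &&
          is_helical(phi1, psi1) && is_helical(phi2, psi2)) next
      om2 <- tors$omega[i + 2L]
      om2_cis <- !is.na(om2) && angle_sep(om2, 0) <= 30
      cls <- classify_turn(phi1, psi1, phi2, psi2, om2_cis, table)
      hb <- tryCatch(turn_hbond(chain, i, place_hydrogen = place_hydrogen),
                     error = function(e) list(o_n_dist = NA_real_,
                                              o_h_dist = NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        i_resno = chain$resno[i],
        sequence = paste(chain$resname[i:(i + 3L)], collapse = "-"),
        phi1 = phi1, psi1 = psi1, phi2 = phi2, psi2 = psi2,
        omega2_cis = om2_cis, ca_dist = ca_d,
        o_n_dist = hb$o_n_dist, o_h_dist = hb$o_h_dist,
        type = cls$type, relaxed = cls$relaxed,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(i_resno = integer(0), sequence = character(0),
                      phi1 = numeric(0), psi1 = numeric(0),
                      phi2 = numeric(0), psi2 = numeric(0),
                      omega2_cis = logical(0), ca_dist = numeric(0),
                      o_n_dist = numeric(0), o_h_dist = numeric(0),
                      type = character(0), relaxed = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

is_helical <- function(phi, psi) {
  phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5
}

#' Hydrogen-bond geometry of a beta-turn
#'
#' Measures the i -> i+3 hydrogen-bond distances of a turn window: the
#' O(i)-N(i+3) heavy-atom distance, and optionally the O(i)-H(i+3)
#' distance with the amide hydrogen constructed geometrically (the input
#' coordinates carry no hydrogens). H is placed 1.01 angstrom from N(i+3)
#' in the peptide plane, opposite the bisector of the N->C(i+2) and
#' N->CA(i+3) bond directions. Prolines at i+3 have no amide hydrogen, so
#' `o_h_dist` is `NA` there.
#'
#' @param chain A [backbone_chain].
#' @param i Index of residue i of the window within the chain (1-based
#'   position, not author numbering).
#' @param place_hydrogen Construct H(i+3)? Default `TRUE`.
#' @return List with `o_n_dist` and `o_h_dist` (angstroms; `o_h_dist` `NA`
#'   when not placed).
#' @export
turn_hbond <- function(chain, i, place_hydrogen = TRUE) {
  stopifnot(inherits(chain, "backbone_chain"), i >= 1, i + 3L <= length(chain))
  o_i <- chain$o[i, ]
  n_i3 <- chain$n[i + 3L, ]
  if (anyNA(o_i)) stop("missing atom: O of residue i")
  if (anyNA(n_i3)) stop("missing atom: N of residue i+3")
  o_n <- atom_distance(o_i, n_i3)
  o_h <- NA_real_
  if (place_hydrogen && chain$resname[i + 3L] != "PRO") {
    h <- place_amide_h(chain$c[i + 2L, ], n_i3, chain$ca[i + 3L, ])
    if (!anyNA(h)) o_h <- atom_distance(o_i, h)
  }
  list(o_n_dist = o_n, o_h_dist = o_h)
}

# amide H: 1.01 A from N, anti to the bisector of N->C_prev and N->CA
place_amide_h <- function(c_prev, n, ca, bond = 1.01) {
  if (anyNA(c(c_prev, n, ca))) return(rep(NA_real_, 3))
  u1 <- c_prev - n; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- ca - n; u2 <- u2 / sqrt(sum(u2^2))
  b <- u1 + u2
  nb <- sqrt(sum(b^2))
  if (nb < 1e-9) return(rep(NA_real_, 3))
  n - bond * b / nb
}
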