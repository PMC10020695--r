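#' Backbone torsion angles of a chain
#'
#' Computes the classical backbone dihedrals per residue:
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) = N(i)-CA(i)-C(i)-N(i+1) and
#' omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i) (the peptide bond preceding residue
#' i). Angles are `NA` at chain termini, across chain breaks (C-N distance
#' above the bonding cutoff) and wherever a required atom is missing.
#'
#' @param chain A [backbone_chain].
#' @return A data.frame with columns `resno`, `ins`, `resname`, `phi`,
#'   `psi`, `omega` (degrees, in (-180, 180]).
#' @export
compute_torsions <- function(chain) {
  stopifnot(inherits(chain, "backbone_chain"))
  nres <- length(chain)
  if (nres < 2 || !any(chain$bonded))
    stop("no torsions: chain needs at least 2 bonded residues")
  safe_dih <- function(p1, p2, p3, p4) {
    if (anyNA(c(p1, p2, p3, p4))) return(NA_real_)
    tryCatch(dihedral_angle(p1, p2, p3, p4), error = function(e) NA_real_)
  }
  phi <- psi <- omega <- rep(NA_real_, nres)
  for (i in seq_len(nres)) {
    prev_bonded <- i > 1 && chain$bonded[i - 1L]
    next_bonded <- i < nres && chain$bonded[i]
    if (prev_bonded) {
      phi[i] <- safe_dih(chain$c[i - 1L, ], chain$n[i, ], chain$ca[i, ], chain$c[i, ])
      omega[i] <- safe_dih(chain$ca[i - 1L, ], chain$c[i - 1L, ], chain$n[i, ], chain$ca[i, ])
    }
    if (next_bonded)
      psi[i] <- safe_dih(chain$n[i, ], chain$ca[i, ], chain$c[i, ], chain$n[i + 1L, ])
  }
  data.frame(resno = chain$resno, ins = chain$ins, resname = chain$resname,
             phi = phi, psi = psi, omega = omega, stringsAsFactors = FALSE)
}
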