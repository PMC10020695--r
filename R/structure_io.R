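#' Construct a backbone chain object
#'
#' A `backbone_chain` holds the ordered backbone (N, CA, C, O) coordinates
#' of one protein chain. Coordinates are stored as n x 3 matrices in
#' angstroms; missing atoms are rows of `NA` (the alpha-carbon is always
#' required). Consecutive residues are flagged bonded when the C(i)-N(i+1)
#' distance is at most `break_cutoff` angstroms, so that torsions are never
#' computed across chain breaks.
#'
#' @param chain_id Single-character chain identifier.
#' @param resno Integer residue numbers as authored in the source file
#'   (strictly increasing once insertion codes are accounted for).
#' @param resname Character vector of 3-letter residue codes.
#' @param n,ca,c,o n x 3 coordinate matrices (angstroms); `ca` must be
#'   complete, the others may contain `NA` rows.
#' @param ins Optional insertion codes ("" when absent).
#' @param source_label Free-text provenance label.
#' @param break_cutoff C-N distance (angstroms) above which consecutive
#'   residues are treated as a chain break. Default 2.0.
#' @return An object of class `backbone_chain`.
#' @export
backbone_chain <- function(chain_id, resno, resname, n, ca, c, o = NULL,
                           ins = NULL, source_label = "", break_cutoff = 2.0) {
  nres <- length(resno)
  as_mat <- function(m) {
    if (is.null(m)) m <- matrix(NA_real_, nres, 3)
    m <- matrix(as.numeric(m), ncol = 3)
    stopifnot(nrow(m) == nres)
    m
  }
  n <- as_mat(n); ca <- as_mat(ca); c <- as_mat(c); o <- as_mat(o)
  if (anyNA(ca)) stop("backbone_chain: every residue needs a CA atom")
  if (is.null(ins)) ins <- rep("", nres)
  resno <- as.integer(resno)
  if (nres > 1) {
    ord <- order(resno, match(ins, unique(ins)))
    if (is.unsorted(ord)) stop("backbone_chain: residues must be in file order")
  }
  bonded <- if (nres > 1) {
    vapply(seq_len(nres - 1L), function(i) {
      if (anyNA(c[i, ]) || anyNA(n[i + 1L, ])) return(FALSE)
      atom_distance(c[i, ], n[i + 1L, ]) <= break_cutoff
    }, logical(1))
  } else logical(0)
  structure(
    list(chain_id = as.character(chain_id), resno = resno, ins = ins,
         resname = as.character(resname), n = n, ca = ca, c = c, o = o,
         bonded = bonded, source_label = source_label),
    class = "backbone_chain")
}

#' @export
length.backbone_chain <- function(x) length(x$resno)

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain %s> %d residues (%s)%s\n",
              x$chain_id, length(x),
              paste0(x$resname[seq_len(min(4, length(x)))], collapse = "-"),
              if (length(x) > 4) "..." else ""))
  nb <- sum(!x$bonded)
  if (nb > 0) cat(sprintf("  %d chain break(s)\n", nb))
  if (nzchar(x$source_label)) cat("  source:", x$source_label, "\n")
  invisible(x)
}

standard_aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Read backbone chains from PDB-format text
#'
#' Parses ATOM records (via [bio3d::read.pdb()]) and extracts the N, CA, C
#' and O backbone atoms of each chain of one model. HETATM records and
#' hydrogens are ignored. Alternate locations are resolved per `altloc`:
#' the default keeps, per atom, the altloc with the highest occupancy,
#' breaking ties by the alphabetically first altloc code. Residues lacking
#' a CA atom are skipped with a warning. Insertion-coded residues are kept
#' in file order with their code recorded.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB-format lines
#'   (anything containing a newline or more than one element is treated as
#'   text).
#' @param model_index Model to read from a multi-model file (default 1; the
#'   crystallographic sources this package targets are single-model).
#' @param altloc `"highest_occupancy"` (default) or `"first"` (keep the
#'   first-encountered altloc of each atom).
#' @return A list of [backbone_chain] objects, one per chain identifier, in
#'   file order.
#' @export
read_backbone <- function(pdb, model_index = 1L,
                          altloc = c("highest_occupancy", "first")) {
  altloc <- match.arg(altloc)
  path <- pdb_as_path(pdb)
  multi <- model_index > 1L
  pdbobj <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = multi, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("empty structure: no ATOM records (", conditionMessage(e), ")"))
  at <- pdbobj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no ATOM records")
  if (multi) {
    if (nrow(pdbobj$xyz) < model_index)
      stop("model_index ", model_index, " exceeds models in file")
    xyz <- matrix(pdbobj$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no backbone atoms")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # resolve altlocs per (chain, residue, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (altloc == "highest_occupancy") {
    occ <- at$o; occ[is.na(occ)] <- 1
    ord <- order(match(key, unique(key)), -occ, at$alt)
  } else {
    ord <- order(match(key, unique(key)))
  }
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "|"),
                       unique(paste(at$chain, at$resno, at$insert, sep = "|")))), ,
           drop = FALSE]

  src <- paste0(basename(path), if (multi) paste0(" model ", model_index) else "")
  chains <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    rkey <- paste(sub$resno, sub$insert, sep = "|")
    ukeys <- unique(rkey)
    grab <- function(keys, ele) {
      m <- matrix(NA_real_, length(keys), 3)
      hit <- sub[sub$elety == ele, , drop = FALSE]
      idx <- match(paste(hit$resno, hit$insert, sep = "|"), keys)
      ok <- !is.na(idx)
      m[idx[ok], ] <- cbind(hit$x, hit$y, hit$z)[ok, , drop = FALSE]
      m
    }
    ca <- grab(ukeys, "CA")
    has_ca <- !is.na(ca[, 1])
    if (any(!has_ca)) {
      warning(sprintf("chain %s: skipped %d residue(s) lacking a CA atom", ch,
                      sum(!has_ca)))
      ukeys <- ukeys[has_ca]
      ca <- ca[has_ca, , drop = FALSE]
    }
    if (length(ukeys) == 0) next
    first_row <- match(ukeys, rkey)
    chains[[ch]] <- backbone_chain(
      chain_id = ch,
      resno = sub$resno[first_row],
      ins = sub$insert[first_row],
      resname = sub$resid[first_row],
      n = grab(ukeys, "N"), ca = ca, c = grab(ukeys, "C"), o = grab(ukeys, "O"),
      source_label = src)
  }
  if (length(chains) == 0) stop("empty structure: no usable residues")
  unname(chains)
}

pdb_as_path <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  lines <- if (length(pdb) == 1) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  tmp <- tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  tmp
}

#' Write backbone chains as PDB-format text
#'
#' Emits fixed-column ATOM records (N, CA, C, O per residue, element column
#' populated) with a TER record per chain and a final END. Coordinates are
#' written at the standard PDB precision of 0.001 angstrom, so a
#' read/write round trip reproduces coordinates to 3 decimals.
#'
#' @param chains A [backbone_chain] or list of them.
#' @param path Optional file to write to.
#' @return Character vector of PDB lines (invisibly when `path` is given).
#' @export
write_backbone <- function(chains, path = NULL) {
  if (inherits(chains, "backbone_chain")) chains <- list(chains)
  if (length(chains) == 0) stop("write_backbone: no chains to write")
  stopifnot(all(vapply(chains, inherits, logical(1), "backbone_chain")))
  lines <- character(0)
  serial <- 0L
  for (chain in chains) {
    for (i in seq_along(chain$resno)) {
      for (ele in c("N", "CA", "C", "O")) {
        xyz <- chain[[tolower(ele)]][i, ]
        if (anyNA(xyz)) next
        serial <- serial + 1L
        name4 <- sprintf(" %-3s", ele) # backbone names start in column 14
        lines <- c(lines, sprintf(
          "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name4, "", substr(chain$resname[i], 1, 3),
          substr(chain$chain_id, 1, 1), chain$resno[i] %% 10000L,
          substr(chain$ins[i], 1, 1),
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, substr(ele, 1, 1)))
      }
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial %% 100000L,
                              substr(chain$resname[length(chain$resno)], 1, 3),
                              substr(chain$chain_id, 1, 1),
                              chain$resno[length(chain$resno)] %% 10000L))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
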