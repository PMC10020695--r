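make_two_chain_fixture <- function() {
  write_backbone(list(
    build_peptide(4, -120, 120, chain_id = "A"),
    build_peptide(3, -60, -45, chain_id = "B", start_resno = 10)))
}

test_that("read_backbone splits chains and keeps residue identity", {
  txt <- make_two_chain_fixture()
  chains <- read_backbone(txt)
  expect_length(chains, 2)
  expect_equal(vapply(chains, function(x) x$chain_id, character(1)), c("A", "B"))
  expect_equal(length(chains[[1]]), 4)
  expect_equal(length(chains[[2]]), 3)
  expect_equal(chains[[2]]$resno, 10:12)
  expect_equal(chains[[1]]$resname, rep("ALA", 4))
})

test_that("HETATM records are ignored", {
  txt <- make_two_chain_fixture()
  txt <- c(txt[txt != "END"],
           "HETATM   99  O   HOH A 200      10.000  10.000  10.000  1.00  0.00           O",
           "END")
  chains <- read_backbone(txt)
  expect_length(chains, 2)
  expect_false(any(vapply(chains, function(ch) 200 %in% ch$resno, logical(1))))
})

test_that("structures without ATOM records are rejected", {
  expect_error(read_backbone(c("REMARK nothing here", "END")), "empty structure")
  expect_error(write_backbone(list()), "no chains")
})

test_that("residues lacking a CA atom are skipped with a warning", {
  txt <- make_two_chain_fixture()
  txt <- txt[!(grepl("^ATOM", txt) & grepl(" CA  ALA A   2 ", txt))]
  expect_warning(chains <- read_backbone(txt), "lacking a CA")
  expect_equal(chains[[1]]$resno, c(1L, 3L, 4L))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  txt <- c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BGLY A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AGLY A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA BGLY A   1       9.458   0.000   0.000  0.60  0.00           C",
    "ATOM      5  C   GLY A   1       2.009   1.422   0.000  1.00  0.00           C",
    "END")
  suppressWarnings(chains <- read_backbone(txt))
  expect_equal(chains[[1]]$ca[1, 1], 9.458) # occupancy 0.60 wins
  suppressWarnings(first <- read_backbone(txt, altloc = "first"))
  expect_equal(first[[1]]$ca[1, 1], 1.458)
})

test_that("write/read round trip preserves coordinates to PDB precision", {
  ch <- build_peptide(8, phi = c(-120, -120, -60, -60, 80, -120, -120, -120),
                      psi = c(120, 120, -30, 120, 0, 120, 120, 120))
  back <- read_backbone(write_backbone(ch))[[1]]
  for (atom in c("n", "ca", "c", "o"))
    expect_lt(max(abs(back[[atom]] - ch[[atom]])), 5e-4 + 1e-12)
  expect_equal(back$resno, ch$resno)
  expect_equal(back$resname, ch$resname)
})

test_that("4-digit residue numbers keep the columns aligned", {
  ch <- build_peptide(2, -60, -45, start_resno = 9998)
  lines <- write_backbone(ch)
  atom_lines <- lines[startsWith(lines, "ATOM")]
  expect_true(all(nchar(atom_lines) == 78))
  expect_equal(substr(atom_lines[1], 23, 26), "9998")
  back <- read_backbone(lines)[[1]]
  expect_equal(back$resno, c(9998L, 9999L))
})

test_that("chain breaks are detected from the C-N distance", {
  ch <- build_peptide(6, -120, 120)
  # pull the last three residues 10 angstroms away: bond 3-4 breaks
  shift <- matrix(rep(c(10, 0, 0), each = 3), 3, 3)
  for (atom in c("n", "ca", "c", "o")) ch[[atom]][4:6, ] <- ch[[atom]][4:6, ] + shift
  ch2 <- backbone_chain("A", ch$resno, ch$resname, ch$n, ch$ca, ch$c, ch$o)
  expect_equal(ch2$bonded, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  tors <- compute_torsions(ch2)
  expect_true(is.na(tors$phi[4]) && is.na(tors$psi[3]) && is.na(tors$omega[4]))
  expect_false(anyNA(tors$phi[2:3]))
})
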