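test_that("the cleavage-site-region torsion quadruple is a type II turn", {
  cls <- classify_turn(-58.86, 126.78, 79.02, -24.45, omega2_cis = FALSE)
  expect_equal(cls$type, "II")
  expect_false(cls$relaxed)
})

test_that("canonical angles of every named type classify as that type", {
  tab <- turn_type_table()
  for (r in seq_len(nrow(tab))) {
    cls <- classify_turn(tab$phi1[r], tab$psi1[r], tab$phi2[r], tab$psi2[r],
                         omega2_cis = tab$cis[r])
    expect_equal(cls$type, tab$type[r])
    expect_false(cls$relaxed)
  }
})

test_that("windows matching no canonical type fall into IV", {
  # confirmed by the brute-force matcher
  expect_equal(oracle_classify(0, 0, 0, 0)$type, "IV")
  expect_equal(classify_turn(0, 0, 0, 0)$type, "IV")
  expect_error(classify_turn(NA, 0, 0, 0), "defined")
})

test_that("classification agrees with a brute-force matcher on random quadruples", {
  set.seed(31)
  for (i in 1:1000) {
    a <- runif(4, -180, 180)
    cis <- runif(1) < 0.3
    got <- classify_turn(a[1], a[2], a[3], a[4], omega2_cis = cis)
    want <- oracle_classify(a[1], a[2], a[3], a[4], cis = cis)
    expect_identical(got, want)
  }
})

test_that("classification is invariant to full 360-degree wraps", {
  set.seed(32)
  for (i in 1:100) {
    a <- runif(4, -180, 180)
    wrapped <- a + sample(c(-360, 0, 360, 720), 4, replace = TRUE)
    expect_identical(classify_turn(a[1], a[2], a[3], a[4]),
                     classify_turn(wrapped[1], wrapped[2], wrapped[3], wrapped[4]))
  }
})

test_that("cis-requiring types need a cis peptide bond", {
  tab <- turn_type_table()
  r <- which(tab$type == "VIb")
  cls_trans <- classify_turn(tab$phi1[r], tab$psi1[r], tab$phi2[r], tab$psi2[r],
                             omega2_cis = FALSE)
  expect_false(cls_trans$type == "VIb")
  cls_cis <- classify_turn(tab$phi1[r], tab$psi1[r], tab$phi2[r], tab$psi2[r],
                           omega2_cis = TRUE)
  expect_equal(cls_cis$type, "VIb")
})

test_that("an ideal type-II turn is detected exactly once", {
  ch <- build_type2_turn_peptide(n_res = 8, turn_i = 3)
  turns <- detect_turns(ch)
  expect_equal(nrow(turns), 1)
  expect_equal(turns$i_resno, 3)
  expect_equal(turns$type, "II")
  expect_false(turns$relaxed)
  expect_lt(turns$ca_dist, 7)
  expect_lt(turns$o_n_dist, 3.5)
})

test_that("the CA(i)-CA(i+3) cutoff excludes wide windows", {
  ch <- build_type2_turn_peptide()
  d <- atom_distance(ch$ca[3, ], ch$ca[6, ])
  expect_equal(nrow(detect_turns(ch, ca_cutoff = d - 0.1)), 0)
  # a fully extended chain has no window under the default cutoff
  ext <- build_peptide(8, -120, 120)
  expect_equal(nrow(detect_turns(ext)), 0)
})

test_that("helix exclusion drops doubly-helical windows only on request", {
  helix <- build_peptide(8, -60, -45)
  with_hel <- detect_turns(helix, exclude_helical = FALSE)
  expect_gt(nrow(with_hel), 0)
  expect_equal(nrow(detect_turns(helix, exclude_helical = TRUE)), 0)
})

test_that("user extension rows in the type table take part in classification", {
  extra <- data.frame(type = "SC2-SC10", phi1 = -100, psi1 = -170,
                      phi2 = 60, psi2 = 35)
  tab <- turn_type_table(extra = extra)
  expect_equal(classify_turn(-100, -170, 60, 35, table = tab)$type, "SC2-SC10")
  # unchanged behaviour for windows matching a built-in type
  expect_equal(classify_turn(-60, 120, 80, 0, table = tab)$type, "II")
})

test_that("turn hydrogen-bond geometry handles prolines and missing atoms", {
  ch <- build_type2_turn_peptide(n_res = 8, turn_i = 3)
  hb <- turn_hbond(ch, 3)
  expect_true(is.finite(hb$o_n_dist) && is.finite(hb$o_h_dist))
  # direct coordinate arithmetic oracle for the O...N distance
  expect_equal(hb$o_n_dist, sqrt(sum((ch$o[3, ] - ch$n[6, ])^2)))
  # proline at i+3: no amide hydrogen, heavy-atom distance still returned
  ch_pro <- ch; ch_pro$resname[6] <- "PRO"
  hb_pro <- turn_hbond(ch_pro, 3)
  expect_true(is.na(hb_pro$o_h_dist))
  expect_equal(hb_pro$o_n_dist, hb$o_n_dist)
  # missing O(i) is an error
  ch_no_o <- ch; ch_no_o$o[3, ] <- NA_real_
  expect_error(turn_hbond(ch_no_o, 3), "missing atom")
})
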