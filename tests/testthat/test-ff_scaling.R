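# NBFIX generation: parsing, combination rules, lambda scaling, round trips.

test_that("parser reads type lines, tolerates dialect noise, reports errors", {
  txt <- c("* comment header", "*", "",
           "NONBONDED nbxmod 5 atom cdiel fshift -",
           "cutnb 14.0 ctofnb 12.0 ctonnb 10.0",
           "OTX  0.0  -0.1600  1.7000 ! water oxygen",
           "CA   0.0  -0.0700  1.9924 ! aromatic carbon",
           "CT3  0.0  -0.0780  2.0400 0.0 -0.01 1.9 ! with 1-4 columns",
           "END")
  p <- parse_charmm_nonbonded(txt)
  expect_length(p$types, 3L)
  expect_length(p$nbfix, 0L)
  expect_equal(p$types$OTX$epsilon, -0.16)
  expect_equal(p$types$OTX$rmin_half, 1.70)
  expect_equal(p$types$CT3$epsilon14, -0.01)

  expect_error(parse_charmm_nonbonded(
    c("NONBONDED", "CA 0.0 -0.07 1.9924", "CA 0.0 -0.08 2.0", "END")),
    "duplicate")
  expect_error(parse_charmm_nonbonded(
    c("NONBONDED", "CA 0.0 bad 1.99", "END")), "line 2")
  expect_warning(parse_charmm_nonbonded(
    c("NONBONDED", "CA 0.0 -0.07 1.99", "BONDS", "CA CA 300 1.5",
      "NBFIX", "CA CA -0.1 3.9", "END")), "skipping unknown section")
})

test_that("combination rules follow CHARMM conventions", {
  a <- atom_type_lj("A", -0.09, 2.0)
  b <- atom_type_lj("B", -0.16, 1.5)
  p <- combine_lj(a, b)
  expect_equal(p$epsilon_ij, -0.12)
  expect_equal(p$rmin_ij, 3.5)
  self <- combine_lj(a, a)
  expect_equal(self$epsilon_ij, a$epsilon)
  expect_equal(self$rmin_ij, 2 * a$rmin_half)
})

test_that("lambda scaling acts on epsilon only and is exactly invertible", {
  p <- pair_lj("A", "B", -0.12, 3.5)
  s <- scale_pair(p, 1.03)
  expect_equal(s$epsilon_ij, -0.1236)
  expect_equal(s$rmin_ij, p$rmin_ij)
  expect_identical(scale_pair(p, 1.0), p)
  back <- scale_pair(scale_pair(p, 1.09), 1 / 1.09)
  expect_equal(back$epsilon_ij, p$epsilon_ij, tolerance = 1e-12)
  expect_error(scale_pair(p, 0), "lambda")
  expect_error(scale_pair(p, -1), "lambda")
})

test_that("generate_nbfix emits the protein x water product, scaled", {
  p <- parse_charmm_nonbonded(fixture_prm())
  tab1 <- generate_nbfix(p$types, water_types = c("OT", "HT"), lam = 1.00)
  expect_s3_class(tab1, "nbfix_table")
  expect_length(tab1$entries, 3L * 2L)

  # lambda = 1 reproduces plain combination rules entry-wise
  df <- as.data.frame(tab1)
  for (i in seq_len(nrow(df))) {
    man <- combine_lj(p$types[[df$type_i[i]]], p$types[[df$type_j[i]]])
    expect_identical(df$epsilon_ij[i], man$epsilon_ij)
    expect_identical(df$rmin_ij[i], man$rmin_ij)
  }

  # epsilon strictly linear in lambda, rmin invariant
  tab3 <- generate_nbfix(p$types, water_types = c("OT", "HT"), lam = 1.03)
  tab9 <- generate_nbfix(p$types, water_types = c("OT", "HT"), lam = 1.09)
  e1 <- as.data.frame(tab1)$epsilon_ij
  expect_equal(as.data.frame(tab3)$epsilon_ij / e1, rep(1.03, 6),
               tolerance = 1e-12)
  expect_equal(as.data.frame(tab9)$epsilon_ij / as.data.frame(tab3)$epsilon_ij,
               rep(1.09 / 1.03, 6), tolerance = 1e-12)
  expect_identical(as.data.frame(tab3)$rmin_ij, as.data.frame(tab1)$rmin_ij)

  expect_error(generate_nbfix(p$types, protein_types = "NOPE",
                              water_types = "OT"), "NOPE")
  expect_error(generate_nbfix(p$types, protein_types = c("CP1", "OT"),
                              water_types = "OT"), "overlap")
})

test_that("stream writer round-trips byte-stably and parsing inverts it", {
  p <- parse_charmm_nonbonded(fixture_prm())
  tab <- generate_nbfix(p$types, water_types = c("OT", "HT"), lam = 1.03,
                        provenance = "fixture")
  txt <- write_nbfix_stream(tab)
  expect_length(grep("^NBFIX$", txt), 1L)
  body <- txt[(grep("^NBFIX$", txt) + 1L):(grep("^END$", txt) - 2L)]
  expect_length(body, 6L)

  reparsed <- parse_charmm_nonbonded(txt)
  expect_length(reparsed$nbfix, 6L)
  got <- reparsed$nbfix[order(vapply(reparsed$nbfix,
                                     function(x) paste(x$type_i, x$type_j), ""))]
  for (i in seq_along(got)) {
    expect_identical(got[[i]]$type_i, tab$entries[[i]]$type_i)
    expect_lt(abs(got[[i]]$epsilon_ij - tab$entries[[i]]$epsilon_ij),
              1e-6)   # format precision: 6 decimals
  }

  # write -> parse -> rebuild -> write is byte-identical
  tab2 <- tab
  tab2$entries <- reparsed$nbfix[order(vapply(reparsed$nbfix,
                                              function(x) paste(x$type_i, x$type_j), ""))]
  expect_identical(write_nbfix_stream(tab2), txt)

  empty <- tab; empty$entries <- list()
  expect_error(write_nbfix_stream(empty), "empty")
})

test_that("duplicate NBFIX pairs in input resolve last-wins with warning", {
  txt <- c("NBFIX", "A B -0.1 3.0", "B A -0.2 3.1", "END")
  expect_warning(p <- parse_charmm_nonbonded(txt), "last wins")
  expect_length(p$nbfix, 1L)
  expect_equal(p$nbfix[[1L]]$epsilon_ij, -0.2)
})
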