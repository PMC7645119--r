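test_that("composition descriptors match brute-force counting", {
  expect_equal(unname(aac("AAAA")[1]), 1)
  expect_equal(sum(aac("AAAA")[-1]), 0)
  expect_equal(unname(aac("ACAC")[c("AAC_A", "AAC_C")]), c(0.5, 0.5),
               ignore_attr = TRUE)
  expect_equal(unname(dpc("ACAC")[c("DPC_AC", "DPC_CA")]), c(2 / 3, 1 / 3))
  expect_equal(unname(dpc("AA")["DPC_AA"]), 1)
  expect_equal(unname(gaac_gdpc("GK")[c("GAAC_aliphatic", "GAAC_positive")]),
               c(0.5, 0.5))
  expect_equal(unname(gaac_gdpc("DDDD")["GAAC_negative"]), 1)

  set.seed(101)
  for (len in c(60, 100, 200)) {
    s <- random_protein(len)
    expect_equal(unname(aac(s)), unname(oracle_aac(s)), tolerance = 1e-12)
    expect_equal(unname(dpc(s)), oracle_dpc(s), tolerance = 1e-12)
    expect_equal(unname(gaac_gdpc(s)), oracle_gaac_gdpc(s),
                 tolerance = 1e-12)
    expect_equal(sum(aac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(dpc(s)), 1, tolerance = 1e-9)
  }
})

test_that("ctd matches an independent scan and its worked examples", {
  v <- ctd("LLLL")
  comp <- v[grep("^CTDC_", names(v))]
  for (attr_name in names(cellopt:::CTD_GROUPS)) {
    cells <- comp[grep(attr_name, names(comp))]
    expect_equal(sum(cells == 1), 1)
    expect_equal(sum(cells), 1)
  }
  expect_true(all(v[grep("^CTDT_", names(v))] == 0))

  # group occurring only at position 1 of a 10-mer: all percentiles 10.0
  v <- ctd("CAAAAAAAAA")  # C alone in hydrophobicity g3
  d <- v[grep("^CTDD_hydrophobicity_g3_", names(v))]
  expect_equal(unname(d), rep(10, 5))

  set.seed(55)
  s <- random_protein(80)
  expect_equal(unname(ctd(s)), oracle_ctd(s), tolerance = 1e-12)
})

test_that("conjoint triad matches brute force", {
  v <- conjoint_triad("ARD")  # classes 1, 5, 6
  expect_equal(sum(v != 0), 1)
  expect_equal(unname(v["CT_156"]), 1)
  v <- conjoint_triad("AAAAA")
  expect_equal(unname(v["CT_111"]), 1)
  set.seed(77)
  s <- random_protein(60)
  expect_equal(unname(conjoint_triad(s)), oracle_ct(s), tolerance = 1e-12)
})

test_that("paac limits and oracle agreement", {
  # homopolymer: all theta 0, first 20 entries reduce to plain AAC
  v <- paac("LLLLLLLL", lambda = 3)
  expect_equal(unname(v[1:20]), unname(aac("LLLLLLLL")), tolerance = 1e-12)
  expect_equal(unname(v[21:23]), rep(0, 3))
  # w = 0: identical to aac padded with zeros
  s <- "MKVLIACDEF"
  v <- paac(s, lambda = 2, w = 0)
  expect_equal(unname(v[1:20]), unname(aac(s)), tolerance = 1e-12)
  expect_equal(unname(v[21:22]), c(0, 0))
  # independent reimplementation
  expect_equal(unname(paac("MKVLI", lambda = 2, w = 0.05)),
               oracle_paac("MKVLI", 2, 0.05), tolerance = 1e-12)
  set.seed(9)
  s <- random_protein(40)
  expect_equal(unname(paac(s, 4, 0.05)), oracle_paac(s, 4, 0.05),
               tolerance = 1e-12)
  expect_error(paac("MKV", lambda = 4), "lower lam")
})

test_that("atom and bond composition follow the embedded formulas", {
  g <- atom_bond("G")  # glycine C2H5NO2
  expect_equal(unname(g[1:5]), c(2, 5, 1, 2, 0) / 10)
  expect_equal(unname(atom_bond("GG")), unname(atom_bond("G")))
  set.seed(4)
  s <- random_protein(30)
  expect_equal(sum(atom_bond(s)[1:5]), 1, tolerance = 1e-12)
  # tryptophan C11H12N2O2: 27 atoms, 2 rings -> 27 - 1 + 2 = 28 bonds
  w <- atom_bond("W")
  expect_equal(unname(w["BOND_aromatic"]), 2)
  expect_equal(unname(w["BOND_total"]), 28)
})

test_that("featurize assembles the documented 973-column default vector", {
  rec <- data.frame(id = c("a", "b"),
                    seq = c(strrep("ACDEFGHIKLMNPQRSTVWY", 2),
                            strrep("ACDEFGHIKLMNPQRSTVWY", 2)))
  fm <- featurize(rec)
  expect_equal(dim(fm), c(2L, 973L))
  expect_false(anyDuplicated(colnames(fm$data)) > 0)
  expect_equal(fm$data[1, ], fm$data[2, ])  # identical sequences

  empty <- featurize(rec[0, ])
  expect_equal(dim(empty), c(0L, 973L))

  short <- data.frame(id = "tiny", seq = "MKV")
  expect_error(featurize(short), "tiny")

  # row order follows input; values independent of other rows
  set.seed(12)
  rec3 <- data.frame(id = c("x", "y", "z"),
                     seq = replicate(3, random_protein(50)))
  fm3 <- featurize(rec3)
  fm_rev <- featurize(rec3[3:1, ])
  expect_equal(fm3$data["y", ], fm_rev$data["y", ])
  expect_equal(rownames(fm_rev$data), c("z", "y", "x"))
})

test_that("composition blocks sum to 1 on random sequences", {
  set.seed(2)
  for (rep in 1:5) {
    s <- random_protein(sample(30:120, 1))
    fm <- featurize(data.frame(id = "q", seq = s))
    v <- fm$data[1, ]
    expect_true(all(is.finite(v)))
    for (prefix in c("^AAC_", "^DPC_", "^GAAC_", "^GDPC_", "^CT_"))
      expect_equal(sum(v[grep(prefix, names(v))]), 1, tolerance = 1e-9)
    for (attr_name in names(cellopt:::CTD_GROUPS))
      expect_equal(sum(v[grep(paste0("^CTDC_", attr_name), names(v))]), 1,
                   tolerance = 1e-9)
    expect_equal(sum(v[grep("^ATOM_", names(v))]), 1, tolerance = 1e-9)
  }
})

test_that("drop_duplicate_columns keeps first occurrences only", {
  set.seed(31)
  m <- matrix(rnorm(30 * 45), 30, 45)
  m <- cbind(m, m[, c(3, 8, 11, 20, 44)])  # plant 5 duplicates
  colnames(m) <- paste0("c", 1:50)
  fm <- drop_duplicate_columns(fm_from_matrix(m))
  expect_equal(ncol(fm$data), 45L)
  expect_equal(colnames(fm$data), paste0("c", 1:45))

  distinct <- fm_from_matrix(matrix(rnorm(20), 5, 4))
  expect_equal(drop_duplicate_columns(distinct)$data, distinct$data)
})

test_that("min-max scaler honours its contract", {
  m <- fm_from_matrix(cbind(a = c(0, 5, 10), b = c(2, 2, 2),
                            c = c(-1, 0, 3)))
  st <- fit_scaler(m)
  sc <- apply_scaler(st, m)
  expect_equal(unname(sc$data[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(sc$data[, "b"]), c(0, 0, 0))  # constant column
  expect_equal(min(sc$data[, "c"]), 0)
  expect_equal(max(sc$data[, "c"]), 1)

  test <- fm_from_matrix(cbind(a = 12, b = 5, c = 1))
  expect_equal(unname(apply_scaler(st, test)$data[1, "a"]), 1.2)  # no clip

  wrong <- fm_from_matrix(cbind(a = 1:3, z = 1:3))
  expect_error(apply_scaler(st, wrong), "column names")
  expect_error(apply_scaler(structure(list(), class = "x"), m), "not fitted")
  expect_error(fit_scaler(fm_from_matrix(matrix(1, 1, 2))))
})
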