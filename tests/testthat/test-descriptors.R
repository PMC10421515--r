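p3 <- path_graph(c("C", "C", "C"))     # weights supplied explicitly below
p2 <- path_graph(c("C", "C"))

test_that("ATSC matches hand computations on tiny graphs", {
  # all-equal weights: centering kills every lag
  for (k in 1:3) expect_identical(atsc(p3, k, c(2, 2, 2)), 0)
  # 3-atom path, weights (1,2,3): lag 1 -> 0, lag 2 -> -1
  expect_equal(atsc(p3, 1, c(1, 2, 3)), 0)
  expect_equal(atsc(p3, 2, c(1, 2, 3)), -1)
  # no pair at the lag -> 0
  expect_identical(atsc(p3, 5, c(1, 2, 3)), 0)
})

test_that("MATS matches hand computations and flags undefined cases", {
  expect_equal(mats(p3, 1, c(1, 2, 3)), 0)
  expect_equal(mats(p2, 1, c(1, 3)), -1)
  expect_error(mats(p3, 1, c(4, 4, 4)),
               class = "plqsar_undefined_descriptor")
  expect_error(mats(p3, 9, c(1, 2, 3)),
               class = "plqsar_undefined_descriptor")
})

test_that("GATS matches hand computations, is non-negative, flags undefined", {
  expect_equal(gats(p3, 1, c(1, 2, 3)), 0.5)
  expect_equal(gats(p2, 1, c(1, 3)), 1)
  # all atoms the same element -> zero variance under any scheme
  expect_error(gats(p3, 1, "electronegativity"),
               class = "plqsar_undefined_descriptor")
  for (s in 1:20) {
    g <- random_graph(sample(3:10, 1L), seed = 300 + s)
    v <- tryCatch(gats(g, sample(1:3, 1L), "electronegativity"),
                  plqsar_undefined_descriptor = function(e) NULL)
    if (!is.null(v)) expect_gte(v, 0)
  }
})

test_that("Burden matrix eigenvalues match the closed-form 2-atom case", {
  # two bonded carbons, both terminal: [[1, 0.11], [0.11, 1]]
  expect_equal(burden_spmin(p2, 1, "ionization"), 0.89, tolerance = 1e-12)
  expect_equal(burden_spmin(p2, 2, "ionization"), 1.11, tolerance = 1e-12)
  single <- molecular_graph(
    data.frame(element = "C", charge = 0L, hcount = 4L),
    data.frame(i = integer(), j = integer(), order = numeric()), "CH4")
  expect_equal(burden_spmin(single, 1, "ionization"), 1)
  expect_error(burden_spmin(p2, 3, "ionization"),
               class = "plqsar_undefined_descriptor")
})

test_that("VR2_D matches the closed-form 2-atom value", {
  expect_equal(vr_d(p2, 2), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(vr_d(p2, 1), sqrt(2), tolerance = 1e-12)
})

test_that("descriptors equal independent brute-force oracles on random graphs", {
  schemes <- c("electronegativity", "polarizability", "ionization")
  n_checked <- 0L
  for (s in 1:60) {
    g <- random_graph(sample(3:12, 1L), seed = 400 + s,
                      elements = c("C", "N", "O", "S", "Cl"))
    sc <- schemes[1L + (s %% 3L)]
    k <- 1L + (s %% 3L)
    expect_equal(atsc(g, k, sc), oracle_atsc(g, k, sc), tolerance = 1e-10)
    mo <- oracle_mats(g, k, sc)
    if (!is.na(mo))
      expect_equal(mats(g, k, sc), mo, tolerance = 1e-10)
    go <- oracle_gats(g, k, sc)
    if (!is.na(go))
      expect_equal(gats(g, k, sc), go, tolerance = 1e-10)
    rk <- min(nrow(g$atoms), 1L + (s %% 4L))
    expect_equal(burden_spmin(g, rk, sc),
                 oracle_burden_spmin(g, rk, sc), tolerance = 1e-10)
    expect_equal(vr_d(g, 2), oracle_vr2_d(g), tolerance = 1e-10)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 50L)
  # benzene under the ionization weighting against the eigen oracle
  b <- parse_smiles("c1ccccc1", "benzene")
  expect_equal(burden_spmin(b, 1, "ionization"),
               oracle_burden_spmin(b, 1, "ionization"), tolerance = 1e-10)
})

test_that("descriptors are invariant under atom relabelling", {
  for (s in 1:12) {
    g <- random_graph(sample(4:10, 1L), seed = 500 + s,
                      elements = c("C", "N", "O"))
    n <- nrow(g$atoms)
    perm <- sample(n)
    g2 <- molecular_graph(
      g$atoms[order(perm), , drop = FALSE],
      data.frame(i = perm[g$bonds$i], j = perm[g$bonds$j],
                 order = g$bonds$order), "perm")
    expect_equal(atsc(g2, 2, "electronegativity"),
                 atsc(g, 2, "electronegativity"), tolerance = 1e-12)
    expect_equal(burden_spmin(g2, 2, "ionization"),
                 burden_spmin(g, 2, "ionization"), tolerance = 1e-10)
    expect_equal(vr_d(g2, 2), vr_d(g, 2), tolerance = 1e-10)
    m1 <- tryCatch(mats(g, 1, "polarizability"),
                   plqsar_undefined_descriptor = function(e) NULL)
    if (!is.null(m1))
      expect_equal(mats(g2, 1, "polarizability"), m1, tolerance = 1e-12)
  }
})

test_that("descriptor values are bit-identical across repeated evaluation", {
  g <- parse_smiles("O=c1c(-c2ccc(O)cc2)coc2cc(O)ccc12", "daidzein")
  for (nm in reference_descriptor_names()) {
    s <- parse_descriptor_name(nm)
    v1 <- plqsar:::compute_descriptor(g, s)
    v2 <- plqsar:::compute_descriptor(g, s)
    expect_identical(v1, v2)
  }
})

test_that("canonical descriptor names round-trip through the parser", {
  for (nm in c("MATS1p", "ATSC6e", "GATS2p", "SpMin8_Bhi", "VR2_D",
               "ATSC3Z", "GATS5i", "SpMin1_Bhe")) {
    expect_equal(parse_descriptor_name(nm)$name, nm)
  }
  expect_error(parse_descriptor_name("BANANA3"), "cannot parse")
  expect_equal(descriptor_spec("MATS", 1, "polarizability")$name, "MATS1p")
})

test_that("descriptor matrix builder masks failures and keeps order", {
  mols <- list(parse_smiles("CCO", "ethanol"),
               path_graph(c("C", "C", "C")),     # zero EN variance
               parse_smiles("O=c1c(-c2ccc(O)cc2)coc2cc(O)ccc12", "daidzein"))
  m <- compute_descriptor_matrix(mols, c("MATS1e", "GATS1e", "VR2_D"))
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(rownames(m), c("ethanol", "CCC", "daidzein"))
  expect_true(is.na(m["CCC", "MATS1e"]) && is.na(m["CCC", "GATS1e"]))
  expect_false(anyNA(m["daidzein", ]))
  fails <- attr(m, "failures")
  expect_setequal(fails$descriptor[fails$id == "CCC"],
                  c("MATS1e", "GATS1e"))
  expect_error(compute_descriptor_matrix(list(), "MATS1e"), "no molecules")
  expect_error(compute_descriptor_matrix(mols, character(0)), "no descriptor")
  expect_error(compute_descriptor_matrix(list(mols[[1L]], mols[[1L]]),
                                         "MATS1e"), "duplicate compound")
})

test_that("reference descriptor set is defined for all 40 benchmark flavonoids", {
  bench <- load_pl_benchmark()
  mols <- parse_smiles(bench$smiles$smiles, bench$smiles$id)
  m <- compute_descriptor_matrix(mols, reference_descriptor_names())
  expect_equal(dim(m), c(40L, 5L))
  expect_false(anyNA(m))
  expect_equal(colnames(m),
               c("MATS1p", "ATSC6e", "GATS2p", "SpMin8_Bhi", "VR2_D"))
})
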