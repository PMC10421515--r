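fp_of <- function(smiles, id = smiles) morgan_fingerprint(
  parse_smiles(smiles, id))

test_that("equivalent SMILES spellings give identical fingerprints", {
  expect_identical(fp_of("OCC", "a")$bits, fp_of("CCO", "b")$bits)
  expect_identical(fp_of("c1ccccc1", "a")$bits,
                   fp_of("C1=CC=CC=C1", "b")$bits)
  expect_false(identical(fp_of("C", "m")$bits, fp_of("c1ccccc1", "b")$bits))
  f <- fp_of("O=c1cc(-c2ccccc2)oc2ccccc12", "flavone")
  expect_gte(length(f$bits), 1L)
  expect_equal(tanimoto(f, f), 1)
})

test_that("tanimoto obeys hand counts, symmetry and range", {
  mk <- function(bits, id) structure(
    list(bits = as.integer(bits), nbits = 2048L, id = id),
    class = "fingerprint")
  expect_equal(tanimoto(mk(c(1, 2, 3), "a"), mk(c(2, 3, 4), "b")), 0.5)
  expect_equal(tanimoto(mk(1:3, "a"), mk(1:3, "b")), 1)
  expect_equal(tanimoto(mk(1:3, "a"), mk(4:6, "b")), 0)
  expect_equal(tanimoto(mk(integer(), "a"), mk(integer(), "b")), 0)
  expect_error(tanimoto(mk(1, "a"),
                        structure(list(bits = 1L, nbits = 1024L, id = "c"),
                                  class = "fingerprint")),
               "length mismatch")
  set.seed(77)
  for (r in 1:200) {
    a <- mk(sample.int(2048, sample(1:60, 1)), "a")
    b <- mk(sample.int(2048, sample(1:60, 1)), "b")
    s <- tanimoto(a, b)
    expect_identical(s, tanimoto(b, a))
    expect_true(s >= 0 && s <= 1)
    expect_equal(tanimoto(a, a), 1)
  }
})

test_that("mini-batch k-means: k = 1 centroid, determinism, family purity", {
  lib <- sim_screening_library(n_decoys = 12, n_planted = 8, seed = 5)
  fps <- lapply(seq_len(nrow(lib$library)), function(k)
    morgan_fingerprint(parse_smiles(lib$library$smiles[k],
                                    lib$library$id[k])))
  one <- cluster_library(fps, k = 1, seed = 3)
  expect_true(all(one$cluster == 1L))
  m <- plqsar:::fingerprint_matrix(fps)
  expect_equal(unname(one$centroids[1L, ]), unname(colMeans(m)))

  a <- cluster_library(fps, k = 4, seed = 9)
  b <- cluster_library(fps, k = 4, seed = 9)
  expect_identical(a$cluster, b$cluster)
  expect_gte(a$inertia, 0)
  expect_error(cluster_library(fps, k = length(fps) + 1L, seed = 1),
               "exceeds")

  # two well-separated families cluster with 100% purity
  fam <- c(lapply(c("CCCCCCCCCC", "CCCCCCCCCCC", "CCCCCCCCC"), fp_of),
           lapply(c("Oc1ccc(-c2coc3cc(O)ccc3c2=O)cc1",
                    "COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1",
                    "Oc1ccc(-c2coc3cc(O)cc(O)c3c2=O)cc1"), fp_of))
  cl <- cluster_library(fam, k = 2, seed = 11)
  expect_equal(length(unique(cl$cluster[1:3])), 1L)
  expect_equal(length(unique(cl$cluster[4:6])), 1L)
  expect_false(cl$cluster[1L] == cl$cluster[4L])
})

test_that("enrichment retains exactly the high-similarity compounds", {
  seeds <- lapply(c("c1ccccc1", "CCOCC"), fp_of)
  hits <- enrich_library(seeds, seeds, threshold = 0.8)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$fs == 1))
  # strict threshold 1.0 excludes everything, even self-matches
  none <- enrich_library(seeds, seeds, threshold = 1.0)
  expect_equal(nrow(none), 0L)
  expect_error(enrich_library(list(), seeds), "empty seed")
})

test_that("planted near-duplicates are recovered with perfect recall/precision", {
  lib <- sim_screening_library(n_decoys = 40, n_planted = 10, seed = 31)
  seeds <- lapply(seq_len(nrow(lib$seeds)), function(k)
    morgan_fingerprint(parse_smiles(lib$seeds$smiles[k], lib$seeds$id[k])))
  fps <- lapply(seq_len(nrow(lib$library)), function(k)
    morgan_fingerprint(parse_smiles(lib$library$smiles[k],
                                    lib$library$id[k])))
  hits <- enrich_library(seeds, fps, threshold = 0.8)
  planted <- lib$library$id[lib$library$role == "planted"]
  expect_setequal(hits$id, planted)
  # library-order invariance
  perm <- sample(seq_along(fps))
  hits2 <- enrich_library(seeds, fps[perm], threshold = 0.8)
  expect_setequal(hits2$id, hits$id)
  expect_equal(hits2$fs[order(hits2$id)], hits$fs[order(hits$id)])
  # hit count is monotone non-increasing in the threshold
  counts <- vapply(c(0.2, 0.5, 0.8, 0.9, 1.0), function(th)
    nrow(enrich_library(seeds, fps, threshold = th)), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("ranking is deterministic, converts units and drops masked hits", {
  hits <- data.frame(id = c("b", "a", "c", "d"),
                     seed_id = "s", fs = c(0.9, 0.9, 0.95, 0.85),
                     cluster = 1L)
  class(hits) <- c("screening_hits", "data.frame")
  desc <- matrix(c(0.5, 0.5, 0.2, NA), 4, 1,
                 dimnames = list(c("a", "b", "c", "d"), "MATS1p"))
  model <- qsar_model(4, c(MATS1p = 2))
  ranked <- rank_candidates(hits, model, desc)
  expect_equal(ranked$id, c("a", "b", "c"))          # tie a/b by id
  expect_equal(ranked$pic50_pre, c(5, 5, 4.4))
  expect_equal(ranked$ic50_pre_uM, 10^(6 - ranked$pic50_pre),
               tolerance = 1e-12)
  expect_equal(attr(ranked, "dropped")$id, "d")
  top <- rank_candidates(hits, model, desc, top_n = 2)
  expect_equal(nrow(top), 2L)
  # input-order invariance
  ranked2 <- rank_candidates(hits[c(3, 1, 4, 2), ], model, desc)
  expect_equal(ranked2$id, ranked$id)
  # round-trip pIC50 -> IC50 -> pIC50
  expect_equal(pic50_from_ic50(ranked$ic50_pre_uM), ranked$pic50_pre,
               tolerance = 1e-9)
})

test_that("ADMET annotation is a pure keyed join", {
  ranked <- data.frame(id = c("x", "y"), seed_id = "s", fs = 0.9,
                       cluster = 1L, pic50_pre = c(6, 5),
                       ic50_pre_uM = c(1, 10))
  class(ranked) <- c("screening_hits", "data.frame")
  out <- annotate_admet(ranked, data.frame(id = character()))
  expect_equal(out$id, ranked$id)
  ann <- data.frame(id = c("x", "zzz"), carcino_rat = c("negative", "bad"))
  out2 <- annotate_admet(ranked, ann)
  expect_equal(out2$carcino_rat, c("negative", NA))
  expect_equal(attr(out2, "unmatched"), "zzz")
  expect_error(annotate_admet(ranked, rbind(ann, ann)), "duplicate")
})

test_that("benchmark candidates annotate onto a ranked list", {
  bench <- load_pl_benchmark()
  cand <- bench$candidates
  ranked <- data.frame(id = cand$id, seed_id = "seed", fs = 0.9,
                       cluster = 1L,
                       pic50_pre = pic50_from_ic50(cand$ic50_pre_uM),
                       ic50_pre_uM = cand$ic50_pre_uM)
  class(ranked) <- c("screening_hits", "data.frame")
  out <- annotate_admet(ranked, cand[, c("id", "carcino_rat", "log_kp")])
  expect_equal(nrow(out), 5L)
  expect_equal(out$carcino_rat[out$id == "CNP0286940"], "negative")
})
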