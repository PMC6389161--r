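test_that("amino-acid composition: homopolymer, uniform, normalization", {
  v <- aaComposition(strrep("A", 40))
  expect_equal(unname(v[["AAC.A"]]), 1)
  expect_equal(sum(v), 1)
  u <- aaComposition(strrep(paste(AA20, collapse = ""), 2))
  expect_true(all(abs(u - 0.05) < 1e-12))
  for (seed in 1:5)
    expect_equal(sum(aaComposition(randSeq(80, seed))), 1, tolerance = 1e-12)
})

test_that("dipeptide composition counts adjacent pairs over L - 1", {
  v <- dipeptideComposition("ACACAC")
  expect_equal(unname(v[["DPC.AC"]]), 3 / 5)
  expect_equal(unname(v[["DPC.CA"]]), 2 / 5)
  expect_equal(sum(v), 1)
  h <- dipeptideComposition(strrep("A", 40))
  expect_equal(unname(h[["DPC.AA"]]), 1)
  for (seed in 1:5)
    expect_equal(sum(dipeptideComposition(randSeq(60, seed))), 1,
                 tolerance = 1e-12)
})

test_that("grouped C/T/D features: length, homopolymer, charge-class runs", {
  v <- ctdFeatures(strrep("A", 40))
  expect_length(v, 336L)
  # A is in the neutral charge class (c2): composition 1, no transitions,
  # one run covering the chain
  expect_equal(unname(v[["CTD.charge.comp.c2"]]), 1)
  expect_equal(unname(v[["CTD.charge.trans.c1c2"]]), 0)
  expect_equal(unname(v[["CTD.charge.seg.c2.longest"]]), 1)

  # K and R share the positive class: KRKR... is one positive run
  kr <- ctdFeatures(strrep("KR", 15))
  expect_equal(unname(kr[["CTD.charge.comp.c1"]]), 1)
  expect_equal(unname(kr[["CTD.charge.seg.c1.count"]]), 1 / 30)
  expect_equal(unname(kr[["CTD.charge.seg.c1.longest"]]), 1)
})

test_that("C/T/D composition triples sum to 1 and positions lie in [0,1]", {
  for (seed in 1:5) {
    v <- ctdFeatures(randSeq(100, seed))
    for (prop in names(propertyAlphabets())) {
      comp <- v[paste0("CTD.", prop, ".comp.c", 1:3)]
      expect_equal(sum(comp), 1, tolerance = 1e-9)
    }
    dist <- v[grep("\\.dist\\.", names(v))]
    expect_true(all(dist >= 0 & dist <= 1))
  }
})

test_that("each property alphabet partitions the 20 residues", {
  for (alpha in propertyAlphabets()) {
    all_aa <- sort(unlist(alpha, use.names = FALSE))
    expect_identical(all_aa, AA20)
  }
})

test_that("residue-index features: 448 values, constant chain, bracketing", {
  tables <- residueIndexTables()
  expect_equal(dim(tables), c(20L, 64L))
  v <- aaindexFeatures(strrep("A", 40), tables)
  expect_length(v, 448L)
  first <- tables["A", 1]
  expect_true(all(abs(v[1:7] - first) < 1e-12))
  # window minima/maxima bracket the whole-sequence mean
  for (seed in 1:3) {
    v <- aaindexFeatures(randSeq(70, seed), tables)
    for (acc in colnames(tables)) {
      mean_ <- v[[paste0("AAIDX.", acc, ".mean")]]
      for (w in c(5, 15, 31)) {
        expect_lte(v[[paste0("AAIDX.", acc, ".min.w", w)]], mean_ + 1e-12)
        expect_gte(v[[paste0("AAIDX.", acc, ".max.w", w)]], mean_ - 1e-12)
      }
    }
  }
})

test_that("windows longer than the chain degrade to one whole-chain window", {
  tables <- residueIndexTables()
  s <- randSeq(30, 20)
  v <- aaindexFeatures(s, tables)
  for (acc in colnames(tables)[1:5]) {
    expect_equal(v[[paste0("AAIDX.", acc, ".min.w31")]],
                 v[[paste0("AAIDX.", acc, ".mean")]])
    expect_equal(v[[paste0("AAIDX.", acc, ".max.w31")]],
                 v[[paste0("AAIDX.", acc, ".mean")]])
  }
})

test_that("whole-chain physicochemical indices match closed forms", {
  expect_equal(unname(globalPhyschem(strrep("A", 40))[["PHYS.aliphatic"]]),
               100)
  expect_equal(unname(globalPhyschem(strrep("V", 40))[["PHYS.aliphatic"]]),
               290)
  # no ionizable side chains: pI is the midpoint of the terminal pKa values
  pka <- titrationPKa()
  pI <- globalPhyschem(strrep("G", 40))[["PHYS.pI"]]
  expect_equal(unname(pI), (pka[["Nterm"]] + pka[["Cterm"]]) / 2,
               tolerance = 2e-3)
  # instability of a 2-residue chain is 10/L times one table lookup
  diwv <- dipeptideInstabilityTable()
  expect_equal(unname(globalPhyschem("AWAW" )[["PHYS.instability"]]),
               10 / 4 * (2 * diwv["A", "W"] + diwv["W", "A"]))
  # net charge at pH 7 from the Henderson-Hasselbalch sum
  cnt <- c(Nterm = 1, Cterm = 1, K = 30)
  expected <- 1 / (1 + 10^(7 - pka[["Nterm"]])) +
    30 / (1 + 10^(7 - pka[["K"]])) - 1 / (1 + 10^(pka[["Cterm"]] - 7))
  expect_equal(unname(globalPhyschem(strrep("K", 30))[["PHYS.charge"]]),
               expected, tolerance = 1e-12)
})

test_that("disorder profile: per-residue, bounded, charge > hydrophobic", {
  s <- randSeq(50, 21)
  d <- disorderProfile(s)
  expect_length(d, 50L)
  expect_true(all(d >= 0 & d <= 1))
  dK <- disorderProfile(strrep("K", 50))
  dW <- disorderProfile(strrep("W", 50))
  expect_true(all(dK > dW))
})

test_that("an external per-residue score file overrides the built-in score", {
  s <- randSeq(40, 22)
  path <- tempfile()
  write.table(data.frame(pos = 1:40, score = seq(0, 1.5, length.out = 40)),
              path, row.names = FALSE, col.names = FALSE)
  d <- disorderProfile(s, scoreFile = path)
  expect_equal(max(d), 1)  # clipped
  expect_equal(d[1], 0)
  short <- tempfile()
  write.table(data.frame(pos = 1:10, score = runif(10)), short,
              row.names = FALSE, col.names = FALSE)
  expect_error(disorderProfile(s, scoreFile = short), "10 rows")
})

test_that("low-complexity mask: zero-entropy and max-entropy windows", {
  expect_true(all(lowComplexityMask(strrep("A", 40)) == 1L))
  # every window of the repeated full alphabet holds 12 distinct residues:
  # entropy log2(12) = 3.58 bits > 2.2
  s <- strrep(paste(AA20, collapse = ""), 3)
  expect_true(all(lowComplexityMask(s) == 0L))
  expect_length(lowComplexityMask(randSeq(55, 23)), 55L)
})

test_that("profile summary emits 34 statistics with documented extremes", {
  z <- profileSummary(rep(0, 50))
  expect_length(z, 34L)
  expect_equal(unname(z[["PROF.frac.above"]]), 0)
  expect_equal(unname(z[["PROF.mean"]]), 0)
  expect_true(all(z[grep("runcount|longest|coverage", names(z))] == 0))
  o <- profileSummary(rep(1, 50))
  expect_equal(unname(o[["PROF.coverage.m1"]]), 1)
  expect_equal(unname(o[["PROF.coverage.m10"]]), 1)
  expect_equal(unname(o[["PROF.longest.m1"]]), 1)
  expect_equal(unname(o[["PROF.pos.last"]]), 1)
})

test_that("the catalog has 1276 uniquely named entries in fixed groups", {
  cat_ <- featureCatalog()
  expect_equal(length(cat_), 1276L)
  expect_false(anyDuplicated(featureNames(cat_)) > 0)
  counts <- table(featureGroups(cat_))
  expect_equal(counts[["AAC"]], 420L)
  expect_equal(counts[["CLUSTER"]], 336L)
  expect_equal(counts[["AAPHYS"]], 448L)
  expect_equal(counts[["PROTPHYS"]], 4L)
  expect_equal(counts[["CXDIS"]], 68L)
  path <- tempfile(fileext = ".tsv")
  writeFeatureCatalog(cat_, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 1276L)
})

test_that("full extraction is deterministic and order-independent", {
  seqs <- c(a = randSeq(40, 24), b = randSeq(90, 25), c = randSeq(31, 26))
  f1 <- extractFeatures(seqs)
  f2 <- extractFeatures(seqs[c(3, 1, 2)])
  expect_identical(f1["b", ], f2["b", ])
  expect_identical(extractFeatures(seqs["a"]), extractFeatures(seqs["a"]))
  expect_equal(dim(f1), c(3L, 1276L))
  expect_true(all(is.finite(f1)))
})

test_that("permuting residues preserves composition but not dipeptides", {
  s <- randSeq(60, 27)
  set.seed(28)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(aaComposition(s), aaComposition(perm))
  expect_false(isTRUE(all.equal(dipeptideComposition(s),
                                dipeptideComposition(perm))))
})
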