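# Pipeline, classification, enumeration, proteome scan, PFM.

test_that("classification thresholds use the at-or-below tie rule", {
  cfg <- classifierConfig(loose = -0.4, stringent = -1.1)
  expect_identical(classifyScore(-1.2, cfg), "strong_binder")
  expect_identical(classifyScore(-1.1, cfg), "strong_binder")  # tie rule
  expect_identical(classifyScore(-0.7, cfg), "binder")
  expect_identical(classifyScore(-0.4, cfg), "binder")         # tie rule
  expect_identical(classifyScore(0.3, cfg), "non_binder")
  expect_identical(classifyScore(c(-2, 0), cfg),
                   c("strong_binder", "non_binder"))
  expect_error(classifierConfig(loose = -1.1, stringent = -0.4),
               "stringent")
})

test_that("Cxxx enumeration is complete, ordered and duplicate-free", {
  seqs <- enumerateCxxx()
  expect_identical(length(seqs), 8000L)
  expect_identical(seqs[1], "CAAA")
  expect_identical(anyDuplicated(seqs), 0L)
  expect_true(all(substr(seqs, 1, 1) == "C"))
  expect_true(all(nchar(seqs) == 4L))
  # set equality with a brute-force triple loop
  aa <- sort(names(caaxbind:::.AA3))
  brute <- character(0)
  for (x in aa) for (y in aa) for (z in aa)
    brute <- c(brute, paste0("C", x, y, z))
  expect_identical(seqs, brute)
})

test_that("the pipeline is deterministic and improves on the unminimized pose", {
  tpl <- toyTemplate()
  r1 <- scoreSequence(tpl, "CVIM", seed = 3)
  r2 <- scoreSequence(tpl, "CVIM", seed = 3)
  expect_identical(r1@score, r2@score)
  expect_identical(r1@classification, r2@classification)
  # packing + minimization never leaves the objective above the threaded
  # single-rotamer start
  expect_lte(r1@diagnostics$endEnergy, r1@diagnostics$startEnergy + 1e-9)
  # stage errors carry the stage name
  expect_error(scoreSequence(tpl, "AVIM"), "threading")
})

test_that("a complementary sequence outscores a charge-mismatched one", {
  tpl <- toyTemplate()
  good <- scoreSequence(tpl, "CVIM", seed = 1)
  bad <- scoreSequence(tpl, "CDKD", seed = 1)
  expect_lt(good@score, bad@score)
})

test_that("proteome scan extracts C-terminal Cxxx motifs with warnings for odd entries", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(
    ">sp|P001|HRAS_LIKE some description",
    "MTEYKLVVVGAGGVGKSALTIQLIQNHFVDEYDPTIEDSYRKQVKLNPPDESGPG",
    "CMSCKCVLS",
    ">sp|P002|NOMOTIF", "MKTAYIAKQRAVIM",
    ">sp|P003|SHORTY", "MKT",
    ">sp|P004|BADLETTER", "MKTAYIAKQRCVXS",
    ">sp|P005|LOWER", "mktayiakqrcvls"), fa)
  expect_warning(expect_warning(hits <- scanProteome(fa), "SHORTY"),
                 "BADLETTER")
  expect_setequal(hits$protein_id, c("sp|P001|HRAS_LIKE", "sp|P005|LOWER"))
  expect_identical(hits$motif[hits$protein_id == "sp|P001|HRAS_LIKE"],
                   "CVLS")
  expect_identical(hits$motif[hits$protein_id == "sp|P005|LOWER"], "CVLS")
  # line-wrapping invariance
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">sp|P001|HRAS_LIKE",
               "MTEYKLVVVGAGGVGKSALTIQLIQNHFVDEYDPTIEDSYRKQVKLNPPDESGPGCMSCKCVLS"),
             fa2)
  h2 <- scanProteome(fa2)
  expect_identical(h2$motif, "CVLS")
  expect_identical(h2$protein_length,
                   hits$protein_length[hits$protein_id ==
                                         "sp|P001|HRAS_LIKE"])
  # unique-motif report
  fa3 <- tempfile(fileext = ".fa")
  writeLines(c(">a", "MAAACVIM", ">b", "MAAAACVIM", ">c", "MCAAACSVQ"), fa3)
  u <- scanProteome(fa3, unique = TRUE)
  expect_identical(u$n_proteins[u$motif == "CVIM"], 2L)
  expect_identical(u$protein_ids[u$motif == "CVIM"], "a,b")
  expect_error(scanProteome(tempfile()), "unreadable FASTA")
})

test_that("position frequency matrices are normalized one-hot mixtures", {
  m1 <- positionFrequencyMatrix("CVIM")
  expect_equal(unname(colSums(m1)), rep(1, 4))
  expect_equal(m1["C", "C"], 1)
  expect_equal(m1["V", "a1"], 1)
  m2 <- positionFrequencyMatrix(c("CVIM", "CVLS"))
  expect_equal(m2["I", "a2"], 0.5)
  expect_equal(m2["L", "a2"], 0.5)
  expect_equal(unname(colSums(m2)), rep(1, 4))
  # pseudocounts keep columns normalized
  m3 <- positionFrequencyMatrix("CVIM", pseudocount = 1)
  expect_equal(unname(colSums(m3)), rep(1, 4))
  expect_error(positionFrequencyMatrix("AVIM"), "start with C")
})
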