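# Threading and rotamer packing.

test_that("threading preserves the template backbone exactly", {
  tpl <- toyTemplate()
  pepT <- atoms(templatePeptide(tpl))
  for (s in c("CNIQ", "CVIM", "CAAA")) {
    pose <- threadSequence(tpl, s)
    at <- pose@atoms
    for (i in seq_len(nrow(pepT))) {
      if (!(pepT$name[i] %in% c("N", "CA", "C", "O", "OXT"))) next
      j <- which(at$segment == "peptide" & at$resno == pepT$resno[i] &
                   at$name == pepT$name[i])
      expect_identical(pose@xyz[j, ],
                       c(pepT$x[i], pepT$y[i], pepT$z[i]))
    }
  }
})

test_that("threading replaces residue types and validates the sequence", {
  tpl <- toyTemplate()
  pose <- threadSequence(tpl, "CVIM")
  at <- pose@atoms[pose@atoms$segment == "peptide", ]
  types <- vapply(1:4, function(p) at$resn[at$pepPos == p][1], "")
  expect_identical(types, c("CYS", "VAL", "ILE", "MET"))
  expect_error(threadSequence(tpl, "AVIM"), "start with C")
  expect_error(threadSequence(tpl, "CVIX"), "non-standard")
  expect_error(threadSequence(tpl, "CVI"), "4-letter")
})

test_that("receptor and ligand coordinates pass through threading unchanged", {
  tpl <- toyTemplate()
  pose <- threadSequence(tpl, "CWLS")
  recT <- atoms(receptor(tpl))
  recRows <- which(pose@atoms$segment == "receptor")
  expect_identical(unname(pose@xyz[recRows, ]),
                   unname(as.matrix(recT[, c("x", "y", "z")])))
})

test_that("rotamer library covers all residue types with correct chi counts", {
  lib <- loadRotamerLibrary()
  nchi <- caaxbind:::.N_CHI
  for (resn in names(nchi)) {
    expect_identical(ncol(lib[[resn]]), as.integer(unname(nchi[resn])))
    expect_gte(nrow(lib[[resn]]), 1L)
  }
  expect_identical(ncol(lib$GLY), 0L)
  # extra-chi expansion adds +-10 degree sub-rotamers on chi1/chi2
  ex <- caaxbind:::.expandExtraChi(lib$LEU)
  expect_identical(nrow(ex), nrow(lib$LEU) * 9L)
  expect_true(all(c(-70, -50) %in% ex[, 1]))
})

test_that("exhaustive packing equals the brute-force minimum over the rotamer grid", {
  tpl <- toyTemplate()
  cst <- toyConstraints()
  ef <- defaultEnergyFunction()
  pose <- threadSequence(tpl, "CVLM")
  # one flexible position with a modest rotamer count
  packed <- packSidechains(pose, flexiblePositions = 3L, extraChi = FALSE,
                           energyFn = ef, constraints = cst, seed = 1)
  expect_true(attr(packed, "packExhaustive"))
  # brute force: rebuild every rotamer by hand and score the full pose
  lib <- loadRotamerLibrary()
  rows <- caaxbind:::.pepSidechainRows(pose, 3L)
  bb <- caaxbind:::.pepRows(pose, 3L)
  nm <- pose@atoms$name[bb]
  frame <- list(N = pose@xyz[bb[nm == "N"], ],
                CA = pose@xyz[bb[nm == "CA"], ],
                C = pose@xyz[bb[nm == "C"], ])
  obj <- function(p) {
    ea <- caaxbind:::.energyArgs(p, ef)
    cs <- caaxbind:::.constraintIdx(p, cst)
    caaxbind:::.cppObjective(p@xyz, ea$radius, ea$eps, ea$charge, ea$dgfree,
                             ea$vol, ea$donor, ea$acceptor, ea$base,
                             ea$group, p@exclusions, ea$weights, cs$ci,
                             cs$cj, cs$d0, cs$sd, ea$wcst)
  }
  best <- Inf
  for (r in seq_len(nrow(lib$LEU))) {
    sc <- buildSidechain("LEU", frame, lib$LEU[r, ])
    cand <- pose
    cand@xyz[rows, ] <- sc[match(pose@atoms$name[rows], rownames(sc)), ]
    best <- min(best, obj(cand))
  }
  best <- min(best, obj(pose))  # current side chain competes too
  expect_equal(obj(packed), best, tolerance = 1e-9)
})

test_that("packing never increases the objective and empty selections are no-ops", {
  tpl <- toyTemplate()
  cst <- toyConstraints()
  ef <- defaultEnergyFunction()
  obj <- function(p) {
    ea <- caaxbind:::.energyArgs(p, ef)
    cs <- caaxbind:::.constraintIdx(p, cst)
    caaxbind:::.cppObjective(p@xyz, ea$radius, ea$eps, ea$charge, ea$dgfree,
                             ea$vol, ea$donor, ea$acceptor, ea$base,
                             ea$group, p@exclusions, ea$weights, cs$ci,
                             cs$cj, cs$d0, cs$sd, ea$wcst)
  }
  for (s in c("CVIM", "CKWR", "CNLQ")) {
    pose <- threadSequence(tpl, s)
    packed <- packSidechains(pose, energyFn = ef, constraints = cst,
                             seed = 7)
    expect_lte(obj(packed), obj(pose) + 1e-9)
  }
  pose <- threadSequence(tpl, "CVIM")
  same <- packSidechains(pose, flexiblePositions = integer(0))
  expect_identical(same@xyz, pose@xyz)
  expect_error(packSidechains(pose, flexiblePositions = 5L),
               "peptide positions")
})

test_that("exhaustive packing is seed-free; annealing is seed-reproducible", {
  tpl <- toyTemplate()
  cst <- toyConstraints()
  pose <- threadSequence(tpl, "CVLM")
  a <- packSidechains(pose, flexiblePositions = c(2L, 3L), extraChi = FALSE,
                      constraints = cst, seed = 1)
  b <- packSidechains(pose, flexiblePositions = c(2L, 3L), extraChi = FALSE,
                      constraints = cst, seed = 999)
  expect_true(attr(a, "packExhaustive"))
  expect_identical(a@xyz, b@xyz)
  # force the annealing path with a tiny exhaustive limit
  c1 <- packSidechains(pose, constraints = cst, seed = 5, limit = 2)
  c2 <- packSidechains(pose, constraints = cst, seed = 5, limit = 2)
  expect_false(attr(c1, "packExhaustive"))
  expect_identical(c1@xyz, c2@xyz)
})
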