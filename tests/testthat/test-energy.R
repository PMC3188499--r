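# Energy model: constraints, decomposition identities, surface area.

test_that("constraint derivation measures the template and honors the sd argument", {
  tpl <- toyTemplate()
  cst <- deriveConstraints(tpl)
  expect_identical(nrow(cst), 5L)
  expect_equal(cst$sd, rep(0.1, 5))
  # d0 equals the configured anchor geometry by construction
  expect_equal(cst$d0[1:2], rep(2.8, 2), tolerance = 0.05)
  expect_equal(cst$d0[3:5], rep(2.3, 3), tolerance = 0.05)
  soft <- deriveConstraints(tpl, sd = 0.25)
  expect_equal(soft$sd, rep(0.25, 5))
  expect_equal(soft$d0, cst$d0)
})

test_that("harmonic constraint energy follows ((d-d0)/sd)^2", {
  tpl <- toyTemplate()
  pose <- threadSequence(tpl, "CNIQ")
  cst <- deriveConstraints(tpl)
  # at the template geometry, peptide-backbone-anchored constraints are at
  # their reference length
  bbIdx <- cst$atom_a %in% c("pep_carboxylate_O", "pep_a2_O")
  expect_equal(constraintEnergy(pose, cst[bbIdx, ]), 0, tolerance = 1e-9)
  # synthetic single constraint: d0 2.8, sd 0.1, displaced by 0.1 then 0.2
  one <- cst[1, ]
  for (case in list(c(0.1, 1), c(0.2, 4))) {
    shifted <- one
    shifted$d0 <- shifted$d0 + case[1]
    expect_equal(constraintEnergy(pose, shifted), case[2],
                 tolerance = 1e-6)
  }
  missing <- cst[1, ]; missing$atom_a <- "no_such_anchor"
  expect_error(constraintEnergy(pose, missing), "no_such_anchor")
})

test_that("per-residue decomposition sums to the total and interface equals complex minus parts", {
  tpl <- toyTemplate()
  cst <- deriveConstraints(tpl)
  ef <- defaultEnergyFunction()
  for (seed in 1:5) {
    pose <- randomPose(seed)
    bd <- scorePose(pose, ef, cst, ibsa = FALSE)
    expect_equal(sum(perResidue(bd)) + constraintTotal(bd), totalScore(bd),
                 tolerance = 1e-6)
    # interface identity: rescore with the peptide translated far away
    apart <- pose
    pepRows <- which(pose@atoms$segment == "peptide")
    apart@xyz[pepRows, 1] <- apart@xyz[pepRows, 1] + 500
    bdApart <- scorePose(apart, ef, NULL, ibsa = FALSE)
    complexE <- totalScore(bd) - constraintTotal(bd)
    expect_equal(interfaceScore(bd), complexE - totalScore(bdApart),
                 tolerance = 1e-6)
  }
})

test_that("pair terms vanish beyond the cutoff and the peptide alone has zero interface", {
  tpl <- toyTemplate()
  pose <- threadSequence(tpl, "CVIM")
  pepRows <- which(pose@atoms$segment == "peptide")
  pose@xyz[pepRows, 1] <- pose@xyz[pepRows, 1] + 100
  bd <- scorePose(pose, ibsa = FALSE)
  expect_equal(interfaceScore(bd), 0)
  expect_equal(buriedSurfaceArea(pose), 0, tolerance = 1e-6)
})

test_that("peptide score subtracts reference energies exactly", {
  tpl <- toyTemplate()
  pose <- threadSequence(tpl, "CVIM")
  cst <- deriveConstraints(tpl)
  refs <- c(CYS = 0.3, VAL = 0.2, ILE = 0.1, MET = 0.1)
  ef <- defaultEnergyFunction(refEnergies = refs)
  bd <- scorePose(pose, ef, cst, ibsa = FALSE)
  withRef <- peptideScore(bd, "CVIM", ef, includeRef = TRUE)
  noRef <- peptideScore(bd, "CVIM", ef, includeRef = FALSE)
  expect_equal(withRef, sum(bd@peptideResidue))
  expect_equal(withRef - noRef, 0.7, tolerance = 1e-9)
  # all-zero references: both schemes coincide
  ef0 <- defaultEnergyFunction()
  expect_equal(peptideScore(bd, "CVIM", ef0, includeRef = TRUE),
               peptideScore(bd, "CVIM", ef0, includeRef = FALSE))
})

test_that("an intra-peptide clash changes the total but not the interface score", {
  # minimal three-atom system on the raw kernel: two peptide atoms, one
  # receptor atom; only the p1-r pair crosses the interface
  kernel <- function(xyz) {
    n <- nrow(xyz)
    caaxbind:::.cppEnergy(xyz, rep(1.8, n), rep(0.12, n), rep(0, n),
                          rep(0.9, n), rep(14, n), rep(0L, n), rep(0L, n),
                          rep(0L, n), c(1L, 1L, 2L),
                          matrix(integer(0), ncol = 2),
                          c(1, 0.55, 1.5, 1, 0.15))
  }
  # r sits 7.5 A from p1 (inside the cutoff); p2 stays beyond the cutoff
  # from r in both poses, so only the intra-peptide p1-p2 term changes
  apartP2 <- rbind(c(0, 0, 0), c(0, 20, 0), c(7.5, 0, 0))
  clashP2 <- rbind(c(0, 0, 0), c(-1.2, 0, 0), c(7.5, 0, 0))
  e1 <- kernel(apartP2); e2 <- kernel(clashP2)
  expect_gt(e2$total, e1$total)              # intra clash raises the total
  expect_equal(e2$cross_interface, e1$cross_interface, tolerance = 1e-9)
  expect_false(e1$cross_interface == 0)
})

test_that("Shrake-Rupley matches the analytic two-sphere buried area", {
  r <- 1.8; probe <- 1.4; d <- 2.5
  xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
  area <- caaxbind:::.cppSasa(xyz, rep(r, 2), probe, 2000L)
  R <- r + probe
  # equal spheres: cap height h = R - d/2 on each
  h <- R - d / 2
  analytic <- 4 * pi * R^2 - 2 * pi * R * h
  expect_equal(area[1], analytic, tolerance = 0.01 * analytic)
  expect_equal(area[2], analytic, tolerance = 0.01 * analytic)
  # far apart: full sphere
  far <- caaxbind:::.cppSasa(rbind(c(0, 0, 0), c(50, 0, 0)), rep(r, 2),
                             probe, 2000L)
  expect_equal(far[1], 4 * pi * R^2, tolerance = 1e-6)
})

test_that("buried surface area decreases monotonically as the peptide leaves", {
  tpl <- toyTemplate()
  pose <- threadSequence(tpl, "CVIM")
  pepRows <- which(pose@atoms$segment == "peptide")
  prev <- Inf
  for (shift in c(0, 3, 6, 12, 30)) {
    p <- pose
    p@xyz[pepRows, 2] <- p@xyz[pepRows, 2] + shift
    b <- buriedSurfaceArea(p)
    expect_lte(b, prev + 1e-6)
    prev <- b
  }
  expect_gt(buriedSurfaceArea(pose), 100)  # the pocket buries real area
})

test_that("an unknown atom type is reported by atom name", {
  tpl <- toyTemplate()
  pose <- threadSequence(tpl, "CVIM")
  ef <- defaultEnergyFunction()
  ef@params <- ef@params[ef@params$type != "S", ]
  expect_error(scorePose(pose, ef), "atom type 'S'")
})
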