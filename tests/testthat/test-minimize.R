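# Torsion-space DFP minimization.

test_that("interface selection follows the Cbeta cutoff with the glycine CA proxy", {
  tpl <- toyTemplate()
  pose <- threadSequence(tpl, "CVIM")
  at <- pose@atoms
  pep <- pose@xyz[at$segment == "peptide", , drop = FALSE]
  # brute-force reference
  want <- NULL
  rows <- which(at$segment == "receptor")
  for (rn in unique(at$resno[rows])) {
    ri <- rows[at$resno[rows] == rn]
    probe <- ri[at$name[ri] == "CB"]
    if (length(probe) == 0) probe <- ri[at$name[ri] == "CA"]
    d <- sqrt(min(colSums((t(pep) - pose@xyz[probe[1], ])^2)))
    if (d <= 8) want <- c(want, rn)
  }
  got <- selectInterfaceSidechains(pose, 8)
  expect_setequal(got$resno, want)
  # boundary behaviour: a cutoff just below/above a residue's distance
  dists <- vapply(unique(at$resno[rows]), function(rn) {
    ri <- rows[at$resno[rows] == rn]
    probe <- ri[at$name[ri] == "CB"]
    if (length(probe) == 0) probe <- ri[at$name[ri] == "CA"]
    sqrt(min(colSums((t(pep) - pose@xyz[probe[1], ])^2)))
  }, numeric(1))
  dmid <- sort(dists)[2]
  below <- selectInterfaceSidechains(pose, dmid - 0.01)
  above <- selectInterfaceSidechains(pose, dmid + 0.01)
  expect_identical(nrow(above), nrow(below) + 1L)
})

test_that("DOF confinement: receptor backbone and non-moving atoms never move", {
  tpl <- toyTemplate()
  cst <- toyConstraints()
  pose <- threadSequence(tpl, "CVLS")
  res <- minimizePose(pose, constraints = cst, maxIter = 15)
  at <- pose@atoms
  recBB <- which(at$segment == "receptor" &
                   at$name %in% c("N", "CA", "C", "O"))
  expect_identical(res@pose@xyz[recBB, ], pose@xyz[recBB, ])
  dofs <- poseDofs(pose)
  movable <- sort(unique(unlist(dofs$moving)))
  frozen <- setdiff(seq_len(nrow(at)), movable)
  expect_identical(res@pose@xyz[frozen, ], pose@xyz[frozen, ])
})

test_that("rebuildCoordinates: identity, kinematic locality and rigid-body inverse", {
  tpl <- toyTemplate()
  pose <- threadSequence(tpl, "CVLM")
  dofs <- poseDofs(pose)
  cur <- caaxbind:::.measureDofs(pose, dofs)
  same <- rebuildCoordinates(pose, cur, dofs)
  expect_equal(same@xyz, pose@xyz, tolerance = 1e-9)
  expect_error(rebuildCoordinates(pose, cur[-1], dofs), "length")

  # rotating one chi1 moves only atoms distal to that CB
  k <- which(dofs$label == "pep3_chi1")
  tgt <- cur
  tgt[k] <- cur[k] + 120
  rot <- rebuildCoordinates(pose, tgt, dofs)
  moved <- which(rowSums(abs(rot@xyz - pose@xyz)) > 1e-9)
  expect_setequal(moved, setdiff(dofs$moving[[k]], dofs$b[k]))
  expect_equal(measureChis(rot, 3)[1],
               ((cur[k] + 120 + 180) %% 360) - 180, tolerance = 1e-6)

  # applying then inverting a rigid-body transform restores coordinates
  rb <- which(grepl("^rb_", dofs$label))
  x <- numeric(length(dofs$type))
  x[rb] <- c(1.5, -2, 0.5, 20, -35, 10)
  fwd <- pose
  fwd@xyz <- caaxbind:::.cppApplyDofs(pose@xyz, dofs$type, dofs$a, dofs$b,
                                      dofs$moving, x)
  back <- caaxbind:::.cppApplyDofs(fwd@xyz, rev(dofs$type[rb]),
                                   rev(dofs$a[rb]), rev(dofs$b[rb]),
                                   rev(dofs$moving[rb]), -rev(x[rb]))
  expect_equal(back, pose@xyz, tolerance = 1e-6)
})

test_that("DFP reaches the analytic minimum of a quadratic within 1e-6", {
  A <- matrix(c(4, 1, 0, 1, 3, -1, 0, -1, 2), 3, 3)
  b <- c(1, -2, 0.5)
  fn <- function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x)
  gr <- function(x) as.numeric(A %*% x - b)
  xStar <- solve(A, b)
  res <- dfpMinimize(fn, gr, x0 = c(5, -5, 5), tol = 1e-12)
  expect_true(res$converged)
  expect_equal(res$x, xStar, tolerance = 1e-6)
  expect_equal(res$value, fn(xStar), tolerance = 1e-9)
  # independent cross-check: stats::optim BFGS lands at the same optimum
  o <- stats::optim(c(5, -5, 5), fn, gr, method = "BFGS")
  expect_equal(res$value, o$value, tolerance = 1e-6)
})

test_that("a pure-constraint pose objective reaches its analytic minimum", {
  # turn all physical terms off: the objective is a sum of harmonic wells
  # whose minimum over rigid-body translation is computable; a constraint
  # stretched by +0.5 A must relax back toward d0
  tpl <- toyTemplate()
  ef <- defaultEnergyFunction(weights = c(lj_attr = 0, lj_rep = 0,
                                          hbond = 0, solv = 0, elec = 0))
  pose <- threadSequence(tpl, "CNIQ")
  cst <- deriveConstraints(tpl)
  cstStretch <- cst
  cstStretch$d0 <- cst$d0 + 0.5
  e0 <- constraintEnergy(pose, cstStretch)
  dofs <- poseDofs(pose, peptideTorsions = FALSE, rigidBody = TRUE,
                   receptorChis = FALSE, ligandDihedrals = FALSE)
  res <- minimizePose(pose, ef, cstStretch, dofs = dofs, tolerance = 1e-9,
                      maxIter = 300)
  eEnd <- constraintEnergy(res@pose, cstStretch)
  expect_lt(eEnd, e0)
  # each constraint distance moved toward its (stretched) reference
  cs <- caaxbind:::.constraintIdx(pose, cstStretch)
  dist <- function(p, k) caaxbind:::.vnorm(p@xyz[cs$ci[k], ] -
                                             p@xyz[cs$cj[k], ])
  for (k in seq_len(5))
    expect_lt(abs(dist(res@pose, k) - cstStretch$d0[k]),
              abs(dist(pose, k) - cstStretch$d0[k]) + 1e-9)
})

test_that("minimization is monotone, deterministic and converges at a minimum", {
  tpl <- toyTemplate()
  cst <- toyConstraints()
  pose <- packSidechains(threadSequence(tpl, "CVIM"), constraints = cst,
                         seed = 1)
  r1 <- minimizePose(pose, constraints = cst, maxIter = 300)
  r2 <- minimizePose(pose, constraints = cst, maxIter = 300)
  expect_lte(r1@endEnergy, r1@startEnergy + 1e-9)
  expect_identical(r1@endEnergy, r2@endEnergy)   # bitwise determinism
  expect_identical(r1@pose@xyz, r2@pose@xyz)
  expect_true(r1@converged)
  # restarting from the converged pose never goes up
  r3 <- minimizePose(r1@pose, constraints = cst, maxIter = 300)
  expect_lte(r3@endEnergy, r1@endEnergy + 1e-9)
  # a start at an exact minimum converges within two iterations
  A <- diag(c(2, 7))
  fn <- function(x) 0.5 * sum(x * (A %*% x))
  res <- dfpMinimize(fn, function(x) as.numeric(A %*% x), x0 = c(0, 0))
  expect_true(res$converged)
  expect_lte(res$iterations, 2L)
  expect_equal(res$value, 0, tolerance = 1e-12)
})
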