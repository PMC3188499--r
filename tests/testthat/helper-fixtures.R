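# Shared fixtures, built once per test run. The toy template is
# deterministic, so caching it is safe.

.fixtureEnv <- new.env(parent = emptyenv())

toyTemplate <- function() {
  if (is.null(.fixtureEnv$tpl))
    .fixtureEnv$tpl <- makeToyTemplate()
  .fixtureEnv$tpl
}

toyConstraints <- function(sd = 0.1) {
  deriveConstraints(toyTemplate(), sd = sd)
}

# a tiny hand-written PDB fixture: one chain, two residues (GLY-ALA) plus a
# water, a metal ion and a hetero ligand atom
miniPdbText <- function() {
  paste(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.004   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.102  1.00  0.00           O",
    "ATOM      5  N   ALA A   2       3.320   1.562  -0.123  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2       3.926   2.878  -0.154  1.00  0.00           C",
    "ATOM      7  C   ALA A   2       5.430   2.742  -0.345  1.00  0.00           C",
    "ATOM      8  O   ALA A   2       5.934   1.625  -0.511  1.00  0.00           O",
    "ATOM      9  CB  ALA A   2       3.330   3.680  -1.312  1.00  0.00           C",
    "HETATM   10  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    "HETATM   11 ZN    ZN A 102       9.000   9.000   9.000  1.00  0.00          ZN",
    "HETATM   12  C1  LIG A 103      10.000  10.000  10.000  1.00  0.00           C"),
    collapse = "\n")
}

# quick random-pose generator for fuzz tests: thread a random sequence and
# jitter the peptide rigid body slightly
randomPose <- function(seed) {
  set.seed(seed)
  aa <- names(caaxbind:::.AA3)
  s <- paste0("C", paste(sample(aa, 3, replace = TRUE), collapse = ""))
  pose <- threadSequence(toyTemplate(), s)
  dofs <- poseDofs(pose, peptideTorsions = FALSE, rigidBody = TRUE,
                   receptorChis = FALSE, ligandDihedrals = FALSE)
  x <- stats::runif(length(dofs$type), -0.5, 0.5)
  pose@xyz <- caaxbind:::.cppApplyDofs(pose@xyz, dofs$type, dofs$a, dofs$b,
                                       dofs$moving, x)
  pose
}
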