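# PDB reading/writing and template preparation.

test_that("a single ATOM record maps to one chain, residue and atom", {
  s <- readPDB("ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N")
  a <- atoms(s)
  expect_identical(nrow(a), 1L)
  expect_identical(a$name, "N")
  expect_identical(a$resn, "ALA")
  expect_equal(c(a$x, a$y, a$z), c(1, 2, 3))
})

test_that("write/read round-trips coordinates to 3 decimals", {
  s <- readPDB(miniPdbText())
  s2 <- readPDB(writePDB(s))
  expect_equal(coords(s2), coords(s), tolerance = 1e-9)
  expect_identical(atoms(s2)$name, atoms(s)$name)
  expect_identical(atoms(s2)$het, atoms(s)$het)
})

test_that("altLoc resolves to the highest-occupancy conformer", {
  txt <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    sep = "\n")
  s <- readPDB(txt)
  expect_identical(nrow(atoms(s)), 1L)
  expect_equal(atoms(s)$x, 5)    # B kept (occ 0.6)
  # tie: alphabetically first altLoc wins
  txt2 <- gsub("0.40", "0.60", txt)
  s2 <- readPDB(txt2)
  expect_equal(atoms(s2)$x, 0)   # A kept
})

test_that("malformed and empty input raise informative errors", {
  expect_error(readPDB("HEADER  nothing here"), "no ATOM/HETATM")
  bad <- paste("ATOM      1  N   ALA A   1       1.000   2.000",
               sep = "")
  expect_error(readPDB(bad), "line 1")
  multi <- paste(miniPdbText(),
                 "ATOM     13  CA  GLY A   5       1.0xx   0.000   0.000  1.00  0.00           C",
                 sep = "\n")
  expect_error(readPDB(multi), "line 13")
})

test_that("writePDB emits fixed columns, HETATM for hetero units, TER and END", {
  s <- readPDB(miniPdbText())
  txt <- writePDB(s)
  lines <- strsplit(txt, "\n")[[1]]
  expect_true(any(grepl("^HETATM", lines)))
  expect_identical(lines[length(lines)], "END")
  expect_true(any(grepl("^TER", lines)))
  # atom names > 4 characters are rejected
  a <- atoms(s); a$name[1] <- "TOOLONG"
  expect_error(writePDB(new("Structure", atoms = a)), "4 characters")
})

test_that("only the first MODEL of a multi-model file is read", {
  one <- "ATOM      1  N   ALA A   1       1.000   0.000   0.000  1.00  0.00           N"
  two <- "ATOM      1  N   ALA A   1       9.000   0.000   0.000  1.00  0.00           N"
  txt <- paste("MODEL     1", one, "ENDMDL", "MODEL     2", two, "ENDMDL",
               "END", sep = "\n")
  s <- readPDB(txt)
  expect_identical(nrow(atoms(s)), 1L)
  expect_equal(atoms(s)$x, 1)
})

test_that("prepareTemplate truncates to 4 residues, strips solvent/metal and keeps the ligand", {
  tpl <- toyTemplate()
  # append two extra upstream peptide residues, a water and a metal
  s <- templateStructure(tpl)
  a <- atoms(s)
  extra <- a[a$chain == "P" & a$resno == 1 & a$name %in%
               c("N", "CA", "C", "O"), ]
  e1 <- extra; e1$resno <- -1L; e1$resn <- "GLY"; e1$x <- e1$x - 40
  e2 <- extra; e2$resno <- 0L; e2$resn <- "ALA"; e2$x <- e2$x - 35
  wat <- a[1, ]; wat$name <- "O"; wat$element <- "O"; wat$resn <- "HOH"
  wat$chain <- "W"; wat$resno <- 900L; wat$het <- TRUE; wat$x <- 50
  zn <- a[1, ]; zn$name <- "ZN"; zn$element <- "ZN"; zn$resn <- "ZN"
  zn$chain <- "W"; zn$resno <- 901L; zn$het <- TRUE; zn$x <- 55
  s2 <- new("Structure", atoms = rbind(e1, e2, a, wat, zn))
  anchorConfig <- list(q_alpha = "A:101:NE2", r_beta = "A:102:NH1",
                       zn_triad_1 = "A:103:SG", zn_triad_2 = "A:104:OG",
                       zn_triad_3 = "A:105:OG1")
  tc <- prepareTemplate(s2, "P", "FAR", "A", anchorConfig)
  expect_identical(peptideSequence(tc), "CNIQ")  # last four residues kept
  all2 <- rbind(atoms(receptor(tc)), atoms(templatePeptide(tc)),
                ligandAtoms(tc))
  expect_false(any(all2$resn %in% c("HOH", "ZN")))
  expect_identical(nrow(ligandAtoms(tc)), 8L)
})

test_that("a missing OXT is rebuilt at ideal sp2 carboxylate geometry", {
  tpl <- toyTemplate()
  s <- templateStructure(tpl)
  a <- atoms(s)
  a <- a[!(a$chain == "P" & a$name == "OXT"), ]
  anchorConfig <- list(q_alpha = "A:101:NE2", r_beta = "A:102:NH1",
                       zn_triad_1 = "A:103:SG", zn_triad_2 = "A:104:OG",
                       zn_triad_3 = "A:105:OG1")
  tc <- prepareTemplate(new("Structure", atoms = a), "P", "FAR", "A",
                        anchorConfig)
  p <- atoms(templatePeptide(tc))
  oxt <- p[p$resno == 4 & p$name == "OXT", ]
  cc <- p[p$resno == 4 & p$name == "C", ]
  d <- sqrt((oxt$x - cc$x)^2 + (oxt$y - cc$y)^2 + (oxt$z - cc$z)^2)
  expect_equal(d, 1.25, tolerance = 0.02)
  # carboxylate is planar: OXT roughly anti to O about the CA-C axis
  ca <- p[p$resno == 4 & p$name == "CA", ]
  o <- p[p$resno == 4 & p$name == "O", ]
  tors <- caaxbind:::dihedralAngle(
    c(o$x, o$y, o$z), c(ca$x, ca$y, ca$z), c(cc$x, cc$y, cc$z),
    c(oxt$x, oxt$y, oxt$z))
  expect_equal(abs(tors), 180, tolerance = 1)
})

test_that("template errors: short peptide, wrong first residue, bad anchor", {
  tpl <- toyTemplate()
  a <- atoms(templateStructure(tpl))
  anchorConfig <- list(q_alpha = "A:101:NE2", r_beta = "A:102:NH1",
                       zn_triad_1 = "A:103:SG", zn_triad_2 = "A:104:OG",
                       zn_triad_3 = "A:105:OG1")
  short <- a[!(a$chain == "P" & a$resno == 1), ]
  expect_error(prepareTemplate(new("Structure", atoms = short), "P", "FAR",
                               "A", anchorConfig), "fewer than 4")
  notCys <- a; notCys$resn[notCys$chain == "P" & notCys$resno == 1] <- "SER"
  expect_error(prepareTemplate(new("Structure", atoms = notCys), "P", "FAR",
                               "A", anchorConfig), "Cys at motif position 1")
  badAnchor <- anchorConfig; badAnchor$q_alpha <- "A:999:NE2"
  expect_error(prepareTemplate(new("Structure", atoms = a), "P", "FAR", "A",
                               badAnchor), "A:999:NE2")
})

test_that("prepareTemplate is idempotent and never alters retained coordinates", {
  tpl <- toyTemplate()
  anchorConfig <- list(q_alpha = "A:101:NE2", r_beta = "A:102:NH1",
                       zn_triad_1 = "A:103:SG", zn_triad_2 = "A:104:OG",
                       zn_triad_3 = "A:105:OG1")
  tc2 <- prepareTemplate(templateStructure(tpl), "P", "FAR", "A",
                         anchorConfig)
  expect_identical(coords(templatePeptide(tc2)),
                   coords(templatePeptide(tpl)))
  expect_identical(coords(receptor(tc2)), coords(receptor(tpl)))
  expect_identical(anchors(tc2), anchors(tpl))
})
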