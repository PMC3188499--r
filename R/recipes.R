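# Ideal-geometry side-chain construction recipes.
#
# Each heavy side-chain atom is placed by NeRF from three previously placed
# atoms (a, b, c) with an ideal bond length (Angstrom), bond angle (degrees)
# and a torsion that is either a fixed number or an expression in the
# residue's chi angles ("chi1", "chi2+180", ...). Bond lengths/angles are
# rounded Engh-Huber-style values; ring geometry is idealised (planar).

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.AA1 <- stats::setNames(names(.AA3), .AA3)

.rec <- function(...) {
  m <- rbind(...)
  data.frame(atom = m[, 1], a = m[, 2], b = m[, 3], c = m[, 4],
             bond = as.numeric(m[, 5]), angle = as.numeric(m[, 6]),
             tors = m[, 7], stringsAsFactors = FALSE)
}

# CB is chiral: dihedral(N, C, CA, CB) = +122.55 deg gives L-amino acids
# (IUPAC sign convention; verified against experimental structures).
.CB <- c("CB", "N", "C", "CA", "1.530", "110.5", "122.55")

.SIDECHAIN_RECIPES <- list(
  GLY = .rec()[0, ],
  ALA = .rec(.CB),
  SER = .rec(.CB, c("OG",  "N",  "CA", "CB", "1.417", "110.8", "chi1")),
  CYS = .rec(.CB, c("SG",  "N",  "CA", "CB", "1.808", "114.4", "chi1")),
  THR = .rec(.CB,
             c("OG1", "N",  "CA", "CB", "1.433", "109.6", "chi1"),
             c("CG2", "N",  "CA", "CB", "1.521", "110.5", "chi1-120")),
  VAL = .rec(.CB,
             c("CG1", "N",  "CA", "CB", "1.521", "110.5", "chi1"),
             c("CG2", "N",  "CA", "CB", "1.521", "110.5", "chi1+122")),
  LEU = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.530", "116.3", "chi1"),
             c("CD1", "CA", "CB", "CG", "1.521", "110.7", "chi2"),
             c("CD2", "CA", "CB", "CG", "1.521", "110.7", "chi2+122")),
  ILE = .rec(.CB,
             c("CG1", "N",  "CA", "CB", "1.530", "110.4", "chi1"),
             c("CG2", "N",  "CA", "CB", "1.521", "110.5", "chi1-122"),
             c("CD1", "CA", "CB", "CG1", "1.513", "113.9", "chi2")),
  MET = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.520", "114.1", "chi1"),
             c("SD",  "CA", "CB", "CG", "1.803", "112.7", "chi2"),
             c("CE",  "CB", "CG", "SD", "1.791", "100.9", "chi3")),
  PRO = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.492", "104.5", "chi1"),
             c("CD",  "CA", "CB", "CG", "1.503", "106.1", "chi2")),
  PHE = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.502", "113.8", "chi1"),
             c("CD1", "CA", "CB", "CG", "1.384", "120.8", "chi2"),
             c("CD2", "CA", "CB", "CG", "1.384", "120.8", "chi2+180"),
             c("CE1", "CB", "CG", "CD1", "1.382", "120.8", "180"),
             c("CE2", "CB", "CG", "CD2", "1.382", "120.8", "180"),
             c("CZ",  "CG", "CD1", "CE1", "1.382", "120.0", "0")),
  TYR = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.512", "113.9", "chi1"),
             c("CD1", "CA", "CB", "CG", "1.389", "120.8", "chi2"),
             c("CD2", "CA", "CB", "CG", "1.389", "120.8", "chi2+180"),
             c("CE1", "CB", "CG", "CD1", "1.382", "121.2", "180"),
             c("CE2", "CB", "CG", "CD2", "1.382", "121.2", "180"),
             c("CZ",  "CG", "CD1", "CE1", "1.378", "119.6", "0"),
             c("OH",  "CD1", "CE1", "CZ", "1.376", "119.9", "180")),
  TRP = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.498", "113.6", "chi1"),
             c("CD1", "CA", "CB", "CG", "1.365", "126.9", "chi2"),
             c("CD2", "CA", "CB", "CG", "1.433", "126.7", "chi2+180"),
             c("NE1", "CB", "CG", "CD1", "1.374", "110.2", "180"),
             c("CE2", "CB", "CG", "CD2", "1.409", "107.2", "180"),
             c("CE3", "NE1", "CE2", "CD2", "1.398", "122.4", "180"),
             c("CZ2", "CG", "CD2", "CE2", "1.394", "122.4", "180"),
             c("CZ3", "CE2", "CD2", "CE3", "1.382", "118.6", "0"),
             c("CH2", "CD2", "CE2", "CZ2", "1.368", "117.5", "0")),
  ASP = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.516", "112.6", "chi1"),
             c("OD1", "CA", "CB", "CG", "1.249", "118.4", "chi2"),
             c("OD2", "CA", "CB", "CG", "1.249", "118.4", "chi2+180")),
  GLU = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.520", "114.1", "chi1"),
             c("CD",  "CA", "CB", "CG", "1.516", "112.6", "chi2"),
             c("OE1", "CB", "CG", "CD", "1.249", "118.4", "chi3"),
             c("OE2", "CB", "CG", "CD", "1.249", "118.4", "chi3+180")),
  ASN = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.516", "112.6", "chi1"),
             c("OD1", "CA", "CB", "CG", "1.231", "120.8", "chi2"),
             c("ND2", "CA", "CB", "CG", "1.328", "116.4", "chi2+180")),
  GLN = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.520", "114.1", "chi1"),
             c("CD",  "CA", "CB", "CG", "1.516", "112.6", "chi2"),
             c("OE1", "CB", "CG", "CD", "1.231", "120.8", "chi3"),
             c("NE2", "CB", "CG", "CD", "1.328", "116.4", "chi3+180")),
  LYS = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.520", "114.1", "chi1"),
             c("CD",  "CA", "CB", "CG", "1.520", "111.3", "chi2"),
             c("CE",  "CB", "CG", "CD", "1.508", "111.9", "chi3"),
             c("NZ",  "CG", "CD", "CE", "1.489", "111.7", "chi4")),
  ARG = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.520", "114.1", "chi1"),
             c("CD",  "CA", "CB", "CG", "1.520", "111.3", "chi2"),
             c("NE",  "CB", "CG", "CD", "1.461", "112.0", "chi3"),
             c("CZ",  "CG", "CD", "NE", "1.329", "124.2", "chi4"),
             c("NH1", "CD", "NE", "CZ", "1.326", "120.0", "0"),
             c("NH2", "CD", "NE", "CZ", "1.326", "120.0", "180")),
  HIS = .rec(.CB,
             c("CG",  "N",  "CA", "CB", "1.497", "113.8", "chi1"),
             c("ND1", "CA", "CB", "CG", "1.371", "122.7", "chi2"),
             c("CD2", "CA", "CB", "CG", "1.356", "131.1", "chi2+180"),
             c("CE1", "CB", "CG", "ND1", "1.319", "109.0", "180"),
             c("NE2", "CB", "CG", "CD2", "1.374", "107.2", "180"))
)

# Number of chi angles per residue type (the rotatable-bond count used by the
# rotamer library and the torsion DOF layout).
.N_CHI <- c(ALA = 0, GLY = 0, SER = 1, CYS = 1, THR = 1, VAL = 1, PRO = 2,
            LEU = 2, ILE = 2, ASP = 2, ASN = 2, PHE = 2, TYR = 2, TRP = 2,
            HIS = 2, MET = 3, GLU = 3, GLN = 3, LYS = 4, ARG = 4)

# chi(k) axis atom pairs per residue type: rotation about b with axis a->b
# moves everything distal to b. Derived from the recipes.
.CHI_AXES <- list(
  SER = list(c("CA", "CB")), CYS = list(c("CA", "CB")),
  THR = list(c("CA", "CB")), VAL = list(c("CA", "CB")),
  PRO = list(c("CA", "CB"), c("CB", "CG")),
  LEU = list(c("CA", "CB"), c("CB", "CG")),
  ILE = list(c("CA", "CB"), c("CB", "CG1")),
  ASP = list(c("CA", "CB"), c("CB", "CG")),
  ASN = list(c("CA", "CB"), c("CB", "CG")),
  PHE = list(c("CA", "CB"), c("CB", "CG")),
  TYR = list(c("CA", "CB"), c("CB", "CG")),
  TRP = list(c("CA", "CB"), c("CB", "CG")),
  HIS = list(c("CA", "CB"), c("CB", "CG")),
  MET = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD")),
  GLU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD")),
  GLN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD")),
  LYS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE")),
  ARG = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"))
)

# Intra-residue heavy-atom bonds (backbone + side chain), used to build the
# bond graph for torsion kinematics and non-bonded exclusions.
.residueBonds <- function(type3) {
  bb <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))
  rec <- .SIDECHAIN_RECIPES[[type3]]
  sc <- NULL
  if (!is.null(rec) && nrow(rec) > 0) {
    # each recipe atom bonds to its 'c' reference
    sc <- cbind(rec$c, rec$atom)
    # ring closures / special bonds not captured by the placement parent
    extra <- switch(type3,
      PHE = rbind(c("CE2", "CZ")),
      TYR = rbind(c("CE2", "CZ")),
      HIS = rbind(c("CE1", "NE2")),
      TRP = rbind(c("NE1", "CE2"), c("CZ3", "CH2")),
      PRO = rbind(c("CD", "N")),
      NULL)
    sc <- rbind(sc, extra)
  }
  rbind(bb, sc)
}

.torsExpr <- function(expr, chi) {
  if (grepl("^chi", expr)) {
    k <- as.integer(substr(expr, 4, 4))
    off <- 0
    if (nchar(expr) > 4) off <- as.numeric(substr(expr, 5, nchar(expr)))
    chi[k] + off
  } else {
    as.numeric(expr)
  }
}
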