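# Atom typing: maps (residue, atom name, element) to nonbonded atom types,
# partial charges and hydrogen-bond donor/acceptor roles. Polar hydrogens are
# not represented; donor directionality is inferred at scoring time from the
# donor's bonded heavy-atom base.

.AROMATIC_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

.DONOR_ATOMS <- list(
  default = "N",  # backbone amide (except proline)
  SER = c("N", "OG"), THR = c("N", "OG1"), TYR = c("N", "OH"),
  ASN = c("N", "ND2"), GLN = c("N", "NE2"), TRP = c("N", "NE1"),
  LYS = c("N", "NZ"), ARG = c("N", "NE", "NH1", "NH2"),
  HIS = c("N", "ND1", "NE2"), PRO = character(0))

.ACCEPTOR_ATOMS <- list(
  default = c("O", "OXT"),
  SER = c("O", "OXT", "OG"), THR = c("O", "OXT", "OG1"),
  TYR = c("O", "OXT", "OH"),
  ASN = c("O", "OXT", "OD1"), GLN = c("O", "OXT", "OE1"),
  ASP = c("O", "OXT", "OD1", "OD2"), GLU = c("O", "OXT", "OE1", "OE2"),
  HIS = c("O", "OXT", "ND1", "NE2"))

# charge rules: small backbone dipoles plus formal charges on ionised side
# chains; the terminal carboxylate is handled by the caller flagging OXT.
.atomCharge <- function(resn, name, hasOXT) {
  bb <- c(N = -0.35, CA = 0.10, C = 0.45, O = -0.45)
  if (name %in% names(bb)) {
    q <- bb[[name]]
    if (hasOXT && name %in% c("O", "C")) q <- c(O = -0.60, C = 0.35)[[name]]
    return(q)
  }
  if (name == "OXT") return(-0.60)
  switch(paste(resn, name),
    "ASP OD1" = -0.55, "ASP OD2" = -0.55, "ASP CG" = 0.30,
    "GLU OE1" = -0.55, "GLU OE2" = -0.55, "GLU CD" = 0.30,
    "LYS NZ" = 0.90, "LYS CE" = 0.10,
    "ARG NE" = -0.10, "ARG CZ" = 0.50, "ARG NH1" = 0.30, "ARG NH2" = 0.30,
    "HIS ND1" = -0.15, "HIS NE2" = -0.15, "HIS CE1" = 0.20,
    "SER OG" = -0.35, "THR OG1" = -0.35, "TYR OH" = -0.35,
    "ASN OD1" = -0.45, "ASN ND2" = -0.30, "ASN CG" = 0.45,
    "GLN OE1" = -0.45, "GLN NE2" = -0.30, "GLN CD" = 0.45,
    "CYS SG" = -0.15,
    0)
}

.atomType <- function(resn, name, element) {
  if (element == "S") return("S")
  if (element == "P") return("P")
  if (element == "N") {
    if (resn == "LYS" && name == "NZ") return("NPos")
    if (resn == "ARG" && name %in% c("NE", "NH1", "NH2")) return("NPos")
    return("NAmide")
  }
  if (element == "O") {
    if (name == "OXT") return("OCoo")
    if (resn %in% c("ASP", "GLU") && grepl("^O[DE][12]$", name))
      return("OCoo")
    if (name %in% c("OG", "OG1", "OH")) return("OHyd")
    return("OCarb")
  }
  if (element == "C") {
    if (name %in% c("C",
                    switch(resn, ASP = "CG", GLU = "CD", ASN = "CG",
                           GLN = "CD", ARG = "CZ", character(0))))
      return("CPol")
    arom <- .AROMATIC_ATOMS[[resn]]
    if (!is.null(arom) && name %in% arom) return("CAro")
    return("CAli")
  }
  "XOther"
}

# Assign per-atom typing columns to a pose atom table. `hasOXT` marks the
# peptide C-terminal residue so its backbone O picks up carboxylate charge.
.typeAtoms <- function(at) {
  n <- nrow(at)
  resKey <- paste(at$segment, at$chain, at$resno, at$insert)
  oxtRes <- unique(resKey[at$name == "OXT"])
  type <- character(n); charge <- numeric(n)
  donor <- logical(n); acceptor <- logical(n)
  for (i in seq_len(n)) {
    rn <- at$resn[i]; nm <- at$name[i]; el <- at$element[i]
    type[i] <- .atomType(rn, nm, el)
    charge[i] <- .atomCharge(rn, nm, resKey[i] %in% oxtRes)
    don <- .DONOR_ATOMS[[rn]]; if (is.null(don)) don <- .DONOR_ATOMS$default
    acc <- .ACCEPTOR_ATOMS[[rn]]
    if (is.null(acc)) acc <- .ACCEPTOR_ATOMS$default
    donor[i] <- nm %in% don
    acceptor[i] <- nm %in% acc || nm == "OXT"
  }
  # hetero/ligand atoms: nonpolar by element unless O/N
  het <- at$segment == "ligand"
  if (any(het)) {
    donor[het] <- FALSE
    acceptor[het] <- at$element[het] %in% c("O", "N")
    charge[het] <- 0
  }
  at$type <- type; at$charge <- charge
  at$donor <- donor; at$acceptor <- acceptor
  at
}
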