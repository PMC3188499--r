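# Threading a Cxxx sequence onto the fixed template backbone, building side
# chains from ideal internal coordinates, and combinatorial rotamer packing.

.validateCxxx <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) != 4L)
    stop("sequence must be a 4-letter Cxxx string")
  letters1 <- strsplit(sequence, "")[[1]]
  if (letters1[1] != "C")
    stop("sequence must start with C (cysteine at motif position 1): ",
         sequence)
  bad <- setdiff(letters1, names(.AA3))
  if (length(bad) > 0)
    stop("non-standard amino-acid letter in sequence: ",
         paste(bad, collapse = ", "))
  letters1
}

#' Build a side chain from ideal internal coordinates
#'
#' Places the heavy side-chain atoms of one residue from its backbone frame
#' using ideal bond lengths/angles and the supplied chi angles. The
#' construction is deterministic; re-measuring any chi of the built side
#' chain returns the input value.
#'
#' @param residueType three-letter residue code.
#' @param backboneFrame named list or 3 x 3 matrix with rows/elements
#'   \code{N}, \code{CA}, \code{C} (positions, Angstrom).
#' @param chiTuple numeric vector of chi angles in degrees; its length must
#'   equal the residue's rotatable-bond count (0 for ALA/GLY).
#' @return numeric matrix of side-chain atom coordinates with atom-name
#'   rownames (CB first; a 0-row matrix for glycine).
#' @export
buildSidechain <- function(residueType, backboneFrame, chiTuple = numeric(0)) {
  if (!residueType %in% names(.SIDECHAIN_RECIPES))
    stop("unknown residue type: ", residueType)
  nchi <- .N_CHI[[residueType]]
  if (length(chiTuple) != nchi)
    stop(residueType, " requires ", nchi, " chi angle(s), got ",
         length(chiTuple))
  if (is.matrix(backboneFrame)) {
    pos <- list(N = backboneFrame["N", ], CA = backboneFrame["CA", ],
                C = backboneFrame["C", ])
  } else {
    pos <- backboneFrame[c("N", "CA", "C")]
  }
  rec <- .SIDECHAIN_RECIPES[[residueType]]
  if (nrow(rec) == 0)
    return(matrix(numeric(0), ncol = 3, nrow = 0,
                  dimnames = list(NULL, NULL)))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    tors <- .torsExpr(r$tors, chiTuple)
    pos[[r$atom]] <- placeAtom(pos[[r$a]], pos[[r$b]], pos[[r$c]],
                               bond = r$bond, angle = r$angle,
                               torsion = tors)
  }
  out <- do.call(rbind, pos[rec$atom])
  rownames(out) <- rec$atom
  out
}

# chi-defining atom quadruples (names) for a residue type
.chiAtoms <- function(resn) {
  rec <- .SIDECHAIN_RECIPES[[resn]]
  nchi <- .N_CHI[[resn]]
  if (nchi == 0) return(list())
  lapply(seq_len(nchi), function(k) {
    row <- rec[rec$tors == paste0("chi", k), ][1, ]
    c(row$a, row$b, row$c, row$atom)
  })
}

#' Measure the chi angles of one peptide position of a pose
#'
#' @param pose a \linkS4class{PoseModel}.
#' @param position peptide position 1..4.
#' @return numeric vector of chi angles in degrees (length 0 for ALA/GLY).
#' @export
measureChis <- function(pose, position) {
  rows <- .pepRows(pose, position)
  resn <- pose@atoms$resn[rows[1]]
  quads <- .chiAtoms(resn)
  vapply(quads, function(q) {
    idx <- rows[match(q, pose@atoms$name[rows])]
    if (any(is.na(idx))) return(NA_real_)
    dihedralAngle(pose@xyz[idx[1], ], pose@xyz[idx[2], ],
                  pose@xyz[idx[3], ], pose@xyz[idx[4], ])
  }, numeric(1))
}

#' Thread a Cxxx sequence onto the template peptide backbone
#'
#' Copies the template backbone (N, CA, C, O, OXT) unchanged, replaces the
#' residue types by the requested sequence, and builds each side chain at
#' the rotamer library's first entry. Receptor and ligand coordinates come
#' from the template as-is.
#'
#' @param template a \linkS4class{TemplateComplex}.
#' @param sequence 4-letter Cxxx sequence (must start with C).
#' @param rotamers rotamer library (see \code{\link{loadRotamerLibrary}}).
#' @return a \linkS4class{PoseModel}.
#' @examples
#' tpl <- makeToyTemplate()
#' pose <- threadSequence(tpl, "CVIM")
#' @export
threadSequence <- function(template, sequence,
                           rotamers = loadRotamerLibrary()) {
  stopifnot(is(template, "TemplateComplex"))
  letters1 <- .validateCxxx(sequence)
  pep <- atoms(templatePeptide(template))
  resIdx <- .splitResidues(pep)
  rows <- NULL
  for (p in 1:4) {
    res <- pep[resIdx[[p]], , drop = FALSE]
    resn <- .AA3[[letters1[p]]]
    bbNames <- intersect(.BACKBONE_NAMES, res$name)
    bb <- res[match(bbNames, res$name), , drop = FALSE]
    bb$resn <- resn
    get <- function(nm) {
      r <- bb[bb$name == nm, ]
      if (nrow(r) != 1L)
        stop("template peptide residue ", p, " lacks backbone atom ", nm)
      c(r$x, r$y, r$z)
    }
    frame <- list(N = get("N"), CA = get("CA"), C = get("C"))
    rot <- rotamers[[resn]]
    chi <- if (ncol(rot) > 0) rot[1, ] else numeric(0)
    sc <- buildSidechain(resn, frame, chi)
    scRows <- NULL
    if (nrow(sc) > 0) {
      scRows <- bb[rep(1, nrow(sc)), , drop = FALSE]
      scRows$name <- rownames(sc)
      scRows$element <- .elementFromName(rownames(sc))
      scRows$x <- sc[, 1]; scRows$y <- sc[, 2]; scRows$z <- sc[, 3]
    }
    rows <- rbind(rows, bb, scRows)
  }
  rownames(rows) <- NULL
  rows$occ <- 1
  rows$het <- FALSE
  .assemblePose(template, rows, sequence)
}

#' Pack peptide side chains over a rotamer library
#'
#' Finds the lowest-energy rotamer assignment for the flexible peptide
#' positions while the receptor stays fixed. All rotamer combinations are
#' enumerated exhaustively when their number does not exceed \code{limit};
#' above the limit a seeded simulated-annealing search (geometric cooling,
#' position-wise Metropolis moves) is used. \code{extraChi} adds sub-rotamers
#' at +-10 degrees around the chi1 and chi2 base values. The current side
#' chains always compete as a candidate, so packing never increases the
#' energy; ties resolve to the lowest candidate index.
#'
#' @param pose a \linkS4class{PoseModel}.
#' @param flexiblePositions subset of 1:4; positions without rotatable chi
#'   angles are skipped. Empty selection returns the pose unchanged.
#' @param extraChi logical, add +-10 degree chi1/chi2 sub-rotamers.
#' @param energyFn an \linkS4class{EnergyFunction}.
#' @param constraints optional constraint table from
#'   \code{\link{deriveConstraints}}; constraint terms that touch a moving
#'   side chain (the cysteine Sgamma) enter the packing objective.
#' @param seed integer seed for the annealing path (the exhaustive path is
#'   seed-free).
#' @param limit exhaustive-enumeration limit on the number of combinations.
#' @param rotamers rotamer library.
#' @param sweeps,t0,tfac annealing schedule: sweep count, initial
#'   temperature, geometric cooling factor.
#' @return a \linkS4class{PoseModel} with repacked side chains; attributes
#'   \code{packEnergy}, \code{packExhaustive}, \code{packCombinations} carry
#'   diagnostics.
#' @export
packSidechains <- function(pose, flexiblePositions = 1:4, extraChi = TRUE,
                           energyFn = defaultEnergyFunction(),
                           constraints = NULL, seed = 1L, limit = 1e5,
                           rotamers = loadRotamerLibrary(), sweeps = 60L,
                           t0 = 2, tfac = 0.85) {
  stopifnot(is(pose, "PoseModel"))
  if (!all(flexiblePositions %in% 1:4))
    stop("flexiblePositions must be peptide positions (1..4)")
  posAtoms <- list(); cands <- list()
  for (p in flexiblePositions) {
    rows <- .pepSidechainRows(pose, p)
    resn <- pose@atoms$resn[.pepRows(pose, p)[1]]
    rot <- rotamers[[resn]]
    if (ncol(rot) == 0 || length(rows) == 0) next
    if (extraChi) rot <- .expandExtraChi(rot)
    bbRows <- .pepRows(pose, p)
    get <- function(nm) pose@xyz[bbRows[pose@atoms$name[bbRows] == nm], ]
    frame <- list(N = get("N"), CA = get("CA"), C = get("C"))
    cur <- pose@xyz[rows, , drop = FALSE]
    cc <- list(cur)
    nm <- pose@atoms$name[rows]
    for (r in seq_len(nrow(rot))) {
      sc <- buildSidechain(resn, frame, rot[r, ])
      cc[[r + 1L]] <- sc[match(nm, rownames(sc)), , drop = FALSE]
    }
    posAtoms[[length(posAtoms) + 1L]] <- as.integer(rows)
    cands[[length(cands) + 1L]] <- lapply(cc, function(m) {
      dimnames(m) <- NULL
      m
    })
  }
  if (length(posAtoms) == 0) return(pose)

  ea <- .energyArgs(pose, energyFn)
  cs <- .constraintIdx(pose, constraints)
  set.seed(seed)
  res <- .cppPack(pose@xyz, posAtoms, cands, ea$radius, ea$eps, ea$charge,
                  ea$dgfree, ea$vol, ea$donor, ea$acceptor, ea$base,
                  ea$group, pose@exclusions, ea$weights, cs$ci, cs$cj,
                  cs$d0, cs$sd, ea$wcst, limit, as.integer(sweeps), t0, tfac)
  xyz <- pose@xyz
  for (k in seq_along(posAtoms))
    xyz[posAtoms[[k]], ] <- cands[[k]][[res$choice[k]]]
  out <- pose
  out@xyz <- xyz
  attr(out, "packEnergy") <- res$energy
  attr(out, "packExhaustive") <- res$exhaustive
  attr(out, "packCombinations") <- res$n_combinations
  out
}
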