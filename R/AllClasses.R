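#' @import methods
NULL

#' Molecular structure as a flat atom table
#'
#' A thin S4 container around a per-atom data frame, the shape in which PDB
#' records naturally arrive. Columns: \code{name} (PDB atom name),
#' \code{element}, \code{resn} (three-letter residue code), \code{chain},
#' \code{resno} (author numbering), \code{insert} (insertion code, \code{""}
#' if none), \code{x}, \code{y}, \code{z} (Angstrom), \code{occ} (occupancy)
#' and \code{het} (logical, HETATM record).
#'
#' @slot atoms data.frame of atom records.
#' @slot title free-text description.
#' @export
setClass("Structure",
  representation(atoms = "data.frame", title = "character"),
  prototype(title = ""))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("name", "element", "resn", "chain", "resno", "insert",
            "x", "y", "z", "occ", "het")
  if (!all(need %in% names(a)))
    return(paste("atom table must contain columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) > 0) {
    if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
      return("atom coordinates must be finite")
    if (any(!nzchar(a$name)))
      return("atom names must be non-empty")
    key <- paste(a$chain, a$resno, a$insert, a$name)
    if (anyDuplicated(key))
      return("duplicate (chain, resno, insert, atom-name) records")
  }
  TRUE
})

#' Scoring template: receptor, tetrapeptide, ligand and constraint anchors
#'
#' The prepared receptor-peptide complex every Cxxx sequence is threaded
#' onto. The peptide holds exactly four residues with roles C, a1, a2, X
#' (position 1 is cysteine, position 4 carries the C-terminal carboxylate);
#' the ligand (an isoprenoid analog in the real system) is kept as one rigid
#' hetero unit; \code{anchors} names the atoms that define the five harmonic
#' distance constraints: the C-terminal carboxylate oxygen, the a2 backbone
#' carbonyl oxygen, the cysteine Sgamma, the two receptor hydrogen-bond
#' partners (a Gln-amide-like and an Arg-guanidinium-like polar atom) and the
#' three thiol-coordination-site ("zinc triad") side-chain atoms.
#'
#' @slot receptor \linkS4class{Structure} with the fixed receptor.
#' @slot peptide \linkS4class{Structure} with exactly 4 residues.
#' @slot ligand data.frame of hetero atom records (same columns as
#'   \code{atoms(receptor)}), possibly empty.
#' @slot anchors data.frame with columns \code{key} (one of
#'   \code{pep_carboxylate_O}, \code{pep_a2_O}, \code{pep_cys_SG},
#'   \code{q_alpha}, \code{r_beta}, \code{zn_triad_1..3}), \code{segment}
#'   (\code{"peptide"}, \code{"receptor"} or \code{"ligand"}), \code{chain},
#'   \code{resno}, \code{insert}, \code{atom}.
#' @export
setClass("TemplateComplex",
  representation(receptor = "Structure", peptide = "Structure",
                 ligand = "data.frame", anchors = "data.frame"))

.ANCHOR_KEYS <- c("pep_carboxylate_O", "pep_a2_O", "pep_cys_SG",
                  "q_alpha", "r_beta", "zn_triad_1", "zn_triad_2",
                  "zn_triad_3")

setValidity("TemplateComplex", function(object) {
  p <- object@peptide@atoms
  rk <- unique(paste(p$chain, p$resno, p$insert))
  if (length(rk) != 4L)
    return("template peptide must contain exactly 4 residues")
  first <- p[paste(p$chain, p$resno, p$insert) == rk[1], ]
  if (first$resn[1] != "CYS" || !("SG" %in% first$name))
    return("template peptide must present Cys (with SG) at motif position 1")
  last <- p[paste(p$chain, p$resno, p$insert) == rk[4], ]
  if (!all(c("O", "OXT") %in% last$name))
    return("X residue must carry both carboxylate oxygens (O and OXT)")
  if (!setequal(object@anchors$key, .ANCHOR_KEYS))
    return(paste("anchors must define exactly:",
                 paste(.ANCHOR_KEYS, collapse = ", ")))
  # every anchor must resolve to exactly one atom
  for (i in seq_len(nrow(object@anchors))) {
    an <- object@anchors[i, ]
    tab <- switch(an$segment, peptide = object@peptide@atoms,
                  receptor = object@receptor@atoms, ligand = object@ligand)
    hit <- tab$chain == an$chain & tab$resno == an$resno &
      tab$insert == an$insert & tab$name == an$atom
    if (sum(hit) != 1L)
      return(sprintf("anchor '%s' (%s %s:%s%s:%s) resolves to %d atoms",
                     an$key, an$segment, an$chain, an$resno, an$insert,
                     an$atom, sum(hit)))
  }
  TRUE
})

#' Full-atom model of one threaded peptide sequence in the template pocket
#'
#' Holds a single flat atom table (receptor + peptide + ligand) with a
#' coordinate matrix, plus the derived topology (bond list, non-bonded
#' exclusions) and the torsion-space degree-of-freedom layout used by the
#' minimizer. Created by \code{\link{threadSequence}}.
#'
#' @slot atoms data.frame with columns \code{name}, \code{element},
#'   \code{resn}, \code{segment} (\code{peptide}/\code{receptor}/
#'   \code{ligand}), \code{chain}, \code{resno}, \code{insert},
#'   \code{pepPos} (1..4 for peptide atoms, NA otherwise).
#' @slot xyz numeric matrix (n x 3), Angstrom.
#' @slot sequence character, the 4-letter Cxxx sequence.
#' @slot bonds integer matrix (m x 2) of 1-based atom indices.
#' @slot exclusions integer matrix of atom pairs within two bonds.
#' @slot anchorIdx named integer vector mapping anchor keys to atom rows.
#' @slot templateBackbone numeric matrix of the template peptide backbone
#'   coordinates (for the threading-preserves-backbone invariant).
#' @export
setClass("PoseModel",
  representation(atoms = "data.frame", xyz = "matrix", sequence = "character",
                 bonds = "matrix", exclusions = "matrix",
                 anchorIdx = "integer", templateBackbone = "matrix"))

setValidity("PoseModel", function(object) {
  if (nrow(object@atoms) != nrow(object@xyz))
    return("atom table and coordinate matrix disagree in length")
  if (ncol(object@xyz) != 3L) return("xyz must have 3 columns")
  if (any(!is.finite(object@xyz))) return("coordinates must be finite")
  if (!.isValidCxxx(object@sequence))
    return("sequence must be a valid Cxxx tetrapeptide")
  TRUE
})

#' Decomposable energy model
#'
#' Term weights, the per-atom-type parameter table and the per-amino-acid
#' reference energies. Scores are reported in dimensionless energy units.
#'
#' @slot weights named numeric: \code{lj_attr}, \code{lj_rep}, \code{hbond},
#'   \code{solv}, \code{elec}, \code{constraint}.
#' @slot params data.frame with one row per atom type: \code{type},
#'   \code{radius} (Angstrom), \code{eps} (well depth), \code{dgfree}
#'   (solvation free energy of the isolated atom; negative for polar atoms),
#'   \code{vol} (solvation volume).
#' @slot refEnergies named numeric of length 20 (three-letter codes), the
#'   per-amino-acid constant subtracted by the no-reference peptide score.
#' @export
setClass("EnergyFunction",
  representation(weights = "numeric", params = "data.frame",
                 refEnergies = "numeric"))

setValidity("EnergyFunction", function(object) {
  need <- c("lj_attr", "lj_rep", "hbond", "solv", "elec", "constraint")
  if (!all(need %in% names(object@weights)))
    return(paste("weights must name:", paste(need, collapse = ", ")))
  if (any(object@weights[setdiff(need, "constraint")] < 0))
    return("term weights must be non-negative")
  if (!all(names(.N_CHI) %in% names(object@refEnergies)))
    return("reference energies must cover all 20 amino acids")
  TRUE
})

#' Per-residue and cross-interface energy decomposition of a scored pose
#'
#' @slot perResidue named numeric, one entry per residue
#'   (\code{segment:chain:resno} keys); pair terms are attributed half/half
#'   to the two residues so the entries sum exactly to \code{total} minus
#'   \code{constraintTotal}.
#' @slot peptideResidue numeric length 4, the peptide rows of
#'   \code{perResidue} in motif order.
#' @slot crossInterface numeric, sum of peptide-receptor(+ligand) pair terms.
#' @slot constraintTotal numeric, harmonic constraint energy.
#' @slot total numeric, weighted physical energy plus constraint energy.
#' @slot terms named numeric, per-term weighted totals.
#' @slot ibsa numeric, buried interface surface area in Angstrom^2.
#' @export
setClass("EnergyBreakdown",
  representation(perResidue = "numeric", peptideResidue = "numeric",
                 crossInterface = "numeric", constraintTotal = "numeric",
                 total = "numeric", terms = "numeric", ibsa = "numeric"))

setValidity("EnergyBreakdown", function(object) {
  if (abs(sum(object@perResidue) + object@constraintTotal - object@total) >
      1e-6)
    return("per-residue decomposition does not sum to the total")
  TRUE
})

#' Binder classification thresholds
#'
#' Scores at or below \code{stringent} classify as \code{strong_binder},
#' between \code{stringent} and \code{loose} as \code{binder}, above
#' \code{loose} as \code{non_binder}. Defaults are the conventional
#' \eqn{-0.4} / \eqn{-1.1} operating points; because energies are model
#' units, recalibrate with \code{\link{calibrateThresholds}} for any new
#' energy parameterisation.
#'
#' @slot loose numeric threshold (energy units), default -0.4.
#' @slot stringent numeric threshold, default -1.1.
#' @export
setClass("ClassifierConfig",
  representation(loose = "numeric", stringent = "numeric"),
  prototype(loose = -0.4, stringent = -1.1))

setValidity("ClassifierConfig", function(object) {
  if (object@stringent > object@loose)
    return("stringent threshold must not exceed the loose threshold")
  TRUE
})

#' ROC curve with area under the curve
#'
#' Lower score = predicted binder throughout this package (scores are
#' energies); most ROC libraries assume the opposite orientation.
#'
#' @slot points data.frame with columns \code{threshold}, \code{fpr},
#'   \code{tpr}, ordered by threshold.
#' @slot auc numeric in \[0, 1\] (trapezoid; ties count one half).
#' @export
setClass("ROCCurve",
  representation(points = "data.frame", auc = "numeric"))

setValidity("ROCCurve", function(object) {
  p <- object@points
  if (!all(c("threshold", "fpr", "tpr") %in% names(p)))
    return("points must have threshold, fpr, tpr columns")
  if (is.unsorted(p$fpr) || is.unsorted(p$tpr))
    return("fpr and tpr must be non-decreasing")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' Result of a torsion-space minimization
#'
#' @slot pose the final \linkS4class{PoseModel}.
#' @slot startEnergy,endEnergy objective values (energy units) before/after.
#' @slot iterations quasi-Newton iterations performed.
#' @slot converged logical; absolute objective change fell below tolerance.
#' @slot tolerance the convergence tolerance used.
#' @export
setClass("MinimizeResult",
  representation(pose = "PoseModel", startEnergy = "numeric",
                 endEnergy = "numeric", iterations = "integer",
                 converged = "logical", tolerance = "numeric"))

setValidity("MinimizeResult", function(object) {
  if (object@endEnergy > object@startEnergy + 1e-9)
    return("minimization must not increase the objective")
  TRUE
})

setMethod("show", "MinimizeResult", function(object) {
  cat(sprintf(
    "MinimizeResult: %.4f -> %.4f in %d iterations (%s, tol %g)\n",
    object@startEnergy, object@endEnergy, object@iterations,
    if (object@converged) "converged" else "not converged",
    object@tolerance))
})

#' Scored, classified Cxxx sequence
#'
#' @slot sequence the 4-letter Cxxx sequence.
#' @slot score peptide score (energy units; no-reference scheme by default).
#' @slot scheme scoring scheme identifier.
#' @slot classification \code{strong_binder}, \code{binder} or
#'   \code{non_binder} under the thresholds in force.
#' @slot diagnostics list: constraint residual, minimizer iterations,
#'   convergence flag, packing mode.
#' @export
setClass("ScoreRecord",
  representation(sequence = "character", score = "numeric",
                 scheme = "character", classification = "character",
                 diagnostics = "list"))

setMethod("show", "ScoreRecord", function(object) {
  cat(sprintf("ScoreRecord %s: %s = %.3f -> %s\n", object@sequence,
              object@scheme, object@score, object@classification))
})

#' Labeled peptide benchmark set
#'
#' @slot records data.frame with columns \code{sequence}, \code{label} and
#'   optionally \code{score}.
#' @slot positiveLabels character, labels counted as positives.
#' @export
setClass("LabeledPeptideSet",
  representation(records = "data.frame", positiveLabels = "character"))

setValidity("LabeledPeptideSet", function(object) {
  r <- object@records
  if (!all(c("sequence", "label") %in% names(r)))
    return("records must have sequence and label columns")
  if (anyDuplicated(r$sequence)) return("sequences must be unique")
  TRUE
})
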