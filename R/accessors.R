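# Accessors and show methods. Slot access from user code should go through
# these.

#' @describeIn Structure-class atom table accessor
#' @param x a \code{Structure}.
#' @export
atoms <- function(x) {
  stopifnot(is(x, "Structure"))
  x@atoms
}

#' @describeIn Structure-class number of atoms
#' @export
nAtoms <- function(x) nrow(atoms(x))

#' Coordinate matrix of a Structure or PoseModel
#' @param x a \code{Structure} or \code{PoseModel}.
#' @return numeric matrix (n x 3).
#' @export
coords <- function(x) {
  if (is(x, "PoseModel")) return(x@xyz)
  a <- atoms(x)
  as.matrix(a[, c("x", "y", "z")])
}

#' One-letter peptide sequence of a pose or template
#' @param x a \code{PoseModel} or \code{TemplateComplex}.
#' @return character scalar (4 letters).
#' @export
peptideSequence <- function(x) {
  if (is(x, "PoseModel")) return(x@sequence)
  stopifnot(is(x, "TemplateComplex"))
  p <- x@peptide@atoms
  keys <- unique(paste(p$chain, p$resno, p$insert))
  res3 <- vapply(keys, function(k)
    p$resn[paste(p$chain, p$resno, p$insert) == k][1], "")
  paste(.AA1[res3], collapse = "")
}

#' @describeIn TemplateComplex-class receptor structure accessor
#' @param x a \code{TemplateComplex}.
#' @export
receptor <- function(x) {
  stopifnot(is(x, "TemplateComplex"))
  x@receptor
}

#' @describeIn TemplateComplex-class peptide structure accessor
#' @export
templatePeptide <- function(x) {
  stopifnot(is(x, "TemplateComplex"))
  x@peptide
}

#' @describeIn TemplateComplex-class ligand atom table accessor
#' @export
ligandAtoms <- function(x) {
  stopifnot(is(x, "TemplateComplex"))
  x@ligand
}

#' @describeIn TemplateComplex-class anchor definition table accessor
#' @export
anchors <- function(x) {
  stopifnot(is(x, "TemplateComplex"))
  x@anchors
}

#' Per-residue energies of an EnergyBreakdown
#' @param x an \code{EnergyBreakdown}.
#' @export
perResidue <- function(x) {
  stopifnot(is(x, "EnergyBreakdown"))
  x@perResidue
}

#' @describeIn perResidue total energy (physical terms + constraints)
#' @export
totalScore <- function(x) {
  stopifnot(is(x, "EnergyBreakdown"))
  x@total
}

#' @describeIn perResidue constraint energy of the breakdown
#' @export
constraintTotal <- function(x) {
  stopifnot(is(x, "EnergyBreakdown"))
  x@constraintTotal
}

#' Area under the curve of a ROCCurve
#' @param x a \code{ROCCurve}.
#' @export
auc <- function(x) {
  stopifnot(is(x, "ROCCurve"))
  x@auc
}

#' @describeIn auc the (threshold, fpr, tpr) point table
#' @export
rocPoints <- function(x) {
  stopifnot(is(x, "ROCCurve"))
  x@points
}

#' Record table of a LabeledPeptideSet
#' @param x a \code{LabeledPeptideSet}.
#' @export
records <- function(x) {
  stopifnot(is(x, "LabeledPeptideSet"))
  x@records
}

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  nres <- length(unique(paste(a$chain, a$resno, a$insert)))
  cat(sprintf("Structure: %d atoms, %d residues, chains: %s\n",
              nrow(a), nres, paste(unique(a$chain), collapse = " ")))
  if (nzchar(object@title)) cat(" ", object@title, "\n")
})

setMethod("show", "TemplateComplex", function(object) {
  cat(sprintf(
    "TemplateComplex: peptide %s | receptor %d atoms | ligand %d atoms\n",
    peptideSequence(object), nrow(object@receptor@atoms),
    nrow(object@ligand)))
  cat("  anchors:", paste(object@anchors$key, collapse = " "), "\n")
})

setMethod("show", "PoseModel", function(object) {
  tab <- table(object@atoms$segment)
  cat(sprintf("PoseModel %s: %d atoms (%s)\n", object@sequence,
              nrow(object@atoms),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf(
    "EnergyBreakdown: total %.3f (constraints %.3f), interface %.3f, iBSA %.1f A^2\n",
    object@total, object@constraintTotal, object@crossInterface,
    object@ibsa))
  cat(sprintf("  peptide residues: %s\n",
              paste(sprintf("%.3f", object@peptideResidue), collapse = " ")))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: AUC = %.4f over %d thresholds (lower score = positive)\n",
              object@auc, nrow(object@points)))
})

setMethod("show", "ClassifierConfig", function(object) {
  cat(sprintf("ClassifierConfig: binder <= %.3g, strong binder <= %.3g\n",
              object@loose, object@stringent))
})

setMethod("show", "LabeledPeptideSet", function(object) {
  tab <- table(object@records$label)
  cat(sprintf("LabeledPeptideSet: %d peptides (%s); positives: %s\n",
              nrow(object@records),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              paste(object@positiveLabels, collapse = ",")))
})

#' Classifier configuration constructor
#'
#' @param loose loose threshold (energy units); scores at or below it are
#'   called binders.
#' @param stringent stringent threshold; scores at or below it are called
#'   strong binders. Must not exceed \code{loose}.
#' @return a \linkS4class{ClassifierConfig}.
#' @export
classifierConfig <- function(loose = -0.4, stringent = -1.1) {
  new("ClassifierConfig", loose = loose, stringent = stringent)
}

.isValidCxxx <- function(s) {
  length(s) == 1L && is.character(s) && nchar(s) == 4L &&
    substr(s, 1, 1) == "C" &&
    all(strsplit(s, "")[[1]] %in% names(.AA3))
}
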