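# The binding-specificity pipeline: thread -> pack -> minimize -> score ->
# classify; plus Cxxx sequence-space enumeration, proteome scanning and
# position frequency matrices.

#' Classify a peptide score against the two thresholds
#'
#' Scores exactly equal to a threshold classify into the more favorable
#' class (the "at-or-below passes" tie rule).
#'
#' @param score numeric vector of peptide scores (energy units; lower =
#'   better binder).
#' @param config a \linkS4class{ClassifierConfig}.
#' @return character vector: \code{strong_binder}, \code{binder} or
#'   \code{non_binder}.
#' @export
classifyScore <- function(score, config = classifierConfig()) {
  stopifnot(is(config, "ClassifierConfig"))
  ifelse(score <= config@stringent, "strong_binder",
         ifelse(score <= config@loose, "binder", "non_binder"))
}

#' Score one Cxxx sequence against a template
#'
#' Runs the full pipeline: thread the sequence onto the template backbone,
#' pack the peptide side chains over the rotamer library (receptor fixed),
#' minimize all peptide torsions, the peptide rigid body, receptor
#' interface side chains and ligand dihedrals under the template's harmonic
#' constraints, then score and classify. The reported score is the
#' no-reference peptide scheme.
#'
#' @param template a \linkS4class{TemplateComplex}.
#' @param sequence 4-letter Cxxx sequence.
#' @param config classification thresholds.
#' @param energyFn energy function.
#' @param constraints constraint table; default derived from the template
#'   at sd 0.1 Angstrom.
#' @param seed integer seed (used only when packing falls back to
#'   annealing).
#' @param extraChi add chi1/chi2 sub-rotamers during packing.
#' @param maxIter minimizer iteration cap.
#' @param rotamers rotamer library.
#' @param returnPose logical; also attach the minimized pose and full
#'   breakdown to the diagnostics.
#' @return a \linkS4class{ScoreRecord}.
#' @export
scoreSequence <- function(template, sequence, config = classifierConfig(),
                          energyFn = defaultEnergyFunction(),
                          constraints = NULL, seed = 1L, extraChi = TRUE,
                          maxIter = 200L, rotamers = loadRotamerLibrary(),
                          returnPose = FALSE) {
  stopifnot(is(template, "TemplateComplex"))
  if (is.null(constraints)) constraints <- deriveConstraints(template)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, ": ", conditionMessage(e), call. = FALSE))
  }
  pose <- stage("threading",
                threadSequence(template, sequence, rotamers = rotamers))
  packed <- stage("packing",
                  packSidechains(pose, flexiblePositions = 1:4,
                                 extraChi = extraChi, energyFn = energyFn,
                                 constraints = constraints, seed = seed,
                                 rotamers = rotamers))
  minres <- stage("minimization",
                  minimizePose(packed, energyFn = energyFn,
                               constraints = constraints,
                               maxIter = maxIter))
  final <- minres@pose
  breakdown <- stage("scoring",
                     scorePose(final, energyFn, constraints, ibsa = FALSE))
  score <- peptideScore(breakdown, sequence, energyFn, includeRef = FALSE)
  diag <- list(
    constraintResidual = constraintEnergy(final, constraints),
    iterations = minres@iterations,
    converged = minres@converged,
    startEnergy = minres@startEnergy,
    endEnergy = minres@endEnergy,
    packExhaustive = isTRUE(attr(packed, "packExhaustive")),
    interfaceScore = interfaceScore(breakdown))
  if (returnPose) {
    diag$pose <- final
    diag$breakdown <- breakdown
  }
  new("ScoreRecord", sequence = sequence, score = score,
      scheme = "peptide_noref", classification = classifyScore(score, config),
      diagnostics = diag)
}

#' Score a batch of Cxxx sequences
#'
#' @param template a \linkS4class{TemplateComplex}.
#' @param sequences character vector of Cxxx sequences.
#' @param ... passed to \code{\link{scoreSequence}}.
#' @param verbose print progress every 10 sequences.
#' @return data.frame with columns \code{sequence}, \code{score},
#'   \code{classification}, \code{constraint_residual}, \code{iterations},
#'   \code{converged}. Results are independent of evaluation order.
#' @export
scoreSequences <- function(template, sequences, ..., verbose = FALSE) {
  out <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    r <- scoreSequence(template, sequences[i], ...)
    out[[i]] <- data.frame(
      sequence = r@sequence, score = r@score,
      classification = r@classification,
      constraint_residual = r@diagnostics$constraintResidual,
      iterations = r@diagnostics$iterations,
      converged = r@diagnostics$converged, stringsAsFactors = FALSE)
    if (verbose && i %% 10 == 0)
      message(sprintf("scored %d/%d", i, length(sequences)))
  }
  do.call(rbind, out)
}

#' Enumerate all Cxxx tetrapeptide sequences
#'
#' @return character vector of all 20^3 = 8000 sequences C + AA^3 in
#'   lexicographic one-letter order (first element "CAAA").
#' @export
enumerateCxxx <- function() {
  aa <- sort(names(.AA3))
  grid <- expand.grid(x3 = aa, x2 = aa, x1 = aa, stringsAsFactors = FALSE)
  paste0("C", grid$x1, grid$x2, grid$x3)
}

#' Scan a proteome for C-terminal Cxxx motifs
#'
#' Reports, for every protein whose final four residues match C-x-x-x with
#' standard amino-acid letters, the motif and protein length. Proteins
#' shorter than four residues or with non-standard letters in the motif
#' window (X, U, B, Z, ...) are skipped with a warning. Matching is
#' case-insensitive and independent of FASTA line wrapping.
#'
#' @param fasta path to a FASTA file of protein sequences.
#' @param unique logical; when TRUE, collapse to one row per unique motif
#'   with columns \code{motif}, \code{n_proteins}, \code{protein_ids}
#'   (comma-separated).
#' @return data.frame of motif hits.
#' @export
scanProteome <- function(fasta, unique = FALSE) {
  seqs <- tryCatch(Biostrings::readAAStringSet(fasta),
                   error = function(e) stop("unreadable FASTA: ",
                                            conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(seqs))
  out <- NULL
  skipped <- 0L
  for (i in seq_along(seqs)) {
    s <- toupper(as.character(seqs[[i]]))
    s <- gsub("\\*$", "", s)  # trailing stop codon marker
    if (nchar(s) < 4L) {
      warning("skipping ", ids[i], ": shorter than 4 residues")
      skipped <- skipped + 1L
      next
    }
    motif <- substr(s, nchar(s) - 3L, nchar(s))
    letters1 <- strsplit(motif, "")[[1]]
    if (!all(letters1 %in% names(.AA3))) {
      warning("skipping ", ids[i], ": non-standard letter in C-terminal window")
      skipped <- skipped + 1L
      next
    }
    if (letters1[1] != "C") next
    out <- rbind(out, data.frame(protein_id = ids[i], motif = motif,
                                 protein_length = nchar(s),
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(protein_id = character(0), motif = character(0),
                      protein_length = integer(0))
  if (unique && nrow(out) > 0) {
    sp <- split(out$protein_id, out$motif)
    out <- data.frame(motif = names(sp),
                      n_proteins = vapply(sp, length, 1L),
                      protein_ids = vapply(sp, paste, "", collapse = ","),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  out
}

#' Position frequency matrix of Cxxx sequences
#'
#' @param sequences character vector of valid Cxxx sequences.
#' @param pseudocount added to every cell before normalization (default 0).
#' @return 20 x 4 numeric matrix (rows: one-letter amino acids, columns
#'   C, a1, a2, X); each column sums to 1.
#' @export
positionFrequencyMatrix <- function(sequences, pseudocount = 0) {
  stopifnot(length(sequences) > 0)
  for (s in sequences) .validateCxxx(s)
  aa <- sort(names(.AA3))
  m <- matrix(pseudocount, nrow = 20, ncol = 4,
              dimnames = list(aa, c("C", "a1", "a2", "X")))
  for (s in sequences) {
    letters1 <- strsplit(s, "")[[1]]
    for (p in 1:4) m[letters1[p], p] <- m[letters1[p], p] + 1
  }
  sweep(m, 2, colSums(m), "/")
}
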