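# Decomposable energy model: weighted Lennard-Jones (linearized repulsion),
# distance-and-angle hydrogen bonds, Gaussian-exclusion implicit solvation,
# Coulomb with distance-dependent dielectric, all switched to zero at an
# 8 Angstrom pair cutoff; plus harmonic distance constraints. Energies are
# dimensionless model units: they are NOT numerically transferable to any
# external force field, and classification thresholds should be calibrated
# (see calibrateThresholds) whenever the parameterisation changes.

.DEFAULT_WEIGHTS <- c(lj_attr = 1.0, lj_rep = 0.55, hbond = 1.5,
                      solv = 1.0, elec = 0.15, constraint = 1.0)

#' Default energy function
#'
#' @param weights optional named numeric overriding any of \code{lj_attr},
#'   \code{lj_rep}, \code{hbond}, \code{solv}, \code{elec},
#'   \code{constraint}.
#' @param refEnergies optional named numeric (three-letter codes) of
#'   per-amino-acid reference energies; the shipped default is all zeros
#'   (no-reference and with-reference peptide scores then coincide).
#' @param paramsPath path to the atom-type parameter table.
#' @return an \linkS4class{EnergyFunction}.
#' @export
defaultEnergyFunction <- function(weights = NULL, refEnergies = NULL,
                                  paramsPath = system.file(
                                    "extdata", "atom_params.tsv",
                                    package = "caaxbind")) {
  w <- .DEFAULT_WEIGHTS
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), names(w))
    if (length(bad) > 0) stop("unknown weight(s): ", paste(bad, collapse = ", "))
    w[names(weights)] <- weights
  }
  params <- utils::read.delim(paramsPath, comment.char = "#",
                              stringsAsFactors = FALSE)
  refs <- stats::setNames(rep(0, length(.N_CHI)), names(.N_CHI))
  if (!is.null(refEnergies)) refs[names(refEnergies)] <- refEnergies
  new("EnergyFunction", weights = w, params = params, refEnergies = refs)
}

# aligned per-atom parameter vectors for the compiled evaluator
.energyArgs <- function(pose, energyFn) {
  at <- pose@atoms
  p <- energyFn@params
  m <- match(at$type, p$type)
  if (any(is.na(m))) {
    bad <- which(is.na(m))[1]
    stop("atom type '", at$type[bad], "' (atom ", at$name[bad], " of ",
         at$resn[bad], " ", at$chain[bad], ":", at$resno[bad],
         ") missing from the parameter table")
  }
  group <- c(peptide = 1L, receptor = 2L, ligand = 3L)[at$segment]
  list(radius = p$radius[m], eps = p$eps[m], charge = at$charge,
       dgfree = p$dgfree[m], vol = p$vol[m],
       donor = as.integer(at$donor), acceptor = as.integer(at$acceptor),
       base = as.integer(at$base), group = unname(group),
       weights = unname(energyFn@weights[c("lj_attr", "lj_rep", "hbond",
                                           "solv", "elec")]),
       wcst = unname(energyFn@weights[["constraint"]]))
}

#' Derive the five template distance constraints
#'
#' Measures, in the template, the two conserved hydrogen-bond distances
#' (C-terminal carboxylate to the Gln-amide anchor; a2 backbone carbonyl O
#' to the Arg-guanidinium anchor) and the three cysteine-Sgamma distances to
#' the thiol-coordination triad, and returns them as harmonic restraints
#' with reference length equal to the measured distance.
#'
#' @param template a \linkS4class{TemplateComplex}.
#' @param sd harmonic standard deviation in Angstrom (default 0.1; 0.25 is
#'   a documented softer alternative).
#' @return data.frame with columns \code{atom_a}, \code{atom_b} (anchor
#'   keys), \code{d0} (Angstrom) and \code{sd}.
#' @export
deriveConstraints <- function(template, sd = 0.1) {
  stopifnot(is(template, "TemplateComplex"), sd > 0)
  an <- anchors(template)
  pos <- function(key) {
    a <- an[an$key == key, ]
    tab <- switch(a$segment, peptide = atoms(templatePeptide(template)),
                  receptor = atoms(receptor(template)),
                  ligand = ligandAtoms(template))
    r <- tab[tab$chain == a$chain & tab$resno == a$resno &
               tab$insert == a$insert & tab$name == a$atom, ]
    if (nrow(r) != 1L) stop("unresolved anchor: ", key)
    c(r$x, r$y, r$z)
  }
  pairs <- rbind(
    c("pep_carboxylate_O", "q_alpha"),
    c("pep_a2_O", "r_beta"),
    c("pep_cys_SG", "zn_triad_1"),
    c("pep_cys_SG", "zn_triad_2"),
    c("pep_cys_SG", "zn_triad_3"))
  d0 <- apply(pairs, 1, function(pr) .vnorm(pos(pr[1]) - pos(pr[2])))
  if (any(d0 <= 0)) stop("constraint reference length must be positive")
  data.frame(atom_a = pairs[, 1], atom_b = pairs[, 2], d0 = d0, sd = sd,
             stringsAsFactors = FALSE)
}

# resolve a constraint table to pose atom indices
.constraintIdx <- function(pose, constraints) {
  if (is.null(constraints) || nrow(constraints) == 0)
    return(list(ci = integer(0), cj = integer(0), d0 = numeric(0),
                sd = numeric(0)))
  look <- function(key) {
    if (!key %in% names(pose@anchorIdx))
      stop("constraint atom '", key, "' missing from pose anchors")
    pose@anchorIdx[[key]]
  }
  list(ci = vapply(constraints$atom_a, look, 1L, USE.NAMES = FALSE),
       cj = vapply(constraints$atom_b, look, 1L, USE.NAMES = FALSE),
       d0 = constraints$d0, sd = constraints$sd)
}

#' Harmonic constraint energy of a pose
#'
#' Sum of \eqn{((d - d0)/sd)^2} over the constraint table (unweighted; the
#' constraint weight of the energy function applies when constraints enter
#' a total score or the minimization objective).
#'
#' @param pose a \linkS4class{PoseModel}.
#' @param constraints constraint table from \code{\link{deriveConstraints}}.
#' @return numeric scalar.
#' @export
constraintEnergy <- function(pose, constraints) {
  cs <- .constraintIdx(pose, constraints)
  if (length(cs$ci) == 0) return(0)
  .cppConstraintEnergy(pose@xyz, cs$ci, cs$cj, cs$d0, cs$sd)
}

#' Score a pose with full decomposition
#'
#' Evaluates all pair terms, attributes each pair energy half/half to its
#' two residues (making the per-residue decomposition sum exactly to the
#' physical total), accumulates the peptide-receptor(+ligand) cross-interface
#' sum, adds the weighted constraint energy, and computes the buried
#' interface surface area.
#'
#' @param pose a \linkS4class{PoseModel}.
#' @param energyFn an \linkS4class{EnergyFunction}.
#' @param constraints optional constraint table.
#' @param ibsa logical; compute buried surface area (small extra cost).
#' @return an \linkS4class{EnergyBreakdown}.
#' @export
scorePose <- function(pose, energyFn = defaultEnergyFunction(),
                      constraints = NULL, ibsa = TRUE) {
  stopifnot(is(pose, "PoseModel"))
  ea <- .energyArgs(pose, energyFn)
  res <- .cppEnergy(pose@xyz, ea$radius, ea$eps, ea$charge, ea$dgfree,
                    ea$vol, ea$donor, ea$acceptor, ea$base, ea$group,
                    pose@exclusions, ea$weights)
  at <- pose@atoms
  resKey <- paste(at$segment, at$chain, at$resno, at$insert, sep = ":")
  per <- tapply(res$per_atom, factor(resKey, levels = unique(resKey)), sum)
  per <- stats::setNames(as.numeric(per), names(per))

  pepKeys <- unique(resKey[at$segment == "peptide"])
  cstRaw <- constraintEnergy(pose, constraints)
  cstTot <- ea$wcst * cstRaw
  terms <- stats::setNames(res$terms,
                           c("lj_attr", "lj_rep", "hbond", "solv", "elec"))
  new("EnergyBreakdown",
      perResidue = per,
      peptideResidue = unname(per[pepKeys]),
      crossInterface = res$cross_interface,
      constraintTotal = cstTot,
      total = res$total + cstTot,
      terms = terms,
      ibsa = if (ibsa) buriedSurfaceArea(pose) else NA_real_)
}

#' Peptide score (with or without per-residue reference energies)
#'
#' The discrimination score: the summed energy contribution of the four
#' peptide residues. With \code{includeRef = FALSE} (the default scheme) the
#' per-amino-acid reference constant is subtracted from each residue;
#' \code{includeRef = TRUE} returns the plain per-residue sum. With the
#' shipped all-zero reference table the two schemes coincide.
#'
#' @param breakdown an \linkS4class{EnergyBreakdown} from a 4-residue
#'   peptide pose.
#' @param sequence the pose's 4-letter sequence (needed to look up
#'   reference energies; may be omitted when all references are zero).
#' @param energyFn the energy function carrying the reference table.
#' @param includeRef logical, see above.
#' @return numeric scalar (energy units).
#' @export
peptideScore <- function(breakdown, sequence = NULL,
                         energyFn = defaultEnergyFunction(),
                         includeRef = FALSE) {
  stopifnot(is(breakdown, "EnergyBreakdown"),
            length(breakdown@peptideResidue) == 4L)
  s <- sum(breakdown@peptideResidue)
  if (includeRef) return(s)
  if (is.null(sequence)) {
    if (any(energyFn@refEnergies != 0))
      stop("sequence required to subtract non-zero reference energies")
    return(s)
  }
  letters1 <- strsplit(sequence, "")[[1]]
  s - sum(energyFn@refEnergies[.AA3[letters1]])
}

#' Interface score
#'
#' The energy of the complex less the energies of the separated partners,
#' i.e. exactly the peptide-receptor(+ligand) cross-interface pair sum of
#' the decomposition.
#'
#' @param breakdown an \linkS4class{EnergyBreakdown}.
#' @return numeric scalar.
#' @export
interfaceScore <- function(breakdown) {
  stopifnot(is(breakdown, "EnergyBreakdown"))
  breakdown@crossInterface
}

#' Buried interface surface area (iBSA)
#'
#' Shrake-Rupley solvent-accessible surface area with a 1.4 Angstrom probe:
#' SASA(peptide) + SASA(receptor + ligand) - SASA(complex).
#'
#' @param pose a \linkS4class{PoseModel}.
#' @param probe probe radius, Angstrom.
#' @param nPoints sphere sample points per atom.
#' @return buried area in Angstrom^2.
#' @export
buriedSurfaceArea <- function(pose, probe = 1.4, nPoints = 240L) {
  ea <- .energyArgs(pose, defaultEnergyFunction())
  pep <- which(pose@atoms$segment == "peptide")
  rest <- which(pose@atoms$segment != "peptide")
  sasaOf <- function(idx) {
    sum(.cppSasa(pose@xyz[idx, , drop = FALSE], ea$radius[idx], probe,
                 as.integer(nPoints)))
  }
  sasaOf(pep) + sasaOf(rest) - sasaOf(seq_len(nrow(pose@atoms)))
}
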