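# Torsion-space quasi-Newton minimization under constraints.
#
# The degree-of-freedom set follows the simple-minimization protocol: all
# peptide phi/psi/omega and side-chain chi angles, the peptide's rigid-body
# placement, the chi angles of receptor interface side chains (Cbeta within
# the cutoff of any peptide atom), and the ligand's rotatable dihedrals. The
# receptor backbone and non-interface side chains never move.

#' Receptor residues whose side chains flank the peptide
#'
#' A receptor residue counts as interface when its Cbeta (Calpha for
#' glycine) lies within \code{cutoff} of any peptide atom.
#'
#' @param pose a \linkS4class{PoseModel}.
#' @param cutoff distance cutoff in Angstrom (default 8).
#' @return data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resn}.
#' @export
selectInterfaceSidechains <- function(pose, cutoff = 8.0) {
  stopifnot(is(pose, "PoseModel"), cutoff > 0)
  at <- pose@atoms
  pep <- pose@xyz[at$segment == "peptide", , drop = FALSE]
  rows <- which(at$segment == "receptor")
  keys <- unique(paste(at$chain[rows], at$resno[rows], at$insert[rows],
                       sep = "\r"))
  out <- NULL
  for (k in keys) {
    ri <- rows[paste(at$chain[rows], at$resno[rows], at$insert[rows],
                     sep = "\r") == k]
    probe <- ri[at$name[ri] == "CB"]
    if (length(probe) == 0) probe <- ri[at$name[ri] == "CA"]
    if (length(probe) == 0) next
    p <- pose@xyz[probe[1], ]
    dmin <- sqrt(min(colSums((t(pep) - p)^2)))
    if (dmin <= cutoff)
      out <- rbind(out, data.frame(chain = at$chain[ri[1]],
                                   resno = at$resno[ri[1]],
                                   insert = at$insert[ri[1]],
                                   resn = at$resn[ri[1]],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resn = character(0))
  out
}

# --- DOF layout -------------------------------------------------------------

.emptyDofs <- function() {
  list(type = integer(0), a = integer(0), b = integer(0),
       moving = list(), label = character(0), quad = list())
}

.addDof <- function(dofs, type, a, b, moving, label, quad = NULL) {
  dofs$type <- c(dofs$type, as.integer(type))
  dofs$a <- c(dofs$a, as.integer(a))
  dofs$b <- c(dofs$b, as.integer(b))
  dofs$moving[[length(dofs$moving) + 1L]] <- as.integer(moving)
  dofs$label <- c(dofs$label, label)
  # plain [[<- would delete the element when quad is NULL
  dofs$quad[length(dofs$quad) + 1L] <- list(quad)
  dofs
}

# torsion about bond a-b; skipped when the bond sits in a ring
.addTorsion <- function(dofs, adj, a, b, label, quad = NULL,
                        restrictTo = NULL) {
  moving <- .componentWithout(adj, b, a, b)
  if (a %in% moving) return(dofs)  # ring bond: not rotatable
  if (!is.null(restrictTo)) moving <- intersect(moving, restrictTo)
  if (length(moving) <= 1) return(dofs)
  .addDof(dofs, 1L, a, b, moving, label, quad)
}

#' Build the degree-of-freedom list for minimization
#'
#' @param pose a \linkS4class{PoseModel}.
#' @param peptideTorsions include all peptide phi/psi/omega and chi angles.
#' @param rigidBody include the peptide's 6 rigid-body degrees of freedom.
#' @param receptorChis include chi angles of receptor interface residues.
#' @param ligandDihedrals include the ligand's rotatable (non-ring,
#'   non-terminal) dihedrals; set \code{FALSE} for a rigid ligand.
#' @param interfaceCutoff Cbeta cutoff (Angstrom) for the interface
#'   selection.
#' @return an opaque DOF list consumed by \code{\link{minimizePose}} and
#'   \code{\link{rebuildCoordinates}}; its \code{label} element names each
#'   degree of freedom.
#' @export
poseDofs <- function(pose, peptideTorsions = TRUE, rigidBody = TRUE,
                     receptorChis = TRUE, ligandDihedrals = TRUE,
                     interfaceCutoff = 8.0) {
  stopifnot(is(pose, "PoseModel"))
  at <- pose@atoms
  adj <- .adjacency(pose@bonds, nrow(at))
  dofs <- .emptyDofs()

  findAtom <- function(rows, nm) {
    i <- rows[at$name[rows] == nm]
    if (length(i) != 1L) NA_integer_ else i
  }

  if (peptideTorsions) {
    for (p in 1:4) {
      rows <- .pepRows(pose, p)
      N <- findAtom(rows, "N"); CA <- findAtom(rows, "CA")
      C <- findAtom(rows, "C")
      prevC <- if (p > 1) findAtom(.pepRows(pose, p - 1L), "C") else NA
      nxtN <- if (p < 4) findAtom(.pepRows(pose, p + 1L), "N") else NA
      # phi: C(i-1)-N-CA-C
      quad <- if (!is.na(prevC)) c(prevC, N, CA, C) else NULL
      dofs <- .addTorsion(dofs, adj, N, CA, sprintf("pep%d_phi", p), quad)
      # psi: N-CA-C-N(i+1) (for the last residue, N-CA-C-O)
      O <- findAtom(rows, "O")
      quad <- c(N, CA, C, if (!is.na(nxtN)) nxtN else O)
      dofs <- .addTorsion(dofs, adj, CA, C, sprintf("pep%d_psi", p), quad)
      # omega: CA-C-N(i+1)-CA(i+1)
      if (!is.na(nxtN)) {
        nxtCA <- findAtom(.pepRows(pose, p + 1L), "CA")
        dofs <- .addTorsion(dofs, adj, C, nxtN, sprintf("pep%d_omega", p),
                            c(CA, C, nxtN, nxtCA))
      }
      # side-chain chis
      resn <- at$resn[rows[1]]
      axes <- .CHI_AXES[[resn]]
      quads <- .chiAtoms(resn)
      if (!is.null(axes)) {
        for (k in seq_along(axes)) {
          a <- findAtom(rows, axes[[k]][1]); b <- findAtom(rows, axes[[k]][2])
          if (is.na(a) || is.na(b)) next
          quad <- rows[match(quads[[k]], at$name[rows])]
          dofs <- .addTorsion(dofs, adj, a, b,
                              sprintf("pep%d_chi%d", p, k), quad)
        }
      }
    }
  }

  if (rigidBody) {
    pepAll <- which(at$segment == "peptide")
    for (ax in 1:3)
      dofs <- .addDof(dofs, 2L, ax, 0L, pepAll, sprintf("rb_trans_%d", ax))
    for (ax in 1:3)
      dofs <- .addDof(dofs, 3L, ax, 0L, pepAll, sprintf("rb_rot_%d", ax))
  }

  if (receptorChis) {
    iface <- selectInterfaceSidechains(pose, interfaceCutoff)
    for (i in seq_len(nrow(iface))) {
      rows <- which(at$segment == "receptor" & at$chain == iface$chain[i] &
                      at$resno == iface$resno[i] &
                      at$insert == iface$insert[i])
      resn <- iface$resn[i]
      axes <- .CHI_AXES[[resn]]
      quads <- .chiAtoms(resn)
      if (is.null(axes)) next
      for (k in seq_along(axes)) {
        a <- findAtom(rows, axes[[k]][1]); b <- findAtom(rows, axes[[k]][2])
        if (is.na(a) || is.na(b)) next
        quad <- rows[match(quads[[k]], at$name[rows])]
        dofs <- .addTorsion(dofs, adj, a, b,
                            sprintf("rec_%s%s_chi%d", iface$resno[i],
                                    iface$insert[i], k), quad,
                            restrictTo = rows)
      }
    }
  }

  if (ligandDihedrals) {
    lig <- which(at$segment == "ligand")
    if (length(lig) >= 4) {
      bonds <- pose@bonds
      inLig <- bonds[, 1] %in% lig & bonds[, 2] %in% lig
      lb <- bonds[inLig, , drop = FALSE]
      for (k in seq_len(nrow(lb))) {
        a <- lb[k, 1]; b <- lb[k, 2]
        moving <- .componentWithout(adj, b, a, b)
        if (a %in% moving) next
        moving <- intersect(moving, lig)
        if (length(moving) < 2 || length(lig) - length(moving) < 2) next
        dofs <- .addDof(dofs, 1L, a, b, moving,
                        sprintf("lig_tors_%d", k))
      }
    }
  }
  dofs
}

# measure current values of torsion DOFs with a defined reference quadruple
.measureDofs <- function(pose, dofs) {
  vapply(seq_along(dofs$type), function(k) {
    q <- dofs$quad[[k]]
    if (dofs$type[k] != 1L || is.null(q) || any(is.na(q))) return(0)
    dihedralAngle(pose@xyz[q[1], ], pose@xyz[q[2], ], pose@xyz[q[3], ],
                  pose@xyz[q[4], ])
  }, numeric(1))
}

#' Rebuild pose coordinates from a torsion state
#'
#' Torsion degrees of freedom with a defined reference quadruple are driven
#' to the requested absolute angle (degrees); rigid-body entries and
#' torsions without a reference (e.g. the N-terminal phi) are interpreted as
#' displacements from the current state (0 = unchanged). Bond lengths and
#' angles are never altered, and atoms outside every moving set keep their
#' coordinates bitwise.
#'
#' @param pose a \linkS4class{PoseModel}.
#' @param torsionState numeric vector matching the DOF layout.
#' @param dofs DOF list from \code{\link{poseDofs}}.
#' @return a \linkS4class{PoseModel} with rebuilt coordinates.
#' @export
rebuildCoordinates <- function(pose, torsionState, dofs = poseDofs(pose)) {
  stopifnot(is(pose, "PoseModel"))
  if (length(torsionState) != length(dofs$type))
    stop("torsion state has length ", length(torsionState),
         " but the DOF layout has ", length(dofs$type), " entries")
  current <- .measureDofs(pose, dofs)
  absolute <- dofs$type == 1L &
    !vapply(dofs$quad, function(q) is.null(q) || any(is.na(q)), TRUE)
  deltas <- ifelse(absolute, torsionState - current, torsionState)
  out <- pose
  out@xyz <- .cppApplyDofs(pose@xyz, dofs$type, dofs$a, dofs$b, dofs$moving,
                           deltas)
  out
}

# --- DFP quasi-Newton -------------------------------------------------------

#' Davidon-Fletcher-Powell minimization
#'
#' Quasi-Newton minimization with the DFP inverse-Hessian update and a
#' backtracking Armijo line search (accepted steps never increase the
#' objective). Convergence is declared when the absolute objective change
#' falls below \code{tol}.
#'
#' @param fn objective function of a numeric vector.
#' @param gr gradient function; default central finite differences of
#'   \code{fn}.
#' @param x0 numeric start vector.
#' @param tol absolute convergence tolerance on the objective (default
#'   1e-4).
#' @param maxIter iteration cap (default 500).
#' @param maxStep largest per-coordinate step per iteration.
#' @return list with \code{x}, \code{value}, \code{iterations},
#'   \code{converged}.
#' @export
dfpMinimize <- function(fn, gr = NULL, x0, tol = 1e-4, maxIter = 500L,
                        maxStep = 20) {
  n <- length(x0)
  if (is.null(gr)) {
    gr <- function(x) {
      h <- 1e-5
      vapply(seq_len(n), function(k) {
        e <- numeric(n); e[k] <- h
        (fn(x + e) - fn(x - e)) / (2 * h)
      }, numeric(1))
    }
  }
  x <- x0
  f <- fn(x)
  if (!is.finite(f)) stop("non-finite objective at the starting point")
  H <- diag(n)
  g <- gr(x)
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    d <- as.numeric(-H %*% g)
    if (sum(d * g) >= 0) {  # not a descent direction: reset
      H <- diag(n)
      d <- -g
    }
    ms <- max(abs(d))
    if (ms < 1e-14) { converged <- TRUE; break }
    if (ms > maxStep) d <- d * (maxStep / ms)
    alpha <- 1
    fNew <- Inf
    ok <- FALSE
    gd <- sum(g * d)
    for (t in 1:40) {
      fNew <- fn(x + alpha * d)
      if (is.finite(fNew) && fNew <= f + 1e-4 * alpha * gd) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) { converged <- TRUE; break }  # no further descent found
    xNew <- x + alpha * d
    gNew <- gr(xNew)
    s <- alpha * d
    yv <- gNew - g
    sy <- sum(s * yv)
    if (sy > 1e-12) {
      Hy <- as.numeric(H %*% yv)
      H <- H + (s %o% s) / sy - (Hy %o% Hy) / sum(yv * Hy)
    }
    dF <- f - fNew
    x <- xNew; f <- fNew; g <- gNew
    if (dF < tol) { converged <- TRUE; break }
  }
  list(x = x, value = f, iterations = iter, converged = converged)
}

#' Minimize a pose under constraints
#'
#' Minimizes the weighted physical energy plus the harmonic constraint
#' energy over the selected torsion and rigid-body degrees of freedom with
#' the DFP quasi-Newton algorithm (central finite-difference gradients).
#' Deterministic for fixed input; atoms outside the movable set keep their
#' coordinates exactly.
#'
#' @param pose a \linkS4class{PoseModel} (finite starting energy; repack
#'   side chains first to relieve hard clashes).
#' @param energyFn an \linkS4class{EnergyFunction}; its \code{constraint}
#'   weight multiplies the constraint term of the objective.
#' @param constraints constraint table from \code{\link{deriveConstraints}}.
#' @param dofs DOF list; default \code{poseDofs(pose)} (the full
#'   simple-minimization set).
#' @param tolerance absolute convergence tolerance (default 1e-4).
#' @param maxIter iteration cap (default 500; non-convergence is reported,
#'   not fatal).
#' @return a \linkS4class{MinimizeResult}.
#' @export
minimizePose <- function(pose, energyFn = defaultEnergyFunction(),
                         constraints = NULL, dofs = NULL, tolerance = 1e-4,
                         maxIter = 500L) {
  stopifnot(is(pose, "PoseModel"), tolerance > 0)
  if (is.null(dofs)) dofs <- poseDofs(pose)
  ea <- .energyArgs(pose, energyFn)
  cs <- .constraintIdx(pose, constraints)
  base <- pose@xyz
  obj <- function(xyz) {
    .cppObjective(xyz, ea$radius, ea$eps, ea$charge, ea$dgfree, ea$vol,
                  ea$donor, ea$acceptor, ea$base, ea$group,
                  pose@exclusions, ea$weights, cs$ci, cs$cj, cs$d0, cs$sd,
                  ea$wcst)
  }
  fn <- function(x) {
    obj(.cppApplyDofs(base, dofs$type, dofs$a, dofs$b, dofs$moving, x))
  }
  gr <- function(x) {
    .cppDofGradient(base, dofs$type, dofs$a, dofs$b, dofs$moving, x,
                    0.05, 0.005, ea$radius, ea$eps, ea$charge, ea$dgfree,
                    ea$vol, ea$donor, ea$acceptor, ea$base, ea$group,
                    pose@exclusions, ea$weights, cs$ci, cs$cj, cs$d0,
                    cs$sd, ea$wcst)
  }
  n <- length(dofs$type)
  f0 <- obj(base)
  if (!is.finite(f0))
    stop("non-finite energy at the start of minimization; ",
         "relieve clashes (e.g. repack side chains) first")
  if (n == 0) {
    return(new("MinimizeResult", pose = pose, startEnergy = f0,
               endEnergy = f0, iterations = 0L, converged = TRUE,
               tolerance = tolerance))
  }
  res <- dfpMinimize(fn, gr, x0 = numeric(n), tol = tolerance,
                     maxIter = as.integer(maxIter))
  out <- pose
  out@xyz <- .cppApplyDofs(base, dofs$type, dofs$a, dofs$b, dofs$moving,
                           res$x)
  new("MinimizeResult", pose = out, startEnergy = f0,
      endEnergy = min(res$value, f0), iterations = res$iterations,
      converged = res$converged, tolerance = tolerance)
}
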