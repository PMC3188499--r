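# Synthetic fixtures: a deterministic toy receptor pocket around an
# extended CNIQ tetrapeptide, plus seeded binder/non-binder peptide sets.
# The pocket reproduces the structural logic of the real enzyme site - a
# solvent-facing a1 position, a buried hydrophobic a2 pocket flanked by a
# hydrophobic probe ligand, an X-reading pocket, two receptor hydrogen-bond
# anchors and a three-atom thiol-coordination site - without copying any
# experimental structure.

#' Synthetic template configuration
#'
#' @param seed integer seed (drives the labeled-peptide generator; the
#'   template itself is fully deterministic).
#' @param pocketSize receptor residue count (>= 13; extras are alanine
#'   shell residues).
#' @param hbondDistance target length (Angstrom) for the two anchor
#'   hydrogen bonds.
#' @param thiolDistance target length for the three Sgamma-coordination
#'   contacts.
#' @param separability 0..1, sampling bias strength of the labeled-peptide
#'   generator (1 = fully biased position distributions).
#' @return named list of settings.
#' @export
syntheticConfig <- function(seed = 1L, pocketSize = 20L,
                            hbondDistance = 2.8, thiolDistance = 2.3,
                            separability = 1.0) {
  stopifnot(hbondDistance > 0, thiolDistance > 0,
            separability >= 0, separability <= 1, pocketSize >= 13L)
  list(seed = as.integer(seed), pocketSize = as.integer(pocketSize),
       hbondDistance = hbondDistance, thiolDistance = thiolDistance,
       separability = separability)
}

# extended-backbone tetrapeptide (phi -120, psi 130, omega 180)
.toyPeptideAtoms <- function() {
  phi <- -120; psi <- 130
  seqs <- c("CYS", "ASN", "ILE", "GLN")
  chis <- list(CYS = -60, ASN = c(-60, 0), ILE = c(-60, 180),
               GLN = c(-60, 180, 0))
  pos <- list()
  pos[["N1"]] <- c(0, 0, 0)
  pos[["CA1"]] <- c(1.458, 0, 0)
  th <- .deg2rad(111)
  pos[["C1"]] <- pos[["CA1"]] + 1.525 * c(-cos(th), sin(th), 0)
  for (i in 2:4) {
    pos[[paste0("N", i)]] <- placeAtom(
      pos[[paste0("N", i - 1)]], pos[[paste0("CA", i - 1)]],
      pos[[paste0("C", i - 1)]], 1.329, 116.2, psi)
    pos[[paste0("O", i - 1)]] <- placeAtom(
      pos[[paste0("N", i - 1)]], pos[[paste0("CA", i - 1)]],
      pos[[paste0("C", i - 1)]], 1.231, 120.5, psi + 180)
    pos[[paste0("CA", i)]] <- placeAtom(
      pos[[paste0("CA", i - 1)]], pos[[paste0("C", i - 1)]],
      pos[[paste0("N", i)]], 1.458, 121.7, 180)
    pos[[paste0("C", i)]] <- placeAtom(
      pos[[paste0("C", i - 1)]], pos[[paste0("N", i)]],
      pos[[paste0("CA", i)]], 1.525, 111.0, phi)
  }
  pos[["O4"]] <- placeAtom(pos[["N4"]], pos[["CA4"]], pos[["C4"]],
                           1.231, 120.5, psi + 180)
  pos[["OXT4"]] <- placeAtom(pos[["N4"]], pos[["CA4"]], pos[["C4"]],
                             1.25, 117.2, psi)
  rows <- NULL
  for (i in 1:4) {
    resn <- seqs[i]
    bb <- c("N", "CA", "C", "O", if (i == 4) "OXT")
    for (nm in bb) {
      p <- pos[[paste0(nm, i)]]
      rows <- rbind(rows, data.frame(
        name = nm, element = substr(nm, 1, 1), resn = resn, chain = "P",
        resno = i, insert = "", x = p[1], y = p[2], z = p[3], occ = 1,
        het = FALSE, stringsAsFactors = FALSE))
    }
    frame <- list(N = pos[[paste0("N", i)]], CA = pos[[paste0("CA", i)]],
                  C = pos[[paste0("C", i)]])
    sc <- buildSidechain(resn, frame, chis[[resn]])
    for (k in seq_len(nrow(sc))) {
      rows <- rbind(rows, data.frame(
        name = rownames(sc)[k], element = .elementFromName(rownames(sc)[k]),
        resn = resn, chain = "P", resno = i, insert = "",
        x = sc[k, 1], y = sc[k, 2], z = sc[k, 3], occ = 1, het = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  rows
}

# a residue built in a canonical frame (CA at origin region)
.canonicalResidue <- function(resn, chi) {
  pos <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0))
  th <- .deg2rad(111)
  pos$C <- pos$CA + 1.525 * c(-cos(th), sin(th), 0)
  pos$O <- placeAtom(pos$N, pos$CA, pos$C, 1.231, 120.5, 130 + 180)
  out <- rbind(N = pos$N, CA = pos$CA, C = pos$C, O = pos$O)
  sc <- buildSidechain(resn, pos, chi)
  rbind(out, sc)
}

# rigid-place a canonical residue so that `keyAtom` lands on `target` and
# the key->CA direction aligns with `outward`; when context coordinates are
# given, the free roll about the outward axis is chosen (from 24 candidates,
# deterministically) to maximise the clearance from the context
.placeResidue <- function(resn, chi, keyAtom, target, outward,
                          context = NULL) {
  m <- .canonicalResidue(resn, chi)
  key <- m[keyAtom, ]
  m <- sweep(m, 2, key)
  u <- .unit(m["CA", ])
  v <- .unit(outward)
  ax <- .cross(u, v)
  if (.vnorm(ax) < 1e-8) {
    R <- if (sum(u * v) > 0) diag(3) else .rotationMatrix(
      if (abs(u[1]) < 0.9) .unit(.cross(u, c(1, 0, 0))) else
        .unit(.cross(u, c(0, 1, 0))), pi)
  } else {
    R <- .rotationMatrix(ax, acos(max(-1, min(1, sum(u * v)))))
  }
  m <- m %*% t(R)
  m <- sweep(m, 2, target, `+`)
  if (is.null(context)) return(m)
  bestRoll <- 0; bestScore <- -Inf
  for (roll in seq(0, 345, by = 15)) {
    Rr <- .rotationMatrix(v, .deg2rad(roll))
    cand <- sweep(sweep(m, 2, target) %*% t(Rr), 2, target, `+`)
    score <- min(vapply(seq_len(nrow(cand)), function(r)
      min(colSums((t(context) - cand[r, ])^2)), numeric(1)))
    if (score > bestScore + 1e-9) { bestScore <- score; bestRoll <- roll }
  }
  Rr <- .rotationMatrix(v, .deg2rad(bestRoll))
  sweep(sweep(m, 2, target) %*% t(Rr), 2, target, `+`)
}

.toyOrthoFrame <- function(u) {
  v <- if (abs(u[1]) < 0.9) .cross(u, c(1, 0, 0)) else .cross(u, c(0, 1, 0))
  v <- .unit(v)
  w <- .unit(.cross(u, v))
  list(v = v, w = w)
}

#' Build the deterministic toy template
#'
#' Constructs an extended CNIQ tetrapeptide, places receptor residues
#' around it (two hydrogen-bond anchor side chains at the configured
#' distances, a Cys/Asp/His thiol-coordination triad, a hydrophobic wall
#' ring around the a2 side chain, an X-reading pocket and an alanine outer
#' shell), adds a hydrophobic probe ligand beside the a2 pocket, relieves
#' residual clashes by deterministic outward translation, and runs the
#' result through \code{\link{prepareTemplate}}.
#'
#' @param config from \code{\link{syntheticConfig}}.
#' @return a \linkS4class{TemplateComplex}.
#' @examples
#' tpl <- makeToyTemplate()
#' deriveConstraints(tpl)
#' @export
makeToyTemplate <- function(config = syntheticConfig()) {
  pep <- .toyPeptideAtoms()
  gp <- function(resno, nm) {
    r <- pep[pep$resno == resno & pep$name == nm, ]
    c(r$x, r$y, r$z)
  }

  # a2 side-chain frame (drives the pocket and the ligand)
  scRows <- pep$resno == 3 & !(pep$name %in% .BACKBONE_NAMES) &
    pep$name != "CB"
  cA2 <- colMeans(as.matrix(pep[scRows, c("x", "y", "z")]))
  ca3 <- gp(3, "CA")
  u3 <- .unit(cA2 - ca3)
  f3 <- .toyOrthoFrame(u3)

  # hydrophobic probe ligand: zig-zag carbon chain beside the a2 pocket, on
  # the side facing away from the cysteine thiol (whose coordination site
  # must stay clear)
  axis <- .unit(gp(4, "CA") - gp(2, "CA"))
  sg0 <- gp(1, "SG")
  pAway <- (cA2 - sg0) - sum((cA2 - sg0) * u3) * u3
  wlig <- if (.vnorm(pAway) > 0.5) .unit(pAway) else f3$w
  base <- cA2 + 1.2 * u3 + 6.0 * wlig
  lig <- NULL
  for (k in 1:8) {
    p <- base + (k - 4.5) * 1.27 * axis + ((k %% 2) - 0.5) * 0.9 * u3
    lig <- rbind(lig, data.frame(
      name = paste0("C", k), element = "C", resn = "FAR", chain = "L",
      resno = 201, insert = "", x = p[1], y = p[2], z = p[3], occ = 1,
      het = TRUE, stringsAsFactors = FALSE))
  }

  placed <- list()   # each: list(resn, m = coord matrix, outward)
  context <- function() {
    rbind(as.matrix(pep[, c("x", "y", "z")]),
          as.matrix(lig[, c("x", "y", "z")]),
          do.call(rbind, lapply(placed, `[[`, "m")))
  }
  add <- function(resn, chi, key, target, outward) {
    placed[[length(placed) + 1L]] <<- list(
      resn = resn,
      m = .placeResidue(resn, chi, key, target, outward, context()),
      outward = .unit(outward))
  }

  # hydrogen-bond anchors
  oxt <- gp(4, "OXT"); c4 <- gp(4, "C")
  uq <- .unit(oxt - c4)
  add("GLN", c(-60, 180, 0), "NE2", oxt + config$hbondDistance * uq, uq)
  # the guanidinium anchor approaches the a2 carbonyl tilted away from the
  # X-position side chain so it does not occupy the X-reading pocket
  o3 <- gp(3, "O"); c3 <- gp(3, "C")
  scRows4 <- pep$resno == 4 & !(pep$name %in% .BACKBONE_NAMES) &
    pep$name != "CB"
  cX <- colMeans(as.matrix(pep[scRows4, c("x", "y", "z")]))
  ur <- .unit(.unit(o3 - c3) + 0.8 * .unit(o3 - cX))
  add("ARG", c(-60, 180, 180, 180), "NH1", o3 + config$hbondDistance * ur,
      ur)

  # thiol-coordination triad around the cysteine Sgamma
  sg <- gp(1, "SG"); cb1 <- gp(1, "CB")
  ut <- .unit(sg - cb1)
  fr <- .toyOrthoFrame(ut)
  # terminal side-chain atoms coordinate the thiol (keeps the approach
  # geometry clean: no ring or branch atoms protrude past the key atom)
  triad <- list(c("CYS", "SG"), c("SER", "OG"), c("THR", "OG1"))
  triadChi <- list(-60, -60, -60)
  for (k in 1:3) {
    ang <- 2 * pi * (k - 1) / 3 + 0.4
    dk <- .unit(cos(.deg2rad(45)) * ut +
                  sin(.deg2rad(45)) * (cos(ang) * fr$v + sin(ang) * fr$w))
    add(triad[[k]][1], triadChi[[k]], triad[[k]][2],
        sg + config$thiolDistance * dk, dk)
  }
  nAnchor <- length(placed)

  # hydrophobic wall ring around the a2 side chain, leaving the ligand's
  # actual sector open
  walls <- list(c("LEU", "CD1"), c("ILE", "CD1"), c("PHE", "CZ"),
                c("LEU", "CD2"))
  wallChi <- list(c(-60, 180), c(-60, 180), c(-60, 90), c(-60, 180))
  ligAngle <- atan2(sum(wlig * f3$w), sum(wlig * f3$v))
  wallAngles <- ligAngle + .deg2rad(c(75, 150, 210, 285))
  for (k in seq_along(walls)) {
    ang <- wallAngles[k]
    t <- cA2 + 1.2 * u3 + 4.7 * (cos(ang) * f3$v + sin(ang) * f3$w)
    add(walls[[k]][1], wallChi[[k]], walls[[k]][2], t, .unit(t - cA2))
  }

  # X-reading pocket near the residue-4 side chain
  ca4 <- gp(4, "CA")
  u4 <- .unit(cX - ca4)
  f4 <- .toyOrthoFrame(u4)
  xpocket <- list(c("SER", "OG"), c("LEU", "CD1"), c("VAL", "CG1"))
  xChi <- list(-60, c(-60, 180), 180)
  for (k in seq_along(xpocket)) {
    ang <- 2 * pi * (k - 1) / length(xpocket) + 1.2
    t <- cX + 1.0 * u4 + 5.0 * (cos(ang) * f4$v + sin(ang) * f4$w)
    add(xpocket[[k]][1], xChi[[k]], xpocket[[k]][2], t, .unit(t - cX))
  }

  # alanine outer shell up to pocketSize residues; each shell residue backs
  # off radially until it clears everything already placed
  centre <- (gp(2, "CA") + gp(3, "CA")) / 2
  nShell <- config$pocketSize - length(placed)
  for (k in seq_len(nShell)) {
    ang <- 2 * pi * (k - 1) / max(1, nShell) + 0.2
    dir <- .unit(cos(ang) * f3$v + sin(ang) * f3$w + 0.35 * u3)
    ctx <- context()
    for (radius in seq(9, 16, by = 0.5)) {
      t <- centre + radius * dir
      m <- .placeResidue("ALA", numeric(0), "CB", t, dir, ctx)
      dmin2 <- min(vapply(seq_len(nrow(m)), function(r)
        min(colSums((t(ctx) - m[r, ])^2)), numeric(1)))
      if (dmin2 >= 3.3^2) break
    }
    placed[[length(placed) + 1L]] <- list(resn = "ALA", m = m,
                                          outward = dir)
  }

  # deterministic clash relief: translate offending non-anchor residues
  # outward until no contact is tighter than the floor (the five anchor
  # residues never move, preserving the configured constraint geometry)
  fixed <- rbind(as.matrix(pep[, c("x", "y", "z")]),
                 as.matrix(lig[, c("x", "y", "z")]))
  for (pass in 1:80) {
    moved <- FALSE
    allRec <- lapply(placed, `[[`, "m")
    for (i in seq_along(placed)) {
      if (i <= nAnchor) next
      others <- rbind(fixed, do.call(rbind, allRec[-i]))
      d2 <- vapply(seq_len(nrow(placed[[i]]$m)), function(r)
        min(colSums((t(others) - placed[[i]]$m[r, ])^2)), numeric(1))
      if (min(d2) < 3.0^2) {
        # step away from the tightest contact, biased outward
        rOwn <- which.min(d2)
        jOth <- which.min(colSums((t(others) - placed[[i]]$m[rOwn, ])^2))
        away <- placed[[i]]$m[rOwn, ] - others[jOth, ]
        away <- if (.vnorm(away) > 1e-6) .unit(away) else
          placed[[i]]$outward
        step <- .unit(0.5 * placed[[i]]$outward + 0.5 * away)
        placed[[i]]$m <- sweep(placed[[i]]$m, 2, 0.25 * step, `+`)
        allRec[[i]] <- placed[[i]]$m
        moved <- TRUE
      }
    }
    if (!moved) break
  }

  rec <- NULL
  for (i in seq_along(placed)) {
    m <- placed[[i]]$m
    rec <- rbind(rec, data.frame(
      name = rownames(m), element = .elementFromName(rownames(m)),
      resn = placed[[i]]$resn, chain = "A", resno = 100L + i, insert = "",
      x = m[, 1], y = m[, 2], z = m[, 3], occ = 1, het = FALSE,
      stringsAsFactors = FALSE))
  }
  rownames(rec) <- NULL

  all <- rbind(rec, pep, lig)
  rownames(all) <- NULL
  s <- new("Structure", atoms = all, title = "synthetic toy template")
  anchorConfig <- list(
    q_alpha = "A:101:NE2", r_beta = "A:102:NH1",
    zn_triad_1 = "A:103:SG", zn_triad_2 = "A:104:OG",
    zn_triad_3 = "A:105:OG1")
  prepareTemplate(s, peptideChain = "P", ligandCodes = "FAR",
                  receptorChains = "A", anchorConfig = anchorConfig)
}

.POS_BIAS <- list(
  a1 = c(V = 3, I = 2, L = 2, A = 3, S = 2, T = 2, C = 1, M = 1, G = 1,
         N = 1),
  a2 = c(I = 4, V = 4, L = 3, A = 2, T = 1, C = 1),
  X = c(M = 3, S = 3, A = 2, Q = 2, C = 1, T = 1, I = 1, V = 1))

# Negative bias: charged/polar residues at the buried a2 and X positions.
# The toy pocket penalises buried charge through the solvation and
# electrostatic terms; it is too open to exclude bulky aromatics sterically,
# so the synthetic negative class is defined on charge/polarity (see the
# methods vignette).
.NEG_BIAS <- list(
  a1 = c(R = 2, K = 2, D = 2, E = 2, G = 2, P = 2, S = 1, N = 1, Q = 1),
  a2 = c(R = 3, K = 3, D = 3, E = 3, N = 2, Q = 2, H = 1, P = 1, G = 1),
  X = c(R = 3, K = 3, D = 2, E = 2, P = 2, G = 1, N = 1, Q = 1))

.sampleLetter <- function(bias, separability) {
  if (stats::runif(1) < separability) {
    sample(names(bias), 1L, prob = bias)
  } else {
    sample(names(.AA3), 1L)
  }
}

#' Generate a labeled synthetic peptide set
#'
#' Positives are drawn from binder-biased position distributions
#' (aliphatic-leaning a2, small/polar X), negatives from an anti-biased
#' distribution (charged or bulky residues at the buried positions). These
#' biases encode the generator's synthetic ground truth, not a fitted
#' biological model. Sets are disjoint, sequences unique, and the draw is a
#' deterministic function of the seed.
#'
#' @param config from \code{\link{syntheticConfig}}.
#' @param nPos,nNeg positive (label MTO) and negative (label NON) counts.
#' @return a \linkS4class{LabeledPeptideSet}.
#' @export
makeLabeledPeptides <- function(config = syntheticConfig(), nPos = 25L,
                                nNeg = 25L) {
  stopifnot(nPos >= 1, nNeg >= 1)
  set.seed(config$seed)
  s <- config$separability
  draw <- function(bias) {
    paste0("C", .sampleLetter(bias$a1, s), .sampleLetter(bias$a2, s),
           .sampleLetter(bias$X, s))
  }
  seen <- character(0)
  take <- function(n, bias) {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("requested counts exceed the distinct sequences available")
      cand <- draw(bias)
      if (cand %in% seen) next
      seen <<- c(seen, cand)
      out <- c(out, cand)
    }
    out
  }
  pos <- take(nPos, .POS_BIAS)
  neg <- take(nNeg, .NEG_BIAS)
  rec <- data.frame(sequence = c(pos, neg),
                    label = rep(c("MTO", "NON"), c(nPos, nNeg)),
                    stringsAsFactors = FALSE)
  new("LabeledPeptideSet", records = rec, positiveLabels = "MTO")
}

#' Write synthetic fixtures to a directory
#'
#' Emits \code{template.pdb} (the toy template as one PDB file) and
#' \code{labeled.tsv} (a labeled peptide table).
#'
#' @param dir output directory (created if needed).
#' @param config from \code{\link{syntheticConfig}}.
#' @param nPos,nNeg labeled-set sizes.
#' @return invisibly, the two file paths.
#' @export
writeFixtures <- function(dir, config = syntheticConfig(), nPos = 25L,
                          nNeg = 25L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- makeToyTemplate(config)
  pdb <- file.path(dir, "template.pdb")
  writePDB(templateStructure(tpl), pdb)
  tsv <- file.path(dir, "labeled.tsv")
  set <- makeLabeledPeptides(config, nPos, nNeg)
  utils::write.table(records(set), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(template = pdb, labeled = tsv))
}
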