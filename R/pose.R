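# Pose assembly: one flat atom table for receptor + peptide + ligand, with
# bond graph, non-bonded exclusions, hydrogen-bond base atoms and constraint
# anchors resolved to row indices. The bond graph also drives the torsion
# kinematics (a torsion moves the connected component distal to its axis).

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

# adjacency list from a bond matrix
.adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# connected component containing `start`, with the edge (a, b) removed
.componentWithout <- function(adj, start, a, b) {
  n <- length(adj)
  seen <- logical(n)
  seen[start] <- TRUE
  queue <- start
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if ((v == a && w == b) || (v == b && w == a)) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

# all pairs within graph distance <= k (returned as a 2-column matrix)
.exclusionPairs <- function(adj, k = 3L) {
  n <- length(adj)
  out <- vector("list", n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (dist[v] >= k) next
      for (w in adj[[v]]) if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    near <- which(dist > 0L)
    near <- near[near > s]
    if (length(near) > 0) out[[s]] <- cbind(s, near)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(integer(0), ncol = 2)
  storage.mode(m) <- "integer"
  m
}

# intra-residue bonds for one residue's rows (global indices), by name
.bondRowsForResidue <- function(at, idx) {
  resn <- at$resn[idx[1]]
  nm <- at$name[idx]
  known <- resn %in% names(.SIDECHAIN_RECIPES)
  if (known) {
    spec <- .residueBonds(resn)
    spec <- rbind(spec, c("C", "OXT"))
    keep <- spec[, 1] %in% nm & spec[, 2] %in% nm
    spec <- spec[keep, , drop = FALSE]
    if (nrow(spec) == 0) return(NULL)
    cbind(idx[match(spec[, 1], nm)], idx[match(spec[, 2], nm)])
  } else {
    .bondsByDistance(at, idx)
  }
}

# distance-based bonds for hetero/unknown residues
.bondsByDistance <- function(at, idx) {
  if (length(idx) < 2) return(NULL)
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  out <- NULL
  for (i in seq_len(length(idx) - 1)) {
    for (j in (i + 1):length(idx)) {
      lim <- if (any(at$element[idx[c(i, j)]] %in% c("S", "P"))) 1.95 else 1.75
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < lim)
        out <- rbind(out, c(idx[i], idx[j]))
    }
  }
  out
}

# full bond list for a pose atom table (coordinates must be present as
# x/y/z columns for distance-based hetero bonds)
.poseBonds <- function(at) {
  out <- NULL
  for (seg in unique(at$segment)) {
    rows <- which(at$segment == seg)
    sat <- at[rows, , drop = FALSE]
    resIdx <- split(rows, factor(paste(sat$chain, sat$resno, sat$insert),
                                 levels = unique(paste(sat$chain, sat$resno,
                                                       sat$insert))))
    prevC <- NA_integer_
    prevChain <- ""
    for (ri in resIdx) {
      out <- rbind(out, .bondRowsForResidue(at, ri))
      # peptide bond to the previous residue in the same chain, when the
      # geometry supports it
      cIdx <- ri[at$name[ri] == "N"]
      if (length(cIdx) == 1 && !is.na(prevC) &&
          at$chain[ri[1]] == prevChain) {
        d <- sqrt(sum((c(at$x[prevC], at$y[prevC], at$z[prevC]) -
                       c(at$x[cIdx], at$y[cIdx], at$z[cIdx]))^2))
        if (d < 1.8) out <- rbind(out, c(prevC, cIdx))
      }
      cc <- ri[at$name[ri] == "C"]
      prevC <- if (length(cc) == 1) cc else NA_integer_
      prevChain <- at$chain[ri[1]]
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  storage.mode(out) <- "integer"
  out
}

# hydrogen-bond base: first bonded heavy neighbour of each atom (0 if none)
.baseIndices <- function(adj) {
  vapply(adj, function(nb) if (length(nb) > 0) min(nb) else 0L, 1L)
}

# Assemble a PoseModel from template parts plus a built peptide atom table.
.assemblePose <- function(template, pepAt, sequence) {
  rec <- atoms(receptor(template))
  lig <- ligandAtoms(template)
  rec$segment <- "receptor"
  pepAt$segment <- "peptide"
  if (nrow(lig) > 0) lig$segment <- "ligand"

  cols <- c("name", "element", "resn", "segment", "chain", "resno", "insert",
            "x", "y", "z")
  at <- rbind(rec[, cols], pepAt[, cols],
              if (nrow(lig) > 0) lig[, cols])
  rownames(at) <- NULL

  # peptide position labels 1..4
  at$pepPos <- NA_integer_
  pepRows <- which(at$segment == "peptide")
  keys <- paste(at$chain[pepRows], at$resno[pepRows], at$insert[pepRows])
  at$pepPos[pepRows] <- as.integer(factor(keys, levels = unique(keys)))

  at <- .typeAtoms(at)
  bonds <- .poseBonds(at)
  adj <- .adjacency(bonds, nrow(at))
  at$base <- .baseIndices(adj)
  excl <- .exclusionPairs(adj, 3L)

  anchorIdx <- .anchorRowIndices(template, at)

  # the thiol-coordination contacts are covalent-like (the constraint term
  # stands in for the removed metal), so they are excluded from the
  # nonbonded sum like bonded pairs
  sgTriad <- cbind(anchorIdx[["pep_cys_SG"]],
                   anchorIdx[c("zn_triad_1", "zn_triad_2", "zn_triad_3")])
  storage.mode(sgTriad) <- "integer"
  excl <- rbind(excl, sgTriad)

  xyz <- as.matrix(at[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  at$x <- at$y <- at$z <- NULL

  tb <- .backboneCoords(xyz, at)
  new("PoseModel", atoms = at, xyz = xyz, sequence = sequence,
      bonds = bonds, exclusions = excl, anchorIdx = anchorIdx,
      templateBackbone = tb)
}

.anchorRowIndices <- function(template, at) {
  an <- anchors(template)
  idx <- integer(nrow(an))
  for (i in seq_len(nrow(an))) {
    hit <- which(at$segment == an$segment[i] & at$chain == an$chain[i] &
                   at$resno == an$resno[i] & at$insert == an$insert[i] &
                   at$name == an$atom[i])
    if (length(hit) != 1L)
      stop("anchor '", an$key[i], "' resolves to ", length(hit),
           " pose atoms")
    idx[i] <- hit
  }
  stats::setNames(idx, an$key)
}

.backboneCoords <- function(xyz, at) {
  sel <- which(at$segment == "peptide" & at$name %in% .BACKBONE_NAMES)
  m <- xyz[sel, , drop = FALSE]
  rownames(m) <- paste(at$pepPos[sel], at$name[sel])
  m
}

# rows of one peptide position
.pepRows <- function(pose, pos) {
  which(pose@atoms$segment == "peptide" & pose@atoms$pepPos == pos)
}

# side-chain rows (everything but backbone) of one peptide position
.pepSidechainRows <- function(pose, pos) {
  r <- .pepRows(pose, pos)
  r[!(pose@atoms$name[r] %in% .BACKBONE_NAMES)]
}
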