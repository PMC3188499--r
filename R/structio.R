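# PDB reading/writing and template preparation.
#
# Reading is delegated to bio3d::read.pdb; this layer adds the contracts the
# pipeline relies on: first-MODEL-only handling, altLoc resolution to the
# highest-occupancy conformer, line-level validation with line numbers, and
# a flat Structure container.

.WATER_RES <- c("HOH", "WAT", "DOD", "H2O")
.METAL_RES <- c("ZN", "MG", "NA", "K", "CL", "CA", "MN", "FE", "FE2", "CU",
                "CD", "HG", "NI", "CO")

.elementFromName <- function(name) {
  # PDB heavy-atom names start with the element symbol once digits are
  # stripped; two-letter elements relevant here: only a handful.
  s <- gsub("[0-9']", "", toupper(name))
  two <- substr(s, 1, 2)
  ifelse(two %in% c("CL", "BR", "ZN", "MG", "FE", "SE"), two,
         substr(s, 1, 1))
}

#' Read a PDB structure
#'
#' Parses PDB-format text or a file into a \linkS4class{Structure}. Only the
#' first MODEL is kept; alternate locations are resolved to the highest
#' occupancy conformer (ties broken toward the alphabetically first altLoc
#' code); coordinates are read to 0.001 Angstrom.
#'
#' @param input path to a PDB file, or a character scalar/vector of PDB
#'   text.
#' @return a \linkS4class{Structure}.
#' @examples
#' pdb <- writePDB(templateStructure(makeToyTemplate()))
#' s <- readPDB(pdb)
#' @export
readPDB <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(input, collapse = "\n"), "\n"))
  }
  if (length(lines) == 0L || !any(grepl("^(ATOM  |HETATM)", lines)))
    stop("empty PDB input: no ATOM/HETATM records found")

  # validate coordinate records before handing off to the parser
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed ATOM/HETATM record at line %d: too short", i))
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(xyz)))))
      stop(sprintf(
        "malformed ATOM/HETATM record at line %d: non-numeric coordinates", i))
  }

  # first model only
  mdl <- grep("^ENDMDL", lines)
  if (length(mdl) > 0) lines <- lines[seq_len(mdl[1] - 1L)]

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  a <- pdb$atom

  elem <- a$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
  elem <- ifelse(is.na(elem) | !nzchar(trimws(elem)),
                 .elementFromName(a$elety), trimws(elem))
  at <- data.frame(
    name = trimws(a$elety),
    element = toupper(elem),
    resn = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    het = a$type == "HETATM",
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)

  # drop hydrogens: structures are handled heavy-atom-only
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]

  # altLoc resolution: highest occupancy, ties -> first altLoc code
  key <- paste(at$chain, at$resno, at$insert, at$name)
  if (anyDuplicated(key)) {
    ord <- order(key, -at$occ, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$name)), ,
             drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  at$alt <- NULL
  rownames(at) <- NULL
  new("Structure", atoms = at, title = "")
}

#' Write a Structure as PDB text
#'
#' Fixed-column PDB records; hetero atoms are written as HETATM, a TER card
#' separates chains and coordinates are formatted \code{\%8.3f}.
#'
#' @param structure a \linkS4class{Structure}.
#' @param file optional path; when given the text is also written there.
#' @return the PDB text as a single character scalar (invisibly when
#'   \code{file} is given).
#' @export
writePDB <- function(structure, file = NULL) {
  a <- atoms(structure)
  if (nrow(a) == 0L) stop("cannot write an empty structure")
  if (any(nchar(a$name) > 4L))
    stop("atom name longer than 4 characters: ",
         paste(unique(a$name[nchar(a$name) > 4L]), collapse = ", "))
  fmtName <- function(n) {
    # standard justification: names of <4 chars start in column 14
    ifelse(nchar(n) >= 4L, substr(sprintf("%-4s", n), 1, 4),
           sprintf(" %-3s", n))
  }
  out <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      r <- sub[i, ]
      out <- c(out, sprintf(
        "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (r$het) "HETATM" else "ATOM", serial, fmtName(r$name), "",
        r$resn, substr(r$chain, 1, 1), r$resno, r$insert,
        r$x, r$y, r$z, r$occ, 0, r$element))
    }
    last <- sub[nrow(sub), ]
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %-3s %1s%4d%1s", serial,
                          last$resn, substr(last$chain, 1, 1), last$resno,
                          last$insert))
  }
  out <- c(out, "END")
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

.residueKeys <- function(at) unique(paste(at$chain, at$resno, at$insert,
                                          sep = "\r"))

.splitResidues <- function(at) {
  split(seq_len(nrow(at)), factor(paste(at$chain, at$resno, at$insert,
                                        sep = "\r"),
                                  levels = .residueKeys(at)))
}

.parseAnchorAddress <- function(s) {
  parts <- strsplit(s, ":")[[1]]
  if (length(parts) < 3L)
    stop("anchor address must be 'chain:resno:atom': ", s)
  list(chain = parts[1], resno = as.integer(parts[2]), atom = parts[3],
       insert = if (length(parts) >= 4L) parts[4] else "")
}

#' Prepare a scoring template from a receptor-peptide complex
#'
#' Truncates the bound peptide to its four C-terminal residues, keeps ligand
#' residues matching \code{ligandCodes} as one rigid hetero unit, removes
#' waters and metal ions (the catalytic metal is replaced by the distance
#' constraints), builds a missing C-terminal OXT at ideal sp2 carboxylate
#' geometry, and resolves the five constraint anchor atoms.
#'
#' @param structure a \linkS4class{Structure} (e.g. from
#'   \code{\link{readPDB}}).
#' @param peptideChain chain identifier of the bound peptide.
#' @param ligandCodes character vector of hetero residue codes kept as the
#'   rigid ligand (may be empty).
#' @param receptorChains chains forming the receptor; default all chains
#'   except \code{peptideChain}.
#' @param anchorConfig named list/vector with receptor anchor addresses
#'   \code{q_alpha}, \code{r_beta}, \code{zn_triad_1}, \code{zn_triad_2},
#'   \code{zn_triad_3}, each \code{"chain:resno:atom"} (see
#'   \code{\link{readConfig}}). Peptide-side anchors are derived: the Cys
#'   Sgamma, the a2 backbone O, and whichever carboxylate oxygen of the X
#'   residue lies nearest the \code{q_alpha} atom.
#' @return a \linkS4class{TemplateComplex}.
#' @export
prepareTemplate <- function(structure, peptideChain, ligandCodes = character(),
                            receptorChains = NULL, anchorConfig) {
  at <- atoms(structure)

  # strip waters and free metal ions
  drop <- at$resn %in% .WATER_RES |
    (at$het & at$resn %in% .METAL_RES & at$element %in% .METAL_RES)
  at <- at[!drop, , drop = FALSE]

  lig <- at[at$het & at$resn %in% ligandCodes, , drop = FALSE]
  at <- at[!(at$het & at$resn %in% ligandCodes), , drop = FALSE]

  pep <- at[at$chain == peptideChain & !at$het, , drop = FALSE]
  resIdx <- .splitResidues(pep)
  if (length(resIdx) < 4L)
    stop("peptide chain '", peptideChain, "' has fewer than 4 residues")
  keep <- utils::tail(resIdx, 4L)
  pep <- pep[sort(unlist(keep)), , drop = FALSE]

  if (pep$resn[1] != "CYS")
    stop("template peptide must present Cys at motif position 1 (found ",
         pep$resn[1], ")")

  # receptor = requested chains minus the peptide
  if (is.null(receptorChains))
    receptorChains <- setdiff(unique(at$chain), peptideChain)
  rec <- at[at$chain %in% receptorChains & at$chain != peptideChain, ,
            drop = FALSE]

  # build OXT at ideal sp2 carboxylate geometry if missing
  lastIdx <- .splitResidues(pep)[[4]]
  lastRes <- pep[lastIdx, , drop = FALSE]
  if (!("OXT" %in% lastRes$name)) {
    get <- function(nm) {
      r <- lastRes[lastRes$name == nm, ]
      if (nrow(r) != 1L)
        stop("cannot build OXT: X residue lacks atom ", nm)
      c(r$x, r$y, r$z)
    }
    n <- get("N"); ca <- get("CA"); cc <- get("C"); o <- get("O")
    torsO <- dihedralAngle(n, ca, cc, o)
    oxt <- placeAtom(n, ca, cc, bond = 1.25, angle = 117.2,
                     torsion = torsO + 180)
    newRow <- lastRes[lastRes$name == "O", , drop = FALSE]
    newRow$name <- "OXT"
    newRow$x <- oxt[1]; newRow$y <- oxt[2]; newRow$z <- oxt[3]
    pep <- rbind(pep, newRow)
  }
  rownames(pep) <- NULL
  rownames(rec) <- NULL
  rownames(lig) <- NULL

  pepS <- new("Structure", atoms = pep, title = "template peptide")
  recS <- new("Structure", atoms = rec, title = "template receptor")

  anchors <- .resolveAnchors(recS, pepS, lig, anchorConfig)
  new("TemplateComplex", receptor = recS, peptide = pepS, ligand = lig,
      anchors = anchors)
}

.resolveAnchors <- function(recS, pepS, lig, anchorConfig) {
  need <- c("q_alpha", "r_beta", "zn_triad_1", "zn_triad_2", "zn_triad_3")
  miss <- setdiff(need, names(anchorConfig))
  if (length(miss) > 0)
    stop("anchor configuration missing: ", paste(miss, collapse = ", "))
  rec <- atoms(recS)
  pep <- atoms(pepS)

  recAnchor <- function(key) {
    ad <- .parseAnchorAddress(anchorConfig[[key]])
    hit <- rec$chain == ad$chain & rec$resno == ad$resno &
      rec$insert == ad$insert & rec$name == ad$atom
    if (sum(hit) != 1L)
      stop("cannot resolve anchor '", key, "' at address ",
           anchorConfig[[key]], " (", sum(hit), " matching atoms)")
    data.frame(key = key, segment = "receptor", chain = ad$chain,
               resno = ad$resno, insert = ad$insert, atom = ad$atom,
               stringsAsFactors = FALSE)
  }
  recA <- do.call(rbind, lapply(need, recAnchor))

  resIdx <- .splitResidues(pep)
  res1 <- pep[resIdx[[1]], , drop = FALSE]
  res3 <- pep[resIdx[[3]], , drop = FALSE]
  res4 <- pep[resIdx[[4]], , drop = FALSE]
  pepAnchor <- function(key, res, atomName) {
    r <- res[res$name == atomName, , drop = FALSE]
    if (nrow(r) != 1L)
      stop("cannot resolve peptide anchor '", key, "': atom ", atomName,
           " not found")
    data.frame(key = key, segment = "peptide", chain = r$chain,
               resno = r$resno, insert = r$insert, atom = atomName,
               stringsAsFactors = FALSE)
  }

  # carboxylate oxygen: the one nearer the q_alpha receptor atom
  qa <- .parseAnchorAddress(anchorConfig[["q_alpha"]])
  qrow <- rec[rec$chain == qa$chain & rec$resno == qa$resno &
                rec$insert == qa$insert & rec$name == qa$atom, ]
  qxyz <- c(qrow$x[1], qrow$y[1], qrow$z[1])
  dist2 <- function(nm) {
    r <- res4[res4$name == nm, ]
    sum((c(r$x, r$y, r$z) - qxyz)^2)
  }
  cooAtom <- if (dist2("OXT") <= dist2("O")) "OXT" else "O"

  rbind(pepAnchor("pep_carboxylate_O", res4, cooAtom),
        pepAnchor("pep_a2_O", res3, "O"),
        pepAnchor("pep_cys_SG", res1, "SG"),
        recA)
}

#' Recombine a TemplateComplex into one Structure
#'
#' Inverse of the template split: receptor chains, then the peptide chain,
#' then ligand hetero records, preserving coordinates bitwise. Useful for
#' writing a prepared template back to PDB and for the idempotency property
#' of \code{\link{prepareTemplate}}.
#'
#' @param template a \linkS4class{TemplateComplex}.
#' @return a \linkS4class{Structure}.
#' @export
templateStructure <- function(template) {
  stopifnot(is(template, "TemplateComplex"))
  at <- rbind(atoms(receptor(template)), atoms(templatePeptide(template)),
              ligandAtoms(template))
  rownames(at) <- NULL
  new("Structure", atoms = at, title = "prepared template")
}
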