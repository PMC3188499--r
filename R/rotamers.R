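#' Load a rotamer library
#'
#' Reads the plain-text rotamer table shipped with the package (or a
#' user-supplied file in the same format) and expands the per-chi candidate
#' angles into the full grid of chi tuples per residue type. The shipped
#' library is a coarse, backbone-independent canonical set
#' (gauche+/gauche-/trans sp3 combinations plus standard aromatic and
#' sp2-terminal values).
#'
#' @param path path to a library file; default the shipped table.
#' @return named list: for each three-letter residue code, a numeric matrix
#'   with one row per rotamer and one column per chi angle (degrees).
#'   ALA/GLY map to a 1 x 0 matrix (the empty tuple).
#' @export
loadRotamerLibrary <- function(path = system.file("extdata", "rotamers.tsv",
                                                  package = "caaxbind")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lib <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    res <- trimws(parts[1])
    if (length(parts) < 2L || !nzchar(trimws(parts[2]))) {
      lib[[res]] <- matrix(numeric(0), nrow = 1, ncol = 0)
      next
    }
    levels <- strsplit(trimws(parts[2]), ";")[[1]]
    opts <- lapply(levels, function(s) as.numeric(strsplit(s, ",")[[1]]))
    if (any(vapply(opts, function(o) any(is.na(o)), TRUE)))
      stop("malformed rotamer entry for ", res)
    grid <- as.matrix(expand.grid(rev(opts)))[, rev(seq_along(opts)),
                                              drop = FALSE]
    dimnames(grid) <- NULL
    lib[[res]] <- grid
  }
  stray <- setdiff(names(.N_CHI), names(lib))
  if (length(stray) > 0)
    stop("rotamer library lacks entries for: ", paste(stray, collapse = ", "))
  bad <- names(lib)[vapply(lib, ncol, 1L) != .N_CHI[names(lib)]]
  if (length(bad) > 0)
    stop("rotamer chi count disagrees with residue topology for: ",
         paste(bad, collapse = ", "))
  lib
}

# Expand a rotamer matrix with +-offset sub-rotamers on chi1 and chi2
# (the "extra rotamers" refinement; offset in degrees).
.expandExtraChi <- function(rot, offset = 10) {
  if (ncol(rot) == 0L) return(rot)
  offs1 <- c(0, -offset, offset)
  offs2 <- if (ncol(rot) >= 2L) c(0, -offset, offset) else 0
  out <- NULL
  for (o1 in offs1) for (o2 in offs2) {
    m <- rot
    m[, 1] <- m[, 1] + o1
    if (ncol(m) >= 2L) m[, 2] <- m[, 2] + o2
    out <- rbind(out, m)
  }
  out[!duplicated(out), , drop = FALSE]
}
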