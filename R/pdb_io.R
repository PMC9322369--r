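# PDB input/output. Parsing relies on bio3d; this layer only normalises the
# record set (first model, altloc A/blank, standard residues) into the
# all-atom model that coarse_grain() consumes, and writes CG structures back
# out with "SC1" pseudo-atoms for the united side chains.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HN", "H1", "H2", "H3")

#' Read an all-atom model from a PDB file
#'
#' Reads the first model of a fixed-column PDB file, keeping `ATOM` records
#' (and `HETATM` records for standard residue types), altloc `"A"` or blank
#' only. Coordinates are in Angstrom.
#'
#' @param path path to a PDB file
#' @return an object of class `aa_model`: a list with `atoms` (data frame
#'   with chain, resno, icode, resid, elety, x, y, z) and `source`
#' @export
#' @examples
#' pdb <- system.file("extdata", "two_residues.pdb", package = "memcg")
#' m <- read_pdb_model(pdb)
#' nrow(m$atoms)
read_pdb_model <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read PDB file: ", path, call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("no ATOM records in ", path, call. = FALSE)
  }
  standard <- names(.default_residue_class())
  keep <- (at$type == "ATOM" | at$resid %in% standard) &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no usable ATOM records in ", path, call. = FALSE)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  rkey <- paste(atoms$chain, atoms$resno, atoms$icode)
  if (!any(atoms$elety == "CA")) {
    stop("structure in ", path, " has no CA atoms; not a protein model",
         call. = FALSE)
  }
  m <- structure(list(atoms = atoms, source = path), class = "aa_model")
  m
}

#' @export
print.aa_model <- function(x, ...) {
  rkey <- paste(x$atoms$chain, x$atoms$resno, x$atoms$icode)
  cat("All-atom model:", length(unique(rkey)), "residues,",
      nrow(x$atoms), "atoms (", x$source, ")\n")
  invisible(x)
}

#' Write a coarse-grained structure as a PDB file
#'
#' Backbone atoms are written with their standard names; the united side
#' chain is written as a pseudo-atom named `SC1`. The file round-trips
#' through [read_pdb_model()] + [coarse_grain()] to within 1e-3 Angstrom.
#'
#' @param cg a [coarse_grain()] structure
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_cg_pdb <- function(cg, path) {
  stopifnot(inherits(cg, "cg_structure"))
  r <- cg$residues
  if (nrow(r) == 0) stop("cannot write an empty CG structure", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(r))) {
    add <- function(name, x, y, z) {
      if (is.na(x)) return(NULL)
      list(elety = name, resid = r$name[i], chain = r$chain[i],
           resno = r$resno[i], icode = r$icode[i], x = x, y = y, z = z)
    }
    rows <- c(rows, Filter(Negate(is.null), list(
      add("N", r$n_x[i], r$n_y[i], r$n_z[i]),
      add("CA", r$ca_x[i], r$ca_y[i], r$ca_z[i]),
      add("C", r$c_x[i], r$c_y[i], r$c_z[i]),
      add("O", r$o_x[i], r$o_y[i], r$o_z[i]),
      add("H", r$h_x[i], r$h_y[i], r$h_z[i]),
      add("SC1", r$sc_x[i], r$sc_y[i], r$sc_z[i]))))
  }
  a <- do.call(rbind, lapply(rows, as.data.frame))
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = a$chain, insert = ifelse(a$icode == "", NA,
                                                      a$icode),
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)))
    TRUE
  }, error = function(e) {
    stop("cannot write CG PDB to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}
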