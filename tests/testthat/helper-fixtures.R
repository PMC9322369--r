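# Shared fixtures: fixed-column PDB writers and randomized synthetic
# structures. Everything is generated in code at test time.

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          altloc = " ", icode = " ", element = "") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, altloc, resid, chain, resno, icode, x, y, z,
          1.00, 0.00, element)
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# two residues (ALA + C-terminal GLY), 8 atoms
two_residue_lines <- function() {
  c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0, 0, element = "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.009, 1.42, 0, element = "C"),
    pdb_atom_line(4, "O", "ALA", "A", 1, 1.251, 2.39, 0, element = "O"),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 2.0, -0.8, -1.2, element = "C"),
    pdb_atom_line(6, "N", "GLY", "A", 2, 3.332, 1.536, 0, element = "N"),
    pdb_atom_line(7, "CA", "GLY", "A", 2, 3.988, 2.839, 0, element = "C"),
    pdb_atom_line(8, "C", "GLY", "A", 2, 5.504, 2.693, 0, element = "C"))
}

# a randomized small membrane-protein-like structure: 1-2 ideal helices
# with mixed sequences, separated so coordinates are never degenerate
rand_structure <- function(seed) {
  set.seed(seed)
  pool <- strsplit("AVLIFMWPGSTNQYCDEKRH", "")[[1]]
  w <- c(rep(3, 15), rep(1, 5))
  n_hel <- sample(1:2, 1)
  cgs <- lapply(seq_len(n_hel), function(i) {
    len <- sample(6L:10L, 1)
    sq <- paste(sample(pool, len, replace = TRUE, prob = w), collapse = "")
    org <- c(stats::runif(1, -5, 5) + (i - 1) * 25, stats::runif(1, -5, 5),
             stats::runif(1, -8, 8))
    ax <- stats::rnorm(3)
    make_helix(helix_spec(sq, origin = org, axis = ax / sqrt(sum(ax^2)),
                          chain = LETTERS[i]))
  })
  memcg:::.cg_bind(cgs, label = paste0("rand", seed))
}

# random rotation matrix (det +1) via QR of a Gaussian matrix
rand_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random enumerable titration system: n sites in a 20 A box with random
# water pKa values in [3, 11] (half acids, half bases)
rand_sites <- function(seed, n) {
  set.seed(seed)
  pos <- lapply(seq_len(n), function(i) stats::runif(3, 0, 20))
  acid <- sample(c(TRUE, FALSE), n, replace = TRUE)
  names3 <- ifelse(acid, "ASP", "LYS")
  pka <- stats::runif(n, 3, 11)
  cfg <- energy_config()
  cg <- make_titration_system(pos, names3, cfg)
  sites <- ionizable_sites(cg, grid = NULL, cfg)
  sites$pka_water <- pka
  sites$pka_intrinsic <- pka   # no environment: intrinsic = water value
  sites
}
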