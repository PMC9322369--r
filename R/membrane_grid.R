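# Implicit membrane: a regular cubic lattice of particles occupying a slab,
# built once per conformation and then frozen for all energy evaluations.

#' Build the membrane particle grid around a protein
#'
#' Fills the slab `|z - slab_center_z| <= slab_half_thickness` with a cubic
#' lattice of spacing `spacing`, covering the protein's xy bounding box
#' extended by `lateral_margin`. Lattice nodes are anchored at the origin
#' (x, y) and at `slab_center_z` (z), so layouts are reproducible under
#' re-building. Nodes closer than `exclusion_radius` to any protein
#' particle are removed. The grid is not modified afterwards.
#'
#' @param cg a `cg_structure` (may be empty)
#' @param gc a [grid_config()]
#' @return an object of class `membrane_grid`: list with `particles`
#'   (n x 3 matrix) and `config`
#' @export
#' @examples
#' g <- build_grid(make_helix(helix_spec("AAAA")), grid_config())
#' nrow(g$particles)
build_grid <- function(cg, gc = grid_config()) {
  stopifnot(inherits(gc, "grid_config"))
  pts <- if (inherits(cg, "cg_structure")) cg_particles(cg) else
    matrix(numeric(0), 0, 3)
  if (nrow(pts) == 0 && gc$lateral_margin == 0) {
    warning("empty protein and zero lateral margin: empty membrane grid")
  }
  bb <- if (nrow(pts) > 0) {
    rbind(apply(pts, 2, min), apply(pts, 2, max))
  } else {
    rbind(c(0, 0, 0), c(0, 0, 0))
  }
  s <- gc$spacing
  eps <- 1e-9
  axis_nodes <- function(lo, hi) {
    ks <- seq(ceiling((lo - eps) / s), floor((hi + eps) / s))
    ks * s
  }
  xs <- axis_nodes(bb[1, 1] - gc$lateral_margin, bb[2, 1] + gc$lateral_margin)
  ys <- axis_nodes(bb[1, 2] - gc$lateral_margin, bb[2, 2] + gc$lateral_margin)
  kz <- seq(-floor((gc$slab_half_thickness + eps) / s),
            floor((gc$slab_half_thickness + eps) / s))
  zs <- gc$slab_center_z + kz * s
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  if (gc$exclusion_radius > 0 && nrow(pts) > 0 && nrow(grid) > 0) {
    r2 <- gc$exclusion_radius^2
    keep <- rep(TRUE, nrow(grid))
    for (i in seq_len(nrow(pts))) {
      d2 <- (grid[, 1] - pts[i, 1])^2 + (grid[, 2] - pts[i, 2])^2 +
        (grid[, 3] - pts[i, 3])^2
      keep <- keep & d2 >= r2
    }
    grid <- grid[keep, , drop = FALSE]
  }
  structure(list(particles = grid, config = gc), class = "membrane_grid")
}

#' @export
print.membrane_grid <- function(x, ...) {
  cat("Membrane grid:", nrow(x$particles), "particles, spacing",
      x$config$spacing, "A, slab half-thickness",
      x$config$slab_half_thickness, "A\n")
  invisible(x)
}

#' Apply a rigid transform to a membrane grid
#'
#' Used to move a frozen grid together with its protein, e.g. in isometry
#' checks; the grid is never rebuilt by this operation.
#' @param grid a `membrane_grid`
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 vector
#' @return the transformed grid
#' @export
transform_grid <- function(grid, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  p <- grid$particles
  if (nrow(p) > 0) {
    grid$particles <- t(rotation %*% t(p) + translation)
  }
  grid
}

#' Environment neighbor counts of an ionizable site
#'
#' Counts the nonpolar side particles, polar side particles and membrane
#' particles whose distance to the site's side particle is at most
#' `cutoff` (a distance exactly equal to the cutoff counts). The site
#' itself is excluded.
#'
#' @param cg a `cg_structure`
#' @param grid a `membrane_grid` (its particles may be empty)
#' @param site_index row index of an ionizable residue in `cg$residues`
#' @param cutoff neighbor cutoff in Angstrom
#' @return a list with integer counts `n_np`, `n_p`, `n_mem`
#' @export
neighbor_counts <- function(cg, grid, site_index, cutoff = 10) {
  r <- cg$residues
  stopifnot(cutoff > 0)
  if (site_index < 1 || site_index > nrow(r)) {
    stop("site_index out of range", call. = FALSE)
  }
  if (r$klass[site_index] != "ionizable") {
    stop("neighbor_counts: residue ", .residue_key(r)[site_index],
         " is not ionizable", call. = FALSE)
  }
  ctr <- c(r$sc_x[site_index], r$sc_y[site_index], r$sc_z[site_index])
  .neighbor_counts_at(ctr, cg, grid, cutoff, exclude = site_index)
}

.neighbor_counts_at <- function(ctr, cg, grid, cutoff, exclude = 0L) {
  r <- cg$residues
  c2 <- cutoff^2 + 1e-9
  count_class <- function(kl) {
    sel <- r$klass == kl & !is.na(r$sc_x) & seq_len(nrow(r)) != exclude
    if (!any(sel)) return(0L)
    d2 <- (r$sc_x[sel] - ctr[1])^2 + (r$sc_y[sel] - ctr[2])^2 +
      (r$sc_z[sel] - ctr[3])^2
    sum(d2 <= c2)
  }
  n_mem <- 0L
  gp <- grid$particles
  if (!is.null(gp) && nrow(gp) > 0) {
    d2 <- (gp[, 1] - ctr[1])^2 + (gp[, 2] - ctr[2])^2 + (gp[, 3] - ctr[3])^2
    n_mem <- sum(d2 <= c2)
  }
  list(n_np = as.integer(count_class("nonpolar")),
       n_p = as.integer(count_class("polar")),
       n_mem = as.integer(n_mem))
}
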