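# Synthetic structure generators: ideal alpha-helices, two-state helix
# bundles, enumerable titration clusters, and a barrier fixture whose
# transition-state origin is analytically explainable. Everything is
# deterministic given its spec, so every pipeline stage is testable
# without external structure files.

# Fixed local-frame offsets (radial, tangential, axial; Angstrom) of the
# backbone atoms relative to each CA of an ideal helix with rise 1.5 A,
# twist 100 deg, CA radius 2.3 A. Tuned once so that near-ideal bond
# lengths are kept, (i, i+4) N-O distances sit in the hydrogen-bond window
# (2.95 A) and all other sequence-separated N-O pairs stay beyond the
# 3.5 A switch-off.
.HELIX_N_OFF <- c(-0.700698, -0.926170, -0.882339)
.HELIX_C_OFF <- c(-0.731090, 0.858772, 1.027205)
.HELIX_O_OFF <- c(-0.430278, 0.889467, 2.220982)

#' Ideal alpha-helix specification
#'
#' @param sequence 1-letter amino-acid string (20 standard letters)
#' @param rise_per_residue axial rise in Angstrom (default 1.5)
#' @param twist_per_residue rotation per residue in degrees (default 100)
#' @param radius CA cylinder radius in Angstrom (default 2.3)
#' @param origin position of the helix frame origin (the axis point at the
#'   z of the first CA)
#' @param axis helix axis direction (normalized internally)
#' @param chain chain identifier
#' @param resno_start first residue number
#' @return an object of class `helix_spec`
#' @export
helix_spec <- function(sequence, rise_per_residue = 1.5,
                       twist_per_residue = 100, radius = 2.3,
                       origin = c(0, 0, 0), axis = c(0, 0, 1),
                       chain = "A", resno_start = 1L) {
  stopifnot(nchar(sequence) > 0, rise_per_residue > 0, radius > 0)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, names(.AA3))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  structure(list(sequence = letters1, rise = rise_per_residue,
                 twist = twist_per_residue, radius = radius,
                 origin = origin, axis = axis / sqrt(sum(axis^2)),
                 chain = chain, resno_start = as.integer(resno_start)),
            class = "helix_spec")
}

# rotation taking (0,0,1) onto the unit vector a
.rot_z_to <- function(a) {
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  c_ <- sum(z * a)
  if (sum(v^2) < 1e-14) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}

#' Generate an ideal alpha-helix CG structure
#'
#' Places CA atoms on a cylinder (`radius`, `rise_per_residue`,
#' `twist_per_residue`), backbone N, C, O by fixed offsets in each
#' residue's local helical frame, and the united side particle radially
#' outward at the residue-type distance. With the default geometry the
#' (i, i+4) donor-acceptor N-O distances are about 2.95 A and all other
#' sequence-separated N-O pairs exceed 3.5 A, so an n-residue helix has
#' exactly `n - 4` backbone hydrogen bonds.
#'
#' @param spec a [helix_spec()]
#' @param config an [energy_config()] (residue tables)
#' @return a `cg_structure`
#' @export
#' @examples
#' h <- make_helix(helix_spec("AAAAAAAAAA"))
#' range(h$residues$ca_z)   # z-span 13.5 A
make_helix <- function(spec, config = energy_config()) {
  stopifnot(inherits(spec, "helix_spec"))
  n <- length(spec$sequence)
  names3 <- unname(.AA3[spec$sequence])
  th <- (seq_len(n) - 1) * spec$twist * pi / 180
  rhat <- cbind(cos(th), sin(th), 0)
  that <- cbind(-sin(th), cos(th), 0)
  zhat <- cbind(0, 0, rep(1, n))
  ca <- spec$radius * rhat + (seq_len(n) - 1) * spec$rise * zhat
  place <- function(off) ca + off[1] * rhat + off[2] * that + off[3] * zhat
  Np <- place(.HELIX_N_OFF)
  Cp <- place(.HELIX_C_OFF)
  Op <- place(.HELIX_O_OFF)
  sd_ <- config$side_dist[names3]
  sd_[is.na(sd_)] <- 2.5
  Sp <- ca + sd_ * rhat
  Sp[names3 == "GLY", ] <- NA_real_
  Rm <- .rot_z_to(spec$axis)
  tx <- function(m) {
    ok <- stats::complete.cases(m)
    m[ok, ] <- t(Rm %*% t(m[ok, , drop = FALSE]) + spec$origin)
    m
  }
  Np <- tx(Np); ca <- tx(ca); Cp <- tx(Cp); Op <- tx(Op); Sp <- tx(Sp)
  cls <- .assign_class(names3, config)
  res <- data.frame(chain = spec$chain,
                    resno = spec$resno_start + seq_len(n) - 1L,
                    icode = "", name = names3,
                    stringsAsFactors = FALSE)
  res$n_x <- Np[, 1]; res$n_y <- Np[, 2]; res$n_z <- Np[, 3]
  res$ca_x <- ca[, 1]; res$ca_y <- ca[, 2]; res$ca_z <- ca[, 3]
  res$c_x <- Cp[, 1]; res$c_y <- Cp[, 2]; res$c_z <- Cp[, 3]
  res$o_x <- Op[, 1]; res$o_y <- Op[, 2]; res$o_z <- Op[, 3]
  res$h_x <- NA_real_; res$h_y <- NA_real_; res$h_z <- NA_real_
  res$sc_x <- Sp[, 1]; res$sc_y <- Sp[, 2]; res$sc_z <- Sp[, 3]
  res$klass <- cls$klass
  res$sign <- cls$sign
  res$pka_water <- cls$pka
  cg <- .new_cg(res, label = paste0("helix:", paste(spec$sequence,
                                                    collapse = "")))
  .validate_cg(cg)
  cg
}

# concatenate the residue tables of several CG structures
.cg_bind <- function(cgs, label = "") {
  res <- do.call(rbind, lapply(cgs, function(x) x$residues))
  cg <- .new_cg(res, label = label)
  .validate_cg(cg)
  cg
}

#' Combine CG structures into one
#'
#' Concatenates the residues of several structures (e.g. helices on
#' different chains) into a single `cg_structure`; residue keys must not
#' collide.
#' @param ... `cg_structure` objects
#' @param label label of the combined structure
#' @return a `cg_structure`
#' @export
cg_combine <- function(..., label = "") {
  .cg_bind(list(...), label = label)
}

#' Two-state helix bundle specification
#'
#' @param n_helices number of parallel helices on a circle (default 4)
#' @param bundle_radius circle radius in Angstrom (default 8)
#' @param moving_helix 1-based index of the helix that moves (default 1)
#' @param tilt_delta tilt angle in degrees between the two states
#' @param helix_length residues per helix (default 18)
#' @param sequences optional character vector of 1-letter sequences, one
#'   per helix; by default a membrane-protein-like pattern with one GLU
#'   and one LYS in the bundle
#' @param seed deterministic-generation seed (kept in the spec; the
#'   default construction is fully deterministic)
#' @return an object of class `two_state_spec`
#' @export
two_state_spec <- function(n_helices = 4, bundle_radius = 8,
                           moving_helix = 1, tilt_delta = 30,
                           helix_length = 18, sequences = NULL,
                           seed = 1L) {
  stopifnot(n_helices >= 1, moving_helix >= 1, moving_helix <= n_helices,
            tilt_delta >= 0, helix_length >= 5)
  if (is.null(sequences)) {
    base <- strrep("LASLA", ceiling(helix_length / 5))
    sequences <- vapply(seq_len(n_helices), function(h) {
      s <- substr(base, 1, helix_length)
      if (h == 1) substr(s, ceiling(helix_length / 2),
                         ceiling(helix_length / 2)) <- "K"
      if (h == 2 && n_helices >= 2) substr(s, ceiling(helix_length / 2),
                                           ceiling(helix_length / 2)) <- "E"
      s
    }, character(1))
  }
  stopifnot(length(sequences) == n_helices)
  structure(list(n_helices = n_helices, bundle_radius = bundle_radius,
                 moving_helix = moving_helix, tilt_delta = tilt_delta,
                 helix_length = helix_length, sequences = sequences,
                 seed = as.integer(seed)),
            class = "two_state_spec")
}

# rotate points about an axis (unit vector u) through point ctr by ang deg
.rotate_about <- function(m, ctr, u, ang) {
  a <- ang * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  Rm <- c_ * diag(3) + s_ * ux + (1 - c_) * (u %o% u)
  t(Rm %*% (t(m) - ctr) + ctr)
}

#' Generate a two-state helix bundle
#'
#' State A: `n_helices` parallel ideal helices on a circle, axes along z,
#' centered on the membrane mid-plane. State B: identical except that the
#' moving helix is tilted by `tilt_delta` degrees about its midpoint
#' (rotation axis tangential to the bundle circle), emulating a localized
#' helix motion between two conformations. Residue keys are identical
#' across the states.
#'
#' @param spec a [two_state_spec()]
#' @param config an [energy_config()]
#' @return a list with `cg_structure` elements `a` and `b`
#' @export
make_two_state_bundle <- function(spec, config = energy_config()) {
  stopifnot(inherits(spec, "two_state_spec"))
  L <- spec$helix_length
  z0 <- -(L - 1) * 1.5 / 2
  helices <- lapply(seq_len(spec$n_helices), function(h) {
    phi <- 2 * pi * (h - 1) / spec$n_helices
    org <- c(spec$bundle_radius * cos(phi), spec$bundle_radius * sin(phi),
             z0)
    make_helix(helix_spec(spec$sequences[h], origin = org,
                          chain = LETTERS[h]), config)
  })
  a <- .cg_bind(helices, label = "bundle_state_a")
  mv <- spec$moving_helix
  hb <- helices[[mv]]
  if (spec$tilt_delta > 0) {
    coords_cols <- .COORD_COLS
    r <- hb$residues
    ctr <- c(mean(r$ca_x), mean(r$ca_y), mean(r$ca_z))
    phi <- 2 * pi * (mv - 1) / spec$n_helices
    # radial rotation axis: the helix ends swing tangentially along the
    # bundle surface instead of into its core
    u <- c(cos(phi), sin(phi), 0)
    for (p in c("n", "ca", "c", "o", "h", "sc")) {
      cols <- paste0(p, c("_x", "_y", "_z"))
      m <- as.matrix(r[, cols])
      ok <- stats::complete.cases(m)
      if (any(ok)) {
        m[ok, ] <- .rotate_about(m[ok, , drop = FALSE], ctr, u,
                                 spec$tilt_delta)
        r[, cols] <- m
      }
    }
    hb <- .new_cg(r, label = hb$label)
  }
  helices_b <- helices
  helices_b[[mv]] <- hb
  b <- .cg_bind(helices_b, label = "bundle_state_b")
  list(a = a, b = b)
}

#' Build an enumerable titration system
#'
#' One residue per site: the united side particle is placed exactly at the
#' given position while minimal backbone stubs are parked far away (40 A
#' apart, 300 A or more above the sites), so only side-side interactions
#' are energetically relevant and the exact titration ensemble is fully
#' determined by the site geometry and pKa table.
#'
#' @param positions list of xyz vectors (Angstrom), one per site
#' @param names 3-letter residue types, one per site
#' @param config an [energy_config()]
#' @return a `cg_structure`
#' @export
#' @examples
#' cg <- make_titration_system(list(c(0, 0, 0), c(5, 0, 0)),
#'                             c("ASP", "ASP"))
#' sum(cg$residues$klass == "ionizable")
make_titration_system <- function(positions, names,
                                  config = energy_config()) {
  if (length(positions) == 0) {
    stop("empty titration system", call. = FALSE)
  }
  if (length(positions) != length(names)) {
    stop("positions and names must have the same length", call. = FALSE)
  }
  n <- length(positions)
  cls <- .assign_class(names, config)
  res <- data.frame(chain = "A", resno = seq_len(n), icode = "",
                    name = names, stringsAsFactors = FALSE)
  for (cc in .COORD_COLS) res[[cc]] <- NA_real_
  for (i in seq_len(n)) {
    stub <- c(0, 0, 300 + 40 * i)
    res[i, c("n_x", "n_y", "n_z")] <- stub + .HELIX_N_OFF
    res[i, c("ca_x", "ca_y", "ca_z")] <- stub
    res[i, c("c_x", "c_y", "c_z")] <- stub + .HELIX_C_OFF
    res[i, c("o_x", "o_y", "o_z")] <- stub + .HELIX_O_OFF
    p <- positions[[i]]
    stopifnot(length(p) == 3)
    if (names[i] != "GLY") res[i, c("sc_x", "sc_y", "sc_z")] <- p
  }
  res$klass <- cls$klass
  res$sign <- cls$sign
  res$pka_water <- cls$pka
  cg <- .new_cg(res, label = "titration_system")
  .validate_cg(cg)
  cg
}

#' Place a structure in the membrane slab frame
#'
#' Translates the structure so that its particle centroid sits at
#' `(0, 0, z_offset)`; the membrane slab normal is the z axis and the
#' slab is centered at `z = 0` under the default [grid_config()].
#'
#' @param cg a `cg_structure`
#' @param z_offset target centroid z in Angstrom
#' @return the translated structure
#' @export
embed_in_membrane <- function(cg, z_offset = 0) {
  p <- cg_particles(cg)
  if (nrow(p) == 0) return(cg)
  ctr <- colMeans(p)
  transform_cg(cg, translation = c(-ctr[1], -ctr[2], z_offset - ctr[3]))
}

#' Two-state fixture with an analytic mid-path barrier
#'
#' A glycine-rich helix carrying a single lysine translates along the
#' membrane normal from well above the slab (state A) to well below it
#' (state B). Linear morphing therefore carries the charged site through
#' the slab center exactly at the path midpoint, where its membrane
#' neighbor count -- and hence its charging self-energy and pKa shift --
#' peaks. A second, distal poly-alanine helix (with one isoleucine)
#' stands far outside every interaction cutoff, static across the path.
#' Mutating the lysine to serine removes the mid-path electrostatic
#' penalty (barrier decreases); mutating the distal isoleucine leaves the
#' barrier unchanged.
#'
#' @param travel half travel distance along z in Angstrom (default 30)
#' @param distal_x lateral position of the static helix (default 60)
#' @param config an [energy_config()]
#' @return a list with `a`, `b` (end states), `charged_key` and
#'   `distal_key` (residue keys for [mutation_scan()])
#' @export
make_barrier_fixture <- function(travel = 30, distal_x = 60,
                                 config = energy_config()) {
  mover_seq <- "GGGGGKGGGGG"
  L <- nchar(mover_seq)
  z0 <- -(L - 1) * 1.5 / 2
  mover_a <- make_helix(helix_spec(mover_seq, origin = c(0, 0, z0 + travel),
                                   chain = "A"), config)
  mover_b <- make_helix(helix_spec(mover_seq, origin = c(0, 0, z0 - travel),
                                   chain = "A"), config)
  distal <- make_helix(helix_spec("AAAAAIAAAAA",
                                  origin = c(distal_x, 0, z0),
                                  chain = "B"), config)
  list(a = .cg_bind(list(mover_a, distal), label = "barrier_fixture_a"),
       b = .cg_bind(list(mover_b, distal), label = "barrier_fixture_b"),
       charged_key = list("A", 6L, ""),
       distal_key = list("B", 6L, ""))
}
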