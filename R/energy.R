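# The coarse-grained folding free energy. Total:
#   G = c1*side_vdw + c2*main_solv + c3*main_hb
#       + side_elec + side_polar + side_hyd + ms_elec + ms_vdw
# with the side-chain electrostatics built from MC/exact titration:
#   side_elec = -2.3RT sum <Q_i>(pKa_i^intr - pKa_i^water)
#               + q_dev + qq_folded - qq_unfolded
# The unfolded reference has charges at their water pKa at infinite
# separation, so qq_unfolded = 0 and any constant reference cancels in
# conformational differences.

#' Self-energy of charging an ionizable site
#'
#' Linear-with-saturation potentials in the environment neighbor counts:
#' `|q| * (a_np min(n_np, n_sat) + a_p min(n_p, n_sat) +
#' a_mem min(n_mem, n_sat))`. Zero for a neutral site.
#'
#' @param sign site sign (-1 acid, +1 base); kept for interface symmetry
#' @param nc neighbor counts, a list with `n_np`, `n_p`, `n_mem`
#' @param q instantaneous charge (0 or the sign)
#' @param config an [energy_config()]
#' @return energy in kcal/mol
#' @export
#' @examples
#' self_energy_site(1, list(n_np = 0, n_p = 0, n_mem = 10), 1,
#'                  energy_config())  # 2.0
self_energy_site <- function(sign, nc, q, config = energy_config()) {
  abs(q) * (config$a_np * min(nc$n_np, config$n_sat) +
            config$a_p * min(nc$n_p, config$n_sat) +
            config$a_mem * min(nc$n_mem, config$n_sat))
}

# screened Coulomb sum over point charges within the cutoff,
# distances clamped from below by clash_clamp
.coulomb_sum <- function(pos, q, config) {
  n <- nrow(pos)
  if (n < 2) return(0)
  live <- which(q != 0)
  if (length(live) < 2) return(0)
  pos <- pos[live, , drop = FALSE]
  q <- q[live]
  d <- as.matrix(stats::dist(pos))
  within <- d <= config$cutoff + 1e-9
  dc <- pmax(d, config$clash_clamp)
  e <- config$coulomb_k * outer(q, q) / (config$eps_eff * dc)
  e[!within] <- 0
  diag(e) <- 0
  sum(e) / 2
}

#' Charge-charge interaction energy of a charge configuration
#'
#' Screened Coulomb sum over ionizable side particles:
#' `sum_{i<j} k q_i q_j / (eps_eff r_ij)` for pairs within the cutoff,
#' with distances below `clash_clamp` (2 A) clamped up as a clash guard.
#'
#' @param cg a `cg_structure`
#' @param q charge vector over the ionizable residues of `cg`, in
#'   structure order; each element 0 or the residue's sign
#' @param config an [energy_config()]
#' @return energy in kcal/mol
#' @export
charge_charge <- function(cg, q, config = energy_config()) {
  r <- cg$residues
  idx <- which(r$klass == "ionizable")
  stopifnot(length(q) == length(idx))
  if (length(idx) < 2) return(0)
  pos <- cbind(r$sc_x[idx], r$sc_y[idx], r$sc_z[idx])
  .coulomb_sum(pos, q, config)
}

#' Side-chain electrostatic free energy
#'
#' Assembles `-2.3RT sum_i <Q_i> (pKa_i^intr - pKa_i^water) + q_dev +
#' qq_folded - qq_unfolded` from a titration result. `qq_folded` is the
#' ensemble-averaged charge-charge energy; the unfolded reference is zero
#' by construction.
#'
#' @param sites an [ionizable_sites()] table
#' @param titr a `titration_result` computed on these sites
#' @param config an [energy_config()]
#' @return a list with `value` and a `components` list (`pka_term`,
#'   `q_dev`, `qq_folded`, `qq_unfolded`, `self_energy`)
#' @export
side_elec <- function(sites, titr, config = energy_config()) {
  if (nrow(sites) != length(titr$mean_charge)) {
    stop("titration result does not match the site table", call. = FALSE)
  }
  rt23 <- 2.3 * R_GAS * config$temperature
  q <- titr$mean_charge
  pka_term <- if (nrow(sites) == 0) 0 else
    -rt23 * sum(q * (sites$pka_intrinsic - sites$pka_water))
  q_dev <- config$q_dev * nrow(sites)
  qq_folded <- if (is.null(titr$qq_mean)) 0 else titr$qq_mean
  self_e <- if (nrow(sites) == 0) 0 else sum(abs(q) * sites$dg_self)
  list(value = pka_term + q_dev + qq_folded - 0,
       components = list(pka_term = pka_term, q_dev = q_dev,
                         qq_folded = qq_folded, qq_unfolded = 0,
                         self_energy = self_e))
}

# 6-12 potential with minimum -eps at r = rm, capped at +cap
.lj <- function(r, rm, eps, cap) {
  s <- (rm / pmax(r, 1e-6))^6
  pmin(eps * (s^2 - 2 * s), cap)
}

#' Side-chain polar, hydrophobic and van der Waals terms
#'
#' Contact-counting polar and hydrophobic terms plus a capped 6-12
#' potential over united side particles:
#' polar = `k_polar` x (polar-polar pairs within the cutoff);
#' hyd = `-k_hyd` x (nonpolar-nonpolar pairs) `- k_hyd_mem` x (nonpolar
#' side particles with at least one membrane particle within the cutoff);
#' vdw = pairwise 6-12 with per-type radii, each pair capped at
#' `+vdw_cap` so unrelaxed morph frames stay finite.
#'
#' @param cg a `cg_structure`
#' @param grid a `membrane_grid` or `NULL` for no membrane
#' @param config an [energy_config()]
#' @return a list with `polar`, `hyd`, `vdw` in kcal/mol
#' @export
side_polar_hyd_vdw <- function(cg, grid = NULL, config = energy_config()) {
  r <- cg$residues
  has_sc <- !is.na(r$sc_x)
  idx <- which(has_sc)
  out <- list(polar = 0, hyd = 0, vdw = 0)
  if (length(idx) >= 2) {
    pos <- cbind(r$sc_x[idx], r$sc_y[idx], r$sc_z[idx])
    d <- as.matrix(stats::dist(pos))
    within <- d <= config$cutoff + 1e-9
    diag(within) <- FALSE
    kl <- r$klass[idx]
    pp <- outer(kl == "polar", kl == "polar") & within
    nn <- outer(kl == "nonpolar", kl == "nonpolar") & within
    out$polar <- config$k_polar * sum(pp) / 2
    out$hyd <- -config$k_hyd * sum(nn) / 2
    rad <- config$vdw_radius[r$name[idx]]
    rad[is.na(rad)] <- 2.5
    rm <- outer(rad, rad, `+`)
    lj <- .lj(d, rm, config$vdw_eps, config$vdw_cap)
    lj[!within] <- 0
    diag(lj) <- 0
    out$vdw <- sum(lj) / 2
  }
  # membrane-contact reward for nonpolar side chains
  gp <- if (is.null(grid)) NULL else grid$particles
  if (!is.null(gp) && nrow(gp) > 0 && length(idx) > 0) {
    np <- idx[r$klass[idx] == "nonpolar"]
    if (length(np) > 0) {
      c2 <- config$cutoff^2 + 1e-9
      n_contact <- sum(vapply(np, function(i) {
        d2 <- (gp[, 1] - r$sc_x[i])^2 + (gp[, 2] - r$sc_y[i])^2 +
          (gp[, 3] - r$sc_z[i])^2
        any(d2 <= c2)
      }, logical(1)))
      out$hyd <- out$hyd - config$k_hyd_mem * n_contact
    }
  }
  out
}

#' Backbone solvation and hydrogen-bond energies
#'
#' Hydrogen bonds: over donor-N / acceptor-O pairs at least 3 residues
#' apart in sequence (inter-chain pairs always allowed), each contributes
#' `hb_energy * s(d)` where `s` switches linearly from 1 at `d <= hb_on`
#' (3.0 A) to 0 at `d >= hb_off` (3.5 A). Solvation: each backbone N or O
#' whose surrounding particle count (protein particles of other residues
#' plus membrane particles within `burial_radius`) exceeds
#' `burial_threshold` pays the desolvation penalty `k_solv`. Both terms
#' are returned unscaled; `c2`, `c3` are applied in [total_energy()].
#'
#' @inheritParams side_polar_hyd_vdw
#' @return a list with `main_solv` and `main_hb` in kcal/mol
#' @export
main_energy <- function(cg, grid = NULL, config = energy_config()) {
  r <- cg$residues
  n <- nrow(r)
  out <- list(main_solv = 0, main_hb = 0)
  if (n == 0) return(out)
  Np <- cbind(r$n_x, r$n_y, r$n_z)
  Op <- cbind(r$o_x, r$o_y, r$o_z)
  okN <- stats::complete.cases(Np)
  okO <- stats::complete.cases(Op)
  # hydrogen bonds
  hb <- 0
  for (i in which(okN)) {
    j <- which(okO)
    sep_ok <- r$chain[j] != r$chain[i] | abs(j - i) >= 3
    j <- j[sep_ok]
    if (length(j) == 0) next
    d <- sqrt((Op[j, 1] - Np[i, 1])^2 + (Op[j, 2] - Np[i, 2])^2 +
                (Op[j, 3] - Np[i, 3])^2)
    s <- pmin(1, pmax(0, (config$hb_off - d) / (config$hb_off - config$hb_on)))
    hb <- hb + config$hb_energy * sum(s)
  }
  out$main_hb <- hb
  # burial of backbone amide atoms
  prot <- cg_particles(cg)
  gp <- if (is.null(grid)) NULL else grid$particles
  env <- rbind(prot, gp)
  b2 <- config$burial_radius^2 + 1e-9
  n_buried <- 0L
  for (i in seq_len(n)) {
    own <- matrix(c(Np[i, ], r$ca_x[i], r$ca_y[i], r$ca_z[i],
                    r$c_x[i], r$c_y[i], r$c_z[i], Op[i, ],
                    r$h_x[i], r$h_y[i], r$h_z[i],
                    r$sc_x[i], r$sc_y[i], r$sc_z[i]),
                  ncol = 3, byrow = TRUE)
    own <- own[stats::complete.cases(own), , drop = FALSE]
    for (atom in list(if (okN[i]) Np[i, ] else NULL,
                      if (okO[i]) Op[i, ] else NULL)) {
      if (is.null(atom)) next
      d2 <- (env[, 1] - atom[1])^2 + (env[, 2] - atom[2])^2 +
        (env[, 3] - atom[3])^2
      cnt <- sum(d2 <= b2)
      # subtract this residue's own atoms
      d2o <- (own[, 1] - atom[1])^2 + (own[, 2] - atom[2])^2 +
        (own[, 3] - atom[3])^2
      cnt <- cnt - sum(d2o <= b2)
      if (cnt > config$burial_threshold) n_buried <- n_buried + 1L
    }
  }
  out$main_solv <- config$k_solv * n_buried
  out
}

#' Backbone / side-chain coupling energies
#'
#' Electrostatics between charged side particles and backbone partial
#' charges (C +0.4, O -0.4, N -0.2, H +0.2; same-residue pairs excluded),
#' and a capped 6-12 between every side particle and the backbone N, CA,
#' C, O atoms of other residues. Both use the common cutoff.
#'
#' @param cg a `cg_structure`
#' @param q_res per-residue charge vector (length `nrow(cg$residues)`,
#'   zero for non-ionizable residues); ensemble-average charges are used
#'   by [total_energy()]
#' @param config an [energy_config()]
#' @return a list with `ms_elec` and `ms_vdw` in kcal/mol
#' @export
main_side_energy <- function(cg, q_res, config = energy_config()) {
  r <- cg$residues
  n <- nrow(r)
  stopifnot(length(q_res) == n)
  out <- list(ms_elec = 0, ms_vdw = 0)
  if (n == 0) return(out)
  bb_def <- list(c = 0.4, o = -0.4, n = -0.2, h = 0.2)
  # stack backbone atoms with their residue index and partial charge
  bb <- do.call(rbind, lapply(c("n", "ca", "c", "o", "h"), function(p) {
    m <- cbind(r[[paste0(p, "_x")]], r[[paste0(p, "_y")]],
               r[[paste0(p, "_z")]])
    ok <- stats::complete.cases(m)
    if (!any(ok)) return(NULL)
    data.frame(x = m[ok, 1], y = m[ok, 2], z = m[ok, 3],
               res = which(ok),
               delta = if (p %in% names(bb_def)) bb_def[[p]] else 0,
               vdw = p != "h")
  }))
  has_sc <- which(!is.na(r$sc_x))
  if (length(has_sc) == 0 || is.null(bb)) return(out)
  rad <- config$vdw_radius[r$name[has_sc]]
  rad[is.na(rad)] <- 2.5
  c2 <- config$cutoff^2 + 1e-9
  e_el <- 0; e_vdw <- 0
  for (k in seq_along(has_sc)) {
    i <- has_sc[k]
    other <- bb$res != i
    dx <- bb$x[other] - r$sc_x[i]
    dy <- bb$y[other] - r$sc_y[i]
    dz <- bb$z[other] - r$sc_z[i]
    d2 <- dx * dx + dy * dy + dz * dz
    within <- d2 <= c2
    if (!any(within)) next
    d <- sqrt(d2[within])
    delta <- bb$delta[other][within]
    if (q_res[i] != 0) {
      dc <- pmax(d, config$clash_clamp)
      e_el <- e_el + sum(config$coulomb_k * q_res[i] * delta /
                           (config$eps_eff * dc))
    }
    is_vdw <- bb$vdw[other][within]
    if (any(is_vdw)) {
      rm <- rad[k] + config$bb_vdw_radius
      e_vdw <- e_vdw + sum(.lj(d[is_vdw], rm, config$vdw_eps,
                               config$vdw_cap))
    }
  }
  out$ms_elec <- e_el
  out$ms_vdw <- e_vdw
  out
}

#' Full coarse-grained free energy of one conformation
#'
#' Runs the complete per-conformation workflow: environment neighbor
#' counts and intrinsic pKa per ionizable site, charge-state determination
#' (exact enumeration when 16 sites or fewer under `mc$mode = "auto"`,
#' Monte Carlo proton transfer otherwise), then every term of the energy
#' decomposition. The returned breakdown satisfies
#' `total = c1*side_vdw + c2*main_solv + c3*main_hb + side_elec +
#' side_polar + side_hyd + ms_elec + ms_vdw` to 1e-9.
#'
#' @param cg a `cg_structure`
#' @param grid a `membrane_grid` built for this conformation (or `NULL`)
#' @param pH the pH (default 7)
#' @param config an [energy_config()]
#' @param mc an [mc_config()]
#' @param seed optional seed overriding `mc$seed` for the MC route
#' @return an object of class `energy_breakdown`: a list of all terms in
#'   kcal/mol plus `total`, the titration result and the site table
#' @export
total_energy <- function(cg, grid = NULL, pH = 7, config = energy_config(),
                         mc = mc_config(), seed = NULL) {
  r <- cg$residues
  zero <- list(side_elec = 0, side_polar = 0, side_hyd = 0, side_vdw = 0,
               main_solv = 0, main_hb = 0, ms_elec = 0, ms_vdw = 0,
               self_energy = 0, qq_folded = 0, qq_unfolded = 0, q_dev = 0,
               total = 0)
  if (nrow(r) == 0) {
    return(structure(c(zero, list(titration = NULL, sites = NULL, pH = pH)),
                     class = "energy_breakdown"))
  }
  sites <- ionizable_sites(cg, grid, config)
  n_sites <- nrow(sites)
  if (n_sites > 0) {
    use_exact <- mc$mode == "exact" || (mc$mode == "auto" && n_sites <= 16)
    if (!is.null(seed)) mc$seed <- as.integer(seed)
    titr <- if (use_exact) exact_titration(sites, pH, config) else
      mcpt_sample(sites, pH, mc, config)
    se <- side_elec(sites, titr, config)
    q_res <- numeric(nrow(r))
    # termini share a residue index with a side-chain site only if both
    # exist; accumulate mean charges per residue
    for (k in seq_len(n_sites)) {
      q_res[sites$res_index[k]] <- q_res[sites$res_index[k]] +
        titr$mean_charge[k]
    }
  } else {
    titr <- NULL
    se <- list(value = 0, components = list(pka_term = 0, q_dev = 0,
                                            qq_folded = 0, qq_unfolded = 0,
                                            self_energy = 0))
    q_res <- numeric(nrow(r))
  }
  sp <- side_polar_hyd_vdw(cg, grid, config)
  me <- main_energy(cg, grid, config)
  ms <- main_side_energy(cg, q_res, config)
  total <- config$c1 * sp$vdw + config$c2 * me$main_solv +
    config$c3 * me$main_hb + se$value + sp$polar + sp$hyd +
    ms$ms_elec + ms$ms_vdw
  structure(list(
    side_elec = se$value, side_polar = sp$polar, side_hyd = sp$hyd,
    side_vdw = sp$vdw, main_solv = me$main_solv, main_hb = me$main_hb,
    ms_elec = ms$ms_elec, ms_vdw = ms$ms_vdw,
    self_energy = se$components$self_energy,
    qq_folded = se$components$qq_folded,
    qq_unfolded = se$components$qq_unfolded,
    q_dev = se$components$q_dev,
    total = total, titration = titr, sites = sites, pH = pH),
    class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("CG energy breakdown (kcal/mol):\n")
  terms <- c("side_elec", "side_polar", "side_hyd", "side_vdw",
             "main_solv", "main_hb", "ms_elec", "ms_vdw")
  for (t in terms) cat(sprintf("  %-10s %10.4f\n", t, x[[t]]))
  cat(sprintf("  %-10s %10.4f\n", "total", x$total))
  invisible(x)
}
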