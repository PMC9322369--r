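# Ionizable-site charge states. Sites carry an environment-shifted
# intrinsic pKa built from the self-energy of charging in place; the charge
# ensemble at fixed pH is then sampled by Metropolis Monte Carlo proton
# transfer, or enumerated exactly for small site sets (the oracle route).

#' Build the ionizable-site table of a structure
#'
#' One row per ionizable residue (plus chain termini when
#' `config$termini_ionizable` is TRUE): side-particle position, charge
#' sign, water pKa, environment neighbor counts, charging self-energy and
#' the resulting intrinsic pKa.
#'
#' @param cg a `cg_structure`
#' @param grid a `membrane_grid` built for this conformation
#' @param config an [energy_config()]
#' @return a data frame of class `ionizable_sites` with columns
#'   `res_index`, `chain`, `resno`, `icode`, `name`, `x`, `y`, `z`,
#'   `sign`, `pka_water`, `n_np`, `n_p`, `n_mem`, `dg_self`,
#'   `pka_intrinsic`
#' @export
ionizable_sites <- function(cg, grid, config = energy_config()) {
  r <- cg$residues
  idx <- which(r$klass == "ionizable")
  rows <- lapply(idx, function(i) {
    nc <- neighbor_counts(cg, grid, i, cutoff = config$cutoff)
    dg <- self_energy_site(sign = r$sign[i], nc = nc, q = r$sign[i],
                           config = config)
    data.frame(res_index = i, chain = r$chain[i], resno = r$resno[i],
               icode = r$icode[i], name = r$name[i],
               x = r$sc_x[i], y = r$sc_y[i], z = r$sc_z[i],
               sign = r$sign[i], pka_water = r$pka_water[i],
               n_np = nc$n_np, n_p = nc$n_p, n_mem = nc$n_mem,
               dg_self = dg, stringsAsFactors = FALSE)
  })
  if (isTRUE(config$termini_ionizable) && nrow(r) > 0) {
    for (ch in unique(r$chain)) {
      sel <- which(r$chain == ch)
      first <- sel[1]; last <- sel[length(sel)]
      term <- list(
        list(i = first, pos = c(r$n_x[first], r$n_y[first], r$n_z[first]),
             sign = 1L, pka = config$pka_n_terminus, nm = "NTR"),
        list(i = last, pos = c(r$ca_x[last], r$ca_y[last], r$ca_z[last]),
             sign = -1L, pka = config$pka_c_terminus, nm = "CTR"))
      for (tt in term) {
        nc <- .neighbor_counts_at(tt$pos, cg, grid, config$cutoff,
                                  exclude = tt$i)
        dg <- self_energy_site(sign = tt$sign, nc = nc, q = tt$sign,
                               config = config)
        rows <- c(rows, list(data.frame(
          res_index = tt$i, chain = ch, resno = r$resno[tt$i],
          icode = r$icode[tt$i], name = tt$nm,
          x = tt$pos[1], y = tt$pos[2], z = tt$pos[3],
          sign = tt$sign, pka_water = tt$pka,
          n_np = nc$n_np, n_p = nc$n_p, n_mem = nc$n_mem,
          dg_self = dg, stringsAsFactors = FALSE)))
      }
    }
  }
  sites <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(res_index = integer(0), chain = character(0),
               resno = integer(0), icode = character(0),
               name = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), sign = integer(0), pka_water = numeric(0),
               n_np = integer(0), n_p = integer(0), n_mem = integer(0),
               dg_self = numeric(0), stringsAsFactors = FALSE)
  sites$pka_intrinsic <- intrinsic_pka(sites$sign, sites$dg_self,
                                       sites$pka_water, config)
  class(sites) <- c("ionizable_sites", "data.frame")
  sites
}

#' Intrinsic pKa from the charging self-energy
#'
#' The intrinsic (protein/membrane environment) pKa is the water pKa
#' shifted by the self-energy of charging the site in place:
#' acids are shifted up by `dg_self / (2.3 RT)` (a desolvated acid is
#' harder to ionize), bases are shifted down by the same amount.
#'
#' @param sign +1 for a base, -1 for an acid (vectorized)
#' @param dg_self charging self-energy in kcal/mol (vectorized)
#' @param pka_water intrinsic water pKa (vectorized)
#' @param config an [energy_config()] (supplies the temperature)
#' @return intrinsic pKa value(s)
#' @export
#' @examples
#' intrinsic_pka(-1, 1.3712, 4.0, energy_config())  # approx 5.0
intrinsic_pka <- function(sign, dg_self, pka_water,
                          config = energy_config()) {
  rt23 <- 2.3 * R_GAS * config$temperature
  pka_water - sign * dg_self / rt23
}

# pairwise interaction matrix J and field h for a site table;
# J(i,j) = k sign_i sign_j / (eps * max(r, clamp)) within the cutoff
.site_couplings <- function(sites, pH, config) {
  n <- nrow(sites)
  rt23 <- 2.3 * R_GAS * config$temperature
  h <- -rt23 * sites$sign * (sites$pka_intrinsic - pH)
  J <- matrix(0, n, n)
  if (n > 1) {
    pos <- as.matrix(sites[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(pos))
    within <- d <= config$cutoff + 1e-9
    dc <- pmax(d, config$clash_clamp)
    J <- config$coulomb_k * outer(sites$sign, sites$sign) /
      (config$eps_eff * dc)
    J[!within] <- 0
    diag(J) <- 0
  }
  list(h = h, J = J)
}

#' Electrostatic free energy of one charge configuration
#'
#' `-2.3 RT sum_i q_i (pKa_i^intr - pH)` plus the charge-charge
#' interaction energy of the configuration. This is the quantity the
#' Metropolis criterion acts on.
#'
#' @param sites an [ionizable_sites()] table (with `pka_intrinsic` set)
#' @param q integer charge vector: each element 0 or the site's sign
#' @param pH the pH
#' @param config an [energy_config()]
#' @return energy in kcal/mol
#' @export
config_energy <- function(sites, q, pH, config = energy_config()) {
  stopifnot(length(q) == nrow(sites))
  if (any(q != 0 & q != sites$sign)) {
    stop("q must be 0 or the site's sign at every site", call. = FALSE)
  }
  cpl <- .site_couplings(sites, pH, config)
  occ <- as.numeric(q != 0)
  as.numeric(occ %*% cpl$h + 0.5 * occ %*% cpl$J %*% occ)
}

.titration_result <- function(mean_charge, charge_sd, g_elec, qq_mean, pH,
                              sites, acceptance = NA_real_) {
  structure(list(mean_charge = mean_charge, charge_sd = charge_sd,
                 g_elec = g_elec, qq_mean = qq_mean,
                 pka_apparent = NULL, pH = pH, sites = sites,
                 acceptance = acceptance),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat("Titration at pH", x$pH, ":", length(x$mean_charge), "site(s)\n")
  if (length(x$mean_charge) > 0) {
    df <- data.frame(name = x$sites$name, resno = x$sites$resno,
                     pka_intrinsic = round(x$sites$pka_intrinsic, 3),
                     mean_charge = round(x$mean_charge, 4))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Exact titration by enumeration (oracle)
#'
#' Enumerates all `2^n` charge configurations, Boltzmann-weights them by
#' their electrostatic free energy, and returns the exact ensemble average
#' charges, the ensemble free energy `-RT log Z`, and the ensemble-averaged
#' charge-charge energy. Limited to 16 sites.
#'
#' @inheritParams config_energy
#' @return a `titration_result` with `charge_sd = 0`
#' @export
#' @examples
#' cg <- make_titration_system(list(c(0, 0, 0)), "ASP")
#' s <- ionizable_sites(cg, grid = NULL)   # no membrane
#' exact_titration(s, pH = 3.9)$mean_charge   # -0.5 at pH = pKa
exact_titration <- function(sites, pH, config = energy_config()) {
  n <- nrow(sites)
  if (n > 16) stop("exact_titration supports at most 16 sites", call. = FALSE)
  rt <- R_GAS * config$temperature
  if (n == 0) {
    return(.titration_result(numeric(0), numeric(0), 0, 0, pH, sites))
  }
  cpl <- .site_couplings(sites, pH, config)
  occ <- as.matrix(expand.grid(rep(list(0:1), n)))[, seq_len(n), drop = FALSE]
  e_h <- occ %*% cpl$h
  e_qq <- rowSums((occ %*% cpl$J) * occ) / 2
  e <- as.numeric(e_h + e_qq)
  emin <- min(e)
  w <- exp(-(e - emin) / rt)
  z <- sum(w)
  p <- w / z
  mean_occ <- as.numeric(p %*% occ)
  mean_charge <- mean_occ * sites$sign
  g <- emin - rt * log(z)
  qq_mean <- sum(p * e_qq)
  .titration_result(mean_charge, rep(0, n), g, qq_mean, pH, sites)
}

#' Sample the charge ensemble by Monte Carlo proton transfer
#'
#' Metropolis sampling over charge configurations with two move types:
#' bulk exchange (one site toggles charged/neutral, exchanging a proton
#' with the bulk) and pair proton transfer (a proton moves from a
#' protonated to a deprotonated site, conserving the proton count). A
#' configuration is accepted when the electrostatic free energy decreases
#' or by the Metropolis criterion. One sweep attempts one move per site.
#'
#' @inheritParams config_energy
#' @param mc an [mc_config()]; its seed makes the chain reproducible
#' @return a `titration_result` with Monte Carlo standard errors in
#'   `charge_sd`; `g_elec` is the production-average electrostatic energy
#' @export
mcpt_sample <- function(sites, pH, mc = mc_config(),
                        config = energy_config()) {
  n <- nrow(sites)
  if (n < 1) stop("mcpt_sample needs at least one site", call. = FALSE)
  if (mc$n_production < 1) stop("zero production sweeps", call. = FALSE)
  rt <- R_GAS * mc$temperature
  cpl <- .site_couplings(sites, pH, config)
  occ0 <- as.integer(sites$sign * (sites$pka_intrinsic - pH) > 0)
  set.seed(mc$seed)
  res <- mcpt_run_cpp(cpl$h, cpl$J, as.integer(sites$sign), rt,
                      mc$n_burn_in, mc$n_production, mc$p_pair, occ0)
  .titration_result(res$mean_charge, res$charge_se, res$e_mean,
                    res$qq_mean, pH, sites, acceptance = res$acceptance)
}

#' Titration curves and apparent pKa values
#'
#' Computes the mean charge of every site on a pH grid (exact enumeration
#' when 16 sites or fewer, Monte Carlo otherwise) and reports the apparent
#' pKa of each site as the pH where its absolute mean charge crosses 0.5,
#' by linear interpolation between bracketing grid points. Sites whose
#' curve never crosses 0.5 inside the grid get `NA` with a warning.
#'
#' @inheritParams mcpt_sample
#' @param pH_grid increasing vector of pH values
#' @return a list with `pH_grid`, `mean_charge` (matrix, one column per
#'   site) and `pka_apparent`
#' @export
titration_curve <- function(sites, pH_grid, config = energy_config(),
                            mc = mc_config()) {
  stopifnot(nrow(sites) > 0, length(pH_grid) >= 2, !is.unsorted(pH_grid))
  n <- nrow(sites)
  use_exact <- mc$mode == "exact" || (mc$mode == "auto" && n <= 16)
  qraw <- vapply(pH_grid, function(ph) {
    tr <- if (use_exact) exact_titration(sites, ph, config) else
      mcpt_sample(sites, ph, mc, config)
    tr$mean_charge
  }, numeric(n))
  qmat <- if (n == 1) matrix(qraw, ncol = 1) else t(qraw)
  pka <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    aq <- abs(qmat[, i])
    cross <- which(diff(sign(aq - 0.5)) != 0)
    if (length(aq[aq == 0.5]) > 0) {
      pka[i] <- pH_grid[which(aq == 0.5)[1]]
    } else if (length(cross) > 0) {
      j <- cross[1]
      f <- (0.5 - aq[j]) / (aq[j + 1] - aq[j])
      pka[i] <- pH_grid[j] + f * (pH_grid[j + 1] - pH_grid[j])
    } else {
      warning("site ", i, ": |mean charge| never crosses 0.5 in the pH grid")
    }
  }
  list(pH_grid = pH_grid, mean_charge = qmat, pka_apparent = pka)
}
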