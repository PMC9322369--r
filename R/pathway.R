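# Conformational pathways: linear Cartesian morphing between residue-
# matched end states, optional steepest-descent relaxation of side
# particles on the CG pair potential, per-frame free energies with
# multi-seed error bars, and barrier / reaction-energy / mutation-scan
# extraction.

#' Morph between two end-state conformations
#'
#' Linear Cartesian interpolation of every matched particle:
#' frame k places each particle at `(1-t) x_a + t x_b` with
#' `t = k / (n_frames - 1)`. Unmatched residues are carried from `a` for
#' `t < 0.5` and from `b` otherwise. The first and last frames equal the
#' end states exactly.
#'
#' @param a,b `cg_structure` end states
#' @param n_frames number of frames including both end states (>= 2,
#'   default 21)
#' @param match a [match_residues()] result; computed if `NULL`. The
#'   match must cover at least 90 percent of the residues of each state.
#' @return a list of `cg_structure` frames with `t` attributes
#' @export
interpolate_frames <- function(a, b, n_frames = 21, match = NULL) {
  stopifnot(n_frames >= 2)
  if (is.null(match)) match <- match_residues(a, b)
  na <- nrow(a$residues); nb <- nrow(b$residues)
  cov_a <- nrow(match$pairs) / na
  cov_b <- nrow(match$pairs) / nb
  if (cov_a < 0.9 || cov_b < 0.9) {
    stop(sprintf(paste0("insufficient residue match coverage for morphing:",
                        " %.0f%% of a, %.0f%% of b (need 90%%)"),
                 100 * cov_a, 100 * cov_b), call. = FALSE)
  }
  ts <- seq(0, 1, length.out = n_frames)
  ra <- a$residues[match$pairs[, 1], , drop = FALSE]
  rb <- b$residues[match$pairs[, 2], , drop = FALSE]
  lapply(seq_along(ts), function(k) {
    t <- ts[k]
    r <- ra
    for (cc in .COORD_COLS) r[[cc]] <- (1 - t) * ra[[cc]] + t * rb[[cc]]
    extra <- if (t < 0.5) {
      a$residues[match$unmatched_a, , drop = FALSE]
    } else {
      b$residues[match$unmatched_b, , drop = FALSE]
    }
    fr <- .new_cg(rbind(r, extra), label = sprintf("t=%.4f", t))
    attr(fr, "t") <- t
    fr
  })
}

# pairwise side-particle energy used by the relaxation: capped 6-12 plus
# the polar / hydrophobic contact terms (piecewise constant, so their
# numerical gradient vanishes away from contact boundaries). With
# `particle` set, returns the sum over pairs involving that particle only.
.side_pair_energy <- function(S, kl, rad, config, particle = NULL,
                              cap = config$vdw_cap) {
  n <- nrow(S)
  if (n < 2) return(0)
  one <- function(i, j) {
    d <- sqrt((S[j, 1] - S[i, 1])^2 + (S[j, 2] - S[i, 2])^2 +
                (S[j, 3] - S[i, 3])^2)
    within <- d <= config$cutoff + 1e-9
    if (!any(within)) return(0)
    dj <- d[within]; jj <- j[within]
    lj <- .lj(dj, rad[i] + rad[jj], config$vdw_eps, cap)
    contact <- config$k_polar * (kl[i] == "polar" & kl[jj] == "polar") -
      config$k_hyd * (kl[i] == "nonpolar" & kl[jj] == "nonpolar")
    sum(lj + contact)
  }
  if (!is.null(particle)) {
    return(one(particle, setdiff(seq_len(n), particle)))
  }
  e <- 0
  for (i in seq_len(n - 1)) e <- e + one(i, (i + 1):n)
  e
}

#' Relax a frame by bounded steepest descent
#'
#' Moves side particles downhill on the side-chain pair surface (capped
#' 6-12 plus contact terms) by numerical gradient, with a per-particle
#' displacement cap of `step_len` Angstrom per step and backtracking so
#' the energy never increases. Backbone atoms are fixed. `n_steps = 0`
#' returns the input unchanged.
#'
#' @param cg a `cg_structure`
#' @param grid unused placeholder for interface symmetry (the relaxation
#'   surface is protein-internal); may be `NULL`
#' @param config an [energy_config()]
#' @param n_steps number of descent steps (default 50)
#' @param step_len displacement cap in Angstrom (default 0.1)
#' @return the relaxed `cg_structure`
#' @export
relax_frame <- function(cg, grid = NULL, config = energy_config(),
                        n_steps = 50, step_len = 0.1) {
  stopifnot(n_steps >= 0)
  if (n_steps == 0) return(cg)
  r <- cg$residues
  idx <- which(!is.na(r$sc_x))
  if (length(idx) < 2) return(cg)
  S <- cbind(r$sc_x[idx], r$sc_y[idx], r$sc_z[idx])
  kl <- r$klass[idx]
  rad <- config$vdw_radius[r$name[idx]]
  rad[is.na(rad)] <- 2.5
  # the descent surface keeps the full repulsive wall (no cap): the
  # plateau of the capped potential has zero gradient, which would leave
  # clashes unresolved
  total_e <- function(S) .side_pair_energy(S, kl, rad, config, cap = Inf)
  local_e <- function(S, i) .side_pair_energy(S, kl, rad, config,
                                              particle = i, cap = Inf)
  e_cur <- total_e(S)
  hgrad <- 1e-4
  for (step in seq_len(n_steps)) {
    G <- matrix(0, nrow(S), 3)
    for (i in seq_len(nrow(S))) {
      for (dim in 1:3) {
        Sp <- S; Sp[i, dim] <- Sp[i, dim] + hgrad
        Sm <- S; Sm[i, dim] <- Sm[i, dim] - hgrad
        G[i, dim] <- (local_e(Sp, i) - local_e(Sm, i)) / (2 * hgrad)
      }
    }
    gmax <- max(sqrt(rowSums(G^2)))
    if (gmax < 1e-8) break
    scale <- step_len / gmax
    accepted <- FALSE
    for (try in 1:8) {
      Snew <- S - scale * G
      e_new <- total_e(Snew)
      if (e_new <= e_cur + 1e-12) {
        S <- Snew; e_cur <- e_new; accepted <- TRUE
        break
      }
      scale <- scale / 2
    }
    if (!accepted) break
  }
  r$sc_x[idx] <- S[, 1]; r$sc_y[idx] <- S[, 2]; r$sc_z[idx] <- S[, 3]
  .new_cg(r, label = cg$label)
}

#' Barrier and reaction energy difference of a profile
#'
#' `barrier = max(g) - g[1]` (earliest maximum on ties) and
#' `reaction_dg = g[1] - g[n]`: a positive reaction energy difference
#' means the final state is more stable than the initial one.
#'
#' @param g numeric vector of per-frame free energies (kcal/mol),
#'   ordered from the initial to the final state
#' @return a list with `barrier`, `barrier_index` (1-based) and
#'   `reaction_dg`
#' @export
#' @examples
#' extract_barrier(c(-200.74, -203.95))$reaction_dg  # 3.21
extract_barrier <- function(g) {
  if (length(g) < 2) {
    stop("extract_barrier needs at least two frame energies", call. = FALSE)
  }
  i <- which.max(g)
  list(barrier = g[i] - g[1], barrier_index = i,
       reaction_dg = g[1] - g[length(g)])
}

#' Free-energy profile along a conformational pathway
#'
#' For every frame: build the membrane grid, optionally relax side
#' particles, and evaluate [total_energy()] once per seed. Frame energies
#' are the per-seed means; the error bars are standard deviations over
#' seeds (zero whenever the exact-titration route is taken, which is
#' deterministic).
#'
#' @param frames list of `cg_structure` frames (>= 2), e.g. from
#'   [interpolate_frames()]
#' @param pH the pH (default 7)
#' @param config an [energy_config()]
#' @param gc a [grid_config()]
#' @param mc an [mc_config()]
#' @param seeds integer vector of seeds (>= 1 seed)
#' @param relax_steps steepest-descent steps per frame (default 0: off)
#' @param relax_step_len displacement cap per step in Angstrom
#' @return an object of class `pathway_profile` with per-frame `g`,
#'   `g_sd`, the per-seed energy matrix, `barrier`,
#'   `barrier_frame_index` and `reaction_dg`
#' @export
pathway_profile <- function(frames, pH = 7, config = energy_config(),
                            gc = grid_config(), mc = mc_config(),
                            seeds = 1L, relax_steps = 0,
                            relax_step_len = 0.1) {
  stopifnot(length(frames) >= 2, length(seeds) >= 1)
  if (any(vapply(frames, function(f) nrow(f$residues) == 0, logical(1)))) {
    stop("pathway contains an empty frame", call. = FALSE)
  }
  gmat <- matrix(NA_real_, length(frames), length(seeds))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    grid <- build_grid(fr, gc)
    if (relax_steps > 0) {
      fr <- relax_frame(fr, grid, config, n_steps = relax_steps,
                        step_len = relax_step_len)
    }
    for (s in seq_along(seeds)) {
      gmat[k, s] <- total_energy(fr, grid, pH, config, mc,
                                 seed = seeds[s])$total
    }
  }
  g <- rowMeans(gmat)
  g_sd <- if (length(seeds) > 1) apply(gmat, 1, stats::sd) else
    rep(0, length(frames))
  bar <- extract_barrier(g)
  structure(list(
    labels = vapply(frames, function(f) f$label, character(1)),
    t = vapply(frames, function(f) attr(f, "t") %||% NA_real_, numeric(1)),
    g = g, g_sd = g_sd, per_seed = gmat,
    barrier = bar$barrier, barrier_frame_index = bar$barrier_index,
    reaction_dg = bar$reaction_dg,
    pH = pH, seeds = seeds),
    class = "pathway_profile")
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat("Pathway profile:", length(x$g), "frames, pH", x$pH, "\n")
  cat(sprintf("  barrier      %8.3f kcal/mol at frame %d\n",
              x$barrier, x$barrier_frame_index))
  cat(sprintf("  reaction dG  %8.3f kcal/mol (G_first - G_last)\n",
              x$reaction_dg))
  invisible(x)
}

#' Mutational scan of the activation barrier
#'
#' Computes the wild-type profile once, then for every mutation applies it
#' to both end states, re-morphs with the same schedule and seeds, and
#' reports the mutant barrier, its change relative to wild type, and the
#' mutant reaction energy difference.
#'
#' @param a,b `cg_structure` end states
#' @param mutations a data frame with columns `chain`, `resno`,
#'   `new_name` (optional `icode`, `label`); may have zero rows
#' @param pH,config,gc,mc,seeds,relax_steps,relax_step_len as in
#'   [pathway_profile()]
#' @param n_frames morphing schedule shared by all profiles
#' @return a data frame of class `mutation_scan` with one row per
#'   mutation (`label`, `barrier_mut`, `barrier_wt`, `delta_barrier`,
#'   `reaction_dg_mut`); the wild-type profile is attached as the
#'   `wild_type` attribute
#' @export
mutation_scan <- function(a, b, mutations, pH = 7,
                          config = energy_config(), gc = grid_config(),
                          mc = mc_config(), seeds = 1L, n_frames = 21,
                          relax_steps = 0, relax_step_len = 0.1) {
  if (is.null(mutations)) {
    mutations <- data.frame(chain = character(0), resno = integer(0),
                            new_name = character(0))
  }
  if (is.null(mutations$icode)) mutations$icode <- rep("", nrow(mutations))
  if (is.null(mutations$label)) {
    mutations$label <- paste0(mutations$chain, mutations$resno,
                              mutations$new_name)
  }
  if (anyDuplicated(mutations$label) > 0) {
    stop("mutation labels must be unique", call. = FALSE)
  }
  run_profile <- function(sa, sb) {
    frames <- interpolate_frames(sa, sb, n_frames = n_frames)
    pathway_profile(frames, pH, config, gc, mc, seeds,
                    relax_steps, relax_step_len)
  }
  wt <- run_profile(a, b)
  rows <- lapply(seq_len(nrow(mutations)), function(i) {
    key <- list(mutations$chain[i], mutations$resno[i], mutations$icode[i])
    ma <- mutate_residue(a, key, mutations$new_name[i], config)
    mb <- mutate_residue(b, key, mutations$new_name[i], config)
    pr <- run_profile(ma, mb)
    data.frame(label = mutations$label[i],
               barrier_mut = pr$barrier, barrier_wt = wt$barrier,
               delta_barrier = pr$barrier - wt$barrier,
               reaction_dg_mut = pr$reaction_dg,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(label = character(0), barrier_mut = numeric(0),
               barrier_wt = numeric(0), delta_barrier = numeric(0),
               reaction_dg_mut = numeric(0), stringsAsFactors = FALSE)
  attr(out, "wild_type") <- wt
  class(out) <- c("mutation_scan", "data.frame")
  out
}
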