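# The energy decomposition: individual terms against closed forms, the
# sum identity, isometry invariance, extensivity, and the ideal-dielectric
# limit.

test_that("charge_charge matches the screened Coulomb closed form", {
  cfg <- energy_config()
  cg <- make_titration_system(list(c(0, 0, 0), c(10, 0, 0)),
                              c("ASP", "LYS"))
  expect_equal(charge_charge(cg, c(-1L, 1L), cfg),
               332.0637 * (-1) / (40 * 10), tolerance = 1e-12)
  # single site and all-neutral configurations contribute nothing
  one <- make_titration_system(list(c(0, 0, 0)), "ASP")
  expect_equal(charge_charge(one, -1L, cfg), 0)
  expect_equal(charge_charge(cg, c(0L, 0L), cfg), 0)
  # clash guard: distances below 2 A are clamped up to 2 A
  close_ <- make_titration_system(list(c(0, 0, 0), c(0.5, 0, 0)),
                                  c("ASP", "LYS"))
  expect_equal(charge_charge(close_, c(-1L, 1L), cfg),
               332.0637 * (-1) / (40 * 2), tolerance = 1e-12)
})

test_that("self_energy_site is linear with saturation and vanishes when
          neutral", {
  cfg <- energy_config()
  expect_equal(self_energy_site(1, list(n_np = 5, n_p = 3, n_mem = 7), 0,
                                cfg), 0)
  expect_equal(self_energy_site(1, list(n_np = 0, n_p = 0, n_mem = 10), 1,
                                cfg), 2.0)
  expect_equal(self_energy_site(-1, list(n_np = 30, n_p = 0, n_mem = 0),
                                -1, cfg), 1.0)   # saturated at n_sat = 20
})

test_that("side_elec assembles the pKa-shift, correction and
          charge-charge parts", {
  cfg <- energy_config()
  rt23 <- 2.3 * 0.0019872 * 300
  # no ionizable residues -> 0
  cg0 <- make_titration_system(list(c(0, 0, 0)), "ALA")
  s0 <- ionizable_sites(cg0, NULL, cfg)
  t0 <- exact_titration(s0, 7, cfg)
  expect_equal(side_elec(s0, t0, cfg)$value, 0)
  # one acid with pKa_intrinsic = pKa_water: first term vanishes
  s <- ionizable_sites(make_titration_system(list(c(0, 0, 0)), "ASP"),
                       NULL, cfg)
  tr <- exact_titration(s, 7, cfg)
  expect_equal(side_elec(s, tr, cfg)$value, 0, tolerance = 1e-12)
  # fully charged acid with a +1 unit shift: -2.3RT * (-1) * 1
  s$pka_intrinsic <- s$pka_water + 1
  tr$mean_charge <- -1
  se <- side_elec(s, tr, cfg)
  expect_equal(se$components$pka_term, rt23, tolerance = 1e-12)
  expect_equal(se$components$qq_unfolded, 0)
  # mismatched titration is a usage error
  expect_error(side_elec(rand_sites(1, 3), tr, cfg), "match")
})

test_that("side polar/hydrophobic/vdW terms follow the contact and 6-12
          rules", {
  cfg <- energy_config()
  # two nonpolar side particles 6 A apart: one hydrophobic contact
  nn <- make_titration_system(list(c(0, 0, 0), c(6, 0, 0)), c("ALA", "ALA"))
  e <- side_polar_hyd_vdw(nn, NULL, cfg)
  expect_equal(e$hyd, -0.1)
  expect_equal(e$polar, 0)
  # polar pair
  pp <- make_titration_system(list(c(0, 0, 0), c(6, 0, 0)), c("SER", "THR"))
  expect_equal(side_polar_hyd_vdw(pp, NULL, cfg)$polar, -0.1)
  # at the 6-12 minimum (r = R_i + R_j = 4 for two ALA) vdw = -well depth
  atmin <- make_titration_system(list(c(0, 0, 0), c(4, 0, 0)),
                                 c("ALA", "ALA"))
  expect_equal(side_polar_hyd_vdw(atmin, NULL, cfg)$vdw, -0.1,
               tolerance = 1e-12)
  # overlapping particles hit the +10 per-pair cap
  clash <- make_titration_system(list(c(0, 0, 0), c(0.02, 0, 0)),
                                 c("ALA", "ALA"))
  expect_equal(side_polar_hyd_vdw(clash, NULL, cfg)$vdw, 10)
  # membrane contact of nonpolar side chains is rewarded once per residue
  fake_grid <- structure(list(particles = rbind(c(0, 0, 3), c(0, 0, 4)),
                              config = grid_config()),
                         class = "membrane_grid")
  em <- side_polar_hyd_vdw(nn, fake_grid, cfg)
  expect_equal(em$hyd, -0.1 - 2 * 0.1)   # pair contact + 2 residues in mem
})

test_that("backbone hydrogen bonds: 6 for a 10-residue ideal helix, none
          for an extended chain", {
  cfg <- energy_config()
  h <- make_helix(helix_spec("AAAAAAAAAA"))
  me <- main_energy(h, NULL, cfg)
  expect_equal(me$main_hb, 6 * cfg$hb_energy, tolerance = 1e-12)
  # brute-force scan confirms exactly 6 donor-acceptor pairs within 3.1 A
  r <- h$residues
  cnt <- 0
  for (i in 1:10) for (j in 1:10) {
    if (abs(i - j) >= 3) {
      d <- sqrt((r$n_x[i] - r$o_x[j])^2 + (r$n_y[i] - r$o_y[j])^2 +
                  (r$n_z[i] - r$o_z[j])^2)
      if (d <= 3.1) cnt <- cnt + 1
    }
  }
  expect_equal(cnt, 6)
  # stretched chain: scale z by 2.4 -> all N-O beyond the switch window
  ext <- transform_cg(h, rotation = diag(c(1, 1, 2.4)))
  expect_equal(main_energy(ext, NULL, cfg)$main_hb, 0)
  # an isolated residue in the water region is not buried
  iso <- make_titration_system(list(c(0, 0, 0)), "ALA")
  expect_equal(main_energy(iso, NULL, cfg)$main_solv, 0)
})

test_that("main-side coupling matches a direct sum over backbone partial
          charges", {
  cfg <- energy_config()
  cg <- make_helix(helix_spec("KAAGAALSA"))
  q_res <- ifelse(cg$residues$name == "LYS", 1, 0)
  ms <- main_side_energy(cg, q_res, cfg)
  # independent re-computation: loop over charged side particles and all
  # backbone atoms of other residues within the cutoff
  deltas <- c(c = 0.4, o = -0.4, n = -0.2)
  r <- cg$residues
  e_ref <- 0
  for (i in which(q_res != 0)) {
    for (j in seq_len(nrow(r))) {
      if (j == i) next
      for (p in names(deltas)) {
        xyz <- c(r[[paste0(p, "_x")]][j], r[[paste0(p, "_y")]][j],
                 r[[paste0(p, "_z")]][j])
        if (any(is.na(xyz))) next
        d <- sqrt(sum((xyz - c(r$sc_x[i], r$sc_y[i], r$sc_z[i]))^2))
        if (d <= 10 + 1e-9) {
          e_ref <- e_ref + 332.0637 * q_res[i] * deltas[[p]] /
            (40 * max(d, 2))
        }
      }
    }
  }
  expect_equal(ms$ms_elec, e_ref, tolerance = 1e-10)
  # all-neutral charges give no electrostatic coupling
  expect_equal(main_side_energy(cg, numeric(nrow(r)), cfg)$ms_elec, 0)
})

test_that("the decomposition identity holds on randomized structures", {
  cfg <- energy_config()
  for (seed in 1:10) {
    cg <- rand_structure(seed)
    grid <- build_grid(cg, grid_config())
    eb <- total_energy(cg, grid, pH = 7, cfg)
    lhs <- eb$total
    rhs <- cfg$c1 * eb$side_vdw + cfg$c2 * eb$main_solv +
      cfg$c3 * eb$main_hb + eb$side_elec + eb$side_polar + eb$side_hyd +
      eb$ms_elec + eb$ms_vdw
    expect_lt(abs(lhs - rhs), 1e-9)
  }
})

test_that("the total energy is invariant under joint rigid motion of
          structure and grid", {
  cfg <- energy_config()
  cg <- rand_structure(3)
  grid <- build_grid(cg, grid_config())
  e0 <- total_energy(cg, grid, 7, cfg)$total
  for (seed in 1:3) {
    R <- rand_rotation(seed)
    tr <- c(5.5, -2.2, 8.8) * seed
    e1 <- total_energy(transform_cg(cg, R, tr),
                       transform_grid(grid, R, tr), 7, cfg)$total
    expect_lt(abs(e1 - e0), 1e-8)
  }
})

test_that("two far-separated copies have exactly twice the single-copy
          energy", {
  cfg <- energy_config()
  one <- make_helix(helix_spec("LAKLDLSLA", origin = c(0, 0, -6)))
  # displacement is a lattice multiple so the membrane environment of the
  # copy is congruent
  two <- memcg:::.cg_bind(list(
    one,
    local({
      cp <- transform_cg(one, translation = c(60, 0, 0))
      cp$residues$chain <- "B"
      memcg:::.new_cg(cp$residues)
    })))
  e1 <- total_energy(one, build_grid(one, grid_config()), 7, cfg)$total
  e2 <- total_energy(two, build_grid(two, grid_config()), 7, cfg)$total
  expect_lt(abs(e2 - 2 * e1), 1e-6)
})

test_that("with an infinite dielectric and zero self slopes the
          electrostics reduce to Henderson-Hasselbalch", {
  cfg <- energy_config(eps_eff = 1e12, a_np = 0, a_p = 0, a_mem = 0)
  cg <- make_titration_system(list(c(0, 0, 0), c(5, 0, 0)), c("ASP", "LYS"))
  grid <- build_grid(cg, grid_config())
  sites <- ionizable_sites(cg, grid, cfg)
  # no self-energy -> no pKa shift
  expect_equal(sites$pka_intrinsic, sites$pka_water)
  tr <- exact_titration(sites, 7, cfg)
  # titration follows the single-site sigmoid with the 2.3 factor of the
  # energy function (base exp(2.3), within 1e-3 of the base-10 form)
  hh <- function(sign, pka, ph) sign / (1 + exp(2.3 * sign * (ph - pka)))
  expect_equal(tr$mean_charge,
               hh(sites$sign, sites$pka_water, 7), tolerance = 1e-9)
  eb <- total_energy(cg, grid, 7, cfg)
  expect_equal(eb$side_elec, 0, tolerance = 1e-6)
})

test_that("an empty structure has zero total energy", {
  cfg <- energy_config()
  empty <- memcg:::.new_cg(make_helix(helix_spec("A"))$residues[0, ])
  eb <- total_energy(empty, NULL, 7, cfg)
  expect_equal(eb$total, 0)
  expect_equal(eb$side_elec, 0)
})
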