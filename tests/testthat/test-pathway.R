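# Morphing, relaxation, profiles, barrier extraction and mutation scans.

test_that("interpolate_frames hits the end states exactly and averages at
          the midpoint", {
  b <- make_two_state_bundle(two_state_spec(helix_length = 10,
                                            tilt_delta = 25))
  # two frames are exactly the end states
  fr2 <- interpolate_frames(b$a, b$b, n_frames = 2)
  expect_equal(fr2[[1]]$residues[, memcg:::.COORD_COLS],
               b$a$residues[, memcg:::.COORD_COLS])
  expect_equal(fr2[[2]]$residues[, memcg:::.COORD_COLS],
               b$b$residues[, memcg:::.COORD_COLS])
  # identical end states morph to identical frames
  frsame <- interpolate_frames(b$a, b$a, n_frames = 5)
  for (f in frsame) {
    expect_equal(f$residues[, memcg:::.COORD_COLS],
                 b$a$residues[, memcg:::.COORD_COLS])
  }
  # odd frame count: the middle frame is the coordinate average
  fr3 <- interpolate_frames(b$a, b$b, n_frames = 3)
  expect_equal(fr3[[2]]$residues$ca_x,
               (b$a$residues$ca_x + b$b$residues$ca_x) / 2)
  # insufficient match coverage is a pathway error
  short <- memcg:::.new_cg(b$b$residues[1:20, ])
  expect_error(interpolate_frames(b$a, short), "coverage")
})

test_that("relax_frame only ever lowers the side-chain pair energy and
          separates clashes", {
  cfg <- energy_config()
  # two clashing side particles 1 A apart
  clash <- make_titration_system(list(c(0, 0, 0), c(1, 0, 0)),
                                 c("ALA", "ALA"))
  relaxed <- relax_frame(clash, NULL, cfg, n_steps = 200, step_len = 0.1)
  d0 <- 1
  d1 <- sqrt(sum((unlist(relaxed$residues[2, c("sc_x", "sc_y", "sc_z")]) -
                    unlist(relaxed$residues[1, c("sc_x", "sc_y", "sc_z")]))^2))
  expect_gt(d1, d0)
  e <- function(cg) side_polar_hyd_vdw(cg, NULL, cfg)$vdw
  expect_lt(e(relaxed), e(clash))
  # zero steps returns the input unchanged
  expect_equal(relax_frame(clash, NULL, cfg, n_steps = 0), clash)
  # a pair resting at the 6-12 minimum does not move
  atmin <- make_titration_system(list(c(0, 0, 0), c(4, 0, 0)),
                                 c("ALA", "ALA"))
  rel <- relax_frame(atmin, NULL, cfg, n_steps = 20)
  expect_equal(rel$residues$sc_x, atmin$residues$sc_x, tolerance = 1e-3)
})

test_that("extract_barrier implements the barrier and reaction-energy
          definitions", {
  # reported end-state free energies of a two-state chloride channel
  bar <- extract_barrier(c(-200.74, -203.95))
  expect_equal(bar$reaction_dg, 3.21, tolerance = 1e-10)
  expect_equal(bar$barrier, 0)
  # interior maximum with the earliest-index tie-break
  b2 <- extract_barrier(c(0, 5, 2))
  expect_equal(b2$barrier, 5)
  expect_equal(b2$barrier_index, 2)
  expect_equal(b2$reaction_dg, -2)
  b3 <- extract_barrier(c(1, 4, 4, 0))
  expect_equal(b3$barrier_index, 2)
  # monotone decreasing profile has zero barrier at the first frame
  b4 <- extract_barrier(c(3, 2, 1))
  expect_equal(b4$barrier, 0)
  expect_equal(b4$barrier_index, 1)
  expect_error(extract_barrier(1), "at least two")
})

test_that("pathway profiles satisfy the barrier algebra and reversal
          symmetry in exact mode", {
  cfg <- energy_config()
  b <- make_two_state_bundle(two_state_spec(helix_length = 10,
                                            tilt_delta = 25))
  frames <- interpolate_frames(b$a, b$b, n_frames = 7)
  pr <- pathway_profile(frames, pH = 7, config = cfg)
  expect_gte(pr$barrier, 0)
  expect_equal(pr$reaction_dg, pr$g[1] - pr$g[length(pr$g)])
  expect_equal(pr$g_sd, rep(0, 7))   # exact titration is deterministic
  # reversed path: opposite reaction energy, barrier algebra identity
  rev_pr <- pathway_profile(rev(frames), pH = 7, config = cfg)
  expect_equal(rev_pr$reaction_dg, -pr$reaction_dg, tolerance = 1e-9)
  expect_equal(pr$barrier - rev_pr$barrier, -pr$reaction_dg,
               tolerance = 1e-9)
  # when the final state is more stable, the forward barrier is smaller
  if (pr$reaction_dg > 0) expect_lt(pr$barrier, rev_pr$barrier)
  if (pr$reaction_dg < 0) expect_gt(pr$barrier, rev_pr$barrier)
  # two identical frames: flat profile
  flat <- pathway_profile(list(frames[[1]], frames[[1]]), config = cfg)
  expect_equal(flat$barrier, 0)
  expect_equal(flat$reaction_dg, 0)
})

test_that("multi-seed profiles report spread only on the Monte Carlo
          route", {
  cfg <- energy_config()
  b <- make_two_state_bundle(two_state_spec(helix_length = 8,
                                            tilt_delta = 15))
  frames <- interpolate_frames(b$a, b$b, n_frames = 3)
  mc <- mc_config(mode = "mc", n_burn_in = 200, n_production = 2000)
  pr <- pathway_profile(frames, config = cfg, mc = mc, seeds = c(1L, 2L, 3L))
  expect_true(any(pr$g_sd > 0))
  # the MC means stay close to the exact-route energies
  ex <- pathway_profile(frames, config = cfg)
  expect_lt(max(abs(pr$g - ex$g)), 0.2)
})

test_that("mutation_scan reports barrier changes against the shared
          wild-type profile", {
  cfg <- energy_config()
  fx <- make_barrier_fixture()
  # empty scan still computes the wild-type profile
  empty <- mutation_scan(fx$a, fx$b, NULL, n_frames = 5, config = cfg)
  expect_equal(nrow(empty), 0)
  wt <- attr(empty, "wild_type")
  expect_gt(wt$barrier, 0)
  # a "mutation" to the same residue type changes nothing
  muts <- data.frame(chain = "B", resno = 6L, new_name = "ILE",
                     label = "same")
  same <- mutation_scan(fx$a, fx$b, muts, n_frames = 5, config = cfg)
  expect_equal(same$delta_barrier, 0)
  # neutralizing the membrane-crossing lysine lowers the barrier;
  # a distal mutation leaves it unchanged
  muts2 <- data.frame(chain = c("A", "B"), resno = c(6L, 6L),
                      new_name = c("SER", "ALA"),
                      label = c("K6S", "distal_I6A"))
  scan <- mutation_scan(fx$a, fx$b, muts2, n_frames = 9, config = cfg)
  expect_lt(scan$delta_barrier[scan$label == "K6S"], 0)
  expect_lt(abs(scan$delta_barrier[scan$label == "distal_I6A"]), 0.1)
  expect_error(
    mutation_scan(fx$a, fx$b,
                  data.frame(chain = "Z", resno = 1L, new_name = "ALA"),
                  n_frames = 3, config = cfg),
    "no residue")
})
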