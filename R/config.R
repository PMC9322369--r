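# Configuration objects: energy-function coefficients and tables, membrane
# grid geometry, and Monte Carlo settings. All physical constants and
# residue tables live here so that every other module is table-driven.

#' Gas constant in kcal/(mol K)
#' @keywords internal
R_GAS <- 0.0019872

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

.default_residue_class <- function() {
  c(ALA = "nonpolar", VAL = "nonpolar", LEU = "nonpolar", ILE = "nonpolar",
    PHE = "nonpolar", MET = "nonpolar", TRP = "nonpolar", PRO = "nonpolar",
    GLY = "nonpolar",
    SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
    TYR = "polar", CYS = "polar",
    ASP = "ionizable", GLU = "ionizable", LYS = "ionizable",
    ARG = "ionizable", HIS = "ionizable")
}

.default_pka_water <- function() {
  c(ASP = 3.9, GLU = 4.3, HIS = 6.5, LYS = 10.5, ARG = 12.5)
}

.default_ionizable_sign <- function() {
  c(ASP = -1L, GLU = -1L, HIS = 1L, LYS = 1L, ARG = 1L)
}

# united side-chain particle radii (Angstrom) used for the 6-12 terms
.default_vdw_radius <- function() {
  c(ALA = 2.0, ARG = 3.0, ASN = 2.5, ASP = 2.4, CYS = 2.2, GLN = 2.7,
    GLU = 2.7, HIS = 2.7, ILE = 2.8, LEU = 2.8, LYS = 2.9, MET = 2.9,
    PHE = 2.9, PRO = 2.4, SER = 2.0, THR = 2.4, TRP = 3.2, TYR = 3.0,
    VAL = 2.5)
}

# radial CA -> side-particle placement distance (Angstrom) for generators
# and pseudo side-chain reconstruction; GLY has no side particle
.default_side_dist <- function() {
  c(ALA = 1.5, ARG = 4.1, ASN = 2.5, ASP = 2.5, CYS = 2.1, GLN = 3.1,
    GLU = 3.1, HIS = 3.2, ILE = 2.3, LEU = 2.6, LYS = 4.0, MET = 2.9,
    PHE = 3.4, PRO = 1.9, SER = 1.9, THR = 1.9, TRP = 3.9, TYR = 3.8,
    VAL = 2.0)
}

#' Energy-function configuration
#'
#' Collects every coefficient, cutoff and lookup table of the coarse-grained
#' free-energy function. The backbone scaling coefficients are
#' `c2 = 0.25` (solvation) and `c3 = 0.15` (hydrogen bonds); the side-chain
#' van der Waals scale `c1` defaults to 0.10. All distances are in Angstrom
#' and all energies in kcal/mol.
#'
#' @param ... named overrides of any default field. Unknown names are an
#'   error so that configuration typos fail fast.
#'
#' @details Fields:
#' \describe{
#'   \item{c1, c2, c3}{dimensionless scaling of side vdW, backbone
#'     solvation and backbone hydrogen bonds in the total energy.}
#'   \item{eps_eff}{uniform effective dielectric for all charge terms
#'     (default 40).}
#'   \item{coulomb_k}{332.0637 kcal A / (mol e^2).}
#'   \item{temperature}{K, used for 2.3RT pKa conversions (default 300).}
#'   \item{a_np, a_p, a_mem}{self-energy slopes, kcal/mol per nonpolar,
#'     polar and membrane neighbor of a charged site.}
#'   \item{n_sat}{neighbor count at which each self-energy term saturates.}
#'   \item{cutoff}{pair-interaction cutoff; a distance exactly equal to the
#'     cutoff still counts.}
#'   \item{clash_clamp}{lower clamp (A) on distances in Coulomb terms so
#'     unrelaxed morph frames stay finite.}
#'   \item{vdw_eps, vdw_cap, bb_vdw_radius}{6-12 well depth, per-pair
#'     repulsive cap, and backbone-atom radius.}
#'   \item{hb_energy, hb_on, hb_off}{backbone H-bond well depth and the
#'     linear switch window over donor-N / acceptor-O distance.}
#'   \item{k_polar, k_hyd, k_hyd_mem}{per-contact constants of the polar
#'     and hydrophobic side-chain terms.}
#'   \item{k_solv, burial_radius, burial_threshold}{backbone desolvation
#'     penalty per buried amide N/O and the burial criterion.}
#'   \item{q_dev}{constant protonation-deviation correction per site
#'     (default 0).}
#'   \item{termini_ionizable}{treat chain termini as ionizable sites
#'     (default FALSE).}
#'   \item{pka_water, residue_class, ionizable_sign, vdw_radius,
#'     side_dist}{named lookup tables over 3-letter residue types.}
#' }
#' @return an object of class `energy_config`
#' @export
#' @examples
#' cfg <- energy_config(eps_eff = 20)
#' cfg$c2
energy_config <- function(...) {
  cfg <- list(
    c1 = 0.10, c2 = 0.25, c3 = 0.15,
    eps_eff = 40, coulomb_k = 332.0637, temperature = 300,
    a_np = 0.05, a_p = -0.05, a_mem = 0.20, n_sat = 20,
    cutoff = 10, clash_clamp = 2,
    vdw_eps = 0.1, vdw_cap = 10, bb_vdw_radius = 1.7,
    hb_energy = -1.0, hb_on = 3.0, hb_off = 3.5,
    k_polar = -0.1, k_hyd = 0.1, k_hyd_mem = 0.1,
    k_solv = 0.5, burial_radius = 6, burial_threshold = 10,
    q_dev = 0,
    termini_ionizable = FALSE,
    pka_n_terminus = 8.0, pka_c_terminus = 3.6,
    pka_water = .default_pka_water(),
    residue_class = .default_residue_class(),
    ionizable_sign = .default_ionizable_sign(),
    vdw_radius = .default_vdw_radius(),
    side_dist = .default_side_dist()
  )
  cfg <- .merge_config(cfg, list(...), "energy_config")
  stopifnot(cfg$eps_eff > 0, cfg$n_sat > 0,
            cfg$c1 >= 0, cfg$c2 >= 0, cfg$c3 >= 0,
            cfg$temperature > 0, cfg$cutoff > 0)
  structure(cfg, class = "energy_config")
}

#' Membrane grid configuration
#'
#' Geometry of the implicit-membrane particle lattice: a cubic lattice of
#' spacing `spacing` filling the slab `|z - slab_center_z| <=
#' slab_half_thickness`, laterally covering the protein bounding box
#' extended by `lateral_margin`, with nodes closer than `exclusion_radius`
#' to any protein particle removed.
#'
#' @param spacing lattice constant in Angstrom (default 3)
#' @param slab_center_z slab mid-plane z in Angstrom (default 0)
#' @param slab_half_thickness half thickness in Angstrom (default 15,
#'   i.e. a 30 A hydrophobic core)
#' @param exclusion_radius protein exclusion radius in Angstrom (default 2.5)
#' @param lateral_margin lateral extension beyond the protein bounding box
#'   in Angstrom (default 15)
#' @return an object of class `grid_config`
#' @export
grid_config <- function(spacing = 3, slab_center_z = 0,
                        slab_half_thickness = 15,
                        exclusion_radius = 2.5, lateral_margin = 15) {
  stopifnot(spacing > 0, slab_half_thickness > 0, exclusion_radius >= 0,
            lateral_margin >= 0)
  structure(list(spacing = spacing, slab_center_z = slab_center_z,
                 slab_half_thickness = slab_half_thickness,
                 exclusion_radius = exclusion_radius,
                 lateral_margin = lateral_margin),
            class = "grid_config")
}

#' Monte Carlo proton-transfer configuration
#'
#' @param temperature K (default 300)
#' @param n_burn_in burn-in sweeps (one sweep = one attempted move per site)
#' @param n_production production sweeps used for averaging
#' @param p_pair fraction of pair proton-transfer moves; the remainder are
#'   single-site bulk exchanges
#' @param seed RNG seed used by [mcpt_sample()]
#' @param mode `"auto"` (exact enumeration when 16 sites or fewer, Monte
#'   Carlo otherwise), `"exact"`, or `"mc"`
#' @return an object of class `mc_config`
#' @export
mc_config <- function(temperature = 300, n_burn_in = 2000,
                      n_production = 20000, p_pair = 0.2, seed = 1L,
                      mode = c("auto", "exact", "mc")) {
  mode <- match.arg(mode)
  stopifnot(temperature > 0, n_burn_in >= 0, n_production > 0,
            p_pair >= 0, p_pair <= 1)
  structure(list(temperature = temperature, n_burn_in = as.integer(n_burn_in),
                 n_production = as.integer(n_production), p_pair = p_pair,
                 seed = as.integer(seed), mode = mode),
            class = "mc_config")
}

# strict merge: overriding an unknown key is an error
.merge_config <- function(base, override, what) {
  if (length(override) == 0) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == "")) {
    stop(what, ": all overrides must be named", call. = FALSE)
  }
  bad <- setdiff(nm, names(base))
  if (length(bad) > 0) {
    stop(what, ": unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (k in nm) base[[k]] <- override[[k]]
  base
}

#' Read a run configuration from YAML
#'
#' The file may contain any of the top-level sections `energy`, `grid`,
#' `mc` and `pathway`; each section overrides the corresponding defaults.
#' Unknown sections or keys are errors.
#'
#' @param path YAML file path, or `NULL` for all defaults
#' @return a list with elements `energy` ([energy_config()]), `grid`
#'   ([grid_config()]), `mc` ([mc_config()]) and `pathway` (list with
#'   `n_frames`, `pH`, `seeds`, `relax_steps`, `relax_step_len`)
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("energy", "grid", "mc", "pathway"))
  if (length(bad) > 0) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pathway <- list(n_frames = 21L, pH = 7, seeds = c(1L, 2L, 3L),
                  relax_steps = 0L, relax_step_len = 0.1)
  pathway <- .merge_config(pathway, raw$pathway %||% list(), "pathway")
  en <- do.call(energy_config, raw$energy %||% list())
  gc <- do.call(grid_config, raw$grid %||% list())
  mc <- do.call(mc_config, raw$mc %||% list())
  list(energy = en, grid = gc, mc = mc, pathway = pathway)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain-list view of a run config, suitable for yaml::write_yaml snapshots
.config_as_list <- function(rc) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.numeric(v) || is.character(v)) v else v)
  }
  list(energy = strip(rc$energy), grid = strip(rc$grid),
       mc = strip(rc$mc), pathway = rc$pathway)
}
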