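# End-to-end pipeline: read end-state PDB files, coarse-grain, morph,
# titrate and evaluate per-frame energies, and write the profile table,
# summary JSON and a config snapshot. Identical inputs, config and seeds
# give byte-identical outputs.

# tiny deterministic rolling hash of a string, for config fingerprints
.fnv1a <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write a pathway profile as TSV
#'
#' Columns: `frame_index` (1-based), `t`, `label`, `g_mean`, `g_sd`.
#' @param profile a [pathway_profile()] object
#' @param path output file
#' @return invisibly, `path`
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pathway_profile"))
  if (length(profile$g) == 0) stop("empty profile", call. = FALSE)
  df <- data.frame(frame_index = seq_along(profile$g),
                   t = sprintf("%.10g", profile$t),
                   label = profile$labels,
                   g_mean = sprintf("%.10g", profile$g),
                   g_sd = sprintf("%.10g", profile$g_sd),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a pathway summary as JSON
#'
#' Keys: `barrier`, `barrier_frame_index`, `reaction_dg`, `pH`, `seeds`,
#' `config_hash` and a per-leg breakdown for chained pathways. Numbers are
#' serialized at full precision.
#' @param profile a [pathway_profile()] object
#' @param path output file
#' @param legs optional per-leg summary list
#' @param config_hash optional config fingerprint string
#' @return invisibly, `path`
#' @export
write_summary_json <- function(profile, path, legs = NULL,
                               config_hash = NULL) {
  stopifnot(inherits(profile, "pathway_profile"))
  if (length(profile$g) == 0) stop("empty profile", call. = FALSE)
  out <- list(barrier = profile$barrier,
              barrier_frame_index = profile$barrier_frame_index,
              reaction_dg = profile$reaction_dg,
              n_frames = length(profile$g),
              pH = profile$pH,
              seeds = as.list(profile$seeds))
  if (!is.null(legs)) out$legs <- legs
  if (!is.null(config_hash)) out$config_hash <- config_hash
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full conformational-pathway pipeline
#'
#' Reads two or more end-state PDB files in pathway order, coarse-grains
#' them, morphs each consecutive pair, and computes the chained
#' free-energy profile (shared junction frames, energies not re-zeroed
#' between legs). Writes `profile.tsv`, `summary.json` and
#' `config_snapshot.yaml` into `out_dir`; progress goes to standard
#' error.
#'
#' @param end_state_paths character vector of two or more PDB paths
#' @param out_dir output directory (created if needed)
#' @param config_path optional YAML run configuration for
#'   [read_run_config()]
#' @param overrides optional list overriding pathway settings
#'   (`n_frames`, `pH`, `seeds`, `relax_steps`, `relax_step_len`)
#' @return invisibly, a list with the chained `profile`, the per-leg
#'   summaries and the output paths
#' @export
run_pipeline <- function(end_state_paths, out_dir, config_path = NULL,
                         overrides = NULL) {
  if (length(end_state_paths) < 2) {
    stop("run_pipeline needs at least two end-state PDB paths",
         call. = FALSE)
  }
  rc <- read_run_config(config_path)
  rc$pathway <- .merge_config(rc$pathway, overrides %||% list(), "pathway")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage [", what, "]: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  message("reading ", length(end_state_paths), " end state(s)")
  states <- lapply(end_state_paths, function(p) {
    stage(paste0("read ", p), coarse_grain(read_pdb_model(p), rc$energy))
  })
  pw <- rc$pathway
  all_frames <- list()
  for (leg in seq_len(length(states) - 1)) {
    fr <- stage(paste0("morph leg ", leg),
                interpolate_frames(states[[leg]], states[[leg + 1]],
                                   n_frames = pw$n_frames))
    if (leg > 1) fr <- fr[-1]  # shared junction frame
    for (f in seq_along(fr)) attr(fr[[f]], "leg") <- leg
    all_frames <- c(all_frames, fr)
  }
  message("profiling ", length(all_frames), " frame(s), pH ", pw$pH,
          ", seeds ", paste(pw$seeds, collapse = ","))
  profile <- stage("profile",
                   pathway_profile(all_frames, pH = pw$pH,
                                   config = rc$energy, gc = rc$grid,
                                   mc = rc$mc, seeds = pw$seeds,
                                   relax_steps = pw$relax_steps,
                                   relax_step_len = pw$relax_step_len))
  # per-leg barriers from the chained energies
  leg_of <- vapply(all_frames, function(f) attr(f, "leg"), numeric(1))
  legs <- lapply(sort(unique(leg_of)), function(l) {
    sel <- which(leg_of == l)
    if (l > 1) sel <- c(max(which(leg_of == l - 1)), sel)
    bar <- extract_barrier(profile$g[sel])
    list(leg = l, barrier = bar$barrier, reaction_dg = bar$reaction_dg)
  })
  snap_path <- file.path(out_dir, "config_snapshot.yaml")
  snap <- .config_as_list(rc)
  yaml::write_yaml(snap, snap_path)
  config_hash <- .fnv1a(paste(readLines(snap_path), collapse = "\n"))
  message("config hash ", config_hash)
  tsv <- write_profile_tsv(profile, file.path(out_dir, "profile.tsv"))
  js <- write_summary_json(profile, file.path(out_dir, "summary.json"),
                           legs = legs, config_hash = config_hash)
  message("wrote ", tsv, " and ", js)
  invisible(list(profile = profile, legs = legs,
                 paths = list(tsv = tsv, json = js, config = snap_path)))
}
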