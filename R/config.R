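# YAML/JSON configuration schema: geometry block, motion block (named
# preset or tabulated (x, a, phi) triples), simulation, decomposition,
# phantom/signal synthesis, unfolding and stats blocks.  Builders map
# config lists onto the package's constructors.

#' Load a pipeline configuration
#'
#' @param path YAML (or JSON) configuration file.
#' @return named list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Build a tube geometry from a config block
#'
#' @param block named list (fields of [tube_geometry()]); `NULL` gives the
#'   default geometry.
#' @return a [tube_geometry()].
#' @export
build_geometry <- function(block = NULL) {
  if (is.null(block)) return(tube_geometry())
  do.call(tube_geometry, block[names(block) %in%
    c("length", "avc_half_width", "avc_center", "avc_flat", "avc_ramp")])
}

#' Build a wall motion model from a config block
#'
#' Supports the named preset (`preset: two_chamber` with its parameters) or
#' tabulated profiles: `table` as a list/matrix of `(x, a, phi)` triples,
#' interpolated periodically.
#'
#' @param geometry a [tube_geometry()].
#' @param block named list; `NULL` gives the default preset.
#' @return a [wall_motion()].
#' @export
build_motion <- function(geometry, block = NULL) {
  if (is.null(block)) return(wall_motion(geometry))
  if (!is.null(block$table)) {
    tab <- do.call(rbind, lapply(block$table, unlist))
    L <- geometry$length
    a_fun <- function(x) .vm_pinterp(tab[, 1], tab[, 2], x, L)
    phi_fun <- function(x) .vm_pinterp(tab[, 1], tab[, 3], x, L)
    return(wall_motion(geometry, amplitude = a_fun, phase = phi_fun,
                       f1 = block$f1 %||% 1,
                       symmetric = block$symmetric %||% TRUE,
                       asymmetry = block$asymmetry %||% 1))
  }
  args <- block[names(block) %in%
    c("f1", "symmetric", "chamber_amplitude", "avc_amplitude", "avc_phase",
      "dphi", "asymmetry")]
  if (!is.null(args$chamber_amplitude)) {
    args$chamber_amplitude <- unlist(args$chamber_amplitude)
  }
  do.call(wall_motion, c(list(geometry = geometry), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a simulation config from config blocks
#'
#' @param config full config list with optional `geometry`, `motion`,
#'   `membrane`, `simulate` blocks.
#' @param seed root seed overriding the config's.
#' @return a [sim_config()].
#' @export
build_sim_config <- function(config, seed = NULL) {
  geom <- build_geometry(config$geometry)
  mot <- build_motion(geom, config$motion)
  memb <- if (is.null(config$membrane)) {
    membrane_params()
  } else {
    do.call(membrane_params, config$membrane[names(config$membrane) %in%
      c("k_s", "k_b", "n_nodes", "semi_axes", "repulsion_strength",
        "repulsion_cutoff")])
  }
  sblock <- config$simulate %||% list()
  args <- sblock[names(sblock) %in%
    c("n_rbc", "seed", "n_per_wall", "steps_per_beat", "n_beats",
      "discard_beats", "samples_per_beat", "n_stations", "eps_factor",
      "reparam_every")]
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, c(list(geometry = geom, motion = mot,
                             membrane = memb), args))
}
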