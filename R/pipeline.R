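# Pipeline orchestration: run the synthesis, simulation, decomposition,
# unfolding and statistics stages from one configuration with a single root
# seed, write plain-text outputs, and record a manifest (config hash,
# per-stage seeds, file checksums) sufficient to re-run bit-identically.

#' Summarize the directional predictions of a decomposition
#'
#' Emits, for the analyzed wall, the signs of the time-average shear
#' `tau0` on the atrial and ventricular flanks of the AVC, the sign of the
#' spatial gradient of the fundamental amplitude `tau1` on each flank, the
#' sign of the mean flux, and three boolean flags: whether `tau0` points
#' away from the AVC on both flanks, whether the `tau1` gradient points
#' toward the AVC center from both flanks, and whether the mean flow is
#' unidirectional atrium-to-ventricle.  Flanks are the stations within half
#' a transition ramp of the AVC segment boundaries.
#'
#' @param decomp a [spatial_profiles()] result.
#' @param geometry the [tube_geometry()] of the simulation.
#' @param mean_flux time-mean flux (positive = atrium to ventricle).
#' @param flank_halfwidth flank window half-width (defaults to half the AVC
#'   transition ramp).
#' @return list of signs and flags.
#' @export
report_directions <- function(decomp, geometry, mean_flux = NA,
                              flank_halfwidth = NULL) {
  seg <- geometry$segments$avc
  st <- decomp$stations
  if (is.null(flank_halfwidth)) {
    flank_halfwidth <- diff(seg) / 6
  }
  iA <- which(abs(st - seg[1]) <= flank_halfwidth)
  iV <- which(abs(st - seg[2]) <= flank_halfwidth)
  if (length(iA) == 0 || length(iV) == 0) {
    stop("AVC flanks are not covered by the station grid")
  }
  tau0_A <- mean(decomp$tau0[iA])
  tau0_V <- mean(decomp$tau0[iV])
  g1 <- gradient_tau1(decomp)
  grad_A <- mean(g1[iA])
  grad_V <- mean(g1[iV])
  tau1_peak <- st[which.max(decomp$tau_k[1, ])]
  inside <- tau1_peak >= seg[1] && tau1_peak <= seg[2]
  list(
    tau0_atrial_flank = tau0_A,
    tau0_ventricular_flank = tau0_V,
    grad_tau1_atrial_flank = grad_A,
    grad_tau1_ventricular_flank = grad_V,
    tau1_peak_station = tau1_peak,
    tau1_peak_in_avc = inside,
    mean_flux = mean_flux,
    tau0_points_away_from_avc = (tau0_A < 0) && (tau0_V > 0),
    grad_tau1_points_toward_avc = (grad_A > 0) && (grad_V < 0),
    mean_flow_unidirectional = is.finite(mean_flux) && mean_flux > 0
  )
}

# deterministic per-stage seed expansion from the root seed
.vm_stage_seed <- function(seed, stage) {
  offs <- c(phantom = 101, signal = 211, simulate = 307, decompose = 401,
            unfold = 503, stats = 601)
  (as.integer(seed) * 7 + offs[[stage]]) %% .Machine$integer.max
}

#' Run the configured pipeline stages
#'
#' Stages (any subset of `"phantom"`, `"signal"`, `"simulate"`,
#' `"decompose"`, `"unfold"`, `"stats"`) execute in dependency order;
#' `decompose` needs `simulate`, `unfold` needs `phantom` (or configured
#' stack paths), `stats` needs a group table.  On stage failure the partial
#' outputs are kept and the manifest marks the failed stage.
#'
#' @param config path to a YAML/JSON config or a config list.
#' @param out_dir output directory (created if needed).
#' @param seed root seed; expanded deterministically per stage.
#' @return the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("valvemorph_run_"),
                         seed = 1) {
  if (is.character(config)) config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$pipeline$stages %||%
    c("signal", "simulate", "decompose")
  order_all <- c("phantom", "signal", "simulate", "decompose", "unfold",
                 "stats")
  stages <- order_all[order_all %in% stages]
  cfg_path <- file.path(out_dir, "config_used.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    root_seed = seed,
    stages = list(),
    files = list(),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  state <- new.env(parent = emptyenv())
  add_file <- function(path) {
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
  }
  run_stage <- function(name, fun) {
    res <- tryCatch({
      fun()
      list(status = "ok")
    }, error = function(e) list(status = "failed",
                                error = conditionMessage(e)))
    res$seed <- .vm_stage_seed(seed, name)
    manifest$stages[[name]] <<- res
    res$status == "ok"
  }
  for (stage in stages) {
    ok <- switch(stage,
      phantom = run_stage("phantom", function() {
        blk <- config$phantom %||% list()
        blk$seed <- .vm_stage_seed(seed, "phantom")
        spec <- do.call(phantom_spec, blk[names(blk) %in%
          names(formals(phantom_spec))])
        for (tp in 1:2) {
          ph <- make_phantom(spec, tp)
          paths <- write_phantom_tiff(
            ph, file.path(out_dir, sprintf("phantom_t%d.tiff", tp)))
          for (p in paths) add_file(p)
          state[[sprintf("phantom_t%d", tp)]] <- ph
        }
      }),
      signal = run_stage("signal", function() {
        blk <- config$signal %||% list()
        blk$seed <- .vm_stage_seed(seed, "signal")
        if (!is.null(blk$harmonics)) {
          blk$harmonics <- as.data.frame(do.call(rbind,
            lapply(blk$harmonics, unlist)))
          names(blk$harmonics) <- c("k", "amplitude", "phase")
        }
        spec <- do.call(signal_spec, blk[names(blk) %in%
          names(formals(signal_spec))])
        sig <- make_signal(spec)
        p <- file.path(out_dir, "signal.csv")
        utils::write.csv(sig, p, row.names = FALSE)
        add_file(p)
        state$signal <- sig
      }),
      simulate = run_stage("simulate", function() {
        scfg <- build_sim_config(config, seed = .vm_stage_seed(seed,
                                                               "simulate"))
        sim <- run_heart_sim(scfg)
        state$sim <- sim
        rec <- wss_record(sim, "upper")
        tu <- data.frame(time = rec$time, rec$tau)
        names(tu) <- c("time", sprintf("station_%02d", seq_along(rec$stations)))
        p1 <- file.path(out_dir, "tau_upper.csv")
        utils::write.csv(tu, p1, row.names = FALSE)
        fl <- data.frame(time = sim$time[sim$retained],
                         sim$flux[sim$retained, , drop = FALSE])
        names(fl) <- names(tu)
        p2 <- file.path(out_dir, "flux.csv")
        utils::write.csv(fl, p2, row.names = FALSE)
        add_file(p1); add_file(p2)
        if (scfg$n_rbc > 0) {
          pr <- concentration_profile(sim)
          p3 <- file.path(out_dir, "concentration.csv")
          utils::write.csv(pr, p3, row.names = FALSE)
          add_file(p3)
        }
      }),
      decompose = run_stage("decompose", function() {
        if (is.null(state$sim)) stop("dependency error: stage 'simulate' ",
                                     "must run before 'decompose'")
        blk <- config$decompose %||% list()
        rec <- wss_record(state$sim, blk$side %||% "upper")
        dec <- spatial_profiles(rec, K = blk$harmonics %||% 3,
                                bins = blk$bins)
        state$decomp <- dec
        prof <- data.frame(
          station = dec$stations, tau0 = dec$tau0,
          t(dec$tau_k), tau_np = dec$tau_np
        )
        names(prof)[3:(2 + dec$K)] <- sprintf("tau%d", seq_len(dec$K))
        p <- file.path(out_dir, "decomposition.csv")
        utils::write.csv(prof, p, row.names = FALSE)
        add_file(p)
        dirs <- report_directions(dec, state$sim$config$geometry,
                                  mean_flux = mean(state$sim$flux[
                                    state$sim$retained, ]))
        p2 <- file.path(out_dir, "directions.json")
        jsonlite::write_json(dirs, p2, auto_unbox = TRUE, digits = NA)
        add_file(p2)
      }),
      unfold = run_stage("unfold", function() {
        if (is.null(state$phantom_t1)) {
          stop("dependency error: stage 'phantom' must run before 'unfold'")
        }
        blk <- config$unfold %||% list()
        Ls <- list()
        for (tp in 1:2) {
          ph <- state[[sprintf("phantom_t%d", tp)]]
          gt <- ph$ground_truth
          # seeds from config, or from the known phantom axis
          seeds <- if (!is.null(blk$seeds)) {
            do.call(rbind, lapply(blk$seeds, unlist))
          } else {
            gt$centerline$points[round(seq(30, nrow(gt$centerline$points) - 30,
                                           length.out = 5)), ]
          }
          cl <- fit_centerline(ph$green, ph$spacing, seeds, ph$origin)
          uf <- unfold(list(green = ph$green, red = ph$red), ph$spacing,
                       cl, ph$origin,
                       n_s = blk$n_s %||% 96, n_theta = blk$n_theta %||% 48,
                       s_range = c(0.06, 0.94) * max(cl$s))
          Ls[[tp]] <- measure_L(uf)
        }
        sr <- shortening(Ls[[1]], Ls[[2]],
                         quadrant_offset = blk$quadrant_offset %||% 0)
        state$shortening <- sr
        p <- file.path(out_dir, "shortening.csv")
        utils::write.csv(data.frame(theta = sr$theta, L1 = sr$L1,
                                    L2 = sr$L2, shortening = sr$shortening,
                                    quadrant = sr$quadrant),
                         p, row.names = FALSE)
        p2 <- file.path(out_dir, "shortening_quadrants.csv")
        utils::write.csv(sr$quadrants, p2, row.names = FALSE)
        add_file(p); add_file(p2)
      }),
      stats = run_stage("stats", function() {
        blk <- config$stats %||% list()
        if (is.null(blk$input)) {
          stop("dependency error: stage 'stats' needs a group table ",
               "('stats: input: <csv>')")
        }
        df <- group_table(utils::read.csv(blk$input))
        groups <- blk$groups %||% unique(df$group)
        if (length(groups) < 2) {
          stop("argument error: stats stage needs two groups to compare")
        }
        summ <- summarize_shortening(df)
        p <- file.path(out_dir, "group_summary.csv")
        utils::write.csv(summ, p, row.names = FALSE)
        cmp <- compare_groups(df, groups[1], groups[2],
                              welch = isTRUE(blk$welch))
        p2 <- file.path(out_dir, "group_tests.csv")
        utils::write.csv(cmp, p2, row.names = FALSE)
        add_file(p); add_file(p2)
      })
    )
    if (!ok) break
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(manifest, list(out_dir = out_dir)))
}
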