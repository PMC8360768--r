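# End-to-end orchestration on synthetic sessions, anatomical property
# maps, and the command-line entry point.

#' Session configuration for the synthetic pipeline
#'
#' Every stochastic stage carries an explicit seed derived from the three
#' master seeds.
#'
#' @param n_units Population size (default 400).
#' @param seeds Named list: `population`, `simulation`, `analysis`.
#' @param contrast Cone contrast of the classification battery (0.75).
#' @param n_trials Trial blocks per full-field condition (default 5, of
#'   `n_cycles` cycles each: 30 cycles total).
#' @param n_cycles Cycles per block (default 6).
#' @param frequency Square-wave frequency, Hz (0.25).
#' @param sample_rate Simulation sample rate, Hz.
#' @param mr_trials Repeats per Mel High/Low step (default 10).
#' @param mr_intensities Number of step intensities (default 1: the model
#'   has no adaptation, so intensities replicate).
#' @param family_limit Use a family-wise 95% shuffle limit across the L
#'   and S conditions for the responsiveness decision (keeps the null
#'   false-positive rate per *unit* at 5%).
#' @param out_dir Output directory or `NULL`.
#' @param verbose Stage-level logging.
#' @param population_args Extra arguments passed to [make_population()].
#' @return List of class `session_config`.
#' @export
pipeline_config <- function(n_units = 400,
                            seeds = list(population = 1, simulation = 2,
                                         analysis = 3),
                            contrast = 0.75, n_trials = 5, n_cycles = 6,
                            frequency = 0.25, sample_rate = 200,
                            mr_trials = 10, mr_intensities = 1,
                            family_limit = TRUE, out_dir = NULL,
                            verbose = FALSE, population_args = list()) {
  stopifnot(all(c("population", "simulation", "analysis") %in% names(seeds)))
  structure(list(n_units = n_units, seeds = seeds, contrast = contrast,
                 n_trials = n_trials, n_cycles = n_cycles,
                 frequency = frequency, sample_rate = sample_rate,
                 mr_trials = mr_trials, mr_intensities = mr_intensities,
                 family_limit = family_limit, out_dir = out_dir,
                 verbose = verbose, population_args = population_args),
            class = "session_config")
}

#' Design the full-field classification battery
#'
#' Solves and builds the four 0.25 Hz square-wave stimuli (L-only,
#' S-only, L+S, L-S) at the given cone contrast, silencing the other
#' cone where applicable and using the spare degree of freedom to
#' minimize rod/melanopsin residuals.
#'
#' @param background A [make_background()] object.
#' @param contrast Cone contrast (default 0.75).
#' @param n_cycles,frequency,sample_rate Passed to [build_square_wave()].
#' @return Named list (`L_only`, `S_only`, `LpS`, `LmS`) of lists with
#'   `solution` and `waveform`.
#' @export
design_stimulus_battery <- function(background, contrast = 0.75,
                                    n_cycles = 6, frequency = 0.25,
                                    sample_rate = 200) {
  specs <- list(
    L_only = contrast_spec(target = c(L = contrast), silence = "S",
                           minimize = c("rod", "mel")),
    S_only = contrast_spec(target = c(S = contrast), silence = "L",
                           minimize = c("rod", "mel")),
    LpS = contrast_spec(target = c(L = contrast, S = contrast),
                        minimize = c("rod", "mel")),
    LmS = contrast_spec(target = c(L = contrast, S = -contrast),
                        minimize = c("rod", "mel")))
  lapply(specs, function(sp) {
    sol <- solve_silent_substitution(background, sp)
    list(solution = sol,
         waveform = build_square_wave(sol, background, frequency = frequency,
                                      n_cycles = n_cycles,
                                      sample_rate = sample_rate))
  })
}

#' Moving-window anatomical property map
#'
#' Aggregates a per-cell value (mean) or label (fraction) over a moving
#' circular window on a regular grid of anatomical positions; nodes with
#' fewer than `min_count` cells are masked (`NA`).
#'
#' @param cells data.frame with `x`, `y` (micrometres) and either `value`
#'   (numeric) or `label` (character).
#' @param radius Window radius, micrometres (default 150).
#' @param min_count Minimum cells per window (default 10).
#' @param target `list(type = "mean")` or `list(type = "fraction", label =
#'   <label>)`.
#' @param grid_step Grid spacing, micrometres (default 25).
#' @return Object of class `anatomical_map`: data.frame `nodes` (`x`,
#'   `y`, `value`, `count`, `masked`) plus parameters.
#' @export
moving_window_map <- function(cells, radius = 150, min_count = 10,
                              target = list(type = "mean"), grid_step = 25) {
  if (nrow(cells) == 0) {
    return(structure(list(nodes = data.frame(x = numeric(0), y = numeric(0),
                                             value = numeric(0),
                                             count = integer(0),
                                             masked = logical(0)),
                          radius = radius, min_count = min_count,
                          target = target),
                     class = "anatomical_map"))
  }
  stopifnot(all(c("x", "y") %in% names(cells)))
  vals <- if (target$type == "mean") {
    stopifnot("value" %in% names(cells))
    cells$value
  } else if (target$type == "fraction") {
    stopifnot("label" %in% names(cells))
    as.numeric(cells$label == target$label)
  } else stop("target$type must be 'mean' or 'fraction'")
  gx <- seq(min(cells$x), max(cells$x), by = grid_step)
  gy <- seq(min(cells$y), max(cells$y), by = grid_step)
  nodes <- expand.grid(x = gx, y = gy)
  r2 <- radius^2
  agg <- vapply(seq_len(nrow(nodes)), function(i) {
    sel <- (cells$x - nodes$x[i])^2 + (cells$y - nodes$y[i])^2 <= r2
    n <- sum(sel)
    c(if (n >= min_count) mean(vals[sel]) else NA_real_, n)
  }, numeric(2))
  nodes$value <- agg[1, ]
  nodes$count <- as.integer(agg[2, ])
  nodes$masked <- is.na(nodes$value)
  structure(list(nodes = nodes, radius = radius, min_count = min_count,
                 target = target, grid_step = grid_step),
            class = "anatomical_map")
}

#' Confusion matrix and accuracy
#'
#' @param truth,predicted Character vectors of equal length.
#' @return List: `table` (truth in rows), `accuracy`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  lev <- sort(unique(c(truth, predicted)))
  tab <- table(factor(truth, lev), factor(predicted, lev))
  list(table = tab, accuracy = sum(diag(tab)) / sum(tab))
}

# map a ground-truth class label onto the analysis label space
truth_opponency_label <- function(class_label) {
  switch(class_label,
         nonopp_ON = "non_opponent", nonopp_OFF = "non_opponent",
         L_ON_S_OFF = "L_ON_S_OFF", S_ON_L_OFF = "S_ON_L_OFF",
         nonresponsive = "non_responsive")
}

#' Run the full synthetic session pipeline
#'
#' Designs the stimulus battery, samples a ground-truth population,
#' simulates full-field responses and Mel High/Low steps, classifies
#' every unit (opponency, cone preference, melanopsin responsiveness),
#' and maps opponency prevalence and cone preference across the
#' anatomical template. Fully reproducible from the config.
#'
#' @param config A [pipeline_config()].
#' @return List of class `session_report`: `units` (per-unit results),
#'   `confusion` (opponency), `mr_confusion`, `battery` (solutions),
#'   `maps`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "session_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("designing stimuli")
  bg <- make_background()
  battery <- design_stimulus_battery(bg, contrast = config$contrast,
                                     n_cycles = config$n_cycles,
                                     frequency = config$frequency,
                                     sample_rate = config$sample_rate)
  steps <- build_step_pair(bg, sample_rate = 100)

  say("sampling population of %d units", config$n_units)
  pop <- do.call(make_population,
                 c(list(n = config$n_units, seed = config$seeds$population),
                   config$population_args))
  truth <- population_truth(pop)

  say("simulating full-field battery")
  period <- 1 / config$frequency
  trial_dur <- config$n_cycles * period
  sims <- lapply(seq_along(battery), function(i) {
    simulate_full_field(pop, battery[[i]]$waveform, n_trials = config$n_trials,
                        seed = derive_seed(config$seeds$simulation, i))
  })
  names(sims) <- names(battery)

  say("simulating Mel High/Low steps")
  step_sims <- lapply(seq_len(config$mr_intensities), function(k) {
    list(high = simulate_full_field(pop, steps$high,
                                    n_trials = config$mr_trials,
                                    seed = derive_seed(config$seeds$simulation,
                                                       100 + k)),
         low = simulate_full_field(pop, steps$low,
                                   n_trials = config$mr_trials,
                                   seed = derive_seed(config$seeds$simulation,
                                                      200 + k)))
  })

  say("classifying units")
  unit_ids <- truth$unit_id
  rows <- vector("list", length(unit_ids))
  for (i in seq_along(unit_ids)) {
    uid <- unit_ids[i]
    spk <- lapply(sims, function(df) df[df$unit_id == uid, , drop = FALSE])
    ms <- lapply(seq_along(spk), function(j) {
      response_amplitude(spk[[j]], period, trial_dur,
                         seed = derive_seed(config$seeds$analysis,
                                            uid * 10 + j))
    })
    names(ms) <- names(spk)
    L_m <- ms$L_only; S_m <- ms$S_only
    if (config$family_limit) {
      flim <- stats::quantile(pmax(L_m$null_amplitudes, S_m$null_amplitudes),
                              0.95, names = FALSE)
      L_m$significant <- L_m$raw > flim
      S_m$significant <- S_m$raw > flim
    }
    amps_mS <- trial_amplitudes(spk$LmS, period, trial_dur)
    amps_pS <- trial_amplitudes(spk$LpS, period, trial_dur)
    opp <- classify_opponency(L_m, S_m, amps_mS, amps_pS)
    mr <- classify_mr(lapply(step_sims, function(s) {
      list(high = s$high[s$high$unit_id == uid, , drop = FALSE],
           low = s$low[s$low$unit_id == uid, , drop = FALSE])
    }))
    pref <- if (L_m$corrected > 0 || S_m$corrected > 0) {
      cone_preference(max(L_m$corrected, 0), max(S_m$corrected, 0))
    } else NA_real_
    rows[[i]] <- data.frame(
      unit_id = uid,
      truth_class = truth$class_label[i],
      truth_label = truth_opponency_label(truth$class_label[i]),
      label = opp$label, evidence = opp$evidence,
      mr_truth = ifelse(truth$mr_flag[i], "MR", "non_MR"),
      mr_label = mr$label,
      amp_L = L_m$signed, amp_S = S_m$signed,
      sig_L = L_m$significant, sig_S = S_m$significant,
      preference = pref,
      x_ml = truth$x_ml[i], y_dv = truth$y_dv[i])
  }
  units <- do.call(rbind, rows)

  confusion <- confusion_matrix(units$truth_label, units$label)
  mr_confusion <- confusion_matrix(units$mr_truth, units$mr_label)

  say("building anatomical maps")
  opp_cells <- data.frame(x = units$x_ml, y = units$y_dv,
                          label = ifelse(units$label %in%
                                           c("L_ON_S_OFF", "S_ON_L_OFF"),
                                         "opponent", "other"))
  maps <- list(
    opponent_prevalence = moving_window_map(
      opp_cells, target = list(type = "fraction", label = "opponent")),
    preference = moving_window_map(
      data.frame(x = units$x_ml, y = units$y_dv,
                 value = units$preference)[!is.na(units$preference), ],
      target = list(type = "mean")))

  cfg_json <- jsonlite::toJSON(unclass(config)[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  config_hash <- unname(tools::md5sum(tf)); unlink(tf)

  report <- structure(list(units = units, confusion = confusion,
                           mr_confusion = mr_confusion,
                           battery = lapply(battery, `[[`, "solution"),
                           steps = steps[c("mel_ratio", "rod_ratio")],
                           maps = maps, config = config,
                           config_hash = config_hash,
                           elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                           units = "secs"))),
                      class = "session_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %d units; opponency accuracy %.3f; MR accuracy %.3f\n",
              nrow(x$units), x$confusion$accuracy, x$mr_confusion$accuracy))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$units, file.path(out_dir, "units.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$confusion$table),
                   file.path(out_dir, "confusion.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    config_hash = report$config_hash,
    seeds = report$config$seeds,
    accuracy = report$confusion$accuracy,
    mr_accuracy = report$mr_confusion$accuracy,
    battery = lapply(report$battery, function(s) {
      list(modulation = as.list(s$modulation),
           achieved = as.list(s$achieved), feasible = s$feasible)
    })), file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Command-line interface
#'
#' Subcommands: `design-stimuli`, `simulate`, `analyze`, `sta`, `rf-map`,
#' `retina-model`, `report`. Common flags: `--config PATH` (JSON),
#' `--seed INT`, `--out DIR`, `--verbose`. `analyze`/`report` run the
#' full pipeline; the other subcommands exercise a single stage at small
#' default scale.
#'
#' @param args Character vector (default `commandArgs(trailingOnly =
#'   TRUE)`).
#' @return Invisibly, the subcommand's result.
#' @export
lgnchrom_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: lgnchrom <design-stimuli|simulate|analyze|sta|rf-map|retina-model|report>",
        "[--config PATH] [--seed INT] [--out DIR] [--verbose]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- list(seed = 1L, out = ".", config = NULL, verbose = FALSE)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--verbose") { opt$verbose <- TRUE; i <- i + 1 }
    else if (a %in% c("--config", "--seed", "--out")) {
      opt[[sub("^--", "", a)]] <- args[i + 1]; i <- i + 2
    } else stop("unknown argument: ", a)
  }
  opt$seed <- as.integer(opt$seed)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  cfg_extra <- if (!is.null(opt$config)) jsonlite::read_json(opt$config,
                                                             simplifyVector = TRUE)
               else list()
  mk_config <- function(defaults) {
    base <- utils::modifyList(defaults, cfg_extra)
    base$seeds <- list(population = derive_seed(opt$seed, 1),
                       simulation = derive_seed(opt$seed, 2),
                       analysis = derive_seed(opt$seed, 3))
    base$out_dir <- opt$out
    base$verbose <- opt$verbose
    do.call(pipeline_config, base)
  }
  res <- switch(cmd,
    "design-stimuli" = {
      bg <- make_background()
      battery <- design_stimulus_battery(bg)
      for (nm in names(battery)) {
        write_solution_json(battery[[nm]]$solution,
                            file.path(opt$out, paste0(nm, "_solution.json")))
        write_waveform_csv(battery[[nm]]$waveform,
                           file.path(opt$out, paste0(nm, "_waveform.csv")))
      }
      battery
    },
    "simulate" = {
      cfg <- mk_config(list(n_units = 50))
      bg <- make_background()
      battery <- design_stimulus_battery(bg, contrast = cfg$contrast)
      pop <- make_population(cfg$n_units, seed = cfg$seeds$population)
      for (nm in names(battery)) {
        spk <- simulate_full_field(pop, battery[[nm]]$waveform,
                                   n_trials = cfg$n_trials,
                                   seed = derive_seed(cfg$seeds$simulation,
                                                      match(nm, names(battery))))
        write_spikes_csv(spk, file.path(opt$out, paste0(nm, "_spikes.csv")))
      }
      write_population_json(pop, file.path(opt$out, "population.json"))
      pop
    },
    "analyze" = ,
    "report" = run_pipeline(mk_config(list(n_units = 50))),
    "sta" = {
      bg <- make_background(variant = "reduced_s")
      wf <- build_white_noise(bg, duration = 300, seed = opt$seed)
      pop <- make_population(10, seed = opt$seed)
      spk <- simulate_white_noise(pop, wf, seed = derive_seed(opt$seed, 2))
      res <- lapply(stats::setNames(nm = unique(spk$unit_id)), function(uid) {
        compute_sta(spk$time_s[spk$unit_id == uid],
                    wf$meta$sequences[, c("L", "S", "rod")],
                    frame_rate = wf$meta$rate,
                    seed = derive_seed(opt$seed, 3))
      })
      write_sta_csv(res, file.path(opt$out, "sta_traces.csv"),
                    file.path(opt$out, "sta_summary.csv"))
      res
    },
    "rf-map" = {
      pop <- make_population(5, seed = opt$seed)
      ev <- square_mapping_events(seed = derive_seed(opt$seed, 1))
      spk <- simulate_spatial(pop, ev, seed = derive_seed(opt$seed, 2))
      fits <- lapply(pop$units, function(u) {
        m <- location_response_map(spk[spk$unit_id == u$unit_id, ], ev)
        f <- fit_rf_center(m)
        data.frame(unit_id = u$unit_id, cell_type = m$cell_type,
                   az = f$center[["azimuth"]], el = f$center[["elevation"]],
                   sigma = f$sigma, ve = f$variance_explained,
                   mappable = f$mappable)
      })
      out <- do.call(rbind, fits)
      utils::write.csv(out, file.path(opt$out, "rf_fits.csv"),
                       row.names = FALSE)
      out
    },
    "retina-model" = {
      sw <- sweep_random_wiring(cone_gradient(), n_strips = 20,
                                seed = opt$seed)
      utils::write.csv(sw$cells, file.path(opt$out, "retina_cells.csv"),
                       row.names = FALSE)
      utils::write.csv(sw$summary, file.path(opt$out, "retina_summary.csv"),
                       row.names = FALSE)
      sw
    },
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
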