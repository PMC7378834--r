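default_pipeline_config <- function() {
  list(seed = 1,
       outdir = NULL,
       generator = list(),
       protocol = list(onset = 20, duration = 20, pulse_frequency = 2,
                       intensity = 2),
       battery_durations = c(1, 5, 10, 20, 60),
       segmentation = list(),
       events = list(),
       spectral = list(),
       coupling = list(step = 0.5),
       write_raw = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Chains every stage on generated data: synthetic field and two-channel
#' movie, feedback simulation and ECoG synthesis, territory segmentation,
#' trace extraction and event detection, population response over a duration
#' battery with a sigmoid fit, spectral band power with gamma metrics and
#' up-states, and astrocyte-gamma coupling. All tables are written as CSV
#' with a stable column order, scalar results as JSON, masks as plain-text
#' PGM label images, and every parameter used is echoed to `params.json`.
#' A fixed seed makes the run byte-reproducible.
#'
#' @param config configuration list or path to a JSON file; see
#'   `gliawave:::default_pipeline_config()` for the recognized fields
#' @param seed overrides `config$seed`
#' @param outdir overrides `config$outdir`; must be set in one of the two
#' @return (invisibly) a list with the in-memory results
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$outdir)) stopf("no output directory configured")
  if (is.null(cfg$seed)) stopf("no seed configured")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- stage("config", do.call(gen_config, cfg$generator))
  seg_cfg <- stage("config", do.call(seg_config, cfg$segmentation))
  ev_cfg <- stage("config", do.call(event_config, cfg$events))
  sp_cfg <- stage("config", do.call(spectral_config, cfg$spectral))
  protocol <- stage("config", do.call(stimulus_protocol, cfg$protocol))
  seed0 <- as.integer(cfg$seed)

  ## --- synthesis -----------------------------------------------------------
  sim <- stage("simulate", {
    field <- make_astrocyte_field(gen, seed = seed0)
    if (protocol$onset + protocol$duration > gen$movie_duration) {
      gen$movie_duration <- protocol$onset + protocol$duration + 10
    }
    mov <- simulate_calcium_movie(field, protocol, gen, seed = seed0)
    fb <- simulate_feedback(protocol, gen, seed = seed0)
    ec <- simulate_ecog(protocol, gen, gamma_envelope = fb, seed = seed0)
    list(field = field, movie = mov, feedback = fb, ecog = ec)
  })
  if (isTRUE(cfg$write_raw)) {
    stage("simulate", {
      write_movie(sim$movie$movie, file.path(cfg$outdir, "movie.tif"))
      write_ecog(sim$ecog$recording, file.path(cfg$outdir, "ecog.csv"))
    })
  }

  ## --- segmentation --------------------------------------------------------
  terrs <- stage("segment", segment_territories(sim$movie$movie,
                                                config = seg_cfg))
  stage("segment", {
    d <- sim$field$truth$dim
    soma_lab <- matrix(0L, d[1], d[2]); arb_lab <- matrix(0L, d[1], d[2])
    for (t in terrs) {
      soma_lab[t$soma_mask] <- t$cell_id
      arb_lab[t$arborization_mask] <- t$cell_id
    }
    write_pgm(soma_lab, file.path(cfg$outdir, "masks_soma.pgm"))
    write_pgm(arb_lab, file.path(cfg$outdir, "masks_arborization.pgm"))
    utils::write.csv(as.data.frame(terrs),
                     file.path(cfg$outdir, "territories.csv"),
                     row.names = FALSE)
  })

  ## --- traces and events ---------------------------------------------------
  evres <- stage("events", {
    traces <- extract_traces(sim$movie$movie, terrs)
    tt <- movie_times(sim$movie$movie)
    tr_rows <- lapply(traces, function(tr) {
      trd <- compute_dff(tr, c(0, protocol$onset))
      data.frame(roi_id = tr$roi_id, compartment = tr$compartment,
                 cell_id = tr$cell_id, time = tt, f = tr$f, dff = trd$dff)
    })
    ev_rows <- lapply(traces, function(tr) {
      ev <- detect_events(tr, ev_cfg, protocol)
      if (nrow(ev)) cbind(ev, cell_id = tr$cell_id) else NULL
    })
    pop <- population_response(terrs, traces, protocol, ev_cfg)
    list(traces = traces,
         trace_table = do.call(rbind, tr_rows),
         event_table = do.call(rbind, ev_rows[!vapply(ev_rows, is.null, logical(1))]),
         population = pop)
  })
  stage("events", {
    utils::write.csv(evres$trace_table, file.path(cfg$outdir, "traces.csv"),
                     row.names = FALSE)
    et <- evres$event_table %||%
      data.frame(roi_id = character(0), compartment = character(0),
                 onset = numeric(0), peak_time = numeric(0),
                 offset = numeric(0), amplitude = numeric(0),
                 n_frames = integer(0), cell_id = integer(0))
    utils::write.csv(et, file.path(cfg$outdir, "events.csv"),
                     row.names = FALSE)
    write_json_file(evres$population, file.path(cfg$outdir, "population.json"))
  })

  ## --- stimulus-response curve over the duration battery -------------------
  fits <- NULL
  if (length(cfg$battery_durations) >= 4) {
    fits <- stage("fitcurves", {
      pct <- vapply(cfg$battery_durations, function(d) {
        g2 <- gen
        g2$movie_duration <- max(gen$movie_duration, protocol$onset + d + 10)
        pr <- stimulus_protocol(protocol$onset, d, protocol$pulse_frequency,
                                protocol$intensity)
        m2 <- simulate_calcium_movie(sim$field, pr, g2,
                                     seed = child_seed(seed0, sprintf("battery%d", round(10 * d))))
        tr2 <- extract_traces(m2$movie, m2$territories)
        population_response(m2$territories, tr2, pr, ev_cfg)$microdomain
      }, numeric(1))
      curve <- response_curve(cfg$battery_durations, pct, kind = "duration")
      fit <- fit_sigmoid(curve)
      utils::write.csv(data.frame(duration = curve$x, pct_responding = curve$y),
                       file.path(cfg$outdir, "response_curve.csv"),
                       row.names = FALSE)
      write_json_file(list(parameters = as.list(stats::coef(fit)),
                           rss = fit$rss, converged = fit$converged,
                           truth_probability =
                             vapply(cfg$battery_durations, function(d) {
                               response_probability(
                                 stimulus_protocol(protocol$onset, d,
                                                   protocol$pulse_frequency,
                                                   protocol$intensity), gen)
                             }, numeric(1))),
                      file.path(cfg$outdir, "fits.json"))
      fit
    })
  }

  ## --- spectral ------------------------------------------------------------
  spres <- stage("spectral", {
    filt <- lowpass_fir(sim$ecog$recording, sp_cfg)
    spec <- smooth_welch(spectrogram_db(filt, sp_cfg), sp_cfg)
    bw <- c(0, protocol$onset)
    bands <- lapply(names(sp_cfg$bands), function(b) {
      relative_power(band_power(spec, b, sp_cfg), bw, protocol)
    })
    names(bands) <- names(sp_cfg$bands)
    gm <- gamma_metrics(bands$gamma, protocol, sp_cfg)
    ups <- detect_upstates(filt, sp_cfg)
    list(spec = spec, bands = bands, gamma = gm, upstates = ups)
  })
  stage("spectral", {
    bp <- do.call(rbind, lapply(names(spres$bands), function(b) {
      s <- spres$bands[[b]]
      data.frame(band = b, time = s$times, power_db = s$power_db,
                 relative_db = s$relative_db)
    }))
    utils::write.csv(bp, file.path(cfg$outdir, "bandpower.csv"),
                     row.names = FALSE)
    utils::write.csv(spres$upstates, file.path(cfg$outdir, "upstates.csv"),
                     row.names = FALSE)
    write_json_file(unclass(spres$gamma),
                    file.path(cfg$outdir, "gamma_metrics.json"))
    utils::write.csv(data.frame(time = sim$feedback$times,
                                gamma_db = sim$feedback$gamma,
                                calcium = sim$feedback$calcium,
                                stimulus = sim$feedback$stimulus),
                     file.path(cfg$outdir, "feedback.csv"), row.names = FALSE)
  })

  ## --- coupling ------------------------------------------------------------
  coup <- stage("couple", {
    tt <- movie_times(sim$movie$movie)
    arb <- Filter(function(tr) tr$compartment == "arborization", evres$traces)
    arb <- Filter(function(tr) {
      t <- Find(function(z) z$cell_id == tr$cell_id, terrs)
      !is.null(t) && qc_pass(t)
    }, arb)
    if (!length(arb)) stopf("no QC-passing arborization traces")
    dffs <- vapply(arb, function(tr) compute_dff(tr, c(0, protocol$onset))$dff,
                   numeric(length(tt)))
    pop_ca <- rowMeans(dffs)
    g <- spres$bands$gamma
    streams <- align_streams(tt, pop_ca, g$times, g$relative_db,
                             step = cfg$coupling$step)
    coupling_result(streams, seed = seed0)
  })
  stage("couple", {
    write_json_file(unclass(coup), file.path(cfg$outdir, "coupling.json"))
  })

  ## --- parameter echo ------------------------------------------------------
  stage("log", {
    write_json_file(list(seed = seed0,
                         protocol = unclass(protocol),
                         generator = unclass(gen),
                         segmentation = unclass(seg_cfg),
                         events = unclass(ev_cfg),
                         spectral = unclass(sp_cfg),
                         battery_durations = cfg$battery_durations,
                         coupling = cfg$coupling),
                    file.path(cfg$outdir, "params.json"))
  })
  invisible(list(config = cfg, sim = sim, territories = terrs,
                 events = evres, fit = fits, spectral = spres,
                 coupling = coup))
}
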