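#' Read and write spike-train files
#'
#' Delimited text with a header line and columns `neuron_id` (0-based
#' integer) and `time_ms` (float), sorted by time. Times are preserved to
#' 1e-3 ms on a round trip.
#'
#' @param path file path.
#' @param trains data.frame with `neuron_id`, `time_ms`.
#' @return `read_spikes`: a `data.table`; `write_spikes`: the path,
#'   invisibly.
#' @export
read_spikes <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("neuron_id", "time_ms") %in% names(x)))
    stop("spike file must have columns neuron_id, time_ms: ", path)
  if (nrow(x)) {
    # a single malformed cell makes fread return a character column: coerce
    # per cell so the offending row can be named
    tm <- suppressWarnings(as.numeric(x$time_ms))
    id <- suppressWarnings(as.integer(x$neuron_id))
    bad <- which(!is.finite(tm) | is.na(id))
    if (length(bad))
      stop("malformed spike row at line ", bad[1] + 1L, " of ", path)
    x$time_ms <- tm
    x$neuron_id <- id
    us <- which(diff(x$time_ms) < 0)
    if (length(us))
      stop("spike times not sorted at line ", us[1] + 2L, " of ", path)
  }
  x[]
}

#' @rdname read_spikes
#' @export
write_spikes <- function(trains, path) {
  trains <- as.data.frame(trains)[, c("neuron_id", "time_ms")]
  trains$time_ms <- round(trains$time_ms, 3)
  data.table::fwrite(trains, path, sep = "\t")
  invisible(path)
}

#' Read and write trace files
#'
#' Delimited text with columns `time_ms` and `value`.
#' @param path file path.
#' @param trace an `opt_trace` or data.frame with `time_ms`, `value`.
#' @export
read_trace <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("time_ms", "value") %in% names(x)))
    stop("trace file must have columns time_ms, value: ", path)
  dt <- if (nrow(x) > 1) x$time_ms[2] - x$time_ms[1] else NA_real_
  .trace(x$time_ms, x$value, dt)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "opt_trace"))
    trace <- data.frame(time_ms = trace$time, value = trace$value)
  data.table::fwrite(trace[, c("time_ms", "value")], path, sep = "\t")
  invisible(path)
}

#' Read and write parameter configurations
#'
#' Structured text (JSON) mirroring the [population_params()] field names;
#' an assembly is a list of group objects under `groups`.
#' @param path file path.
#' @param pop [population_params()] or [assembly_population()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(g) population_params(
    n_neurons = g$n_neurons, rate_to_active = g$rate_to_active,
    rate_to_quiescent = g$rate_to_quiescent,
    resting_half_gap = g$resting_half_gap,
    time_constant = g$time_constant,
    stationary_cov = if (is.matrix(g$stationary_cov)) g$stationary_cov
      else matrix(unlist(g$stationary_cov), g$n_neurons, g$n_neurons),
    rate_at_threshold = g$rate_at_threshold,
    spiking_steepness = g$spiking_steepness,
    refractory = g$refractory, release_prob = g$release_prob)
  if (!is.null(x$groups)) {
    gl <- if (is.data.frame(x$groups)) split(x$groups, seq_len(nrow(x$groups)))
      else x$groups
    assembly_population(lapply(gl, mk))
  } else mk(x)
}

#' @rdname read_config
#' @export
write_config <- function(pop, path) {
  strip <- function(g) unclass(g)
  x <- if (inherits(pop, "assembly_population"))
    list(groups = lapply(pop$groups, strip)) else strip(pop)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

.param_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Generate synthetic fixture bundles
#'
#' Writes, to `dir`, the spike trains, signals, protocols and synthetic
#' "recorded" traces needed to exercise every module without any external
#' data, plus a `manifest.json` recording the kind, seed, parameters hash and
#' file list. Kinds: `"fig1"` (independent neurons), `"fig2-cor2"`
#' (second-order correlations), `"fig2-switching"` (state switching),
#' `"fig4"` (four assemblies + signal), `"fig5-protocols"` (uncaging bursts,
#' 7 stimuli, ISIs 1-20 ms, plus optimal-response traces with additive
#' Gaussian noise), `"fig2s1"` (single-neuron validation trajectory).
#'
#' @param kind fixture kind.
#' @param seed RNG seed (recorded in the manifest).
#' @param dir output directory (created if needed).
#' @param duration_s duration for the trajectory kinds.
#' @return invisibly, the manifest as a list.
#' @export
make_fixtures <- function(kind = c("fig1", "fig2-cor2", "fig2-switching",
                                   "fig4", "fig5-protocols", "fig2s1"),
                          seed = 1, dir = ".", duration_s = 10) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(name) { files <<- c(files, name); file.path(dir, name) }
  pop <- switch(kind,
    "fig1" = load_preset("fig1bc"),
    "fig2-cor2" = load_preset("cor2"),
    "fig2-switching" = load_preset("fig2cd"),
    "fig4" = load_preset("fig4"),
    "fig5-protocols" = load_preset("NC"),
    "fig2s1" = load_preset("fig2s1"))
  if (kind == "fig5-protocols") {
    isis <- c(1, 2, 5, 10, 20)
    set.seed(seed)
    pre <- load_preset("NC", n_neurons = 10L)
    for (i in seq_along(isis)) {
      pr <- burst_protocol(7, isis[i], t0 = 20)
      write_spikes(data.frame(neuron_id = pr$events$site,
                              time_ms = pr$events$time_ms),
                   put(sprintf("protocol_isi%02d.tsv", isis[i])))
      spk <- protocol_to_spikes(pr)
      traj <- run_filter(spk, pre, dt = 0.5,
                         duration_ms = max(spk$time_ms) + 150)
      v <- .lowpass(traj$mean, 0.5, 10)
      v <- (v - v[1]) * 0.1 + rnorm(length(v), 0, 0.02)
      write_trace(.trace(traj$time, v, 0.5),
                  put(sprintf("trace_isi%02d.tsv", isis[i])))
    }
  } else {
    dt_sim <- if (kind == "fig2s1") 0.2 else 0.5 # fig2s1's link is steeper
    traj <- simulate_population(pop, duration_s, dt = dt_sim, seed = seed,
                                keep_potentials = FALSE)
    write_spikes(traj$spikes, put("spikes.tsv"))
    write_trace(.trace((seq_along(traj$signal) - 1) * traj$dt, traj$signal,
                       traj$dt), put("signal.tsv"))
  }
  manifest <- list(kind = kind, seed = seed,
                   package_version = as.character(utils::packageVersion("optidend")),
                   params_hash = .param_hash(unclass(pop)), files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.cli_usage <- function() {
  paste(
    "usage: optidend <command> [--flag value ...]",
    "commands:",
    "  simulate     --preset P --duration S [--dt MS] [--seed I] --out DIR",
    "  filter       --preset P --spikes F [--tau-post MS] [--mode voltage|rate]",
    "               [--dt MS] [--duration MS] --out F",
    "  validate-adf --preset P --spikes F [--particles M] [--seed I] [--dt MS] --out F",
    "  benchmark    --scenario fig4 [--runs N] [--train S] [--test S] [--seed I] --out F",
    "  fit-dendrite --preset P --protocols F1,F2,... --traces F1,F2,... --out F",
    "  make-fixtures --kind K [--seed I] --out DIR",
    sep = "\n")
}

.parse_flags <- function(argv) {
  flags <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(argv)) stop("missing value for flag ", a)
    flags[[substring(a, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `filter`, `validate-adf`,
#' `benchmark`, `fit-dendrite` and `make-fixtures`. Returns 0 on success, 2
#' on a usage error (with the usage text on stderr) and 1 on a runtime
#' failure. An executable wrapper is installed under `exec/optidend`.
#'
#' @param argv character vector of arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`). A `--config file.json` flag merges
#'   the file's key/value pairs over the command-line flags.
#' @return integer exit code, invisibly.
#' @export
run_cli <- function(argv) {
  code <- tryCatch({
    if (length(argv) < 1) { message(.cli_usage()); return(invisible(2L)) }
    cmd <- argv[1]
    if (!cmd %in% c("simulate", "filter", "validate-adf", "benchmark",
                    "fit-dendrite", "make-fixtures")) {
      message("unknown command: ", cmd, "\n", .cli_usage())
      return(invisible(2L))
    }
    fl <- tryCatch(.parse_flags(argv[-1]), error = function(e) {
      message(conditionMessage(e), "\n", .cli_usage()); NULL
    })
    if (is.null(fl)) return(invisible(2L))
    if (!is.null(fl$config)) { # structured-text config overrides flags
      cfg <- jsonlite::read_json(fl$config, simplifyVector = TRUE)
      fl[names(cfg)] <- lapply(cfg, as.character)
    }
    need <- function(nm) {
      if (is.null(fl[[nm]])) stop("missing required flag --", nm, call. = FALSE)
      fl[[nm]]
    }
    num <- function(nm, default) {
      if (is.null(fl[[nm]])) default else as.numeric(fl[[nm]])
    }
    preset_of <- function(nm) {
      p <- tryCatch(load_preset(nm), error = function(e) {
        message(conditionMessage(e)); NULL
      })
      p
    }
    seed <- as.integer(num("seed", 1))
    log_line <- function(...) message(sprintf(
      "[optidend %s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))

    if (cmd == "simulate") {
      pop <- preset_of(need("preset")); if (is.null(pop)) return(invisible(2L))
      out <- need("out")
      traj <- simulate_population(pop, num("duration", 10),
                                  dt = num("dt", 0.1), seed = seed,
                                  keep_potentials = FALSE)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_spikes(traj$spikes, file.path(out, "spikes.tsv"))
      write_trace(.trace((seq_along(traj$signal) - 1) * traj$dt,
                         traj$signal, traj$dt),
                  file.path(out, "signal.tsv"))
      st <- data.frame(time_ms = (seq_len(ncol(traj$states)) - 1) * traj$dt)
      for (gi in seq_len(nrow(traj$states)))
        st[[paste0("group", gi - 1L)]] <- traj$states[gi, ]
      data.table::fwrite(st, file.path(out, "states.tsv"), sep = "\t")
      jsonlite::write_json(
        list(command = "simulate", preset = need("preset"), seed = seed,
             dt = traj$dt, duration_s = num("duration", 10),
             params_hash = .param_hash(unclass(pop))),
        file.path(out, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
      log_line("simulate: wrote %d spikes to %s", nrow(traj$spikes), out)
    } else if (cmd == "filter") {
      pop <- preset_of(need("preset")); if (is.null(pop)) return(invisible(2L))
      spk <- read_spikes(need("spikes"))
      dt <- num("dt", 0.1)
      traj <- run_filter(spk, pop, dt = dt,
                         duration_ms = num("duration", NULL))
      mode <- if (is.null(fl$mode)) "voltage" else fl$mode
      tr <- if (mode == "rate") rate_readout(traj, num("tau-post", 0))
        else optimal_response(traj, num("tau-post", 0))
      write_trace(tr, need("out"))
      log_line("filter: wrote %d samples to %s", length(tr$value), need("out"))
    } else if (cmd == "validate-adf") {
      pop <- preset_of(need("preset")); if (is.null(pop)) return(invisible(2L))
      spk <- read_spikes(need("spikes"))
      cmpr <- compare_adf_pf(spk, pop, n_particles = num("particles", 10000),
                             seed = seed, dt = num("dt", 0.1))
      writeLines(c(
        sprintf("normalized mean abs difference, zeta: %.4f", cmpr$zeta$mad_norm),
        sprintf("normalized rms difference,     zeta: %.4f", cmpr$zeta$rms_norm),
        sprintf("normalized mean abs difference, u:    %.4f", cmpr$u$mad_norm),
        sprintf("normalized rms difference,     u:    %.4f", cmpr$u$rms_norm)),
        need("out"))
      log_line("validate-adf: report written to %s", need("out"))
    } else if (cmd == "benchmark") {
      sc <- need("scenario")
      pop <- preset_of(sc); if (is.null(pop)) return(invisible(2L))
      res <- benchmark_models(pop, n_runs = as.integer(num("runs", 20)),
                              train_s = num("train", 240),
                              test_s = num("test", 120), seed = seed)
      data.table::fwrite(res, need("out"), sep = "\t")
      log_line("benchmark: %d runs written to %s", max(res$run), need("out"))
    } else if (cmd == "fit-dendrite") {
      pn <- need("preset")
      if (!pn %in% c("NC", "HP", "cor2", "ind")) {
        message("preset must be one of NC, HP, cor2, ind")
        return(invisible(2L))
      }
      pf <- strsplit(need("protocols"), ",")[[1]]
      tf <- strsplit(need("traces"), ",")[[1]]
      if (length(pf) != length(tf)) stop("need one trace file per protocol")
      conds <- mapply(function(p, t) {
        ev <- read_spikes(p)
        tr <- read_trace(t)
        list(protocol = stimulus_protocol(
               data.frame(time_ms = ev$time_ms, site = ev$neuron_id),
               n_sites = max(ev$neuron_id) + 1L),
             trace = tr$value, sample_khz = 1 / tr$dt)
      }, pf, tf, SIMPLIFY = FALSE)
      fit <- fit_optimal_to_traces(conds, preset = pn, dt = num("dt", 0.5),
                                   N_grid = 1:40)
      jsonlite::write_json(unclass(fit), need("out"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
      log_line("fit-dendrite: eps_fitting = %.4g written to %s",
               fit$eps_fitting, need("out"))
    } else if (cmd == "make-fixtures") {
      make_fixtures(need("kind"), seed = seed, dir = need("out"))
      log_line("make-fixtures: %s written to %s", need("kind"), need("out"))
    }
    0L
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("missing required flag|unknown preset", msg)) 2L else 1L
  })
  invisible(as.integer(code))
}
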