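# File readers/writers, configuration resolution, and the command-line
# pipeline entry point.

#' Read a tag trace from CSV
#'
#' Required columns: `t`, `depth`, `pitch`, `speed`, `gyro_y`; a header row
#' is mandatory and lines starting with `#` are comments. Time is seconds
#' from deployment start. An irregular (but monotone) time grid is resampled
#' to `target_rate` by linear interpolation with a warning; non-monotone
#' time is an error.
#'
#' @param path CSV file path.
#' @param target_rate sampling rate to enforce (Hz), default 10.
#' @return A [tag_trace()].
#' @export
read_tag_trace <- function(path, target_rate = 10) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("t", "depth", "pitch", "speed", "gyro_y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("tag trace file missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(diff(df$t) <= 0)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  dt <- diff(df$t)
  regular <- max(dt) - min(dt) <= 1e-6
  on_rate <- abs(stats::median(dt) - 1 / target_rate) < 1e-9
  if (!regular || !on_rate) {
    warning(sprintf("irregular or off-rate sampling; resampling to %g Hz by linear interpolation",
                    target_rate))
    grid <- seq(df$t[1], df$t[nrow(df)], by = 1 / target_rate)
    df <- data.frame(
      t = grid,
      depth = stats::approx(df$t, df$depth, grid)$y,
      pitch = stats::approx(df$t, df$pitch, grid)$y,
      speed = stats::approx(df$t, df$speed, grid)$y,
      gyro_y = stats::approx(df$t, df$gyro_y, grid)$y
    )
  }
  tag_trace(df$t, df$depth, df$pitch, df$speed, df$gyro_y,
            sample_rate = target_rate)
}

#' Write a tag trace to CSV
#' @param trace a [tag_trace()].
#' @param path output path.
#' @export
write_tag_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tag kinematic trace: t (s), depth (m), pitch (rad), speed (m s-1), gyro_y (rad s-1)",
             con)
  utils::write.csv(trace[, c("t", "depth", "pitch", "speed", "gyro_y")],
                   con, row.names = FALSE)
}

#' Resolve a run configuration
#'
#' Bundles every tunable of the pipeline into one serialisable list, so any
#' output directory can carry the exact parameter set that produced it.
#'
#' @param seed master seed.
#' @param params an [energetic_params()].
#' @param thresholds a [detection_thresholds()].
#' @param allometry a [default_allometry()].
#' @param n_sample middle lunges per deployment.
#' @param vpos_end posterior-volume endpoint convention.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, params = energetic_params(),
                       thresholds = detection_thresholds(),
                       allometry = default_allometry(), n_sample = 30,
                       vpos_end = "half", out_dir = "lungeforge_out") {
  structure(list(seed = seed, params = params, thresholds = thresholds,
                 allometry = allometry, n_sample = n_sample,
                 vpos_end = vpos_end, out_dir = out_dir),
            class = "run_config")
}

write_config <- function(config, path) {
  jsonlite::write_json(
    rapply(unclass(config), function(x) x, how = "list"),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
}

#' Run the full analysis pipeline
#'
#' Either simulates a cohort (`simulate_species` given) or reads tag-trace
#' and morphometrics files, then detects lunges, computes engulfment and
#' energetics, fits the standard log-log regressions, and writes the output
#' bundle: `lunges.csv`, `energetics_by_individual.csv`,
#' `regressions.csv`, `config.json`, and a `MANIFEST` recording completion
#' state. Numeric outputs are bit-reproducible for a fixed configuration.
#'
#' @param config a [run_config()].
#' @param trace_files character vector of tag-trace CSVs (one deployment
#'   each); ignored when `simulate_species` is given.
#' @param morph_file morphometrics CSV covering the deployments, with
#'   `individual_id` matching the trace file base names.
#' @param simulate_species named integer vector of deployments to simulate
#'   per species, e.g. `c(blue = 3, minke = 3)`.
#' @param n_dives dives per simulated deployment.
#' @return Invisibly, the per-lunge table.
#' @export
run_pipeline <- function(config = run_config(), trace_files = NULL,
                         morph_file = NULL, simulate_species = NULL,
                         n_dives = 3) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(config$out_dir, "MANIFEST")
  writeLines(c("status: running"), manifest)
  write_config(config, file.path(config$out_dir, "config.json"))

  ok <- FALSE
  on.exit({
    if (!ok) writeLines("status: failed (partial outputs retained)", manifest)
  })

  deployments <- if (!is.null(simulate_species)) {
    simulate_cohort(simulate_species, n_dives = n_dives, seed = config$seed)
  } else {
    if (is.null(trace_files) || is.null(morph_file)) {
      stop("either simulate_species or trace_files + morph_file required",
           call. = FALSE)
    }
    morphs <- read_morphometrics(morph_file, config$allometry)
    lapply(trace_files, function(f) {
      id <- sub("\\.csv$", "", basename(f))
      m <- morphs[[id]]
      if (is.null(m)) {
        stop(sprintf("no morphometrics row for individual '%s'", id),
             call. = FALSE)
      }
      list(trace = read_tag_trace(f), morph = m)
    })
  }

  tab <- analyze_cohort(deployments, config$params, config$thresholds,
                        n_sample = config$n_sample, seed = config$seed)
  if (is.null(tab) || !nrow(tab)) {
    stop("no lunges detected in any deployment", call. = FALSE)
  }
  message(sprintf("analysed %d lunges from %d deployments",
                  nrow(tab), length(deployments)))
  utils::write.csv(tab, file.path(config$out_dir, "lunges.csv"),
                   row.names = FALSE)

  ind <- summarize_individuals(tab)
  # attach body length for the allometric fits
  Ls <- vapply(deployments, function(d) d$morph$L_body, numeric(1))
  names(Ls) <- vapply(deployments, function(d) d$morph$individual_id,
                      character(1))
  ind$L_body <- Ls[ind$individual_id]
  utils::write.csv(ind,
                   file.path(config$out_dir, "energetics_by_individual.csv"),
                   row.names = FALSE)

  reg <- try(regression_report(
    cbind(tab, L_body = Ls[tab$individual_id]),
    responses = c("E_cost", "E_gain", "FE", "V_total"),
    predictor = "L_body", group = "species"), silent = TRUE)
  if (!inherits(reg, "try-error") && !is.null(reg)) {
    utils::write.csv(reg, file.path(config$out_dir, "regressions.csv"),
                     row.names = FALSE)
  }

  writeLines(c("status: complete",
               sprintf("lunges: %d", nrow(tab)),
               sprintf("individuals: %d", nrow(ind))), manifest)
  ok <- TRUE
  invisible(tab)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic deployment's trace CSV,
#' morphometrics CSV, and ground-truth JSON), `detect` (lunge table from a
#' trace CSV), `engulf` / `energetics` (per-lunge engulfment and energetic
#' tables from a trace, a lunge table, and a morphometrics file), `scale`
#' (log-log regression report over a lunge table), `analyze` (full
#' pipeline), `stability` (sample-size stability table). Run via the
#' installed `lungeforge` script or
#' `Rscript -e 'lungeforge::lungeforge_cli()' <args>`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, the subcommand's main result.
#' @export
lungeforge_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lungeforge <simulate|detect|engulf|energetics|scale|analyze|stability> [options]",
    "  simulate   --species S --seed N --n-dives K --out DIR",
    "  detect     --trace FILE [--seed N] [--n-sample N] --out DIR",
    "  engulf     --trace FILE --lunges FILE --morph FILE [--id ID] --out DIR",
    "  energetics --trace FILE --lunges FILE --morph FILE [--id ID] --out DIR",
    "  scale      --lunges FILE [--predictor COL] [--responses A,B] --out DIR",
    "  analyze    --species S[,S...] --n-per-species K --seed N --out DIR",
    "  stability  --species S --seed N --out DIR", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- args[1]
  opt <- list(species = "blue", seed = 1L, `n-dives` = 3L, out = "lf_out",
              trace = NULL, `n-sample` = 30L, `n-per-species` = 2L)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key, call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(opt$seed)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

  if (cmd == "simulate") {
    dep <- simulate_deployment(species_profile(opt$species),
                               n_dives = as.integer(opt$`n-dives`),
                               seed = seed)
    write_tag_trace(dep$trace,
                    file.path(opt$out, paste0(dep$morph$individual_id, ".csv")))
    utils::write.csv(as.data.frame(dep$morph),
                     file.path(opt$out, "morphometrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(dep$truth, file.path(opt$out, "truth.json"),
                         digits = NA)
    message(sprintf("wrote deployment %s (%d lunges) to %s",
                    dep$morph$individual_id, nrow(dep$truth), opt$out))
    return(invisible(dep))
  }
  if (cmd == "detect") {
    trace <- read_tag_trace(opt$trace)
    ev <- detect_lunges(trace)
    if (!is.null(opt$`n-sample`) && nrow(ev)) {
      ev_s <- sample_middle_lunges(ev, as.integer(opt$`n-sample`), seed)
      utils::write.csv(ev_s, file.path(opt$out, "lunges_sampled.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(ev, file.path(opt$out, "lunges.csv"), row.names = FALSE)
    message(sprintf("detected %d lunges", nrow(ev)))
    return(invisible(ev))
  }
  if (cmd == "analyze") {
    species <- strsplit(opt$species, ",")[[1]]
    counts <- stats::setNames(rep(as.integer(opt$`n-per-species`),
                                  length(species)), species)
    cfg <- run_config(seed = seed, out_dir = opt$out)
    tab <- run_pipeline(cfg, simulate_species = counts,
                        n_dives = as.integer(opt$`n-dives`))
    return(invisible(tab))
  }
  if (cmd %in% c("engulf", "energetics")) {
    trace <- read_tag_trace(opt$trace)
    lunges <- utils::read.csv(opt$lunges %||% stop("--lunges required"))
    morphs <- read_morphometrics(opt$morph %||% stop("--morph required"))
    morph <- morphs[[opt$id %||% names(morphs)[1]]]
    rows <- lapply(seq_len(nrow(lunges)), function(i) {
      eng <- engulf_lunge(trace, lunges[i, ], morph)
      base <- data.frame(lunge_id = lunges$lunge_id[i] %||% i,
                         V_pos = eng$V_pos, V_ant = eng$V_ant,
                         V_total = eng$V_total, M_W = eng$M_W,
                         D_engulf = eng$D_engulf,
                         force_residual = eng$force_residual,
                         normalized_residual = eng$normalized_residual)
      if (cmd == "energetics") {
        cbind(base, lunge_energetics(lunges[i, ], eng, morph))
      } else base
    })
    out <- do.call(rbind, rows)
    utils::write.csv(out, file.path(opt$out, paste0(cmd, ".csv")),
                     row.names = FALSE)
    message(sprintf("wrote %s for %d lunges", cmd, nrow(out)))
    return(invisible(out))
  }
  if (cmd == "scale") {
    lunges <- utils::read.csv(opt$lunges %||% stop("--lunges required"))
    rep_tab <- regression_report(
      lunges, responses = strsplit(opt$responses %||% "E_cost,E_gain,FE",
                                   ",")[[1]],
      predictor = opt$predictor %||% "L_body",
      group = if ("species" %in% names(lunges)) "species" else NULL,
      by_individual = "individual_id" %in% names(lunges))
    utils::write.csv(rep_tab, file.path(opt$out, "regressions.csv"),
                     row.names = FALSE)
    return(invisible(rep_tab))
  }
  if (cmd == "stability") {
    dep <- simulate_deployment(species_profile(opt$species), n_dives = 6,
                               seed = seed)
    ev <- detect_lunges(dep$trace)
    tab <- sample_size_stability(ev, sizes = c(5, 10, 15, 20, 25),
                                 replicates = 50, seed = seed)
    utils::write.csv(tab, file.path(opt$out, "stability.csv"),
                     row.names = FALSE)
    return(invisible(tab))
  }
  stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
}
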