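# End-to-end analysis: lunge table -> engulfment -> energetics for one
# deployment, and cohort-level aggregation.

#' Analyse one deployment end to end
#'
#' Detects lunges (or accepts a precomputed lunge table), samples middle
#' lunges, and computes engulfment and energetics for each sampled lunge.
#'
#' @param trace a [tag_trace()].
#' @param morph a [complete_morphometrics()] record.
#' @param params an [energetic_params()].
#' @param thresholds a [detection_thresholds()].
#' @param n_sample middle lunges to sample per deployment (default 30).
#' @param seed seed for the middle-lunge sample.
#' @param lunges optional precomputed `lunge_table` (skips detection).
#' @param all_lunges analyse every detected lunge instead of the
#'   middle-lunge sample.
#' @return data.frame, one row per analysed lunge: lunge kinematics joined
#'   with engulfment volumes/forces and energetic terms, plus
#'   `individual_id` and `species`.
#' @export
analyze_deployment <- function(trace, morph, params = energetic_params(),
                               thresholds = detection_thresholds(),
                               n_sample = 30, seed = NULL, lunges = NULL,
                               all_lunges = FALSE) {
  ev <- lunges %||% detect_lunges(trace, thresholds)
  if (!nrow(ev)) return(cbind(empty_lunge_table()))
  picked <- if (all_lunges) ev else {
    mid <- ev[ev$position_in_dive == "middle", , drop = FALSE]
    if (nrow(mid)) sample_middle_lunges(ev, n_sample, seed) else ev
  }
  dives <- find_dives(trace)
  rows <- lapply(seq_len(nrow(picked)), function(i) {
    lg <- picked[i, , drop = FALSE]
    eng <- try(engulf_lunge(trace, lg, morph, rho = params$rho), silent = TRUE)
    if (inherits(eng, "try-error")) return(NULL)
    lg$ln_dive <- if (!is.na(lg$dive_id)) {
      sum(ev$dive_id == lg$dive_id, na.rm = TRUE)
    } else NA_integer_
    lg$dT_dive <- if (!is.na(lg$dive_id)) {
      d <- dives[dives$dive_id == lg$dive_id, ]
      d$t_end - d$t_start
    } else NA_real_
    en <- lunge_energetics(lg, eng, morph, params)
    cbind(lg,
          data.frame(V_pos = eng$V_pos, V_ant = eng$V_ant,
                     V_total = eng$V_total, M_W = eng$M_W,
                     D_engulf = eng$D_engulf,
                     force_residual = eng$force_residual,
                     normalized_residual = eng$normalized_residual),
          en)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(cbind(empty_lunge_table()))
  out <- do.call(rbind, rows)
  out$individual_id <- morph$individual_id
  out$species <- morph$species
  rownames(out) <- NULL
  out
}

#' Analyse a synthetic cohort
#'
#' Runs [analyze_deployment()] over a list of deployments (e.g. from
#' [simulate_cohort()]) and binds the per-lunge tables.
#'
#' @param deployments list of `synthetic_deployment` objects (or lists with
#'   `trace` and `morph`).
#' @param params,thresholds,n_sample,seed,all_lunges passed through; the
#'   per-deployment sampling seed is derived from `seed`.
#' @return Combined per-lunge data.frame.
#' @export
analyze_cohort <- function(deployments, params = energetic_params(),
                           thresholds = detection_thresholds(),
                           n_sample = 30, seed = 1, all_lunges = FALSE) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      length(deployments)))
  tabs <- lapply(seq_along(deployments), function(i) {
    d <- deployments[[i]]
    analyze_deployment(d$trace, d$morph, params, thresholds,
                       n_sample = n_sample, seed = seeds[i],
                       all_lunges = all_lunges)
  })
  tabs <- tabs[vapply(tabs, nrow, integer(1)) > 0]
  if (!length(tabs)) return(NULL)
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Per-individual summary of a cohort lunge table
#'
#' Mean and standard error of the main engulfment and energetic outputs per
#' individual, in the style of a species summary table.
#'
#' @param lunge_table output of [analyze_cohort()].
#' @param columns columns to summarise.
#' @return data.frame with one row per individual: each column's mean and
#'   `<col>_se`.
#' @export
summarize_individuals <- function(lunge_table,
                                  columns = c("U_MO", "U_MC", "dT_accel",
                                              "dT_decel", "V_total",
                                              "E_cost", "E_gain", "FE")) {
  sp <- split(lunge_table, lunge_table$individual_id)
  rows <- lapply(sp, function(d) {
    out <- data.frame(individual_id = d$individual_id[1],
                      species = d$species[1], n_lunges = nrow(d))
    for (cn in columns) {
      x <- d[[cn]]
      out[[cn]] <- mean(x, na.rm = TRUE)
      out[[paste0(cn, "_se")]] <- stats::sd(x, na.rm = TRUE) /
        sqrt(sum(is.finite(x)))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
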