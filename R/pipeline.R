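#' Default pipeline configuration
#'
#' Returns the full run configuration as a named list. The defaults are the
#' standard study conditions: 40-s DRCs of 1,600 25-ms chords on a 1-64 kHz
#' quarter-octave grid, 80 dB SPL mean level with 20/40 dB ranges for the
#' low/high-contrast conditions, 16-step (400 ms) STRF history with the
#' first second of stimulation excluded from fitting, a 0.04 predictive CC
#' screen, and the published laminar population composition for the
#' simulator. Any field can be overridden via `...`.
#'
#' @param ... Named overrides of default fields.
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = TRUE,
    f_min = 1000, f_max = 64000, spacing_oct = 0.25,
    mean_db = 80, range_low_db = 20, range_high_db = 40,
    n_chords = 1600, chord_s = 0.025, ramp_s = 0.005,
    history_steps = 16, exclude_initial_chords = 40,
    fit_fraction = 0.9, cc_threshold = 0.04,
    sigma_s_per_m = 0.3, disk_um = 250,
    layer_bounds_um = c(225, 425, 675),
    outlier_k_tuning = 1.96, outlier_k_gain = 3,
    anova_ss_type = "III",
    population = list(),   # overrides for population_spec()
    out_dir = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `run_config`; `write_config()` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  # YAML serialises named atomic vectors as plain sequences, dropping the
  # names; convert them to named lists so layer names survive the round trip
  namify <- function(x) {
    if (is.list(x)) {
      lapply(x, namify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(namify(unclass(config)), path)
  invisible(path)
}

#' Run the full contrast-gain-control pipeline
#'
#' Orchestrates every stage end-to-end: DRC stimulus generation for both
#' contrast conditions, synthetic population generation (known ground
#' truth), per-unit predictive screening, dual-condition STRF + sigmoid
#' fitting, tuning metrics, laminar assignment via inverse-CSD border
#' detection on simulated noise-burst LFPs, and the population statistics.
#' Fully deterministic given the configuration: rerunning with the same
#' config reproduces the outputs bit for bit.
#'
#' @param config A [default_config()] list.
#' @param progress Print per-stage progress to stderr.
#' @return A list: `table` (per-unit population table), `truth` (simulated
#'   ground truth), `border_um` (estimated L1-L2/3 border), `stats`
#'   (medians, signed-rank tests, laminar ANOVA, gain-threshold
#'   correlation), `report` (text lines), `config` and `manifest`. If
#'   `config$out_dir` is set, writes `units.csv`, `report.txt`,
#'   `manifest.json` and the config there.
#' @export
run_pipeline <- function(config = default_config(), progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!isTRUE(config$simulate)) {
    stop("only simulated runs are supported: set config$simulate = TRUE")
  }
  note <- function(...) if (progress) message(sprintf(...))
  seed <- config$seed

  note("stimgen: drawing DRC conditions")
  grid <- make_tone_grid(config$f_min, config$f_max, config$spacing_oct)
  stim_low <- draw_chord_levels(
    drc_level_spec(config$mean_db, config$range_low_db), config$n_chords,
    grid, seed = child_seed(seed, 11), chord_duration = config$chord_s,
    ramp_duration = config$ramp_s, condition_label = "low"
  )
  stim_high <- draw_chord_levels(
    drc_level_spec(config$mean_db, config$range_high_db), config$n_chords,
    grid, seed = child_seed(seed, 12), chord_duration = config$chord_s,
    ramp_duration = config$ramp_s, condition_label = "high"
  )

  note("synthetic: generating population")
  spec <- do.call(population_spec, c(config$population, list(seed = seed)))
  units <- generate_population(spec, grid = grid)
  truth <- attr(units, "truth")

  note("csd: laminar border from simulated noise-burst LFP")
  probe_depths <- seq(-75, by = 50, length.out = 32)
  fm <- build_forward_matrix(probe_depths, sigma = config$sigma_s_per_m,
                             disk_um = config$disk_um)
  true_csd <- laminar_csd_template(probe_depths, border_um = 0)
  lfp <- simulate_laminar_lfp(true_csd, fm,
                              noise_sd = 0.01 * max(abs(fm$P %*% true_csd)),
                              seed = child_seed(seed, 21))
  csd <- estimate_csd(lfp, fm)
  border <- find_reversal_depth(csd, window = 11:30, baseline = 1:10)

  note("strf/gainmodel: fitting %d units", length(units))
  rows_template <- NULL
  unit_rows <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    u$noise_sd <- calibrate_noise_sd(u, stim_low,
                                     target_cc = spec$target_cc)
    sim <- simulate_responses(u, stim_low, stim_high,
                              seed = child_seed(seed, 1000 + i))
    rows_l <- fit_rows_for(sim$X_low, config$exclude_initial_chords)
    rows_h <- fit_rows_for(sim$X_high, config$exclude_initial_chords)
    cv_l <- cross_validated_cc(sim$X_low, sim$y_low, rows = rows_l,
                               fit_fraction = config$fit_fraction,
                               cc_threshold = config$cc_threshold)
    cv_h <- cross_validated_cc(sim$X_high, sim$y_high, rows = rows_h,
                               fit_fraction = config$fit_fraction,
                               cc_threshold = config$cc_threshold)
    predictive <- cv_l$predictive && cv_h$predictive
    row <- data.frame(
      unit = i, depth_um = u$depth_um,
      layer = as.character(assign_layer(u$depth_um - border,
                                        config$layer_bounds_um)),
      penetration_id = as.character(u$penetration_id),
      cc_low = cv_l$cc_test, cc_high = cv_h$cc_test,
      predictive = predictive,
      true_gain_change_pct = u$gain_change_pct,
      stringsAsFactors = FALSE
    )
    if (predictive) {
      fit <- fit_dual_condition_model(sim$X_low, sim$y_low, sim$X_high,
                                      sim$y_high, rows_low = rows_l,
                                      rows_high = rows_h)
      ch <- summarize_changes(fit)
      tm_l <- tuning_metrics(cv_l$strf, grid)
      tm_h <- tuning_metrics(cv_h$strf, grid)
      row <- cbind(row, data.frame(
        gain_low = ch$gain_low, gain_high = ch$gain_high,
        gain_change_pct = ch$gain_change_pct,
        threshold_change_pct = ch$threshold_change_pct,
        baseline_change_pct = ch$baseline_change_pct,
        bf_low = tm_l$bf, bf_high = tm_h$bf,
        bw_low = tm_l$bandwidth, bw_high = tm_h$bandwidth,
        it_low = tm_l$integration_time, it_high = tm_h$integration_time,
        largest_coeff_low = tm_l$largest_coeff,
        largest_coeff_high = tm_h$largest_coeff
      ))
    } else {
      row <- cbind(row, data.frame(
        gain_low = NA_real_, gain_high = NA_real_,
        gain_change_pct = NA_real_, threshold_change_pct = NA_real_,
        baseline_change_pct = NA_real_,
        bf_low = NA_real_, bf_high = NA_real_,
        bw_low = NA_real_, bw_high = NA_real_,
        it_low = NA_real_, it_high = NA_real_,
        largest_coeff_low = NA_real_, largest_coeff_high = NA_real_
      ))
    }
    unit_rows[[i]] <- row
  }
  tab <- do.call(rbind, unit_rows)

  note("stats: population summaries")
  fit_tab <- tab[tab$predictive & !is.na(tab$gain_change_pct), ,
                 drop = FALSE]
  stats_out <- list(
    n_total = nrow(tab),
    n_predictive = nrow(fit_tab),
    median_gain_change_pct = stats::median(fit_tab$gain_change_pct),
    median_threshold_change_pct =
      stats::median(fit_tab$threshold_change_pct),
    median_baseline_change_pct = stats::median(fit_tab$baseline_change_pct)
  )
  if (nrow(fit_tab) >= 6) {
    stats_out$gain_signed_rank <-
      paired_signed_rank(fit_tab$gain_low, fit_tab$gain_high)
  }
  if (nlevels(droplevels(factor(fit_tab$layer))) >= 2 &&
      nrow(fit_tab) >= 8) {
    stats_out$laminar <- tryCatch(
      suppressWarnings(laminar_anova(fit_tab,
                                     outlier_k = config$outlier_k_gain,
                                     ss_type = config$anova_ss_type)),
      error = function(e) NULL
    )
    stats_out$gain_threshold <- tryCatch(
      gain_threshold_correlation(fit_tab,
                                 outlier_k = config$outlier_k_gain),
      error = function(e) NULL
    )
  }
  report <- if (nrow(fit_tab) >= 6) {
    population_report(fit_tab)
  } else {
    c(sprintf("Contrast gain control population report (n = %d units)",
              nrow(tab)),
      sprintf("Predictive units: %d - too few for population statistics",
              nrow(fit_tab)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("contrastgain")),
    r_version = as.character(getRversion()),
    config_hash = rlang::hash(unclass(config)),
    seed = seed,
    n_units = nrow(tab),
    n_predictive = nrow(fit_tab)
  )

  out <- list(
    table = tab, truth = truth, border_um = as.numeric(border),
    stats = stats_out, report = report, config = config,
    manifest = manifest
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(config$out_dir, "units.csv"),
                     row.names = FALSE)
    writeLines(report, file.path(config$out_dir, "report.txt"))
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_config(config, file.path(config$out_dir, "config.yaml"))
  }
  out
}

# Stereotyped evoked CSD for laminar simulation: a superficial source above
# the border and a sink below it, with a smooth early-response time course.
# Columns 1:10 are pre-stimulus baseline; the response peaks around column
# 20.
laminar_csd_template <- function(depths_um, border_um = 0, n_time = 40) {
  n_ch <- length(depths_um)
  spatial <- ifelse(
    depths_um < border_um,
    exp(-((depths_um - (border_um - 50)) / 60)^2),        # source above
    -exp(-((depths_um - (border_um + 150)) / 150)^2)      # sink below
  )
  tt <- seq_len(n_time)
  temporal <- ifelse(tt <= 10, 0, exp(-((tt - 20) / 6)^2))
  outer(spatial, temporal)
}
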