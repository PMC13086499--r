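#' Experiment drivers
#'
#' End-to-end synthetic reproductions of the canonical study designs:
#' point-source positioning, cylinder distal-edge localisation, dose
#' series, background series, and range-shift series. Every driver is
#' fully reproducible from its configuration and master seed, both of
#' which are embedded in the returned report.
#'
#' @name experiments
NULL

new_report <- function(name, rows, summary, truth = NULL,
                       config = NULL, seed = NULL, extra = list()) {
  structure(c(list(name = name, rows = rows, summary = summary,
                   truth = truth, config = config, seed = seed), extra),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s: %d rows\n", x$name, nrow(x$rows)))
  print(x$summary)
  invisible(x)
}

#' Summary statistics per group
#'
#' Mean, sample standard deviation (n-1; `NA` for single rows), min and
#' max of `value_col` per level of `by`. Deterministic.
#'
#' @param rows data.frame of per-replicate results.
#' @param value_col name of the value column.
#' @param by name(s) of grouping column(s); `NULL` summarises all rows.
#' @return data.frame with `n`, `mean`, `sd`, `min`, `max` per group.
#' @export
summarize_rows <- function(rows, value_col, by = NULL) {
  v <- rows[[value_col]]
  grp <- if (is.null(by)) rep("all", nrow(rows))
         else interaction(rows[by], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(v, grp), function(x) {
    c(n = length(x), mean = mean(x),
      sd = if (length(x) > 1) sd(x) else NA_real_,
      min = min(x), max = max(x))
  })
  out <- data.frame(group = names(agg), do.call(rbind, agg),
                    row.names = NULL)
  if (!is.null(by) && length(by) == 1) names(out)[1] <- by
  out
}

# shared simulate -> select -> reconstruct -> profile pipeline
acquire_profile <- function(geometry, phantom, activity, acq, rspec,
                            band_halfwidth_mm = 9, window = window_spec(),
                            dose_mu = NULL, events = NULL) {
  sel <- if (is.null(events)) {
    select_coincidences(
      simulate_listmode(geometry, phantom, activity, acq, dose_mu = dose_mu),
      window)
  } else events
  img <- reconstruct_events(sel, geometry, rspec)
  list(events = sel, image = img,
       profile = combine_band(img, band_halfwidth_mm))
}

#' Point-source positioning experiment
#'
#' Steps a point source along the x axis through the field of view,
#' reconstructs each acquisition (OSEM, default 5 subsets x 10
#' iterations on the closed ring), fits a Gaussian to the beam-axis
#' profile, and regresses measured against physical positions. With
#' `with_water = TRUE` the source sits in the filled water tank
#' (uncorrected attenuation), otherwise in air.
#'
#' @param positions_mm source x positions, mm.
#' @param with_water simulate inside the filled water tank.
#' @param n_emissions expected emitted coincidences per position.
#' @param seed master seed.
#' @param config configuration list (see [default_config()]).
#' @return an `experiment_report`; `summary` holds the linear fit
#'   (slope, intercept, r2) and the maximum absolute position error.
#' @export
run_point_positioning <- function(positions_mm = seq(-100, 100, by = 10),
                                  with_water = FALSE,
                                  n_emissions = 30000,
                                  seed = 1L, config = default_config()) {
  geometry <- config_geometry(config, mode = "closed_ring")
  phantom <- build_phantom("water_tank", list(filled = with_water),
                           config$phantom$grid_n,
                           config$phantom$grid_spacing_mm)
  rspec <- config_recon(config, n_subsets = 5L, n_iterations = 10L)
  rows <- lapply(seq_along(positions_mm), function(i) {
    x0 <- positions_mm[i]
    act <- build_activity(phantom, model_params = list(
      model = "point", x_mm = x0, y_mm = 0))
    acq <- config_acq(config, counts_per_mu = n_emissions,
                      background_rate_per_s = 0,
                      seed = substream_seed(seed, paste0("pos", i)))
    res <- acquire_profile(geometry, phantom, act, acq, rspec,
                           band_halfwidth_mm = 6, dose_mu = 1)
    fit <- fit_gaussian(res$profile)
    data.frame(position_mm = x0, measured_mm = fit$center,
               fwhm_mm = fit$fwhm, error_mm = fit$center - x0,
               n_selected = nrow(res$events))
  })
  rows <- do.call(rbind, rows)
  lfit <- linear_positioning_fit(rows$measured_mm, rows$position_mm)
  summary <- data.frame(slope = lfit$slope, intercept = lfit$intercept,
                        r2 = lfit$r2,
                        max_abs_error_mm = max(abs(rows$error_mm)))
  new_report("point_positioning", rows, summary,
             truth = list(positions_mm = positions_mm),
             config = config, seed = seed,
             extra = list(with_water = with_water))
}

#' Cylinder distal-edge experiment
#'
#' A uniform cylindrical activity with a flat distal end is stepped along
#' the beam axis in sub-millimetre increments; each acquisition is split
#' into `n_stat_subsets` equal-count subsets, each reconstructed (MLEM,
#' default 1 subset x 20 iterations) and edge-measured, giving a mean and
#' standard deviation of the distal 50% edge per position and a
#' measured-vs-physical step regression.
#'
#' @param n_steps number of positions.
#' @param step_mm step size between positions, mm.
#' @param with_water stand the cylinder inside the filled water tank.
#' @param n_emissions expected emitted coincidences per position.
#' @param n_stat_subsets equal-count subsets per position.
#' @param seed master seed.
#' @param config configuration list.
#' @return an `experiment_report`; `summary` holds per-position mean/sd
#'   and attributes the step regression (`slope`, `r2`).
#' @export
run_cylinder_edge <- function(n_steps = 7, step_mm = 0.5,
                              with_water = FALSE, n_emissions = 120000,
                              n_stat_subsets = 9, seed = 1L,
                              config = default_config()) {
  geometry <- config_geometry(config, mode = "closed_ring")
  rspec <- config_recon(config, n_subsets = 1L, n_iterations = 20L)
  base_x <- 20
  offsets <- (seq_len(n_steps) - 1) * step_mm
  rows <- list(); truth_edges <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    dx <- base_x + offsets[i]
    phantom <- build_phantom("cylinder_holder",
                             list(filled = with_water, distal_x_mm = dx),
                             config$phantom$grid_n,
                             config$phantom$grid_spacing_mm)
    act <- build_activity(phantom, model_params = list(
      model = "cylinder", distal_x_mm = dx))
    truth_edges[i] <- act$truth$true_distal50
    acq <- config_acq(config, counts_per_mu = n_emissions,
                      background_rate_per_s = 0,
                      seed = substream_seed(seed, paste0("step", i)))
    sel <- select_coincidences(
      simulate_listmode(geometry, phantom, act, acq, dose_mu = 1))
    subsets <- split_equal_count(sel, n_stat_subsets)
    for (s in seq_along(subsets)) {
      img <- reconstruct_events(subsets[[s]], geometry, rspec)
      prof <- combine_band(img, band_halfwidth_mm = 9)
      est <- measure_ar(prof,
                        smooth_sigma_mm = config$analysis$smooth_sigma_mm)
      rows[[length(rows) + 1L]] <- data.frame(
        step = i, physical_offset_mm = offsets[i], subset = s,
        distal_edge50_mm = est$distal_edge50, ar_mm = est$ar,
        n_events = nrow(subsets[[s]]))
    }
  }
  rows <- do.call(rbind, rows)
  per_pos <- summarize_rows(rows, "distal_edge50_mm", "step")
  lfit <- linear_positioning_fit(per_pos$mean, offsets)
  summary <- cbind(per_pos, physical_offset_mm = offsets,
                   true_edge_mm = truth_edges)
  new_report("cylinder_edge", rows, summary,
             truth = list(true_edges_mm = truth_edges,
                          offsets_mm = offsets),
             config = config, seed = seed,
             extra = list(step_fit = lfit, with_water = with_water))
}

#' Dose-series experiment
#'
#' Simulates one full high-dose acquisition (default 25 MU including
#' intrinsic background), derives lower dose-equivalent datasets by even
#' temporal sub-sampling (union of the first `d` of `full_dose_mu`
#' round-robin subsets emulates a `d` MU acquisition with proportionally
#' reduced background), reconstructs and measures the AR at every dose
#' level and seed.
#'
#' @param doses_mu dose-equivalent levels to measure, MU.
#' @param seeds master seeds (one full acquisition each).
#' @param phantom_spec `"lucite_in_water"` or `"head_analog"`.
#' @param full_dose_mu dose of the simulated full acquisition, MU.
#' @param config configuration list.
#' @return an `experiment_report`; rows hold per (seed, dose) AR and edge
#'   positions, `summary` the per-dose mean/sd of the AR.
#' @export
run_dose_series <- function(doses_mu = c(1, 5, 10, 25), seeds = 1:9,
                            phantom_spec = "lucite_in_water",
                            full_dose_mu = 25,
                            config = default_config()) {
  stopifnot(all(doses_mu <= full_dose_mu))
  setup <- beam_setup(phantom_spec, config, n_sheets = 1L,
                      dose_mu = full_dose_mu)
  rspec <- config_recon(config, n_subsets = 1L, n_iterations = 10L)
  rows <- list()
  for (sd_i in seeds) {
    acq <- config_acq(config, seed = sd_i)
    sel <- select_coincidences(
      simulate_listmode(setup$geometry, setup$phantom, setup$activity, acq))
    parts <- subsample_temporal(sel, as.integer(full_dose_mu))
    for (d in doses_mu) {
      ev <- do.call(rbind, lapply(parts[seq_len(d)], as.data.frame))
      ev <- as_event_list(ev)
      img <- reconstruct_events(ev, setup$geometry, rspec)
      prof <- combine_band(img, config$recon$band_halfwidth_mm)
      est <- measure_ar(prof, config$analysis$smooth_sigma_mm)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd_i, dose_mu = d, ar_mm = est$ar,
        distal_edge50_mm = est$distal_edge50,
        proximal_edge50_mm = est$proximal_edge50,
        n_events = nrow(ev))
    }
  }
  rows <- do.call(rbind, rows)
  summary <- summarize_rows(rows, "ar_mm", "dose_mu")
  summary$sd_distal <- summarize_rows(rows, "distal_edge50_mm",
                                      "dose_mu")$sd
  summary$dose_mu <- as.numeric(as.character(summary$dose_mu))
  summary <- summary[order(summary$dose_mu), ]
  new_report("dose_series", rows, summary,
             truth = setup$activity$truth, config = config,
             seed = seeds[1], extra = list(seeds = seeds))
}

#' Background-series experiment
#'
#' Measures how intrinsic-background contamination degrades the AR: the
#' reference AR comes from the full high-dose acquisition; the test AR
#' from one minimal-background dose-equivalent sub-dataset with
#' increasing durations of separately acquired blank-scan events
#' injected. Reports `|AR_test - AR_ref|` against injected seconds.
#'
#' @param inject_seconds blank durations to inject, s.
#' @param seeds master seeds.
#' @param phantom_spec phantom for the beam acquisition.
#' @param full_dose_mu full acquisition dose, MU.
#' @param config configuration list.
#' @return an `experiment_report`; `summary` holds the seed-averaged
#'   `|delta AR|` per injected duration and its Spearman correlation with
#'   duration.
#' @export
run_background_series <- function(inject_seconds = c(0, 5, 10, 20, 30, 45, 60),
                                  seeds = 1:5,
                                  phantom_spec = "head_analog",
                                  full_dose_mu = 25,
                                  config = default_config()) {
  setup <- beam_setup(phantom_spec, config, n_sheets = 1L,
                      dose_mu = full_dose_mu)
  rspec <- config_recon(config, n_subsets = 1L, n_iterations = 10L)
  rows <- list()
  for (sd_i in seeds) {
    acq <- config_acq(config, seed = sd_i)
    sel <- select_coincidences(
      simulate_listmode(setup$geometry, setup$phantom, setup$activity, acq))
    ref_img <- reconstruct_events(sel, setup$geometry, rspec)
    ref_ar <- measure_ar(combine_band(ref_img,
                                      config$recon$band_halfwidth_mm),
                         config$analysis$smooth_sigma_mm)
    base <- subsample_temporal(sel, as.integer(full_dose_mu))[[1]]
    blank_raw <- simulate_blank(
      setup$geometry, duration_s = max(inject_seconds) + 1,
      background_rate_per_s = config$acquisition$background_rate_per_s,
      seed = substream_seed(sd_i, "blank"))
    blank <- select_coincidences(blank_raw)
    for (bs in inject_seconds) {
      ev <- inject_background(base, blank, bs,
                              seed = substream_seed(sd_i, paste0("inj", bs)))
      img <- reconstruct_events(ev, setup$geometry, rspec)
      est <- measure_ar(combine_band(img, config$recon$band_halfwidth_mm),
                        config$analysis$smooth_sigma_mm)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd_i, inject_s = bs, ar_mm = est$ar,
        ref_ar_mm = ref_ar$ar, dar_mm = abs(est$ar - ref_ar$ar),
        n_events = nrow(ev))
    }
  }
  rows <- do.call(rbind, rows)
  summary <- summarize_rows(rows, "dar_mm", "inject_s")
  summary$inject_s <- as.numeric(as.character(summary$inject_s))
  summary <- summary[order(summary$inject_s), ]
  rho <- cor(summary$inject_s, summary$mean, method = "spearman")
  new_report("background_series", rows, summary,
             truth = setup$activity$truth, config = config,
             seed = seeds[1],
             extra = list(seeds = seeds, spearman_rho = rho))
}

#' Range-shift series experiment
#'
#' Simulates planned (1 sheet), overshot (0 sheets) and undershot
#' (2 sheets) beams at a given dose level, measures the distal-edge shift
#' of the overshot/undershot acquisitions against the planned one per
#' seed, and compares with the expected +/- `sheet_wet` shift.
#'
#' @param dose_mu dose-analog per acquisition, MU.
#' @param seeds master seeds (replicates).
#' @param phantom_spec phantom (`"head_analog"` by default).
#' @param config configuration list.
#' @return an `experiment_report`; rows hold the per-seed measured
#'   shifts, `summary` the mean/sd of measured shift and of the absolute
#'   shift error per direction.
#' @export
run_shift_series <- function(dose_mu = 5, seeds = 1:9,
                             phantom_spec = "head_analog",
                             config = default_config()) {
  rspec <- config_recon(config, n_subsets = 1L, n_iterations = 10L)
  sheet <- config$beam$sheet_wet_mm
  rows <- list()
  for (sd_i in seeds) {
    est <- list()
    for (ns in c(1L, 0L, 2L)) {
      setup <- beam_setup(phantom_spec, config, n_sheets = ns,
                          dose_mu = dose_mu)
      acq <- config_acq(config, seed = substream_seed(sd_i, paste0("ns", ns)))
      res <- acquire_profile(setup$geometry, setup$phantom,
                             setup$activity, acq, rspec,
                             config$recon$band_halfwidth_mm)
      est[[as.character(ns)]] <- list(
        ar = measure_ar(res$profile, config$analysis$smooth_sigma_mm),
        truth = setup$activity$truth, n = nrow(res$events))
    }
    for (dir in c("overshot", "undershot")) {
      ns <- if (dir == "overshot") "0" else "2"
      expected <- if (dir == "overshot") sheet else -sheet
      meas <- measure_shift(est[[ns]]$ar, est[["1"]]$ar,
                            config$analysis$shift_convention)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd_i, direction = dir, measured_shift_mm = meas,
        expected_shift_mm = expected,
        error_mm = meas - expected,
        n_events = est[[ns]]$n)
    }
  }
  rows <- do.call(rbind, rows)
  summary <- summarize_rows(rows, "measured_shift_mm", "direction")
  err <- summarize_rows(rows, "error_mm", "direction")
  summary$mean_abs_error_mm <- vapply(
    split(abs(rows$error_mm), rows$direction), mean, 0)[summary$direction]
  summary$sd_error_mm <- err$sd
  new_report("shift_series", rows, summary,
             truth = list(expected_shift_mm = c(overshot = sheet,
                                                undershot = -sheet)),
             config = config, seed = seeds[1],
             extra = list(seeds = seeds, dose_mu = dose_mu))
}

# --- configuration adapters -------------------------------------------

config_geometry <- function(config, mode = NULL) {
  g <- config$geometry
  build_geometry(mode %||% g$mode, g$ring_inner_diameter_mm,
                 g$crystal_pitch_mm, g$n_detectors_closed,
                 g$crystals_per_detector_row, g$axial_extent_mm)
}

config_recon <- function(config, n_subsets = NULL, n_iterations = NULL) {
  r <- config$recon
  recon_spec(r$grid_n, r$pixel_size_mm,
             n_subsets %||% r$n_subsets,
             n_iterations %||% r$n_iterations, r$nonneg_floor)
}

config_acq <- function(config, ...) {
  a <- config$acquisition
  over <- list(...)
  args <- modifyList(list(
    duration_s = a$duration_s, counts_per_mu = a$counts_per_mu,
    energy_fwhm_frac = a$energy_fwhm_frac, time_fwhm_ns = a$time_fwhm_ns,
    background_rate_per_s = a$background_rate_per_s,
    scatter_fraction = a$scatter_fraction,
    positron_blur_sigma_mm = a$positron_blur_sigma_mm,
    seed = a$seed), over)
  do.call(acquisition_spec, args)
}

# open-ring beam setup on a given phantom spec
beam_setup <- function(phantom_spec, config, n_sheets = 1L, dose_mu = 25) {
  geometry <- config_geometry(config, mode = "open_ring")
  phantom <- build_phantom(phantom_spec, list(),
                           config$phantom$grid_n,
                           config$phantom$grid_spacing_mm)
  entrance <- switch(phantom_spec,
                     head_analog = -80,
                     lucite_in_water = config$beam$entrance_position_mm,
                     config$beam$entrance_position_mm)
  beam <- beam_spec(config$beam$energy_mev, dose_mu, entrance,
                    n_sheets, config$beam$sheet_wet_mm,
                    config$beam$beam_sigma_mm)
  activity <- build_activity(phantom, beam)
  list(geometry = geometry, phantom = phantom, beam = beam,
       activity = activity)
}
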