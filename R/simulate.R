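#' Acquisition specification
#'
#' Parameters of a simulated list-mode acquisition: duration, expected
#' emitted true coincidences per MU, detector energy/timing resolutions,
#' intrinsic background rate, optional scatter fraction, and the master
#' seed from which all named random substreams (emission, attenuation,
#' energy, timing, background) are derived.
#'
#' @param duration_s acquisition duration, s.
#' @param counts_per_mu expected emitted true coincidences per MU.
#' @param energy_fwhm_frac energy resolution as FWHM fraction of 511 keV.
#' @param time_fwhm_ns coincidence timing resolution FWHM, ns.
#' @param background_rate_per_s intrinsic random-coincidence rate, 1/s.
#' @param scatter_fraction fraction of trues re-emitted as scatter
#'   (0 disables the scatter model).
#' @param positron_blur_sigma_mm optional isotropic Gaussian blur on
#'   emission positions (positron range / acollinearity stand-in).
#' @param seed master seed (integer).
#' @return an `acquisition_spec` list.
#' @export
acquisition_spec <- function(duration_s = 60, counts_per_mu = NULL,
                             energy_fwhm_frac = 0.272, time_fwhm_ns = 9.2,
                             background_rate_per_s = 0,
                             scatter_fraction = 0,
                             positron_blur_sigma_mm = 0,
                             seed = 1L) {
  cfg <- default_config()$acquisition
  stopifnot(duration_s >= 0, background_rate_per_s >= 0,
            scatter_fraction >= 0, scatter_fraction < 1)
  structure(list(
    duration_s = duration_s,
    counts_per_mu = counts_per_mu %||% cfg$counts_per_mu,
    energy_fwhm_frac = energy_fwhm_frac,
    time_fwhm_ns = time_fwhm_ns,
    background_rate_per_s = background_rate_per_s,
    background_energy_kev = cfg$background_energy_kev,
    background_dt_halfwidth_ns = cfg$background_dt_halfwidth_ns,
    scatter_fraction = scatter_fraction,
    scatter_angle_sd_deg = cfg$scatter_angle_sd_deg,
    scatter_energy_kev = cfg$scatter_energy_kev,
    positron_blur_sigma_mm = positron_blur_sigma_mm,
    seed = as.integer(seed)
  ), class = "acquisition_spec")
}

event_columns <- c("event_id", "crystal_a", "crystal_b", "energy_a_kev",
                   "energy_b_kev", "t_a_ns", "t_b_ns", "truth_class")

# construct an event_list data.frame; sorts by (t_a_ns, then original
# order) and renumbers event_id, giving the canonical deterministic order
as_event_list <- function(df, resort = TRUE) {
  if (nrow(df) && resort) df <- df[order(df$t_a_ns), , drop = FALSE]
  df$event_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- df[, event_columns]
  class(df) <- c("event_list", "data.frame")
  df
}

empty_event_list <- function() {
  as_event_list(data.frame(
    event_id = integer(0), crystal_a = integer(0), crystal_b = integer(0),
    energy_a_kev = numeric(0), energy_b_kev = numeric(0),
    t_a_ns = numeric(0), t_b_ns = numeric(0),
    truth_class = character(0)))
}

#' @export
print.event_list <- function(x, ...) {
  cls <- table(x$truth_class)
  cat(sprintf("<event_list> %d events (%s)\n", nrow(x),
              if (nrow(x)) paste(names(cls), cls, sep = "=",
                                 collapse = ", ") else "empty"))
  invisible(x)
}

# exit-point angles on the ring circle for emission points P and in-plane
# direction angles phi (both photons: +u and -u)
ring_exit_angles <- function(px, py, phi, R) {
  ux <- cos(phi); uy <- sin(phi)
  pu <- px * ux + py * uy
  disc <- sqrt(pmax(pu^2 + R^2 - (px^2 + py^2), 0))
  t1 <- -pu + disc
  t2 <- pu + disc
  list(a = atan2(py + t1 * uy, px + t1 * ux),
       b = atan2(py - t2 * uy, px - t2 * ux))
}

#' Simulate a list-mode coincidence acquisition
#'
#' Draws `Poisson(dose_mu * counts_per_mu)` true annihilations from the
#' activity map (or its continuous point sources), assigns each an
#' isotropic in-plane line of response, keeps events whose two photons
#' both strike active crystals, thins the survivors by the chord
#' attenuation factor `exp(-integral of mu)`, smears photon energies
#' (Gaussian around 511 keV) and the coincidence time difference, and
#' appends intrinsic-background random coincidences on uniformly drawn
#' active crystal pairs. Every event carries a truth class
#' (`true`, `scatter`, `random`). Fully reproducible from `acq$seed`.
#'
#' @param geometry a [build_geometry()] object.
#' @param phantom a [build_phantom()] object (attenuation medium).
#' @param activity a [build_activity()] object.
#' @param acq an [acquisition_spec()].
#' @param dose_mu dose in MU; defaults to the activity's beam dose (or 1
#'   for beam-less models).
#' @return an `event_list` data.frame with columns `event_id`,
#'   `crystal_a`, `crystal_b`, `energy_a_kev`, `energy_b_kev`, `t_a_ns`,
#'   `t_b_ns`, `truth_class`, sorted by `t_a_ns`.
#' @export
simulate_listmode <- function(geometry, phantom, activity, acq,
                              dose_mu = NULL) {
  stopifnot(inherits(geometry, "detector_geometry"),
            inherits(activity, "activity_map"))
  if (activity$grid_n != phantom$grid_n ||
      activity$grid_spacing_mm != phantom$grid_spacing_mm)
    stop("phantom and activity grids do not match")
  dose <- dose_mu %||% (activity$beam$dose_mu %||% 1)
  has_source <- sum(activity$activity) > 0 ||
    NROW(activity$point_sources) > 0
  if (!has_source && dose > 0)
    stop("zero total activity with nonzero dose")

  n_emit <- if (dose > 0 && has_source) {
    with_seed(substream_seed(acq$seed, "counts"),
              rpois(1, dose * acq$counts_per_mu))
  } else 0L

  trues <- if (n_emit > 0) {
    sim_true_events(geometry, phantom, activity, acq, n_emit)
  } else empty_event_list()

  n_bg <- if (acq$background_rate_per_s > 0 && acq$duration_s > 0) {
    with_seed(substream_seed(acq$seed, "background_counts"),
              rpois(1, acq$background_rate_per_s * acq$duration_s))
  } else 0L
  bg <- if (n_bg > 0) {
    sim_random_events(geometry, n_bg, acq$duration_s, acq,
                      substream_seed(acq$seed, "background"))
  } else empty_event_list()

  as_event_list(rbind(as.data.frame(trues), as.data.frame(bg)))
}

sim_true_events <- function(geometry, phantom, activity, acq, n_emit) {
  R <- geometry$ring_radius_mm
  sp <- activity$grid_spacing_mm
  n <- activity$grid_n

  em <- with_seed(substream_seed(acq$seed, "emission"), {
    if (NROW(activity$point_sources) > 0) {
      ps <- activity$point_sources
      idx <- if (nrow(ps) > 1) sample_weighted(n_emit, ps$weight)
             else rep(1L, n_emit)
      px <- rnorm(n_emit, ps$x_mm[idx], ps$sigma_mm[idx])
      py <- rnorm(n_emit, ps$y_mm[idx], ps$sigma_mm[idx])
    } else {
      vox <- sample_weighted(n_emit, activity$activity)
      ix <- (vox - 1L) %% n
      iy <- (vox - 1L) %/% n
      px <- activity$xmin_mm + (ix + runif(n_emit)) * sp
      py <- activity$ymin_mm + (iy + runif(n_emit)) * sp
    }
    if (acq$positron_blur_sigma_mm > 0) {
      px <- px + rnorm(n_emit, 0, acq$positron_blur_sigma_mm)
      py <- py + rnorm(n_emit, 0, acq$positron_blur_sigma_mm)
    }
    phi <- runif(n_emit, 0, pi)
    list(px = px, py = py, phi = phi)
  })

  ex <- ring_exit_angles(em$px, em$py, em$phi, R)
  ca <- crystal_at_angle(geometry, ex$a)
  cb <- crystal_at_angle(geometry, ex$b)
  hit <- !is.na(ca) & !is.na(cb) & ca != cb

  # attenuation survival along the emission chord (exact exit points)
  ux <- cos(em$phi); uy <- sin(em$phi)
  pu <- em$px * ux + em$py * uy
  disc <- sqrt(pmax(pu^2 + R^2 - (em$px^2 + em$py^2), 0))
  x0 <- em$px + (-pu + disc) * ux; y0 <- em$py + (-pu + disc) * uy
  x1 <- em$px - (pu + disc) * ux;  y1 <- em$py - (pu + disc) * uy
  mu_int <- rep(0, n_emit)
  if (any(phantom$mu > 0) && any(hit)) {
    mu_int[hit] <- .siddon_forward(
      as.numeric(phantom$mu), phantom$grid_n, phantom$grid_n,
      phantom$grid_spacing_mm, phantom$xmin_mm, phantom$ymin_mm,
      x0[hit], y0[hit], x1[hit], y1[hit])
  }
  surv <- with_seed(substream_seed(acq$seed, "attenuation"),
                    runif(n_emit)) < exp(-mu_int)
  keep <- which(hit & surv)
  n_keep <- length(keep)
  if (!n_keep) return(empty_event_list())

  ca <- ca[keep]; cb <- cb[keep]
  truth <- rep("true", n_keep)

  # optional Compton-scatter model: the second photon is deflected and
  # loses energy; events whose deflected photon misses a crystal are lost
  sc_energy_b <- rep(NA_real_, n_keep)
  if (acq$scatter_fraction > 0) {
    sc <- with_seed(substream_seed(acq$seed, "scatter"), {
      is_sc <- runif(n_keep) < acq$scatter_fraction
      defl <- rnorm(n_keep, 0, acq$scatter_angle_sd_deg * pi / 180)
      # triangular on [lo, hi] with mode hi: hi - (hi-lo)*(1-sqrt(u))
      lo <- acq$scatter_energy_kev[1]; hi <- acq$scatter_energy_kev[2]
      en <- hi - (hi - lo) * (1 - sqrt(runif(n_keep)))
      list(is_sc = is_sc, defl = defl, en = en)
    })
    if (any(sc$is_sc)) {
      i <- which(sc$is_sc)
      phi2 <- em$phi[keep][i] + pi + sc$defl[i]
      ex2 <- ring_exit_angles(em$px[keep][i], em$py[keep][i], phi2 - pi, R)
      # photon 2 travels along -u of (phi2 - pi), i.e. direction phi2
      cb2 <- crystal_at_angle(geometry, ex2$b)
      ok <- !is.na(cb2) & cb2 != ca[i]
      drop <- i[!ok]
      cb[i[ok]] <- cb2[ok]
      truth[i[ok]] <- "scatter"
      sc_energy_b[i[ok]] <- sc$en[i[ok]]
      if (length(drop)) {
        sel <- setdiff(seq_len(n_keep), drop)
        ca <- ca[sel]; cb <- cb[sel]; truth <- truth[sel]
        sc_energy_b <- sc_energy_b[sel]
        n_keep <- length(sel)
      }
    }
  }

  sigma_e <- acq$energy_fwhm_frac * 511 / (2 * sqrt(2 * log(2)))
  en <- with_seed(substream_seed(acq$seed, "energy"), {
    list(a = rnorm(n_keep, 511, sigma_e), b = rnorm(n_keep, 511, sigma_e))
  })
  eb <- ifelse(is.na(sc_energy_b), en$b, sc_energy_b)

  sigma_t <- acq$time_fwhm_ns / (2 * sqrt(2 * log(2)))
  tm <- with_seed(substream_seed(acq$seed, "timing"), {
    ta <- runif(n_keep, 0, acq$duration_s * 1e9)
    list(ta = ta, tb = ta + rnorm(n_keep, 0, sigma_t))
  })

  as_event_list(data.frame(
    event_id = seq_len(n_keep),
    crystal_a = ca, crystal_b = cb,
    energy_a_kev = en$a, energy_b_kev = eb,
    t_a_ns = tm$ta, t_b_ns = tm$tb,
    truth_class = truth))
}

# uniform random coincidences over existing (active) crystal pairs with
# the configured background spectrum and a uniform pairing-time spread
sim_random_events <- function(geometry, n_bg, duration_s, acq, seed) {
  ids <- geometry$crystals$id[geometry$crystals$active]
  with_seed(seed, {
    a <- ids[sample.int(length(ids), n_bg, replace = TRUE)]
    b <- ids[sample.int(length(ids), n_bg, replace = TRUE)]
    same <- a == b
    while (any(same)) {  # resample collisions to keep pairs distinct
      b[same] <- ids[sample.int(length(ids), sum(same), replace = TRUE)]
      same <- a == b
    }
    lo <- acq$background_energy_kev[1]; hi <- acq$background_energy_kev[2]
    ta <- runif(n_bg, 0, duration_s * 1e9)
    hw <- acq$background_dt_halfwidth_ns
    as_event_list(data.frame(
      event_id = seq_len(n_bg),
      crystal_a = a, crystal_b = b,
      energy_a_kev = runif(n_bg, lo, hi),
      energy_b_kev = runif(n_bg, lo, hi),
      t_a_ns = ta, t_b_ns = ta + runif(n_bg, -hw, hw),
      truth_class = rep("random", n_bg)))
  })
}

#' Simulate a blank scan
#'
#' A randoms-only acquisition with no source in the field of view: the
#' intrinsic-scintillator background captured by a blank scan. All events
#' carry truth class `random`.
#'
#' @param geometry a [build_geometry()] object.
#' @param duration_s blank scan duration, s (> 0).
#' @param background_rate_per_s random-coincidence rate, 1/s.
#' @param seed integer seed.
#' @param acq optional [acquisition_spec()] supplying the background
#'   spectrum and pairing window.
#' @return an `event_list` with only `random` events.
#' @export
simulate_blank <- function(geometry, duration_s = 60,
                           background_rate_per_s = 2000, seed = 1L,
                           acq = acquisition_spec(seed = seed)) {
  stopifnot(duration_s >= 0)
  n_bg <- if (duration_s > 0 && background_rate_per_s > 0) {
    with_seed(substream_seed(seed, "blank_counts"),
              rpois(1, duration_s * background_rate_per_s))
  } else 0L
  if (!n_bg) return(empty_event_list())
  sim_random_events(geometry, n_bg, duration_s, acq,
                    substream_seed(seed, "blank"))
}
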