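#' Gaussian-smooth a profile
#'
#' Discrete Gaussian-kernel convolution with reflective boundaries;
#' `sigma_mm = 0` is the identity.
#'
#' @param p a `pet_profile` (uniformly spaced `position_mm`, `intensity`).
#' @param sigma_mm kernel standard deviation, mm.
#' @return smoothed `pet_profile`.
#' @export
smooth_profile <- function(p, sigma_mm = 2.0) {
  stopifnot(sigma_mm >= 0)
  if (sigma_mm == 0 || nrow(p) < 3) return(p)
  dx <- profile_spacing(p)
  half <- max(1L, ceiling(4 * sigma_mm / dx))
  k <- dnorm((-half:half) * dx, sd = sigma_mm)
  k <- k / sum(k)
  n <- nrow(p)
  # reflective padding
  pad <- c(p$intensity[pmin(half + 1L, n):2],
           p$intensity,
           p$intensity[(n - 1L):max(n - half, 1L)])
  # guard short profiles where reflection cannot supply `half` samples
  while (length(pad) < n + 2L * half)
    pad <- c(pad[1], pad, pad[length(pad)])
  sm <- as.numeric(stats::filter(pad, k, sides = 2))
  new_profile(p$position_mm, sm[(half + 1L):(half + n)])
}

profile_spacing <- function(p) {
  d <- diff(p$position_mm)
  if (any(d <= 0)) stop("profile positions must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("profile positions must be uniformly spaced")
  mean(d)
}

# cubic-spline refinement onto a fine uniform grid; supplies the
# sub-sample precision of all position estimates
refine_profile <- function(p, spacing_mm = 0.1) {
  dx <- profile_spacing(p)
  if (dx <= spacing_mm) return(p)
  xs <- seq(p$position_mm[1], p$position_mm[nrow(p)], by = spacing_mm)
  new_profile(xs, spline(p$position_mm, p$intensity, xout = xs)$y)
}

#' Locate the distal (or proximal) peak by maximum curvature
#'
#' The "distal peak" is the plateau-to-falloff turnover of the profile:
#' the concave-down curvature extremum of the (max-normalised) profile at
#' the start of the final descent. The search runs over positions beyond
#' the global maximum (before it, mirrored, for `side = "proximal"`);
#' candidate turnovers are local maxima of `-f''` where the profile is
#' concave down, at a level of at least `min_level` of the global maximum
#' and with curvature at least `prominence` of the strongest candidate
#' (this rejects low-level tail wiggles and keeps profiles with an
#' attenuation-uncorrected entrance hot spot from being mistaken for the
#' falloff). Among qualified candidates the most distal (distal side) /
#' most proximal (proximal side) one is returned.
#'
#' @param p a smoothed `pet_profile`.
#' @param side `"distal"` or `"proximal"`.
#' @param min_level minimum profile level of a candidate turnover, as a
#'   fraction of the global maximum.
#' @param prominence minimum curvature of a candidate, as a fraction of
#'   the strongest candidate's curvature.
#' @return peak position, mm.
#' @export
find_distal_peak <- function(p, side = c("distal", "proximal"),
                             min_level = 0.25, prominence = 0.3) {
  side <- match.arg(side)
  n <- nrow(p)
  if (n < 3) stop("profile too short")
  f <- p$intensity / max(p$intensity)
  curv <- c(NA, -diff(f, differences = 2), NA)  # > 0 where concave down
  imax <- which.max(f)
  in_region <- if (side == "distal") seq(imax, n) else seq(1L, imax)
  cv <- ifelse(is.na(curv), -Inf, curv)
  # curvature below numerical noise on the normalised profile does not
  # qualify as a turnover (a straight profile has none)
  cv_tol <- 1e-9
  # local maxima of the concave-down curvature (boundaries qualify)
  is_locmax <- c(TRUE, cv[2:(n - 1)] >= cv[1:(n - 2)] &
                   cv[2:(n - 1)] >= cv[3:n], TRUE)
  cand <- intersect(which(is_locmax & cv > cv_tol & f >= min_level),
                    in_region)
  if (length(cand)) {
    cand <- cand[cv[cand] >= prominence * max(cv[cand])]
    i <- if (side == "distal") max(cand) else min(cand)
  } else {
    # under-resolved turnover (no interior curvature peak at a qualified
    # level): fall back to the plain maximum-curvature sample
    ok <- intersect(which(cv > cv_tol & is.finite(cv) & f >= min_level),
                    in_region)
    if (!length(ok))
      stop("no ", side, " peak: profile has no concave-down turnover")
    i <- ok[which.max(cv[ok])]
  }
  p$position_mm[i]
}

#' 50%-of-peak edge position
#'
#' Reference level = half the profile intensity at `peak_pos`. Scans
#' outward from the peak (increasing x for the distal side, decreasing
#' for the proximal side) and returns the first crossing of the
#' reference level, linearly interpolated between bracketing samples.
#'
#' @param p a `pet_profile`.
#' @param peak_pos peak position, mm (within the profile).
#' @param side `"distal"` or `"proximal"`.
#' @return edge position, mm.
#' @export
find_edge50 <- function(p, peak_pos, side = c("distal", "proximal")) {
  side <- match.arg(side)
  x <- p$position_mm; f <- p$intensity
  if (peak_pos < x[1] || peak_pos > x[length(x)])
    stop("peak position outside profile")
  level <- approx(x, f, xout = peak_pos)$y / 2
  i0 <- which.min(abs(x - peak_pos))
  idx <- if (side == "distal") seq(i0, length(x)) else seq(i0, 1L)
  fi <- f[idx]
  below <- which(fi < level)
  if (!length(below)) stop("edge outside profile: 50% level never crossed")
  j <- below[1]
  if (j == 1) return(x[idx[1]])
  # linear interpolation between the bracketing samples
  xa <- x[idx[j - 1]]; xb <- x[idx[j]]
  fa <- fi[j - 1]; fb <- fi[j]
  xa + (level - fa) / (fb - fa) * (xb - xa)
}

#' Measure the activity range of a profile
#'
#' The AR statistic: Gaussian smoothing, cubic-spline refinement to a
#' fine grid, maximum-curvature peak localisation on both sides, 50%
#' edge interpolation, and `ar = distal_edge50 - proximal_edge50`.
#' Invariant under intensity scaling and equivariant under translation.
#'
#' @param p a `pet_profile`.
#' @param smooth_sigma_mm Gaussian smoothing sigma, mm (0 disables).
#' @param refine_spacing_mm spline-refined sampling, mm.
#' @param measure_proximal set `FALSE` to skip the proximal side (e.g.
#'   pure falloff templates); proximal fields are then `NA`.
#' @return an `ar_estimate`: list with `distal_peak_pos`,
#'   `proximal_peak_pos`, `distal_edge50`, `proximal_edge50`, `ar` (mm)
#'   and the analysis metadata.
#' @export
measure_ar <- function(p, smooth_sigma_mm = 2.0, refine_spacing_mm = 0.1,
                       measure_proximal = TRUE) {
  stopifnot(nrow(p) >= 3)
  ps <- smooth_profile(p, smooth_sigma_mm)
  pr <- refine_profile(ps, refine_spacing_mm)
  dpk <- find_distal_peak(pr, "distal")
  de <- find_edge50(pr, dpk, "distal")
  if (measure_proximal) {
    ppk <- find_distal_peak(pr, "proximal")
    pe <- find_edge50(pr, ppk, "proximal")
  } else ppk <- pe <- NA_real_
  structure(list(
    distal_peak_pos = dpk, proximal_peak_pos = ppk,
    distal_edge50 = de, proximal_edge50 = pe,
    ar = de - pe,
    smooth_sigma_mm = smooth_sigma_mm,
    refine_spacing_mm = refine_spacing_mm
  ), class = "ar_estimate")
}

#' @export
print.ar_estimate <- function(x, ...) {
  cat(sprintf(
    "<ar_estimate> distal50 = %.2f mm, proximal50 = %.2f mm, AR = %.2f mm\n",
    x$distal_edge50, x$proximal_edge50, x$ar))
  invisible(x)
}

#' Range shift between two AR estimates
#'
#' Difference between a test and a reference measurement. The default
#' convention compares distal-edge positions (the proximal edge is pinned
#' by the beam entrance); `convention = "ar"` compares AR values instead.
#'
#' @param ar_test,ar_ref `ar_estimate` objects.
#' @param convention `"distal_edge"` or `"ar"`.
#' @return shift, mm (positive = test edge beyond reference: overshoot).
#' @export
measure_shift <- function(ar_test, ar_ref,
                          convention = c("distal_edge", "ar")) {
  convention <- match.arg(convention)
  if (convention == "distal_edge")
    ar_test$distal_edge50 - ar_ref$distal_edge50
  else ar_test$ar - ar_ref$ar
}

#' Fit a Gaussian with constant baseline to a profile
#'
#' Least-squares fit of `A * exp(-(x - c)^2 / (2 s^2)) + b`; used for
#' point-source position and spatial-resolution (FWHM) measurements.
#'
#' @param p a single-peaked `pet_profile`.
#' @param window_sigmas half-width of the fitting window around the
#'   initial peak estimate, in units of the initial width estimate.
#' @return a `gauss_fit`: list with `center` (mm), `fwhm` (mm),
#'   `amplitude`, `baseline`, `sigma`.
#' @export
fit_gaussian <- function(p, window_sigmas = 8) {
  x <- p$position_mm; f <- p$intensity
  b0 <- min(f)
  a0 <- max(f) - b0
  c0 <- x[which.max(f)]
  above <- x[f - b0 > a0 / 2]
  s0 <- max((max(above) - min(above)) / 2.3548, profile_spacing(p) / 2)
  # restrict to a window around the peak: far-field flat baseline carries
  # no information and can make the gradient singular
  win <- abs(x - c0) <= window_sigmas * s0
  if (sum(win) >= 6) { x <- x[win]; f <- f[win] }
  fit <- tryCatch(
    nls(f ~ A * exp(-(x - cc)^2 / (2 * ss^2)) + b,
        start = list(A = a0, cc = c0, ss = s0, b = b0),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) {
      if (requireNamespace("minpack.lm", quietly = TRUE)) {
        minpack.lm::nlsLM(f ~ A * exp(-(x - cc)^2 / (2 * ss^2)) + b,
                          start = list(A = a0, cc = c0, ss = s0, b = b0),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500))
      } else {
        stop("Gaussian fit failed to converge: ", conditionMessage(e),
             " (start: A=", signif(a0, 4), " c=", signif(c0, 4),
             " s=", signif(s0, 4), ")")
      }
    })
  co <- coef(fit)
  structure(list(center = unname(co["cc"]),
                 sigma = abs(unname(co["ss"])),
                 fwhm = 2 * sqrt(2 * log(2)) * abs(unname(co["ss"])),
                 amplitude = unname(co["A"]),
                 baseline = unname(co["b"])),
            class = "gauss_fit")
}

#' Ordinary least-squares fit of measured vs physical positions
#'
#' @param measured,physical numeric vectors, mm.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
linear_positioning_fit <- function(measured, physical) {
  stopifnot(length(measured) == length(physical), length(measured) >= 2)
  fit <- lm(measured ~ physical)
  # summary.lm warns on exactly collinear input, which is a legitimate
  # noiseless case here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r2 = r2)
}
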