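#' Beam specification
#'
#' Bundles the proton-beam parameters that determine the parametric
#' activity distribution: beam energy, delivered dose (MU), entrance
#' position along the beam (x) axis, the number of inserted range-shifter
#' sheets and their water-equivalent thickness, and the lateral Gaussian
#' beam width.
#'
#' @param energy_mev proton energy, MeV.
#' @param dose_mu delivered dose in monitor units (> 0).
#' @param entrance_position_mm beam entrance x position, mm.
#' @param n_sheets number of inserted range-shifter sheets (0, 1 or 2;
#'   0 = overshot, 1 = planned, 2 = undershot beam range).
#' @param sheet_wet_mm water-equivalent range shift per sheet, mm.
#' @param beam_sigma_mm lateral Gaussian width of the pencil beam, mm.
#' @return a `beam_spec` list.
#' @export
beam_spec <- function(energy_mev = 109.4, dose_mu = 25,
                      entrance_position_mm = -100, n_sheets = 1L,
                      sheet_wet_mm = 6.8, beam_sigma_mm = 4.5) {
  stopifnot(dose_mu > 0 || dose_mu == 0, n_sheets %in% 0:2,
            sheet_wet_mm > 0, beam_sigma_mm > 0)
  structure(list(
    energy_mev = energy_mev, dose_mu = dose_mu,
    entrance_position_mm = entrance_position_mm,
    n_sheets = as.integer(n_sheets), sheet_wet_mm = sheet_wet_mm,
    beam_sigma_mm = beam_sigma_mm
  ), class = "beam_spec")
}

#' Proton range from beam energy (Bragg-Kleeman law)
#'
#' Range in water R(cm) = a * E(MeV)^p, divided by the medium's relative
#' stopping power, returned in mm.
#'
#' @param energy_mev proton energy, MeV.
#' @param medium medium name (must appear in the configured RSP table).
#' @param beam_cfg beam section of the configuration (for the
#'   Bragg-Kleeman constants and RSP table).
#' @return range in the medium, mm.
#' @export
proton_range_mm <- function(energy_mev, medium = "water",
                            beam_cfg = default_config()$beam) {
  rsp <- beam_cfg$rsp[[medium]]
  if (is.null(rsp)) stop("no relative stopping power configured for ", medium)
  10 * beam_cfg$bragg_kleeman_a_cm * energy_mev^beam_cfg$bragg_kleeman_p / rsp
}

# logistic width parameter from an 80%->20% falloff span:
# x20 - x80 = 2*ln(4)*w
falloff_width <- function(span_80_20_mm) span_80_20_mm / (2 * log(4))

# 1-D depth template closure: linear entrance ramp (width w_p) times a
# logistic distal falloff with 50% point at depth d50
depth_template <- function(d50_depth_mm, w_p = 2, w_d = falloff_width(4)) {
  force(d50_depth_mm); force(w_p); force(w_d)
  function(d) {
    ramp <- pmin(pmax(d / w_p, 0), 1)
    ramp / (1 + exp((d - d50_depth_mm) / w_d))
  }
}

# Analytic truth of a 1-D template: the distal turnover (max |A''| on the
# concave-down side, located numerically), the 50%-of-turnover-level
# distal crossing, and the proximal mirror. All in depth coordinates.
template_truth <- function(tmpl, d50_depth_mm, w_p, w_d) {
  dd2 <- function(d, h = 1e-3) (tmpl(d + h) - 2 * tmpl(d) + tmpl(d - h)) / h^2
  q <- optimize(function(d) dd2(d),
                lower = d50_depth_mm - 8 * w_d, upper = d50_depth_mm,
                tol = 1e-8)$minimum
  ref_d <- tmpl(q)
  distal50 <- uniroot(function(d) tmpl(d) - ref_d / 2,
                      lower = q, upper = d50_depth_mm + 15 * w_d,
                      tol = 1e-9)$root
  # proximal turnover: the ramp-to-plateau kink at depth w_p
  ref_p <- tmpl(w_p)
  proximal50 <- uniroot(function(d) tmpl(d) - ref_p / 2,
                        lower = 0, upper = w_p, tol = 1e-9)$root
  list(turnover_distal = q, true_distal50 = distal50,
       true_proximal50 = proximal50, true_ar = distal50 - proximal50)
}

#' Build a parametric activity map
#'
#' Builds the positron-emitter activity distribution on the phantom grid.
#' Three models:
#' \describe{
#'   \item{`beam` (default)}{proton-induced activity: a 1-D depth template
#'     (linear entrance ramp of width `proximal_ramp_mm`, unit plateau,
#'     logistic distal falloff whose 80%->20% span is `falloff_80_20_mm`)
#'     with the 50% point at depth `R(energy)/RSP - n_sheets * sheet_wet`,
#'     extruded laterally with Gaussian width `beam$beam_sigma_mm`.}
#'   \item{`cylinder`}{a uniform cylinder cross-section with a flat
#'     (sharp-logistic) distal end at `model_params$distal_x_mm` --- the
#'     moving radioactive-syringe phantom.}
#'   \item{`point`}{a point source at `model_params$x_mm`,
#'     `model_params$y_mm` with physical extent `model_params$sigma_mm`;
#'     stored as continuous source coordinates (exact sub-pixel truth)
#'     and sampled directly by the simulator.}
#' }
#' Activity is zeroed outside the phantom medium (`label == "air"`). The
#' `truth` element holds the analytic 50% crossings of the noiseless
#' template (reference level = template value at its maximum-curvature
#' turnover, matching the edge statistic of [measure_ar()]).
#'
#' @param phantom a [build_phantom()] object.
#' @param beam a [beam_spec()] (ignored by the `point` model).
#' @param model_params list: `model` ("beam", "cylinder", "point") plus
#'   model-specific parameters; `beam`-model defaults come from
#'   `default_config()$beam`.
#' @return an `activity_map`: grid of relative activity density matching
#'   the phantom, `truth` (true_proximal50 / true_distal50 / true_ar in
#'   absolute x, mm), and model metadata.
#' @export
build_activity <- function(phantom, beam = beam_spec(),
                           model_params = list()) {
  model <- model_params$model %||% "beam"
  cfg <- default_config()$beam
  n <- phantom$grid_n
  cx <- phantom$x_centers_mm
  X <- matrix(cx, n, n)
  Y <- matrix(cx, n, n, byrow = TRUE)
  act <- matrix(0, n, n)
  point_sources <- NULL

  if (model == "point") {
    x0 <- model_params$x_mm %||% 0
    y0 <- model_params$y_mm %||% 0
    point_sources <- data.frame(
      x_mm = x0, y_mm = y0,
      sigma_mm = model_params$sigma_mm %||% 0.5,
      weight = 1)
    truth <- list(x_mm = x0, y_mm = y0)
  } else if (model == "cylinder") {
    dx <- model_params$distal_x_mm %||% 20
    len <- model_params$length_mm %||% 80
    hw <- (model_params$width_mm %||% 20) / 2
    w_p <- model_params$proximal_ramp_mm %||% cfg$proximal_ramp_mm
    w_d <- falloff_width(model_params$falloff_80_20_mm %||% 2)
    entrance <- dx - len
    tmpl <- depth_template(len, w_p, w_d)
    prof <- tmpl(pmax(X - entrance, 0))
    prof[X < entrance] <- 0
    act <- prof * (abs(Y) <= hw)
    tt <- template_truth(tmpl, len, w_p, w_d)
    truth <- list(true_proximal50 = entrance + tt$true_proximal50,
                  true_distal50 = entrance + tt$true_distal50,
                  true_ar = tt$true_ar,
                  d50_depth_mm = len, entrance_mm = entrance)
  } else if (model == "beam") {
    entrance <- beam$entrance_position_mm
    # medium at first activated point decides the stopping power
    medium <- model_params$medium %||% beam_medium(phantom, entrance)
    w_p <- model_params$proximal_ramp_mm %||% cfg$proximal_ramp_mm
    w_d <- falloff_width(model_params$falloff_80_20_mm %||%
                           cfg$falloff_80_20_mm)
    d50_depth <- proton_range_mm(beam$energy_mev, medium, cfg) -
      beam$n_sheets * beam$sheet_wet_mm
    x50 <- entrance + d50_depth
    if (!point_in_medium(phantom, x50, 0))
      stop("range exceeds phantom: distal 50% point at x = ",
           signif(x50, 5), " mm is outside the phantom medium")
    tmpl <- depth_template(d50_depth, w_p, w_d)
    prof <- tmpl(pmax(X - entrance, 0))
    prof[X < entrance] <- 0
    act <- prof * exp(-Y^2 / (2 * beam$beam_sigma_mm^2))
    tt <- template_truth(tmpl, d50_depth, w_p, w_d)
    truth <- list(true_proximal50 = entrance + tt$true_proximal50,
                  true_distal50 = entrance + tt$true_distal50,
                  true_ar = tt$true_ar,
                  d50_depth_mm = d50_depth, entrance_mm = entrance,
                  medium = medium)
  } else stop("unknown activity model: ", model)

  act[phantom$label == "air"] <- 0

  structure(list(
    activity = act,
    grid_n = n,
    grid_spacing_mm = phantom$grid_spacing_mm,
    xmin_mm = phantom$xmin_mm, ymin_mm = phantom$ymin_mm,
    x_centers_mm = cx,
    truth = truth,
    model = model,
    beam = if (model == "point") NULL else beam,
    point_sources = point_sources
  ), class = "activity_map")
}

# medium label at the first non-air pixel along +x from the entrance on
# the beam axis (y = 0)
beam_medium <- function(phantom, entrance_mm) {
  iy <- which.min(abs(phantom$x_centers_mm))
  on_path <- phantom$x_centers_mm >= entrance_mm
  labs <- phantom$label[on_path, iy]
  labs <- labs[labs != "air"]
  if (!length(labs)) stop("beam path contains no phantom medium")
  labs[1]
}

point_in_medium <- function(phantom, x, y) {
  ix <- findInterval(x, phantom$xmin_mm +
                       (0:phantom$grid_n) * phantom$grid_spacing_mm,
                     all.inside = FALSE)
  iy <- findInterval(y, phantom$ymin_mm +
                       (0:phantom$grid_n) * phantom$grid_spacing_mm)
  if (ix < 1 || ix > phantom$grid_n || iy < 1 || iy > phantom$grid_n)
    return(FALSE)
  phantom$label[ix, iy] != "air"
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("<activity_map> model=%s", x$model))
  if (!is.null(x$truth$true_ar))
    cat(sprintf(": distal50=%.2f mm, proximal50=%.2f mm, AR=%.2f mm",
                x$truth$true_distal50, x$truth$true_proximal50,
                x$truth$true_ar))
  cat("\n")
  invisible(x)
}
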