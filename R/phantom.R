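#' Build a gridded attenuation phantom
#'
#' Builds a 2-D phantom on a square pixel grid centred on the scanner
#' field of view: a per-pixel medium `label` map and the corresponding
#' 511 keV linear attenuation `mu` map (1/mm). Available specs:
#'
#' \describe{
#'   \item{`air`}{empty field of view, mu = 0 everywhere.}
#'   \item{`water_tank`}{160 x 160 mm water square (the 16 cm tank cross
#'     section), centred; `params$filled = FALSE` keeps the geometry but
#'     leaves it empty (mu = 0).}
#'   \item{`lucite_in_water`}{a 25 x 350 mm Lucite bar cross-section
#'     (long axis along the beam/x axis, upstream face at
#'     `params$bar_x_mm`, default -100 mm, so the entrance lies inside
#'     the field of view; clipped to the grid) embedded in the
#'     160 x 160 mm water square; `params$filled = FALSE` empties the
#'     tank around the bar.}
#'   \item{`head_analog`}{a head-sized disc (default radius 80 mm) of
#'     head-analog medium.}
#'   \item{`cylinder_holder`}{a water-filled cylinder cross-section
#'     (`params$length_mm` x `params$width_mm`, flat distal end at
#'     `params$distal_x_mm`) standing in air, optionally inside the filled
#'     water tank (`params$filled = TRUE`).}
#' }
#'
#' @param spec_name one of the specs above.
#' @param params spec-specific overrides (see Description); `params$mu`
#'   may override the per-medium attenuation defaults.
#' @param grid_n,grid_spacing_mm grid size (pixels) and pixel size (mm).
#' @return A `phantom` object: list with `label` and `mu` matrices
#'   (x index = rows), grid descriptors, and the spec/params used.
#' @export
build_phantom <- function(spec_name, params = list(),
                          grid_n = 160L, grid_spacing_mm = 2.0) {
  specs <- c("air", "water_tank", "lucite_in_water", "head_analog",
             "cylinder_holder")
  if (!spec_name %in% specs)
    stop("unknown phantom spec: ", spec_name)

  mu_tab <- modifyList(default_config()$phantom$mu_511kev_per_mm,
                       params$mu %||% list())
  n <- as.integer(grid_n)
  sp <- grid_spacing_mm
  cx <- (seq_len(n) - (n + 1) / 2) * sp
  X <- matrix(cx, n, n)              # x varies along rows
  Y <- matrix(cx, n, n, byrow = TRUE)

  label <- matrix("air", n, n)
  filled <- isTRUE(params$filled %||% TRUE)

  if (spec_name == "water_tank") {
    half <- (params$tank_mm %||% 160) / 2
    inside <- abs(X) <= half & abs(Y) <= half
    if (filled) label[inside] <- "water"
  } else if (spec_name == "lucite_in_water") {
    half <- (params$tank_mm %||% 160) / 2
    bar_halfwidth <- (params$bar_width_mm %||% 25) / 2
    bar_x0 <- params$bar_x_mm %||% -100
    bar_x1 <- bar_x0 + (params$bar_length_mm %||% 350)
    tank <- abs(X) <= half & abs(Y) <= half
    bar <- abs(Y) <= bar_halfwidth & X >= bar_x0 & X <= bar_x1
    if (filled) label[tank] <- "water"
    label[bar] <- "lucite"
  } else if (spec_name == "head_analog") {
    r <- params$radius_mm %||% 80
    label[X^2 + Y^2 <= r^2] <- "head_analog"
  } else if (spec_name == "cylinder_holder") {
    filled <- isTRUE(params$filled %||% FALSE)
    half <- (params$tank_mm %||% 160) / 2
    dx <- params$distal_x_mm %||% 20
    len <- params$length_mm %||% 80
    hw <- (params$width_mm %||% 20) / 2
    if (filled) label[abs(X) <= half & abs(Y) <= half] <- "water"
    label[X <= dx & X >= dx - len & abs(Y) <= hw] <- "water"
  }

  mu <- matrix(0, n, n)
  for (med in unique(as.vector(label)))
    mu[label == med] <- mu_tab[[med]]

  structure(list(
    spec_name = spec_name,
    grid_n = n,
    grid_spacing_mm = sp,
    xmin_mm = -n * sp / 2,
    ymin_mm = -n * sp / 2,
    x_centers_mm = cx,
    label = label,
    mu = mu,
    mu_table = mu_tab,
    params = params
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  media <- table(x$label)
  cat(sprintf("<phantom> %s: %dx%d grid @ %.1f mm; media: %s\n",
              x$spec_name, x$grid_n, x$grid_n, x$grid_spacing_mm,
              paste(names(media), media, sep = "=", collapse = ", ")))
  invisible(x)
}

# pixel-centre coordinate vectors of a phantom/image-like grid
grid_coords <- function(obj) obj$x_centers_mm
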