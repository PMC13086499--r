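#' Build the PET detector ring geometry
#'
#' Constructs a closed ring of `n_detectors_closed` flat-panel detector
#' positions, or an open ring with the two detectors along the beam
#' (+x/-x) axis removed so the proton beam can traverse the scanner. Each
#' detector occupies an equal angular sector; its in-plane crystal row is
#' discretised into equal angular bins whose centres lie on the nominal
#' ring circle (radius = half the inner diameter). The simulation is 2-D
#' in the beam-containing plane; the axial extent is metadata only.
#'
#' @param mode `"closed_ring"` (20 detectors) or `"open_ring"`
#'   (18 detectors; the two along the beam axis removed).
#' @param ring_inner_diameter_mm inner ring diameter, mm (default 418).
#' @param crystal_pitch_mm nominal crystal pitch, mm (default 2.09).
#' @param n_detectors_closed number of detector panels in the closed ring.
#' @param crystals_per_detector_row in-plane crystals per detector.
#' @param axial_extent_mm axial ring height, mm (metadata only).
#' @return A `detector_geometry` object: list with the ring parameters, a
#'   `crystals` data.frame (`id`, `detector`, `angle_rad`, `x_mm`, `y_mm`,
#'   `active`), the removed detector indices, and `n_active` crystals.
#' @examples
#' g <- build_geometry("open_ring")
#' g$n_detectors       # 18
#' sum(g$crystals$active)
#' @export
build_geometry <- function(mode = c("closed_ring", "open_ring"),
                           ring_inner_diameter_mm = 418,
                           crystal_pitch_mm = 2.09,
                           n_detectors_closed = 20L,
                           crystals_per_detector_row = 32L,
                           axial_extent_mm = 66) {
  if (length(mode) != 1L || !mode %in% c("closed_ring", "open_ring"))
    stop("invalid geometry mode: ", paste(mode, collapse = "/"))
  if (ring_inner_diameter_mm <= 0) stop("ring diameter must be positive")

  nd <- as.integer(n_detectors_closed)
  nc <- as.integer(crystals_per_detector_row)
  R <- ring_inner_diameter_mm / 2
  sector <- 2 * pi / nd

  # detector d is centred at angle (d-1)*sector; the beam runs along x,
  # so detectors 1 (0 rad) and 1 + nd/2 (pi rad) face the beam ports
  removed <- integer(0)
  if (mode == "open_ring") removed <- c(1L, 1L + nd %/% 2L)

  det <- rep(seq_len(nd), each = nc)
  k <- rep(seq_len(nc), times = nd)
  angle <- (det - 1) * sector - sector / 2 + (k - 0.5) * sector / nc
  crystals <- data.frame(
    id = seq_len(nd * nc),
    detector = det,
    angle_rad = angle,
    x_mm = R * cos(angle),
    y_mm = R * sin(angle),
    active = !(det %in% removed)
  )

  structure(list(
    mode = mode,
    n_detectors = nd - length(removed),
    n_detectors_closed = nd,
    ring_radius_mm = R,
    ring_inner_diameter_mm = ring_inner_diameter_mm,
    crystals_per_detector_row = nc,
    crystal_pitch_mm = crystal_pitch_mm,
    removed_detector_indices = removed,
    axial_extent_mm = axial_extent_mm,
    crystals = crystals,
    n_active = sum(crystals$active)
  ), class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> %s: %d detectors, %d active crystals, R = %.1f mm\n",
    x$mode, x$n_detectors, x$n_active, x$ring_radius_mm))
  invisible(x)
}

# Map in-plane photon direction angles (rad) to crystal ids (or NA if the
# photon exits through an open-ring gap). Sectors tile the full circle, so
# the bin is a pure angular quantisation starting at -sector/2.
crystal_at_angle <- function(geometry, theta) {
  nd <- geometry$n_detectors_closed
  nc <- geometry$crystals_per_detector_row
  nbin <- nd * nc
  sector <- 2 * pi / nd
  frac <- ((theta + sector / 2) / (2 * pi)) %% 1
  id <- pmin(floor(frac * nbin), nbin - 1) + 1L
  det <- (id - 1L) %/% nc + 1L
  id[det %in% geometry$removed_detector_indices] <- NA_integer_
  id
}

# Endpoint coordinates (crystal centres) for vectors of crystal ids.
crystal_xy <- function(geometry, id) {
  cbind(geometry$crystals$x_mm[id], geometry$crystals$y_mm[id])
}

# All unordered active-crystal pairs as a two-column integer matrix
# (a < b). These are the existing lines of response of the scanner.
active_pairs <- function(geometry) {
  ids <- geometry$crystals$id[geometry$crystals$active]
  n <- length(ids)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  cbind(a = ids[i], b = ids[j])
}
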