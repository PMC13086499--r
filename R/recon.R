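#' Reconstruction specification
#'
#' @param grid_n image grid size (pixels per side).
#' @param pixel_size_mm pixel size, mm.
#' @param n_subsets number of ordered subsets (1 = plain MLEM).
#' @param n_iterations number of (full) iterations.
#' @param nonneg_floor relative floor guarding divisions by the forward
#'   projection (fraction of its maximum).
#' @return a `recon_spec` list.
#' @export
recon_spec <- function(grid_n = 160L, pixel_size_mm = 2.0,
                       n_subsets = 5L, n_iterations = 10L,
                       nonneg_floor = 1e-12) {
  stopifnot(n_subsets >= 1, n_iterations >= 1, pixel_size_mm > 0)
  structure(list(grid_n = as.integer(grid_n),
                 pixel_size_mm = pixel_size_mm,
                 n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations),
                 nonneg_floor = nonneg_floor),
            class = "recon_spec")
}

new_image <- function(intensity, pixel_size_mm) {
  n <- nrow(intensity)
  structure(list(
    intensity = intensity,
    grid_n = n,
    pixel_size_mm = pixel_size_mm,
    xmin_mm = -n * pixel_size_mm / 2,
    ymin_mm = -n * pixel_size_mm / 2,
    x_centers_mm = (seq_len(n) - (n + 1) / 2) * pixel_size_mm
  ), class = "pet_image")
}

#' @export
print.pet_image <- function(x, ...) {
  cat(sprintf("<pet_image> %dx%d @ %.2f mm, total intensity %.4g\n",
              x$grid_n, x$grid_n, x$pixel_size_mm, sum(x$intensity)))
  invisible(x)
}

#' Histogram list-mode events into a sinogram
#'
#' Counts events per unordered active-crystal pair (line of response).
#'
#' @param events an `event_list`.
#' @param geometry the [build_geometry()] the events were acquired on.
#' @return a `sinogram`: data.frame with columns `a`, `b` (crystal ids,
#'   `a < b`) and integer `count`, plus the geometry as an attribute.
#' @export
histogram_events <- function(events, geometry) {
  ok <- geometry$crystals$active
  if (nrow(events)) {
    bad <- !(events$crystal_a %in% geometry$crystals$id[ok]) |
      !(events$crystal_b %in% geometry$crystals$id[ok])
    if (any(bad)) stop("events reference unknown or inactive crystal ids")
  }
  a <- pmin(events$crystal_a, events$crystal_b)
  b <- pmax(events$crystal_a, events$crystal_b)
  dt <- data.table::data.table(a = a, b = b)
  cnt <- dt[, .N, by = c("a", "b")]
  data.table::setorderv(cnt, c("a", "b"))
  out <- data.frame(a = cnt$a, b = cnt$b, count = cnt$N)
  attr(out, "geometry") <- geometry
  class(out) <- c("sinogram", "data.frame")
  out
}

# LOR endpoint coordinates for pair matrix/data.frame with columns a, b
lor_coords <- function(geometry, a, b) {
  pa <- crystal_xy(geometry, a)
  pb <- crystal_xy(geometry, b)
  list(x0 = pa[, 1], y0 = pa[, 2], x1 = pb[, 1], y1 = pb[, 2])
}

# projection-angle stride subset assignment (deterministic, identical for
# measured and all-LOR sets); 16 interleaved wedge groups per subset
lor_subset <- function(geometry, a, b, n_subsets) {
  if (n_subsets == 1L) return(rep(1L, length(a)))
  co <- lor_coords(geometry, a, b)
  ang <- atan2(co$y1 - co$y0, co$x1 - co$x0) %% pi
  (floor((ang / pi) * n_subsets * 16) %% n_subsets) + 1L
}

#' Forward project an image along lines of response
#'
#' Siddon ray tracing with exact chord-length weights: for each LOR the
#' value is the line integral of the image between the two crystal
#' centres. Linear in the image; the exact adjoint of [back_project()].
#'
#' @param image a `pet_image` (or matrix with `pixel_size_mm` attr).
#' @param geometry the detector geometry.
#' @param lors two-column matrix/data.frame of crystal id pairs; all
#'   existing (active) pairs when `NULL`.
#' @return numeric vector of line integrals (mm-weighted).
#' @export
forward_project <- function(image, geometry, lors = NULL) {
  if (is.null(lors)) lors <- active_pairs(geometry)
  co <- lor_coords(geometry, lors[, 1], lors[, 2])
  .siddon_forward(as.numeric(image$intensity), image$grid_n, image$grid_n,
                  image$pixel_size_mm, image$xmin_mm, image$ymin_mm,
                  co$x0, co$y0, co$x1, co$y1)
}

#' Back project LOR values into an image
#'
#' Exact adjoint of [forward_project()]: accumulates each LOR value into
#' the pixels its chord crosses, weighted by the intersection lengths.
#'
#' @param lor_values numeric vector, one value per LOR.
#' @param geometry the detector geometry.
#' @param lors two-column matrix of crystal id pairs; all existing pairs
#'   when `NULL`.
#' @param spec a [recon_spec()] defining the image grid.
#' @return a `pet_image`.
#' @export
back_project <- function(lor_values, geometry, lors = NULL,
                         spec = recon_spec()) {
  if (is.null(lors)) lors <- active_pairs(geometry)
  co <- lor_coords(geometry, lors[, 1], lors[, 2])
  n <- spec$grid_n
  img <- .siddon_back(as.numeric(lor_values), n, n, spec$pixel_size_mm,
                      -n * spec$pixel_size_mm / 2, -n * spec$pixel_size_mm / 2,
                      co$x0, co$y0, co$x1, co$y1)
  new_image(matrix(img, n, n), spec$pixel_size_mm)
}

# cache for sensitivity images / subset structures (keyed on geometry +
# grid + subset count; computing them is pure)
.rangepet_cache <- new.env(parent = emptyenv())

geometry_key <- function(geometry, spec, n_subsets = 1L) {
  paste(geometry$mode, geometry$ring_inner_diameter_mm,
        geometry$n_detectors_closed, geometry$crystals_per_detector_row,
        spec$grid_n, spec$pixel_size_mm, n_subsets, sep = "|")
}

#' Geometric sensitivity image
#'
#' Backprojection of ones over all existing LORs: the per-pixel total
#' detection weight used as the MLEM/OSEM normalisation. Open-ring
#' sensitivity is pixel-wise below the closed-ring one (fewer LORs).
#' Results are cached per geometry/grid.
#'
#' @param geometry the detector geometry.
#' @param spec a [recon_spec()].
#' @param n_subsets when > 1, returns a list of per-subset sensitivity
#'   images (summing to the total).
#' @return a `pet_image`, or a list of them when `n_subsets > 1`.
#' @export
sensitivity_image <- function(geometry, spec = recon_spec(),
                              n_subsets = 1L) {
  key <- geometry_key(geometry, spec, n_subsets)
  hit <- .rangepet_cache[[key]]
  if (!is.null(hit)) return(hit)
  pairs <- active_pairs(geometry)
  res <- if (n_subsets == 1L) {
    back_project(rep(1, nrow(pairs)), geometry, pairs, spec)
  } else {
    sub <- lor_subset(geometry, pairs[, 1], pairs[, 2], n_subsets)
    lapply(seq_len(n_subsets), function(s)
      back_project(rep(1, sum(sub == s)), geometry,
                   pairs[sub == s, , drop = FALSE], spec))
  }
  .rangepet_cache[[key]] <- res
  res
}

#' MLEM / OSEM reconstruction
#'
#' Standard multiplicative expectation-maximisation update
#' `x <- (x / s_subset) * At_subset(y / A_subset x)` over
#' projection-angle-stride subsets, with a relative floor guarding the
#' division. No attenuation, scatter or randoms correction terms are
#' applied. LORs whose chord does not intersect the image grid carry no
#' tomographic information and are dropped from the data. Deterministic
#' given its inputs.
#'
#' @param sinogram a [histogram_events()] sinogram.
#' @param geometry the detector geometry.
#' @param spec a [recon_spec()].
#' @param track_likelihood when `TRUE` (and `n_subsets == 1`), attaches
#'   attributes `loglik` (Poisson log-likelihood per iteration) and
#'   `count_balance` (sum of `s * x` per iteration, which the MLEM fixed
#'   point keeps equal to the total measured counts).
#' @return a `pet_image`; nonnegative everywhere.
#' @export
osem_reconstruct <- function(sinogram, geometry, spec = recon_spec(),
                             track_likelihood = FALSE) {
  n <- spec$grid_n
  if (!nrow(sinogram) || sum(sinogram$count) == 0) {
    warning("empty sinogram: returning zero image")
    return(new_image(matrix(0, n, n), spec$pixel_size_mm))
  }
  s_tot <- sensitivity_image(geometry, spec, 1L)
  s_sub <- if (spec$n_subsets > 1L)
    sensitivity_image(geometry, spec, spec$n_subsets) else list(s_tot)

  # drop LORs that miss the grid (e.g. randoms between adjacent crystals)
  co <- lor_coords(geometry, sinogram$a, sinogram$b)
  chord <- .siddon_chord(n, n, spec$pixel_size_mm,
                         -n * spec$pixel_size_mm / 2,
                         -n * spec$pixel_size_mm / 2,
                         co$x0, co$y0, co$x1, co$y1)
  keep <- chord > 0
  sino <- sinogram[keep, , drop = FALSE]
  if (!nrow(sino)) {
    warning("no measured LOR intersects the image grid: zero image")
    return(new_image(matrix(0, n, n), spec$pixel_size_mm))
  }
  sub_of <- lor_subset(geometry, sino$a, sino$b, spec$n_subsets)

  x <- ifelse(s_tot$intensity > 0, 1, 0)
  img <- new_image(x, spec$pixel_size_mm)
  loglik <- count_balance <- numeric(0)
  lors_all <- cbind(sino$a, sino$b)
  y_all <- sino$count

  for (it in seq_len(spec$n_iterations)) {
    for (s in seq_len(spec$n_subsets)) {
      in_sub <- sub_of == s
      if (!any(in_sub)) next
      lors <- lors_all[in_sub, , drop = FALSE]
      y <- y_all[in_sub]
      p <- forward_project(img, geometry, lors)
      floor_abs <- spec$nonneg_floor * max(p, 1e-300)
      ratio <- y / pmax(p, floor_abs)
      bp <- back_project(ratio, geometry, lors, spec)$intensity
      ssub <- s_sub[[s]]$intensity
      img$intensity <- ifelse(ssub > 0, img$intensity * bp / ssub, 0)
    }
    if (track_likelihood && spec$n_subsets == 1L) {
      p <- forward_project(img, geometry, lors_all)
      floor_abs <- spec$nonneg_floor * max(p, 1e-300)
      loglik <- c(loglik, sum(y_all * log(pmax(p, floor_abs))) -
                    sum(s_tot$intensity * img$intensity))
      count_balance <- c(count_balance,
                         sum(s_tot$intensity * img$intensity))
    }
  }
  if (track_likelihood) {
    attr(img, "loglik") <- loglik
    attr(img, "count_balance") <- count_balance
    attr(img, "total_counts") <- sum(y_all)
  }
  img
}

#' Reconstruct directly from an event list
#'
#' Convenience wrapper: [histogram_events()] then [osem_reconstruct()].
#'
#' @inheritParams osem_reconstruct
#' @param events an `event_list`.
#' @return a `pet_image`.
#' @export
reconstruct_events <- function(events, geometry, spec = recon_spec(),
                               track_likelihood = FALSE) {
  osem_reconstruct(histogram_events(events, geometry), geometry, spec,
                   track_likelihood = track_likelihood)
}

#' Combine a transverse band of image rows into a beam-axis profile
#'
#' Sums image intensity over the transverse (y) band `|y| <= halfwidth`
#' per beam-axis (x) position: the slice-combination step that trades
#' transverse resolution for count statistics before range analysis.
#' `band_halfwidth_mm = 0` selects the single row nearest the beam axis.
#'
#' @param image a `pet_image`.
#' @param band_halfwidth_mm transverse half-width of the band, mm.
#' @param center_mm transverse centre of the band (default 0, the beam
#'   axis).
#' @return a `pet_profile` data.frame (`position_mm`, `intensity`).
#' @export
combine_band <- function(image, band_halfwidth_mm = 9, center_mm = 0) {
  yc <- image$x_centers_mm
  if (band_halfwidth_mm < 0) stop("band half-width must be >= 0")
  sel <- if (band_halfwidth_mm == 0) {
    which.min(abs(yc - center_mm))
  } else {
    which(abs(yc - center_mm) <= band_halfwidth_mm)
  }
  if (!length(sel)) stop("band lies outside the image grid")
  inten <- if (length(sel) == 1) image$intensity[, sel]
           else rowSums(image$intensity[, sel, drop = FALSE])
  new_profile(image$x_centers_mm, inten)
}

new_profile <- function(position_mm, intensity) {
  stopifnot(length(position_mm) == length(intensity))
  out <- data.frame(position_mm = position_mm, intensity = intensity)
  class(out) <- c("pet_profile", "data.frame")
  out
}
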