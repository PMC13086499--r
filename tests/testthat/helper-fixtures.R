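# Shared fixtures: everything is generated in code at test time.

default_w_d <- rangepet:::falloff_width(4)

# analytic depth template + its truth, as a profile on a given grid
template_profile <- function(d50 = 80, spacing = 0.5, w_p = 2,
                             w_d = default_w_d, xmax = 140) {
  tmpl <- rangepet:::depth_template(d50, w_p, w_d)
  x <- seq(-20, xmax, by = spacing)
  rangepet:::new_profile(x, tmpl(x))
}

template_truth_of <- function(d50, w_p = 2, w_d = default_w_d) {
  rangepet:::template_truth(rangepet:::depth_template(d50, w_p, w_d),
                            d50, w_p, w_d)
}

# a small synthetic event list with controllable fields
synthetic_events <- function(n = 100, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    event_id = seq_len(n),
    crystal_a = sample(33:64, n, replace = TRUE),
    crystal_b = sample(353:384, n, replace = TRUE),
    energy_a_kev = runif(n, 300, 700),
    energy_b_kev = runif(n, 300, 700),
    t_a_ns = sort(runif(n, 0, 60e9)),
    t_b_ns = 0,
    truth_class = sample(c("true", "random"), n, replace = TRUE))
  df$t_b_ns <- df$t_a_ns + rnorm(n, 0, 4)
  rangepet:::as_event_list(df, resort = FALSE)
}

# quick acquisition with reduced counts and no background
quick_acq <- function(counts = 20000, seed = 1, background = 0, ...) {
  acquisition_spec(counts_per_mu = counts, seed = seed,
                   background_rate_per_s = background, ...)
}

# small open-ring Lucite-beam setup used by several recon tests
lucite_setup <- function(n_sheets = 1L, dose_mu = 2) {
  cfg <- default_config()
  rangepet:::beam_setup("lucite_in_water", cfg, n_sheets = n_sheets,
                        dose_mu = dose_mu)
}

# independent exact chord-length oracle: Liang-Barsky clipping of the
# segment against every pixel box (O(n_pixels) per ray, but exact)
chord_lengths_oracle <- function(x0, y0, x1, y1, n, px, xmin, ymin) {
  out <- matrix(0, n, n)
  dx <- x1 - x0; dy <- y1 - y0
  L <- sqrt(dx^2 + dy^2)
  for (ix in seq_len(n)) for (iy in seq_len(n)) {
    bx0 <- xmin + (ix - 1) * px; bx1 <- bx0 + px
    by0 <- ymin + (iy - 1) * px; by1 <- by0 + px
    t0 <- 0; t1 <- 1; ok <- TRUE
    for (cl in list(c(-dx, x0 - bx0), c(dx, bx1 - x0),
                    c(-dy, y0 - by0), c(dy, by1 - y0))) {
      p <- cl[1]; q <- cl[2]
      if (p == 0) { if (q < 0) { ok <- FALSE; break } }
      else {
        r <- q / p
        if (p < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
        if (t0 > t1) { ok <- FALSE; break }
      }
    }
    if (ok && t1 > t0) out[ix, iy] <- (t1 - t0) * L
  }
  out
}
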