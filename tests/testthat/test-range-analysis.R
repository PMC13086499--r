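test_that("smoothing is identity at sigma 0 and preserves constants and mass", {
  p <- template_profile(80, spacing = 0.5)
  expect_identical(smooth_profile(p, 0), p)
  const <- rangepet:::new_profile(seq(0, 50, 0.5), rep(3.5, 101))
  expect_equal(smooth_profile(const, 3)$intensity, const$intensity,
               tolerance = 1e-12)
  # unit impulse spreads into a discrete Gaussian of matching second moment
  imp <- rangepet:::new_profile(seq(-30, 30, 0.5), 0 + (seq(-30, 30, 0.5) == 0))
  sm <- smooth_profile(imp, 2)
  m2 <- sum(sm$intensity * sm$position_mm^2) / sum(sm$intensity)
  expect_equal(sqrt(m2), 2, tolerance = 0.01)
})

test_that("maximum-curvature peak localisation matches analytic turnovers", {
  # plateau then linear ramp: curvature concentrates at the kink
  x <- seq(0, 80, 0.5)
  f <- ifelse(x < 50, 1, pmax(1 - (x - 50) / 10, 0))
  pk <- find_distal_peak(rangepet:::new_profile(x, f))
  expect_lt(abs(pk - 50), 0.51)
  # logistic falloff: analytic max |f''| at level (3 + sqrt(3)) / 6
  w <- default_w_d
  xl <- seq(0, 140, 0.1)
  fl <- 1 / (1 + exp((xl - 80) / w))
  # root-found from the closed-form level of the turnover
  lev <- (3 + sqrt(3)) / 6
  q_root <- uniroot(function(x) 1 / (1 + exp((x - 80) / w)) - lev,
                    c(60, 80))$root
  pk_l <- find_distal_peak(rangepet:::new_profile(xl, fl))
  expect_lt(abs(pk_l - q_root), 0.5)
  # turnover precedes the 50% point of a falling edge
  expect_lt(pk_l, 80)
  # monotone profile: no turnover anywhere
  lin <- rangepet:::new_profile(xl, 1 - xl / 200)
  expect_error(find_distal_peak(lin), "no distal peak")
})

test_that("50% edge interpolation is exact on steps and logistics", {
  # unit step between samples at 59.5 and 60.5 crosses at 60.0
  x <- seq(0, 100, 1) + 0.5
  f <- as.numeric(x < 60)
  e <- find_edge50(rangepet:::new_profile(x, f), peak_pos = 50.5,
                   side = "distal")
  expect_equal(e, 60.0, tolerance = 1e-9)
  # analytic logistic with reference level at the plateau: edge at d50
  w <- default_w_d
  xl <- seq(0, 140, 0.1)
  fl <- 1 / (1 + exp((xl - 80) / w))
  e80 <- find_edge50(rangepet:::new_profile(xl, fl), peak_pos = 20,
                     side = "distal")
  expect_lt(abs(e80 - 80), 0.25)
  expect_error(find_edge50(rangepet:::new_profile(xl, fl + 10), 20,
                           "distal"), "never crossed")
})

test_that("the AR statistic is scale invariant and translation equivariant", {
  p <- template_profile(75, spacing = 1)
  est <- measure_ar(p)
  half <- rangepet:::new_profile(p$position_mm, 0.5 * p$intensity)
  est_h <- measure_ar(half)
  expect_equal(est_h$distal_edge50, est$distal_edge50, tolerance = 1e-9)
  expect_equal(est_h$ar, est$ar, tolerance = 1e-9)
  shifted <- rangepet:::new_profile(p$position_mm + 6.8, p$intensity)
  est_s <- measure_ar(shifted)
  expect_equal(est_s$distal_edge50, est$distal_edge50 + 6.8,
               tolerance = 1e-6)
  expect_equal(est_s$proximal_edge50, est$proximal_edge50 + 6.8,
               tolerance = 1e-6)
  expect_equal(est_s$ar, est$ar, tolerance = 1e-6)
  expect_equal(measure_shift(est_s, est), 6.8, tolerance = 1e-6)
  expect_equal(measure_shift(est, est), 0)
})

test_that("halving the profile spacing barely moves the distal edge", {
  for (d50 in c(70, 90)) {
    e1 <- measure_ar(template_profile(d50, spacing = 1))$distal_edge50
    e2 <- measure_ar(template_profile(d50, spacing = 0.5))$distal_edge50
    expect_lt(abs(e1 - e2), 0.25)
  }
})

test_that("edge precision improves monotonically with profile counts", {
  # Poisson replicates of the noiseless template at four count levels
  tmpl <- template_profile(80, spacing = 2)
  levels <- c(200, 1000, 5000, 25000)
  sds <- vapply(levels, function(total) {
    edges <- vapply(1:9, function(s) {
      set.seed(1000 * total + s)
      lam <- tmpl$intensity / sum(tmpl$intensity) * total
      noisy <- rangepet:::new_profile(tmpl$position_mm, rpois(nrow(tmpl), lam))
      measure_ar(noisy)$distal_edge50
    }, 0)
    sd(edges)
  }, 0)
  expect_true(all(diff(sds) <= 0.05))
  expect_lt(sds[4], sds[1])
})

test_that("Gaussian fits recover exact parameters and source positions", {
  x <- seq(-20, 40, 0.5)
  f <- 2.5 * exp(-(x - 10)^2 / (2 * (3 / 2.3548)^2)) + 0.3
  fit <- fit_gaussian(rangepet:::new_profile(x, f))
  expect_equal(fit$center, 10, tolerance = 1e-5)
  expect_equal(fit$fwhm, 3, tolerance = 1e-4)
  expect_equal(fit$amplitude, 2.5, tolerance = 1e-4)
  expect_equal(fit$baseline, 0.3, tolerance = 1e-3)
  lf <- linear_positioning_fit(seq(-90, 90, 10), seq(-90, 90, 10))
  expect_equal(lf$slope, 1)
  expect_equal(lf$intercept, 0, tolerance = 1e-12)
  expect_equal(lf$r2, 1)
  lf2 <- linear_positioning_fit(seq(-90, 90, 10) + 0.3, seq(-90, 90, 10))
  expect_equal(lf2$slope, 1, tolerance = 1e-9)
  expect_equal(lf2$intercept, 0.3, tolerance = 1e-9)
})
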