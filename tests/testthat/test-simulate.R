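test_that("simulation is byte-identical under a fixed seed", {
  g <- build_geometry("open_ring")
  ph <- build_phantom("air")
  act <- build_activity(ph, model_params = list(model = "point"))
  acq <- quick_acq(counts = 5000, seed = 42, background = 500)
  e1 <- simulate_listmode(g, ph, act, acq, dose_mu = 1)
  e2 <- simulate_listmode(g, ph, act, acq, dose_mu = 1)
  expect_identical(e1, e2)
  e3 <- simulate_listmode(g, ph, act, quick_acq(5000, seed = 43,
                                                background = 500),
                          dose_mu = 1)
  expect_false(identical(e1, e3))
})

test_that("no source and no background yields an empty event list", {
  g <- build_geometry("closed_ring")
  ph <- build_phantom("air")
  act <- build_activity(ph, model_params = list(model = "point"))
  ev <- simulate_listmode(g, ph, act, quick_acq(1000), dose_mu = 0)
  expect_equal(nrow(ev), 0)
  # zero activity everywhere with nonzero dose is a configuration error
  beam_act <- build_activity(build_phantom("water_tank"),
                             beam_spec(entrance_position_mm = -80,
                                       n_sheets = 0))
  beam_act$activity[] <- 0
  expect_error(simulate_listmode(g, ph, beam_act, quick_acq(1000),
                                 dose_mu = 1),
               "zero total activity")
})

test_that("point source at the origin only populates LORs through the origin", {
  g <- build_geometry("open_ring")
  ph <- build_phantom("air")
  act <- build_activity(ph, model_params = list(model = "point",
                                                sigma_mm = 1e-6))
  ev <- simulate_listmode(g, ph, act, quick_acq(30000, seed = 5),
                          dose_mu = 1)
  expect_gt(nrow(ev), 20000)
  co <- rangepet:::lor_coords(g, ev$crystal_a, ev$crystal_b)
  d <- abs(co$x0 * (co$y1 - co$y0) - co$y0 * (co$x1 - co$x0)) /
    sqrt((co$x1 - co$x0)^2 + (co$y1 - co$y0)^2)
  expect_lte(max(d), g$crystal_pitch_mm)
})

test_that("attenuation thinning matches the analytic mean-survival oracle", {
  g <- build_geometry("closed_ring")
  filled <- build_phantom("water_tank")
  empty <- build_phantom("water_tank", list(filled = FALSE))
  act <- build_activity(filled, model_params = list(model = "point",
                                                    sigma_mm = 1e-6))
  acq <- quick_acq(40000, seed = 9)
  n_f <- nrow(simulate_listmode(g, filled, act, acq, dose_mu = 1))
  n_e <- nrow(simulate_listmode(g, empty, act, acq, dose_mu = 1))
  # paired seeds: the filled-tank acceptance is a subset of the empty one
  expect_lte(n_f, n_e)
  # oracle: chord of the 160 mm square through the origin at angle phi
  mu_w <- default_config()$phantom$mu_511kev_per_mm$water
  set.seed(1)
  phi <- runif(50000, 0, pi)
  L <- 160 / pmax(abs(cos(phi)), abs(sin(phi)))
  p_surv <- mean(exp(-mu_w * L))
  sigma <- sqrt(p_surv * (1 - p_surv) / n_e)
  expect_lt(abs(n_f / n_e - p_surv), 3 * sigma + 0.01)
})

test_that("accepted counts grow linearly with dose", {
  g <- build_geometry("open_ring")
  ph <- build_phantom("air")
  act <- build_activity(ph, model_params = list(model = "point"))
  doses <- 1:6
  counts <- vapply(doses, function(d)
    nrow(simulate_listmode(g, ph, act, quick_acq(3000, seed = 100 + d),
                           dose_mu = d)), 0)
  fit <- summary(lm(counts ~ doses))
  slope <- fit$coefficients["doses", ]
  ratio <- sum(counts) / sum(doses)
  expect_lt(abs(slope["Estimate"] - ratio), 3 * slope["Std. Error"])
})

test_that("blank scans are Poisson in count and uniform over crystal pairs", {
  g <- build_geometry("closed_ring")
  rate <- 500; dur <- 60
  bl <- simulate_blank(g, dur, rate, seed = 7)
  expect_true(all(bl$truth_class == "random"))
  expect_lt(abs(nrow(bl) - rate * dur), 3 * sqrt(rate * dur) + 1)
  expect_true(all(bl$crystal_a != bl$crystal_b))
  # chi-square uniformity at detector-pair granularity
  bl2 <- simulate_blank(g, 120, 1000, seed = 8)
  da <- (pmin(bl2$crystal_a, bl2$crystal_b) - 1) %/% 32 + 1
  db <- (pmax(bl2$crystal_a, bl2$crystal_b) - 1) %/% 32 + 1
  key <- paste(pmin(da, db), pmax(da, db))
  lev <- c(outer(1:20, 1:20, function(i, j)
    ifelse(i <= j, paste(i, j), NA)))
  lev <- lev[!is.na(lev)]
  obs <- table(factor(key, levels = lev))
  # expected pair weights: within-detector C(32,2), across 32*32
  ij <- do.call(rbind, strsplit(lev, " "))
  w <- ifelse(ij[, 1] == ij[, 2], 32 * 31 / 2, 32 * 32)
  pval <- suppressWarnings(chisq.test(obs, p = w / sum(w))$p.value)
  expect_gt(pval, 1e-4)
  expect_equal(nrow(simulate_blank(g, 0, rate)), 0)
})

test_that("scatter model deflects and degrades tagged events", {
  g <- build_geometry("closed_ring")
  ph <- build_phantom("air")
  act <- build_activity(ph, model_params = list(model = "point"))
  acq <- quick_acq(20000, seed = 11, scatter_fraction = 0.3)
  ev <- simulate_listmode(g, ph, act, acq, dose_mu = 1)
  sc <- ev[ev$truth_class == "scatter", ]
  expect_gt(nrow(sc), 0.2 * nrow(ev))
  expect_true(all(sc$energy_b_kev <= 511))
  expect_true(all(sc$energy_b_kev >= 250))
})
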