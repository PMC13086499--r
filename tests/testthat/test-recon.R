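test_that("forward projection matches an independent exact clipping oracle", {
  g <- build_geometry("closed_ring")
  set.seed(21)
  sp <- recon_spec(16, 20, 1, 1)
  img <- rangepet:::new_image(matrix(runif(256), 16, 16), 20)
  pairs <- rangepet:::active_pairs(g)
  pairs <- pairs[sample(nrow(pairs), 40), ]
  co <- rangepet:::lor_coords(g, pairs[, 1], pairs[, 2])
  fp <- forward_project(img, g, pairs)
  oracle <- vapply(seq_len(40), function(i) {
    w <- chord_lengths_oracle(co$x0[i], co$y0[i], co$x1[i], co$y1[i],
                              16, 20, -160, -160)
    sum(w * img$intensity)
  }, 0)
  expect_equal(fp, oracle, tolerance = 1e-9)
  # uniform unit image: line integral equals the chord length
  ones <- rangepet:::new_image(matrix(1, 16, 16), 20)
  fp1 <- forward_project(ones, g, pairs)
  oracle1 <- vapply(seq_len(40), function(i)
    sum(chord_lengths_oracle(co$x0[i], co$y0[i], co$x1[i], co$y1[i],
                             16, 20, -160, -160)), 0)
  expect_equal(fp1, oracle1, tolerance = 1e-9)
})

test_that("back projection is the exact adjoint of forward projection", {
  g <- build_geometry("open_ring")
  set.seed(22)
  sp <- recon_spec(16, 20, 1, 1)
  pairs <- rangepet:::active_pairs(g)
  pairs <- pairs[sample(nrow(pairs), 800), ]
  x <- rangepet:::new_image(matrix(runif(256), 16, 16), 20)
  y <- runif(800)
  lhs <- sum(forward_project(x, g, pairs) * y)
  rhs <- sum(x$intensity * back_project(y, g, pairs, sp)$intensity)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  # zero input backprojects to a zero image
  expect_true(all(back_project(rep(0, 800), g, pairs, sp)$intensity == 0))
})

test_that("event histogramming counts each line of response", {
  g <- build_geometry("open_ring")
  empty <- rangepet:::empty_event_list()
  expect_equal(nrow(histogram_events(empty, g)), 0)
  ev <- synthetic_events(400, seed = 23)
  sg <- histogram_events(ev, g)
  expect_equal(sum(sg$count), 400)
  expect_true(all(sg$a < sg$b))
  bad <- ev; bad$crystal_a[1] <- 1L  # detector 1 is removed in open ring
  expect_error(histogram_events(bad, g), "unknown or inactive")
})

test_that("sensitivity is radially symmetric closed and reduced open", {
  sp <- recon_spec()
  s_cl <- sensitivity_image(build_geometry("closed_ring"), sp)
  s_op <- sensitivity_image(build_geometry("open_ring"), sp)
  n <- sp$grid_n
  xc <- s_cl$x_centers_mm
  R2 <- outer(xc^2, xc^2, `+`)
  ring <- R2 >= 55^2 & R2 <= 65^2
  cv <- sd(s_cl$intensity[ring]) / mean(s_cl$intensity[ring])
  expect_lt(cv, 0.10)
  expect_true(all(s_op$intensity <= s_cl$intensity + 1e-9))
  expect_true(all(s_cl$intensity[R2 <= 160^2] > 0))
  expect_true(all(s_op$intensity[R2 <= 160^2] > 0))
})

test_that("MLEM concentrates a point, conserves counts, and OSEM agrees", {
  g <- build_geometry("closed_ring")
  ph <- build_phantom("air")
  act <- build_activity(ph, model_params = list(model = "point",
                                                x_mm = 30, y_mm = -20,
                                                sigma_mm = 1e-6))
  ev <- simulate_listmode(g, ph, act, quick_acq(20000, seed = 24),
                          dose_mu = 1)
  sg <- histogram_events(ev, g)
  sp <- recon_spec(n_subsets = 1, n_iterations = 20)
  img <- osem_reconstruct(sg, g, sp, track_likelihood = TRUE)
  expect_true(all(img$intensity >= 0))
  # mass concentrates around the source
  xc <- img$x_centers_mm
  near <- outer(abs(xc - 30) <= 6, abs(xc + 20) <= 6, "&")
  expect_gt(sum(img$intensity[near]) / sum(img$intensity), 0.9)
  # count conservation at the MLEM fixed-point update
  cb <- attr(img, "count_balance")
  expect_lt(max(abs(cb - attr(img, "total_counts"))) /
              attr(img, "total_counts"), 1e-6)
  # OSEM accelerates the same estimate
  img5 <- osem_reconstruct(sg, g, recon_spec(n_subsets = 5,
                                             n_iterations = 4))
  expect_gt(cor(as.numeric(img5$intensity), as.numeric(img$intensity)),
            0.95)
  expect_warning(osem_reconstruct(histogram_events(
    rangepet:::empty_event_list(), g), g, sp), "empty sinogram")
})

test_that("band combination reduces images to beam-axis profiles", {
  m <- matrix(1, 160, 160)
  img <- rangepet:::new_image(m, 2)
  p0 <- combine_band(img, 0)
  expect_equal(nrow(p0), 160)
  expect_true(all(p0$intensity == 1))
  p9 <- combine_band(img, 9)
  expect_true(all(p9$intensity == p9$intensity[1]))
  expect_equal(p9$intensity[1], sum(abs(img$x_centers_mm) <= 9))
  expect_error(combine_band(img, 9, center_mm = 400), "outside")
  # a Gaussian beam of sigma 4.5 mm is mostly inside a 9 mm band
  gm <- exp(-outer(rep(1, 160), img$x_centers_mm^2) / (2 * 4.5^2))
  gimg <- rangepet:::new_image(gm, 2)
  expect_gt(sum(combine_band(gimg, 9)$intensity) / sum(gm), 0.95)
})

test_that("open and closed ring reconstructions localise the same edge", {
  setup <- lucite_setup(dose_mu = 3)
  gcl <- build_geometry("closed_ring")
  acq <- quick_acq(92000, seed = 25)
  ev <- select_coincidences(
    simulate_listmode(gcl, setup$phantom, setup$activity, acq, dose_mu = 3))
  det_a <- (ev$crystal_a - 1) %/% 32 + 1
  det_b <- (ev$crystal_b - 1) %/% 32 + 1
  open_ok <- !(det_a %in% c(1, 11)) & !(det_b %in% c(1, 11))
  ev_op <- rangepet:::as_event_list(as.data.frame(ev)[open_ok, ],
                                    resort = FALSE)
  go <- build_geometry("open_ring")
  sp <- recon_spec(n_subsets = 1, n_iterations = 10)
  e_cl <- measure_ar(combine_band(reconstruct_events(ev, gcl, sp), 9))
  e_op <- measure_ar(combine_band(reconstruct_events(ev_op, go, sp), 9))
  expect_lt(abs(e_cl$distal_edge50 - e_op$distal_edge50), 1.0)
})
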