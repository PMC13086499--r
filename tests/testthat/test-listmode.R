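test_that("window selection keeps exactly the in-window events", {
  mk <- function(ea, eb, dt) {
    rangepet:::as_event_list(data.frame(
      event_id = 1L, crystal_a = 1L, crystal_b = 400L,
      energy_a_kev = ea, energy_b_kev = eb, t_a_ns = 0, t_b_ns = dt,
      truth_class = "true"), resort = FALSE)
  }
  w <- window_spec()
  expect_equal(nrow(select_coincidences(mk(511, 511, 0), w)), 1)
  expect_equal(nrow(select_coincidences(mk(300, 511, 0), w)), 0)
  expect_equal(nrow(select_coincidences(mk(511, 511, 15), w)), 0)
  expect_equal(nrow(select_coincidences(mk(350, 650, 10), w)), 1)
})

test_that("selection is idempotent and monotone in window width", {
  ev <- synthetic_events(500, seed = 3)
  w <- window_spec()
  s1 <- select_coincidences(ev, w)
  expect_equal(as.data.frame(select_coincidences(s1, w)),
               as.data.frame(s1))
  wide_e <- window_spec(250, 750, 20)
  wide_t <- window_spec(350, 650, 40)
  expect_gte(nrow(select_coincidences(ev, wide_e)), nrow(s1))
  expect_gte(nrow(select_coincidences(ev, wide_t)), nrow(s1))
})

test_that("equal-count splitting partitions contiguously with balanced sizes", {
  ev <- synthetic_events(9000, seed = 4)
  parts <- split_equal_count(ev, 9)
  expect_equal(vapply(parts, nrow, 0), rep(1000, 9))
  ev10 <- synthetic_events(10, seed = 5)
  expect_equal(vapply(split_equal_count(ev10, 3), nrow, 0), c(4, 3, 3))
  expect_identical(as.data.frame(split_equal_count(ev10, 1)[[1]]),
                   as.data.frame(ev10))
  # contiguous in time and exact union
  re <- do.call(rbind, lapply(parts, as.data.frame))
  expect_equal(re$t_a_ns, ev$t_a_ns)
  expect_error(split_equal_count(ev10, 11), "cannot split")
})

test_that("temporal sub-sampling is an exact round-robin partition", {
  ev <- synthetic_events(1000, seed = 6)
  subs <- subsample_temporal(ev, 25)
  expect_length(subs, 25)
  expect_equal(sum(vapply(subs, nrow, 0)), 1000)
  expect_lte(diff(range(vapply(subs, nrow, 0))), 1)
  # reassembling by interleaving recovers the input multiset exactly
  re <- do.call(rbind, lapply(subs, as.data.frame))
  expect_equal(sort(re$t_a_ns), ev$t_a_ns)
  expect_identical(as.data.frame(subsample_temporal(ev, 1)[[1]]),
                   as.data.frame(ev))
  expect_error(subsample_temporal(ev, 0), "denominator")
  expect_error(subsample_temporal(ev, 25, 5), "n_subsets")
  # each subset samples the full acquisition window evenly: subset mean
  # rates agree within Poisson scatter
  spans <- vapply(subs, function(s) diff(range(s$t_a_ns)), 0)
  expect_gt(min(spans) / max(spans), 0.8)
})

test_that("background injection preserves counts and the time window", {
  base <- synthetic_events(800, seed = 7)
  g <- build_geometry("closed_ring")
  blank <- simulate_blank(g, 60, 200, seed = 8)
  expect_identical(inject_background(base, blank, 0), base)
  merged <- inject_background(base, blank, 60, seed = 1)
  expect_equal(nrow(merged), nrow(base) + nrow(blank))
  expect_true(!is.unsorted(merged$t_a_ns))
  expect_true(all(merged$t_a_ns <= max(base$t_a_ns) + 1))
  # partial injection takes only the early blank events
  part <- inject_background(base, blank, 20, seed = 1)
  n20 <- sum(blank$t_a_ns <= 20e9)
  expect_equal(nrow(part), nrow(base) + n20)
  # injected timestamps are remapped but time differences survive
  # timestamps are ~6e10 ns, so recovered differences carry ~1e-5 ns
  # double rounding
  expect_lt(max(abs(sort(merged$t_b_ns - merged$t_a_ns) -
                      sort(c(base$t_b_ns - base$t_a_ns,
                             blank$t_b_ns - blank$t_a_ns)))), 1e-3)
})
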