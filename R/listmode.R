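#' Energy / timing window specification
#'
#' @param energy_low_kev,energy_high_kev photon energy window bounds, keV
#'   (defaults 350 and 650).
#' @param timing_full_width_ns coincidence timing window full width, ns
#'   (default 20: events kept when `|t_a - t_b| <= 10` ns).
#' @return a `window_spec` list.
#' @export
window_spec <- function(energy_low_kev = 350, energy_high_kev = 650,
                        timing_full_width_ns = 20) {
  stopifnot(energy_low_kev < energy_high_kev, timing_full_width_ns > 0)
  structure(list(energy_low_kev = energy_low_kev,
                 energy_high_kev = energy_high_kev,
                 timing_full_width_ns = timing_full_width_ns),
            class = "window_spec")
}

#' Select coincidences by energy and timing windows
#'
#' Keeps events whose both photon energies fall inside the energy window
#' and whose time difference satisfies
#' `|t_a - t_b| <= timing_full_width_ns / 2`. Order is preserved.
#'
#' @param events an `event_list`.
#' @param w a [window_spec()].
#' @return the filtered `event_list` (event ids renumbered).
#' @export
select_coincidences <- function(events, w = window_spec()) {
  keep <- events$energy_a_kev >= w$energy_low_kev &
    events$energy_a_kev <= w$energy_high_kev &
    events$energy_b_kev >= w$energy_low_kev &
    events$energy_b_kev <= w$energy_high_kev &
    abs(events$t_a_ns - events$t_b_ns) <= w$timing_full_width_ns / 2
  as_event_list(as.data.frame(events)[keep, , drop = FALSE], resort = FALSE)
}

#' Split an event list into k equal-count subsets
#'
#' Contiguous-in-time partition into `k` subsets whose sizes differ by at
#' most one (remainder events go to the earliest subsets); the union is
#' exactly the input.
#'
#' @param events a time-sorted `event_list`.
#' @param k number of subsets (`1 <= k <= nrow(events)`).
#' @return list of `k` event_lists.
#' @export
split_equal_count <- function(events, k) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  n <- nrow(events)
  if (k > n) stop("cannot split ", n, " events into ", k, " subsets")
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  lapply(seq_len(k), function(i)
    as_event_list(as.data.frame(events)[starts[i]:stops[i], , drop = FALSE],
                  resort = FALSE))
}

#' Evenly sub-sample an event list in time
#'
#' Round-robin assignment on the time-sorted events: event `i` (0-based)
#' goes to subset `i mod denominator`. Each subset is an even 1/denominator
#' sample of the acquisition (a dose-equivalent sub-dataset); the subsets
#' are statistically interchangeable and their union is exactly the input.
#'
#' @param events a time-sorted `event_list`.
#' @param denominator sub-sampling factor (e.g. 25 turns a 25 MU
#'   acquisition into 25 sub-datasets of equivalent 1 MU dose).
#' @param n_subsets number of subsets to return; must equal `denominator`.
#' @return list of `denominator` event_lists.
#' @export
subsample_temporal <- function(events, denominator, n_subsets = denominator) {
  denominator <- as.integer(denominator)
  if (denominator < 1) stop("denominator must be >= 1")
  if (n_subsets != denominator)
    stop("n_subsets must equal denominator")
  grp <- (seq_len(nrow(events)) - 1L) %% denominator
  df <- as.data.frame(events)
  lapply(0:(denominator - 1L), function(g)
    as_event_list(df[grp == g, , drop = FALSE], resort = FALSE))
}

#' Inject blank-scan background into an event list
#'
#' Appends the blank-scan events whose timestamps fall within the first
#' `blank_seconds` of the blank acquisition, remapping their timestamps
#' uniformly (seeded) over the base acquisition window so the merged data
#' remain a valid time series, then re-sorts by time.
#'
#' @param base the base `event_list`.
#' @param blank a blank-scan `event_list` (timestamps starting near 0).
#' @param blank_seconds seconds of blank scan to inject (0 = none).
#' @param seed seed for the timestamp remapping.
#' @return merged, time-sorted `event_list`.
#' @export
inject_background <- function(base, blank, blank_seconds, seed = 1L) {
  if (blank_seconds <= 0 || nrow(blank) == 0) return(base)
  sel <- blank$t_a_ns <= blank_seconds * 1e9
  add <- as.data.frame(blank)[sel, , drop = FALSE]
  if (nrow(add)) {
    t0 <- min(base$t_a_ns, 0)
    t1 <- if (nrow(base)) max(base$t_a_ns) else blank_seconds * 1e9
    dt <- add$t_b_ns - add$t_a_ns
    add$t_a_ns <- with_seed(substream_seed(seed, "inject"),
                            runif(nrow(add), t0, t1))
    add$t_b_ns <- add$t_a_ns + dt
  }
  as_event_list(rbind(as.data.frame(base), add))
}
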