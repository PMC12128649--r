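# flatten params + geometry into the scalar list the compiled engine takes
engine_pars <- function(params, geom = clutch_geometry(params)) {
  list(
    n_c = params$n_c, n_m = params$n_m,
    F_m = params$F_m, v_u = params$v_u, F_b = params$F_b,
    k_on = params$k_on, k_off = params$k_off, k_c = params$k_c,
    k_s = params$k_s, k_s_eps0 = params$k_s_eps0,
    l = params$l, l_prime = geom$l_prime, F0 = geom$F0, x0 = geom$x0,
    canonical = identical(params$model_variant, "canonical"),
    bell_signed = identical(params$bell_force, "signed"),
    load_share = identical(params$bell_load, "shared")
  )
}

#' Exponential event time from a uniform variate
#'
#' Inverse-CDF draw of the waiting time to the next event of a Poisson
#' process with the given rate: `t = -log(u) / rate`. This is the elementary
#' draw behind the first-reaction scheduling of clutch engagement and
#' disengagement events.
#'
#' @param rate Event rate (1/s), > 0.
#' @param u Uniform variate in the open interval (0, 1); vectorised.
#' @return Waiting time(s), s.
#' @examples
#' draw_event_time(0.3, 0.5)    # log(2) / 0.3
#' @export
draw_event_time <- function(rate, u) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate <= 0)) {
    stop("`rate` must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(u) || any(!is.finite(u)) || any(u <= 0) || any(u >= 1)) {
    stop("`u` must lie strictly inside (0, 1)", call. = FALSE)
  }
  -log(u) / rate
}

#' Initial state of the clutch ensemble
#'
#' All clutches disengaged and pinned at the clutch-free equilibrium of the
#' anchorage (the origin, except in the transverse configuration where the
#' residual force pre-displaces the substrate), with the motors running at
#' their unloaded velocity.
#'
#' @param params A [clutch_params()] object.
#' @return An object of class `clutch_state`: list with fields `t`, `x_s`,
#'   `x_c`, `engaged`, `v_f`.
#' @export
initial_clutch_state <- function(params) {
  geom <- clutch_geometry(params)
  xs0 <- solve_equilibrium(numeric(0), params, geom)
  st <- list(
    t = 0, x_s = xs0, x_c = rep(xs0, params$n_c),
    engaged = rep(FALSE, params$n_c),
    v_f = hill_velocity(substrate_force(xs0, params, geom) - geom$F0, params)
  )
  class(st) <- "clutch_state"
  st
}

#' Advance the clutch ensemble by one stochastic event
#'
#' Executes a single iteration of the first-reaction scheme: draws a
#' candidate event time for every clutch (engagement at rate `k_on` if
#' disengaged, disengagement at the force-dependent Bell rate if engaged),
#' advances time by the minimum, advects the engaged clutches by the
#' retrograde flow over that interval, flips the winning clutch, re-solves
#' the substrate force balance and recomputes the flow velocity. Uses the
#' current R random-number stream; call [set.seed()] beforehand for
#' reproducibility.
#'
#' @param state A `clutch_state`, e.g. from [initial_clutch_state()].
#' @param params A [clutch_params()] object.
#' @return The post-event `clutch_state`.
#' @examples
#' p <- clutch_params(n_c = 1)
#' set.seed(1)
#' clutch_step(initial_clutch_state(p), p)   # first event must engage
#' @export
clutch_step <- function(state, params) {
  stopifnot(inherits(state, "clutch_state"))
  res <- .clutch_engine(engine_pars(params), 1L, FALSE, state)
  st <- res$state
  class(st) <- "clutch_state"
  st
}

#' @export
print.clutch_state <- function(x, ...) {
  cat(sprintf("<clutch_state> t = %.4g s, x_s = %.4g nm, engaged %d/%d, v_f = %.4g nm/s\n",
              x$t, x$x_s, sum(x$engaged), length(x$engaged), x$v_f))
  invisible(x)
}

#' Run a motor-clutch Gillespie simulation
#'
#' Simulates a fixed budget of engagement/disengagement events from the
#' all-disengaged initial state, using the first-reaction method with fresh
#' exponential draws for every clutch at every iteration. The same
#' `(params, n_events, seed)` triple always reproduces the identical trace.
#'
#' @param params A [clutch_params()] object.
#' @param n_events Number of stochastic events to simulate (>= 0).
#' @param seed Optional integer seed passed to [set.seed()]; if `NULL` the
#'   current RNG stream is used.
#' @param record Keep the full per-event trace (`TRUE`, the default) or only
#'   running summary statistics (`FALSE`, much lighter for sweeps).
#' @param burn_in Averaging window: `"first-failure"` (default) discards
#'   everything up to the first time the engaged count returns to zero,
#'   removing the deterministic loading ramp; `"none"` averages the whole
#'   trace. If no failure occurs the whole trace is used.
#' @return An object of class `clutch_sim` with elements `trace` (a tibble,
#'   one row per event, or `NULL` when `record = FALSE`), `failure_times`,
#'   `summary` (one-row tibble of time-weighted means, see [glance()]),
#'   `final_state`, and the run's provenance (`params`, `seed`, `n_events`,
#'   `burn_in`).
#' @examples
#' sim <- run_clutch_simulation(clutch_params(n_c = 20), n_events = 500, seed = 1)
#' glance(sim)
#' @export
run_clutch_simulation <- function(params, n_events = 10000, seed = NULL,
                                  record = TRUE,
                                  burn_in = c("first-failure", "none")) {
  stopifnot(inherits(params, "clutch_params"))
  burn_in <- match.arg(burn_in)
  n_events <- as.integer(n_events)
  stopifnot(length(n_events) == 1L, !is.na(n_events), n_events >= 0L)
  if (!is.null(seed)) set.seed(seed)

  geom <- clutch_geometry(params)
  res <- .clutch_engine(engine_pars(params, geom), n_events, record, NULL)

  trace <- NULL
  if (record) {
    trace <- as_tibble(res$trace)
    trace$event <- c("disengage", "init", "engage")[trace$event + 2L]
    trace$clutch[trace$event == "init"] <- NA_integer_
  }

  summary <- summarize_accumulators(res, burn_in)
  out <- list(
    trace = trace,
    failure_times = res$failure_times,
    summary = summary,
    final_state = structure(res$state, class = "clutch_state"),
    params = params, geom = geom,
    seed = seed, n_events = n_events, burn_in = burn_in
  )
  class(out) <- "clutch_sim"
  out
}

# pick the averaging window from the engine's running accumulators
summarize_accumulators <- function(res, burn_in) {
  tot <- res$acc_total
  use_burn <- identical(burn_in, "first-failure") && !is.na(res$t_burn) &&
    res$t_end > res$t_burn
  if (use_burn) {
    b <- res$acc_at_burn
    acc <- lapply(names(tot), function(f) tot[[f]] - b[[f]])
    names(acc) <- names(tot)
    window_start <- res$t_burn
  } else {
    acc <- tot
    window_start <- 0
  }
  dur <- acc$duration
  ft <- res$failure_times
  tibble(
    mean_v_f = if (dur > 0) acc$vf / dur else NA_real_,
    mean_x_s = if (dur > 0) acc$xs / dur else NA_real_,
    mean_traction_force = if (dur > 0) acc$Fs / dur else NA_real_,
    mean_engaged = if (dur > 0) acc$engaged / dur else NA_real_,
    mean_clutch_force = if (dur > 0) acc$Fc / dur else NA_real_,
    mean_cycle_time = cycle_time(ft),
    n_failures = length(ft),
    window_start = window_start,
    duration = dur
  )
}

# mean spacing of successive global-failure events; NA when fewer than two
cycle_time <- function(failure_times) {
  if (length(failure_times) < 2L) return(NA_real_)
  mean(diff(failure_times))
}

#' Recompute the summary of a recorded trace
#'
#' Time-weighted means of the retrograde flow, substrate position, traction
#' force, engaged count and total clutch force over a recorded trace, with
#' the same burn-in conventions as [run_clutch_simulation()]. Each
#' inter-event interval is weighted by its duration and carries the state
#' that held during it. This is an independent R-level computation from the
#' stored trace and must agree with the engine's running accumulators.
#'
#' @param sim A `clutch_sim` with a recorded trace.
#' @param burn_in `"first-failure"` or `"none"`; defaults to the run's own
#'   setting.
#' @return A one-row tibble with the same columns as `glance(sim)`.
#' @export
summarize_trace <- function(sim, burn_in = sim$burn_in) {
  stopifnot(inherits(sim, "clutch_sim"))
  if (is.null(sim$trace)) {
    stop("this simulation was run with `record = FALSE`; no trace to summarize",
         call. = FALSE)
  }
  burn_in <- match.arg(burn_in, c("first-failure", "none"))
  tr <- sim$trace
  n <- nrow(tr)
  if (n < 2L) {
    stop("trace has no inter-event interval to average", call. = FALSE)
  }
  dt <- diff(tr$t)
  start <- 0
  ft <- sim$failure_times
  if (identical(burn_in, "first-failure") && length(ft) > 0 &&
      max(tr$t) > ft[1]) {
    start <- ft[1]
  }
  keep <- tr$t[-n] >= start
  w <- dt[keep]
  wmean <- function(x) sum(w * x[-n][keep]) / sum(w)
  tibble(
    mean_v_f = wmean(tr$v_f),
    mean_x_s = wmean(tr$x_s),
    mean_traction_force = wmean(tr$F_s),
    mean_engaged = wmean(tr$engaged),
    mean_clutch_force = wmean(tr$F_clutch_total),
    mean_cycle_time = cycle_time(ft),
    n_failures = length(ft),
    window_start = start,
    duration = sum(w)
  )
}

#' @export
print.clutch_sim <- function(x, ...) {
  cat("<clutch_sim>\n")
  cat(sprintf("  %s model, %s strain (eps0 = %g), n_c = %d, k_s = %g pN/nm\n",
              x$params$model_variant, x$params$strain_mode, x$params$eps0,
              x$params$n_c, x$params$k_s))
  cat(sprintf("  %d events over %.4g s, %d global failures%s\n",
              x$n_events, x$final_state$t, length(x$failure_times),
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  s <- x$summary
  cat(sprintf("  mean v_f = %.4g nm/s, mean traction = %.4g pN, mean engaged = %.4g\n",
              s$mean_v_f, s$mean_traction_force, s$mean_engaged))
  invisible(x)
}

#' @rdname run_clutch_simulation
#' @param x,object A `clutch_sim` object.
#' @param ... Unused.
#' @export
glance.clutch_sim <- function(x, ...) {
  x$summary
}

#' @rdname run_clutch_simulation
#' @export
tidy.clutch_sim <- function(x, ...) {
  if (is.null(x$trace)) {
    stop("this simulation was run with `record = FALSE`; no trace to tidy",
         call. = FALSE)
  }
  x$trace
}

#' @rdname run_clutch_simulation
#' @export
autoplot.clutch_sim <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("this simulation was run with `record = FALSE`; nothing to plot",
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    dplyr::select(object$trace, "t", "x_s", "engaged", "v_f"),
    cols = c("x_s", "engaged", "v_f"),
    names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(long$quantity, levels = c("x_s", "engaged", "v_f"),
                          labels = c("substrate position (nm)",
                                     "engaged clutches",
                                     "retrograde flow (nm/s)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
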