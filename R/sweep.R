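#' Logarithmically spaced grid of clutch counts
#'
#' Integer grid obtained by rounding a geometric progression between `lo`
#' and `hi`; both endpoints are always included. Rounding collisions at
#' small counts are deduplicated with a warning, so the returned grid may be
#' shorter than `n`.
#'
#' @param lo,hi Smallest and largest clutch count (integers, `1 <= lo < hi`).
#' @param n Number of grid points requested (>= 2).
#' @return Strictly increasing integer vector.
#' @examples
#' log_spaced_grid(10, 1000, 3)   # 10, 100, 1000
#' log_spaced_grid(10, 200, 25)
#' @export
log_spaced_grid <- function(lo, hi, n) {
  stopifnot(is.numeric(lo), is.numeric(hi), is.numeric(n),
            length(lo) == 1L, length(hi) == 1L, length(n) == 1L)
  if (lo < 1 || lo >= hi || n < 2) {
    stop("need 1 <= lo < hi and n >= 2", call. = FALSE)
  }
  g <- round(exp(seq(log(lo), log(hi), length.out = n)))
  out <- unique(as.integer(g))
  if (length(out) < n) {
    warning("log-spaced grid has rounding collisions; returning ",
            length(out), " distinct counts instead of ", n, call. = FALSE)
  }
  out
}

#' Sweep the clutch number and measure mean retrograde flow
#'
#' Runs one Gillespie simulation per `(n_c, seed)` pair, with the motor
#' count tracking the clutch count at every grid point, and averages the
#' post-burn-in mean retrograde flow across seeds. The resulting flow-versus-
#' `n_c` curve is biphasic, and its spline-interpolated minimum defines the
#' optimal clutch number (see [optimal_nc()]).
#'
#' @param params A [clutch_params()] object; its `n_c` is overridden by the
#'   grid values.
#' @param nc_grid Integer vector of clutch counts, e.g. from
#'   [log_spaced_grid()].
#' @param n_events Event budget per run.
#' @param seeds Integer vector of seeds; one run per seed per grid point,
#'   averaged before interpolation.
#' @param burn_in Passed to [run_clutch_simulation()].
#' @return An object of class `clutch_sweep` with elements `runs` (tibble:
#'   `n_c`, `seed`, `mean_v_f`, plus the other per-run summary columns),
#'   `curve` (tibble: `n_c`, `mean_v_f` averaged over seeds), `optimum`
#'   (one-row tibble from [optimal_nc()]) and provenance fields.
#' @examples
#' p <- clutch_params(k_s = 1, model_variant = "canonical")
#' sw <- sweep_nc(p, nc_grid = log_spaced_grid(10, 400, 6),
#'                n_events = 1000, seeds = 1)
#' glance(sw)
#' @export
sweep_nc <- function(params, nc_grid, n_events = 20000, seeds = 1:3,
                     burn_in = "first-failure") {
  stopifnot(inherits(params, "clutch_params"),
            is.numeric(nc_grid), length(nc_grid) >= 1,
            all(nc_grid >= 1), !is.unsorted(nc_grid, strictly = TRUE))
  grid <- tidyr::expand_grid(n_c = as.integer(nc_grid),
                             seed = as.integer(seeds))
  runs <- purrr::pmap(grid, function(n_c, seed) {
    p <- params
    p$n_c <- n_c
    p$n_m <- n_c
    sim <- tryCatch(
      run_clutch_simulation(p, n_events = n_events, seed = seed,
                            record = FALSE, burn_in = burn_in),
      error = function(e) e
    )
    if (inherits(sim, "error")) {
      warning("run at n_c = ", n_c, ", seed = ", seed, " failed (",
              conditionMessage(sim), "); excluded from the sweep",
              call. = FALSE)
      return(NULL)
    }
    dplyr::bind_cols(tibble(n_c = n_c, seed = seed), glance(sim))
  })
  runs <- dplyr::bind_rows(purrr::compact(runs))
  if (nrow(runs) == 0L) stop("every run in the sweep failed", call. = FALSE)

  curve <- dplyr::summarise(
    dplyr::group_by(runs, .data$n_c),
    mean_v_f = mean(.data$mean_v_f),
    .groups = "drop"
  )
  out <- list(
    runs = runs,
    curve = curve,
    optimum = spline_argmin(curve$n_c, curve$mean_v_f),
    params = params, n_events = n_events, seeds = as.integer(seeds),
    burn_in = burn_in
  )
  class(out) <- "clutch_sweep"
  out
}

# cubic-spline argmin of mean flow over log(n_c); dense scan + local refine
spline_argmin <- function(nc, vf, n_dense = 10000L) {
  stopifnot(length(nc) == length(vf), !is.unsorted(nc, strictly = TRUE))
  if (length(nc) < 4L) {
    i <- which.min(vf)
    return(tibble(optimal_nc = as.numeric(nc[i]), min_v_f = vf[i],
                  boundary = i %in% c(1L, length(nc))))
  }
  lx <- log(nc)
  sf <- splinefun(lx, vf, method = "fmm")
  xs <- seq(min(lx), max(lx), length.out = n_dense)
  ys <- sf(xs)
  i <- which.min(ys)
  boundary <- i %in% c(1L, n_dense)
  if (!boundary) {
    opt <- optimize(sf, interval = c(xs[i - 1L], xs[i + 1L]))
    x_opt <- opt$minimum
    y_opt <- opt$objective
  } else {
    x_opt <- xs[i]
    y_opt <- ys[i]
  }
  tibble(optimal_nc = exp(x_opt), min_v_f = y_opt, boundary = boundary)
}

#' Optimal clutch number of a sweep
#'
#' Interpolates the mean retrograde flow against `log(n_c)` with a cubic
#' spline, scans a dense grid for the global minimum and refines it locally.
#' The minimising clutch count (generally non-integer) is the model's
#' readout of the adhesion size a cell would assemble on that substrate.
#' A curve whose minimum sits on the edge of the grid is flagged
#' `boundary = TRUE`; ties resolve to the smallest count. Fewer than four
#' grid points fall back to the gridded minimum.
#'
#' @param x A `clutch_sweep`, or a numeric vector of clutch counts.
#' @param ... Unused for sweeps; for the default method, `vf` is the mean
#'   flow at each count.
#' @return One-row tibble: `optimal_nc`, `min_v_f`, `boundary`.
#' @examples
#' nc <- log_spaced_grid(10, 1000, 9)
#' vf <- (log(nc) - log(60))^2 + 10   # synthetic biphasic curve
#' optimal_nc(nc, vf)
#' @export
optimal_nc <- function(x, ...) UseMethod("optimal_nc")

#' @rdname optimal_nc
#' @export
optimal_nc.clutch_sweep <- function(x, ...) {
  x$optimum
}

#' @rdname optimal_nc
#' @param vf Mean retrograde flow at each clutch count (default method).
#' @export
optimal_nc.default <- function(x, vf, ...) {
  spline_argmin(as.numeric(x), as.numeric(vf))
}

#' @export
print.clutch_sweep <- function(x, ...) {
  cat("<clutch_sweep>\n")
  cat(sprintf("  %s model, %s strain (eps0 = %g), k_s = %g pN/nm\n",
              x$params$model_variant, x$params$strain_mode, x$params$eps0,
              x$params$k_s))
  cat(sprintf("  grid: %d clutch counts in [%d, %d], %d seed(s), %d events/run\n",
              nrow(x$curve), min(x$curve$n_c), max(x$curve$n_c),
              length(x$seeds), x$n_events))
  o <- x$optimum
  cat(sprintf("  optimal n_c = %.4g (min mean v_f = %.4g nm/s)%s\n",
              o$optimal_nc, o$min_v_f,
              if (o$boundary) " [boundary minimum]" else ""))
  invisible(x)
}

#' @rdname sweep_nc
#' @param x,object A `clutch_sweep` object.
#' @param ... Unused.
#' @export
tidy.clutch_sweep <- function(x, ...) {
  x$runs
}

#' @rdname sweep_nc
#' @export
glance.clutch_sweep <- function(x, ...) {
  dplyr::bind_cols(
    x$optimum,
    tibble(n_grid = nrow(x$curve), n_seeds = length(x$seeds),
           n_events = x$n_events, k_s = x$params$k_s,
           eps0 = x$params$eps0, strain_mode = x$params$strain_mode,
           model_variant = x$params$model_variant)
  )
}

#' @rdname sweep_nc
#' @export
autoplot.clutch_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$n_c, y = .data$mean_v_f)) +
    ggplot2::geom_point(data = object$runs, alpha = 0.35, size = 1) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimum$optimal_nc,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "number of clutches", y = "mean retrograde flow (nm/s)") +
    ggplot2::theme_minimal()
}

# normalized optima and secant-slope rates of change of a strain series
normalize_optima <- function(eps_levels, optima) {
  stopifnot(length(eps_levels) == length(optima),
            !is.unsorted(eps_levels, strictly = TRUE))
  if (eps_levels[1] != 0) {
    stop("the strain levels must include 0 as the normalization baseline",
         call. = FALSE)
  }
  normalized <- optima / optima[1]
  tibble(
    eps0 = eps_levels,
    optimal_nc = optima,
    normalized = normalized
  )
}

secant_slopes <- function(eps_levels, normalized) {
  tibble(
    eps0_from = eps_levels[-length(eps_levels)],
    eps0_to = eps_levels[-1],
    slope = diff(normalized) / diff(eps_levels)
  )
}

#' Optimal clutch number as a function of residual strain
#'
#' Repeats the clutch-number sweep at each residual-strain level, collects
#' the spline optima, normalises them by the zero-strain optimum and
#' computes the rates of change as slopes of the secant lines connecting
#' consecutive normalised points. This is the package's summary of how the
#' strain energy stored in the substrate shifts the optimal adhesion size.
#'
#' @param params A [clutch_params()] object (its `eps0` and `strain_mode`
#'   are overridden).
#' @param eps_levels Residual strain levels; must contain 0 (the
#'   normalisation baseline) and be strictly increasing.
#' @param mode `"axial"` or `"transverse"` strain orientation.
#' @param nc_grid,n_events,seeds,burn_in Passed to [sweep_nc()].
#' @return An object of class `clutch_strain_response` with elements
#'   `optima` (tibble: `eps0`, `optimal_nc`, `normalized`, `min_v_f`,
#'   `boundary`), `slopes` (tibble of secant slopes between consecutive
#'   strain levels), `sweeps` (list of the underlying `clutch_sweep`
#'   objects) and provenance fields.
#' @export
strain_response <- function(params, eps_levels, mode = c("axial", "transverse"),
                            nc_grid, n_events = 20000, seeds = 1:3,
                            burn_in = "first-failure") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(eps_levels), length(eps_levels) >= 2,
            !is.unsorted(eps_levels, strictly = TRUE))
  if (!any(eps_levels == 0)) {
    stop("`eps_levels` must include 0 (the normalization baseline)",
         call. = FALSE)
  }
  sweeps <- purrr::map(eps_levels, function(e) {
    p <- params
    p$eps0 <- e
    p$strain_mode <- if (e == 0) "none" else mode
    validate_clutch_params(p)
    sweep_nc(p, nc_grid = nc_grid, n_events = n_events, seeds = seeds,
             burn_in = burn_in)
  })
  optima_raw <- purrr::map_dbl(sweeps, function(s) s$optimum$optimal_nc)
  optima <- dplyr::bind_cols(
    normalize_optima(eps_levels, optima_raw),
    tibble(
      min_v_f = purrr::map_dbl(sweeps, function(s) s$optimum$min_v_f),
      boundary = purrr::map_lgl(sweeps, function(s) s$optimum$boundary)
    )
  )
  out <- list(
    optima = optima,
    slopes = secant_slopes(eps_levels, optima$normalized),
    sweeps = sweeps,
    mode = mode, params = params, nc_grid = nc_grid,
    n_events = n_events, seeds = as.integer(seeds)
  )
  class(out) <- "clutch_strain_response"
  out
}

#' @export
print.clutch_strain_response <- function(x, ...) {
  cat("<clutch_strain_response>\n")
  cat(sprintf("  %s residual strain, k_s = %g pN/nm, %d strain levels\n",
              x$mode, x$params$k_s, nrow(x$optima)))
  print(as.data.frame(x$optima), row.names = FALSE)
  invisible(x)
}

#' @rdname strain_response
#' @param x,object A `clutch_strain_response` object.
#' @param ... Unused.
#' @export
tidy.clutch_strain_response <- function(x, ...) {
  x$optima
}

#' @rdname strain_response
#' @export
glance.clutch_strain_response <- function(x, ...) {
  tibble(
    mode = x$mode, k_s = x$params$k_s,
    baseline_nc = x$optima$optimal_nc[1],
    max_increase_pct = 100 * (max(x$optima$normalized) - 1),
    n_levels = nrow(x$optima),
    n_events = x$n_events, n_seeds = length(x$seeds)
  )
}

#' @rdname strain_response
#' @export
autoplot.clutch_strain_response <- function(object, ...) {
  ggplot2::ggplot(object$optima,
                  ggplot2::aes(x = .data$eps0, y = .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "residual strain",
                  y = "optimal n_c (normalised to zero strain)") +
    ggplot2::theme_minimal()
}
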