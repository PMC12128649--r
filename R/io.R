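#' Named experiment presets
#'
#' Two bundles of run settings: `"paper-full"` is the full-budget protocol
#' (100,000 events per run, a single run per grid point) used for the
#' headline analyses, and `"desk"` is a reduced-budget protocol (20,000
#' events, 3 replicate seeds per grid point, averaged) that reproduces the
#' same optima to within a few tens of percent in minutes rather than hours.
#' Both use the standard molecular constants (the [clutch_params()]
#' defaults); the substrate stiffness is an experimental choice and must
#' always be supplied explicitly.
#'
#' @param name `"paper-full"` or `"desk"`.
#' @return List with fields `name`, `n_events`, `seeds`.
#' @seealso [default_nc_grid()]
#' @export
clutch_preset <- function(name = c("desk", "paper-full")) {
  name <- match.arg(name)
  switch(name,
    "paper-full" = list(name = name, n_events = 100000L, seeds = 1L),
    "desk" = list(name = name, n_events = 20000L, seeds = 1:3)
  )
}

#' Default clutch-count grid for a substrate stiffness
#'
#' The sweep grids used throughout the analyses: 25 log-spaced counts in
#' \[10, 200\] on the soft substrate (`k_s = 0.1` pN/nm) and 20 log-spaced
#' counts in \[10, 1000\] on the stiff one (`k_s = 1` pN/nm). Stiffnesses
#' up to 0.3 pN/nm use the soft grid.
#'
#' @param k_s Substrate spring constant (pN/nm).
#' @return Integer vector of clutch counts.
#' @export
default_nc_grid <- function(k_s) {
  if (k_s <= 0.3) log_spaced_grid(10, 200, 25) else log_spaced_grid(10, 1000, 20)
}

config_param_keys <- c("n_c", "k_s", "eps0", "strain_mode", "model_variant",
                       "F_m", "v_u", "F_b", "k_on", "k_off", "k_c",
                       "k_s_eps0", "l", "bell_load", "bell_force")
config_run_keys <- c("preset", "n_events", "seeds", "burn_in", "output_dir")

#' Load and validate a run configuration
#'
#' Reads a YAML mapping of model parameters and run settings, expands the
#' named preset (config values override preset values), and validates every
#' physical invariant through [clutch_params()]. Unknown keys are an error,
#' not a warning, so typos cannot silently fall back to defaults. The
#' substrate stiffness `k_s` has no default and must be present.
#'
#' @param path Path to a YAML config file.
#' @param overrides Named list applied on top of the file (used by the
#'   command-line interface for flag overrides).
#' @return An object of class `clutch_config`: list with `params`
#'   (a [clutch_params()]), `n_events`, `seeds`, `burn_in`, `output_dir`
#'   and `preset`.
#' @export
load_clutch_config <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg[names(overrides)] <- overrides

  unknown <- setdiff(names(cfg), c(config_param_keys, config_run_keys))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  preset <- clutch_preset(if (is.null(cfg$preset)) "desk" else cfg$preset)
  if (is.null(cfg$k_s)) {
    stop("config is missing the required field `k_s` (substrate stiffness, pN/nm)",
         call. = FALSE)
  }
  par_args <- cfg[intersect(names(cfg), config_param_keys)]
  params <- do.call(clutch_params, par_args)

  out <- list(
    params = params,
    n_events = as.integer(if (is.null(cfg$n_events)) preset$n_events else cfg$n_events),
    seeds = as.integer(if (is.null(cfg$seeds)) preset$seeds else cfg$seeds),
    burn_in = if (is.null(cfg$burn_in)) "first-failure" else
      match.arg(cfg$burn_in, c("first-failure", "none")),
    output_dir = cfg$output_dir,
    preset = preset$name
  )
  class(out) <- "clutch_config"
  out
}

#' Write and read simulation traces and summaries
#'
#' Traces are written as RFC-4180 CSV with a header row (one row per event:
#' time, event type, clutch index, substrate position, engaged count,
#' substrate force, retrograde flow, total clutch force); summaries as a
#' JSON sidecar carrying the parameters, seed and the time-weighted summary
#' statistics. Floats are serialised at full precision so a write-then-read
#' round trip reproduces the in-memory values exactly.
#'
#' @param sim A `clutch_sim` from [run_clutch_simulation()].
#' @param path Output file path.
#' @return `write_*` return `path` invisibly; `read_clutch_trace` returns a
#'   tibble, `read_clutch_summary` a list.
#' @name clutch_io
NULL

# render doubles with 17 significant digits so CSV round-trips exactly
fmt_full <- function(x) {
  out <- sub("^\\s+", "", sprintf("%.17g", x))
  out[is.na(x)] <- NA_character_
  out
}

#' @rdname clutch_io
#' @export
write_clutch_trace <- function(sim, path) {
  stopifnot(inherits(sim, "clutch_sim"))
  if (is.null(sim$trace)) {
    stop("simulation has no recorded trace", call. = FALSE)
  }
  tr <- sim$trace
  for (col in names(tr)) {
    if (is.double(tr[[col]])) tr[[col]] <- fmt_full(tr[[col]])
  }
  readr::write_csv(tr, path)
  invisible(path)
}

#' @rdname clutch_io
#' @export
read_clutch_trace <- function(path) {
  # base strtod parsing is correctly rounded, so the 17-digit CSV values
  # reproduce the original doubles bit for bit
  df <- utils::read.csv(path, colClasses = c(
    t = "numeric", event = "character", clutch = "integer",
    x_s = "numeric", engaged = "integer", F_s = "numeric",
    v_f = "numeric", F_clutch_total = "numeric"
  ))
  as_tibble(df)
}

#' @rdname clutch_io
#' @export
write_clutch_summary <- function(sim, path) {
  stopifnot(inherits(sim, "clutch_sim"))
  payload <- list(
    params = unclass(sim$params),
    seed = sim$seed,
    n_events = sim$n_events,
    burn_in = sim$burn_in,
    n_failures = length(sim$failure_times),
    summary = as.list(sim$summary)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname clutch_io
#' @export
read_clutch_summary <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Persist sweep and strain-response results
#'
#' Long-format CSV (one row per run: stiffness, variant, strain mode,
#' residual strain, clutch count, seed, summary statistics) plus a JSON
#' index holding the interpolated optima.
#'
#' @param x A `clutch_sweep` or `clutch_strain_response`.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem.
#' @return Invisibly, the paths written.
#' @export
write_sweep_results <- function(x, dir, stem = "sweep") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  idx <- file.path(dir, paste0(stem, "_index.json"))
  if (inherits(x, "clutch_sweep")) {
    runs <- dplyr::bind_cols(
      tibble(k_s = x$params$k_s, model_variant = x$params$model_variant,
             strain_mode = x$params$strain_mode, eps0 = x$params$eps0,
             .rows = nrow(x$runs)),
      x$runs
    )
    readr::write_csv(runs, csv)
    jsonlite::write_json(
      list(optimum = as.list(x$optimum), n_events = x$n_events,
           seeds = x$seeds),
      idx, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  } else if (inherits(x, "clutch_strain_response")) {
    runs <- dplyr::bind_rows(purrr::map2(
      x$sweeps, x$optima$eps0,
      function(s, e) dplyr::bind_cols(
        tibble(k_s = s$params$k_s, model_variant = s$params$model_variant,
               strain_mode = s$params$strain_mode, eps0 = e,
               .rows = nrow(s$runs)),
        s$runs
      )
    ))
    readr::write_csv(runs, csv)
    jsonlite::write_json(
      list(mode = x$mode, optima = x$optima, slopes = x$slopes,
           n_events = x$n_events, seeds = x$seeds),
      idx, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  } else {
    stop("`x` must be a clutch_sweep or clutch_strain_response", call. = FALSE)
  }
  invisible(c(csv = csv, index = idx))
}
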