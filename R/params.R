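#' Model parameters for a motor-clutch simulation
#'
#' Bundles the kinetic and mechanical constants of the motor-clutch model
#' together with the geometry of the residual-strain configuration. The
#' defaults for the molecular constants are the standard parameter set used
#' throughout the analyses shipped with this package: motor stall force 2 pN,
#' unloaded motor velocity 120 nm/s, bond rupture force 2 pN, on-rate 0.3/s,
#' unloaded off-rate 0.1/s and clutch spring constant 0.8 pN/nm.
#'
#' The substrate anchorage consists of two linear springs: the classical
#' substrate spring `k_s` (horizontal, along the clutch axis) and an
#' orthogonal spring `k_s_eps0` of rest length `l` that stores residual
#' strain `eps0`. Residual strain can be imposed along the orthogonal
#' spring's own axis (`strain_mode = "axial"`, which stretches its length to
#' `l * (1 + eps0)` without changing the initial geometry) or along the
#' substrate spring's axis (`strain_mode = "transverse"`, which displaces the
#' anchorage junction sideways by an offset `x0` and introduces a residual
#' force `F0` into the horizontal balance).
#'
#' The number of myosin motors always tracks the number of clutches
#' (`n_m == n_c`), so the ensemble stall force scales with the adhesion size.
#'
#' @param n_c Number of available molecular clutches (integer, >= 1).
#' @param k_s Substrate spring constant (pN/nm).
#' @param eps0 Residual strain stored in the orthogonal spring
#'   (dimensionless, >= 0). Defined as `(l' - l) / l` where `l'` is the
#'   deformed length.
#' @param strain_mode One of `"none"`, `"axial"`, `"transverse"`; the
#'   direction along which the residual strain is imposed.
#' @param model_variant `"modified"` (two-spring anchorage) or `"canonical"`
#'   (substrate spring only; requires `strain_mode = "none"` and `eps0 = 0`).
#' @param F_m Single-motor stall force (pN).
#' @param v_u Unloaded motor velocity (nm/s).
#' @param F_b Characteristic bond rupture force in the Bell law (pN).
#' @param k_on Clutch engagement rate (1/s).
#' @param k_off Unloaded clutch off-rate (1/s).
#' @param k_c Clutch spring constant (pN/nm).
#' @param k_s_eps0 Orthogonal spring constant (pN/nm); by convention set
#'   equal to `k_s`.
#' @param l Undeformed (rest) length of the orthogonal spring (nm).
#' @param bell_load How the tension feeding the Bell off-rate of an engaged
#'   clutch is evaluated. `"shared"` (the default) divides the total force
#'   transmitted through the adhesion equally over the engaged clutches
#'   (`F = (F_s - F0) / m`), the equal-load-sharing convention of classical
#'   adhesion-cluster kinetics; `"individual"` uses each clutch's own
#'   elastic tension `k_c * (x_c_i - x_s)`. Load sharing is required to
#'   reproduce the biphasic flow-versus-`n_c` curves with optima in the
#'   tens-to-hundreds range; under individual loading the exponential
#'   off-rate culls the most-stretched bond so fast that collective loading
#'   collapses and the optimum moves far to the right (see the methods
#'   vignette).
#' @param bell_force `"signed"` applies the Bell exponent to the signed
#'   clutch force exactly as written in the rate law, so compressed clutches
#'   unbind more slowly; `"magnitude"` uses `|F_c|` instead. Only relevant
#'   for `bell_load = "individual"`; the shared load is never negative.
#'
#' @return An object of class `clutch_params`: a named list of validated
#'   parameters.
#' @seealso [clutch_geometry()], [run_clutch_simulation()]
#' @examples
#' p <- clutch_params(n_c = 50, k_s = 1)
#' p
#' clutch_params(n_c = 100, k_s = 0.1, eps0 = 1, strain_mode = "axial")
#' @export
clutch_params <- function(n_c = 50,
                          k_s = 1,
                          eps0 = 0,
                          strain_mode = c("none", "axial", "transverse"),
                          model_variant = c("modified", "canonical"),
                          F_m = 2,
                          v_u = 120,
                          F_b = 2,
                          k_on = 0.3,
                          k_off = 0.1,
                          k_c = 0.8,
                          k_s_eps0 = k_s,
                          l = 1000,
                          bell_load = c("shared", "individual"),
                          bell_force = c("signed", "magnitude")) {
  strain_mode <- match.arg(strain_mode)
  model_variant <- match.arg(model_variant)
  bell_load <- match.arg(bell_load)
  bell_force <- match.arg(bell_force)

  p <- list(
    n_c = as.integer(n_c), n_m = as.integer(n_c),
    F_m = F_m, v_u = v_u, F_b = F_b,
    k_on = k_on, k_off = k_off, k_c = k_c,
    k_s = k_s, k_s_eps0 = k_s_eps0, l = l,
    eps0 = eps0, strain_mode = strain_mode,
    model_variant = model_variant,
    bell_load = bell_load, bell_force = bell_force
  )
  class(p) <- "clutch_params"
  validate_clutch_params(p)
  p
}

validate_clutch_params <- function(p) {
  stopifnot(is.list(p))
  num_pos <- c("F_m", "v_u", "F_b", "k_on", "k_off", "k_c", "k_s",
               "k_s_eps0", "l")
  for (f in num_pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter `", f, "` must be a single strictly positive number",
           call. = FALSE)
    }
  }
  if (!is.numeric(p$eps0) || length(p$eps0) != 1L || !is.finite(p$eps0) ||
      p$eps0 < 0) {
    stop("parameter `eps0` must be a single number >= 0", call. = FALSE)
  }
  if (is.na(p$n_c) || p$n_c < 1L) {
    stop("parameter `n_c` must be an integer >= 1", call. = FALSE)
  }
  if (p$n_m != p$n_c) {
    stop("the motor count `n_m` must equal the clutch count `n_c`",
         call. = FALSE)
  }
  if (p$model_variant == "canonical" &&
      (p$strain_mode != "none" || p$eps0 > 0)) {
    stop("the canonical variant has no orthogonal spring: it requires ",
         "`strain_mode = \"none\"` and `eps0 = 0`", call. = FALSE)
  }
  if (p$strain_mode == "none" && p$eps0 > 0) {
    stop("`eps0 > 0` requires `strain_mode` \"axial\" or \"transverse\"",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.clutch_params <- function(x, ...) {
  cat("<clutch_params>\n")
  cat(sprintf("  variant: %s   strain: %s (eps0 = %g)\n",
              x$model_variant, x$strain_mode, x$eps0))
  cat(sprintf("  n_c = n_m = %d\n", x$n_c))
  cat(sprintf("  motors: F_m = %g pN, v_u = %g nm/s\n", x$F_m, x$v_u))
  cat(sprintf("  clutches: k_on = %g /s, k_off = %g /s, F_b = %g pN, k_c = %g pN/nm (Bell: %s load, %s force)\n",
              x$k_on, x$k_off, x$F_b, x$k_c, x$bell_load, x$bell_force))
  cat(sprintf("  substrate: k_s = %g pN/nm, k_s_eps0 = %g pN/nm, l = %g nm\n",
              x$k_s, x$k_s_eps0, x$l))
  invisible(x)
}

#' Derived geometry of the residual-strain configuration
#'
#' Computes the deformed length of the orthogonal spring, the transverse
#' offset of the anchorage junction and the residual force entering the
#' horizontal force balance, from the residual strain and its orientation.
#'
#' In axial mode the spring is stretched along its own axis: its deformed
#' length is `l * (1 + eps0)`, the geometry of the clutch axis is unchanged,
#' and the residual force is entirely carried by the support constraints so
#' it does not enter the horizontal balance (`F0 = 0`). In transverse mode
#' the junction is displaced sideways by `x0 = l * sqrt((1 + eps0)^2 - 1)`,
#' the strain--offset relation `eps0 = sqrt(l^2 + x0^2)/l - 1` holds exactly,
#' and a residual force `F0 = k_s_eps0 * eps0 * l + k_s * x0` is added to the
#' clutch side of the balance.
#'
#' @param params A [clutch_params()] object.
#' @return An object of class `clutch_geometry`: list with fields `l_prime`
#'   (deformed orthogonal-spring length, nm), `x0` (transverse offset, nm)
#'   and `F0` (residual force, pN).
#' @examples
#' clutch_geometry(clutch_params(eps0 = 3, strain_mode = "axial"))
#' clutch_geometry(clutch_params(eps0 = 1, strain_mode = "transverse"))
#' @export
clutch_geometry <- function(params) {
  stopifnot(inherits(params, "clutch_params"))
  g <- switch(params$strain_mode,
    none = list(l_prime = params$l, x0 = 0, F0 = 0),
    axial = list(l_prime = params$l * (1 + params$eps0), x0 = 0, F0 = 0),
    transverse = {
      x0 <- transverse_offset(params$eps0, params$l)
      list(l_prime = params$l, x0 = x0,
           F0 = residual_force_transverse(params$eps0, params))
    }
  )
  class(g) <- "clutch_geometry"
  g
}

#' @export
print.clutch_geometry <- function(x, ...) {
  cat(sprintf("<clutch_geometry> l' = %g nm, x0 = %g nm, F0 = %g pN\n",
              x$l_prime, x$x0, x$F0))
  invisible(x)
}
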