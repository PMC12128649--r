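# Exponent cap for the Bell law: beyond this the off-rate saturates at
# k_off * exp(50) (~5e21 * k_off), keeping event times positive and finite.
BELL_EXP_CAP <- 50

#' Bell slip-bond off-rate
#'
#' Force-dependent dissociation rate of an engaged clutch,
#' `k_off * exp(F_c / F_b)`. The exponent is capped at `50` so that extreme
#' forces saturate the rate instead of overflowing to `Inf`. With
#' `bell_force = "signed"` (the default) the signed clutch force enters the
#' exponent, so a compressed clutch (negative force) unbinds more slowly
#' than an unloaded one; with `"magnitude"` the absolute force is used.
#'
#' @param F_c Clutch force (pN); vectorised.
#' @param params A [clutch_params()] object.
#' @return Off-rate(s), 1/s.
#' @examples
#' p <- clutch_params()
#' bell_off_rate(0, p)              # k_off
#' bell_off_rate(2, p)              # k_off * e
#' @export
bell_off_rate <- function(F_c, params) {
  stopifnot(is.numeric(F_c), all(is.finite(F_c)))
  f <- if (params$bell_force == "magnitude") abs(F_c) else F_c
  params$k_off * exp(pmin(f / params$F_b, BELL_EXP_CAP))
}

#' Hookean clutch force
#'
#' Force carried by a clutch spring stretched between the clutch attachment
#' point and the substrate anchorage, `k_c * (x_c - x_s)`. Positive when the
#' clutch is ahead of the substrate (stretched by the retrograde flow).
#'
#' @param x_c Clutch position (nm); vectorised.
#' @param x_s Substrate position (nm).
#' @param k_c Clutch spring constant (pN/nm).
#' @return Force(s), pN.
#' @examples
#' clutch_force(10, 4, 0.8)   # 4.8 pN
#' @export
clutch_force <- function(x_c, x_s, k_c) {
  stopifnot(is.numeric(x_c), is.numeric(x_s), is.numeric(k_c),
            all(is.finite(x_c)), all(is.finite(x_s)))
  k_c * (x_c - x_s)
}

#' Restoring force of the two-spring substrate anchorage
#'
#' Horizontal restoring force exerted by the substrate spring plus the
#' orthogonal spring when the anchorage junction is displaced by `x_s`:
#'
#' `F_s = k_s_eps0 * (sqrt(l'^2 + x_s^2) - l) * x_s / sqrt(l'^2 + x_s^2)
#'        + k_s * x_s`
#'
#' where `l'` is the deformed length of the orthogonal spring and `l` its
#' rest length. For the canonical variant only the linear `k_s * x_s` term
#' is present. The orthogonal term is nonlinear: it vanishes at the origin,
#' is odd in `x_s` when `l' = l`, and stiffens the anchorage at
#' displacements comparable to the spring length.
#'
#' @param x_s Substrate displacement (nm); vectorised.
#' @param params A [clutch_params()] object.
#' @param geom A [clutch_geometry()] object (defaults to the geometry
#'   derived from `params`).
#' @return Force(s), pN.
#' @examples
#' p <- clutch_params(k_s = 1, eps0 = 3, strain_mode = "axial")
#' substrate_force(10, p)
#' @export
substrate_force <- function(x_s, params, geom = clutch_geometry(params)) {
  stopifnot(is.numeric(x_s), all(is.finite(x_s)))
  if (params$model_variant == "canonical") {
    return(params$k_s * x_s)
  }
  r <- sqrt(geom$l_prime^2 + x_s^2)
  params$k_s_eps0 * (r - params$l) * x_s / r + params$k_s * x_s
}

#' Transverse offset producing a given residual strain
#'
#' Inverts the strain--offset relation `eps0 = sqrt(l^2 + x0^2)/l - 1` of
#' the transverse configuration: the sideways displacement of the anchorage
#' junction that stretches the orthogonal spring of rest length `l` by a
#' strain `eps0` is `x0 = l * sqrt((1 + eps0)^2 - 1)`.
#'
#' @param eps0 Residual strain (>= 0); vectorised.
#' @param l Orthogonal-spring rest length (nm).
#' @return Offset(s), nm.
#' @examples
#' transverse_offset(1, 1000)   # 1000 * sqrt(3)
#' @export
transverse_offset <- function(eps0, l) {
  stopifnot(is.numeric(eps0), is.numeric(l), l > 0)
  if (any(!is.finite(eps0)) || any(eps0 < 0)) {
    stop("`eps0` must be finite and >= 0", call. = FALSE)
  }
  l * sqrt((1 + eps0)^2 - 1)
}

#' Residual force of the transverse configuration
#'
#' Force required to hold the anchorage junction at the transverse offset
#' `x0`, which enters the horizontal force balance on the clutch side:
#' `F0 = k_s_eps0 * eps0 * l + k_s * x0`.
#'
#' @param eps0 Residual strain (>= 0).
#' @param params A [clutch_params()] object.
#' @return Force, pN.
#' @examples
#' p <- clutch_params(k_s = 1, eps0 = 0.25, strain_mode = "transverse")
#' residual_force_transverse(0.25, p)   # 250 + 750 = 1000 pN
#' @export
residual_force_transverse <- function(eps0, params) {
  x0 <- transverse_offset(eps0, params$l)
  params$k_s_eps0 * eps0 * params$l + params$k_s * x0
}

#' Solve the substrate force balance
#'
#' Finds the substrate displacement `x_s` at which the total force carried by
#' the engaged clutches (plus, in the transverse configuration, the residual
#' force `F0`) balances the restoring force of the two-spring anchorage:
#'
#' `F0 + sum_i k_c * (x_c_i - x_s) = F_s(x_s)`
#'
#' The balance residual is strictly decreasing in `x_s` (slope at most
#' `-(k_s + m * k_c)`), so the root is unique. The canonical variant is
#' linear and solved in closed form,
#' `x_s = k_c * sum(x_c) / (k_s + m * k_c)`; otherwise a safeguarded
#' bracketing root-finder is used with the bracket expanded geometrically
#' until it straddles the root, to an absolute tolerance of 1e-10 nm.
#'
#' @param engaged_positions Positions of the engaged clutches (nm); may be
#'   empty.
#' @param params A [clutch_params()] object.
#' @param geom A [clutch_geometry()] object.
#' @return Substrate displacement `x_s` (nm). The returned root satisfies
#'   the balance to better than `1e-9 * max(1, |F_s|)` pN; a failure to
#'   bracket or converge is an error, never a silent return.
#' @examples
#' p <- clutch_params(n_c = 2, k_s = 1, model_variant = "canonical")
#' solve_equilibrium(c(10, 20), p)   # 24 / 2.6
#' @export
solve_equilibrium <- function(engaged_positions, params,
                              geom = clutch_geometry(params)) {
  stopifnot(is.numeric(engaged_positions), all(is.finite(engaged_positions)))
  m <- length(engaged_positions)
  S <- sum(engaged_positions)

  if (params$model_variant == "canonical") {
    return(params$k_c * S / (params$k_s + m * params$k_c))
  }
  if (m == 0L && geom$F0 == 0) {
    return(0)
  }

  balance <- function(x) {
    geom$F0 + params$k_c * (S - m * x) - substrate_force(x, params, geom)
  }

  lo <- 0
  if (balance(lo) < 0) {
    # all engaged positions behind the origin; expand downwards
    step <- 1
    while (balance(lo) < 0 && step < 1e12) {
      lo <- lo - step
      step <- step * 2
    }
  }
  hi <- max(1, engaged_positions, geom$x0)
  n_exp <- 0L
  while (balance(hi) > 0) {
    hi <- hi * 2
    n_exp <- n_exp + 1L
    if (n_exp > 200L) {
      stop("equilibrium solver failed to bracket the root (m = ", m,
           ", sum x_c = ", signif(S, 6), ", F0 = ", signif(geom$F0, 6), ")",
           call. = FALSE)
    }
  }

  root <- uniroot(balance, c(lo, hi), tol = 1e-10)$root
  resid <- abs(balance(root))
  if (!is.finite(resid) ||
      resid > 1e-9 * max(1, abs(substrate_force(root, params, geom)))) {
    stop("equilibrium solver did not converge: residual ", signif(resid, 3),
         " pN at x_s = ", signif(root, 8), " nm (m = ", m, ")",
         call. = FALSE)
  }
  root
}

#' Hill force-velocity relation for the motor ensemble
#'
#' Retrograde actin flow velocity under a motor load `F`, linear between the
#' unloaded velocity `v_u` at zero load and stall at the ensemble stall
#' force `n_m * F_m`: `v_f = v_u * (1 - F / (n_m * F_m))`. The result is
#' clamped to `[0, v_u]`: the motors neither reverse beyond stall nor exceed
#' their unloaded speed under assisting loads.
#'
#' The load is the force transmitted to the motors through the engaged
#' clutches; at mechanical equilibrium this equals the substrate force minus
#' any residual force held by the pre-strained anchorage.
#'
#' @param F_s Motor load (pN); vectorised.
#' @param params A [clutch_params()] object.
#' @return Velocity(ies), nm/s, in `[0, v_u]`.
#' @examples
#' p <- clutch_params(n_c = 50)
#' hill_velocity(0, p)     # v_u
#' hill_velocity(100, p)   # stall: n_m * F_m = 100 pN
#' @export
hill_velocity <- function(F_s, params) {
  stopifnot(is.numeric(F_s), all(is.finite(F_s)))
  v <- params$v_u * (1 - F_s / (params$n_m * params$F_m))
  pmin(pmax(v, 0), params$v_u)
}
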