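#' Blood properties
#'
#' Newtonian blood at standard hemodynamic values: density 1056 kg/m^3 and
#' dynamic viscosity 3.5e-3 Pa s.
#'
#' @param density kg/m^3, > 0.
#' @param viscosity dynamic viscosity, Pa s, > 0.
#' @return an object of class `blood_properties`.
#' @export
blood_properties <- function(density = 1056, viscosity = 3.5e-3) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "blood_properties")
}

#' Pa per mmHg
#' @export
MMHG_PA <- 133.322

#' Boundary conditions for the flow solve
#'
#' The inlet is held at the mean proximal (aortic) pressure, the quantity a
#' catheter tip reports during any coronary procedure. The outlet is coupled
#' to a lumped distal resistance representing the myocardial bed; the
#' default 8.721e9 Pa s m^-3 is the generic population-average value used
#' when no invasive distal measurement is available. The venous reference
#' pressure on the far side of the resistance defaults to 0, the usual FFR
#' convention.
#'
#' @param p_inlet_mmhg mean proximal pressure in mmHg (converted internally
#'   at 1 mmHg = 133.322 Pa). Give either this or `p_inlet_pa`.
#' @param p_inlet_pa mean proximal pressure in Pa (overrides the mmHg form).
#' @param r_distal distal resistance, Pa s m^-3, > 0.
#' @param p_venous venous reference pressure, Pa, >= 0.
#' @return an object of class `boundary_conditions` (pressures in Pa).
#' @export
boundary_conditions <- function(p_inlet_mmhg = 93, p_inlet_pa = NULL,
                                r_distal = 8.721e9, p_venous = 0) {
  p_in <- if (is.null(p_inlet_pa)) p_inlet_mmhg * MMHG_PA else p_inlet_pa
  if (r_distal <= 0) stop("distal resistance must be positive")
  if (p_venous < 0) stop("venous pressure must be >= 0")
  if (p_in < p_venous) stop("inlet pressure must exceed the venous reference")
  structure(list(p_inlet = p_in, r_distal = r_distal, p_venous = p_venous),
            class = "boundary_conditions")
}

# Segment-wise Poiseuille resistance of a sampled vessel, SI units.
# r_bar is the mean of the two station radii.
.vessel_poiseuille_resistance <- function(s_m, r_m, mu) {
  ds <- diff(s_m)
  rbar <- (r_m[-1] + r_m[-length(r_m)]) / 2
  8 * mu * ds / (pi * rbar^4)
}

# Borda-Carnot expansion losses. Each maximal run of increasing area,
# from a local area minimum A_min up to the downstream recovery A_down,
# contributes dP = 1/2 rho Q^2 (1/A_min - 1/A_down)^2. Returns, per
# segment, the quadratic-loss coefficient so cumulative pressure profiles
# stay monotone within an expansion.
.borda_carnot_coefficients <- function(r_m, rho) {
  A <- pi * r_m^2
  n <- length(A)
  kseg <- numeric(n - 1L)
  i <- 1L
  while (i < n) {
    if (A[i + 1L] > A[i]) {
      j <- i
      while (j < n && A[j + 1L] > A[j]) j <- j + 1L
      # expansion run i..j: distribute the run's total loss across segments
      # by the (1/A_min - 1/A(s))^2 profile so p(s) is non-increasing
      phi <- 0.5 * rho * (1 / A[i] - 1 / A[i:j])^2
      kseg[i:(j - 1L)] <- diff(phi)
      i <- j
    } else i <- i + 1L
  }
  kseg
}

#' Solve steady flow with the reduced-order network backend
#'
#' Fast analytic surrogate for full CFD: each inter-station segment carries
#' a local Poiseuille resistance `8 mu ds / (pi rbar^4)`, and every area
#' expansion adds a Borda-Carnot separation loss
#' `1/2 rho Q^2 (1/A_min - 1/A_down)^2`. The flow rate solves the lumped
#' balance `P_inlet - P_venous = dP_vessel(Q) + Q * R_distal`, a monotone
#' scalar root-find carried to 1e-10 relative tolerance; station pressures
#' follow by accumulating losses from the inlet.
#'
#' @param vessel a `vessel_geometry` (geometry in mm; converted to SI
#'   internally).
#' @param bc a [boundary_conditions()].
#' @param blood a [blood_properties()].
#' @return a `flow_solution` (backend `"reduced"`) carrying the flow rate
#'   `Q` (m^3/s), per-station absolute pressures (Pa), the vessel
#'   resistance, and a convergence report. Use [pressure_at()] and
#'   [compute_vffr()] on it.
#' @examples
#' v <- make_synthetic_vessel(50, 1.5)
#' sol <- solve_reduced(v, boundary_conditions(), blood_properties())
#' compute_vffr(sol, 0, vessel_length(v))
#' @export
solve_reduced <- function(vessel, bc = boundary_conditions(),
                          blood = blood_properties()) {
  validate_vessel(vessel)
  sec <- vessel$sections
  s_m <- sec$s * 1e-3
  r_m <- sec$r * 1e-3
  mu <- blood$viscosity; rho <- blood$density

  rseg <- .vessel_poiseuille_resistance(s_m, r_m, mu)
  kseg <- .borda_carnot_coefficients(r_m, rho)
  Rv <- sum(rseg); K <- sum(kseg)
  dP <- bc$p_inlet - bc$p_venous

  if (dP == 0) {   # equilibrium: no driving pressure, no flow
    return(structure(list(
      backend = "reduced", Q = 0,
      s = sec$s, p = rep(bc$p_inlet, nrow(sec)),
      R_vessel = Rv, K_expansion = K,
      bc = bc, blood = blood,
      vessel_name = vessel$name, vessel_length = max(sec$s),
      convergence = list(converged = TRUE, iterations = 0L,
                         outlet_relation_residual = 0, root_precision = 0)
    ), class = "flow_solution"))
  }

  f <- function(Q) (Rv + bc$r_distal) * Q + K * Q^2 - dP
  q_upper <- dP / bc$r_distal   # f(q_upper) >= 0 since Rv, K >= 0
  q_scale <- dP / (Rv + bc$r_distal)
  rt <- stats::uniroot(f, c(0, q_upper), tol = 1e-10 * q_scale)
  Q <- rt$root

  p <- bc$p_inlet - c(0, cumsum(rseg * Q + kseg * Q^2))
  out_rel <- abs(p[length(p)] - bc$p_venous - Q * bc$r_distal) / bc$p_inlet

  structure(list(
    backend = "reduced",
    Q = Q,
    s = sec$s,                 # mm
    p = p,                     # Pa, absolute (referenced to P_venous = 0)
    R_vessel = Rv,
    K_expansion = K,
    bc = bc, blood = blood,
    vessel_name = vessel$name,
    vessel_length = max(sec$s),
    convergence = list(converged = TRUE, iterations = rt$iter,
                       outlet_relation_residual = out_rel,
                       root_precision = rt$estim.prec)
  ), class = "flow_solution")
}

#' Cross-section-averaged pressure at arbitrary arc lengths
#'
#' @param solution a `flow_solution` from [solve_reduced()] or [solve_3d()].
#' @param s numeric vector of arc lengths (mm) inside the solved domain.
#' @return absolute pressures (Pa).
#' @export
pressure_at <- function(solution, s) {
  stopifnot(inherits(solution, "flow_solution"))
  if (any(s < -1e-9) || any(s > solution$vessel_length + 1e-9))
    stop("arc length outside the solved domain")
  stats::approx(solution$s, solution$p, xout = s, rule = 2)$y
}

#' Virtual fractional flow reserve between two marked points
#'
#' FFR is the ratio of distal to proximal pressure, `Pd / Pa`, under
#' hyperemic flow, with both pressures absolute (venous reference 0).
#' The two marks are arc lengths on the solved vessel, mirroring the two
#' points an operator drops on the angiogram.
#'
#' @param solution a `flow_solution`.
#' @param s_proximal proximal mark (mm).
#' @param s_distal distal mark (mm), > `s_proximal`.
#' @return an object of class `ffr_result` with fields `p_proximal`,
#'   `p_distal` (Pa) and `vffr`.
#' @export
compute_vffr <- function(solution, s_proximal, s_distal) {
  if (!(s_proximal >= 0 && s_proximal < s_distal &&
        s_distal <= solution$vessel_length + 1e-9))
    stop("require 0 <= s_proximal < s_distal <= vessel length")
  pp <- pressure_at(solution, s_proximal)
  pd <- pressure_at(solution, s_distal)
  structure(list(s_proximal = s_proximal, s_distal = s_distal,
                 p_proximal = pp, p_distal = pd, vffr = pd / pp,
                 backend = solution$backend),
            class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat(sprintf("vFFR = %.3f  (Pd %.0f Pa / Pa %.0f Pa, s = %.1f..%.1f mm, %s backend)\n",
              x$vffr, x$p_distal, x$p_proximal, x$s_proximal, x$s_distal,
              x$backend))
  invisible(x)
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> backend %s\n", x$backend))
  cat(sprintf("  Q = %.4g ml/s, inlet %.0f Pa, outlet %.0f Pa\n",
              x$Q * 1e6, x$p[1], x$p[length(x$p)]))
  conv <- x$convergence
  cat(sprintf("  converged: %s (outlet relation residual %.2g)\n",
              conv$converged, conv$outlet_relation_residual))
  invisible(x)
}

#' @export
summary.flow_solution <- function(object, ...) {
  x <- object
  res <- list(
    backend = x$backend, Q = x$Q,
    p_inlet = x$p[1], p_outlet = x$p[length(x$p)],
    effective_distal_resistance =
      (x$p[length(x$p)] - x$bc$p_venous) / x$Q,
    vffr_whole_vessel = x$p[length(x$p)] / x$p[1],
    convergence = x$convergence
  )
  class(res) <- "summary.flow_solution"
  res
}

#' @export
print.summary.flow_solution <- function(x, ...) {
  cat(sprintf("Flow solution (%s backend)\n", x$backend))
  cat(sprintf("  Q                      : %.4g ml/s\n", x$Q * 1e6))
  cat(sprintf("  inlet / outlet pressure: %.0f / %.0f Pa\n",
              x$p_inlet, x$p_outlet))
  cat(sprintf("  (P_out - P_v)/Q        : %.4g Pa s m^-3\n",
              x$effective_distal_resistance))
  cat(sprintf("  whole-vessel vFFR      : %.3f\n", x$vffr_whole_vessel))
  invisible(x)
}

#' @export
plot.flow_solution <- function(x, ...) {
  graphics::plot(x$s, x$p / MMHG_PA, type = "l",
                 xlab = "arc length s [mm]", ylab = "pressure [mmHg]",
                 main = sprintf("pressure profile (%s backend)", x$backend),
                 ...)
  invisible(x)
}

#' Predict pressure (Pa) at new arc lengths
#' @param object a `flow_solution`.
#' @param s arc lengths (mm); defaults to the solved stations.
#' @param ... unused.
#' @export
predict.flow_solution <- function(object, s = object$s, ...) {
  pressure_at(object, s)
}
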