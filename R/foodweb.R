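#' Food-web model parameters
#'
#' Constructs the parameter set for the three-compartment virus (V) -
#' bacteria (B) - grazer (G) food-web model. Viruses are supplied at a
#' constant rate, consumed by bacteria and grazers following mass-action
#' kinetics, and decay abiotically; bacteria grow exponentially, assimilate
#' viral biomass, are grazed, and suffer quadratic mortality; grazers
#' assimilate bacteria and viruses and suffer quadratic mortality.
#'
#' Defaults are the reference parameterisation used throughout the package
#' (chosen to qualitatively reproduce coastal bottle-incubation dynamics):
#' calling `foodweb_params()` with no arguments returns it.
#'
#' @param S_v virus supply rate (viruses ml^-1 day^-1)
#' @param phi_gv virus clearance rate by grazers (ml grazer^-1 day^-1)
#' @param phi_bv virus clearance rate by bacteria (ml bacteria^-1 day^-1)
#' @param phi_gb bacteria clearance rate by grazers (ml grazer^-1 day^-1)
#' @param mu_b bacterial specific growth rate (day^-1)
#' @param delta_v abiotic virus decay rate (day^-1)
#' @param delta_b bacterial quadratic mortality coefficient (ml bacteria^-1 day^-1)
#' @param delta_g grazer quadratic mortality coefficient (ml grazer^-1 day^-1)
#' @param eps_gb transfer efficiency bacteria -> grazer (dimensionless, 0-1)
#' @param eps_gv transfer efficiency virus -> grazer (dimensionless, 0-1)
#' @param eps_bv transfer efficiency virus -> bacteria (dimensionless, 0-1)
#' @return an object of class `foodweb_params` (named list)
#' @export
foodweb_params <- function(S_v = 5e7, phi_gv = 1e-3, phi_bv = 1e-6,
                           phi_gb = 1e-3, mu_b = 0.8, delta_v = 0.1,
                           delta_b = 1e-6, delta_g = 0.1,
                           eps_gb = 0.1, eps_gv = 1e-6, eps_bv = 1e-3) {
  p <- list(S_v = S_v, phi_gv = phi_gv, phi_bv = phi_bv, phi_gb = phi_gb,
            mu_b = mu_b, delta_v = delta_v, delta_b = delta_b,
            delta_g = delta_g, eps_gb = eps_gb, eps_gv = eps_gv,
            eps_bv = eps_bv)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative (got ", v, ")")
  }
  for (nm in c("eps_gb", "eps_gv", "eps_bv")) {
    if (p[[nm]] > 1)
      stop("efficiency '", nm, "' must lie in [0, 1] (got ", p[[nm]], ")")
  }
  structure(p, class = "foodweb_params")
}

#' @export
print.foodweb_params <- function(x, ...) {
  cat("Food-web model parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Food-web state vector
#'
#' @param V virus concentration (ml^-1)
#' @param B bacteria concentration (ml^-1)
#' @param G grazer concentration (ml^-1)
#' @return named numeric vector of class `foodweb_state`
#' @export
foodweb_state <- function(V, B, G) {
  s <- c(V = as.numeric(V), B = as.numeric(B), G = as.numeric(G))
  if (any(!is.finite(s))) stop("state components must be finite")
  bad <- names(s)[s < 0]
  if (length(bad))
    stop("state component '", bad[1L], "' must be non-negative (got ",
         s[[bad[1L]]], ")")
  structure(s, class = "foodweb_state")
}

as_foodweb_state <- function(x) {
  if (inherits(x, "foodweb_state")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    if (!is.null(names(x)) && all(c("V", "B", "G") %in% names(x)))
      return(foodweb_state(x[["V"]], x[["B"]], x[["G"]]))
    return(foodweb_state(x[[1L]], x[[2L]], x[[3L]]))
  }
  stop("cannot interpret input as a (V, B, G) food-web state")
}

#' Right-hand side of the food-web model
#'
#' Evaluates the instantaneous rates of change
#' \deqn{dV/dt = S_v - \phi_{gv} G V - \phi_{bv} B V - \delta_v V}
#' \deqn{dB/dt = \mu_b B + \epsilon_{bv} \phi_{bv} B V - \phi_{gb} G B - \delta_b B^2}
#' \deqn{dG/dt = \epsilon_{gb} \phi_{gb} G B + \epsilon_{gv} \phi_{gv} G V - \delta_g G^2}
#'
#' @param state a `foodweb_state` (or coercible length-3 numeric)
#' @param params a `foodweb_params`
#' @return named numeric vector `c(dV, dB, dG)` in ml^-1 day^-1
#' @export
foodweb_derivatives <- function(state, params) {
  s <- as_foodweb_state(state)
  if (!inherits(params, "foodweb_params")) params <- do.call(foodweb_params, as.list(params))
  V <- s[["V"]]; B <- s[["B"]]; G <- s[["G"]]
  with(unclass(params), c(
    dV = S_v - phi_gv * G * V - phi_bv * B * V - delta_v * V,
    dB = mu_b * B + eps_bv * phi_bv * B * V - phi_gb * G * B - delta_b * B^2,
    dG = eps_gb * phi_gb * G * B + eps_gv * phi_gv * G * V - delta_g * G^2
  ))
}

# unvalidated rhs used inside the integrator (lsoda may probe slightly
# negative states; the derivative formula itself is well defined there)
foodweb_rhs <- function(t, y, p) {
  V <- y[1L]; B <- y[2L]; G <- y[3L]
  list(c(
    p$S_v - p$phi_gv * G * V - p$phi_bv * B * V - p$delta_v * V,
    p$mu_b * B + p$eps_bv * p$phi_bv * B * V - p$phi_gb * G * B - p$delta_b * B^2,
    p$eps_gb * p$phi_gb * G * B + p$eps_gv * p$phi_gv * G * V - p$delta_g * G^2
  ))
}

#' Integrate the food-web model
#'
#' Solves the model with a stiff-capable adaptive integrator
#' ([deSolve::lsoda]). Components that go transiently negative by less than
#' `1e-12` relative to the state scale are clipped to zero; larger negative
#' excursions or solver failure raise an error rather than returning NaNs.
#'
#' @param initial initial `foodweb_state`
#' @param params `foodweb_params`
#' @param duration integration horizon (days, > 0)
#' @param output_times times (days) at which to report the state; must lie in
#'   `[0, duration]`. Default: 201 evenly spaced points.
#' @param rtol,atol relative / absolute solver tolerances
#' @return a `foodweb_trajectory`: list with `times`, `states`
#'   (matrix with columns V, B, G) and `params`
#' @export
foodweb_integrate <- function(initial, params, duration,
                              output_times = NULL, rtol = 1e-8, atol = 1e-6) {
  s0 <- as_foodweb_state(initial)
  if (!inherits(params, "foodweb_params")) params <- do.call(foodweb_params, as.list(params))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (is.null(output_times)) output_times <- seq(0, duration, length.out = 201L)
  if (any(output_times < 0 | output_times > duration))
    stop("output_times must lie within [0, duration]")
  times <- sort(unique(c(0, as.numeric(output_times))))

  out <- deSolve::lsoda(y = unclass(s0), times = times, func = foodweb_rhs,
                        parms = unclass(params), rtol = rtol, atol = atol)
  diag <- attributes(out)
  if (!is.null(diag$istate) && diag$istate[1L] < 0)
    stop("food-web integration failed (lsoda istate = ", diag$istate[1L],
         "); try smaller duration or looser tolerances")
  states <- unname(out[, 2:4, drop = FALSE])
  colnames(states) <- c("V", "B", "G")
  if (any(!is.finite(states)))
    stop("food-web integration produced non-finite states")
  # clip only numerically-trivial negatives
  scale <- pmax(apply(abs(states), 1L, max), 1)
  neg <- states < 0
  if (any(neg)) {
    tooneg <- states < -1e-12 * scale
    if (any(tooneg))
      stop("food-web integration produced substantially negative states ",
           "(min = ", min(states), ")")
    states[neg] <- 0
  }
  structure(list(times = out[, 1L], states = states, params = params),
            class = "foodweb_trajectory")
}

#' @export
print.foodweb_trajectory <- function(x, ...) {
  cat("Food-web trajectory: ", length(x$times), " time points over ",
      max(x$times), " days\n", sep = "")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' @export
as.data.frame.foodweb_trajectory <- function(x, ...) {
  data.frame(time_days = x$times,
             V_per_ml = x$states[, "V"],
             B_per_ml = x$states[, "B"],
             G_per_ml = x$states[, "G"])
}

#' Run the food-web model to equilibrium
#'
#' Integrates until the relative derivative norm
#' `max_i |dX_i/dt| / max(X_i, 1)` falls below `tol`, or errors (carrying the
#' last state in the condition as field `last_state`) if `max_days` is
#' exhausted.
#'
#' @inheritParams foodweb_integrate
#' @param tol relative derivative norm tolerance (> 0)
#' @param max_days give up after this many days
#' @return the equilibrium `foodweb_state`, with attribute `days_elapsed`
#' @export
run_to_equilibrium <- function(initial, params, tol = 1e-9, max_days = 5000) {
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  s <- as_foodweb_state(initial)
  if (!inherits(params, "foodweb_params")) params <- do.call(foodweb_params, as.list(params))
  elapsed <- 0
  chunk <- 100
  crit <- function(st) {
    d <- foodweb_derivatives(st, params)
    max(abs(d) / pmax(unclass(st), 1))
  }
  while (elapsed < max_days) {
    if (crit(s) < tol) {
      attr(s, "days_elapsed") <- elapsed
      return(s)
    }
    dt <- min(chunk, max_days - elapsed)
    traj <- foodweb_integrate(s, params, dt, output_times = dt)
    st <- traj$states[nrow(traj$states), ]
    s <- foodweb_state(st[["V"]], st[["B"]], st[["G"]])
    elapsed <- elapsed + dt
  }
  if (crit(s) < tol) {
    attr(s, "days_elapsed") <- elapsed
    return(s)
  }
  stop(errorCondition(
    paste0("no equilibrium within ", max_days,
           " days (relative derivative norm ", signif(crit(s), 3),
           " > tol ", tol, ")"),
    class = "foodweb_convergence_error",
    last_state = s, days_elapsed = elapsed))
}

#' Filtration treatment specification
#'
#' Describes a simulated bottle-incubation treatment. Filtration levels mimic
#' sequential size fractionation of seawater: `"lt100"` (< 100 um; full
#' community), `"lt1p2"` (< 1.2 um; protist grazers removed) and `"lt0p1"`
#' (< 0.1 um; bacteria and grazers removed). `supply_cut` mimics adding a
#' one-time virus spike with no ongoing production (supply set to zero).
#'
#' @param filtration one of `"lt100"`, `"lt1p2"`, `"lt0p1"`
#' @param supply_cut zero the virus supply at t = 0 (default TRUE)
#' @param duration incubation length in days
#' @param output_times sampling times (days); default mirrors the bottle
#'   experiment grid 0, 0.5, 1, 2, 4, 8 d
#' @return object of class `treatment_spec`
#' @export
treatment_spec <- function(filtration = c("lt100", "lt1p2", "lt0p1"),
                           supply_cut = TRUE, duration = 8,
                           output_times = c(0, 0.5, 1, 2, 4, 8)) {
  filtration <- match.arg(filtration)
  if (duration <= 0) stop("duration must be > 0")
  if (any(output_times < 0 | output_times > duration))
    stop("output_times must lie within [0, duration]")
  structure(list(filtration = filtration, supply_cut = isTRUE(supply_cut),
                 duration = duration, output_times = output_times),
            class = "treatment_spec")
}

#' Simulate a filtration treatment
#'
#' Spins the full model up to equilibrium, applies the filtration (removing
#' grazers, or bacteria and grazers, instantaneously), optionally cuts the
#' virus supply, and integrates for the treatment duration. Filtration is
#' idealised as complete removal; `retention` keeps that fraction of the
#' removed compartments instead (default 0).
#'
#' @param spec a `treatment_spec`
#' @param params `foodweb_params`
#' @param initial spin-up initial condition (results are insensitive to it by
#'   construction, since the model is first run to equilibrium)
#' @param spike if non-NULL, the virus compartment is set to this
#'   concentration (ml^-1) at t = 0 after filtration, mimicking a virus
#'   addition of known size
#' @param retention fraction of a filtered compartment that survives
#'   filtration (0 = ideal filter)
#' @param eq_tol,max_days passed to [run_to_equilibrium()]
#' @return a `foodweb_trajectory` with attributes `treatment` (the
#'   `treatment_spec` used) and `equilibrium` (the pre-filtration state)
#' @export
simulate_treatment <- function(spec, params,
                               initial = foodweb_state(1e6, 1e5, 1e2),
                               spike = NULL, retention = 0,
                               eq_tol = 1e-9, max_days = 5000) {
  if (!inherits(spec, "treatment_spec")) stop("spec must be a treatment_spec")
  if (!inherits(params, "foodweb_params")) params <- do.call(foodweb_params, as.list(params))
  if (retention < 0 || retention > 1) stop("retention must be in [0, 1]")
  eq <- run_to_equilibrium(initial, params, tol = eq_tol, max_days = max_days)
  V <- eq[["V"]]; B <- eq[["B"]]; G <- eq[["G"]]
  if (spec$filtration == "lt1p2") {
    G <- G * retention
  } else if (spec$filtration == "lt0p1") {
    B <- B * retention
    G <- G * retention
  }
  if (!is.null(spike)) V <- as.numeric(spike)
  p <- params
  if (spec$supply_cut) p$S_v <- 0
  traj <- foodweb_integrate(foodweb_state(V, B, G), p,
                            duration = spec$duration,
                            output_times = spec$output_times)
  attr(traj, "treatment") <- spec
  attr(traj, "equilibrium") <- eq
  traj
}

#' Virus removal fraction along a trajectory
#'
#' Fraction of the initial (post-filtration) virus concentration removed by
#' each output time: `1 - V(t) / V(0)`.
#'
#' @param traj a `foodweb_trajectory`
#' @return numeric vector aligned with `traj$times`
#' @export
removal_fraction <- function(traj) {
  if (!inherits(traj, "foodweb_trajectory")) stop("traj must be a foodweb_trajectory")
  V <- traj$states[, "V"]
  if (V[1L] <= 0) stop("initial virus concentration is zero; removal undefined")
  1 - V / V[1L]
}

#' Read / write food-web parameters as JSON
#'
#' @param path file path
#' @param params `foodweb_params`
#' @return `read_foodweb_params` returns a `foodweb_params`
#' @export
write_foodweb_params <- function(params, path) {
  if (!inherits(params, "foodweb_params")) stop("params must be foodweb_params")
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_foodweb_params
#' @export
read_foodweb_params <- function(path) {
  do.call(foodweb_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a trajectory as CSV
#'
#' Columns: `time_days, V_per_ml, B_per_ml, G_per_ml`.
#' @param traj `foodweb_trajectory`
#' @param path file path
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
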