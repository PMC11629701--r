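# independent reference implementations used as oracles; kept deliberately
# separate from the package code paths they check

# fixed-step classical RK4 integrator over the food-web right-hand side,
# written directly from the model equations
rk4_reference <- function(state, params, duration, dt = 1e-3) {
  f <- function(y) {
    V <- y[1]; B <- y[2]; G <- y[3]
    c(params$S_v - params$phi_gv * G * V - params$phi_bv * B * V -
        params$delta_v * V,
      params$mu_b * B + params$eps_bv * params$phi_bv * B * V -
        params$phi_gb * G * B - params$delta_b * B^2,
      params$eps_gb * params$phi_gb * G * B +
        params$eps_gv * params$phi_gv * G * V - params$delta_g * G^2)
  }
  y <- as.numeric(state)
  n <- round(duration / dt)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# algebraic interior fixed point: G* and V* eliminated analytically, the
# remaining scalar equation in B* solved by uniroot
algebraic_equilibrium <- function(params) {
  p <- params
  vg_of_B <- function(B) {
    # G = (eps_gb phi_gb B + eps_gv phi_gv V) / delta_g ; V from dV/dt = 0
    a <- p$eps_gb * p$phi_gb * B / p$delta_g
    b <- p$eps_gv * p$phi_gv / p$delta_g
    cc <- p$phi_bv * B + p$delta_v
    # phi_gv (a + b V) V + cc V - S_v = 0
    A <- p$phi_gv * b
    Bq <- p$phi_gv * a + cc
    Cq <- -p$S_v
    V <- if (A > 0) (-Bq + sqrt(Bq^2 - 4 * A * Cq)) / (2 * A) else -Cq / Bq
    c(V = V, G = a + b * V)
  }
  resid <- function(B) {
    vg <- vg_of_B(B)
    p$mu_b + p$eps_bv * p$phi_bv * vg[["V"]] - p$phi_gb * vg[["G"]] -
      p$delta_b * B
  }
  B <- stats::uniroot(resid, c(1, 1e9), tol = 1e-12)$root
  vg <- vg_of_B(B)
  c(V = vg[["V"]], B = B, G = vg[["G"]])
}

# brute-force exact two-sided signed-rank p-value by enumerating all 2^n
# sign assignments (mid-rank ties included)
wilcoxon_enumeration_p <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% rk)
  lo <- mean(Ws <= W_obs + 1e-9)
  hi <- mean(Ws >= W_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# textbook Welch statistic
welch_reference <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# a small planted-disk scene shared by several segmentation tests
make_disk_scene <- function(seed = 42L, dim_px = c(128L, 128L),
                            n_cycles = 10L, beam_fwhm_nm = 0,
                            particles = NULL) {
  if (is.null(particles))
    particles <- data.frame(
      row = c(25, 30, 64, 70, 100, 100, 40),
      col = c(25, 90, 50, 110, 30, 85, 60),
      diameter_um = c(1.0, 0.8, 1.5, 0.7, 1.2, 0.9, 0.15),  # last below 0.3 um
      c_density = 5, n_density = 2,
      f13C = 0.0111, f15N = 0.0037)
  scene_spec(dim_px = dim_px, particles = particles, n_cycles = n_cycles,
             beam_fwhm_nm = beam_fwhm_nm, seed = seed)
}

jaccard <- function(pixels, mask) {
  got <- matrix(FALSE, nrow(mask), ncol(mask))
  got[pixels] <- TRUE
  sum(got & mask) / sum(got | mask)
}
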