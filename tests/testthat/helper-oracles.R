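# Independent oracles used across the test files.

# Fixed-step classical Runge-Kutta integrator, written without reference to
# the deSolve-based pipeline; checks the adaptive integration, with the
# right-hand side itself validated separately against hand-coded formulas.
rk4_integrate <- function(initial, params, mask, horizon, dt = 1e-3,
                          output_step = 0.1, options = model_options()) {
  f <- function(y) community_rhs(y, params, mask, options)
  times <- seq(0, horizon, by = output_step)
  steps_per_out <- round(output_step / dt)
  out <- matrix(NA_real_, length(times), 8,
                dimnames = list(NULL, names(initial)))
  y <- initial
  out[1, ] <- y
  for (i in seq_along(times)[-1]) {
    for (s in seq_len(steps_per_out)) {
      k1 <- f(y)
      k2 <- f(y + dt / 2 * k1)
      k3 <- f(y + dt / 2 * k2)
      k4 <- f(y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i, ] <- pmax(y, 0)
  }
  list(times = times, states = out)
}

# sup-norm error of each state series relative to its own maximum scale
max_rel_error <- function(sim, oracle) {
  vapply(colnames(oracle$states), function(v) {
    a <- sim$trajectory[[v]]
    b <- oracle$states[, v]
    scale <- max(abs(b), 1e-12)
    max(abs(a - b)) / scale
  }, numeric(1))
}

# hand-coded right-hand side, written directly from the model equations
# (printed nitrate form), independent of the flux-term machinery
reference_rhs <- function(y, p) {
  H <- y[["H"]]; I <- y[["I"]]; P <- y[["P"]]; D <- y[["D"]]
  A <- y[["A"]]; C <- y[["C"]]; R <- y[["R"]]; N <- y[["N"]]
  fh <- N / (p$K_h + N); fd <- N / (p$K_d + N); fa <- N / (p$K_a + N)
  phi <- p$a * H / (1 + p$a * p$h * H)
  preyC <- H + I + D; preyR <- A + P
  Gc <- p$G_cmax * preyC / (p$K_Gc + preyC)
  rc <- p$r_cmax * (preyC - p$x_c) / (p$K_rc + (preyC - p$x_c))
  rr <- p$r_rmax * (preyR - p$x_r) / (p$K_rr + (preyR - p$x_r))
  Gr <- p$G_rmax * preyR / (p$K_Gr + preyR) *
    0.94 / (1 + 219000 * p$Temp^(-4.35)) * 24
  qH <- ifelse(preyC > 0, H / preyC, 0)
  qI <- ifelse(preyC > 0, I / preyC, 0)
  qD <- ifelse(preyC > 0, D / preyC, 0)
  qP <- ifelse(preyR > 0, P / preyR, 0)
  qA <- ifelse(preyR > 0, A / preyR, 0)
  c(H = p$r_h * H * fh - phi * P - C * Gc * qH,
    I = phi * P - I / p$h - C * Gc * qI,
    P = p$eps * I / p$h - phi * P - p$m * P - R * Gr * qP,
    D = p$r_d * D * fd - C * Gc * qD,
    A = p$r_a * A * fa - R * Gr * qA,
    C = rc * C,
    R = rr * R,
    N = -(H * p$r_h * fh * p$Q_h + H * p$r_d * fd * p$Q_d +
            H * p$r_a * fa * p$Q_a))
}

# random admissible full-community states for property-style loops
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    community_state(
      H = runif(1, 0, 1e7), I = runif(1, 0, 1e6), P = runif(1, 0, 1e9),
      D = runif(1, 0, 1e7), A = runif(1, 0, 1e9), C = runif(1, 0, 1e5),
      R = runif(1, 0, 1e4), N = runif(1, 0, 40)
    )
  })
}
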