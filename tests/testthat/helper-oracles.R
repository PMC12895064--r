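# Independent direct-arithmetic transcriptions of the four model
# equations, used only as oracles; they share no code with the package
# evaluators.

oracle_harmonic <- function(t, A, gamma, omega, phi, y) {
  A * exp(gamma * t / 2) * cos(omega * t + phi) + y
}

oracle_square <- function(t, A, gamma, omega, phi, y) {
  A * exp(gamma * t / 2) *
    (sin(omega * t + phi) + 0.25 * sin(3 * omega * t + 3 * phi)) + y
}

oracle_cycloid <- function(t, A, gamma, omega, phi, y) {
  A * exp(gamma * t / 2) *
    (-0.5) * (cos(2 * omega * t + 2 * phi) - 2 * cos(omega * t + phi)) + y
}

oracle_transient <- function(t, A, omega, p_tau, sigma, y) {
  period <- 2 * pi / omega
  u <- t - period * floor(t / period)
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    out[i] <- if (u[i] - p_tau >= 0) {
      A * exp(-0.5 * ((u[i] - p_tau) / sigma)^2) + y
    } else {
      y
    }
  }
  out
}

oracle_eval <- function(kind, t, p) {
  switch(kind,
    harmonic = oracle_harmonic(t, p$A, p$gamma, p$omega, p$phi, p$y),
    square = oracle_square(t, p$A, p$gamma, p$omega, p$phi, p$y),
    cycloid = oracle_cycloid(t, p$A, p$gamma, p$omega, p$phi, p$y),
    transient = oracle_transient(t, p$A, p$omega, p$p_tau, p$sigma, p$y))
}

# One random admissible parameter draw for `kind`.
draw_oracle_params <- function(kind, gamma_zero = FALSE) {
  omega <- runif(1, 2 * pi / 28, 2 * pi / 20)
  period <- 2 * pi / omega
  list(A = runif(1, 0.5, 3),
       gamma = if (gamma_zero) 0 else runif(1, -0.1, 0.1),
       omega = omega,
       phi = runif(1, 0, 2 * pi),
       y = runif(1, -2, 2),
       p_tau = runif(1, 0, period * 0.999),
       sigma = runif(1, 0.5, 3))
}

# Brute-force Kendall tau-b by explicit pair enumeration, with tie
# correction.
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    tab <- table(v)
    sum(tab * (tab - 1) / 2)
  }
  n1 <- tie_term(x)
  n2 <- tie_term(y)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Hand-coded Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Upper-tail F probability through the incomplete-beta identity,
# independent of stats::pf's direct route.
oracle_f_tail <- function(f, df1, df2) {
  stats::pbeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
}

withr_local_file <- function(name) {
  withr::local_tempfile(pattern = sub("\\..*$", "", name),
                        fileext = paste0(".", sub("^.*\\.", "", name)),
                        .local_envir = parent.frame())
}

# Noiseless single-feature series on the default circadian design.
make_series <- function(kind, params, span = 48, interval = 2,
                        replicates = 2, noise_sd = 0) {
  grid <- seq(0, span - interval, by = interval)
  tt <- rep(grid, each = replicates)
  mu <- oracle_eval(kind, tt, params)
  data.frame(time = tt,
             replicate = rep(paste0("r", seq_len(replicates)),
                             times = length(grid)),
             value = mu + rnorm(length(tt), 0, noise_sd))
}
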