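# Independent numerical oracles used to validate the closed-form machinery.
# These deliberately avoid the package's own likelihood code paths: plain
# composite-Simpson quadrature over dense grids, and direct arithmetic.

simpson_weights <- function(n) {
  # n odd number of points
  w <- rep(c(4, 2), length.out = n - 2)
  c(1, w[-length(w)], 4, 1) / 3
}

simpson <- function(fx, h) {
  n <- length(fx)
  stopifnot(n %% 2 == 1)
  h * sum(simpson_weights(n) * fx)
}

# \int N(u_v; s, sv^2) N(u_a; s, sa^2) N(s; mu, sp^2) ds by quadrature
quad_pair_c1 <- function(u_v, u_a, sv, sa, mu, sp,
                         lower = -20, upper = 20, n = 16001) {
  s <- seq(lower, upper, length.out = n)
  h <- s[2] - s[1]
  simpson(dnorm(u_v, s, sv) * dnorm(u_a, s, sa) * dnorm(s, mu, sp), h)
}

# product of the two single-cue marginals, each by quadrature
quad_pair_c2 <- function(u_v, u_a, sv, sa, mu, sp,
                         lower = -20, upper = 20, n = 16001) {
  s <- seq(lower, upper, length.out = n)
  h <- s[2] - s[1]
  simpson(dnorm(u_v, s, sv) * dnorm(s, mu, sp), h) *
    simpson(dnorm(u_a, s, sa) * dnorm(s, mu, sp), h)
}

# log-normal numerosity marginals by quadrature over s > 0
quad_lnorm_c1 <- function(x_v, x_a, sv, sa, mu_p, sp,
                          lower = 1e-6, upper = 60, n = 16001) {
  s <- seq(lower, upper, length.out = n)
  h <- s[2] - s[1]
  simpson(dlnorm(x_v, log(s), sv) * dlnorm(x_a, log(s), sa) *
            dlnorm(s, log(mu_p), sp), h)
}

quad_lnorm_single <- function(x, sigma, mu_p, sp,
                              lower = 1e-6, upper = 60, n = 16001) {
  s <- seq(lower, upper, length.out = n)
  h <- s[2] - s[1]
  simpson(dlnorm(x, log(s), sigma) * dlnorm(s, log(mu_p), sp), h)
}

# posterior over the causal structure from quadrature marginals
quad_posterior_c1 <- function(x_v, x_a, t_v, t_a, p, use_temporal = TRUE) {
  lx1 <- quad_pair_c1(x_v, x_a, p$sigma_v, p$sigma_a, p$mu_p, p$sigma_p)
  lx2 <- quad_pair_c2(x_v, x_a, p$sigma_v, p$sigma_a, p$mu_p, p$sigma_p)
  if (use_temporal) {
    lt1 <- quad_pair_c1(t_v, t_a, p$sigma_vt, p$sigma_at, p$mu_tp, p$sigma_tp,
                        lower = -5000, upper = 5000, n = 40001)
    lt2 <- quad_pair_c2(t_v, t_a, p$sigma_vt, p$sigma_at, p$mu_tp, p$sigma_tp,
                        lower = -5000, upper = 5000, n = 40001)
  } else {
    lt1 <- lt2 <- 1
  }
  num <- lx1 * lt1 * p$p_common
  num / (num + lx2 * lt2 * (1 - p$p_common))
}

# analytic response-cell probabilities for a unisensory Gaussian trial:
# the single-cue estimate is linear in the evidence, so the three readout
# bins are Gaussian tail areas
uni_cell_probs_analytic <- function(true_count, sigma, p) {
  a <- (1 / sigma^2) / (1 / sigma^2 + 1 / p$sigma_p^2)
  b <- (p$mu_p / p$sigma_p^2) / (1 / sigma^2 + 1 / p$sigma_p^2)
  m <- a * true_count + b
  s <- a * sigma
  c(pnorm(0.5, m, s),
    pnorm(1.5, m, s) - pnorm(0.5, m, s),
    1 - pnorm(1.5, m, s))
}

# independent recomputation of the variance-explained statistic from a
# dataset and a set of per-condition prediction tables
r2_reference <- function(data, pred_tables) {
  obs <- c(); prd <- c()
  for (key in names(pred_tables)) {
    parts <- strsplit(key, "_")[[1]]
    nf <- as.integer(substr(parts[1], 1, 1))
    nb <- as.integer(substr(parts[1], 3, 3))
    soa <- as.integer(sub("soa", "", parts[2]))
    sel <- data$n_flashes == nf & data$n_beeps == nb & data$soa_ms == soa
    tab <- pred_tables[[key]]
    if (nf >= 1 && nb >= 1) {
      for (r in 0:2) obs <- c(obs, mean(data$resp_flashes[sel] == r))
      prd <- c(prd, rowSums(tab))
      for (r in 0:2) obs <- c(obs, mean(data$resp_beeps[sel] == r))
      prd <- c(prd, colSums(tab))
    } else if (nf >= 1) {
      for (r in 0:2) obs <- c(obs, mean(data$resp_flashes[sel] == r))
      prd <- c(prd, tab)
    } else {
      for (r in 0:2) obs <- c(obs, mean(data$resp_beeps[sel] == r))
      prd <- c(prd, tab)
    }
  }
  1 - sum((obs - prd)^2) / sum((obs - mean(obs))^2)
}

# random parameter/evidence draws for the oracle-equivalence checks
draw_oracle_case <- function() {
  list(params = bci_params(sigma_v = runif(1, 0.2, 2),
                           sigma_a = runif(1, 0.2, 2),
                           p_common = runif(1, 0.05, 0.95),
                           sigma_p = runif(1, 0.3, 3),
                           mu_p = runif(1, 0, 3),
                           sigma_vt = runif(1, 20, 150),
                           sigma_at = runif(1, 20, 150),
                           mu_tp = runif(1, -200, 400),
                           sigma_tp = runif(1, 100, 800)),
       x_v = runif(1, -3, 5), x_a = runif(1, -3, 5),
       t_v = runif(1, -800, 1300), t_a = runif(1, -800, 1300))
}
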