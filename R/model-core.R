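#' @name model-core
#' @title Closed-form machinery of the numerosity-by-time causal-inference observer
#'
#' @description
#' The observer receives four pieces of trial evidence: numerosity evidence
#' `x_v`, `x_a` (noisy internal counts of flashes and beeps) and onset evidence
#' `t_v`, `t_a` (noisy internal arrival times, ms). Two causal structures
#' compete: a common cause (`C = 1`), under which both modalities' evidence
#' arises from one latent source, and independent causes (`C = 2`). Each
#' structure's likelihood is obtained by marginalizing the latent source(s)
#' under Gaussian noise and a Gaussian prior, which has a closed form:
#' for the common cause the two cues must agree with each other and jointly
#' with the prior; for independent causes each cue is reconciled with the prior
#' separately. Numerosity and time are conditionally independent given `C`, so
#' the posterior probability of a common cause multiplies the two dimensions'
#' likelihood factors with the prior `p_common` and normalizes over `C`.
#'
#' All functions are vectorized over their evidence arguments.
NULL

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  invisible(x)
}

# log \int N(u_v; s, sv^2) N(u_a; s, sa^2) N(s; mu, sp^2) ds
log_pair_c1 <- function(u_v, u_a, sv, sa, mu, sp) {
  vw <- 1 / (1 / sv^2 + 1 / sa^2)
  w <- (u_v / sv^2 + u_a / sa^2) * vw
  dnorm(u_v - u_a, 0, sqrt(sv^2 + sa^2), log = TRUE) +
    dnorm(w, mu, sqrt(vw + sp^2), log = TRUE)
}

# log [\int N(u_v; s, sv^2) N(s; mu, sp^2) ds][\int N(u_a; s, sa^2) N(s; mu, sp^2) ds]
log_pair_c2 <- function(u_v, u_a, sv, sa, mu, sp) {
  dnorm(u_v, mu, sqrt(sv^2 + sp^2), log = TRUE) +
    dnorm(u_a, mu, sqrt(sa^2 + sp^2), log = TRUE)
}

log_numerosity_likelihoods <- function(x_v, x_a, params) {
  if (params$family == "lognormal") {
    if (any(x_v <= 0) || any(x_a <= 0))
      stop("log-normal numerosity evidence must be > 0", call. = FALSE)
    y_v <- log(x_v); y_a <- log(x_a); lmu <- log(params$mu_p)
    list(c1 = log_pair_c1(y_v, y_a, params$sigma_v, params$sigma_a,
                          lmu, params$sigma_p) - y_v - y_a,
         c2 = log_pair_c2(y_v, y_a, params$sigma_v, params$sigma_a,
                          lmu, params$sigma_p) - y_v - y_a)
  } else {
    list(c1 = log_pair_c1(x_v, x_a, params$sigma_v, params$sigma_a,
                          params$mu_p, params$sigma_p),
         c2 = log_pair_c2(x_v, x_a, params$sigma_v, params$sigma_a,
                          params$mu_p, params$sigma_p))
  }
}

log_temporal_likelihoods <- function(t_v, t_a, params) {
  list(c1 = log_pair_c1(t_v, t_a, params$sigma_vt, params$sigma_at,
                        params$mu_tp, params$sigma_tp),
       c2 = log_pair_c2(t_v, t_a, params$sigma_vt, params$sigma_at,
                        params$mu_tp, params$sigma_tp))
}

#' Marginal likelihoods of paired numerosity evidence under each causal structure
#'
#' Computes `p(x_v, x_a | C = 1)` (single latent numerosity shared by both
#' modalities, marginalized under the numerosity prior) and
#' `p(x_v, x_a | C = 2)` (independent latent numerosities, each marginalized
#' under the same prior). Under the Gaussian family both are closed-form
#' Gaussian densities; under the log-normal family the same closed forms apply
#' on the log-numerosity scale.
#'
#' @param x_v,x_a Numerosity evidence (finite numeric vectors; strictly
#'   positive for the log-normal family).
#' @param params A [bci_params()] object.
#' @param log Return log-densities?
#' @return A list with components `c1` and `c2` (densities, or log-densities
#'   when `log = TRUE`).
#' @examples
#' numerosity_likelihoods(1, 2, bci_params())
#' @export
numerosity_likelihoods <- function(x_v, x_a, params, log = FALSE) {
  validate_bci_params(params)
  check_finite(x_v, "x_v"); check_finite(x_a, "x_a")
  l <- log_numerosity_likelihoods(x_v, x_a, params)
  if (log) l else lapply(l, exp)
}

#' Marginal likelihoods of paired onset evidence under each causal structure
#'
#' The temporal analogue of [numerosity_likelihoods()]: the latent event time
#' is marginalized under the temporal prior, with the onset noise SDs
#' `sigma_vt` / `sigma_at` in place of the numerosity noise SDs. The temporal
#' dimension is always Gaussian.
#'
#' @param t_v,t_a Onset evidence in ms (finite numeric vectors).
#' @inheritParams numerosity_likelihoods
#' @return A list with components `c1` and `c2`.
#' @examples
#' temporal_likelihoods(0, 500, bci_params())
#' @export
temporal_likelihoods <- function(t_v, t_a, params, log = FALSE) {
  validate_bci_params(params)
  check_finite(t_v, "t_v"); check_finite(t_a, "t_a")
  l <- log_temporal_likelihoods(t_v, t_a, params)
  if (log) l else lapply(l, exp)
}

#' Posterior probability of a common cause
#'
#' Combines the numerosity and temporal likelihood factors (conditionally
#' independent given the causal structure) with the prior `p_common` and
#' normalizes over the two structures:
#' `p_c1 = L_num_c1 * L_t_c1 * p_common / (L_num_c1 * L_t_c1 * p_common +
#' L_num_c2 * L_t_c2 * (1 - p_common))`.
#'
#' `denominator = "marginal"` replaces the normalizing constant with the
#' product of the two per-dimension mixture marginals. That form does not
#' normalize the joint posterior (the probabilities of the two structures need
#' not sum to one) and is provided only for sensitivity analyses; the default
#' `"joint"` is the standard Bayes normalization.
#'
#' @param x_v,x_a Numerosity evidence (bimodal trial; both required).
#' @param t_v,t_a Onset evidence in ms.
#' @param params A [bci_params()] object.
#' @param use_temporal If `FALSE`, the temporal factors are dropped (set to 1),
#'   reducing the observer to causal inference on numerosity alone.
#' @param denominator `"joint"` (standard normalization) or `"marginal"`.
#' @return A list with `p_c1` and the four likelihood factors
#'   `l_num_c1`, `l_num_c2`, `l_t_c1`, `l_t_c2`.
#' @examples
#' posterior_common_cause(1, 2, 0, 0, bci_params())$p_c1
#' @export
posterior_common_cause <- function(x_v, x_a, t_v, t_a, params,
                                   use_temporal = TRUE,
                                   denominator = c("joint", "marginal")) {
  denominator <- match.arg(denominator)
  validate_bci_params(params)
  check_finite(x_v, "x_v"); check_finite(x_a, "x_a")
  if (use_temporal) {
    check_finite(t_v, "t_v"); check_finite(t_a, "t_a")
  }
  ln <- log_numerosity_likelihoods(x_v, x_a, params)
  if (use_temporal) {
    lt <- log_temporal_likelihoods(t_v, t_a, params)
  } else {
    z <- rep(0, length(ln$c1))
    lt <- list(c1 = z, c2 = z)
  }
  pc <- params$p_common
  if (denominator == "joint") {
    if (pc >= 1) {
      p1 <- rep(1, length(ln$c1))
    } else if (pc <= 0) {
      p1 <- rep(0, length(ln$c1))
    } else {
      l1 <- log(pc) + ln$c1 + lt$c1
      l2 <- log1p(-pc) + ln$c2 + lt$c2
      p1 <- stats::plogis(l1 - l2)
    }
  } else {
    num <- exp(ln$c1 + lt$c1) * pc
    dx <- exp(ln$c1) * pc + exp(ln$c2) * (1 - pc)
    dt <- exp(lt$c1) * pc + exp(lt$c2) * (1 - pc)
    p1 <- num / (dx * dt)
  }
  list(p_c1 = p1,
       l_num_c1 = exp(ln$c1), l_num_c2 = exp(ln$c2),
       l_t_c1 = exp(lt$c1), l_t_c2 = exp(lt$c2))
}

#' Single-cue (segregated) numerosity estimate
#'
#' Posterior-mean numerosity for one cue under its own cause: the
#' precision-weighted combination of the evidence `x` (precision `1/sigma^2`)
#' and the numerosity prior (`mu_p`, precision `1/sigma_p^2`). Under the
#' log-normal family the shrinkage happens on the log scale and the posterior
#' mean `exp(m + v/2)` is returned.
#'
#' @param x Numerosity evidence for the present modality.
#' @param sigma Noise SD of that modality (> 0).
#' @param params A [bci_params()] object (supplies the prior).
#' @return Numeric vector of estimates.
#' @examples
#' estimate_segregated(2, 0.33, bci_params())
#' @export
estimate_segregated <- function(x, sigma, params) {
  validate_bci_params(params)
  check_finite(x, "x")
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (params$family == "lognormal") {
    if (any(x <= 0)) stop("log-normal evidence must be > 0", call. = FALSE)
    prec <- 1 / sigma^2 + 1 / params$sigma_p^2
    m <- (log(x) / sigma^2 + log(params$mu_p) / params$sigma_p^2) / prec
    exp(m + 0.5 / prec)
  } else {
    (x / sigma^2 + params$mu_p / params$sigma_p^2) /
      (1 / sigma^2 + 1 / params$sigma_p^2)
  }
}

#' Fused (common-cause) numerosity estimate
#'
#' Precision-weighted combination of the visual evidence, the auditory
#' evidence, and (unless `flat_prior = TRUE`) the numerosity prior; this is the
#' optimal estimate when a single source generated both streams. With
#' `flat_prior = TRUE` the prior term is removed, leaving pure
#' reliability-weighted cue combination.
#'
#' @param x_v,x_a Numerosity evidence.
#' @param params A [bci_params()] object.
#' @param flat_prior Drop the prior term?
#' @return Numeric vector of fused estimates.
#' @examples
#' estimate_fused(1, 2, bci_params())
#' @export
estimate_fused <- function(x_v, x_a, params, flat_prior = FALSE) {
  validate_bci_params(params)
  check_finite(x_v, "x_v"); check_finite(x_a, "x_a")
  if (params$family == "lognormal") {
    if (any(x_v <= 0) || any(x_a <= 0))
      stop("log-normal evidence must be > 0", call. = FALSE)
    prec <- 1 / params$sigma_v^2 + 1 / params$sigma_a^2 +
      if (flat_prior) 0 else 1 / params$sigma_p^2
    m <- (log(x_v) / params$sigma_v^2 + log(x_a) / params$sigma_a^2 +
            if (flat_prior) 0 else log(params$mu_p) / params$sigma_p^2) / prec
    exp(m + 0.5 / prec)
  } else {
    prec <- 1 / params$sigma_v^2 + 1 / params$sigma_a^2 +
      if (flat_prior) 0 else 1 / params$sigma_p^2
    (x_v / params$sigma_v^2 + x_a / params$sigma_a^2 +
       if (flat_prior) 0 else params$mu_p / params$sigma_p^2) / prec
  }
}

#' Model-averaged numerosity estimates for a bimodal trial
#'
#' The final per-modality estimate is the posterior-probability-weighted mix of
#' the fused and segregated estimates (model averaging, which minimizes
#' expected squared error):
#' `s_hat_a = p_c1 * s_fused + (1 - p_c1) * s_a_seg`, and analogously for
#' vision. Each output therefore lies between its fused and segregated
#' estimates.
#'
#' @inheritParams posterior_common_cause
#' @return A data frame with columns `s_hat_v`, `s_hat_a`, `s_hat_fused`,
#'   `s_hat_v_seg`, `s_hat_a_seg`, `p_c1`.
#' @examples
#' estimate_model_average(1, 2, 0, 300, bci_params())
#' @export
estimate_model_average <- function(x_v, x_a, t_v, t_a, params,
                                   use_temporal = TRUE,
                                   denominator = c("joint", "marginal")) {
  post <- posterior_common_cause(x_v, x_a, t_v, t_a, params,
                                 use_temporal = use_temporal,
                                 denominator = denominator)
  fused <- estimate_fused(x_v, x_a, params)
  seg_v <- estimate_segregated(x_v, params$sigma_v, params)
  seg_a <- estimate_segregated(x_a, params$sigma_a, params)
  p1 <- post$p_c1
  data.frame(s_hat_v = p1 * fused + (1 - p1) * seg_v,
             s_hat_a = p1 * fused + (1 - p1) * seg_a,
             s_hat_fused = fused,
             s_hat_v_seg = seg_v,
             s_hat_a_seg = seg_a,
             p_c1 = p1)
}

#' Map a continuous numerosity estimate to a discrete report
#'
#' Observers answer with one of three keys (0, 1, or 2). The continuous
#' estimate is read out as the nearest integer, clamped to `[0, 2]`; half-way
#' ties round up.
#'
#' @param s_hat Finite numeric vector of continuous estimates.
#' @return Integer vector in `{0, 1, 2}`.
#' @examples
#' discretize_response(c(1.4, -0.7, 1.5))
#' @export
discretize_response <- function(s_hat) {
  check_finite(s_hat, "s_hat")
  as.integer(pmin(2, pmax(0, floor(s_hat + 0.5))))
}
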