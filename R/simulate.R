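#' @name simulator
#' @title Monte Carlo simulation of flash/beep trials
#'
#' @description
#' The generative observer works forward: true counts and onsets define the
#' stimulus; each present modality delivers numerosity evidence
#' `x ~ N(true count, sigma^2)` and onset evidence `t ~ N(true onset,
#' sigma_t^2)` (all draws independent); the observer then applies causal
#' inference (or the constrained variant's rule) and reads out a discrete 0/1/2
#' report per present modality. One seeded generator is used per dataset,
#' consumed in trial order; every trial consumes exactly four standard-normal
#' draws (absent modalities' draws are burned) so that trial streams stay
#' aligned across conditions.
NULL

# segregated estimate with optional flat prior (internal; vectorized)
seg_estimate <- function(x, sigma, params, flat_prior = FALSE) {
  if (params$family == "lognormal") {
    if (flat_prior) return(exp(log(x) + 0.5 * sigma^2))
    prec <- 1 / sigma^2 + 1 / params$sigma_p^2
    m <- (log(x) / sigma^2 + log(params$mu_p) / params$sigma_p^2) / prec
    exp(m + 0.5 / prec)
  } else {
    if (flat_prior) return(x)
    (x / sigma^2 + params$mu_p / params$sigma_p^2) /
      (1 / sigma^2 + 1 / params$sigma_p^2)
  }
}

# vectorized evidence -> responses map shared by the simulator and the R
# likelihood engine. nv/na: true counts (0 = absent); ov/oa: true onsets;
# z: n x 4 matrix of standard normals (x_v, x_a, t_v, t_a).
responses_from_samples <- function(nv, na, ov, oa, params, flags, z) {
  n <- length(nv)
  resp_v <- rep(NA_integer_, n)
  resp_a <- rep(NA_integer_, n)
  lognorm <- params$family == "lognormal"
  noisy_count <- function(true, sigma, zz) {
    if (lognorm) exp(log(true) + sigma * zz) else true + sigma * zz
  }
  bi <- nv >= 1L & na >= 1L
  if (any(bi)) {
    x_v <- noisy_count(nv[bi], params$sigma_v, z[bi, 1L])
    x_a <- noisy_count(na[bi], params$sigma_a, z[bi, 2L])
    if (flags$force_fusion) {
      est <- estimate_fused(x_v, x_a, params, flat_prior = flags$flat_prior)
      resp_v[bi] <- resp_a[bi] <- discretize_response(est)
    } else {
      t_v <- ov[bi] + params$sigma_vt * z[bi, 3L]
      t_a <- oa[bi] + params$sigma_at * z[bi, 4L]
      ma <- estimate_model_average(x_v, x_a, t_v, t_a, params,
                                   use_temporal = flags$use_temporal)
      resp_v[bi] <- discretize_response(ma$s_hat_v)
      resp_a[bi] <- discretize_response(ma$s_hat_a)
    }
  }
  uv <- nv >= 1L & na == 0L
  if (any(uv)) {
    x_v <- noisy_count(nv[uv], params$sigma_v, z[uv, 1L])
    resp_v[uv] <- discretize_response(
      seg_estimate(x_v, params$sigma_v, params, flat_prior = flags$flat_prior))
  }
  ua <- na >= 1L & nv == 0L
  if (any(ua)) {
    x_a <- noisy_count(na[ua], params$sigma_a, z[ua, 2L])
    resp_a[ua] <- discretize_response(
      seg_estimate(x_a, params$sigma_a, params, flat_prior = flags$flat_prior))
  }
  list(resp_v = resp_v, resp_a = resp_a)
}

#' Draw one trial's internal sensory evidence
#'
#' Samples the four pieces of evidence for a trial from the generative model,
#' using the current R random stream. Four standard-normal draws are always
#' consumed, so trial streams remain aligned whether or not both modalities
#' are present; absent modalities carry `NA` evidence and a `FALSE` presence
#' flag, and their evidence must never be used downstream.
#'
#' @param n_flashes,n_beeps True stimulus counts (0 = modality absent).
#' @param soa_ms Stimulus onset asynchrony in ms (must be 0 for unisensory
#'   trials).
#' @param lead Leading modality for bimodal trials.
#' @param params A [bci_params()] object.
#' @return A list with `x_v`, `x_a`, `t_v`, `t_a`, `has_v`, `has_a`.
#' @examples
#' set.seed(1)
#' sample_sensory(1, 2, 150, "visual_first", bci_params())
#' @export
sample_sensory <- function(n_flashes, n_beeps, soa_ms = 0,
                           lead = c("visual_first", "auditory_first"),
                           params = bci_params()) {
  lead <- match.arg(lead)
  validate_bci_params(params)
  stopifnot(n_flashes %in% 0:2, n_beeps %in% 0:2, n_flashes + n_beeps >= 1)
  if ((n_flashes == 0 || n_beeps == 0) && soa_ms != 0)
    stop("unisensory trials must have soa_ms = 0", call. = FALSE)
  z <- rnorm(4)
  has_v <- n_flashes >= 1
  has_a <- n_beeps >= 1
  if (has_v && has_a) {
    on <- true_onsets(n_flashes, n_beeps, soa_ms, lead)
  } else {
    on <- c(s_vt = 0, s_at = 0)
  }
  noisy <- function(true, sigma, zz) {
    if (params$family == "lognormal") exp(log(true) + sigma * zz)
    else true + sigma * zz
  }
  list(x_v = if (has_v) noisy(n_flashes, params$sigma_v, z[1]) else NA_real_,
       x_a = if (has_a) noisy(n_beeps, params$sigma_a, z[2]) else NA_real_,
       t_v = if (has_v) on[["s_vt"]] + params$sigma_vt * z[3] else NA_real_,
       t_a = if (has_a) on[["s_at"]] + params$sigma_at * z[4] else NA_real_,
       has_v = has_v, has_a = has_a)
}

#' Simulate one trial's discrete flash/beep reports
#'
#' Samples sensory evidence with [sample_sensory()] and pushes it through the
#' requested observer variant: for bimodal trials, causal inference and model
#' averaging (or the fused rule for the `fusion`/`mle` variants) followed by
#' discrete readout of each modality's estimate; for unisensory trials, the
#' single-cue shrinkage estimate of the present modality. Absent modalities
#' report `NA`.
#'
#' @inheritParams sample_sensory
#' @param variant Observer variant, see [bci_variants()].
#' @return A list with integer `resp_v` and `resp_a` (`NA` for an absent
#'   modality).
#' @examples
#' set.seed(1)
#' simulate_trial(1, 2, 0, "visual_first", bci_params())
#' @export
simulate_trial <- function(n_flashes, n_beeps, soa_ms = 0,
                           lead = c("visual_first", "auditory_first"),
                           params = bci_params(), variant = "bci2d") {
  lead <- match.arg(lead)
  validate_bci_params(params)
  stopifnot(n_flashes %in% 0:2, n_beeps %in% 0:2, n_flashes + n_beeps >= 1)
  flags <- variant_flags(variant)
  z <- matrix(rnorm(4), 1L, 4L)
  if (n_flashes >= 1 && n_beeps >= 1) {
    on <- true_onsets(n_flashes, n_beeps, soa_ms, lead)
  } else {
    on <- c(s_vt = 0, s_at = 0)
  }
  r <- responses_from_samples(as.integer(n_flashes), as.integer(n_beeps),
                              on[["s_vt"]], on[["s_at"]], params, flags, z)
  list(resp_v = r$resp_v, resp_a = r$resp_a)
}

#' Simulate a full observer dataset
#'
#' Runs [simulate_trial()] over every trial of a design with a single seeded
#' random stream consumed in trial order, returning a trial-level dataset in
#' the package's standard schema.
#'
#' @param design A [build_design()] object (or data frame with columns
#'   `n_flashes`, `n_beeps`, `soa_ms`, `lead`).
#' @param params Generating [bci_params()].
#' @param seed Integer seed for the observer's random stream.
#' @param observer_id Identifier stored in the dataset.
#' @param variant Generating observer variant.
#' @return A data frame of class `"bci_data"` with columns `observer_id`,
#'   `trial_index`, `n_flashes`, `n_beeps`, `soa_ms`, `lead`, `resp_flashes`,
#'   `resp_beeps` (`NA` responses for absent modalities).
#' @examples
#' d <- simulate_observer(build_design(reps = 1), bci_params(), seed = 7)
#' head(d)
#' @export
simulate_observer <- function(design, params = bci_params(), seed = 1L,
                              observer_id = "obs1", variant = "bci2d") {
  validate_bci_params(params)
  flags <- variant_flags(variant)
  n <- nrow(design)
  set.seed(seed)
  z <- matrix(rnorm(4L * n), ncol = 4L, byrow = TRUE)
  nv <- as.integer(design$n_flashes)
  na_ <- as.integer(design$n_beeps)
  ov <- oa <- numeric(n)
  bi <- nv >= 1L & na_ >= 1L
  if (any(bi)) {
    vf <- design$lead[bi] == "visual_first"
    ov[bi] <- ifelse(vf, 0, design$soa_ms[bi])
    oa[bi] <- ifelse(vf, design$soa_ms[bi], 0)
  }
  r <- responses_from_samples(nv, na_, ov, oa, params, flags, z)
  out <- data.frame(observer_id = observer_id,
                    trial_index = seq_len(n),
                    n_flashes = nv, n_beeps = na_,
                    soa_ms = as.integer(design$soa_ms),
                    lead = as.character(design$lead),
                    resp_flashes = r$resp_v, resp_beeps = r$resp_a,
                    stringsAsFactors = FALSE)
  class(out) <- c("bci_data", "data.frame")
  out
}

#' Between-observer variability of the generating parameters
#'
#' Default per-parameter SDs used when a synthetic cohort draws each
#' observer's generating parameters around the group means: the across-subject
#' SDs implied by the group-level standard errors of the five free parameters
#' in the modelled paradigm (SE times the square root of the group size of
#' 24).
#'
#' @return Named numeric vector of SDs for `sigma_v`, `sigma_a`, `p_common`,
#'   `sigma_p`, `mu_p`.
#' @examples
#' between_observer_sd()
#' @export
between_observer_sd <- function() {
  c(sigma_v = 0.07, sigma_a = 0.003, p_common = 0.06,
    sigma_p = 0.24, mu_p = 0.12) * sqrt(24)
}

#' Generate a synthetic observer cohort
#'
#' Simulates `n_observers` datasets from the generative model. Per-observer
#' seeds are derived deterministically from the master `seed`, so the whole
#' cohort is reproducible from one integer. By default every observer shares
#' the generating parameters in `params`; passing `between_sd` (a named vector
#' of SDs for free parameters, e.g. [between_observer_sd()]) instead draws
#' each observer's parameters from normal distributions around `params`,
#' truncated to the standard fitting bounds.
#'
#' @param n_observers Number of observers.
#' @param params Group-level generating [bci_params()].
#' @param design A [build_design()] object shared by all observers.
#' @param seed Master integer seed.
#' @param variant Generating variant.
#' @param between_sd Optional named numeric vector of between-observer SDs.
#' @return A list of `"bci_data"` datasets (class `"bci_cohort"`), with the
#'   per-observer generating parameters attached as attribute
#'   `"generating_params"`.
#' @examples
#' coh <- simulate_cohort(2, design = build_design(reps = 1), seed = 3)
#' length(coh)
#' @export
simulate_cohort <- function(n_observers, params = bci_params(),
                            design = build_design(), seed = 1L,
                            variant = "bci2d", between_sd = NULL) {
  stopifnot(n_observers >= 1)
  validate_bci_params(params)
  set.seed(seed)
  obs_seeds <- sample.int(.Machine$integer.max - 1L, n_observers)
  par_draws <- vector("list", n_observers)
  b <- default_bounds()
  for (i in seq_len(n_observers)) {
    pi <- params
    if (!is.null(between_sd)) {
      for (nm in names(between_sd)) {
        lo <- b[[nm]][1]; hi <- b[[nm]][2]
        pi[[nm]] <- min(max(rnorm(1, params[[nm]], between_sd[[nm]]), lo), hi)
      }
      validate_bci_params(pi)
    }
    par_draws[[i]] <- pi
  }
  out <- vector("list", n_observers)
  for (i in seq_len(n_observers)) {
    out[[i]] <- simulate_observer(design, par_draws[[i]], seed = obs_seeds[i],
                                  observer_id = sprintf("obs%02d", i),
                                  variant = variant)
  }
  names(out) <- vapply(out, function(d) d$observer_id[1], "")
  structure(out, generating_params = par_draws, seed = as.integer(seed),
            variant = variant, class = c("bci_cohort", "list"))
}

#' Monte Carlo response distribution for one condition
#'
#' Simulates `n_mc` trials of a single condition and tabulates the empirical
#' distribution of reports: a 3x3 joint table over (flash report, beep report)
#' for bimodal conditions, or a 3-vector for unisensory conditions. The result
#' is deterministic given `seed`.
#'
#' @inheritParams sample_sensory
#' @param n_mc Number of Monte Carlo trials (>= 1).
#' @param seed Integer seed.
#' @param variant Observer variant (use `"bci1d"` to ignore the temporal
#'   dimension).
#' @return A list of class `"bci_response_distribution"` with the `condition`,
#'   the probability `table`, `n_mc` and `seed`.
#' @examples
#' rd <- response_distribution(1, 2, 0, n_mc = 1000, seed = 1)
#' sum(rd$table)
#' @export
response_distribution <- function(n_flashes, n_beeps, soa_ms = 0,
                                  lead = c("visual_first", "auditory_first"),
                                  params = bci_params(), n_mc = 10000,
                                  seed = 1L, variant = "bci2d") {
  lead <- match.arg(lead)
  if (n_mc < 1) stop("n_mc must be >= 1", call. = FALSE)
  validate_bci_params(params)
  stopifnot(n_flashes %in% 0:2, n_beeps %in% 0:2, n_flashes + n_beeps >= 1)
  ct <- condition_table(data.frame(n_flashes = n_flashes, n_beeps = n_beeps,
                                   soa_ms = soa_ms, lead = lead))
  counts <- engine_cell_counts(ct, params, variant, n_mc, seed)
  if (ct$bimodal[1]) {
    tab <- matrix(counts[1, ] / n_mc, 3, 3, byrow = TRUE,
                  dimnames = list(flash = 0:2, beep = 0:2))
  } else {
    tab <- setNames(counts[1, 1:3] / n_mc, 0:2)
  }
  structure(list(condition = ct$condition[1], n_flashes = n_flashes,
                 n_beeps = n_beeps, soa_ms = soa_ms, lead = lead,
                 table = tab, n_mc = n_mc, seed = as.integer(seed)),
            class = "bci_response_distribution")
}

#' @export
print.bci_response_distribution <- function(x, ...) {
  cat("Simulated response distribution for", x$condition,
      sprintf("(n_mc = %d, seed = %d)\n", x$n_mc, x$seed))
  print(round(x$table, 4))
  invisible(x)
}
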