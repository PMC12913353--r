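#' Fitting bounds for the free parameters
#'
#' Box constraints used by [fit_bci()] (the optimizer searches an unconstrained
#' transformed space mapped into these boxes): sensory noise SDs in
#' `[0.05, 5]` numerosity units, prior SD in `[0.1, 10]`, prior mean in
#' `[0, 3]`, common-cause prior in `[0.01, 0.99]`.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(sigma_v = c(0.05, 5), sigma_a = c(0.05, 5),
       p_common = c(0.01, 0.99), sigma_p = c(0.1, 10), mu_p = c(0, 3))
}

#' Control settings for model fitting
#'
#' @param n_mc Monte Carlo trials per condition for the likelihood
#'   approximation.
#' @param restarts Number of Nelder-Mead restarts from Latin-hypercube
#'   starting points.
#' @param seed Integer seed controlling the common random numbers and the
#'   starting points.
#' @param epsilon Per-cell probability floor.
#' @param maxit Maximum simplex iterations per restart.
#' @param reltol Relative convergence tolerance per restart.
#' @param bounds Named list of `c(lower, upper)` boxes, see
#'   [default_bounds()].
#' @param refine_n_mc Monte Carlo sample for the refinement stage: after the
#'   multi-start search at `n_mc`, the best solution is polished with a single
#'   simplex run on a likelihood surface this many draws per condition
#'   (default `6 * n_mc`; set to 0 to disable). The finer surface removes the
#'   Monte Carlo noise floor that otherwise lets weakly identified parameters
#'   (notably the prior SD) drift along flat ridges.
#' @param refine_maxit Maximum simplex iterations per refinement run.
#' @param refine_top Number of distinct coarse solutions carried into the
#'   refinement stage. The restart optima are ranked by coarse likelihood and
#'   up to `refine_top` mutually distant ones (different basins) are each
#'   polished on the fine surface; the best refined solution wins. With
#'   weakly identified parameters the coarse surface can misrank basins, so
#'   refining only the single best restart occasionally locks in the wrong
#'   one.
#' @return A list of class `"bci_control"`.
#' @examples
#' bci_control(n_mc = 2000, restarts = 2)
#' @export
bci_control <- function(n_mc = 10000, restarts = 10, seed = 1L,
                        epsilon = 1e-4, maxit = 500, reltol = 1e-6,
                        bounds = default_bounds(), refine_n_mc = NULL,
                        refine_maxit = 400, refine_top = 3) {
  stopifnot(n_mc >= 1, restarts >= 1, epsilon >= 0, maxit >= 1,
            refine_top >= 1)
  if (is.null(refine_n_mc)) refine_n_mc <- 6L * as.integer(n_mc)
  structure(list(n_mc = as.integer(n_mc), restarts = as.integer(restarts),
                 seed = as.integer(seed), epsilon = epsilon,
                 maxit = as.integer(maxit), reltol = reltol, bounds = bounds,
                 refine_n_mc = as.integer(refine_n_mc),
                 refine_maxit = as.integer(refine_maxit),
                 refine_top = as.integer(refine_top)),
            class = "bci_control")
}

#' Read fit settings from a flat JSON config file
#'
#' Recognized keys: `n_mc`, `restarts`, `seed`, `epsilon`, `maxit`, `reltol`,
#' `variant`, and `bounds` (an object of `[lower, upper]` pairs). Missing keys
#' take the [bci_control()] defaults. The `variant` (if present) is attached
#' as an attribute.
#'
#' @param path Path to a JSON file.
#' @return A `"bci_control"` object (with attribute `"variant"` if given).
#' @export
read_fit_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctl <- bci_control()
  for (nm in c("n_mc", "restarts", "seed", "epsilon", "maxit", "reltol",
               "refine_n_mc", "refine_maxit"))
    if (!is.null(cfg[[nm]])) ctl[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$bounds))
    for (nm in names(cfg$bounds)) ctl$bounds[[nm]] <- as.numeric(cfg$bounds[[nm]])
  ctl <- bci_control(ctl$n_mc, ctl$restarts, ctl$seed, ctl$epsilon,
                     ctl$maxit, ctl$reltol, ctl$bounds,
                     refine_n_mc = if (is.null(cfg$refine_n_mc)) NULL else ctl$refine_n_mc,
                     refine_maxit = ctl$refine_maxit)
  if (!is.null(cfg$variant)) attr(ctl, "variant") <- cfg$variant
  ctl
}

# bounded <-> unconstrained transforms (log-odds of position within the box)
to_unconstrained <- function(theta, bounds) {
  vapply(names(theta), function(nm) {
    b <- bounds[[nm]]
    stats::qlogis(min(max((theta[[nm]] - b[1]) / (b[2] - b[1]), 1e-6), 1 - 1e-6))
  }, 0)
}
to_bounded <- function(u, nms, bounds) {
  th <- vapply(seq_along(nms), function(i) {
    b <- bounds[[nms[i]]]
    b[1] + (b[2] - b[1]) * stats::plogis(u[i])
  }, 0)
  names(th) <- nms
  th
}

#' Fit an observer model by maximum likelihood
#'
#' Maximizes the multinomial Monte Carlo likelihood of a trial-level
#' flash/beep dataset over the chosen variant's free parameters, holding the
#' temporal parameters fixed (they are not constrained by numerosity reports).
#' The search runs in a transformed unconstrained space (log-odds of position
#' within the [default_bounds()] boxes), restarted from Latin-hypercube
#' starting points; common random numbers make the objective deterministic, so
#' the whole fit is reproducible from the control seed. The multi-start search
#' at `n_mc` draws per condition is followed by a refinement stage that
#' polishes the best solution on a finer surface (`refine_n_mc` draws), which
#' substantially sharpens weakly identified parameters such as the prior SD.
#'
#' @param data A `"bci_data"` dataset (or data frame in the standard schema).
#' @param variant Observer variant to fit, see [bci_variants()].
#' @param control A [bci_control()] object.
#' @param base_params A [bci_params()] object supplying the fixed temporal
#'   parameters and the likelihood family.
#' @return An object of class `"bci_fit"` with components `coefficients`
#'   (estimated free parameters), `params` (full parameter object), `logLik`,
#'   `k`, `n`, `bic`, `r_squared`, `restarts` (per-restart table), `converged`
#'   and the settings used. Methods: `print`, `summary`, `coef`, `logLik`,
#'   `predict`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' d <- simulate_observer(build_design(), seed = 1)
#' f <- fit_bci(d, control = bci_control(n_mc = 2000, restarts = 2))
#' f
#' }
#' @export
fit_bci <- function(data, variant = "bci2d", control = bci_control(),
                    base_params = bci_params()) {
  cl <- match.call()
  data <- validate_bci_data(data)
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  free_nms <- variant_free_names(variant)
  bounds <- control$bounds
  ct <- condition_table(data)
  obs <- observed_cell_counts(data, ct)
  set.seed(control$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  z <- draw_engine_z(nrow(ct), control$n_mc, sub_seeds[1])

  make_negll <- function(m, zz) {
    function(u) {
      free <- to_bounded(u, free_nms, bounds)
      av <- apply_variant(variant, free, base = base_params)
      counts <- engine_cell_counts(ct, av$params, variant, m, seed = NA, z = zz)
      probs <- floor_probs(counts, ct, m, control$epsilon)
      -sum(obs * log(pmax(probs, .Machine$double.xmin)))
    }
  }
  negll <- make_negll(control$n_mc, z)

  set.seed(sub_seeds[2])
  k <- length(free_nms)
  starts <- lhs::randomLHS(control$restarts, k)
  runs <- vector("list", control$restarts)
  for (r in seq_len(control$restarts)) {
    s <- 0.05 + 0.9 * starts[r, ]
    u0 <- stats::qlogis(s)
    opt <- optim(u0, negll, method = "Nelder-Mead",
                 control = list(maxit = control$maxit, reltol = control$reltol))
    runs[[r]] <- opt
  }
  vals <- vapply(runs, function(o) o$value, 0)
  opt <- runs[[which.min(vals)]]
  # refinement: polish the top distinct coarse solutions on a finer Monte
  # Carlo surface and keep the best refined one (the coarse surface's noise
  # floor can misrank basins of weakly identified parameters)
  n_mc_final <- control$n_mc
  z_final <- z
  if (control$refine_n_mc > control$n_mc) {
    ord <- order(vals)
    cands <- list(runs[[ord[1]]])
    for (j in ord[-1]) {
      if (length(cands) >= control$refine_top) break
      dist <- min(vapply(cands, function(cc)
        sqrt(sum((cc$par - runs[[j]]$par)^2)), 0))
      if (dist > 1) cands[[length(cands) + 1L]] <- runs[[j]]
    }
    n_mc_final <- control$refine_n_mc
    z_final <- draw_engine_z(nrow(ct), n_mc_final, sub_seeds[3])
    negll_fine <- make_negll(n_mc_final, z_final)
    refined <- lapply(cands, function(cc)
      optim(cc$par, negll_fine, method = "Nelder-Mead",
            control = list(maxit = control$refine_maxit,
                           reltol = control$reltol / 10)))
    opt <- refined[[which.min(vapply(refined, function(o) o$value, 0))]]
  }
  coefs <- to_bounded(opt$par, free_nms, bounds)
  av <- apply_variant(variant, coefs, base = base_params)
  n <- nrow(data)
  ll <- -opt$value
  counts <- engine_cell_counts(ct, av$params, variant, n_mc_final,
                               seed = NA, z = z_final)
  probs <- floor_probs(counts, ct, n_mc_final, control$epsilon)
  pred <- structure(list(conditions = ct, probs = probs, variant = variant,
                         n_mc = n_mc_final, seed = control$seed,
                         epsilon = control$epsilon, params = av$params),
                    class = "bci_predictions")
  restart_tab <- data.frame(restart = seq_along(runs),
                            loglik = -vals,
                            convergence = vapply(runs, function(o) o$convergence, 0L))
  fit <- list(call = cl, variant = variant, coefficients = coefs,
              params = av$params, flags = av$flags,
              logLik = ll, k = k, n = n, bic = bic(ll, k, n),
              r_squared = goodness_of_fit_r2(data, pred),
              restarts = restart_tab,
              converged = opt$convergence == 0L,
              control = control, predictions = pred, data = data)
  class(fit) <- "bci_fit"
  fit
}

#' @export
print.bci_fit <- function(x, ...) {
  cat(sprintf("Causal-inference observer fit, variant '%s' (%d free parameters, %d trials)\n",
              x$variant, x$k, x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("logLik = %.3f, BIC = %.3f, R^2 = %.4f, converged: %s\n",
              x$logLik, x$bic, x$r_squared, x$converged))
  invisible(x)
}

#' @export
summary.bci_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.bci_fit")
}

#' @export
print.summary.bci_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nFixed temporal parameters:\n")
  cat(sprintf("  sigma_vt = %g, sigma_at = %g, mu_tp = %g, sigma_tp = %g\n",
              f$params$sigma_vt, f$params$sigma_at, f$params$mu_tp,
              f$params$sigma_tp))
  cat(sprintf("\nRestarts (n_mc = %d, seed = %d):\n",
              f$control$n_mc, f$control$seed))
  print(f$restarts, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bci_fit <- function(object, ...) object$coefficients

#' @export
logLik.bci_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
predict.bci_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  predict_response_probs(object$params, newdata, variant = object$variant,
                         n_mc = max(object$control$n_mc, 1000L),
                         seed = object$control$seed,
                         epsilon = object$control$epsilon)
}

#' @export
residuals.bci_fit <- function(object, ...) {
  pv <- proportion_vectors(object$data, object$predictions$conditions,
                           object$predictions$probs)
  setNames(pv$obs - pv$pred, pv$labels)
}

#' @export
plot.bci_fit <- function(x, ...) {
  pv <- proportion_vectors(x$data, x$predictions$conditions,
                           x$predictions$probs)
  graphics::plot(pv$pred, pv$obs, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "predicted response proportion",
                 ylab = "observed response proportion",
                 main = sprintf("%s fit: R^2 = %.3f", x$variant, x$r_squared),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.bci_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  design <- object$data[, c("n_flashes", "n_beeps", "soa_ms", "lead")]
  out <- lapply(seq_len(nsim), function(i)
    simulate_observer(design, object$params, seed = sim_seeds[i],
                      observer_id = sprintf("sim%02d", i),
                      variant = object$variant))
  if (nsim == 1L) out[[1L]] else out
}
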