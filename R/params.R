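#' Observer parameters for the multidimensional causal-inference model
#'
#' Container for the nine generative parameters of the numerosity-by-time
#' Bayesian causal inference observer. Five are the free parameters normally
#' estimated from flash/beep report data: the sensory noise SDs `sigma_v` and
#' `sigma_a` (numerosity units), the prior probability of a common cause
#' `p_common`, and the numerosity prior `mu_p` / `sigma_p`. The remaining four
#' describe the temporal dimension and are conventionally fixed, because
#' observers report only numerosity: onset noise SDs `sigma_vt` and `sigma_at`
#' and the temporal prior `mu_tp` / `sigma_tp`, all in milliseconds relative to
#' the onset of the first stimulus in the trial.
#'
#' The defaults are the group-mean estimates for adult observers in the
#' audiovisual flash/beep numerosity paradigm this package models (free
#' parameters), together with the fixed temporal values used in that paradigm.
#'
#' @param sigma_v Visual numerosity noise SD (> 0, numerosity units).
#' @param sigma_a Auditory numerosity noise SD (> 0, numerosity units).
#' @param p_common Prior probability that the flash and beep streams share a
#'   single cause, in `[0, 1]`.
#' @param sigma_p Numerosity prior SD (> 0).
#' @param mu_p Numerosity prior mean.
#' @param sigma_vt Visual onset noise SD (> 0, ms).
#' @param sigma_at Auditory onset noise SD (> 0, ms).
#' @param mu_tp Temporal prior mean (ms relative to first stimulus onset).
#' @param sigma_tp Temporal prior SD (> 0, ms).
#' @param family Numerosity likelihood family: `"gaussian"` (default) or
#'   `"lognormal"` (robustness variant; noise and prior act on log-numerosity,
#'   so `sigma_v`, `sigma_a`, `sigma_p` are in log units and `mu_p` is the
#'   prior median).
#'
#' @return An object of class `"bci_params"`: a named list of the nine
#'   parameters plus the likelihood family.
#' @examples
#' p <- bci_params()
#' p
#' bci_params(sigma_v = 1, p_common = 0.5)
#' @export
bci_params <- function(sigma_v = 0.63, sigma_a = 0.33, p_common = 0.62,
                       sigma_p = 1.33, mu_p = 1.43,
                       sigma_vt = 60, sigma_at = 40,
                       mu_tp = 100, sigma_tp = 500,
                       family = c("gaussian", "lognormal")) {
  family <- match.arg(family)
  p <- list(sigma_v = sigma_v, sigma_a = sigma_a, p_common = p_common,
            sigma_p = sigma_p, mu_p = mu_p,
            sigma_vt = sigma_vt, sigma_at = sigma_at,
            mu_tp = mu_tp, sigma_tp = sigma_tp,
            family = family)
  class(p) <- "bci_params"
  validate_bci_params(p)
  p
}

validate_bci_params <- function(p) {
  sds <- c("sigma_v", "sigma_a", "sigma_p", "sigma_vt", "sigma_at", "sigma_tp")
  for (nm in sds) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite value > 0", nm), call. = FALSE)
  }
  for (nm in c("mu_p", "mu_tp")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite value", nm), call. = FALSE)
  }
  pc <- p$p_common
  if (!is.numeric(pc) || length(pc) != 1L || !is.finite(pc) || pc < 0 || pc > 1)
    stop("'p_common' must be a single value in [0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.bci_params <- function(x, ...) {
  cat("Causal-inference observer parameters (", x$family,
      " numerosity likelihood)\n", sep = "")
  cat(sprintf("  numerosity: sigma_v = %.3g, sigma_a = %.3g, prior N(%.3g, %.3g^2)\n",
              x$sigma_v, x$sigma_a, x$mu_p, x$sigma_p))
  cat(sprintf("  p_common  : %.3g\n", x$p_common))
  cat(sprintf("  time (ms) : sigma_vt = %.3g, sigma_at = %.3g, prior N(%.3g, %.3g^2)\n",
              x$sigma_vt, x$sigma_at, x$mu_tp, x$sigma_tp))
  invisible(x)
}

# coerce a named list / vector of overrides onto an existing params object
modify_params <- function(base, free) {
  if (length(free) == 0L) return(base)
  stopifnot(!is.null(names(free)), all(nzchar(names(free))))
  bad <- setdiff(names(free), setdiff(names(base), "family"))
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(free)) base[[nm]] <- as.numeric(free[[nm]])
  validate_bci_params(base)
  base
}
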