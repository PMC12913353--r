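#' The four nested observer-model variants
#'
#' * `bci2d` — full causal inference on numerosity and time (5 free
#'   parameters: `sigma_v`, `sigma_a`, `p_common`, `sigma_p`, `mu_p`).
#' * `bci1d` — causal inference on numerosity only; all temporal likelihood
#'   factors are dropped (same 5 free parameters).
#' * `fusion` — forced fusion: the posterior probability of a common cause is
#'   pinned at 1 and both reports derive from the fused estimate (4 free
#'   parameters: `sigma_v`, `sigma_a`, `sigma_p`, `mu_p`).
#' * `mle` — flat-prior cue combination: forced fusion with the numerosity
#'   prior removed, i.e. pure reliability weighting (2 free parameters:
#'   `sigma_v`, `sigma_a`).
#'
#' @return A data frame with one row per variant: `variant`, `k` (free
#'   parameter count) and a `description`; the `free` attribute holds the free
#'   parameter names per variant.
#' @examples
#' bci_variants()
#' @export
bci_variants <- function() {
  free <- list(
    bci2d = c("sigma_v", "sigma_a", "p_common", "sigma_p", "mu_p"),
    bci1d = c("sigma_v", "sigma_a", "p_common", "sigma_p", "mu_p"),
    fusion = c("sigma_v", "sigma_a", "sigma_p", "mu_p"),
    mle = c("sigma_v", "sigma_a"))
  out <- data.frame(
    variant = names(free),
    k = vapply(free, length, 1L),
    description = c(
      "causal inference over numerosity and onset time",
      "causal inference over numerosity only",
      "forced fusion (common cause assumed)",
      "flat-prior reliability-weighted fusion"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "free") <- free
  out
}

variant_free_names <- function(variant) {
  v <- bci_variants()
  free <- attr(v, "free")
  if (!variant %in% names(free))
    stop("unknown variant: ", variant, call. = FALSE)
  free[[variant]]
}

# evaluation flags used by the simulation/likelihood engine
variant_flags <- function(variant) {
  switch(variant,
         bci2d  = list(use_temporal = TRUE,  force_fusion = FALSE, flat_prior = FALSE, mode = 0L),
         bci1d  = list(use_temporal = FALSE, force_fusion = FALSE, flat_prior = FALSE, mode = 1L),
         fusion = list(use_temporal = FALSE, force_fusion = TRUE,  flat_prior = FALSE, mode = 2L),
         mle    = list(use_temporal = FALSE, force_fusion = TRUE,  flat_prior = TRUE,  mode = 3L),
         stop("unknown variant: ", variant, call. = FALSE))
}

#' Instantiate a variant's free parameters as a full parameter object
#'
#' Checks that `free` supplies exactly the variant's free parameters, merges
#' them with the fixed temporal parameters (and any other fields of `base`),
#' and returns the full parameter object together with the variant's
#' evaluation flags.
#'
#' @param variant One of `"bci2d"`, `"bci1d"`, `"fusion"`, `"mle"`.
#' @param free Named numeric vector or list of the variant's free parameters.
#' @param base A [bci_params()] object supplying fixed parameters (temporal
#'   SDs/prior and, for constrained variants, any untouched fields).
#' @return A list with `params` (a `bci_params` object) and `flags`
#'   (`use_temporal`, `force_fusion`, `flat_prior`).
#' @examples
#' apply_variant("mle", c(sigma_v = 0.6, sigma_a = 0.3))
#' @export
apply_variant <- function(variant, free, base = bci_params()) {
  need <- variant_free_names(variant)
  if (is.null(names(free)) || !setequal(names(free), need) ||
      length(free) != length(need))
    stop(sprintf("variant '%s' requires exactly the free parameters: %s",
                 variant, paste(need, collapse = ", ")), call. = FALSE)
  params <- modify_params(base, as.list(free)[need])
  if (variant %in% c("fusion", "mle")) params$p_common <- 1
  list(params = params, flags = variant_flags(variant))
}

#' Bayesian Information Criterion
#'
#' `BIC = k * ln(n) - 2 * loglik`, with `k` the number of free parameters and
#' `n` the number of trials. Lower is better.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters (>= 0).
#' @param n Number of trials (>= 1).
#' @return Numeric BIC value.
#' @examples
#' bic(-100, 5, 200)
#' @export
bic <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) - 2 * loglik
}
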