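#' @name inference
#' @title Response-probability predictions, likelihood and fit quality
#'
#' @description
#' Discrete flash/beep reports enter the likelihood as a multinomial over
#' response cells: the 3x3 joint (flash report, beep report) cell for bimodal
#' conditions and the 3 marginal cells for unisensory conditions. Cell
#' probabilities are approximated by Monte Carlo simulation from the
#' generative observer with common random numbers, floored at a small
#' `epsilon` and renormalized so that no observed cell has zero predicted
#' probability.
NULL

# observed (n_cond x 9) cell-count matrix aligned with a condition_table
observed_cell_counts <- function(data, ct) {
  key <- condition_id(data$n_flashes, data$n_beeps, data$soa_ms)
  ci <- match(key, ct$condition)
  if (anyNA(ci))
    stop("dataset contains conditions not covered by the predictions: ",
         paste(unique(key[is.na(ci)]), collapse = ", "), call. = FALSE)
  counts <- matrix(0L, nrow(ct), 9L)
  bim <- ct$bimodal[ci]
  cell <- integer(nrow(data))
  cell[bim] <- 3L * data$resp_flashes[bim] + data$resp_beeps[bim] + 1L
  uni_v <- !bim & data$n_flashes >= 1L
  uni_a <- !bim & data$n_beeps >= 1L
  cell[uni_v] <- data$resp_flashes[uni_v] + 1L
  cell[uni_a] <- data$resp_beeps[uni_a] + 1L
  tb <- tabulate((ci - 1L) * 9L + cell, nbins = nrow(ct) * 9L)
  counts + matrix(tb, nrow(ct), 9L, byrow = TRUE)
}

#' Predicted response probabilities per condition
#'
#' Simulates `n_mc` trials per condition from the observer model and returns
#' the per-condition response-cell probabilities, floored at `epsilon` and
#' renormalized. Deterministic given `seed`; the same deviates are reused for
#' any parameter value at the same `(design, n_mc, seed)`, making the implied
#' likelihood surface smooth in the parameters.
#'
#' @param params A [bci_params()] object.
#' @param design A design/dataset data frame (columns `n_flashes`, `n_beeps`,
#'   `soa_ms`, `lead`) whose unique conditions are predicted.
#' @param variant Observer variant (see [bci_variants()]).
#' @param n_mc Monte Carlo trials per condition (>= 1000).
#' @param seed Integer seed.
#' @param epsilon Probability floor per cell (applied before renormalization).
#' @return An object of class `"bci_predictions"`: the condition table, the
#'   `n_cond x 9` probability matrix (bimodal cell `3 * flash + beep + 1`;
#'   unisensory cell `resp + 1`), and the simulation settings.
#' @examples
#' pr <- predict_response_probs(bci_params(), build_design(reps = 1),
#'                              n_mc = 1000, seed = 1)
#' pr
#' @export
predict_response_probs <- function(params, design, variant = "bci2d",
                                   n_mc = 10000, seed = 1L, epsilon = 1e-4) {
  if (nrow(design) == 0L) stop("empty design", call. = FALSE)
  if (n_mc < 1000) stop("n_mc must be >= 1000", call. = FALSE)
  validate_bci_params(params)
  ct <- condition_table(design)
  counts <- engine_cell_counts(ct, params, variant, n_mc, seed)
  probs <- floor_probs(counts, ct, n_mc, epsilon)
  structure(list(conditions = ct, probs = probs, variant = variant,
                 n_mc = as.integer(n_mc), seed = as.integer(seed),
                 epsilon = epsilon, params = params),
            class = "bci_predictions")
}

#' @export
print.bci_predictions <- function(x, ...) {
  cat(sprintf("Predicted response probabilities: %d conditions, variant '%s' (n_mc = %d, seed = %d)\n",
              nrow(x$conditions), x$variant, x$n_mc, x$seed))
  invisible(x)
}

#' Multinomial log-likelihood of an observer dataset
#'
#' Sum over trials of the log predicted probability of the observed response
#' cell (joint flash/beep cell for bimodal trials, marginal cell for
#' unisensory trials), with cell probabilities from Monte Carlo simulation at
#' `params`. The `epsilon` floor guarantees a finite value.
#'
#' @param data A `"bci_data"` dataset (see [simulate_observer()],
#'   [read_bci_data()]).
#' @inheritParams predict_response_probs
#' @return A single finite log-likelihood value.
#' @examples
#' d <- simulate_observer(build_design(reps = 2), seed = 1)
#' bci_loglik(d, bci_params(), n_mc = 2000)
#' @export
bci_loglik <- function(data, params, variant = "bci2d", n_mc = 10000,
                       seed = 1L, epsilon = 1e-4) {
  if (is.null(nrow(data)) || nrow(data) == 0L)
    stop("empty dataset", call. = FALSE)
  validate_bci_params(params)
  ct <- condition_table(data)
  obs <- observed_cell_counts(data, ct)
  counts <- engine_cell_counts(ct, params, variant, n_mc, seed)
  probs <- floor_probs(counts, ct, n_mc, epsilon)
  sum(obs * log(pmax(probs, .Machine$double.xmin)))
}

# observed/predicted response-proportion vectors over
# conditions x modalities x categories (marginals per modality)
proportion_vectors <- function(data, ct, probs) {
  obs_counts <- observed_cell_counts(data, ct)
  obs <- numeric(0); pred <- numeric(0); labels <- character(0)
  for (i in seq_len(nrow(ct))) {
    n_i <- sum(obs_counts[i, ])
    if (ct$bimodal[i]) {
      joint_o <- matrix(obs_counts[i, ], 3, 3, byrow = TRUE) / n_i
      joint_p <- matrix(probs[i, ], 3, 3, byrow = TRUE)
      obs <- c(obs, rowSums(joint_o), colSums(joint_o))
      pred <- c(pred, rowSums(joint_p), colSums(joint_p))
      labels <- c(labels,
                  paste0(ct$condition[i], "_flash", 0:2),
                  paste0(ct$condition[i], "_beep", 0:2))
    } else {
      modality <- if (ct$n_flashes[i] >= 1) "flash" else "beep"
      obs <- c(obs, obs_counts[i, 1:3] / n_i)
      pred <- c(pred, probs[i, 1:3])
      labels <- c(labels, paste0(ct$condition[i], "_", modality, 0:2))
    }
  }
  list(obs = obs, pred = pred, labels = labels)
}

#' Variance explained over response proportions
#'
#' `R^2 = 1 - SS_res / SS_tot` computed over the vector of observed
#' response-category proportions — per condition, per modality, per response
#' category (0/1/2), using per-modality marginals — against the corresponding
#' predicted probabilities, with `SS_tot` taken about the grand mean of the
#' observed proportions. Values lie in `(-Inf, 1]`; 1 is a perfect fit and 0
#' matches a constant (grand-mean) predictor.
#'
#' @param data A `"bci_data"` dataset.
#' @param predictions A `"bci_predictions"` object covering every condition in
#'   `data` (e.g. from [predict_response_probs()] or `predict()` on a fit).
#' @return A single numeric value.
#' @examples
#' d <- simulate_observer(build_design(reps = 5), seed = 2)
#' pr <- predict_response_probs(bci_params(), d, n_mc = 5000)
#' goodness_of_fit_r2(d, pr)
#' @export
goodness_of_fit_r2 <- function(data, predictions) {
  stopifnot(inherits(predictions, "bci_predictions"))
  if (is.null(nrow(data)) || nrow(data) == 0L)
    stop("empty dataset", call. = FALSE)
  pv <- proportion_vectors(data, predictions$conditions, predictions$probs)
  ss_res <- sum((pv$obs - pv$pred)^2)
  ss_tot <- sum((pv$obs - mean(pv$obs))^2)
  1 - ss_res / ss_tot
}
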