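# Shared Monte Carlo cell-count engine.
#
# Conditions are simulated in blocks of n_mc draws each; the standard-normal
# deviates are drawn once per (n_conditions, n_mc, seed) and reused across
# parameter proposals (common random numbers), which makes the Monte Carlo
# likelihood surface deterministic in the parameters and safe to optimize.
#
# Cell layout of the returned (n_conditions x 9) count matrix:
#   bimodal conditions:   column 3 * resp_flash + resp_beep + 1
#   unisensory conditions: column resp + 1 (columns 4:9 zero)

draw_engine_z <- function(n_cond, n_mc, seed) {
  set.seed(seed)
  matrix(rnorm(4L * n_cond * n_mc), ncol = 4L)
}

# ct: a condition_table(); z: optional pre-drawn deviate matrix
engine_cell_counts <- function(ct, params, variant, n_mc, seed, z = NULL) {
  flags <- variant_flags(variant)
  n_cond <- nrow(ct)
  if (is.null(z)) z <- draw_engine_z(n_cond, n_mc, seed)
  stopifnot(nrow(z) == n_cond * n_mc, ncol(z) == 4L)
  if (params$family == "gaussian") {
    counts <- cell_counts_cpp(
      as.integer(ct$n_flashes), as.integer(ct$n_beeps),
      as.numeric(ct$onset_v), as.numeric(ct$onset_a),
      as.integer(n_mc), z,
      params$sigma_v, params$sigma_a, params$p_common,
      params$sigma_p, params$mu_p,
      params$sigma_vt, params$sigma_at, params$mu_tp, params$sigma_tp,
      flags$mode)
  } else {
    counts <- cell_counts_r(ct, params, flags, n_mc, z)
  }
  rownames(counts) <- ct$condition
  counts
}

# reference/vectorized R path; also the only path for the log-normal family
cell_counts_r <- function(ct, params, flags, n_mc, z) {
  n_cond <- nrow(ct)
  idx <- rep(seq_len(n_cond), each = n_mc)
  r <- responses_from_samples(ct$n_flashes[idx], ct$n_beeps[idx],
                              ct$onset_v[idx], ct$onset_a[idx],
                              params, flags, z)
  counts <- matrix(0L, n_cond, 9L)
  bi <- ct$bimodal[idx]
  if (any(bi)) {
    cell <- (idx[bi] - 1L) * 9L + 3L * r$resp_v[bi] + r$resp_a[bi] + 1L
    tb <- tabulate(cell, nbins = n_cond * 9L)
    counts <- counts + matrix(tb, n_cond, 9L, byrow = TRUE)
  }
  uni <- !ct$bimodal[idx]
  if (any(uni)) {
    resp <- ifelse(is.na(r$resp_v[uni]), r$resp_a[uni], r$resp_v[uni])
    cell <- (idx[uni] - 1L) * 9L + resp + 1L
    tb <- tabulate(cell, nbins = n_cond * 9L)
    counts <- counts + matrix(tb, n_cond, 9L, byrow = TRUE)
  }
  counts
}

# counts -> per-condition cell probabilities with floor epsilon + renormalize
floor_probs <- function(counts, ct, n_mc, epsilon) {
  probs <- counts / n_mc
  for (i in seq_len(nrow(probs))) {
    ncell <- if (ct$bimodal[i]) 9L else 3L
    p <- pmax(probs[i, seq_len(ncell)], epsilon)
    probs[i, seq_len(ncell)] <- p / sum(p)
  }
  probs
}
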