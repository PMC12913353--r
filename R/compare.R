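#' Fit and compare the nested observer models across a cohort
#'
#' Fits every requested variant to every observer with a shared fit
#' configuration, tabulates per-observer log-likelihood and BIC, and — when at
#' least two observers succeed — runs paired t-tests of BIC between the
#' reference variant (the 2D causal-inference model, when present) and each
#' alternative, Bonferroni-corrected over the number of comparisons. Fit
#' failures are recorded per cell and do not stop the run.
#'
#' @param datasets A `"bci_cohort"` or list of `"bci_data"` datasets (a single
#'   dataset is accepted and treated as a one-observer cohort).
#' @param variants Character vector of variants to fit (see [bci_variants()]).
#' @param control Shared [bci_control()].
#' @param base_params Fixed-parameter template, see [fit_bci()].
#' @return An object of class `"bci_comparison"`: `table` (observer x variant
#'   rows), `summary` (per-variant mean and SE of BIC), `tests` (pairwise
#'   paired t-tests, `NULL` for a single observer or single variant), and
#'   `fits` (the underlying `"bci_fit"` objects).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(2, design = build_design(reps = 2), seed = 1)
#' cmp <- compare_bci_models(coh, c("bci2d", "fusion"),
#'                           control = bci_control(n_mc = 2000, restarts = 2))
#' cmp
#' }
#' @export
compare_bci_models <- function(datasets,
                               variants = c("bci2d", "bci1d", "fusion", "mle"),
                               control = bci_control(),
                               base_params = bci_params()) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1, length(variants) >= 1)
  obs_ids <- vapply(seq_along(datasets), function(i) {
    id <- datasets[[i]]$observer_id[1]
    if (is.null(id) || is.na(id)) sprintf("obs%02d", i) else as.character(id)
  }, "")
  rows <- list(); fits <- list()
  for (i in seq_along(datasets)) {
    for (v in variants) {
      res <- tryCatch(fit_bci(datasets[[i]], variant = v, control = control,
                              base_params = base_params),
                      error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          observer = obs_ids[i], variant = v, loglik = NA_real_, k = NA_integer_,
          n = NA_integer_, bic = NA_real_, converged = NA,
          error = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        fits[[paste(obs_ids[i], v, sep = ".")]] <- res
        rows[[length(rows) + 1L]] <- data.frame(
          observer = obs_ids[i], variant = v, loglik = res$logLik, k = res$k,
          n = res$n, bic = res$bic, converged = res$converged,
          error = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(unique(tab$variant), function(v) {
    b <- tab$bic[tab$variant == v]
    b <- b[is.finite(b)]
    data.frame(variant = v, n_observers = length(b),
               mean_bic = mean(b), se_bic = stats::sd(b) / sqrt(length(b)),
               mean_loglik = mean(tab$loglik[tab$variant == v], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  reference <- if ("bci2d" %in% variants) "bci2d" else variants[1]
  others <- setdiff(unique(tab$variant), reference)
  tests <- NULL
  if (length(datasets) >= 2 && length(others) >= 1) {
    tl <- list()
    for (v in others) {
      b_ref <- tab$bic[tab$variant == reference][order(tab$observer[tab$variant == reference])]
      b_alt <- tab$bic[tab$variant == v][order(tab$observer[tab$variant == v])]
      ok <- is.finite(b_ref) & is.finite(b_alt)
      if (sum(ok) < 2) next
      d <- b_ref[ok] - b_alt[ok]
      if (all(d == 0)) {
        tstat <- 0; pval <- 1; dfree <- sum(ok) - 1
      } else {
        tt <- t.test(d)
        tstat <- unname(tt$statistic); pval <- tt$p.value
        dfree <- unname(tt$parameter)
      }
      tl[[v]] <- data.frame(comparison = paste(reference, "vs", v),
                            mean_bic_diff = mean(d), t = tstat, df = dfree,
                            p = pval, stringsAsFactors = FALSE)
    }
    if (length(tl)) {
      tests <- do.call(rbind, tl)
      tests$p_bonferroni <- pmin(1, tests$p * nrow(tests))
      row.names(tests) <- NULL
    }
  }
  structure(list(table = tab, summary = sm, tests = tests, fits = fits,
                 reference = reference, control = control),
            class = "bci_comparison")
}

#' @export
print.bci_comparison <- function(x, digits = 2, ...) {
  cat("Model comparison across", length(unique(x$table$observer)),
      "observer(s)\n\nPer-variant BIC summary (lower is better):\n")
  print(transform(x$summary, mean_bic = round(mean_bic, digits),
                  se_bic = round(se_bic, digits),
                  mean_loglik = round(mean_loglik, digits)),
        row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nPaired t-tests on BIC (reference:", x$reference, "):\n")
    print(transform(x$tests, mean_bic_diff = round(mean_bic_diff, digits),
                    t = round(t, 2), p = signif(p, 3),
                    p_bonferroni = signif(p_bonferroni, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a model comparison to delimited text and JSON
#'
#' Writes `comparison.csv` (one row per observer x variant), `summary.csv`
#' (per-variant means/SEs plus pairwise tests when present) and a
#' machine-readable `comparison.json` mirror into `dir`.
#'
#' @param x A `"bci_comparison"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(x, dir) {
  stopifnot(inherits(x, "bci_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(x$table, file.path(dir, "comparison.csv"), row.names = FALSE)
  write.csv(x$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(table = x$table, summary = x$summary, tests = x$tests,
         reference = x$reference),
    file.path(dir, "comparison.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}

#' Parameter-recovery study
#'
#' Generates a synthetic cohort from known parameters, refits the generating
#' variant to every observer, and summarizes how well the free parameters are
#' recovered: per-observer recovered values, per-parameter cohort mean, SE,
#' bias and RMSE, plus the mean refit R-squared.
#'
#' @param n_observers Number of synthetic observers.
#' @param params Generating [bci_params()].
#' @param design Shared [build_design()].
#' @param variant Generating and fitted variant.
#' @param control Fit settings ([bci_control()]).
#' @param seed Master seed for cohort generation.
#' @param between_sd Optional between-observer SDs, see [simulate_cohort()].
#' @return An object of class `"bci_recovery"` with `recovered` (per-observer
#'   table), `summary` (per-parameter generating value, cohort mean/SE, bias,
#'   RMSE), `mean_r_squared`, and the fits.
#' @examples
#' \donttest{
#' rec <- recover_parameters(2, design = build_design(reps = 2), seed = 1,
#'                           control = bci_control(n_mc = 2000, restarts = 2))
#' rec
#' }
#' @export
recover_parameters <- function(n_observers = 8, params = bci_params(),
                               design = build_design(), variant = "bci2d",
                               control = bci_control(), seed = 1L,
                               between_sd = NULL) {
  cohort <- simulate_cohort(n_observers, params = params, design = design,
                            seed = seed, variant = variant,
                            between_sd = between_sd)
  gen <- attr(cohort, "generating_params")
  free_nms <- variant_free_names(variant)
  fits <- lapply(cohort, fit_bci, variant = variant, control = control,
                 base_params = params)
  rec <- do.call(rbind, lapply(seq_along(fits), function(i) {
    data.frame(observer = names(cohort)[i],
               parameter = free_nms,
               generating = vapply(free_nms, function(nm) gen[[i]][[nm]], 0),
               recovered = unname(coef(fits[[i]])[free_nms]),
               r_squared = fits[[i]]$r_squared,
               converged = fits[[i]]$converged,
               stringsAsFactors = FALSE)
  }))
  row.names(rec) <- NULL
  sm <- do.call(rbind, lapply(free_nms, function(nm) {
    r <- rec[rec$parameter == nm, ]
    data.frame(parameter = nm,
               generating_mean = mean(r$generating),
               recovered_mean = mean(r$recovered),
               recovered_se = stats::sd(r$recovered) / sqrt(nrow(r)),
               bias = mean(r$recovered - r$generating),
               rmse = sqrt(mean((r$recovered - r$generating)^2)),
               stringsAsFactors = FALSE)
  }))
  structure(list(recovered = rec, summary = sm,
                 mean_r_squared = mean(rec$r_squared[!duplicated(rec$observer)]),
                 fits = fits, variant = variant, seed = as.integer(seed),
                 n_observers = n_observers, control = control),
            class = "bci_recovery")
}

#' @export
print.bci_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d observers, variant '%s' (seed %d)\n\n",
              x$n_observers, x$variant, x$seed))
  print(transform(x$summary, generating_mean = round(generating_mean, 3),
                  recovered_mean = round(recovered_mean, 3),
                  recovered_se = round(recovered_se, 4),
                  bias = round(bias, 3), rmse = round(rmse, 3)),
        row.names = FALSE)
  cat(sprintf("\nMean refit R^2: %.4f\n", x$mean_r_squared))
  invisible(x)
}
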