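ctl_small <- function(...) bci_control(n_mc = 2000, restarts = 2, maxit = 200, ...)

test_that("predicted cell probabilities respect the floor and common random numbers", {
  p <- bci_params()
  des <- build_design(reps = 1)
  pr <- predict_response_probs(p, des, n_mc = 2000, seed = 3)
  # probabilities normalized per condition over the condition's cells
  for (i in seq_len(nrow(pr$conditions))) {
    ncell <- if (pr$conditions$bimodal[i]) 9 else 3
    expect_equal(sum(pr$probs[i, seq_len(ncell)]), 1, tolerance = 1e-12)
    expect_true(all(pr$probs[i, seq_len(ncell)] > 0))  # floor: no zero cells
  }
  # a cell with no simulated mass still gets positive floored probability:
  # an extremely precise observer never reports 0 flashes to 2 flashes
  prec <- bci_params(sigma_v = 0.05, sigma_a = 0.05, p_common = 0)
  pr2 <- predict_response_probs(prec, des, n_mc = 2000, seed = 3)
  i <- which(pr2$conditions$condition == "2F0B_soa0")
  expect_gt(pr2$probs[i, 1], 0)
  expect_lt(pr2$probs[i, 1], 1e-3)
  # determinism under a shared seed
  pr3 <- predict_response_probs(p, des, n_mc = 2000, seed = 3)
  expect_identical(pr$probs, pr3$probs)
  expect_error(predict_response_probs(p, des, n_mc = 500), ">= 1000")
  expect_error(predict_response_probs(p, des[0, ]), "empty")
})

test_that("Monte Carlo unisensory cell probabilities match the analytic binning", {
  p <- bci_params()
  des <- data.frame(n_flashes = c(1L, 0L), n_beeps = c(0L, 2L),
                    soa_ms = 0L, lead = "visual_first")
  n <- 1e5
  pr <- predict_response_probs(p, des, n_mc = n, seed = 5, epsilon = 0)
  exact_v <- uni_cell_probs_analytic(1, p$sigma_v, p)
  exact_a <- uni_cell_probs_analytic(2, p$sigma_a, p)
  i_v <- which(pr$conditions$condition == "1F0B_soa0")
  i_a <- which(pr$conditions$condition == "0F2B_soa0")
  for (k in 1:3) {
    se_v <- sqrt(exact_v[k] * (1 - exact_v[k]) / n)
    se_a <- sqrt(exact_a[k] * (1 - exact_a[k]) / n)
    expect_lt(abs(pr$probs[i_v, k] - exact_v[k]), 3 * se_v + 1e-12)
    expect_lt(abs(pr$probs[i_a, k] - exact_a[k]), 3 * se_a + 1e-12)
  }
})

test_that("log-likelihood matches the analytic value on unisensory-only data", {
  p <- bci_params()
  uni <- data.frame(observer_id = "u", trial_index = 1:40,
                    n_flashes = rep(c(1L, 0L), 20), n_beeps = rep(c(0L, 2L), 20),
                    soa_ms = 0L, lead = "visual_first",
                    resp_flashes = rep(c(1L, NA), 20),
                    resp_beeps = rep(c(NA, 2L), 20))
  n <- 1e5
  got <- bci_loglik(uni, p, n_mc = n, seed = 9, epsilon = 0)
  exact <- 20 * log(uni_cell_probs_analytic(1, p$sigma_v, p)[2]) +
    20 * log(uni_cell_probs_analytic(2, p$sigma_a, p)[3])
  # MC standard error of the summed log-likelihood
  se <- sqrt(sum(c(20, 20)^2 *
                   (1 - uni_cell_probs_analytic(1, p$sigma_v, p)[2]) /
                   (n * uni_cell_probs_analytic(1, p$sigma_v, p)[2])))
  expect_lt(abs(got - exact), 4 * se + 0.05)
  expect_error(bci_loglik(uni[0, ], p), "empty")
})

test_that("the generating parameters dominate a perturbed alternative in likelihood", {
  p <- bci_params()
  p_wrong <- bci_params(sigma_v = 2 * p$sigma_v)
  des <- build_design()
  wins <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    d <- simulate_observer(des, p, seed = 4000 + r)
    ll_true <- bci_loglik(d, p, n_mc = 4000, seed = 77)
    ll_wrong <- bci_loglik(d, p_wrong, n_mc = 4000, seed = 77)
    wins <- wins + (ll_true > ll_wrong)
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})

test_that("the common-random-numbers likelihood surface is deterministic", {
  d <- simulate_observer(build_design(), seed = 2)
  p <- bci_params()
  expect_identical(bci_loglik(d, p, n_mc = 3000, seed = 10),
                   bci_loglik(d, p, n_mc = 3000, seed = 10))
})

test_that("variance explained has the right fixed points and matches a re-implementation", {
  d <- simulate_observer(build_design(reps = 5), seed = 6)
  ct <- sifibci:::condition_table(d)
  obs <- sifibci:::observed_cell_counts(d, ct)
  # predictions identical to the observed proportions give R^2 = 1
  probs_obs <- obs / rowSums(obs)
  pred <- structure(list(conditions = ct, probs = probs_obs, variant = "bci2d",
                         n_mc = 1000L, seed = 1L, epsilon = 0,
                         params = bci_params()), class = "bci_predictions")
  expect_equal(goodness_of_fit_r2(d, pred), 1)
  # grand-mean predictions give R^2 = 0
  pv <- sifibci:::proportion_vectors(d, ct, probs_obs)
  gm <- mean(pv$obs)
  # build a probability matrix whose marginals are all equal to the grand
  # mean: for bimodal cells use the product-free uniform assignment that
  # makes every per-modality marginal gm (gm = 1/3 by construction)
  expect_equal(gm, 1 / 3)
  probs_flat <- probs_obs
  probs_flat[ct$bimodal, ] <- 1 / 9
  probs_flat[!ct$bimodal, 1:3] <- 1 / 3
  pred_flat <- pred; pred_flat$probs <- probs_flat
  expect_equal(goodness_of_fit_r2(d, pred_flat), 0)
  # independent re-implementation on model predictions
  pr <- predict_response_probs(bci_params(), d, n_mc = 5000, seed = 8)
  tabs <- list()
  for (i in seq_len(nrow(ct))) {
    tabs[[ct$condition[i]]] <- if (ct$bimodal[i])
      matrix(pr$probs[i, ], 3, 3, byrow = TRUE) else pr$probs[i, 1:3]
  }
  expect_equal(goodness_of_fit_r2(d, pr), r2_reference(d, tabs))
  # coverage mismatch is rejected
  d_extra <- d
  d_extra$soa_ms[d$n_flashes >= 1 & d$n_beeps >= 1][1:3] <- 300L
  pr_small <- predict_response_probs(bci_params(), d[d$soa_ms == 0, ],
                                     n_mc = 1000, seed = 1)
  expect_error(goodness_of_fit_r2(d, pr_small), "not covered")
})

test_that("fitting is deterministic and honors the variant's arity", {
  d <- simulate_observer(build_design(), seed = 14)
  f1 <- fit_bci(d, variant = "mle", control = ctl_small(seed = 5))
  f2 <- fit_bci(d, variant = "mle", control = ctl_small(seed = 5))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$logLik, f2$logLik)
  expect_named(coef(f1), c("sigma_v", "sigma_a"))
  expect_equal(f1$k, 2)
  expect_equal(f1$bic, bic(f1$logLik, 2, nrow(d)))
  ll <- logLik(f1)
  expect_equal(attr(ll, "df"), 2)
  expect_equal(attr(ll, "nobs"), 200)
  expect_equal(stats::BIC(f1), f1$bic)
})

test_that("fit methods expose predictions, residuals and simulation", {
  d <- simulate_observer(build_design(), seed = 15)
  f <- fit_bci(d, variant = "fusion", control = ctl_small(seed = 2))
  expect_s3_class(predict(f), "bci_predictions")
  r <- residuals(f)
  expect_equal(length(r), 16 * 6 + 4 * 3)
  expect_lt(max(abs(r)), 1)
  s <- simulate(f, seed = 3)
  expect_s3_class(s, "bci_data")
  expect_equal(nrow(s), nrow(d))
  expect_output(print(summary(f)), "Restarts")
  # plotting runs silently to a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(f))
})

test_that("fit settings round-trip through a flat JSON config", {
  cfgf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_mc = 2500, restarts = 3, seed = 7,
                            epsilon = 1e-3, variant = "bci1d",
                            bounds = list(sigma_v = c(0.1, 3))),
                       cfgf, auto_unbox = TRUE)
  ctl <- read_fit_config(cfgf)
  expect_equal(ctl$n_mc, 2500L)
  expect_equal(ctl$restarts, 3L)
  expect_equal(ctl$epsilon, 1e-3)
  expect_equal(ctl$bounds$sigma_v, c(0.1, 3))
  expect_equal(ctl$bounds$sigma_p, c(0.1, 10))
  expect_equal(attr(ctl, "variant"), "bci1d")
})
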