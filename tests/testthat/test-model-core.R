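test_that("closed-form numerosity likelihoods match the quadrature oracle", {
  p <- bci_params()
  l <- numerosity_likelihoods(1, 2, p)
  expect_equal(l$c1, quad_pair_c1(1, 2, p$sigma_v, p$sigma_a, p$mu_p, p$sigma_p),
               tolerance = 1e-8)
  expect_equal(l$c2, quad_pair_c2(1, 2, p$sigma_v, p$sigma_a, p$mu_p, p$sigma_p),
               tolerance = 1e-8)

  set.seed(101)
  for (i in 1:25) {
    cs <- draw_oracle_case()
    l <- numerosity_likelihoods(cs$x_v, cs$x_a, cs$params)
    expect_lt(abs(l$c1 - quad_pair_c1(cs$x_v, cs$x_a, cs$params$sigma_v,
                                      cs$params$sigma_a, cs$params$mu_p,
                                      cs$params$sigma_p)), 1e-8)
    expect_lt(abs(l$c2 - quad_pair_c2(cs$x_v, cs$x_a, cs$params$sigma_v,
                                      cs$params$sigma_a, cs$params$mu_p,
                                      cs$params$sigma_p)), 1e-8)
  }
})

test_that("numerosity likelihoods: coincidence favors a common cause", {
  p <- bci_params(sigma_v = 0.7, sigma_a = 0.7, sigma_p = 0.7, mu_p = 1.2)
  l <- numerosity_likelihoods(p$mu_p, p$mu_p, p)
  expect_gt(l$c1, l$c2)
})

test_that("very wide numerosity prior reaches the flat-prior limit", {
  p <- bci_params(sigma_p = 1e6)
  l <- numerosity_likelihoods(c(1, 0.5, 2), c(2, 2.5, 0), p)
  expect_equal(l$c1,
               mapply(quad_pair_c1, c(1, 0.5, 2), c(2, 2.5, 0),
                      MoreArgs = list(sv = p$sigma_v, sa = p$sigma_a,
                                      mu = p$mu_p, sp = p$sigma_p)),
               tolerance = 1e-8)
  # in the limit the common-cause likelihood is proportional to the density
  # of the cue disagreement
  ratio <- l$c1 / dnorm(c(1, 0.5, 2) - c(2, 2.5, 0), 0,
                        sqrt(p$sigma_v^2 + p$sigma_a^2))
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-6)
})

test_that("closed-form temporal likelihoods match the quadrature oracle", {
  p <- bci_params()
  l <- temporal_likelihoods(0, 500, p)
  expect_lt(abs(l$c1 - quad_pair_c1(0, 500, p$sigma_vt, p$sigma_at, p$mu_tp,
                                    p$sigma_tp, lower = -5000, upper = 5000,
                                    n = 40001)), 1e-8)
  expect_lt(abs(l$c2 - quad_pair_c2(0, 500, p$sigma_vt, p$sigma_at, p$mu_tp,
                                    p$sigma_tp, lower = -5000, upper = 5000,
                                    n = 40001)), 1e-8)
  # coincidence at the prior mean favors the common cause
  lc <- temporal_likelihoods(p$mu_tp, p$mu_tp, p)
  expect_gt(lc$c1, lc$c2)
  # the common-cause integrand is symmetric under swapping the two streams
  swapped <- bci_params(sigma_vt = p$sigma_at, sigma_at = p$sigma_vt)
  expect_equal(temporal_likelihoods(0, 500, p)$c1,
               temporal_likelihoods(500, 0, swapped)$c1)
})

test_that("posterior over causal structure matches the quadrature oracle", {
  p <- bci_params()
  got <- posterior_common_cause(1, 2, 0, 0, p)
  expect_equal(got$p_c1, quad_posterior_c1(1, 2, 0, 0, p), tolerance = 1e-8)
  set.seed(202)
  for (i in 1:5) {
    cs <- draw_oracle_case()
    got <- posterior_common_cause(cs$x_v, cs$x_a, cs$t_v, cs$t_a, cs$params)
    expect_lt(abs(got$p_c1 - quad_posterior_c1(cs$x_v, cs$x_a, cs$t_v, cs$t_a,
                                               cs$params)), 1e-8)
    expect_true(got$p_c1 >= 0 && got$p_c1 <= 1)
    expect_true(all(c(got$l_num_c1, got$l_num_c2, got$l_t_c1, got$l_t_c2) >= 0))
  }
})

test_that("posterior edge cases and monotonicity", {
  expect_equal(posterior_common_cause(1, 2, 0, 400,
                                      bci_params(p_common = 1))$p_c1, 1)
  expect_equal(posterior_common_cause(1, 2, 0, 400,
                                      bci_params(p_common = 0))$p_c1, 0)
  p <- bci_params()
  # non-increasing in numerosity disparity, all else fixed
  deltas <- seq(0, 4, by = 0.5)
  post_x <- posterior_common_cause(1 + deltas, rep(1, length(deltas)),
                                   rep(0, length(deltas)), rep(0, length(deltas)), p)$p_c1
  expect_true(all(diff(post_x) <= 1e-12))
  # non-increasing in temporal disparity, all else fixed
  tdel <- seq(0, 1000, by = 100)
  post_t <- posterior_common_cause(rep(1, length(tdel)), rep(1, length(tdel)),
                                   rep(0, length(tdel)), tdel, p)$p_c1
  expect_true(all(diff(post_t) <= 1e-12))
})

test_that("dropping the temporal dimension equals the wide-temporal-noise limit", {
  p <- bci_params()
  p_wide <- bci_params(sigma_vt = 1e7, sigma_at = 1e7)
  x_v <- c(1, 0.4, 2.2); x_a <- c(2, 1.1, 0.6)
  p1_no_t <- posterior_common_cause(x_v, x_a, 0, 0, p, use_temporal = FALSE)$p_c1
  p1_wide <- posterior_common_cause(x_v, x_a, c(0, 100, 300), c(0, 250, 0),
                                    p_wide)$p_c1
  expect_equal(p1_no_t, p1_wide, tolerance = 1e-6)
})

test_that("the product-of-marginals denominator is non-normalizing but reproducible", {
  p <- bci_params()
  joint <- posterior_common_cause(1, 2, 0, 300, p)
  marg <- posterior_common_cause(1, 2, 0, 300, p, denominator = "marginal")
  # direct arithmetic re-derivation of the printed form
  pc <- p$p_common
  expect_equal(marg$p_c1,
               (joint$l_num_c1 * joint$l_t_c1 * pc) /
                 ((joint$l_num_c1 * pc + joint$l_num_c2 * (1 - pc)) *
                    (joint$l_t_c1 * pc + joint$l_t_c2 * (1 - pc))))
  # and it differs from the normalized posterior in general
  expect_false(isTRUE(all.equal(marg$p_c1, joint$p_c1)))
})

test_that("segregated estimate follows precision weighting", {
  p <- bci_params()
  # direct arithmetic oracle
  expect_equal(estimate_segregated(2, 0.33, p),
               (2 / 0.33^2 + 1.43 / 1.33^2) / (1 / 0.33^2 + 1 / 1.33^2))
  # flat-prior limit returns the evidence
  expect_equal(estimate_segregated(2, 0.33, bci_params(sigma_p = 1e8)), 2,
               tolerance = 1e-9)
  # prior mean is a fixed point
  expect_equal(estimate_segregated(p$mu_p, 0.5, p), p$mu_p)
  # result is between evidence and prior mean
  est <- estimate_segregated(c(-1, 0.2, 3), 0.4, p)
  expect_true(all(est > pmin(c(-1, 0.2, 3), p$mu_p) &
                    est < pmax(c(-1, 0.2, 3), p$mu_p)))
})

test_that("fused estimate combines the cues and the prior", {
  p <- bci_params()
  expect_equal(estimate_fused(1, 2, p),
               (1 / p$sigma_v^2 + 2 / p$sigma_a^2 + p$mu_p / p$sigma_p^2) /
                 (1 / p$sigma_v^2 + 1 / p$sigma_a^2 + 1 / p$sigma_p^2))
  # all cues agreeing at c returns c
  pc <- bci_params(mu_p = 1.7)
  expect_equal(estimate_fused(1.7, 1.7, pc), 1.7)
  # symmetric flat-prior limit is the arithmetic mean
  psym <- bci_params(sigma_v = 0.5, sigma_a = 0.5, sigma_p = 1e8)
  expect_equal(estimate_fused(1, 2, psym), 1.5, tolerance = 1e-9)
  # bounded by the three inputs
  est <- estimate_fused(0.2, 2.5, p)
  expect_true(est > min(0.2, 2.5, p$mu_p) && est < max(0.2, 2.5, p$mu_p))
  # explicit flat-prior flag removes the prior term
  expect_equal(estimate_fused(1, 2, psym, flat_prior = TRUE), 1.5)
})

test_that("model-averaged estimates are convex combinations", {
  p <- bci_params()
  est <- estimate_model_average(1, 2, 0, 300, p)
  expect_equal(est$s_hat_v,
               est$p_c1 * est$s_hat_fused + (1 - est$p_c1) * est$s_hat_v_seg)
  expect_equal(est$s_hat_a,
               est$p_c1 * est$s_hat_fused + (1 - est$p_c1) * est$s_hat_a_seg)
  set.seed(33)
  for (i in 1:10) {
    cs <- draw_oracle_case()
    e <- estimate_model_average(cs$x_v, cs$x_a, cs$t_v, cs$t_a, cs$params)
    expect_gte(e$s_hat_v, min(e$s_hat_fused, e$s_hat_v_seg) - 1e-12)
    expect_lte(e$s_hat_v, max(e$s_hat_fused, e$s_hat_v_seg) + 1e-12)
    expect_gte(e$s_hat_a, min(e$s_hat_fused, e$s_hat_a_seg) - 1e-12)
    expect_lte(e$s_hat_a, max(e$s_hat_fused, e$s_hat_a_seg) + 1e-12)
  }
  # collapse to fusion / segregation at the prior extremes
  e1 <- estimate_model_average(1, 2, 0, 0, bci_params(p_common = 1))
  expect_equal(e1$s_hat_v, e1$s_hat_fused)
  expect_equal(e1$s_hat_a, e1$s_hat_fused)
  e0 <- estimate_model_average(1, 2, 0, 0, bci_params(p_common = 0))
  expect_equal(e0$s_hat_a, e0$s_hat_a_seg)
  expect_equal(e0$s_hat_v, e0$s_hat_v_seg)
})

test_that("model-averaged estimates match the composed oracle", {
  p <- bci_params()
  e <- estimate_model_average(1, 2, 0, 300, p)
  p1 <- quad_posterior_c1(1, 2, 0, 300, p)
  fused <- (1 / p$sigma_v^2 + 2 / p$sigma_a^2 + p$mu_p / p$sigma_p^2) /
    (1 / p$sigma_v^2 + 1 / p$sigma_a^2 + 1 / p$sigma_p^2)
  seg_v <- (1 / p$sigma_v^2 + p$mu_p / p$sigma_p^2) /
    (1 / p$sigma_v^2 + 1 / p$sigma_p^2)
  seg_a <- (2 / p$sigma_a^2 + p$mu_p / p$sigma_p^2) /
    (1 / p$sigma_a^2 + 1 / p$sigma_p^2)
  expect_equal(e$s_hat_v, p1 * fused + (1 - p1) * seg_v, tolerance = 1e-8)
  expect_equal(e$s_hat_a, p1 * fused + (1 - p1) * seg_a, tolerance = 1e-8)
})

test_that("discrete readout rounds to the nearest key with ties up", {
  expect_identical(discretize_response(c(1.4, -0.7, 1.5, 0.5, 2.9, 0.49)),
                   c(1L, 0L, 2L, 1L, 2L, 0L))
  expect_error(discretize_response(NaN), "finite")
  expect_error(discretize_response(Inf), "finite")
})

test_that("non-finite evidence is rejected", {
  p <- bci_params()
  expect_error(numerosity_likelihoods(NA_real_, 1, p), "finite")
  expect_error(temporal_likelihoods(0, Inf, p), "finite")
  expect_error(posterior_common_cause(1, NaN, 0, 0, p), "finite")
})

test_that("log-normal numerosity family matches its quadrature oracle", {
  p <- bci_params(family = "lognormal", sigma_v = 0.5, sigma_a = 0.3,
                  sigma_p = 0.6, mu_p = 1.4)
  l <- numerosity_likelihoods(1.2, 2.1, p)
  expect_equal(l$c1, quad_lnorm_c1(1.2, 2.1, 0.5, 0.3, 1.4, 0.6),
               tolerance = 1e-7)
  expect_equal(l$c2,
               quad_lnorm_single(1.2, 0.5, 1.4, 0.6) *
                 quad_lnorm_single(2.1, 0.3, 1.4, 0.6),
               tolerance = 1e-7)
  # posterior-mean estimate under the log-normal family, against quadrature
  s <- seq(1e-6, 60, length.out = 16001)
  h <- s[2] - s[1]
  post <- dlnorm(2.1, log(s), 0.3) * dlnorm(s, log(1.4), 0.6)
  expect_equal(estimate_segregated(2.1, 0.3, p),
               simpson(s * post, h) / simpson(post, h), tolerance = 1e-6)
  expect_error(numerosity_likelihoods(-1, 2, p), "> 0")
})
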