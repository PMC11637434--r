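test_that("k-means initialization separates clusters and handles edge cases", {
  r <- init_responsibilities(c(10, 10, 10, 20, 20, 20), 2)
  expect_equal(dim(r), c(6, 2))
  expect_true(all(rowSums(r) == 1))
  expect_equal(colSums(r), c(3, 3))
  expect_true(all(r[1:3, 1] == 1) && all(r[4:6, 2] == 1))

  expect_equal(init_responsibilities(c(5, 7, 9), 1), matrix(1, 3, 1))

  # K above the number of distinct lengths is reduced
  expect_message(r2 <- init_responsibilities(c(1, 1, 2, 2), 3), "reducing")
  expect_equal(ncol(r2), 2)

  # against the exhaustive sorted-split two-means oracle
  set.seed(21)
  x <- round(c(rnorm(250, 13, 1), rnorm(150, 20, 1)))
  r3 <- init_responsibilities(x, 2)
  centers <- sort(colSums(r3 * x) / colSums(r3))
  oracle <- best_split_2means(x)
  expect_lt(max(abs(centers - oracle$centers)), 0.5)
})

test_that("posterior updates match the weighted-moment oracle to 1e-10", {
  set.seed(5)
  x <- round(rnorm(80, 17, 2))
  hy <- vb_hyperparams(x)
  r <- init_responsibilities(x, 2)
  post <- update_posteriors(x, r, hy)
  oracle <- moment_oracle(x, r, hy)
  for (f in c("Nk", "xbar", "Sk", "m", "beta", "w", "v")) {
    expect_equal(post[[f]], oracle[[f]], tolerance = 1e-10)
  }
  # derived sigma is the expected-precision transform
  expect_equal(post$sigma, 1 / sqrt(post$v * post$w), tolerance = 1e-12)

  # empty component reverts to the prior
  r0 <- cbind(rep(1, length(x)), 0)
  post0 <- update_posteriors(x, r0, hy)
  expect_equal(post0$m[2], hy$m0)
  expect_equal(post0$beta[2], hy$beta0)
  expect_equal(post0$w[2], hy$w0)
  expect_equal(post0$v[2], hy$v0)

  # degenerate data with a diffuse prior: posterior mean at the data value
  hy2 <- vb_hyperparams(beta0 = 1e-6, m0 = 0, w0 = 1, v0 = 3)
  xc <- rep(15, 40)
  pc <- update_posteriors(xc, matrix(1, 40, 1), hy2)
  expect_equal(pc$m[1], 15, tolerance = 1e-4)
  expect_equal(pc$Sk[1], 0)
})

test_that("responsibility updates are row-stochastic with correct limits", {
  # well-separated sharp components fitted from their own data: a point at
  # a component mean takes essentially all responsibility there
  xfit <- c(rep(10, 26), rep(11, 5), rep(20, 26), rep(21, 5))
  hy <- vb_hyperparams(xfit)
  post <- update_posteriors(xfit, init_responsibilities(xfit, 2), hy)
  r <- update_responsibilities(c(10, 20), post, mode = "free")
  expect_gt(r[1, 1], 0.999)
  expect_gt(r[2, 2], 0.999)
  expect_equal(rowSums(r), c(1, 1), tolerance = 1e-9)

  # identical components: responsibilities equal the weights exactly
  post2 <- list(m = rep(15, 2), beta = rep(5, 2), w = rep(0.5, 2),
                v = rep(8, 2))
  x <- c(10, 14, 15, 20)
  w <- c(0.3, 0.7)
  r2 <- update_responsibilities(x, post2, weights = w, mode = "pinned")
  expect_equal(r2, matrix(rep(w, each = length(x)), ncol = 2),
               tolerance = 1e-12)

  # pinned zero weight receives zero responsibility
  r3 <- update_responsibilities(x, post2, weights = c(1, 0), mode = "pinned")
  expect_true(all(r3[, 2] == 0))
})

test_that("K=1 converged ELBO equals the Normal-Gamma closed-form marginal", {
  set.seed(42)
  for (rep in 1:3) {
    x <- round(rnorm(50 + 100 * rep, 15 + rep, 0.5 + rep))
    hy <- vb_hyperparams(x, beta0 = 10^(-rep), v0 = 2 + rep)
    fit <- fit_vb(x, 1, "free", hyper = hy, tol = 1e-12, max_iter = 50)
    expect_equal(fit$elbo, ng_log_marginal(x, hy), tolerance = 1e-6)
  }
})

test_that("ELBO is finite, computable and non-decreasing across iterations", {
  set.seed(8)
  x <- round(c(rnorm(120, 13, 1), rnorm(80, 19, 1.5)))
  hy <- vb_hyperparams(x)
  fit <- fit_vb(x, 2, "free", hyper = hy, tol = 1e-12, max_iter = 50)
  expect_true(all(is.finite(fit$elbo_trace)))
  expect_true(all(diff(fit$elbo_trace) > -1e-6))
  # one manual update cycle also increases the bound
  r <- init_responsibilities(x, 2)
  post <- update_posteriors(x, r, hy)
  r1 <- update_responsibilities(x, post, mode = "free")
  post1 <- update_posteriors(x, r1, hy)
  e1 <- compute_elbo(x, r1, post1, hy, mode = "free")
  r2 <- update_responsibilities(x, post1, mode = "free")
  post2 <- update_posteriors(x, r2, hy)
  e2 <- compute_elbo(x, r2, post2, hy, mode = "free")
  expect_gte(e2, e1 - 1e-9)
  # pinned mode is monotone too
  fitp <- fit_vb(x, 2, "pinned", pinned_weights = c(0.6, 0.4), hyper = hy,
                 tol = 1e-12, max_iter = 50)
  expect_true(all(diff(fitp$elbo_trace) > -1e-6))
})

test_that("fit_vb recovers generating parameters", {
  set.seed(33)
  x1 <- round(rnorm(500, 15, 1))
  f1 <- fit_vb(x1, 1)
  expect_lt(abs(f1$mu[1] - 15), 3 * 1 / sqrt(500) + 0.3)  # SE plus rounding bias

  x2 <- round(c(rnorm(700, 13, 1), rnorm(300, 20, 1)))
  f2 <- fit_vb(x2, 2, "free")
  ord <- order(f2$mu)
  expect_lt(abs(f2$mu[ord[1]] - 13), 0.3)
  expect_lt(abs(f2$mu[ord[2]] - 20), 0.3)
  expect_lt(abs(f2$weights[ord[1]] - 0.7), 0.05)
  expect_equal(sum(f2$Nk), 1000, tolerance = 1e-6)
  expect_true(all(abs(rowSums(f2$r) - 1) < 1e-9))

  # agreement with a classical EM oracle on a well-separated problem
  em <- em_gmm_oracle(x2, 2, mu0 = c(12, 21))
  orde <- order(em$mu)
  expect_lt(max(abs(sort(f2$mu) - sort(em$mu))), 0.1)
  expect_lt(max(abs(sort(f2$sigma) - sort(em$sigma))), 0.1)

  # K=2 on unimodal data: the components collapse onto one mode (their
  # means end up within one joint standard deviation), the effective-K=1
  # signal that the deconvolution's goodness-of-fit selection acts on
  set.seed(12)
  x3 <- round(rnorm(600, 16, 1.2))
  f3 <- fit_vb(x3, 2, "free")
  expect_lt(abs(diff(f3$mu)), 1.5 * max(f3$sigma))

  # determinism
  f2b <- fit_vb(x2, 2, "free")
  expect_identical(f2$mu, f2b$mu)
  expect_identical(f2$elbo, f2b$elbo)
})

test_that("fit_vb validates pinned weights and reduces excessive K", {
  x <- round(rnorm(50, 15, 1))
  expect_error(fit_vb(x, 2, "pinned", pinned_weights = c(0.9, 0.3)),
               "probability vector")
  expect_error(fit_vb(x, 2, "pinned"), "length K")
  expect_message(f <- fit_vb(c(10, 10, 11, 11), 4, "free"), "reducing")
  expect_lte(f$K, 2)
})
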