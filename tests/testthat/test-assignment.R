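make_problem <- function(B, mu, sigma, sp_mu = 16, sp_sigma = 2, n = 400,
                         seed = 1) {
  set.seed(seed)
  sp <- gauss_spectrum("p", sp_mu, sp_sigma, n)
  assignment_problem(B, mu, sigma, sp)
}

test_that("objective matches an independently coded evaluator", {
  set.seed(14)
  for (i in 1:5) {
    G <- sample(2:3, 1); K <- sample(2:3, 1)
    B <- runif(G, 0.2, 1)
    B <- sort(B / sum(B), decreasing = TRUE)
    mu <- runif(K, 12, 22); sigma <- runif(K, 0.8, 2.5)
    sp <- gauss_spectrum("x", 17, 2.5, 300)
    prob <- assignment_problem(B, mu, sigma, sp)
    A <- random_A(G, K)
    expect_equal(objective_value(A, prob),
                 objective_oracle(A, B, mu, sigma, sp), tolerance = 1e-9)
  }
})

test_that("objective is near zero for a self-consistent component", {
  # empirical spectrum is exactly the discretized Gaussian scaled to n
  mu <- 16; sigma <- 1.5; n <- 1e6
  support <- seq(8, 24)
  p <- pnorm(support + 0.5, mu, sigma) - pnorm(support - 0.5, mu, sigma)
  sp <- length_spectrum("c", support, round(n * p / sum(p)))
  # fitted sigma on binned data carries the rounding variance
  prob <- assignment_problem(1, mu, sqrt(sigma^2 + 1 / 12), sp)
  expect_lt(objective_value(matrix(1, 1, 1), prob), 1e-4)
})

test_that("label permutations leave the objective unchanged", {
  prob <- make_problem(c(0.6, 0.4), c(13, 19), c(1, 1.5))
  A <- rbind(c(1, 0), c(0, 1))
  perm <- c(2, 1)
  prob_p <- make_problem(c(0.6, 0.4), c(13, 19)[perm], c(1, 1.5)[perm])
  expect_equal(objective_value(A, prob),
               objective_value(A[, perm], prob_p), tolerance = 1e-12)
})

test_that("sharing a component wins when the truth is shared", {
  set.seed(3)
  sp <- gauss_spectrum("sh", 15, 1, 800)  # both clones share one mode
  prob <- assignment_problem(c(0.7, 0.3), c(15, 22), c(1, 1), sp)
  shared <- rbind(c(1, 0), c(1, 0))
  split <- rbind(c(1, 0), c(0, 1))
  expect_lt(objective_value(shared, prob), objective_value(split, prob))
})

test_that("exhaustive solver is a verified brute force with lex tie-break", {
  set.seed(4)
  G <- 3; K <- 3
  B <- c(0.5, 0.3, 0.2)
  mu <- c(12, 16, 21); sigma <- c(1, 1.2, 0.9)
  sp <- gauss_spectrum("e", 16, 3, 500)
  prob <- assignment_problem(B, mu, sigma, sp)
  sol <- solve_exhaustive(prob)
  expect_equal(sol$n_evaluated, 27)
  expect_true(all(rowSums(sol$A) == 1))
  # independent brute force over all 27 matrices
  best <- Inf
  for (a1 in 1:3) for (a2 in 1:3) for (a3 in 1:3) {
    A <- matrix(0, 3, 3)
    A[cbind(1:3, c(a1, a2, a3))] <- 1
    best <- min(best, objective_oracle(A, B, mu, sigma, sp))
  }
  expect_equal(sol$objective, best, tolerance = 1e-9)
  # fuzz: the optimum beats random feasible matrices
  for (i in 1:25) {
    expect_lte(sol$objective, objective_value(random_A(G, K), prob) + 1e-12)
  }
  # G=1: one-hot on the best single component
  prob1 <- assignment_problem(1, mu, sigma, sp)
  sol1 <- solve_exhaustive(prob1)
  expect_equal(sum(sol1$A), 1)
  expect_equal(sol1$n_evaluated, 3)
  # enumeration cap
  expect_error(solve_exhaustive(prob, cap = 10), "cap")
})

test_that("derive_weights reproduces the published weight patterns", {
  B <- c(0.707, 0.293)
  expect_equal(derive_weights(diag(2), B), c(0.707, 0.293))
  shared <- rbind(c(1, 0), c(1, 0))
  expect_equal(derive_weights(shared, c(0.7, 0.3)), c(1, 0))
  A3 <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(derive_weights(A3, c(0.5, 0.3, 0.2)), c(0.7, 0.3))
  # always a probability vector
  set.seed(2)
  for (i in 1:20) {
    G <- sample(1:5, 1); K <- sample(1:4, 1)
    B <- runif(G)
    B <- sort(B / sum(B), decreasing = TRUE)
    Y <- derive_weights(random_A(G, K), B)
    expect_equal(sum(Y), 1, tolerance = 1e-12)
    expect_true(all(Y >= 0))
  }
})

test_that("milp solver agrees with exhaustive enumeration", {
  has_milp <- requireNamespace("lpSolve", quietly = TRUE)
  set.seed(9)
  for (i in 1:20) {
    G <- sample(2:4, 1); K <- sample(2:4, 1)
    B <- runif(G, 0.1, 1)
    B <- sort(B / sum(B), decreasing = TRUE)
    mu <- sort(runif(K, 10, 24)); sigma <- runif(K, 0.8, 2.2)
    sp <- gauss_spectrum(paste0("m", i), mean(mu), 3, 400, lo = 4, hi = 30)
    prob <- assignment_problem(B, mu, sigma, sp)
    ex <- solve_exhaustive(prob)
    got <- suppressWarnings(
      if (has_milp) solve_milp(prob)
      else suppressMessages(solve_milp(prob))  # exhaustive fallback path
    )
    expect_equal(got$objective, ex$objective, tolerance = 1e-6)
    expect_true(all(rowSums(got$A) == 1))
  }
  # small instance: identical assignment either way
  prob2 <- make_problem(c(0.8, 0.2), c(14, 19), c(1, 1))
  s1 <- solve_exhaustive(prob2)
  s2 <- suppressWarnings(
    if (has_milp) solve_milp(prob2) else suppressMessages(solve_milp(prob2)))
  expect_equal(s2$Y, s1$Y)
})

test_that("assignment problem validates inputs", {
  sp <- gauss_spectrum("v", 15, 1, 100)
  expect_error(assignment_problem(c(0.7, 0.3), 15, 1e-7, sp), "degenerate")
  expect_error(assignment_problem(c(0.7, 0.7), 15, 1, sp), "sum to 1")
  prob <- assignment_problem(1, 15, 1, sp)
  expect_error(objective_value(matrix(c(1, 1), 1, 2), prob))
  expect_error(objective_value(matrix(0, 1, 1), prob), "unit row sums")
})
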