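#' Hyperparameters of the Normal-Gamma variational mixture
#'
#' The one-dimensional specialization of the Normal-Wishart conjugate prior:
#' the component precision Lambda_k has a Gamma prior parameterized, Wishart
#' style, by a scalar scale `w0` and degrees of freedom `v0` (shape v0/2,
#' rate 1/(2 w0), so E\[Lambda\] = v0 w0), and the mean has a conditional
#' Normal prior N(m0, (beta0 Lambda)^-1). `alpha0` is the symmetric
#' Dirichlet concentration over mixing weights, used only in free-weight
#' mode.
#'
#' Defaults are weakly informative and data-centered: `m0` is the sample
#' mean, `w0` the reciprocal sample variance, `beta0 = 1e-3`, `v0 = 3`,
#' `alpha0 = 1`.
#'
#' @param lengths Numeric vector of observed repeat lengths, used for the
#'   data-dependent defaults. May be omitted if `m0` and `w0` are given.
#' @param beta0,m0,w0,v0,alpha0 Prior parameters (see above).
#' @return Object of class `vb_hyperparams`.
#' @export
vb_hyperparams <- function(lengths = NULL, beta0 = 1e-3, m0 = NULL, w0 = NULL,
                           v0 = 3, alpha0 = 1) {
  if (is.null(m0)) {
    if (is.null(lengths)) stop("m0 must be given when lengths are absent")
    m0 <- mean(lengths)
  }
  if (is.null(w0)) {
    if (is.null(lengths)) stop("w0 must be given when lengths are absent")
    v <- stats::var(lengths) * (length(lengths) - 1) / length(lengths)
    if (!is.finite(v) || v < 1e-2) v <- 1e-2  # guard near-degenerate spectra
    w0 <- 1 / v
  }
  stopifnot(beta0 > 0, w0 > 0, v0 >= 1, alpha0 > 0)
  structure(list(beta0 = beta0, m0 = m0, w0 = w0, v0 = v0, alpha0 = alpha0),
            class = "vb_hyperparams")
}

# collapse expanded lengths to (values, weights)
.collapse <- function(lengths) {
  tb <- table(lengths)
  list(x = as.numeric(names(tb)), w = as.numeric(tb))
}

# deterministic weighted 1-D k-means (Lloyd, quantile init)
.kmeans1d <- function(x, w, K) {
  J <- length(x)
  stopifnot(K <= J)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  qs <- (2 * seq_len(K) - 1) / (2 * K)
  centers <- vapply(qs, function(q) x[which(cw >= q)[1]], 0)
  centers <- sort(centers)
  assign_prev <- rep(0L, J)
  for (it in 1:200) {
    d <- abs(outer(x, centers, "-"))
    a <- max.col(-d, ties.method = "first")
    for (k in seq_len(K)) {           # re-seed empty clusters at worst point
      if (!any(a == k)) {
        far <- which.max(d[cbind(seq_len(J), a)])
        centers[k] <- x[far]
        a[far] <- k
      }
    }
    if (identical(a, assign_prev)) break
    assign_prev <- a
    for (k in seq_len(K)) {
      sel <- a == k
      centers[k] <- sum(w[sel] * x[sel]) / sum(w[sel])
    }
  }
  res <- integer(J)
  res[o] <- a
  list(assignment = res, centers = centers)
}

#' Initialize responsibilities by k-means
#'
#' Hard one-hot responsibilities from a deterministic weighted 1-D k-means
#' clustering of the read lengths. If `K` exceeds the number of distinct
#' lengths it is reduced to that number (with a message).
#'
#' @param lengths Numeric vector of per-read lengths.
#' @param K Number of components.
#' @param seed Integer seed (kept for interface stability; the initializer
#'   is deterministic).
#' @return N x K one-hot matrix of responsibilities.
#' @export
init_responsibilities <- function(lengths, K, seed = 1L) {
  stopifnot(length(lengths) >= 1, K >= 1)
  nd <- length(unique(lengths))
  if (K > nd) {
    message("K=", K, " exceeds ", nd, " distinct lengths; reducing K to ", nd)
    K <- nd
  }
  cl <- .collapse(lengths)
  km <- .kmeans1d(cl$x, cl$w, K)
  # order cluster labels by center so labels are deterministic left-to-right
  relabel <- order(order(km$centers))
  a_unique <- relabel[km$assignment]
  a <- a_unique[match(lengths, cl$x)]
  r <- matrix(0, nrow = length(lengths), ncol = K)
  r[cbind(seq_along(lengths), a)] <- 1
  r
}

# weighted M-step: the four conjugate updates plus sufficient statistics
.vb_mstep <- function(x, w, r, hyper) {
  K <- ncol(r)
  wr <- w * r
  Nk <- colSums(wr)
  xbar <- numeric(K); Sk <- numeric(K)
  for (k in seq_len(K)) {
    if (Nk[k] > 0) {
      xbar[k] <- sum(wr[, k] * x) / Nk[k]
      Sk[k] <- sum(wr[, k] * (x - xbar[k])^2) / Nk[k]
    } else {
      xbar[k] <- hyper$m0
      Sk[k] <- 0
    }
  }
  beta_k <- hyper$beta0 + Nk
  m_k <- (hyper$beta0 * hyper$m0 + Nk * xbar) / beta_k
  v_k <- hyper$v0 + Nk
  w_inv <- 1 / hyper$w0 + Nk * Sk +
    (hyper$beta0 * Nk / beta_k) * (xbar - hyper$m0)^2
  w_k <- 1 / w_inv
  alpha_k <- hyper$alpha0 + Nk
  list(Nk = Nk, xbar = xbar, Sk = Sk,
       m = m_k, beta = beta_k, w = w_k, v = v_k, alpha = alpha_k,
       mu = m_k, sigma = 1 / sqrt(v_k * w_k))
}

#' Posterior hyperparameter update (M-step)
#'
#' Evaluates the conjugate Normal-Gamma updates
#' `beta_k = beta0 + N_k`, `m_k = (beta0 m0 + N_k xbar_k)/beta_k`,
#' `v_k = v0 + N_k`,
#' `w_k^-1 = w0^-1 + N_k S_k + (beta0 N_k / beta_k)(xbar_k - m0)^2`,
#' with `N_k`, `xbar_k`, `S_k` the responsibility-weighted counts, means
#' and scatters. An empty component (`N_k = 0`) reverts to the prior.
#'
#' @param lengths Numeric vector of per-read lengths.
#' @param r N x K row-stochastic responsibility matrix.
#' @param hyper A [vb_hyperparams].
#' @return List with `Nk`, `xbar`, `Sk`, posterior `m`, `beta`, `w`, `v`,
#'   `alpha`, and the derived `mu` (= `m`) and `sigma` (= 1/sqrt(v w),
#'   from the expected precision E\[Lambda_k\] = v_k w_k).
#' @export
update_posteriors <- function(lengths, r, hyper) {
  stopifnot(nrow(r) == length(lengths))
  rs <- rowSums(r)
  if (any(abs(rs - 1) > 1e-8)) stop("responsibility rows must sum to 1")
  .vb_mstep(as.numeric(lengths), rep(1, length(lengths)), r, hyper)
}

.eln_lambda <- function(post) digamma(post$v / 2) + log(2) + log(post$w)

# E-step on (x, w): log-space with max subtraction
.vb_estep <- function(x, post, log_weights) {
  K <- length(post$m)
  eln_lam <- .eln_lambda(post)
  lnrho <- matrix(rep(log_weights + 0.5 * (eln_lam - log(2 * pi)), each = length(x)),
                  nrow = length(x))
  for (k in seq_len(K)) {
    quad <- 1 / post$beta[k] + post$v[k] * post$w[k] * (x - post$m[k])^2
    lnrho[, k] <- lnrho[, k] - 0.5 * quad
  }
  mx <- apply(lnrho, 1, max)
  if (any(!is.finite(mx))) {
    stop("responsibility underflow at length ", x[which(!is.finite(mx))[1]])
  }
  r <- exp(lnrho - mx)
  r / rowSums(r)
}

#' Responsibility update (E-step)
#'
#' Mean-field update of the latent assignments:
#' `ln rho_nk = E[ln pi_k] + (E[ln Lambda_k] - ln 2pi)/2 -
#'  (1/beta_k + v_k w_k (L_n - m_k)^2)/2`, normalized per read in log
#' space. In `free` mode `E[ln pi_k]` is the Dirichlet expectation
#' `digamma(alpha_k) - digamma(sum alpha)`; in `pinned` mode the mixing
#' weights are externally fixed and `E[ln pi_k] = log(weight_k)`, with
#' zero-weight components receiving exactly zero responsibility.
#'
#' @param lengths Numeric vector of per-read lengths.
#' @param posterior Posterior list from [update_posteriors()].
#' @param weights K-vector of mixing weights (pinned mode) or `NULL` to use
#'   the Dirichlet posterior in `posterior$alpha` (free mode).
#' @param mode `"free"` or `"pinned"`.
#' @return N x K row-stochastic responsibility matrix.
#' @export
update_responsibilities <- function(lengths, posterior, weights = NULL,
                                    mode = c("free", "pinned")) {
  mode <- match.arg(mode)
  lw <- .log_weights(posterior, weights, mode)
  .vb_estep(as.numeric(lengths), posterior, lw)
}

.log_weights <- function(posterior, weights, mode) {
  if (mode == "free") {
    digamma(posterior$alpha) - digamma(sum(posterior$alpha))
  } else {
    if (is.null(weights)) stop("pinned mode requires weights")
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6) {
      stop("pinned weights must be a probability vector")
    }
    log(weights)
  }
}

.ln_wishart_B <- function(w, v) -(v / 2) * (log(w) + log(2)) - lgamma(v / 2)

# full variational lower bound on (x, w) weighted data
.vb_elbo <- function(x, w, r, post, hyper, mode, weights = NULL) {
  K <- length(post$m)
  Nk <- post$Nk; xbar <- post$xbar; Sk <- post$Sk
  eln_lam <- .eln_lambda(post)
  e_lik <- 0.5 * sum(Nk * (eln_lam - log(2 * pi) - 1 / post$beta -
                             post$v * post$w * (Sk + (xbar - post$m)^2)))
  if (mode == "free") {
    eln_pi <- digamma(post$alpha) - digamma(sum(post$alpha))
    e_pz <- sum(Nk * eln_pi)
    e_ppi <- lgamma(K * hyper$alpha0) - K * lgamma(hyper$alpha0) +
      (hyper$alpha0 - 1) * sum(eln_pi)
    e_qpi <- sum((post$alpha - 1) * eln_pi) +
      lgamma(sum(post$alpha)) - sum(lgamma(post$alpha))
  } else {
    lw <- log(weights)
    e_pz <- sum(ifelse(Nk > 0, Nk * lw, 0))
    e_ppi <- 0
    e_qpi <- 0
  }
  e_pmu <- sum(0.5 * (log(hyper$beta0 / (2 * pi)) + eln_lam -
                        hyper$beta0 / post$beta -
                        hyper$beta0 * post$v * post$w * (post$m - hyper$m0)^2)) +
    K * .ln_wishart_B(hyper$w0, hyper$v0) +
    (hyper$v0 - 2) / 2 * sum(eln_lam) -
    0.5 * sum(post$v * post$w) / hyper$w0
  lr <- r * log(r)
  lr[r == 0] <- 0
  e_qz <- sum(w * rowSums(lr))
  h_lam <- -.ln_wishart_B(post$w, post$v) -
    (post$v - 2) / 2 * eln_lam + post$v / 2
  e_qmu <- sum(0.5 * eln_lam + 0.5 * log(post$beta / (2 * pi)) - 0.5 - h_lam)
  e_lik + e_pz + e_ppi + e_pmu - e_qz - e_qpi - e_qmu
}

#' Evidence lower bound of the variational mixture
#'
#' In free-weight mode this is the standard variational Gaussian-mixture
#' bound with Dirichlet weight terms; in pinned mode the Dirichlet terms
#' are replaced by the fixed-weight cross-entropy `sum_k N_k log Y_k`.
#' For `K = 1` the converged bound equals the closed-form Normal-Gamma
#' log marginal likelihood, because the variational family then contains
#' the exact posterior.
#'
#' @param lengths Numeric vector of per-read lengths.
#' @param r N x K responsibility matrix.
#' @param posterior Posterior list from [update_posteriors()].
#' @param hyper A [vb_hyperparams].
#' @param weights Pinned K-vector of weights, or `NULL` in free mode.
#' @param mode `"free"` or `"pinned"`.
#' @return Finite scalar ELBO.
#' @export
compute_elbo <- function(lengths, r, posterior, hyper, weights = NULL,
                         mode = c("free", "pinned")) {
  mode <- match.arg(mode)
  val <- .vb_elbo(as.numeric(lengths), rep(1, length(lengths)), r, posterior,
                  hyper, mode, weights)
  if (!is.finite(val)) stop("non-finite ELBO")
  val
}

#' Fit the variational Gaussian mixture
#'
#' Coordinate ascent alternating the responsibility update and the
#' conjugate posterior update until the relative ELBO change drops below
#' `tol` or `max_iter` is reached. Initialization is k-means (hard
#' responsibilities) unless a warm-start posterior is supplied.
#'
#' @param lengths Numeric vector of per-read lengths (N >= K).
#' @param K Number of components.
#' @param weights_mode `"free"` (Dirichlet posterior over weights) or
#'   `"pinned"` (weights fixed at `pinned_weights`).
#' @param pinned_weights K-vector summing to 1, required in pinned mode.
#' @param hyper A [vb_hyperparams]; defaults to data-driven values.
#' @param seed Integer seed for initialization.
#' @param max_iter,tol Stopping rule: stop when
#'   `|ELBO_j+1 - ELBO_j| <= tol * |ELBO_j|`.
#' @param init Optional posterior list used as a warm start (the first
#'   E-step is run from it instead of k-means).
#' @return Object of class `vb_state`: responsibilities `r` (N x K),
#'   posterior parameters, `weights`, `mu`, `sigma`, `Nk`, `elbo`,
#'   `elbo_trace`, `converged`.
#' @export
fit_vb <- function(lengths, K, weights_mode = c("free", "pinned"),
                   pinned_weights = NULL, hyper = NULL, seed = 1L,
                   max_iter = 500L, tol = 1e-4, init = NULL) {
  weights_mode <- match.arg(weights_mode)
  lengths <- as.numeric(lengths)
  stopifnot(length(lengths) >= 1)
  cl <- .collapse(lengths)
  if (K > length(cl$x)) {
    message("K=", K, " exceeds ", length(cl$x), " distinct lengths; reducing")
    K <- length(cl$x)
    if (weights_mode == "pinned" && length(pinned_weights) > K) {
      pinned_weights <- pinned_weights[seq_len(K)] / sum(pinned_weights[seq_len(K)])
    }
  }
  stopifnot(length(lengths) >= K)
  if (is.null(hyper)) hyper <- vb_hyperparams(lengths)
  if (weights_mode == "pinned") {
    if (is.null(pinned_weights) || length(pinned_weights) != K) {
      stop("pinned mode requires weights of length K")
    }
    if (abs(sum(pinned_weights) - 1) > 1e-6 || any(pinned_weights < 0)) {
      stop("pinned weights must be a probability vector of length K")
    }
  }
  x <- cl$x; wts <- cl$w
  if (is.null(init)) {
    r1 <- init_responsibilities(lengths, K, seed)
    # collapse one-hot init onto unique values (identical lengths share labels)
    r <- r1[match(x, lengths), , drop = FALSE]
    K <- ncol(r)
    if (weights_mode == "pinned" && length(pinned_weights) != K) {
      pinned_weights <- pinned_weights[seq_len(K)] / sum(pinned_weights[seq_len(K)])
    }
  } else {
    lw <- if (weights_mode == "pinned") log(pinned_weights)
          else .log_weights(init, NULL, "free")
    r <- .vb_estep(x, init, lw)
  }
  elbo_trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    post <- .vb_mstep(x, wts, r, hyper)
    lw <- if (weights_mode == "pinned") log(pinned_weights)
          else .log_weights(post, NULL, "free")
    r <- .vb_estep(x, post, lw)
    post <- .vb_mstep(x, wts, r, hyper)  # keep sufficient stats in sync with r
    elbo <- .vb_elbo(x, wts, r, post, hyper, weights_mode, pinned_weights)
    elbo_trace <- c(elbo_trace, elbo)
    if (it > 1) {
      d <- elbo - elbo_trace[it - 1]
      if (abs(d) <= tol * abs(elbo_trace[it - 1])) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) warning("VB did not converge in ", max_iter, " iterations")
  weights <- if (weights_mode == "pinned") pinned_weights
             else post$alpha / sum(post$alpha)
  r_full <- r[match(lengths, x), , drop = FALSE]
  structure(
    list(K = K, r = r_full, r_unique = r, x = x, x_weights = wts,
         Nk = post$Nk, xbar = post$xbar, Sk = post$Sk,
         m = post$m, beta = post$beta, w = post$w, v = post$v,
         alpha = post$alpha, weights = weights,
         mu = post$mu, sigma = post$sigma,
         elbo = elbo_trace[length(elbo_trace)], elbo_trace = elbo_trace,
         converged = converged, hyper = hyper, mode = weights_mode),
    class = "vb_state"
  )
}

#' @export
print.vb_state <- function(x, ...) {
  cat("<vb_state> K=", x$K, " mode=", x$mode,
      " elbo=", format(x$elbo, digits = 8),
      " iters=", length(x$elbo_trace),
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  for (k in seq_len(x$K)) {
    cat(sprintf("  k=%d mu=%.3f sigma=%.3f weight=%.3f Nk=%.1f\n",
                k, x$mu[k], x$sigma[k], x$weights[k], x$Nk[k]))
  }
  invisible(x)
}
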