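#' Normal-sample baseline for one locus
#'
#' The matched normal's spectrum summarized by its weighted mean and
#' (population) standard deviation; the per-clone test compares each fitted
#' tumor component against this baseline histogram.
#'
#' @param spectrum Normal-sample [length_spectrum].
#' @return Object of class `normal_baseline` with `locus_id`, `mu`,
#'   `sigma`, `n` and the underlying `spectrum`.
#' @export
normal_baseline <- function(spectrum) {
  stopifnot(inherits(spectrum, "length_spectrum"))
  st <- spectrum_stats(spectrum)
  structure(list(locus_id = spectrum$locus_id, mu = st$mu, sigma = st$sigma,
                 n = st$n, spectrum = spectrum),
            class = "normal_baseline")
}

# partition bins into pooled groups so every group's expected count is
# >= min_exp: smallest bins merge into their smaller adjacent neighbor
.pool_partition <- function(expd, min_exp = 1) {
  grp <- seq_along(expd)
  agg <- expd
  repeat {
    ids <- unique(grp)
    if (length(ids) <= 1) break
    tot <- vapply(ids, function(i) sum(expd[grp == i]), 0)
    if (min(tot) >= min_exp) break
    o <- which.min(tot)
    pos <- which(grp == ids[o])
    left <- if (o > 1) tot[o - 1] else Inf
    right <- if (o < length(ids)) tot[o + 1] else Inf
    target <- if (left <= right) ids[o - 1] else ids[o + 1]
    grp[pos] <- target
  }
  match(grp, unique(grp))
}

# Gaussian bin masses over a support grid with open tails, vectorized over
# (mu, sigma) pairs: returns length(support) x length(mu) matrix
.gauss_bin_mass <- function(support, mu, sigma) {
  lo <- support[1]; hi <- support[length(support)]
  edges <- c(support[-length(support)] + 0.5)
  upper <- stats::pnorm(outer(edges, mu, "-") / rep(sigma, each = length(edges)))
  rbind(upper, 1)[seq_along(support), , drop = FALSE] -
    rbind(0, upper)[seq_along(support), , drop = FALSE]
}

#' Per-clone MSI/MSS test against the matched normal
#'
#' Default test (`"chisq"`): a Pearson-type chi-square statistic comparing
#' the clone's expected unit-bin counts (Gaussian(mu, sigma) bin mass times
#' `n_eff`, Sheppard-corrected, with open tails) against the normal
#' spectrum's proportions scaled to `n_eff`, over the union support of both
#' distributions with low-expectation bins pooled. Because both sides are
#' estimated from finite reads (the normal histogram is itself multinomial
#' noise and the clone parameters are fitted), the chi-square reference
#' distribution is badly miscalibrated; the p-value is therefore obtained
#' by a parametric bootstrap under the pooled null: both sides are redrawn
#' from the combined distribution, the clone Gaussian is refitted by
#' moments on each redraw, and the statistic is recomputed. The
#' alternative (`"ztest"`) is a two-sided z-test on the difference of
#' means.
#'
#' @param mu,sigma Fitted clone component parameters (sigma on the
#'   integer-binned scale, as fitted).
#' @param n_eff Effective read count attributed to the component
#'   (component weight times total tumor reads).
#' @param baseline A [normal_baseline].
#' @param alpha Significance level (default 0.05); status is MSI iff
#'   `p < alpha`.
#' @param test `"chisq"` (default) or `"ztest"`.
#' @param nboot Bootstrap replicates for the null distribution (default
#'   400).
#' @param seed Integer seed for the bootstrap (the global RNG state is
#'   restored afterwards).
#' @return List with `status` (`"MSI"`, `"MSS"` or `"untestable"`),
#'   `statistic` and `p_value`.
#' @export
test_clone_status <- function(mu, sigma, n_eff, baseline, alpha = 0.05,
                              test = c("chisq", "ztest"), nboot = 400L,
                              seed = 1L) {
  test <- match.arg(test)
  if (n_eff < 5 || baseline$n < 5) {
    return(list(status = "untestable", statistic = NA_real_, p_value = NA_real_))
  }
  bsp <- baseline$spectrum
  if (sigma < 1e-8) {
    # zero-variance clone: compare against the baseline mode directly
    mode_len <- bsp$lengths[which.max(bsp$counts)]
    same <- abs(mu - mode_len) < 0.5
    p <- if (same) 1 else 0
    status <- if (p < alpha) "MSI" else "MSS"
    return(list(status = status, statistic = if (same) 0 else Inf, p_value = p))
  }
  if (test == "ztest") {
    se <- sqrt(baseline$sigma^2 / baseline$n + sigma^2 / n_eff)
    z <- (mu - baseline$mu) / max(se, 1e-12)
    p <- 2 * stats::pnorm(-abs(z))
    return(list(status = if (p < alpha) "MSI" else "MSS",
                statistic = z, p_value = p))
  }
  n <- round(n_eff)
  m <- bsp$n
  lo <- min(min(bsp$lengths), floor(mu - 5 * sigma))
  hi <- max(max(bsp$lengths), ceiling(mu + 5 * sigma))
  support <- seq(lo, hi)
  sg <- .debin_sigma(sigma)  # fitted sigma carries the integer-rounding variance
  pr <- as.numeric(.gauss_bin_mass(support, mu, sg))
  bcnt <- numeric(length(support))
  bcnt[match(bsp$lengths, support)] <- bsp$counts
  # parametric pooled null: under H0 clone and baseline share one Gaussian,
  # so the null distribution is the Gaussian moment-fitted to the pooled
  # reads (a smooth null keeps the bootstrap statistic comparable to the
  # observed one)
  pooled_cnt <- bcnt + n * pr
  mu0 <- sum(support * pooled_cnt) / sum(pooled_cnt)
  sd0 <- sqrt(sum(pooled_cnt * (support - mu0)^2) / sum(pooled_cnt))
  p0 <- as.numeric(.gauss_bin_mass(support, mu0, .debin_sigma(sd0)))
  grp <- .pool_partition(n * p0, min_exp = 1)
  if (max(grp) < 2) {
    return(list(status = "untestable", statistic = NA_real_, p_value = NA_real_))
  }
  pool <- function(v) rowsum(v, grp)
  p0_pool <- as.numeric(pool(p0))
  stat_of <- function(phi_pool, pb_pool) {
    colSums((n * phi_pool - n * pb_pool)^2 / (n * p0_pool))
  }
  stat <- stat_of(pool(pr), pool(bcnt / m))[1]
  # parametric bootstrap under H0: redraw both sides from p0, refit the
  # clone Gaussian by moments on each clone redraw
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed((seed + 15485863L) %% .Machine$integer.max)
  Cb <- stats::rmultinom(nboot, m, p0)
  Ct <- stats::rmultinom(nboot, n, p0)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  mean_t <- colSums(support * Ct) / n
  var_t <- colSums(support^2 * Ct) / n - mean_t^2
  sg_t <- .debin_sigma(sqrt(pmax(var_t, 1e-8)))
  phi_star <- .gauss_bin_mass(support, mean_t, sg_t)
  stat_star <- stat_of(pool(phi_star), pool(Cb / m))
  p <- (1 + sum(stat_star >= stat)) / (nboot + 1)
  list(status = if (p < alpha) "MSI" else "MSS", statistic = stat, p_value = p)
}

#' Call per-clone status at one locus
#'
#' Each clone inherits the parameters of its assigned component; clones
#' sharing a component share one test (the component is a single
#' distribution with `n_eff = Y_k * N`). The locus verdict is MSI iff any
#' testable clone is MSI; if every clone is untestable the verdict is NA.
#'
#' @param dec A `locus_deconvolution` (or a skip record, which yields an
#'   NA verdict).
#' @param baseline A [normal_baseline] for the same locus.
#' @param structure A [clonal_structure].
#' @param alpha Significance level.
#' @param test Test form passed to [test_clone_status()].
#' @return Object of class `locus_call`: `locus_id`, `verdict` (`"MSI"`,
#'   `"MSS"` or `NA`), and `clone_calls`, a data frame with one row per
#'   clone (clone, component, mu, sigma, pi, normal_mu, normal_sigma,
#'   status, statistic, p_value).
#' @export
call_locus <- function(dec, baseline, structure, alpha = 0.05,
                       test = c("chisq", "ztest")) {
  test <- match.arg(test)
  if (!inherits(dec, "locus_deconvolution")) {
    return(structure(list(locus_id = dec$locus_id, verdict = NA_character_,
                          clone_calls = NULL,
                          reason = dec$reason %||% "not deconvolved"),
                     class = "locus_call"))
  }
  G <- structure$G
  comp_tests <- vector("list", dec$K)
  for (k in seq_len(dec$K)) {
    if (dec$pi[k] > 0) {
      comp_tests[[k]] <- test_clone_status(dec$mu[k], dec$sigma[k],
                                           dec$pi[k] * dec$n, baseline,
                                           alpha, test)
    }
  }
  rows <- lapply(seq_len(G), function(g) {
    k <- which(dec$A[g, ] == 1)
    tt <- comp_tests[[k]]
    data.frame(locus_id = dec$locus_id, clone = g, component = k,
               mu = dec$mu[k], sigma = dec$sigma[k], pi = dec$pi[k],
               normal_mu = baseline$mu, normal_sigma = baseline$sigma,
               status = tt$status, statistic = tt$statistic,
               p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  testable <- calls$status %in% c("MSI", "MSS")
  verdict <- if (!any(testable)) NA_character_
             else if (any(calls$status[testable] == "MSI")) "MSI" else "MSS"
  structure(list(locus_id = dec$locus_id, verdict = verdict,
                 clone_calls = calls),
            class = "locus_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate locus calls into a sample verdict
#'
#' The sample score is the fraction of evaluated (non-NA) loci with at
#' least one MSI clone. The verdict is `MSS` when the score is below
#' `threshold`; otherwise `MSI` when every testable clone call at every MSI
#' locus is MSI (fully clonal instability), and `partial-MSI` when MSS
#' clone calls coexist with instability.
#'
#' @param locus_calls List of `locus_call` objects.
#' @param threshold Minimum MSI-locus fraction for an unstable sample
#'   verdict (default 0.2).
#' @return Object of class `sample_report`: `locus_calls`, `sample_score`,
#'   `sample_status`, `n_loci`, `n_msi_loci`.
#' @export
call_sample <- function(locus_calls, threshold = 0.2) {
  verdicts <- vapply(locus_calls, `[[`, "", "verdict")
  usable <- !is.na(verdicts)
  if (!any(usable)) {
    return(structure(list(locus_calls = locus_calls, sample_score = NA_real_,
                          sample_status = NA_character_,
                          n_loci = 0L, n_msi_loci = 0L),
                     class = "sample_report"))
  }
  n_msi <- sum(verdicts[usable] == "MSI")
  score <- n_msi / sum(usable)
  if (score < threshold) {
    status <- "MSS"
  } else {
    msi_loci <- locus_calls[usable][verdicts[usable] == "MSI"]
    all_clonal <- all(vapply(msi_loci, function(lc) {
      st <- lc$clone_calls$status
      all(st[st %in% c("MSI", "MSS")] == "MSI")
    }, TRUE))
    status <- if (all_clonal) "MSI" else "partial-MSI"
  }
  structure(list(locus_calls = locus_calls, sample_score = score,
                 sample_status = status, n_loci = sum(usable),
                 n_msi_loci = n_msi),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat("<sample_report> ", x$n_msi_loci, "/", x$n_loci,
      " MSI loci (score=", format(x$sample_score, digits = 3),
      ") status=", x$sample_status, "\n", sep = "")
  invisible(x)
}
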