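#' Deconvolution configuration
#'
#' @param max_outer_iters Maximum alternations between the variational fit
#'   and the assignment solve per candidate K (default 20).
#' @param elbo_tol Relative ELBO change below which the inner variational
#'   loop stops (default 1e-4).
#' @param max_vb_iters Iteration cap of one variational fit (default 500).
#' @param K_strategy `"select_by_objective"` (sweep K = 1..G and keep the
#'   K with the lowest assignment objective, ties to smaller K) or
#'   `"fixed"` (use `K_fixed`).
#' @param K_fixed Component count when `K_strategy = "fixed"`.
#' @param seed Integer seed driving all initialization.
#' @param min_component_weight Assigned components with weight below this
#'   are treated as degenerate and the candidate K is disfavored
#'   (default 0.01).
#' @param min_reads Loci with fewer reads than this in either sample are
#'   skipped (default 20).
#' @param assignment_starts Number of distinct-weight assignment starts for
#'   the outer alternation (default 3; guards against local optima).
#' @param gof_boot Parametric-bootstrap replicates for the
#'   fit-adequacy test that stops the K sweep (default 200).
#' @param gof_level Level of that adequacy test: a candidate K is adequate
#'   when its objective is below the `1 - gof_level` bootstrap quantile of
#'   the objective under its own fitted mixture (default 0.05).
#' @param solver Assignment backend, `"exhaustive"` or `"milp"`.
#' @return Object of class `deconvolve_config`.
#' @export
deconvolve_config <- function(max_outer_iters = 20L, elbo_tol = 1e-4,
                              max_vb_iters = 500L,
                              K_strategy = c("select_by_objective", "fixed"),
                              K_fixed = NULL, seed = 1L,
                              min_component_weight = 0.01, min_reads = 20L,
                              assignment_starts = 3L,
                              gof_boot = 200L, gof_level = 0.05,
                              solver = c("exhaustive", "milp")) {
  K_strategy <- match.arg(K_strategy)
  solver <- match.arg(solver)
  stopifnot(max_outer_iters >= 1, elbo_tol > 0, gof_boot >= 20,
            gof_level > 0, gof_level < 1)
  structure(list(max_outer_iters = max_outer_iters, elbo_tol = elbo_tol,
                 max_vb_iters = max_vb_iters, K_strategy = K_strategy,
                 K_fixed = K_fixed, seed = as.integer(seed),
                 min_component_weight = min_component_weight,
                 min_reads = min_reads,
                 assignment_starts = as.integer(assignment_starts),
                 gof_boot = as.integer(gof_boot),
                 gof_level = gof_level, solver = solver),
            class = "deconvolve_config")
}

# alternate pinned VB refits with A re-solves from one assignment start;
# A-updates that worsen the objective are rejected (guarantees a monotone
# objective trace and termination)
.alternate_from <- function(lengths, tumor, B, K, fit, start, config,
                            fix_A = FALSE) {
  A <- start$A; Y <- start$Y
  obj_trace <- start$objective
  elbo_trace <- fit$elbo_trace
  converged <- fit$converged
  if (K > 1) {
    for (it in seq_len(config$max_outer_iters)) {
      fit2 <- suppressWarnings(
        fit_vb(lengths, K, "pinned", pinned_weights = Y, hyper = fit$hyper,
               seed = config$seed, max_iter = config$max_vb_iters,
               tol = config$elbo_tol, init = fit)
      )
      prob2 <- assignment_problem(B, fit2$mu, fit2$sigma, tumor)
      if (fix_A) {
        # hypothesis mode: hold this clone-to-component assignment and
        # just refit the components under its weights
        fit <- fit2
        elbo_trace <- c(elbo_trace, fit2$elbo_trace)
        converged <- fit2$converged
        obj_trace <- c(obj_trace, objective_value(A, prob2))
        break
      }
      sol2 <- solve_assignment(prob2, config$solver)
      if (sol2$objective > obj_trace[length(obj_trace)] + 1e-9) {
        break  # reject an A-update that worsens the fit; keep previous state
      }
      fit <- fit2
      elbo_trace <- c(elbo_trace, fit2$elbo_trace)
      converged <- fit2$converged
      stable <- identical(sol2$A, A)
      A <- sol2$A; Y <- sol2$Y
      obj_trace <- c(obj_trace, sol2$objective)
      if (stable) break
    }
  }
  list(fit = fit, A = A, Y = Y, obj_trace = obj_trace,
       objective = obj_trace[length(obj_trace)],
       elbo_trace = elbo_trace, converged = converged)
}

# one candidate K: free VB fit, then the VB/assignment alternation started
# from the best few distinct-weight assignments (multi-start guards the
# alternation against local optima where a light minor component is
# cheaper to drop than to carry at its clone fraction)
.deconvolve_K <- function(lengths, tumor, B, K, config) {
  fit <- fit_vb(lengths, K, "free", hyper = NULL, seed = config$seed,
                max_iter = config$max_vb_iters, tol = config$elbo_tol)
  K <- fit$K  # may have been reduced to the distinct-length count
  prob <- assignment_problem(B, fit$mu, fit$sigma, tumor)
  starts <- if (config$solver == "exhaustive") {
    .assignment_candidates(prob, config$assignment_starts)
  } else {
    list(solve_assignment(prob, config$solver))
  }
  # each start is a clone-structure hypothesis, evaluated by refitting the
  # components under its weights with the assignment held fixed; the
  # leading start additionally runs the free alternation with re-solved
  # assignments. Adequate (statistically consistent) states are preferred
  # over ones with a marginally lower squared error that fail to account
  # for part of the spectrum.
  runs <- list()
  for (i in seq_along(starts)) {
    runs[[length(runs) + 1L]] <-
      .alternate_from(lengths, tumor, B, K, fit, starts[[i]], config,
                      fix_A = i > 1L)
  }
  best <- NULL
  for (res in runs) {
    gof <- .fit_adequacy(tumor, res$fit$mu, res$fit$sigma, res$Y,
                         nboot = config$gof_boot, level = config$gof_level,
                         seed = config$seed)
    res$gof_stat <- gof$stat
    res$gof_threshold <- gof$threshold
    res$adequate <- gof$adequate
    if (is.null(best) ||
        (res$adequate && !best$adequate) ||
        (res$adequate == best$adequate &&
         res$objective < best$objective - 1e-9)) {
      best <- res
    }
  }
  Y <- best$Y
  degenerate <- any(Y > 0 & Y < config$min_component_weight)
  list(K = K, fit = best$fit, A = best$A, Y = Y,
       objective = best$objective, obj_trace = best$obj_trace,
       gof_stat = best$gof_stat, gof_threshold = best$gof_threshold,
       adequate = best$adequate,
       elbo_trace = best$elbo_trace, converged = best$converged,
       degenerate = degenerate)
}

# parametric-bootstrap goodness of fit of a mixture to a spectrum: Pearson
# statistic over pooled unit bins (tail-sensitive, unlike the assignment
# SSE), with its null distribution obtained by redrawing spectra from the
# fitted mixture. Bootstrap replicates are not refitted, which makes the
# escalation decision slightly conservative.
.fit_adequacy <- function(tumor, mu, sigma, Y, nboot = 200L,
                          level = 0.05, seed = 1L) {
  sigma_c <- .debin_sigma(sigma)
  live <- Y > 0
  lo <- max(0, min(tumor$lengths[1], floor(min(mu[live] - 6 * sigma_c[live]))))
  hi <- max(tumor$lengths[length(tumor$lengths)],
            ceiling(max(mu[live] + 6 * sigma_c[live])))
  support <- seq(lo, hi)
  q <- numeric(length(support))
  for (k in which(live)) q <- q + Y[k] * bin_prob(support, mu[k], sigma_c[k])
  q <- q / sum(q)
  n <- tumor$n
  cnt <- numeric(length(support))
  cnt[match(tumor$lengths, support)] <- tumor$counts
  grp <- .pool_partition(n * q, min_exp = 1)
  pool <- function(v) rowsum(v, grp)
  q_pool <- as.numeric(pool(q))
  stat <- sum((as.numeric(pool(cnt)) - n * q_pool)^2 / (n * q_pool))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed((seed + 104729L) %% .Machine$integer.max)
  boot <- stats::rmultinom(nboot, n, q)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  stat_star <- colSums((pool(boot) - n * q_pool)^2 / (n * q_pool))
  threshold <- stats::quantile(stat_star, probs = 1 - level, names = FALSE,
                               type = 8)
  list(stat = stat, threshold = threshold, adequate = stat <= threshold)
}

#' Deconvolve one locus into per-clone components
#'
#' Runs, for each candidate number of components K in 1..G, a free
#' variational fit initialized by k-means, an exact assignment of clones to
#' components, and then alternates pinned-weight refits with re-solved
#' assignments until the assignment stabilizes. The sweep stops at the
#' smallest K whose converged objective passes a parametric-bootstrap
#' goodness-of-fit test against its own fitted mixture (i.e. the residual
#' is explainable by multinomial sampling noise); if no candidate is
#' adequate, the lowest objective wins with ties (within 1e-9) toward
#' smaller K. Candidates carrying a spuriously small component weight are
#' disfavored.
#'
#' @param tumor Tumor [length_spectrum].
#' @param structure A [clonal_structure].
#' @param config A [deconvolve_config].
#' @return Object of class `locus_deconvolution`: `locus_id`, `K`, `mu`,
#'   `sigma`, posterior hyperparameters (`m`, `beta`, `w`, `v`), binary
#'   assignment `A` (G x K), mixing weights `pi` (= Y), `objective`,
#'   `obj_trace`, `elbo_trace`, `converged`, `n`.
#' @export
deconvolve_locus <- function(tumor, structure, config = deconvolve_config()) {
  stopifnot(inherits(tumor, "length_spectrum"),
            inherits(structure, "clonal_structure"))
  if (tumor$n < 1) stop("empty spectrum for locus ", tumor$locus_id)
  G <- structure$G
  lengths <- expand_reads(tumor)
  K_max <- min(G, length(unique(lengths)))
  Ks <- if (config$K_strategy == "fixed") {
    min(config$K_fixed, K_max)
  } else {
    seq_len(K_max)
  }
  # sweep K ascending and stop at the first parsimonious adequate fit: a
  # candidate that passes the bootstrap goodness-of-fit test already
  # explains the spectrum, so larger K would only fit sampling noise
  cands <- list()
  best <- NULL
  for (K in Ks) {
    cand <- .deconvolve_K(lengths, tumor, structure$B, K, config)
    cands[[length(cands) + 1L]] <- cand
    if (cand$adequate && !cand$degenerate) {
      best <- cand
      break
    }
  }
  if (is.null(best)) {
    # no adequate fit: lowest objective wins, ties (1e-9) toward smaller K,
    # candidates with spuriously small component weights disfavored
    pool <- cands[!vapply(cands, `[[`, TRUE, "degenerate")]
    if (length(pool) == 0) pool <- cands
    best <- pool[[1]]
    for (cand in pool[-1]) {
      if (cand$objective < best$objective - 1e-9) best <- cand
    }
  }
  fit <- best$fit
  structure(
    list(locus_id = tumor$locus_id, K = best$K, G = G,
         mu = fit$mu, sigma = fit$sigma,
         m = fit$m, beta = fit$beta, w = fit$w, v = fit$v,
         A = best$A, pi = best$Y, Nk = fit$Nk,
         objective = best$objective, obj_trace = best$obj_trace,
         gof_stat = best$gof_stat, gof_threshold = best$gof_threshold,
         adequate = best$adequate,
         elbo_trace = best$elbo_trace, converged = best$converged,
         n = tumor$n),
    class = "locus_deconvolution"
  )
}

#' @export
print.locus_deconvolution <- function(x, ...) {
  cat("<locus_deconvolution> ", x$locus_id, " K=", x$K,
      " objective=", format(x$objective, digits = 4),
      if (x$converged) "" else " (NOT converged)", "\n", sep = "")
  for (k in seq_len(x$K)) {
    cat(sprintf("  k=%d mu=%.2f sigma=%.2f pi=%.3f clones={%s}\n",
                k, x$mu[k], x$sigma[k], x$pi[k],
                paste(which(x$A[, k] == 1), collapse = ",")))
  }
  invisible(x)
}

#' Deconvolve a batch of loci
#'
#' Loci are independent; results are identical for any worker count. Each
#' locus gets a seed derived deterministically from the configured seed and
#' its position, so serial and parallel execution agree. Loci with fewer
#' than `config$min_reads` reads are skipped with a skip record, and a
#' failure in one locus does not abort the batch.
#'
#' @param tumor_spectra Named list of tumor [length_spectrum].
#' @param structure A [clonal_structure].
#' @param config A [deconvolve_config].
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return List parallel to `tumor_spectra`; each element is either a
#'   `locus_deconvolution` or a skip/error record (a list with `locus_id`,
#'   `skipped = TRUE` and a `reason`).
#' @export
deconvolve_sample <- function(tumor_spectra, structure,
                              config = deconvolve_config(), workers = 1L) {
  stopifnot(length(tumor_spectra) >= 1)
  run_one <- function(i) {
    sp <- tumor_spectra[[i]]
    if (sp$n < config$min_reads) {
      return(list(locus_id = sp$locus_id, skipped = TRUE,
                  reason = paste0("insufficient coverage (", sp$n, " reads)")))
    }
    cfg <- config
    cfg$seed <- (config$seed + i * 7919L) %% .Machine$integer.max
    tryCatch(deconvolve_locus(sp, structure, cfg),
             error = function(e) list(locus_id = sp$locus_id, skipped = TRUE,
                                      reason = conditionMessage(e)))
  }
  idx <- seq_along(tumor_spectra)
  out <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, run_one, mc.cores = workers)
  } else {
    lapply(idx, run_one)
  }
  names(out) <- vapply(tumor_spectra, `[[`, "", "locus_id")
  out
}
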