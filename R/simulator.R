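#' Default clone fractions for a given clone count
#'
#' Used by the simulator when no fraction vector is supplied: a primary
#' clone plus progressively smaller minors, fixed once so that experiment
#' grids are comparable across runs.
#'
#' @param G Number of clones (1..5 have stated defaults; larger G falls
#'   back to a geometric-ish decay normalized to 1).
#' @return Numeric fraction vector of length G, descending, summing to 1.
#' @export
default_clone_fractions <- function(G) {
  presets <- list(`1` = 1, `2` = c(0.7, 0.3), `3` = c(0.5, 0.3, 0.2),
                  `4` = c(0.4, 0.3, 0.2, 0.1),
                  `5` = c(0.3, 0.25, 0.2, 0.15, 0.1))
  key <- as.character(G)
  if (!is.null(presets[[key]])) return(presets[[key]])
  B <- 0.5^seq_len(G)
  sort(B / sum(B), decreasing = TRUE)
}

#' Simulation configuration
#'
#' Describes one synthetic tumor-normal experiment: a panel of
#' microsatellite loci, a clonal structure, and the generating parameter
#' ranges. Defaults mirror a mono-repeat MSI panel: 60 loci (half MSI),
#' normal means 12-25 repeat units, per-component standard deviations
#' 0.5-2.5 units and MSI mean shifts of 3-8 units in either direction.
#'
#' @param n_loci Number of loci (default 60).
#' @param frac_msi Fraction of MSI loci (default 0.5; exactly
#'   `round(n_loci * frac_msi)` loci are made unstable).
#' @param G Number of clones (default 2).
#' @param B Clone fractions; `default_clone_fractions(G)` when NULL.
#' @param depth Reads per locus per sample (default 200).
#' @param read_len Read length in bp, context only (default 200).
#' @param mu_range Range of normal (germline) mean lengths, repeat units.
#' @param sigma_range Range of per-component standard deviations.
#' @param delta_mu_range Range of the absolute MSI mean shift.
#' @param overlap_level Optional factor in (0, 1] multiplying
#'   `delta_mu_range` to push components together (overlap experiments).
#' @param deletion_bias Probability that an MSI shift is a deletion
#'   (default 0.5, i.e. symmetric).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 60L, frac_msi = 0.5, G = 2L, B = NULL,
                       depth = 200L, read_len = 200L,
                       mu_range = c(12, 25), sigma_range = c(0.5, 2.5),
                       delta_mu_range = c(3, 8), overlap_level = NULL,
                       deletion_bias = 0.5, seed = 1L) {
  if (is.null(B)) B <- default_clone_fractions(G)
  B <- clonal_structure(B)$B
  stopifnot(length(B) == G, frac_msi >= 0, frac_msi <= 1, depth >= 1,
            delta_mu_range[1] > 0)
  if (!is.null(overlap_level)) {
    stopifnot(overlap_level > 0, overlap_level <= 1)
    delta_mu_range <- delta_mu_range * overlap_level
  }
  structure(list(n_loci = as.integer(n_loci), frac_msi = frac_msi,
                 G = as.integer(G), B = B, depth = as.integer(depth),
                 read_len = as.integer(read_len), mu_range = mu_range,
                 sigma_range = sigma_range, delta_mu_range = delta_mu_range,
                 deletion_bias = deletion_bias, seed = as.integer(seed)),
            class = "sim_config")
}

# ground truth table: one row per locus, per-clone parameter columns
.simulate_truth <- function(config) {
  n <- config$n_loci; G <- config$G
  n_msi <- round(n * config$frac_msi)
  msi_loci <- sort(sample.int(n, n_msi))
  mu_N <- stats::runif(n, config$mu_range[1], config$mu_range[2])
  sigma_N <- stats::runif(n, config$sigma_range[1], config$sigma_range[2])
  mu_g <- matrix(rep(mu_N, G), ncol = G)
  sigma_g <- matrix(rep(sigma_N, G), ncol = G)
  msi_g <- matrix(FALSE, nrow = n, ncol = G)
  for (i in msi_loci) {
    repeat {                       # uniformly chosen nonempty clone subset
      sel <- stats::runif(G) < 0.5
      if (any(sel)) break
    }
    for (g in which(sel)) {
      delta <- stats::runif(1, config$delta_mu_range[1], config$delta_mu_range[2])
      sign <- if (stats::runif(1) < config$deletion_bias) -1 else 1
      mu_g[i, g] <- max(1.5, mu_N[i] + sign * delta)
      sigma_g[i, g] <- stats::runif(1, config$sigma_range[1], config$sigma_range[2])
      msi_g[i, g] <- TRUE
    }
  }
  truth <- data.frame(locus_id = sprintf("sim%03d", seq_len(n)),
                      mu_N = mu_N, sigma_N = sigma_N,
                      locus_msi = seq_len(n) %in% msi_loci)
  for (g in seq_len(G)) {
    truth[[paste0("mu_", g)]] <- mu_g[, g]
    truth[[paste0("sigma_", g)]] <- sigma_g[, g]
    truth[[paste0("msi_", g)]] <- msi_g[, g]
  }
  truth
}

# multinomial draw from an integer-binned Gaussian mixture, lengths >= 1
.draw_spectrum <- function(locus_id, mus, sigmas, weights, depth) {
  lo <- max(1, floor(min(mus - 6 * sigmas)))
  hi <- ceiling(max(mus + 6 * sigmas))
  support <- seq(lo, hi)
  p <- numeric(length(support))
  for (j in seq_along(mus)) {
    pj <- bin_prob(support, mus[j], sigmas[j])
    pj[1] <- pj[1] + stats::pnorm(lo - 0.5, mus[j], sigmas[j])  # truncate at 1
    pj[length(pj)] <- pj[length(pj)] + 1 - stats::pnorm(hi + 0.5, mus[j], sigmas[j])
    p <- p + weights[j] * pj
  }
  p <- p / sum(p)
  counts <- as.numeric(stats::rmultinom(1, depth, p))
  length_spectrum(locus_id, support, counts)
}

#' Simulate the paired spectra of one locus
#'
#' The tumor spectrum is a multinomial draw of `depth` reads from the
#' clone-fraction-weighted mixture of the per-clone integer-binned
#' Gaussians; the normal spectrum is a draw from the germline Gaussian.
#' Lengths are truncated at 1 repeat unit.
#'
#' @param truth_row One row of the truth table from [simulate_dataset()].
#' @param B Clone fraction vector.
#' @param depth Reads per sample.
#' @param seed Optional integer seed.
#' @return List with `tumor` and `normal` [length_spectrum].
#' @export
simulate_locus <- function(truth_row, B, depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- length(B)
  mus <- as.numeric(truth_row[paste0("mu_", seq_len(G))])
  sigmas <- as.numeric(truth_row[paste0("sigma_", seq_len(G))])
  tumor <- .draw_spectrum(truth_row$locus_id, mus, sigmas, B, depth)
  normal <- .draw_spectrum(truth_row$locus_id, truth_row$mu_N,
                           truth_row$sigma_N, 1, depth)
  list(tumor = tumor, normal = normal)
}

#' Simulate a full tumor-normal dataset with per-clone truth
#'
#' @param config A [sim_config].
#' @return List with `tumor` and `normal` (named lists of
#'   [length_spectrum]), `truth` (data frame with per-locus, per-clone
#'   generating parameters and MSI flags) and the `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  truth <- .simulate_truth(config)
  tumor <- vector("list", config$n_loci)
  normal <- vector("list", config$n_loci)
  for (i in seq_len(config$n_loci)) {
    pair <- simulate_locus(truth[i, ], config$B, config$depth)
    tumor[[i]] <- pair$tumor
    normal[[i]] <- pair$normal
  }
  names(tumor) <- truth$locus_id
  names(normal) <- truth$locus_id
  list(tumor = tumor, normal = normal, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits `tumor.tsv` and `normal.tsv` in the native spectrum dialect,
#' `truth.tsv`, and `clones.json`.
#'
#' @param ds Dataset from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectrum_table(as_records(ds$tumor, "tumor"), file.path(dir, "tumor.tsv"))
  write_spectrum_table(as_records(ds$normal, "normal"), file.path(dir, "normal.tsv"))
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(clones = ds$config$B), file.path(dir, "clones.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Run the full deconvolve-and-call pipeline on paired spectra
#'
#' @param tumor,normal Named lists of [length_spectrum] (same loci).
#' @param structure A [clonal_structure].
#' @param config A [deconvolve_config].
#' @param alpha Per-clone significance level.
#' @param test Test form (`"chisq"` or `"ztest"`).
#' @param workers Parallel workers for the deconvolution.
#' @param sample_threshold MSI-locus fraction for the sample verdict.
#' @return List with `report` (a `sample_report`), `decs` (per-locus
#'   deconvolutions) and `verdicts` (named character vector per locus).
#' @export
run_pipeline <- function(tumor, normal, structure,
                         config = deconvolve_config(), alpha = 0.05,
                         test = "chisq", workers = 1L,
                         sample_threshold = 0.2) {
  decs <- deconvolve_sample(tumor, structure, config, workers)
  calls <- lapply(names(decs), function(id) {
    call_locus(decs[[id]], normal_baseline(normal[[id]]), structure,
               alpha, test)
  })
  names(calls) <- names(decs)
  report <- call_sample(calls, sample_threshold)
  verdicts <- vapply(calls, `[[`, "", "verdict")
  list(report = report, decs = decs, verdicts = verdicts)
}

#' Score pipeline predictions against simulation truth
#'
#' @param verdicts Named per-locus verdict vector from [run_pipeline()].
#' @param truth Truth table from [simulate_dataset()].
#' @return List with `counts` (a [confusion_counts]) and `metrics`.
#' @export
evaluate_calls <- function(verdicts, truth) {
  pred <- verdicts[truth$locus_id]
  counts <- confusion_counts(pred == "MSI", truth$locus_msi)
  list(counts = counts, metrics = compute_metrics(counts))
}

#' Run a simulate-deconvolve-call-score experiment grid
#'
#' For each configuration and replicate: simulate a dataset, run the
#' pipeline, and score locus-level calls against truth. Per-replicate seeds
#' derive deterministically from each config's seed.
#'
#' @param grid List of [sim_config] objects.
#' @param replicates Replicates per configuration (default 10).
#' @param dconfig A [deconvolve_config] shared across runs.
#' @param alpha Per-clone significance level.
#' @param workers Parallel workers per pipeline run.
#' @return Data frame with one row per configuration: the configuration
#'   summary plus mean Acc/Pre/Rec/MCC/Gain across replicates.
#' @export
run_experiment_grid <- function(grid, replicates = 10L,
                                dconfig = deconvolve_config(), alpha = 0.05,
                                workers = 1L) {
  rows <- lapply(seq_along(grid), function(ci) {
    cfg <- grid[[ci]]
    mats <- matrix(NA_real_, nrow = replicates, ncol = 5,
                   dimnames = list(NULL, c("Acc", "Pre", "Rec", "MCC", "Gain")))
    for (r in seq_len(replicates)) {
      rcfg <- cfg
      rcfg$seed <- (cfg$seed + 131L * r) %% .Machine$integer.max
      ds <- simulate_dataset(rcfg)
      dcfg <- dconfig
      dcfg$seed <- rcfg$seed
      res <- tryCatch(
        run_pipeline(ds$tumor, ds$normal, clonal_structure(cfg$B),
                     dcfg, alpha, workers = workers),
        error = function(e) NULL
      )
      if (is.null(res)) next
      ev <- evaluate_calls(res$verdicts, ds$truth)
      mats[r, ] <- unlist(ev$metrics)
    }
    data.frame(G = cfg$G, primary = cfg$B[1], depth = cfg$depth,
               n_loci = cfg$n_loci, replicates = sum(!is.na(mats[, 1])),
               Acc = mean(mats[, "Acc"], na.rm = TRUE),
               Pre = mean(mats[, "Pre"], na.rm = TRUE),
               Rec = mean(mats[, "Rec"], na.rm = TRUE),
               MCC = mean(mats[, "MCC"], na.rm = TRUE),
               Gain = mean(mats[, "Gain"], na.rm = TRUE))
  })
  do.call(rbind, rows)
}
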