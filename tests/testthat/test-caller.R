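test_that("identical clone and baseline distributions give a null call", {
  set.seed(10)
  bl <- normal_baseline(gauss_spectrum("b", 18, 1.5, 400))
  fit <- fit_vb(expand_reads(gauss_spectrum("t", 18, 1.5, 400)), 1)
  tt <- test_clone_status(fit$mu, fit$sigma, 400, bl)
  expect_equal(tt$status, "MSS")
  expect_gt(tt$p_value, 0.05)
})

test_that("a 6-unit shift is overwhelmingly detected", {
  set.seed(11)
  bl <- normal_baseline(gauss_spectrum("b", 18, 1, 400))
  tt <- test_clone_status(mu = 24, sigma = 1, n_eff = 200, baseline = bl)
  expect_equal(tt$status, "MSI")
  expect_lt(tt$p_value, 0.01)  # bootstrap p floors at 1/(nboot+1)
  # direct-statistic oracle: the Pearson statistic must be enormous when
  # all clone mass sits where the baseline has none
  expect_gt(tt$statistic, 100)
})

test_that("alpha limits behave as thresholds", {
  set.seed(12)
  bl <- normal_baseline(gauss_spectrum("b", 15, 1, 300))
  same <- test_clone_status(15, 1, 300, bl, alpha = 0)
  expect_equal(same$status, "MSS")
  shifted <- test_clone_status(19, 1, 300, bl, alpha = 1)
  expect_equal(shifted$status, "MSI")
})

test_that("untestable and degenerate inputs are fenced", {
  set.seed(13)
  bl <- normal_baseline(gauss_spectrum("b", 15, 1, 300))
  expect_equal(test_clone_status(15, 1, 4, bl)$status, "untestable")
  thin <- normal_baseline(length_spectrum("t", 15, 3))
  expect_equal(test_clone_status(15, 1, 300, thin)$status, "untestable")
  # zero-variance clone at the baseline mode is a fast-path MSS
  z <- test_clone_status(15, 0, 300, bl)
  expect_equal(z$status, "MSS")
  z2 <- test_clone_status(22, 0, 300, bl)
  expect_equal(z2$status, "MSI")
})

test_that("statistic increases monotonically with the mean shift", {
  set.seed(14)
  bl <- normal_baseline(gauss_spectrum("b", 16, 1.5, 500))
  stats <- sapply(seq(0, 5, by = 0.5), function(d)
    test_clone_status(16 + d, 1.5, 300, bl)$statistic)
  expect_true(all(diff(stats) > -1e-9))
})

test_that("the z-test alternative responds to mean shifts", {
  set.seed(15)
  bl <- normal_baseline(gauss_spectrum("b", 16, 1.5, 500))
  null_t <- test_clone_status(16.01, 1.5, 400, bl, test = "ztest")
  expect_equal(null_t$status, "MSS")
  alt_t <- test_clone_status(19, 1.5, 400, bl, test = "ztest")
  expect_equal(alt_t$status, "MSI")
})

test_that("call_locus propagates components to clones and verdicts", {
  st <- clonal_structure(c(0.7, 0.3))
  # synthetic deconvolution: major clone matches the normal, minor shifted
  dec <- structure(list(
    locus_id = "L1", K = 2, G = 2,
    mu = c(16, 22), sigma = c(1.2, 1),
    A = rbind(c(1, 0), c(0, 1)), pi = c(0.7, 0.3), n = 400,
    converged = TRUE
  ), class = "locus_deconvolution")
  set.seed(16)
  bl <- normal_baseline(gauss_spectrum("L1", 16, 1.2, 400))
  lc <- call_locus(dec, bl, st)
  expect_equal(nrow(lc$clone_calls), 2)
  expect_equal(lc$clone_calls$status, c("MSS", "MSI"))
  expect_equal(lc$verdict, "MSI")  # minor-clone instability rescues the locus
  expect_equal(lc$clone_calls$pi, c(0.7, 0.3))
  # shared component: both clones share one test and status
  dec2 <- dec
  dec2$A <- rbind(c(1, 0), c(1, 0)); dec2$pi <- c(1, 0)
  lc2 <- call_locus(dec2, bl, st)
  expect_equal(lc2$clone_calls$status, c("MSS", "MSS"))
  expect_equal(lc2$verdict, "MSS")
  expect_equal(lc2$clone_calls$statistic[1], lc2$clone_calls$statistic[2])
  # skip records yield NA verdicts
  lc3 <- call_locus(list(locus_id = "skip", skipped = TRUE, reason = "thin"),
                    bl, st)
  expect_true(is.na(lc3$verdict))
})

test_that("sample aggregation implements the partial-MSI rule", {
  mk <- function(id, verdict, statuses) {
    structure(list(locus_id = id, verdict = verdict,
                   clone_calls = data.frame(status = statuses)),
              class = "locus_call")
  }
  all_mss <- lapply(1:15, function(i) mk(paste0("L", i), "MSS", c("MSS", "MSS")))
  expect_equal(call_sample(all_mss)$sample_status, "MSS")
  expect_equal(call_sample(all_mss)$sample_score, 0)

  partial <- c(lapply(1:10, function(i) mk(paste0("L", i), "MSI", c("MSS", "MSI"))),
               lapply(11:15, function(i) mk(paste0("L", i), "MSS", c("MSS", "MSS"))))
  rp <- call_sample(partial)
  expect_equal(rp$sample_status, "partial-MSI")
  expect_equal(rp$sample_score, 10 / 15)

  full <- lapply(1:15, function(i) mk(paste0("L", i), "MSI", c("MSI", "MSI")))
  expect_equal(call_sample(full)$sample_status, "MSI")

  nas <- lapply(1:3, function(i) mk(paste0("L", i), NA_character_, "untestable"))
  expect_true(is.na(call_sample(nas)$sample_status))
  # threshold boundary: score below threshold is MSS
  few <- c(lapply(1:2, function(i) mk(paste0("L", i), "MSI", c("MSI", "MSI"))),
           lapply(3:15, function(i) mk(paste0("L", i), "MSS", c("MSS", "MSS"))))
  expect_equal(call_sample(few, threshold = 0.2)$sample_status, "MSS")
})
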