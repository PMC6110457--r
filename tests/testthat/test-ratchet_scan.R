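test_that("coverage preprocessing bins and masks as specified", {
  # constant coverage over 10 kb with no masks: 100 bins of 10
  prof <- preprocess_coverage(rep(10, 10000), 1001, 11000,
                              spanning_reads = 1)
  expect_s3_class(prof, "CoverageProfile")
  expect_length(prof$bins, 100L)
  expect_true(all(prof$bins == 10))

  # a repeat with a large spike: repeat + 100 nt flanks replaced by the
  # median of the 900 nt on each side
  cv <- rep(10, 10000)
  cv[4001:4300] <- 1000                       # spike inside the repeat
  rp <- GenomicRanges::GRanges("chrS", IRanges::IRanges(5001, 5300))
  prof2 <- preprocess_coverage(cv, 1001, 11000, repeats = rp,
                               spanning_reads = 1)
  # masked block is repeat (4001..4300 local) +/- 100 nt
  expect_true(all(prof2$counts[3901:4400] == 10))
  expect_true(all(prof2$counts == 10))

  # binning equals a direct mean on a random profile
  set.seed(8)
  cv3 <- rpois(8500, 30)
  prof3 <- preprocess_coverage(cv3, 1, 8500, spanning_reads = 1)
  oracle <- vapply(seq_len(85), function(b)
    mean(cv3[((b - 1) * 100 + 1):(b * 100)]), numeric(1))
  expect_equal(prof3$bins, oracle)

  # short introns and unsupported introns are skipped with a reason
  sk <- preprocess_coverage(rep(5, 8000), 1, 8000, spanning_reads = 1)
  expect_s3_class(sk, "skipped_intron")
  expect_match(sk$reason, "8000")
  sk2 <- preprocess_coverage(rep(5, 9000), 1, 9000, spanning_reads = 0)
  expect_s3_class(sk2, "skipped_intron")
})

test_that("heteroscedastic regression finds noiseless lines immediately", {
  x <- 0:99
  y <- 100 - 0.01 * x
  fit <- heteroscedastic_regression(y, x)
  expect_equal(fit$slope, -0.01, tolerance = 1e-10)
  expect_equal(fit$intercept, 100, tolerance = 1e-8)
  expect_lte(fit$iterations, 2L)
  expect_equal(fit$rss, 0, tolerance = 1e-12)

  const <- heteroscedastic_regression(rep(7, 50))
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_equal(const$intercept, 7, tolerance = 1e-12)
})

test_that("regression under Poisson noise sits in the analytic WLS region", {
  set.seed(15)
  x <- 0:199
  mu <- 80 - 0.3 * x
  y <- rpois(200, mu)
  fit <- heteroscedastic_regression(y, x)
  # oracle: closed-form weighted LS with the true-mean weights and its
  # standard errors
  w <- 1 / mu
  sw <- sum(w); swx <- sum(w * x)
  sxx <- sum(w * (x - swx / sw)^2)
  se_slope <- sqrt(1 / sxx)       # var(y_i) = mu_i = 1/w_i
  se_int <- sqrt(1 / sw + (swx / sw)^2 / sxx)
  expect_lt(abs(fit$slope - (-0.3)), 3 * se_slope)
  expect_lt(abs(fit$intercept - 80), 3 * se_int)
})

test_that("BIC evaluation and acceptance probability match hand arithmetic", {
  set.seed(4)
  cv <- c(100 - (1:5000) * 0.015, 30 - (1:5000) * 0.004) + rnorm(10000)
  prof <- preprocess_coverage(cv, 1, 10000, spanning_reads = 1)
  L <- prof$length
  # hand-computed BIC for the zero-site and one-site (bin 50) models
  f0 <- heteroscedastic_regression(prof$bins, x = 0:99)
  bic0 <- L * f0$rss + 0
  f1a <- heteroscedastic_regression(prof$bins[1:50], x = 0:49)
  f1b <- heteroscedastic_regression(prof$bins[51:100], x = 50:99)
  bic1 <- L * (f1a$rss + f1b$rss) + 2 * 2 * log(L)
  s0 <- sawtooth_bic(prof, integer(0))
  s1 <- sawtooth_bic(prof, 50L)
  expect_equal(s0$bic, bic0, tolerance = 1e-12)
  # the 50/60 split here has no 1.5-fold jump: the state is invalid
  expect_false(s1$valid)
  # acceptance between two arbitrary BIC values is exp(-dBIC/5)
  expect_equal(mcmc_acceptance(bic0, bic0 + 7), exp(-7 / 5))
  expect_equal(mcmc_acceptance(bic0, bic0 + 7, from_zero = TRUE),
               exp(-7 / 5) / 2)
  expect_equal(mcmc_acceptance(bic0, bic0 - 3), 1)
})

test_that("null coverage stays in the zero-site state", {
  spec <- sawtooth_spec(11000, seed = 81)
  sim <- simulate_sawtooth_coverage(spec)
  prof <- preprocess_coverage(sim$coverage, 1, 11000, spanning_reads = 1)
  tr <- mcmc_sawtooth(prof, iterations = 5e4, burn_in = 5e3,
                      sample_every = 50, seed = 82)
  expect_lt(max(tr$prob), 0.08)
})

test_that("a planted 3-fold jump concentrates probability at its bin", {
  spec <- sawtooth_spec(12000, sites = 6000, start_density = c(20, 30),
                        decay = 0.5, seed = 83)  # 30 / 10 = 3-fold jump
  sim <- simulate_sawtooth_coverage(spec)
  prof <- preprocess_coverage(sim$coverage, 1, 12000, spanning_reads = 1)
  tr <- mcmc_sawtooth(prof, iterations = 1e5, burn_in = 1e4,
                      sample_every = 50, seed = 84)
  near <- 55:65                 # within +/- 5 bins of the planted bin 60
  expect_gt(max(tr$prob[near]), 0.08)
  expect_gt(sum(tr$prob[near]), 0.9 * sum(tr$prob))
  # oracle: exhaustive BIC over all 0- and 1-site models
  cand <- 5:115
  bics <- vapply(cand, function(s) sawtooth_bic(prof, s)$bic, numeric(1))
  best <- cand[which.min(bics)]
  expect_true(abs(best - 60) <= 5)
  expect_lt(min(bics, na.rm = TRUE), sawtooth_bic(prof, integer(0))$bic)
  # track probabilities sum to the mean sites per sample
  expect_equal(sum(tr$prob), mean(tr$state_sizes), tolerance = 1e-9)
})

test_that("the chain's state-size distribution is stable after burn-in", {
  spec <- sawtooth_spec(10000, seed = 85)
  sim <- simulate_sawtooth_coverage(spec)
  prof <- preprocess_coverage(sim$coverage, 1, 10000, spanning_reads = 1)
  tr <- mcmc_sawtooth(prof, iterations = 9e4, burn_in = 9e3,
                      sample_every = 30, seed = 86)
  n <- length(tr$state_sizes)
  third <- floor(n / 3)
  s2 <- tr$state_sizes[(third + 1):(2 * third)]
  s3 <- tr$state_sizes[(2 * third + 1):(3 * third)]
  sizes <- 0:max(tr$state_sizes)
  tv <- 0.5 * sum(abs(tabulate(s2 + 1, length(sizes)) / length(s2) -
                        tabulate(s3 + 1, length(sizes)) / length(s3)))
  expect_lt(tv, 0.05)
})

test_that("flank potential has the stated logistic geometry", {
  expect_equal(flank_potential(500), 0.5)
  expect_lt(flank_potential(1000), 0.01)
  expect_gt(flank_potential(0), 0.99)
  # position potential: 1 inside, symmetric logistic outside
  expect_equal(position_potential(1500, 1000, 2000), 1)
  expect_equal(position_potential(500, 1000, 2000), 0.5)
  expect_equal(position_potential(2500, 1000, 2000), 0.5)
})

test_that("peak calling picks the brute-force maximum of S(i)", {
  expt <- simulate_ratchet_experiment(n_recursive = 1, n_decoy = 0,
                                      seed = 87)
  pwm <- build_pwms(expt$annotation, expt$genome)
  iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
  prof <- preprocess_coverage(expt$coverage[[expt$truth$intron_id]],
                              iv[1], iv[2], spanning_reads = 1)
  # all-zero track: no peaks
  tr0 <- structure(list(prob = numeric(length(prof$bins)),
                        profile = prof), class = "SiteProbabilityTrack")
  expect_equal(nrow(call_peaks(tr0, expt$genome, pwm)), 0L)
  # force a region around the planted site and one far decoy region
  pr <- numeric(length(prof$bins))
  pr[59:61] <- 1; pr[20] <- 1
  tr <- structure(list(prob = pr, profile = prof),
                  class = "SiteProbabilityTrack")
  pk <- call_peaks(tr, expt$genome, pwm)
  # brute force: score every AG|GT in the intron against each region
  sites <- scan_aggt(expt$genome, "chrS", iv[1], iv[2], "+")
  M <- as.numeric(score_sites(
    site_window(expt$genome, "chrS", sites, "+", pwm), pwm))
  for (r in seq_len(nrow(pk))) {
    S <- position_potential(sites, pk$region_start[r], pk$region_end[r]) *
      pmax(M - 0.8, 0)
    expect_equal(pk$site[r], sites[which.max(S)])
    expect_equal(pk$sawtooth_score[r], max(S), tolerance = 1e-12)
  }
  expect_true(expt$truth$site %in% pk$site)
})

test_that("FDR shuffles preserve region count and lengths", {
  expt <- simulate_ratchet_experiment(n_recursive = 1, n_decoy = 0,
                                      seed = 89)
  pwm <- build_pwms(expt$annotation, expt$genome)
  iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
  prof <- preprocess_coverage(expt$coverage[[expt$truth$intron_id]],
                              iv[1], iv[2], spanning_reads = 1)
  pr <- numeric(length(prof$bins)); pr[58:62] <- 1
  tr <- structure(list(prob = pr, profile = prof),
                  class = "SiteProbabilityTrack")
  pk <- call_peaks(tr, expt$genome, pwm)
  out <- estimate_sawtooth_fdr(pk, tr, expt$genome, pwm,
                               n_shuffles = 1000, seed = 90)
  sl <- attr(out, "shuffle_lengths")
  expect_equal(nrow(sl), 1000L)
  obs_lens <- pk$region_end - pk$region_start + 1L
  expect_true(all(t(sl) == obs_lens))
  reg <- attr(out, "shuffled_regions")
  expect_true(all(reg$start >= prof$start & reg$end <= prof$end))
  # a strong planted site should rarely be matched by chance
  expect_lte(out$fdr[out$site == expt$truth$site], 0.5)
  # zero observed peaks produce an empty result
  empty <- call_peaks(tr0 <- structure(
    list(prob = numeric(length(prof$bins)), profile = prof),
    class = "SiteProbabilityTrack"), expt$genome, pwm)
  expect_equal(nrow(estimate_sawtooth_fdr(empty, tr0, expt$genome, pwm,
                                          n_shuffles = 5, seed = 1)), 0L)
})
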