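sim_session <- function(seed = 1, alpha = 0.45, beta = 0.29) {
  sched <- generate_schedule(seed, n_practice = 0)
  rec <- simulate_agent(sched, alpha, beta, seed = seed + 1)
  trace <- trace_from_choices(rec, sched, alpha, beta)
  list(sched = sched, rec = rec, trace = trace)
}

test_that("gamma response kernel is a unit-sum density peaking at the analytic mode", {
  h <- gamma_hrf(0.05)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_true(all(h >= 0))
  # continuous mode of Gamma(shape 4, scale 1.5) is (4 - 1) * 1.5 = 4.5 s
  peak_t <- (which.max(h) - 1) * 0.05
  expect_equal(peak_t, 4.5, tolerance = 0.1)
  expect_gt(peak_t, 4); expect_lt(peak_t, 7)
  # unit-sum kernel: convolving a constant leaves its level unchanged
  x <- rep(3, 500)
  y <- stats::convolve(x, rev(gamma_hrf(0.5)), type = "open")[seq_along(x)]
  expect_equal(mean(y[100:400]), 3, tolerance = 1e-6)
  expect_error(gamma_hrf(0), "positive")
})

test_that("design matrix has the expected 16 columns and n_volumes rows", {
  ss <- sim_session()
  motion <- matrix(rnorm(440 * 6, sd = 0.1), 440)
  X <- build_design(ss$sched, ss$rec, ss$trace$rpe, motion = motion,
                    tr = 2, n_volumes = 440)
  expect_equal(dim(unclass(X)), c(440L, 16L))
  expect_equal(colnames(X)[1:5],
               c("stim_reward", "stim_bivalent", "fb_reward", "fb_bivalent",
                 "rpe"))
  task <- X[, 1:5]
  expect_true(all(apply(abs(task), 2, max) > 0))
  expect_true(all(is.finite(X)))
  # mean-centering keeps the modulator from duplicating the feedback column
  fb_all <- X[, "fb_reward"] + X[, "fb_bivalent"]
  expect_lt(abs(cor(X[, "rpe"], fb_all)), 0.999)
  # motion columns pass through unconvolved
  expect_equal(unname(X[, "motion1"]), motion[, 1])
})

test_that("zero modulator is flagged and missed trials contribute no feedback event", {
  ss <- sim_session(3)
  expect_warning(build_design(ss$sched, ss$rec, rep(0, 160), tr = 2,
                              n_volumes = 440), "all zero")

  rec_miss <- ss$rec
  rec_miss$choice[5:20] <- "none"
  trace_miss <- trace_from_choices(rec_miss, ss$sched, 0.45, 0.29)
  X_full <- build_design(ss$sched, ss$rec, ss$trace$rpe, tr = 2, n_volumes = 440)
  X_miss <- build_design(ss$sched, rec_miss, trace_miss$rpe, tr = 2,
                         n_volumes = 440)
  # fewer feedback events -> smaller integrated feedback regressor
  expect_lt(sum(X_miss[, "fb_reward"] + X_miss[, "fb_bivalent"]),
            sum(X_full[, "fb_reward"] + X_full[, "fb_bivalent"]))
  expect_error(build_design(ss$sched, ss$rec, rep(1, 10)), "per main trial")
})

test_that("voxelwise OLS recovers planted effects and is calibrated on pure noise", {
  ss <- sim_session(5)
  X <- build_design(ss$sched, ss$rec, ss$trace$rpe, tr = 2, n_volumes = 440)
  set.seed(50)
  n_vox <- 300
  B <- matrix(0, n_vox, ncol(X)); colnames(B) <- colnames(X)
  planted <- 1:150
  B[planted, "rpe"] <- 2
  Y <- B %*% t(unclass(X)) + matrix(rnorm(n_vox * 440), n_vox)
  fl <- fit_first_level(Y, X, contrast = "rpe")

  # planted betas recovered within 3 SE of truth, voxel by voxel
  frac_in <- mean(abs(fl$beta[planted, "rpe"] - 2) <= 3 * fl$se[planted])
  expect_gt(frac_in, 0.98)
  # null voxels: z approximately standard normal
  z0 <- fl$z[-planted]
  expect_lt(abs(mean(z0)), 0.2)
  expect_lt(abs(sd(z0) - 1), 0.15)
  expect_equal(fl$df, 440 - (ncol(X) + 1))  # intercept added internally
})

test_that("scaling the data scales betas but leaves z untouched; rank deficiency errors", {
  ss <- sim_session(6)
  X <- build_design(ss$sched, ss$rec, ss$trace$rpe, tr = 2, n_volumes = 440)
  set.seed(51)
  Y <- matrix(rnorm(50 * 440), 50) + 2 * matrix(unclass(X)[, "rpe"], 50, 440,
                                                byrow = TRUE)
  f1 <- fit_first_level(Y, X)
  f2 <- fit_first_level(2 * Y, X)
  expect_equal(f2$beta[, "rpe"], 2 * f1$beta[, "rpe"])
  expect_equal(f2$z, f1$z, tolerance = 1e-10)

  Xbad <- cbind(unclass(X), dup = unclass(X)[, "rpe"])
  expect_error(fit_first_level(Y, Xbad), "rank deficient")
})

test_that("4D input, masks and beta maps keep spatial structure", {
  ss <- sim_session(7)
  X <- build_design(ss$sched, ss$rec, ss$trace$rpe, tr = 2, n_volumes = 100)
  d3 <- c(4, 4, 3)
  set.seed(52)
  bold <- array(rnorm(prod(d3) * 100), c(d3, 100))
  mask <- array(TRUE, d3); mask[1, 1, 1] <- FALSE
  fl <- fit_first_level(bold, X, mask = mask)
  expect_equal(dim(fl$z), d3)
  expect_true(is.na(fl$z[1, 1, 1]))
  expect_true(all(is.finite(fl$z[mask])))
  bm <- beta_map(fl)
  expect_equal(dim(bm), d3)
})

test_that("discarding initial volumes shifts onsets consistently", {
  ss <- sim_session(8)
  bold <- array(rnorm(4 * 4 * 3 * 443), c(4, 4, 3, 443))
  out <- discard_initial_volumes(bold, ss$sched, n_discard = 3, tr = 2)
  expect_equal(dim(out$bold)[4], 440L)
  expect_equal(out$schedule$stim_onset_s, ss$sched$stim_onset_s - 6)
  expect_equal(out$schedule$feedback_onset_s, ss$sched$feedback_onset_s - 6)
  # the shift is uniform, so inter-event intervals are untouched (round trip)
  expect_equal(diff(out$schedule$stim_onset_s), diff(ss$sched$stim_onset_s))
  expect_equal(out$schedule$stim_onset_s + 3 * 2, ss$sched$stim_onset_s)
})

test_that("spatial smoothing preserves constants and reduces noise variance", {
  const <- array(5, c(8, 8, 6))
  expect_equal(smooth_volume(const), const, tolerance = 1e-8)
  set.seed(53)
  noise <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  sm <- smooth_volume(noise)
  expect_lt(var(as.vector(sm)), var(as.vector(noise)) / 2)
})

test_that("NIfTI volumes round-trip through disk", {
  set.seed(54)
  vol <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(as.vector(back), as.vector(vol), tolerance = 1e-6)
  expect_equal(dim(back), dim(vol))
})
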