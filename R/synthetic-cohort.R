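# Truncated-normal draws by inverse-CDF; errors on infeasible truncation.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  if (p_hi - p_lo < 1e-12) {
    stop("infeasible truncation: [", lo, ", ", hi, "] has ~zero mass under N(",
         mean, ", ", sd, ")", call. = FALSE)
  }
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

#' Specification of a synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator: group sizes,
#' group-specific learning-rate and temperature distributions (truncated
#' normals), symptom-score distributions, the planted RPE effect (regions,
#' baseline amplitude, per-SD delusion slope), acquisition geometry and
#' noise. Defaults emulate the study conditions: 78 patients and 43
#' controls; learning rate 0.45 +/- 0.20 (controls) vs 0.39 +/- 0.28
#' (patients) truncated to \[0, 1\]; temperature 0.29 +/- 0.19 vs
#' 0.30 +/- 0.27 truncated to (0.01, 10\]; 440 retained volumes at TR 2 s;
#' and a head-motion violator fraction of 12/103.
#'
#' @param n_patients,n_controls Group sizes.
#' @param alpha_control,alpha_patient,beta_control,beta_patient Length-2
#'   vectors `c(mean, sd)` of the parameter distributions.
#' @param grid Spatial grid dimensions (default `c(16, 16, 12)`).
#' @param tr,n_volumes Acquisition timing.
#' @param noise_sd BOLD white-noise SD (default 1).
#' @param rpe_amplitude Baseline RPE-response amplitude inside planted
#'   regions (default 1).
#' @param delusion_slope Change in RPE amplitude per SD of the delusion
#'   score (default -0.5: higher delusion scores, weaker RPE signal).
#' @param symptom_cor Latent correlation between the delusion and
#'   referentiality scores (default 0.5).
#' @param motion_violator_fraction Fraction of subjects generated with
#'   excessive head motion (default 12/103).
#' @param p_miss Per-trial probability of no response (default 0.02).
#' @param regions Named list of planted-effect regions, each a list of
#'   index ranges `list(x =, y =, z =)`; defaults are two axis-aligned
#'   blobs labelled "striatum_like" and "frontal_like" (labels are for
#'   testing only, no anatomical claim).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 78L, n_controls = 43L,
                        alpha_control = c(0.45, 0.20),
                        alpha_patient = c(0.39, 0.28),
                        beta_control = c(0.29, 0.19),
                        beta_patient = c(0.30, 0.27),
                        grid = c(16L, 16L, 12L),
                        tr = 2, n_volumes = 440L,
                        noise_sd = 1, rpe_amplitude = 1,
                        delusion_slope = -0.5,
                        symptom_cor = 0.5,
                        motion_violator_fraction = 12 / 103,
                        p_miss = 0.02,
                        regions = NULL) {
  if (is.null(regions)) {
    # axis-aligned blobs placed proportionally so any grid size works
    grid <- as.integer(grid)
    rng <- function(d, a, b) max(1L, round(d * a)):min(d, max(1L, round(d * b)))
    regions <- list(
      striatum_like = list(x = rng(grid[1], 0.22, 0.38),
                           y = rng(grid[2], 0.45, 0.62),
                           z = rng(grid[3], 0.40, 0.58)),
      frontal_like = list(x = rng(grid[1], 0.66, 0.82),
                          y = rng(grid[2], 0.20, 0.38),
                          z = rng(grid[3], 0.66, 0.84)))
  }
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    alpha_control = alpha_control, alpha_patient = alpha_patient,
    beta_control = beta_control, beta_patient = beta_patient,
    beta_bounds = c(0.01, 10),
    grid = as.integer(grid), tr = tr, n_volumes = as.integer(n_volumes),
    noise_sd = noise_sd, rpe_amplitude = rpe_amplitude,
    delusion_slope = delusion_slope, symptom_cor = symptom_cor,
    motion_violator_fraction = motion_violator_fraction,
    p_miss = p_miss, regions = regions), class = "cohort_spec")
}

# Logical 3D mask of the planted regions
region_mask <- function(spec, which = names(spec$regions)) {
  m <- array(FALSE, spec$grid)
  for (r in spec$regions[which]) m[r$x, r$y, r$z] <- TRUE
  m
}

#' Generate a complete synthetic cohort
#'
#' Draws per-subject model parameters from the group-specific truncated
#' normals, simulates each subject's choices on a fresh task schedule,
#' draws demographic covariates and (for patients) symptom scores, builds
#' head-motion series with a planted fraction of motion violators, and
#' fixes per-subject BOLD seeds so each subject's 4D volume can be
#' synthesized on demand by [simulate_subject_bold()] (volumes are not held
#' in memory). The planted imaging effect: voxelwise RPE amplitude =
#' `rpe_amplitude + delusion_slope * standardized delusion score` inside
#' the designated regions (controls get the baseline amplitude), zero
#' outside. All ground truth is retained for recovery testing.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed; identical seeds give identical cohorts.
#' @return A `synthetic_cohort` list: `subjects` (tibble of ground-truth
#'   parameters, covariates, symptom scores, motion summaries, amplitudes),
#'   `schedules` and `records` (per-subject lists), `motion` (per-subject
#'   `n_volumes x 6` matrices), `spec`, `seed`, `effect_mask`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  set.seed(seed)
  n <- spec$n_patients + spec$n_controls
  group <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))

  draw_par <- function(ms, lo, hi, n) rtrunc_norm(n, ms[1], ms[2], lo, hi)
  alpha <- ifelse(group == "patient",
                  draw_par(spec$alpha_patient, 0, 1, n),
                  draw_par(spec$alpha_control, 0, 1, n))
  beta <- ifelse(group == "patient",
                 draw_par(spec$beta_patient, spec$beta_bounds[1],
                          spec$beta_bounds[2], n),
                 draw_par(spec$beta_control, spec$beta_bounds[1],
                          spec$beta_bounds[2], n))

  age <- round(rtrunc_norm(n, 40, 10, 18, 65))
  sex <- stats::rbinom(n, 1, 0.7)
  premorbid_iq <- round(stats::rnorm(n, 100, 10))

  # correlated symptom scores via a Gaussian copula (patients only)
  z1 <- stats::rnorm(n)
  z2 <- spec$symptom_cor * z1 +
    sqrt(1 - spec$symptom_cor^2) * stats::rnorm(n)
  tn_q <- function(z, mean, sd, lo, hi) {
    p_lo <- stats::pnorm(lo, mean, sd); p_hi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(p_lo + stats::pnorm(z) * (p_hi - p_lo), mean, sd)
  }
  is_pat <- group == "patient"
  psyrats <- ifelse(is_pat, round(tn_q(z1, 12, 5, 0, 24), 1), NA_real_)
  iris <- ifelse(is_pat, round(tn_q(z2, 5, 2.5, 0, 10), 1), NA_real_)
  panss_dis <- ifelse(is_pat, round(rtrunc_norm(n, 9, 3, 3, 21), 1), NA_real_)
  panss_neg <- ifelse(is_pat, round(rtrunc_norm(n, 18, 6, 7, 49), 1), NA_real_)
  cpz <- ifelse(is_pat, round(stats::rlnorm(n, log(400), 0.5)), NA_real_)

  # planted RPE amplitude: baseline for controls, baseline + slope * z(score)
  psy_z <- rep(0, n)
  if (any(is_pat)) psy_z[is_pat] <- as.numeric(scale(psyrats[is_pat]))
  amplitude <- spec$rpe_amplitude + ifelse(is_pat,
                                           spec$delusion_slope * psy_z, 0)

  violator <- rep(FALSE, n)
  n_viol <- round(spec$motion_violator_fraction * n)
  if (n_viol > 0) violator[sample.int(n, n_viol)] <- TRUE

  sub_seeds <- matrix(sample.int(2^30, 4L * n), n)

  schedules <- vector("list", n)
  records <- vector("list", n)
  motion <- vector("list", n)
  max_mm <- mean_mm <- numeric(n)
  for (i in seq_len(n)) {
    schedules[[i]] <- generate_schedule(sub_seeds[i, 1], n_practice = 0)
    records[[i]] <- simulate_agent(schedules[[i]], alpha[i], beta[i],
                                   seed = sub_seeds[i, 2],
                                   p_miss = spec$p_miss)
    set.seed(sub_seeds[i, 3])
    mo <- simulate_motion(spec$n_volumes, violator[i])
    motion[[i]] <- mo
    disp <- abs(mo[, 4:6])    # translations (mm)
    max_mm[i] <- max(disp)
    mean_mm[i] <- mean(disp)
  }

  subjects <- tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group, alpha_true = alpha, beta_true = beta,
    age = age, sex = sex, premorbid_iq = premorbid_iq,
    psyrats_delusions = psyrats, iris_pervasiveness = iris,
    panss_disorganization = panss_dis, panss_negative = panss_neg,
    cpz_equivalents = cpz,
    rpe_amplitude_true = amplitude,
    motion_violator = violator,
    max_abs_mm = max_mm, mean_abs_mm = mean_mm,
    bold_seed = sub_seeds[, 4])

  structure(list(subjects = subjects, schedules = schedules,
                 records = records, motion = motion, spec = spec,
                 seed = seed, effect_mask = region_mask(spec)),
            class = "synthetic_cohort")
}

# Smooth random-walk motion series (rotations rad, translations mm);
# violators are rescaled to exceed the exclusion thresholds.
simulate_motion <- function(n_volumes, violator = FALSE) {
  walk <- function(step) {
    w <- cumsum(stats::rnorm(n_volumes, 0, step))
    stats::filter(w, rep(1 / 5, 5), sides = 2, circular = TRUE)
  }
  rot <- sapply(1:3, function(i) walk(2e-5))
  trans <- sapply(1:3, function(i) walk(0.01))
  m <- max(abs(trans))
  target <- if (violator) stats::runif(1, 3.2, 6) else stats::runif(1, 0.3, 2.0)
  trans <- trans * target / max(m, 1e-9)
  if (!violator && mean(abs(trans)) > 0.28) {
    trans <- trans * 0.28 / mean(abs(trans))
  }
  cbind(rot, trans)
}

#' Synthesize one subject's BOLD series
#'
#' Builds the subject's generating design (their own trial-wise RPE trace
#' at their true parameters as modulator, motion included) and produces
#' BOLD = design x true betas + white Gaussian noise. The RPE column's true
#' beta equals the subject's planted amplitude inside the effect regions
#' and 0 outside; the four condition regressors get amplitude 0.5
#' everywhere; baseline 100.
#'
#' @param cohort A `synthetic_cohort`.
#' @param i Subject index (row of `cohort$subjects`).
#' @return 4D array `c(spec$grid, n_volumes)`.
#' @export
simulate_subject_bold <- function(cohort, i) {
  spec <- cohort$spec
  sub <- cohort$subjects[i, ]
  sched <- cohort$schedules[[i]]
  rec <- cohort$records[[i]]
  trace <- trace_from_choices(rec, sched, sub$alpha_true, sub$beta_true)
  X <- build_design(sched, rec, trace$rpe, motion = cohort$motion[[i]],
                    tr = spec$tr, n_volumes = spec$n_volumes)
  nv <- prod(spec$grid)
  eff <- as.vector(cohort$effect_mask)
  B <- matrix(0, nv, ncol(X))
  colnames(B) <- colnames(X)
  B[, c("stim_reward", "stim_bivalent", "fb_reward", "fb_bivalent")] <- 0.5
  B[eff, "rpe"] <- sub$rpe_amplitude_true
  set.seed(sub$bold_seed)
  Y <- B %*% t(unclass(X)) + 100 +
    matrix(stats::rnorm(nv * spec$n_volumes, 0, spec$noise_sd), nv)
  array(Y, c(spec$grid, spec$n_volumes))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Reproduces the study's computational chain end to end: (1) fit each
#' subject's choices by maximum likelihood; (2) pool the fitted parameters
#' as the cross-subject median; (3) replay each subject's RPE trace at the
#' median parameters, build their first-level design (RPE parametric
#' modulator, temporal derivatives, motion), synthesize their BOLD and
#' estimate the voxelwise GLM; (4) run the delusion-score correlation
#' analysis in the patient group with age, sex and premorbid IQ as
#' covariates, with permutation cluster correction in the negative
#' direction.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_perm Permutations for cluster correction (default 1000).
#' @param seed Seed for optimizer starts and permutations.
#' @param n_starts Optimizer starts per subject fit (default 5).
#' @param extra_covariates Character vector of additional patient
#'   covariates to adjust for, out of `"panss_disorganization"`,
#'   `"panss_negative"`, `"cpz_equivalents"` (default none).
#' @param z_thresh Cluster-forming threshold (default 3.1).
#' @return A `pipeline_result` list: `fits` (per-subject tibble),
#'   `median_params`, `rpe_maps` (subjects x voxels matrix of first-level
#'   RPE betas), `stat_map` (patient delusion-slope map), `clusters`
#'   (`cluster_result`), `cohort_subjects`.
#' @export
run_pipeline <- function(cohort, n_perm = 1000, seed = 1L, n_starts = 5L,
                         extra_covariates = character(), z_thresh = 3.1) {
  spec <- cohort$spec
  n <- nrow(cohort$subjects)
  set.seed(seed)
  fit_seeds <- sample.int(2^30, n)

  fits <- purrr::map_dfr(seq_len(n), function(i) {
    f <- fit_subject(cohort$records[[i]], cohort$schedules[[i]],
                     seed = fit_seeds[i], n_starts = n_starts)
    tibble::tibble(subject_id = cohort$subjects$subject_id[i],
                   alpha_hat = f$alpha_hat, beta_hat = f$beta_hat,
                   nll = f$nll, converged = f$converged)
  })
  med <- group_median_params(fits)

  rpe_maps <- matrix(NA_real_, n, prod(spec$grid))
  for (i in seq_len(n)) {
    sched <- cohort$schedules[[i]]
    rec <- cohort$records[[i]]
    trace <- trace_from_choices(rec, sched, med$alpha, med$beta)
    X <- build_design(sched, rec, trace$rpe, motion = cohort$motion[[i]],
                      tr = spec$tr, n_volumes = spec$n_volumes)
    bold <- simulate_subject_bold(cohort, i)
    fl <- fit_first_level(bold, X, contrast = "rpe")
    rpe_maps[i, ] <- fl$beta[, "rpe"]
  }
  attr(rpe_maps, "dim3") <- spec$grid

  is_pat <- cohort$subjects$group == "patient"
  pat_maps <- structure(rpe_maps[is_pat, , drop = FALSE], dim3 = spec$grid)
  covars <- cohort$subjects[is_pat, c("age", "sex", "premorbid_iq",
                                      extra_covariates)]
  scores <- cohort$subjects$psyrats_delusions[is_pat]
  smap <- symptom_correlation_map(pat_maps, scores, covars)
  clusters <- cluster_inference(
    smap, z_thresh = z_thresh, direction = "neg",
    null_fun = perm_null_score(pat_maps, scores, covars),
    n_perm = n_perm, seed = seed)

  structure(list(fits = fits, median_params = med, rpe_maps = rpe_maps,
                 stat_map = smap, clusters = clusters,
                 cohort_subjects = cohort$subjects),
            class = "pipeline_result")
}

#' Ground-truth recovery report
#'
#' Compares pipeline outputs with the cohort's planted ground truth:
#' Pearson correlation and mean bias between true and fitted model
#' parameters, the Dice overlap between significant negative clusters
#' (corrected p < 0.05) and the planted effect regions, and whether the
#' detected association's sign matches the planted slope.
#'
#' @param cohort The `synthetic_cohort` the pipeline ran on.
#' @param result The matching `pipeline_result`.
#' @param p_threshold Corrected-p cutoff for calling a cluster significant.
#' @return A one-row tibble: `alpha_cor`, `alpha_bias`, `beta_cor`,
#'   `beta_bias`, `dice`, `n_significant_clusters`, `sign_correct`.
#' @export
ground_truth_report <- function(cohort, result, p_threshold = 0.05) {
  truth <- cohort$subjects
  fits <- result$fits
  safe_cor <- function(a, b) if (stats::sd(a) < 1e-12) NA_real_ else stats::cor(a, b)

  lab <- attr(result$clusters, "label_map")
  sig <- result$clusters$label[!is.na(result$clusters$p_corrected) &
                                 result$clusters$p_corrected < p_threshold]
  detected <- array(lab %in% sig & lab > 0, dim(lab))
  planted <- cohort$effect_mask
  inter <- sum(detected & planted)
  dice <- if (sum(detected) + sum(planted) == 0) NA_real_ else
    2 * inter / (sum(detected) + sum(planted))

  # sign of the planted and detected association
  is_pat <- truth$group == "patient"
  mean_slope_z <- mean(result$stat_map$z[planted], na.rm = TRUE)
  sign_correct <- if (cohort$spec$delusion_slope == 0) NA else
    sign(mean_slope_z) == sign(cohort$spec$delusion_slope)

  tibble::tibble(
    alpha_cor = safe_cor(truth$alpha_true, fits$alpha_hat),
    alpha_bias = mean(fits$alpha_hat - truth$alpha_true),
    beta_cor = safe_cor(truth$beta_true, fits$beta_hat),
    beta_bias = mean(fits$beta_hat - truth$beta_true),
    dice = dice,
    n_significant_clusters = length(sig),
    sign_correct = sign_correct)
}

#' Write a synthetic cohort to disk
#'
#' Writes the directory layout the analysis functions consume: per-subject
#' BIDS-style events TSVs and 6-column motion tables, a cohort covariate
#' CSV, and (optionally) 4D BOLD NIfTI volumes plus the planted-effect
#' mask. All files are labelled synthetic by the `synthetic_` prefix of the
#' ground-truth file.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param write_bold Also write per-subject 4D NIfTI volumes (default
#'   FALSE; they are large and can be regenerated from the seeds).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_bold = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$subjects$subject_id
  for (i in seq_along(ids)) {
    write_events_tsv(cohort$schedules[[i]],
                     file.path(dir, paste0(ids[i], "_events.tsv")),
                     records = cohort$records[[i]])
    mo <- cohort$motion[[i]]
    colnames(mo) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
    readr::write_csv(tibble::as_tibble(mo),
                     file.path(dir, paste0(ids[i], "_motion.csv")))
    if (write_bold) {
      write_volume(simulate_subject_bold(cohort, i),
                   file.path(dir, paste0(ids[i], "_bold.nii.gz")))
    }
  }
  readr::write_csv(cohort$subjects, file.path(dir, "synthetic_cohort.csv"))
  write_volume(cohort$effect_mask + 0,
               file.path(dir, "synthetic_effect_mask.nii.gz"))
  invisible(dir)
}
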