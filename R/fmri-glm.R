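#' Gamma hemodynamic response function
#'
#' Gamma-density impulse response with mean lag 6 s and SD 3 s (shape 4,
#' scale 1.5 s), sampled at interval `dt` over `length_s` seconds and
#' normalized to unit sum, so convolving a constant series leaves its mean
#' unchanged. The continuous kernel peaks at its mode, 4.5 s.
#'
#' @param dt Sampling interval in seconds (> 0); typically the TR or a finer
#'   microtime grid.
#' @param length_s Kernel support in seconds (default 30).
#' @param mean_lag,sd Gamma mean and standard deviation in seconds.
#' @return Numeric kernel sampled at `0, dt, 2 dt, ...`, summing to 1.
#' @export
#' @examples
#' h <- gamma_hrf(0.1)
#' (which.max(h) - 1) * 0.1   # near the 4.5 s mode
gamma_hrf <- function(dt, length_s = 30, mean_lag = 6, sd = 3) {
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  shape <- (mean_lag / sd)^2
  scale <- sd^2 / mean_lag
  tt <- seq(0, length_s, by = dt)
  k <- stats::dgamma(tt, shape = shape, scale = scale)
  k / sum(k)
}

#' Build a first-level design matrix with an RPE parametric modulator
#'
#' Constructs the task regressors on a fine microtime grid, convolves them
#' with the gamma response function, and samples at volume acquisition
#' times. Regressors: stimulus onsets as 2.5 s events in rewarded and
#' bivalent pairs separately, feedback onsets as 1 s events in rewarded and
#' bivalent pairs separately, and the trial-wise reward prediction error as
#' a parametric modulator at feedback onset (1 s events weighted by the
#' mean-centered RPE). A temporal derivative is appended for each convolved
#' task regressor and the six motion parameters enter unconvolved, giving
#' 5 + 5 + 6 = 16 columns under defaults. Missed trials contribute no
#' feedback or modulator event.
#'
#' @param schedule A `task_schedule` (main trials used).
#' @param records Trial records aligned with the schedule (for missed-trial
#'   handling).
#' @param rpe Numeric RPE value per main trial (e.g. the `rpe` column of
#'   [trace_from_choices()] at the group median parameters); `NA` allowed at
#'   missed trials.
#' @param motion `n_volumes x 6` matrix/data frame of motion parameters, or
#'   `NULL` to omit motion columns.
#' @param tr Repetition time in seconds (default 2).
#' @param n_volumes Number of volumes (default 440).
#' @param center_rpe Mean-center the modulator before convolution (default
#'   TRUE), decorrelating it from the unmodulated feedback regressors.
#' @param add_derivatives Append temporal derivatives of the task
#'   regressors (default TRUE).
#' @param microtime Microtime resolution as a fraction of TR (default 1/16).
#' @return An `fmri_design`: numeric matrix `n_volumes x p` with named
#'   columns (`stim_reward`, `stim_bivalent`, `fb_reward`, `fb_bivalent`,
#'   `rpe`, derivatives `d_*`, `motion1..6`), with `tr` stored as an
#'   attribute. An all-zero modulator column triggers a warning.
#' @export
build_design <- function(schedule, records, rpe, motion = NULL,
                         tr = 2, n_volumes = 440,
                         center_rpe = TRUE, add_derivatives = TRUE,
                         microtime = 1 / 16) {
  sch <- main_trials(schedule)
  check_alignment(records, sch)
  if (length(rpe) != nrow(sch)) {
    stop("`rpe` must supply one value per main trial", call. = FALSE)
  }
  responded <- !is.na(records$choice) & records$choice != "none"
  if (any(!is.finite(rpe[responded]))) {
    stop("non-finite RPE on a responded trial", call. = FALSE)
  }

  dt <- tr * microtime
  total_s <- n_volumes * tr
  n_fine <- ceiling(total_s / dt) + 1L
  grid_box <- function(onsets, durations, weights = NULL) {
    x <- numeric(n_fine)
    if (length(onsets) == 0) return(x)
    w <- weights %||% rep(1, length(onsets))
    for (k in seq_along(onsets)) {
      i0 <- floor(onsets[k] / dt) + 1L
      i1 <- min(n_fine, ceiling((onsets[k] + durations[k]) / dt))
      if (i0 <= n_fine) x[i0:min(i1, n_fine)] <- x[i0:min(i1, n_fine)] + w[k]
    }
    x
  }

  rewarded <- sch$condition == "rewarded"
  fb_keep <- responded   # missed trials: no feedback shown, no modulator
  mod <- rpe[fb_keep]
  if (center_rpe && length(mod) > 0) mod <- mod - mean(mod)

  fine <- list(
    stim_reward = grid_box(sch$stim_onset_s[rewarded], rep(2.5, sum(rewarded))),
    stim_bivalent = grid_box(sch$stim_onset_s[!rewarded], rep(2.5, sum(!rewarded))),
    fb_reward = grid_box(sch$feedback_onset_s[rewarded & fb_keep],
                         rep(1, sum(rewarded & fb_keep))),
    fb_bivalent = grid_box(sch$feedback_onset_s[!rewarded & fb_keep],
                           rep(1, sum(!rewarded & fb_keep))),
    rpe = grid_box(sch$feedback_onset_s[fb_keep], rep(1, sum(fb_keep)), mod)
  )
  if (all(fine$rpe == 0)) {
    warning("RPE modulator column is all zero", call. = FALSE)
  }

  h <- gamma_hrf(dt)
  vol_idx <- floor(((seq_len(n_volumes) - 1) * tr) / dt) + 1L
  conv_sample <- function(x) {
    y <- stats::convolve(x, rev(h), type = "open")[seq_along(x)]
    y[vol_idx]
  }
  cols <- lapply(fine, conv_sample)
  X <- do.call(cbind, cols)
  colnames(X) <- names(fine)

  if (add_derivatives) {
    D <- apply(X, 2, function(v) c(0, diff(v)) / tr)
    colnames(D) <- paste0("d_", colnames(X))
    X <- cbind(X, D)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes || ncol(motion) != 6) {
      stop("`motion` must be n_volumes x 6", call. = FALSE)
    }
    colnames(motion) <- paste0("motion", 1:6)
    X <- cbind(X, motion)
  }
  structure(X, tr = tr, class = c("fmri_design", "matrix", "array"))
}

#' Discard initial (signal-stabilization) volumes
#'
#' Drops the first `n_discard` volumes of a 4D series and shifts event
#' onsets earlier by `n_discard * tr` seconds so timing stays consistent.
#'
#' @param bold 4D array (x, y, z, time).
#' @param schedule A `task_schedule` whose onsets are to be shifted.
#' @param n_discard Number of leading volumes to drop (default 3).
#' @param tr Repetition time in seconds.
#' @return A list with `bold` (trimmed) and `schedule` (onsets shifted).
#' @export
discard_initial_volumes <- function(bold, schedule, n_discard = 3L, tr = 2) {
  stopifnot(length(dim(bold)) == 4, n_discard >= 0)
  shift <- n_discard * tr
  sched <- schedule
  sched$stim_onset_s <- sched$stim_onset_s - shift
  sched$feedback_onset_s <- sched$feedback_onset_s - shift
  list(bold = bold[, , , seq_len(dim(bold)[4] - n_discard) + n_discard,
                   drop = FALSE],
       schedule = sched)
}

# Map t statistics to z scores at the given df, stable in the far tails.
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  z[pos] <- -stats::qnorm(stats::pt(t[pos], df, lower.tail = FALSE,
                                    log.p = TRUE), log.p = TRUE)
  neg <- !is.na(t) & t < 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}

#' Fit the first-level voxelwise GLM
#'
#' Ordinary least squares of every voxel time series on the design matrix
#' (an intercept is added internally). Returns per-column beta maps and the
#' z map for the contrast column (`rpe` by default), with t statistics
#' mapped to z scores at the model's residual degrees of freedom.
#'
#' @param bold 4D array (x, y, z, time) or a voxels-by-time matrix.
#' @param design An `fmri_design` (or plain matrix) with `nrow(design)`
#'   equal to the number of time points.
#' @param contrast Name (or index) of the design column of interest
#'   (default `"rpe"`).
#' @param mask Optional logical/0-1 3D array; voxels outside get `NA`.
#' @return A `first_level_fit` list: `beta` (matrix voxels x columns or 4D
#'   array when the input was 4D; includes the intercept as column
#'   `(Intercept)`), `z` (3D array or vector for the contrast column), `se`,
#'   `df`, `contrast`, `dim` (spatial dims or NULL).
#' @export
fit_first_level <- function(bold, design, contrast = "rpe", mask = NULL) {
  spatial_dim <- NULL
  if (length(dim(bold)) == 4) {
    spatial_dim <- dim(bold)[1:3]
    Y <- matrix(bold, prod(spatial_dim), dim(bold)[4])
  } else {
    Y <- as.matrix(bold)
  }
  X <- cbind(`(Intercept)` = 1, unclass(design))
  if (ncol(Y) != nrow(X)) stop("time dimension of `bold` must match design rows",
                               call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  if (is.character(contrast)) {
    ci <- match(contrast, colnames(X))
    if (is.na(ci)) stop("contrast column '", contrast, "' not in design",
                        call. = FALSE)
  } else ci <- contrast + 1L  # +1 for the intercept

  mask_vec <- NULL
  if (!is.null(mask)) {
    mask_vec <- as.logical(as.vector(mask))
    Yfit <- Y[mask_vec, , drop = FALSE]
  } else Yfit <- Y

  # betas: (X'X)^-1 X' Y', residual variance per voxel
  coef <- t(qr.coef(qrX, t(Yfit)))
  res <- Yfit - coef %*% t(X)
  df <- nrow(X) - ncol(X)
  sigma2 <- rowSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se_c <- sqrt(sigma2 * XtXinv[ci, ci])
  tstat <- coef[, ci] / se_c
  zc <- t_to_z(tstat, df)

  expand <- function(v, ncol_ = NULL) {
    if (is.null(mask_vec)) return(v)
    if (is.null(ncol_)) {
      out <- rep(NA_real_, nrow(Y)); out[mask_vec] <- v; out
    } else {
      out <- matrix(NA_real_, nrow(Y), ncol_); out[mask_vec, ] <- v; out
    }
  }
  beta <- expand(coef, ncol(X))
  colnames(beta) <- colnames(X)
  z <- expand(zc)
  se <- expand(se_c)
  if (!is.null(spatial_dim)) {
    z <- array(z, spatial_dim)
    se <- array(se, spatial_dim)
  }
  structure(list(beta = beta, z = z, se = se, df = df,
                 contrast = colnames(X)[ci], dim = spatial_dim),
            class = "first_level_fit")
}

#' Extract a beta map from a first-level fit
#'
#' @param fit A `first_level_fit`.
#' @param column Design column name (default the fit's contrast).
#' @return A 3D array (if the fit was spatial) or numeric vector of betas.
#' @export
beta_map <- function(fit, column = fit$contrast) {
  b <- fit$beta[, column]
  if (!is.null(fit$dim)) b <- array(b, fit$dim)
  b
}

#' Gaussian spatial smoothing of volumes
#'
#' Separable Gaussian filter applied to each volume; an optional pre-step
#' mirroring standard spatial smoothing before group analysis.
#'
#' @param vol 3D or 4D array.
#' @param fwhm_mm Full width at half maximum in mm (default 5).
#' @param voxel_mm Voxel size in mm (scalar or length 3; default 3.5).
#' @return Array of the same shape.
#' @export
smooth_volume <- function(vol, fwhm_mm = 5, voxel_mm = 3.5) {
  voxel_mm <- rep(voxel_mm, length.out = 3)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_mm
  kern <- function(s) {
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k / sum(k)
  }
  smooth_axis <- function(a, axis, k) {
    r <- (length(k) - 1L) / 2L
    apply_along <- function(v) {
      n <- length(v)
      vp <- c(rep(v[1], r), v, rep(v[n], r))   # replicate-pad edges
      stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
    }
    d <- dim(a)
    perm <- c(axis, setdiff(seq_along(d), axis))
    m <- matrix(aperm(a, perm), d[axis])
    m <- apply(m, 2, apply_along)
    aperm(array(m, d[perm]), order(perm))
  }
  f3 <- function(v3) {
    for (ax in 1:3) v3 <- smooth_axis(v3, ax, kern(sigma_vox[ax]))
    v3
  }
  if (length(dim(vol)) == 3) return(f3(vol))
  out <- vol
  for (t in seq_len(dim(vol)[4])) out[, , , t] <- f3(vol[, , , t])
  out
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti for 3D/4D volumes and masks.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol Array to write.
#' @return `read_volume()` returns an array; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attr(a, "affine") <- tryCatch(structure(RNifti::xform(img), class = NULL),
                                error = function(e) NULL)
  a
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(unclass(vol)), path)
  invisible(path)
}
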