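#' Stack per-subject maps into a subjects-by-voxels matrix
#'
#' @param maps A list of equally-shaped 3D arrays (or vectors), or an
#'   already-stacked matrix (returned unchanged).
#' @return Numeric matrix, one row per subject, with the spatial dimensions
#'   in `attr(, "dim3")` when the inputs were arrays.
#' @export
stack_maps <- function(maps) {
  if (is.matrix(maps)) return(maps)
  d3 <- dim(maps[[1]])
  out <- do.call(rbind, lapply(maps, as.vector))
  attr(out, "dim3") <- d3
  out
}

# Voxelwise OLS of Y (n x v) on X (n x p); z map for column `ci`.
vox_ols <- function(Y, X, ci) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("group design is rank deficient", call. = FALSE)
  coef <- qr.coef(qrX, Y)                 # p x v
  res <- Y - X %*% coef
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[ci, ci])
  tstat <- coef[ci, ] / se
  list(beta = coef[ci, ], se = se, t = tstat, z = t_to_z(tstat, df), df = df)
}

# Build a group design matrix from a covariate data frame: intercept first,
# then each column, numeric covariates mean-centered (except any column
# named in `keep_raw`).
group_design_matrix <- function(covariates, keep_raw = character()) {
  X <- cbind(`(Intercept)` = rep(1, nrow(covariates)))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    v <- as.numeric(v)
    if (!nm %in% keep_raw) v <- v - mean(v)
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- nm
  }
  X
}

#' Voxelwise group-level GLM map
#'
#' Ordinary least squares of per-subject first-level maps on a group design
#' (intercept plus mean-centered covariates), returning the z map for the
#' requested effect: the group mean (`contrast = "(Intercept)"`), a group
#' difference (a 0/1 group column), or a symptom slope.
#'
#' @param maps List of per-subject 3D maps or a subjects-by-voxels matrix.
#' @param covariates Data frame of per-subject regressors (may be `NULL`
#'   for a pure group mean). Character/factor columns are coded 0/1; all
#'   columns are mean-centered.
#' @param contrast Name of the design column of interest (default
#'   `"(Intercept)"`, the group mean).
#' @return A `stat_map` list: `z` and `beta` (3D arrays when the input maps
#'   were 3D), `se`, `df`, `contrast`, `dim`.
#' @export
group_glm_map <- function(maps, covariates = NULL,
                          contrast = "(Intercept)") {
  Y <- stack_maps(maps)
  d3 <- attr(Y, "dim3")
  if (nrow(Y) < 3) stop("need at least 3 subjects", call. = FALSE)
  X <- if (is.null(covariates)) {
    cbind(`(Intercept)` = rep(1, nrow(Y)))
  } else group_design_matrix(covariates)
  ci <- match(contrast, colnames(X))
  if (is.na(ci)) stop("contrast '", contrast, "' not in group design",
                      call. = FALSE)
  fit <- vox_ols(Y, X, ci)
  shape <- function(v) if (is.null(d3)) v else array(v, d3)
  structure(list(z = shape(fit$z), beta = shape(fit$beta),
                 se = shape(fit$se), df = fit$df, contrast = contrast,
                 dim = d3), class = "stat_map")
}

#' Covariate-adjusted symptom-correlation map
#'
#' Voxelwise slope of the per-subject RPE effect on a symptom score,
#' adjusting for age, sex and premorbid IQ (and optionally disorganization,
#' negative symptoms or antipsychotic dose), in the patient group. The
#' score is standardized so the slope is per SD of the score; the z map of
#' the slope is the primary output and negative z indicates the
#' hypothesized inverse association.
#'
#' @param maps Patient maps (list of 3D arrays or matrix).
#' @param scores Numeric symptom scores, one per patient; must vary.
#' @param covariates Data frame of adjustment covariates (may be `NULL`).
#' @param standardize Standardize the score vector (default TRUE).
#' @return A `stat_map` (see [group_glm_map()]) for the score slope.
#' @export
symptom_correlation_map <- function(maps, scores, covariates = NULL,
                                    standardize = TRUE) {
  if (stats::sd(scores) < 1e-12) {
    stop("symptom scores are constant; slope undefined", call. = FALSE)
  }
  sc <- if (standardize) as.numeric(scale(scores)) else scores - mean(scores)
  covs <- tibble::tibble(score = sc)
  if (!is.null(covariates)) covs <- dplyr::bind_cols(covs, covariates)
  group_glm_map(maps, covs, contrast = "score")
}

# 26- or 6-connectivity neighbor offsets (3 x k matrix of voxel steps)
neighbor_offsets <- function(connectivity = 26) {
  if (connectivity == 6) {
    t(matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
             nrow = 3))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26", call. = FALSE)
}

#' Label connected supra-threshold components
#'
#' Breadth-first labeling of connected components of a 3D logical array
#' under 26- (default) or 6-connectivity.
#'
#' @param bin 3D logical (or 0/1) array.
#' @param connectivity 26 or 6.
#' @return Integer 3D array: 0 background, 1..K component labels.
#' @export
label_clusters <- function(bin, connectivity = 26) {
  d <- dim(bin)
  stopifnot(length(d) == 3)
  bin <- array(as.logical(bin) & !is.na(bin), d)
  lab <- array(0L, d)
  offs <- neighbor_offsets(connectivity)
  idx <- which(bin)
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      co <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        x <- co[1] + offs[k, 1]; y <- co[2] + offs[k, 2]; z <- co[3] + offs[k, 3]
        if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) next
        if (bin[x, y, z] && lab[x, y, z] == 0L) {
          lab[x, y, z] <- cur
          queue <- c(queue, (z - 1L) * d[1] * d[2] + (y - 1L) * d[1] + x)
        }
      }
    }
  }
  lab
}

# Max cluster size of a thresholded map (fast path for permutations)
max_cluster_size <- function(zvec, d3, z_thresh, mask_vec, offs_conn) {
  bin <- array(FALSE, d3)
  bin[mask_vec & !is.na(zvec) & zvec > z_thresh] <- TRUE
  if (!any(bin)) return(0L)
  lab <- label_clusters(bin, offs_conn)
  max(tabulate(lab[lab > 0L]))
}

#' Permutation cluster-level inference
#'
#' Thresholds a z map at the cluster-forming threshold (default z > 3.1),
#' labels connected supra-threshold components, and assigns each cluster a
#' family-wise-error corrected p value as the permutation tail probability
#' of the maximum cluster size under a user-supplied null map generator
#' (sign-flipping for one-sample effects, score shuffling for
#' correlations; see [perm_null_onesample()] and [perm_null_score()]).
#'
#' @param zmap 3D z array (a `stat_map`'s `z`, or the object itself).
#' @param z_thresh Cluster-forming threshold (default 3.1).
#' @param direction `"pos"` tests z > threshold, `"neg"` tests z <
#'   -threshold (the map is negated internally).
#' @param connectivity 26 (default) or 6.
#' @param mask Optional logical 3D array restricting the search.
#' @param null_fun Function of no arguments returning one permuted z map
#'   (same shape); `NULL` skips corrected p values.
#' @param n_perm Number of permutations (default 1000, >= 100 when
#'   `null_fun` is given).
#' @param seed Seed for the permutation stream.
#' @return A `cluster_result` tibble: `label`, `size_voxels`, `peak_z`,
#'   `peak_x`, `peak_y`, `peak_z_idx` (1-based voxel indices),
#'   `p_corrected` (`NA` without `null_fun`), ordered by decreasing size.
#'   The label map is in `attr(, "label_map")`, the null maximum-size
#'   distribution in `attr(, "null_max_sizes")`.
#' @export
cluster_inference <- function(zmap, z_thresh = 3.1, direction = c("pos", "neg"),
                              connectivity = 26, mask = NULL,
                              null_fun = NULL, n_perm = 1000, seed = 1) {
  direction <- match.arg(direction)
  if (inherits(zmap, "stat_map")) zmap <- zmap$z
  d3 <- dim(zmap)
  stopifnot(length(d3) == 3)
  sgn <- if (direction == "neg") -1 else 1
  zz <- sgn * zmap
  mask_arr <- if (is.null(mask)) array(TRUE, d3) else array(as.logical(mask), d3)
  if (!any(mask_arr)) stop("mask is empty", call. = FALSE)
  if (!any(is.finite(zz[mask_arr]))) stop("z map has no finite values in mask",
                                          call. = FALSE)

  bin <- mask_arr & !is.na(zz) & zz > z_thresh
  lab <- label_clusters(bin, connectivity)
  k <- max(lab)
  null_max <- NULL
  if (!is.null(null_fun) && k > 0) {
    if (n_perm < 100) stop("need n_perm >= 100", call. = FALSE)
    set.seed(seed)
    null_max <- vapply(seq_len(n_perm), function(i) {
      max_cluster_size(sgn * as.vector(null_fun()), d3, z_thresh,
                       as.vector(mask_arr), connectivity)
    }, numeric(1))
  }
  rows <- purrr::map(seq_len(k), function(ci) {
    vox <- which(lab == ci)
    zc <- zz[vox]
    peak <- vox[which.max(zc)]
    pc <- arrayInd(peak, d3)
    tibble::tibble(label = ci, size_voxels = length(vox),
                   peak_z = sgn * zz[peak],
                   peak_x = pc[1], peak_y = pc[2], peak_z_idx = pc[3],
                   p_corrected = if (is.null(null_max)) NA_real_ else
                     (1 + sum(null_max >= length(vox))) / (n_perm + 1))
  })
  out <- if (k > 0) dplyr::arrange(dplyr::bind_rows(rows),
                                   dplyr::desc(.data$size_voxels))
  else tibble::tibble(label = integer(), size_voxels = integer(),
                      peak_z = numeric(), peak_x = integer(),
                      peak_y = integer(), peak_z_idx = integer(),
                      p_corrected = numeric())
  attr(out, "label_map") <- lab
  attr(out, "null_max_sizes") <- null_max
  class(out) <- c("cluster_result", class(out))
  out
}

#' Null-map generators for permutation inference
#'
#' `perm_null_onesample()` returns a closure that sign-flips the
#' per-subject maps (exchangeable under a symmetric null) and recomputes
#' the group z map. `perm_null_score()` returns a closure that shuffles the
#' symptom scores across subjects and recomputes the covariate-adjusted
#' slope z map.
#'
#' @param maps Per-subject maps (list or matrix).
#' @param covariates Optional covariate data frame (passed through).
#' @param scores Symptom scores (for `perm_null_score`).
#' @return A function of no arguments returning a permuted z map; pass as
#'   `null_fun` to [cluster_inference()].
#' @export
perm_null_onesample <- function(maps, covariates = NULL) {
  Y <- stack_maps(maps)
  d3 <- attr(Y, "dim3")
  n <- nrow(Y)
  function() {
    s <- sample(c(-1, 1), n, replace = TRUE)
    m <- group_glm_map(structure(s * Y, dim3 = d3), covariates,
                       contrast = "(Intercept)")
    m$z
  }
}

#' @rdname perm_null_onesample
#' @export
perm_null_score <- function(maps, scores, covariates = NULL) {
  Y <- stack_maps(maps)
  d3 <- attr(Y, "dim3")
  function() {
    m <- symptom_correlation_map(structure(Y, dim3 = d3),
                                 sample(scores), covariates)
    m$z
  }
}

#' Region-of-interest summary and group comparison
#'
#' Mean map value inside an ROI mask per subject, with a Welch t comparison
#' between groups (covariate-adjusted via OLS when covariates are given).
#'
#' @param maps Per-subject maps (list or matrix).
#' @param mask Logical/0-1 3D array (or vector) defining the ROI; must be
#'   nonempty and match the map shape.
#' @param group Optional vector of group labels (2 levels) for comparison.
#' @param covariates Optional data frame of adjustment covariates.
#' @return Tibble `subject`, `roi_mean` (plus `group`); when `group` is
#'   given, the comparison (`estimate` = group difference, `t_stat`, `p`)
#'   is stored in `attr(, "comparison")`.
#' @export
roi_summary <- function(maps, mask, group = NULL, covariates = NULL) {
  Y <- stack_maps(maps)
  m <- as.logical(as.vector(mask))
  if (length(m) != ncol(Y)) stop("mask does not align with maps", call. = FALSE)
  if (!any(m)) stop("ROI mask is empty", call. = FALSE)
  out <- tibble::tibble(subject = seq_len(nrow(Y)),
                        roi_mean = rowMeans(Y[, m, drop = FALSE]))
  if (!is.null(group)) {
    out$group <- group
    g <- factor(group)
    stopifnot(nlevels(g) == 2)
    if (is.null(covariates)) {
      tt <- stats::t.test(out$roi_mean ~ g)
      cmp <- tibble::tibble(
        estimate = unname(tt$estimate[1] - tt$estimate[2]),
        t_stat = unname(tt$statistic), p = tt$p.value)
    } else {
      dat <- dplyr::bind_cols(tibble::tibble(roi_mean = out$roi_mean,
                                             group = as.numeric(g) - 1),
                              covariates)
      fit <- stats::lm(roi_mean ~ ., data = dat)
      co <- unname(summary(fit)$coefficients["group", ])
      cmp <- tibble::tibble(estimate = co[1], t_stat = co[3], p = co[4])
    }
    attr(out, "comparison") <- cmp
  }
  out
}

#' Write a cluster table as CSV
#'
#' @param clusters A `cluster_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(clusters, path) {
  readr::write_csv(tibble::as_tibble(clusters), path)
  invisible(path)
}
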