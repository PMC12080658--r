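random_maps <- function(n, d3, seed, mu = 0) {
  set.seed(seed)
  structure(matrix(rnorm(n * prod(d3), mean = mu), n), dim3 = d3)
}

test_that("cluster labeling agrees with an independent flood fill", {
  set.seed(60)
  for (k in 1:6) {
    bin <- array(runif(8 * 7 * 6) < 0.25, c(8, 7, 6))
    for (conn in c(6, 26)) {
      lab <- label_clusters(bin, conn)
      ref <- oracle_flood_fill(bin, conn)
      # same partition up to label permutation
      expect_equal(max(lab), max(ref))
      expect_equal(lab > 0, ref > 0)
      if (max(lab) > 0) {
        cross <- table(lab[lab > 0], ref[ref > 0])
        expect_true(all(rowSums(cross > 0) == 1))
        expect_true(all(colSums(cross > 0) == 1))
      }
    }
  }
})

test_that("two disjoint supra-threshold blobs give exactly two clusters with correct sizes", {
  z <- array(0, c(10, 10, 8))
  z[2:3, 2:3, 2:3] <- 5    # 8 voxels
  z[7:9, 7:8, 5:6] <- 4    # 12 voxels
  res <- cluster_inference(z, z_thresh = 3.1)
  expect_equal(nrow(res), 2L)
  expect_equal(sort(res$size_voxels), c(8L, 12L))
  expect_equal(res$peak_z[res$size_voxels == 8], 5)
  # below threshold everywhere -> no clusters
  expect_equal(nrow(cluster_inference(z, z_thresh = 10)), 0L)
  # negative direction finds sign-flipped blobs
  resn <- cluster_inference(-z, z_thresh = 3.1, direction = "neg")
  expect_equal(nrow(resn), 2L)
  expect_true(all(resn$peak_z < 0))
})

test_that("group mean map detects a planted blob and is ~0 on zero input", {
  d3 <- c(8, 8, 6)
  zero_maps <- structure(matrix(0, 10, prod(d3)), dim3 = d3)
  m0 <- group_glm_map(zero_maps)
  expect_true(all(abs(m0$beta) < 1e-12))

  maps <- random_maps(20, d3, seed = 61)
  blob <- array(FALSE, d3); blob[3:5, 3:5, 2:4] <- TRUE
  maps[, as.vector(blob)] <- maps[, as.vector(blob)] + 2
  m <- group_glm_map(maps)
  expect_gt(mean(m$z[blob]), 3)
  expect_lt(abs(mean(m$z[!blob])), 0.2)
  expect_error(group_glm_map(maps[1:2, ]), "at least 3")
})

test_that("adding a covariate uncorrelated with the effect leaves the slope unbiased", {
  d3 <- c(6, 6, 4)
  n <- 40
  set.seed(62)
  score <- rnorm(n)
  noise_cov <- rnorm(n)
  maps <- structure(outer(score, rep(0.8, prod(d3))) +
                      matrix(rnorm(n * prod(d3), sd = 0.5), n), dim3 = d3)
  m1 <- symptom_correlation_map(maps, score)
  m2 <- symptom_correlation_map(maps, score,
                                covariates = tibble::tibble(nc = noise_cov))
  # slope per SD of score ~ 0.8 * sd(score)
  expect_equal(mean(m1$beta), 0.8 * sd(score), tolerance = 0.05)
  expect_equal(mean(m2$beta), mean(m1$beta), tolerance = 0.02)
  expect_error(symptom_correlation_map(maps, rep(1, n)), "constant")
})

test_that("planted negative symptom association is found inside and not outside the region", {
  d3 <- c(10, 10, 6)
  n <- 40
  set.seed(63)
  score <- rnorm(n)
  blob <- array(FALSE, d3); blob[2:4, 2:4, 2:4] <- TRUE
  maps <- matrix(rnorm(n * prod(d3), sd = 0.4), n)
  maps[, as.vector(blob)] <- maps[, as.vector(blob)] - outer(score, rep(1, sum(blob)))
  maps <- structure(maps, dim3 = d3)
  covars <- tibble::tibble(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5))
  smap <- symptom_correlation_map(maps, score, covars)
  cl <- cluster_inference(smap, direction = "neg",
                          null_fun = perm_null_score(maps, score, covars),
                          n_perm = 200, seed = 4)
  expect_gte(nrow(cl), 1L)
  sig <- cl[cl$p_corrected < 0.05, ]
  expect_gte(nrow(sig), 1L)
  lab <- attr(cl, "label_map")
  detected <- lab %in% sig$label & lab > 0
  dice <- 2 * sum(detected & blob) / (sum(detected) + sum(blob))
  expect_gt(dice, 0.7)
  # the sign of the association is negative where planted
  expect_lt(mean(smap$z[blob]), 0)

  # an orthogonal extra covariate preserves the detected cluster set
  extra <- tibble::tibble(age = covars$age, sex = covars$sex,
                          cpz = rnorm(n))
  smap2 <- symptom_correlation_map(maps, score, extra)
  cl2 <- cluster_inference(smap2, direction = "neg")
  det2 <- attr(cl2, "label_map") > 0
  overlap <- sum(det2 & detected) / max(1, sum(det2 | detected))
  expect_gt(overlap, 0.8)
})

test_that("sign-flip permutation null keeps the one-sample FWE near its nominal level", {
  d3 <- c(6, 6, 4)
  set.seed(64)
  hits <- replicate(40, {
    maps <- structure(matrix(rnorm(12 * prod(d3)), 12), dim3 = d3)
    m <- group_glm_map(maps)
    cl <- cluster_inference(m, z_thresh = 2.3,
                            null_fun = perm_null_onesample(maps),
                            n_perm = 100, seed = sample.int(1e6, 1))
    nrow(cl) > 0 && any(cl$p_corrected < 0.05)
  })
  expect_lt(mean(hits), 0.25)  # loose bound at 40 replicates; exact level checked at scale elsewhere
})

test_that("ROI summaries average inside the mask and compare groups", {
  d3 <- c(6, 6, 4)
  mask <- array(FALSE, d3); mask[2:3, 2:3, 2] <- TRUE
  const_maps <- structure(matrix(7, 6, prod(d3)), dim3 = d3)
  out <- roi_summary(const_maps, mask)
  expect_equal(out$roi_mean, rep(7, 6))

  maps <- random_maps(30, d3, seed = 65)
  g <- rep(c("a", "b"), each = 15)
  same <- roi_summary(maps, mask, group = g)
  expect_lt(abs(attr(same, "comparison")$t_stat), 2.5)

  maps2 <- maps
  maps2[g == "b", as.vector(mask)] <- maps2[g == "b", as.vector(mask)] + 3
  diffd <- roi_summary(maps2, mask, group = g)
  cmp <- attr(diffd, "comparison")
  expect_lt(cmp$estimate, 0)           # group a minus group b
  expect_equal(abs(cmp$estimate), 3, tolerance = 1)
  expect_lt(cmp$p, 0.001)
  # covariate-adjusted route gives a similar difference
  cov_cmp <- attr(roi_summary(maps2, mask, group = g,
                              covariates = tibble::tibble(x = rnorm(30))),
                  "comparison")
  expect_equal(cov_cmp$estimate, -cmp$estimate, tolerance = 1)

  expect_error(roi_summary(maps, array(FALSE, d3)), "empty")
  expect_error(roi_summary(maps, mask[1:5]), "align")
})

test_that("cluster tables serialize to CSV", {
  z <- array(0, c(6, 6, 4)); z[2:3, 2:3, 2] <- 5
  cl <- cluster_inference(z)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cluster_csv(cl, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$size_voxels, cl$size_voxels)
})
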