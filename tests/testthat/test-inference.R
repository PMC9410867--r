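test_that("window planning matches the worked examples", {
  p1 <- plan_windows(c(96, 96, 96))
  expect_equal(nrow(p1$origins), 1L)
  expect_equal(as.vector(p1$origins[1, ]), c(1L, 1L, 1L))

  p2 <- plan_windows(c(144, 144, 144))
  expect_equal(nrow(p2$origins), 8L)
  expect_setequal(unique(p2$origins[, 1]), c(1L, 49L))

  p3 <- plan_windows(c(100, 100, 100))
  expect_setequal(unique(p3$origins[, 1]), c(1L, 5L))  # end-aligned 100-96
})

test_that("planned windows cover every voxel for random shapes", {
  set.seed(19)
  for (trial in 1:50) {
    shape <- sample(20:200, 3, replace = TRUE)
    size <- sample(c(16L, 32L, 96L), 1)
    plan <- plan_windows(shape, size = size, step = size %/% 2L)
    cover <- array(0L, plan$padded_shape)
    for (r in seq_len(nrow(plan$origins))) {
      o <- plan$origins[r, ]
      cover[o[1] + seq_len(size) - 1L, o[2] + seq_len(size) - 1L,
            o[3] + seq_len(size) - 1L] <- 1L
    }
    expect_true(all(cover == 1L))
    # origins in bounds
    expect_true(all(plan$origins >= 1L))
    expect_true(all(sweep(plan$origins, 2, plan$padded_shape - size + 1L,
                          "<=")))
  }
})

test_that("overlap fusion averages window predictions", {
  # model that predicts a constant depending on the window's mean intensity
  vol <- normalized_volume(array(0.5, c(24, 16, 16)), id = "v")
  plan <- plan_windows(c(24, 16, 16), size = 16L, step = 8L)
  expect_equal(nrow(plan$origins), 2L)
  calls <- 0L
  model <- function(patch) {
    calls <<- calls + 1L
    array(if (calls == 1L) 0.2 else 0.6, dim(patch))
  }
  fused <- predict_volume(model, vol, plan)
  # voxels covered by only the first window: 0.2; overlap: mean(0.2, 0.6)
  expect_equal(fused[1, 1, 1], 0.2)
  expect_equal(fused[12, 1, 1], 0.4)
  expect_equal(fused[20, 1, 1], 0.6)
  # max fusion takes the larger prediction on the overlap
  calls <- 0L
  fmax <- predict_volume(model, vol, plan, fusion = "max")
  expect_equal(fmax[12, 1, 1], 0.6)
})

test_that("background windows are skipped and an all-zero scan predicts zero", {
  vol <- normalized_volume(array(0, c(16, 16, 16)), id = "z")
  model <- function(patch) stop("model must not be called on background")
  fused <- predict_volume(model, vol, plan_windows(c(16, 16, 16), 16L, 8L))
  expect_true(all(fused == 0))
  # stitching: non-overlapping windows reproduce the per-window outputs
  vol2 <- normalized_volume(array(0.3, c(32, 16, 16)), id = "s")
  plan2 <- plan_windows(c(32, 16, 16), size = 16L, step = 16L)
  k <- 0L
  model2 <- function(patch) { k <<- k + 1L; array(k / 10, dim(patch)) }
  fused2 <- predict_volume(model2, vol2, plan2)
  expect_equal(unique(as.vector(fused2[1:16, , ])), 0.1)
  expect_equal(unique(as.vector(fused2[17:32, , ])), 0.2)
})

test_that("scans smaller than the window are padded and cropped back", {
  set.seed(33)
  vol <- normalized_volume(array(runif(10 * 12 * 20, 0.2, 1), c(10, 12, 20)),
                           id = "small")
  model <- function(patch) array(0.7, dim(patch))
  fused <- predict_volume(model, vol, plan_windows(dim(vol$voxels), 16L, 8L))
  expect_equal(dim(fused), c(10L, 12L, 20L))
  expect_true(all(fused == 0.7))
})

test_that("proposal extraction thresholds, filters and sorts correctly", {
  pm <- array(0, c(20, 20, 20))
  pm[2:11, 2:11, 2:6] <- 0.9    # 500 voxels at 0.9
  props <- extract_proposals(pm, threshold = 0.4, min_voxels = 300L)
  expect_length(props, 1L)
  expect_equal(props[[1]]$volume, 500L)
  expect_equal(props[[1]]$confidence, 0.9)

  # 299 voxels below the volume filter: dropped despite high probability
  pm2 <- array(0, c(20, 20, 20))
  pm2[2:11, 2:11, 2:4] <- 0.99  # 300
  pm2[2, 2, 2] <- 0             # -> 299
  expect_length(extract_proposals(pm2, 0.4, 300L), 0L)

  # two blobs sorted by descending confidence
  pm3 <- array(0, c(30, 30, 10))
  pm3[1:10, 1:10, 1:4] <- 0.5   # 400 voxels
  pm3[20:26, 20:26, 2:8] <- 0.8 # 343 voxels
  props3 <- extract_proposals(pm3, 0.4, 300L)
  expect_length(props3, 2L)
  expect_equal(sapply(props3, `[[`, "confidence"), c(0.8, 0.5))
  expect_equal(sapply(props3, `[[`, "volume"), c(343L, 400L))

  # threshold comparison is inclusive
  pm4 <- array(0, c(10, 10, 10))
  pm4[1:5, 1:5, 1:5] <- 0.4
  expect_length(extract_proposals(pm4, 0.4, 50L), 1L)
})

test_that("raising the threshold never increases surviving proposal volume", {
  set.seed(27)
  pm <- array(runif(18^3)^2, c(18, 18, 18))
  vols <- sapply(c(0.2, 0.4, 0.6, 0.8), function(t) {
    sum(vapply(extract_proposals(pm, t, 5L), `[[`, 1L, "volume"))
  })
  expect_true(all(diff(vols) <= 0))
})

test_that("proposal extraction agrees with the flood-fill + mean oracle", {
  set.seed(55)
  for (trial in 1:20) {
    d <- sample(6:14, 3, replace = TRUE)
    pm <- array(runif(prod(d)), d)
    thr <- runif(1, 0.3, 0.7)
    minv <- sample(1:5, 1)
    props <- extract_proposals(pm, thr, minv)
    ref <- oracle_label((pm >= thr) * 1L, 26L)
    keep <- if (max(ref) > 0L)
      which(tabulate(ref[ref > 0L], nbins = max(ref)) >= minv) else integer(0)
    expect_length(props, length(keep))
    got_conf <- sort(vapply(props, `[[`, 1, "confidence"))
    ref_conf <- sort(vapply(keep, function(k) mean(pm[ref == k]), 1))
    expect_equal(got_conf, ref_conf, tolerance = 1e-12)
  }
})
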