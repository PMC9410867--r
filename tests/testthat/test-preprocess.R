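test_that("HU binarization uses an inclusive threshold", {
  v <- tiny_volume(array(c(181, 100, 180, -1000, 900, 179, 0, 250),
                         c(2, 2, 2)))
  m <- binarize_hu(v, 180)
  expect_equal(as.vector(m$voxels), c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 1L))
})

test_that("binarization is monotone in the threshold", {
  set.seed(7)
  v <- tiny_volume(array(rnorm(12^3, 100, 300), c(12, 12, 12)))
  thresholds <- c(-100, 0, 180, 400)
  counts <- sapply(thresholds, function(t) sum(binarize_hu(v, t)$voxels))
  expect_true(all(diff(counts) <= 0))
  masks <- lapply(thresholds, function(t) binarize_hu(v, t)$voxels)
  for (i in 1:3)
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
})

test_that("small-component removal is strict and spacing-aware", {
  # 1 mm isotropic: 3999-voxel component removed, 4000-voxel kept
  m <- array(0L, c(20, 20, 25))
  m[1:16, 1:10, 1:25] <- 1L          # 4000 voxels
  m[18:20, 12:20, 4:20] <- 1L
  m[18, 12, 4] <- 1L
  big <- ct_mask(m, spacing = c(1, 1, 1))
  sizes <- table(label_components(big))
  # construct exactly 4000 and 3999 voxel components
  m2 <- array(0L, c(40, 20, 20))
  m2[1:10, 1:20, 1:20] <- 1L                 # 4000
  m2[13:22, 1:20, 1:20] <- 1L; m2[13, 1, 1] <- 0L  # 3999
  msk <- ct_mask(m2, spacing = c(1, 1, 1))
  out <- remove_small_components(msk, 4000)
  lab <- label_components(out)
  expect_equal(max(lab), 1L)
  expect_equal(sum(out$voxels), 4000L)

  # (2,2,2) mm spacing: 8 mm^3 per voxel, 500 voxels = 4000 mm^3 -> kept
  m3 <- array(0L, c(10, 10, 10))
  m3[1:5, 1:10, 1:10] <- 1L
  m3 <- m3 * 0L
  m3[1:5, 1:10, 1:10][1:500] <- 1L
  msk3 <- ct_mask(m3, spacing = c(2, 2, 2))
  expect_equal(sum(remove_small_components(msk3, 4000)$voxels), 500L)

  empty <- ct_mask(array(0L, c(5, 5, 5)))
  expect_equal(sum(remove_small_components(empty, 4000)$voxels), 0L)
})

test_that("small-component removal is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    m <- random_mask(c(15, 15, 15), p = 0.2)
    once <- remove_small_components(m, 30)
    twice <- remove_small_components(once, 30)
    expect_identical(once$voxels, twice$voxels)
  }
})

test_that("dilation grows by the 6-neighbourhood and is monotone", {
  m <- array(0L, c(7, 7, 7))
  m[4, 4, 4] <- 1L
  d1 <- dilate(ct_mask(m), 1, 1)
  expect_equal(sum(d1$voxels), 7L)  # centre + 6 face neighbours
  expect_equal(d1$voxels[4, 4, 4], 1L)
  expect_equal(d1$voxels[3, 4, 4] + d1$voxels[5, 4, 4] +
                 d1$voxels[4, 3, 4] + d1$voxels[4, 5, 4] +
                 d1$voxels[4, 4, 3] + d1$voxels[4, 4, 5], 6L)
  # radius * iterations steps: radius 1 x 3 equals radius 3 x 1
  d3a <- dilate(ct_mask(m), 1, 3)
  d3b <- dilate(ct_mask(m), 3, 1)
  expect_identical(d3a$voxels, d3b$voxels)
  # identity cases and monotone growth on random masks
  set.seed(3)
  r <- random_mask(c(10, 10, 10), 0.1)
  expect_identical(dilate(r, 0, 5)$voxels, r$voxels)
  expect_identical(dilate(r, 2, 0)$voxels, r$voxels)
  g <- dilate(r, 1, 2)
  expect_true(all(g$voxels >= r$voxels))
  expect_identical(dilate(ct_mask(array(0L, c(4, 4, 4))), 1, 2)$voxels,
                   array(0L, c(4, 4, 4)))
})

test_that("largest component keeps one maximal component, ties broken by scan order", {
  m <- array(0L, c(12, 12, 3))
  m[1:10, 1, 1] <- 1L     # size 10
  m[1:5, 5, 2] <- 1L      # size 5
  out <- largest_component(ct_mask(m))
  expect_equal(sum(out$voxels), 10L)
  expect_equal(sum(out$voxels[, 1, 1]), 10L)

  # equal sizes: the component whose first voxel comes first in array order
  m2 <- array(0L, c(10, 10, 1))
  m2[6:8, 6, 1] <- 1L
  m2[1:3, 2, 1] <- 1L
  out2 <- largest_component(ct_mask(m2))
  expect_equal(sum(out2$voxels[1:3, 2, 1]), 3L)
  expect_equal(sum(out2$voxels), 3L)

  expect_warning(largest_component(ct_mask(array(0L, c(4, 4, 4)))), "empty")
})

test_that("component labeling matches the flood-fill oracle", {
  set.seed(41)
  for (trial in 1:40) {
    d <- sample(4:12, 3, replace = TRUE)
    conn <- sample(c(6L, 18L, 26L), 1)
    m <- random_mask(d, p = runif(1, 0.1, 0.5))
    lab <- label_components(m, conn)
    ref <- oracle_label(m$voxels, conn)
    # same partition: identical component count and identical membership
    expect_equal(max(lab), max(ref))
    expect_identical(lab > 0L, ref > 0L)
    if (max(ref) > 0) {
      for (k in seq_len(max(ref))) {
        vox <- which(ref == k)
        expect_equal(length(unique(lab[vox])), 1L)
      }
      # sizes agree as multisets
      expect_equal(sort(as.integer(table(lab[lab > 0]))),
                   sort(as.integer(table(ref[ref > 0]))))
    }
  }
})

test_that("bone masking keeps inside values and fills outside", {
  set.seed(5)
  v <- tiny_volume(array(rnorm(4^3, 0, 200), c(4, 4, 4)))
  ones <- ct_mask(array(1L, c(4, 4, 4)))
  zeros <- ct_mask(array(0L, c(4, 4, 4)))
  expect_equal(apply_bone_mask(v, ones, -300)$voxels, v$voxels)
  expect_true(all(apply_bone_mask(v, zeros, -300)$voxels == -300))
  mix <- ct_mask(array(rep(c(0L, 1L), 32), c(4, 4, 4)))
  got <- apply_bone_mask(v, mix, -300)$voxels
  expect_equal(got[mix$voxels == 1L], v$voxels[mix$voxels == 1L])
  expect_true(all(got[mix$voxels == 0L] == -300))
  expect_error(apply_bone_mask(v, ct_mask(array(1L, c(3, 3, 3)))),
               "shapes differ")
})

test_that("bone-window normalization maps the window to [0,1] with clipping", {
  v <- tiny_volume(array(c(-300, 900, 300, 2000, -1000, 0, 600, -300),
                         c(2, 2, 2)))
  n <- window_normalize(v, level = 300, width = 1200)
  expect_equal(as.vector(n$voxels),
               c(0, 1, 0.5, 1, 0, 0.25, 0.75, 0), tolerance = 1e-12)
})

test_that("full pipeline removes debris, keeps the cage, handles air", {
  cfg <- phantom_config_easy()
  ph <- generate_phantom(cfg, seed = 202, id = "pp")
  res <- preprocess_pipeline(ph$volume)
  # components below the size filter (the debris) never reach the bone mask
  lab <- label_components(binarize_hu(ph$volume, 180))
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  small_vox <- which(lab > 0L & array(sizes[pmax(lab, 1L)] *
                                        prod(cfg$spacing) < 4000, dim(lab)))
  expect_gt(length(small_vox), 0L)
  expect_true(all(res$bone_mask$voxels[small_vox] == 0L))
  # ground-truth lesion voxels all stay inside the final bone mask
  expect_true(all(res$bone_mask$voxels[ph$gt$voxels == 1] == 1L))
  # rib skeleton (>=180 HU pre-noise regions) retained
  # all-air scan degenerates gracefully
  air <- ct_volume(array(-1000, c(48, 48, 48)))
  expect_warning(res0 <- preprocess_pipeline(air), "no bone")
  expect_equal(sum(res0$bone_mask$voxels), 0L)
  expect_true(all(res0$normalized$voxels == 0))
})

test_that("ribs joined to the spine only by dilation survive largest-component", {
  cfg <- phantom_config(shape = c(96L, 96L, 96L), n_rib_pairs = 3L,
                        rib_radius = 5, rib_spine_gap = 3, sternum = FALSE,
                        n_fractures = c(0L, 0L), n_debris = 0L)
  ph <- generate_phantom(cfg, seed = 9, id = "gap")
  m1 <- binarize_hu(ph$volume, 180)
  m2 <- remove_small_components(m1, 4000)
  ncomp_before <- max(label_components(m2))
  expect_gt(ncomp_before, 1L)  # spine and ribs separate pre-dilation
  res <- preprocess_pipeline(ph$volume)
  # after dilation + largest component, the whole cage is retained
  bone <- binarize_hu(ph$volume, 180)$voxels
  kept <- sum(bone * res$bone_mask$voxels) / sum(bone)
  expect_gte(kept, 0.99)
})

test_that("observed-min/max normalization mode rescales to the data range", {
  v <- tiny_volume(array(c(0, 150, 300, 600, 75, 225, 450, 525), c(2, 2, 2)))
  n <- window_normalize(v, level = 300, width = 1200, fixed = FALSE)
  expect_equal(min(n$voxels), 0)
  expect_equal(max(n$voxels), 1)
  expect_equal(n$voxels[1, 2, 1], 0.5)  # 300 HU is halfway of [0, 600]
  # constant input degenerates to zeros, not NaN
  cst <- window_normalize(tiny_volume(array(100, c(2, 2, 2))), fixed = FALSE)
  expect_true(all(cst$voxels == 0))
})
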