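test_that("global average pooling reduces each channel to its spatial mean", {
  F <- array(0, c(3, 2, 2, 2))
  F[1, , , ] <- 4.2                 # constant channel
  F[2, , , ] <- array(0:7, c(2, 2, 2))  # mean 3.5
  expect_equal(gap(F), c(4.2, 3.5, 0))
})

test_that("CFAM with zero weights halves both feature maps", {
  set.seed(2)
  F_e <- array(rnorm(2 * 3 * 3 * 3), c(2, 3, 3, 3))
  F_d <- array(rnorm(2 * 3 * 3 * 3), c(2, 3, 3, 3))
  w <- list(w = rep(0, 5), b = 0)
  r <- cfam_forward(F_e, F_d, w)
  expect_equal(r$F_e_prime, 0.5 * F_e, tolerance = 1e-12)
  expect_equal(r$F_d_prime, 0.5 * F_d, tolerance = 1e-12)
  expect_true(all(r$M_e == 0.5) && all(r$M_d == 0.5))
})

test_that("CFAM matches direct evaluation of its definition", {
  set.seed(31)
  for (trial in 1:6) {
    C <- sample(2:4, 1)
    sp <- sample(2:4, 3, replace = TRUE)
    n <- sample(c(3, 5), 1)
    F_e <- array(rnorm(C * prod(sp)), c(C, sp))
    F_d <- array(rnorm(C * prod(sp)), c(C, sp))
    w <- rnorm(n)
    b <- rnorm(1)
    got <- cfam_forward(F_e, F_d, list(w = w, b = b))
    ref <- oracle_cfam(F_e, F_d, w, b)
    expect_equal(got$F_e_prime, ref$F_e_prime, tolerance = 1e-5)
    expect_equal(got$F_d_prime, ref$F_d_prime, tolerance = 1e-5)
    expect_equal(got$M_e, ref$M_e, tolerance = 1e-5)
    expect_equal(got$M_d, ref$M_d, tolerance = 1e-5)
  }
  # hand-worked case: kernel [0,1,0] passes the statistic through sigmoid
  F_e <- array(1, c(2, 2, 2, 2)); F_e[2, , , ] <- 3
  F_d <- array(-1, c(2, 2, 2, 2)); F_d[2, , , ] <- 0.5
  got <- cfam_forward(F_e, F_d, list(w = c(0, 1, 0), b = 0))
  expect_equal(got$M_e, 1 / (1 + exp(-c(1, 3))), tolerance = 1e-12)
  expect_equal(got$M_d, 1 / (1 + exp(-c(-1, 0.5))), tolerance = 1e-12)
  expect_error(cfam_forward(F_e, F_d, list(w = c(1, 1), b = 0)), "odd")
  expect_error(cfam_forward(F_e, array(0, c(2, 2, 2, 3)),
                            list(w = c(0, 1, 0), b = 0)), "identical")
})

test_that("SGAM with zero weights halves the features; groups divide channels", {
  set.seed(4)
  F <- array(rnorm(4 * 2 * 2 * 2), c(4, 2, 2, 2))
  wz <- lapply(1:2, function(g) list(pw_w = rep(0, 2), pw_b = 0,
                                     sp_w = array(0, c(3, 3, 3)), sp_b = 0))
  out <- sgam_forward(F, wz, G = 2, kernel = 3)
  expect_equal(out, 0.5 * F, tolerance = 1e-12)
  expect_error(sgam_forward(F, wz, G = 3), "does not divide")
})

test_that("SGAM matches the nested-loop oracle, including G = 1", {
  set.seed(17)
  for (G in c(1, 2, 4)) {
    C <- 4
    sp <- c(3, 2, 3)
    F <- array(rnorm(C * prod(sp)), c(C, sp))
    w <- random_sgam_weights(C, G, kernel = 3)
    got <- sgam_forward(F, w, G, kernel = 3)
    ref <- oracle_sgam(F, w, G, kernel = 3)
    expect_equal(got, ref, tolerance = 1e-5)
  }
  # default 7^3 kernel on a small map
  C <- 2; sp <- c(4, 4, 4)
  F <- array(rnorm(C * prod(sp)), c(C, sp))
  w <- random_sgam_weights(C, 2, kernel = 7)
  expect_equal(sgam_forward(F, w, 2, kernel = 7),
               oracle_sgam(F, w, 2, kernel = 7), tolerance = 1e-5)
})

test_that("SGAM groups are independent: zeroing one group leaves others unchanged", {
  set.seed(23)
  F <- array(rnorm(4 * 3 * 3 * 3), c(4, 3, 3, 3))
  w <- random_sgam_weights(4, 2, kernel = 3)
  base <- sgam_forward(F, w, 2, kernel = 3)
  w2 <- w
  w2[[2]] <- list(pw_w = rep(0, 2), pw_b = 0,
                  sp_w = array(0, c(3, 3, 3)), sp_b = 0)
  alt <- sgam_forward(F, w2, 2, kernel = 3)
  expect_identical(alt[1:2, , , ], base[1:2, , , ])
  expect_equal(alt[3:4, , , ], 0.5 * F[3:4, , , ], tolerance = 1e-12)
})

test_that("attention gating preserves sign and strictly shrinks magnitude", {
  set.seed(12)
  F_e <- array(rnorm(2 * 8), c(2, 2, 2, 2))
  F_d <- array(rnorm(2 * 8), c(2, 2, 2, 2))
  r <- cfam_forward(F_e, F_d, list(w = rnorm(5), b = rnorm(1)))
  expect_true(all(sign(r$F_e_prime) == sign(F_e)))
  expect_true(all(abs(r$F_e_prime) < abs(F_e) | F_e == 0))
  w <- random_sgam_weights(2, 2, kernel = 3)
  out <- sgam_forward(F_d, w, 2, kernel = 3)
  expect_true(all(sign(out) == sign(F_d)))
  expect_true(all(abs(out) < abs(F_d) | F_d == 0))
})

test_that("encoder blocks preserve spatial shape and follow channel doubling", {
  net <- cfsg_model(model_config(base_channels = 4, sgam_groups = 2),
                    seed = 5)
  F <- array(runif(8^3), c(1, 8, 8, 8))
  out1 <- encoder_block(net, F, 1)
  expect_equal(dim(out1), c(4, 8, 8, 8))
  out2 <- encoder_block(net, array(rnorm(4 * 4^3), c(4, 4, 4, 4)), 2)
  expect_equal(dim(out2), c(8, 4, 4, 4))
  expect_true(all(is.finite(out1)))
})

test_that("encoder block with zero conv weights reduces to the projected residual", {
  net <- cfsg_model(model_config(base_channels = 4, sgam_groups = 2),
                    seed = 5)
  net$params[["e2.conv1"]]$w[] <- 0
  net$params[["e2.conv2"]]$w[] <- 0
  net$params[["e2.conv1"]]$b[] <- 0
  net$params[["e2.conv2"]]$b[] <- 0
  # identity-like projection: channel c of output copies channel c of input
  net$params[["e2.proj"]]$w[] <- 0
  for (c in 1:4) net$params[["e2.proj"]]$w[1, 1, 1, c, c] <- 1
  net$params[["e2.proj"]]$b[] <- 0
  x <- array(rnorm(4 * 3^3), c(4, 3, 3, 3))
  out <- encoder_block(net, x, 2)
  # conv path contributes only batch-norm of zero = 0, so the output is the
  # ReLU of the projected residual: channels 1-4 copy x, channels 5-8 are 0
  expect_equal(out[1:4, , , ], pmax(x, 0), tolerance = 1e-6)
  expect_true(all(out[5:8, , , ] == 0))
})

test_that("decoder block runs the CFAM/SGAM sequence and keeps shapes", {
  cfgs <- list(model_config(base_channels = 4, sgam_groups = 2),
               model_config(base_channels = 4, use_cfam = FALSE),
               model_config(base_channels = 4, use_sgam = FALSE),
               model_config(base_channels = 4, use_cfam = FALSE,
                            use_sgam = FALSE))
  F_e <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  F_d <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  for (cf in cfgs) {
    net <- cfsg_model(cf, seed = 3)
    out <- decoder_block(net, F_e, F_d, 1)
    expect_equal(dim(out), dim(F_e))
    expect_true(all(is.finite(out)))
  }
})

test_that("full forward pass maps patches to probabilities of the same shape", {
  net <- cfsg_model(model_config(base_channels = 2, sgam_groups = 2),
                    seed = 8)
  x <- array(runif(16^3), c(16, 16, 16))
  p <- cfsg_forward(net, x)
  expect_equal(dim(p), c(16, 16, 16))
  expect_true(all(p > 0 & p < 1))
  # determinism: same weights, same input -> identical output
  p2 <- cfsg_forward(net, x)
  expect_identical(p, p2)
  expect_error(cfsg_forward(net, array(0.1, c(12, 12, 12))), "divisible by 8")
})

test_that("model initialization is seeded and reproducible", {
  a <- cfsg_model(model_config(base_channels = 2, sgam_groups = 1), seed = 42)
  b <- cfsg_model(model_config(base_channels = 2, sgam_groups = 1), seed = 42)
  expect_identical(a$params, b$params)
  c <- cfsg_model(model_config(base_channels = 2, sgam_groups = 1), seed = 43)
  expect_false(identical(a$params, c$params))
})

test_that("attention modules strictly add parameters over the backbone", {
  base <- model_config(base_channels = 8, sgam_groups = 4)
  n_full <- count_params(cfsg_model(base, seed = 1))
  no_cfam <- modifyList(base, list(use_cfam = FALSE))
  class(no_cfam) <- "model_config"
  no_sgam <- modifyList(base, list(use_sgam = FALSE))
  class(no_sgam) <- "model_config"
  neither <- modifyList(base, list(use_cfam = FALSE, use_sgam = FALSE))
  class(neither) <- "model_config"
  n_nc <- count_params(cfsg_model(no_cfam, seed = 1))
  n_ns <- count_params(cfsg_model(no_sgam, seed = 1))
  n_bb <- count_params(cfsg_model(neither, seed = 1))
  expect_gt(n_full, n_nc)
  expect_gt(n_full, n_ns)
  expect_gt(n_nc, n_bb)
  expect_gt(n_ns, n_bb)
  # G = 1 variant exists and differs only in grouping
  g1 <- model_config(base_channels = 8, sgam_groups = 1)
  expect_true(count_params(cfsg_model(g1, seed = 1)) > n_bb)
})

test_that("model configuration validates its invariants", {
  expect_error(model_config(cfam_kernel = 4), "odd")
  expect_error(model_config(base_channels = 6, sgam_groups = 4), "divide")
  expect_silent(model_config(base_channels = 6, sgam_groups = 4,
                             use_sgam = FALSE))
})

test_that("checkpoints round-trip the model and its configuration", {
  tmp <- withr::local_tempdir()
  net <- cfsg_model(model_config(base_channels = 2, sgam_groups = 2),
                    seed = 19)
  p <- file.path(tmp, "ckpt.rds")
  save_checkpoint(net, p)
  back <- load_checkpoint(p)
  expect_identical(back$params, net$params)
  expect_identical(back$config, net$config)
  x <- array(runif(8^3), c(8, 8, 8))
  expect_identical(cfsg_forward(back, x), cfsg_forward(net, x))
})

test_that("the two-convolution CFAM variant produces valid, distinct maps", {
  set.seed(77)
  F_e <- array(rnorm(2 * 27), c(2, 3, 3, 3))
  F_d <- array(rnorm(2 * 27), c(2, 3, 3, 3))
  w <- list(w_e = rnorm(5), b_e = rnorm(1), w_d = rnorm(5), b_d = rnorm(1))
  r <- cfam_forward(F_e, F_d, w, shared = FALSE)
  expect_equal(dim(r$F_e_prime), dim(F_e))
  expect_true(all(r$M_e > 0 & r$M_e < 1))
  expect_true(all(r$M_d > 0 & r$M_d < 1))
  # a model built with the unshared variant trains its separate kernels
  cfgu <- model_config(base_channels = 4, sgam_groups = 2,
                       cfam_shared = FALSE)
  net <- cfsg_model(cfgu, seed = 2)
  expect_true(all(c("w_e", "w_d") %in% names(net$params[["d1.cfam"]])))
  p <- cfsg_forward(net, array(runif(8^3), c(8, 8, 8)))
  expect_true(all(p > 0 & p < 1))
})
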