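#' Fit the CFSG U-Net rib-fracture detector
#'
#' Trains the dual-attention residual U-Net on preprocessed scans with the
#' combined Dice + weighted-BCE objective, balanced 60/40 positive/negative
#' patch sampling and flip/rotation/scale augmentation, using Adam. Scans
#' are split by whole scan into training and validation sets (the published
#' protocol reserves roughly one scan in eight for validation within the
#' train+validation pool); the returned model carries the weights of the
#' epoch with the lowest validation loss.
#'
#' @param x list of [normalized_volume] scans (preprocessed network inputs).
#' @param y list of voxel-aligned fracture [ct_mask] ground truths.
#' @param model a [model_config] describing the architecture.
#' @param control a [train_config] with optimizer and sampling settings.
#' @param val optional list with elements `x`, `y`: explicit validation
#'   scans. If `NULL`, a split is made from `x`/`y` when enough scans exist.
#' @param verbose print per-epoch losses.
#' @return Object of class `cfsg_unet`: the fitted `model` (weights +
#'   batch-norm state), `history` (per-epoch losses), `config`, `control`.
#' @seealso [predict.cfsg_unet()], [froc()]
#' @export
cfsg_fit <- function(x, y, model = model_config(), control = train_config(),
                     val = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "model_config"), inherits(control, "train_config"))
  if (length(x) == 0L) stop("empty training dataset")
  if (length(x) != length(y)) stop("x and y lengths differ")
  set.seed(control$seed)
  if (is.null(val)) {
    n <- length(x)
    nval <- if (n >= 4L) max(1L, round(n / 8)) else 0L
    if (nval > 0L) {
      vi <- sample.int(n, nval)
      val <- list(x = x[vi], y = y[vi])
      x <- x[-vi]
      y <- y[-vi]
    }
  }
  net <- cfsg_model(model, seed = sample.int(.Machine$integer.max, 1L))
  opt <- adam_init(net$params)
  # fixed validation patch set, evaluated every epoch in eval mode
  val_patches <- NULL
  if (!is.null(val) && length(val$x) > 0L) {
    val_patches <- unlist(lapply(seq_along(val$x), function(i)
      sample_patches(val$x[[i]], val$y[[i]],
                     n = max(4L, control$patches_per_epoch %/%
                               (4L * length(val$x))),
                     cfg = control)), recursive = FALSE)
  }
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_dice = numeric(), train_wbce = numeric(),
                     val_loss = numeric())
  best <- list(loss = Inf, params = net$params, bn = as.list(net$bn$bn))
  nscan <- length(x)
  for (ep in seq_len(control$epochs)) {
    scan_of <- sample.int(nscan, control$patches_per_epoch, replace = TRUE)
    patches <- vector("list", control$patches_per_epoch)
    for (t in seq_along(scan_of)) {
      s <- sample_patches(x[[scan_of[t]]], y[[scan_of[t]]], 1L,
                          cfg = control)[[1]]
      if (control$augment)
        s <- augment(s, control$rot_deg, control$scale_range)
      patches[[t]] <- s
    }
    ep_tot <- ep_dice <- ep_wbce <- 0
    nb <- 0L
    for (b0 in seq(1L, length(patches), by = control$batch_size)) {
      batch <- patches[b0:min(b0 + control$batch_size - 1L, length(patches))]
      st <- train_step(net, batch, control, opt)
      net$params <- st$params
      ep_tot <- ep_tot + st$total
      ep_dice <- ep_dice + st$dice
      ep_wbce <- ep_wbce + st$wbce
      nb <- nb + 1L
    }
    vloss <- if (!is.null(val_patches))
      eval_loss(net, val_patches, control) else ep_tot / nb
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_tot / nb,
                                   train_dice = ep_dice / nb,
                                   train_wbce = ep_wbce / nb,
                                   val_loss = vloss))
    if (vloss < best$loss)
      best <- list(loss = vloss, params = net$params,
                   bn = as.list(net$bn$bn))
    if (verbose)
      message(sprintf("[train] epoch %3d  train %.4f  val %.4f",
                      ep, ep_tot / nb, vloss))
  }
  net$params <- best$params
  net$bn <- local({
    e <- new.env(parent = emptyenv())
    e$bn <- best$bn
    e
  })
  structure(list(model = net, config = model, control = control,
                 history = hist, best_val = best$loss,
                 call = match.call()),
            class = "cfsg_unet")
}

batch_tensor <- function(patches, field) {
  d <- dim(patches[[1]][[field]])
  arr <- array(0, c(d, 1L, length(patches)))
  for (i in seq_along(patches)) arr[, , , 1L, i] <- patches[[i]][[field]]
  arr
}

train_step <- function(net, batch, control, opt) {
  xb <- batch_tensor(batch, "image")
  yb <- batch_tensor(batch, "label")
  B <- length(batch)
  tape <- ag_tape()
  pw <- wrap_params(net$params)
  pred <- net_forward(tape, pw, ag_leaf(xb), net$config, net$bn, train = TRUE)
  tot <- dc <- wb <- 0
  g <- array(0, dim(pred$value))
  for (i in seq_len(B)) {
    p_i <- pred$value[, , , 1L, i]
    y_i <- yb[, , , 1L, i]
    lv <- total_loss(p_i, y_i, alpha = control$alpha)
    tot <- tot + lv$total / B
    dc <- dc + lv$dice / B
    wb <- wb + lv$wbce / B
    g[, , , 1L, i] <- total_loss_grad(p_i, y_i, alpha = control$alpha) / B
  }
  ag_backward(tape, pred, seed_grad = g)
  grads <- lapply(pw, function(layer) lapply(layer, function(nd) {
    if (is.null(nd$grad)) array(0, dim(nd$value) %||% length(nd$value))
    else nd$grad
  }))
  list(total = tot, dice = dc, wbce = wb,
       params = adam_step(net$params, grads, opt, control))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eval_loss <- function(net, patches, control) {
  tot <- 0
  for (p in patches) {
    pr <- cfsg_forward(net, p$image, train = FALSE)
    tot <- tot + total_loss(pr, p$label, alpha = control$alpha)$total
  }
  tot / length(patches)
}

adam_init <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(layer) lapply(layer, function(p) p * 0))
  e$v <- e$m
  e$t <- 0L
  e
}

adam_step <- function(params, grads, opt, control) {
  opt$t <- opt$t + 1L
  b1 <- control$beta1; b2 <- control$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (ln in names(params)) {
    for (pn in names(params[[ln]])) {
      p <- params[[ln]][[pn]]
      g <- grads[[ln]][[pn]] + control$weight_decay * p
      m <- b1 * opt$m[[ln]][[pn]] + (1 - b1) * g
      v <- b2 * opt$v[[ln]][[pn]] + (1 - b2) * g * g
      opt$m[[ln]][[pn]] <- m
      opt$v[[ln]][[pn]] <- v
      params[[ln]][[pn]] <-
        p - control$lr * (m / c1) / (sqrt(v / c2) + control$adam_eps)
    }
  }
  params
}

#' @export
print.cfsg_unet <- function(x, ...) {
  cat("Fitted CFSG U-Net rib-fracture detector\n")
  print(x$model)
  n <- nrow(x$history)
  cat(sprintf("%d epochs; final train loss %.4f; best validation loss %.4f\n",
              n, x$history$train_loss[n], x$best_val))
  invisible(x)
}

#' @export
summary.cfsg_unet <- function(object, ...) {
  cat("Fitted CFSG U-Net rib-fracture detector\n\n")
  print(object$model)
  cfgs <- object$control
  cat(sprintf("Objective: Dice + weighted BCE (alpha = %g)\n", cfgs$alpha))
  cat(sprintf("Optimizer: Adam lr %g, beta (%g, %g), weight decay %g\n",
              cfgs$lr, cfgs$beta1, cfgs$beta2, cfgs$weight_decay))
  cat(sprintf("Sampling: %d^3 patches, %.0f%% positive, %d per epoch\n",
              cfgs$patch_size, 100 * cfgs$pos_fraction,
              cfgs$patches_per_epoch))
  cat("\nLoss history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.cfsg_unet <- function(object, ...) object$model$params

#' @export
plot.cfsg_unet <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "total loss",
                 ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", legend = c("train", "validation"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
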