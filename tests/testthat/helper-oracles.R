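# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different algorithms from the package internals
# (queue-based flood fill in R, nested-loop convolutions, exhaustive
# threshold enumeration).

# connected-component labeling by explicit BFS over an offset table
oracle_label <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  l1 <- rowSums(abs(offs))
  offs <- offs[l1 > 0 & switch(as.character(connectivity),
                               "6" = l1 <= 1, "18" = l1 <= 2, "26" = TRUE), ]
  lab <- array(0L, d)
  nxt <- 0L
  stack <- integer(sum(mask != 0))
  for (v in which(mask != 0)) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    top <- 1L
    stack[1L] <- v
    lab[v] <- nxt
    while (top > 0L) {
      u <- stack[top]
      top <- top - 1L
      uc <- arrayInd(u, d)
      for (r in seq_len(nrow(offs))) {
        w <- uc + offs[r, ]
        if (any(w < 1) || any(w > d)) next
        wi <- w[1] + d[1] * (w[2] - 1 + d[2] * (w[3] - 1))
        if (mask[wi] != 0 && lab[wi] == 0L) {
          lab[wi] <- nxt
          top <- top + 1L
          stack[top] <- wi
        }
      }
    }
  }
  lab
}

# direct evaluation of the channel-fusion attention definition:
# GAP statistics, concatenation, 1D convolution, sigmoid, reweighting
oracle_cfam <- function(F_e, F_d, w, b) {
  C <- dim(F_e)[1]
  s_e <- sapply(seq_len(C), function(c) mean(F_e[c, , , ]))
  s_d <- sapply(seq_len(C), function(c) mean(F_d[c, , , ]))
  s <- c(s_e, s_d)
  n <- length(w)
  pad <- (n - 1) / 2
  z <- numeric(2 * C)
  for (t in seq_len(2 * C)) {
    acc <- b
    for (u in seq_len(n)) {
      src <- t + u - 1 - pad
      if (src >= 1 && src <= 2 * C) acc <- acc + w[u] * s[src]
    }
    z[t] <- acc
  }
  a <- 1 / (1 + exp(-z))
  Fe2 <- F_e
  Fd2 <- F_d
  for (c in seq_len(C)) {
    Fe2[c, , , ] <- a[c] * F_e[c, , , ]
    Fd2[c, , , ] <- a[C + c] * F_d[c, , , ]
  }
  list(F_e_prime = Fe2, F_d_prime = Fd2, M_e = a[seq_len(C)],
       M_d = a[C + seq_len(C)])
}

# direct evaluation of the grouped spatial attention definition
oracle_sgam <- function(F, weights, G, kernel = 7L) {
  C <- dim(F)[1]
  sp <- dim(F)[2:4]
  Cg <- C / G
  out <- F
  pad <- (kernel - 1) / 2
  for (g in seq_len(G)) {
    chans <- (g - 1) * Cg + seq_len(Cg)
    wg <- weights[[g]]
    s <- array(wg$pw_b, sp)
    for (i in 1:sp[1]) for (j in 1:sp[2]) for (k in 1:sp[3])
      s[i, j, k] <- wg$pw_b + sum(wg$pw_w * F[chans, i, j, k])
    att <- array(0, sp)
    for (i in 1:sp[1]) for (j in 1:sp[2]) for (k in 1:sp[3]) {
      acc <- wg$sp_b
      for (u in 1:kernel) for (v in 1:kernel) for (t in 1:kernel) {
        si <- i + u - 1 - pad; sj <- j + v - 1 - pad; sk <- k + t - 1 - pad
        if (si >= 1 && si <= sp[1] && sj >= 1 && sj <= sp[2] &&
            sk >= 1 && sk <= sp[3])
          acc <- acc + wg$sp_w[u, v, t] * s[si, sj, sk]
      }
      att[i, j, k] <- 1 / (1 + exp(-acc))
    }
    for (c in chans) out[c, , , ] <- att * F[c, , , ]
  }
  out
}

# exhaustive FROC: every distinct confidence as threshold, counts rebuilt
# from the raw records each time
oracle_froc <- function(evaluations, rates = c(0.5, 1, 2, 4, 8)) {
  total_gt <- sum(sapply(evaluations, `[[`, "n_gt"))
  nscan <- length(evaluations)
  rec <- do.call(rbind, lapply(evaluations, `[[`, "records"))
  sens <- sapply(rates, function(r) {
    best <- 0
    for (t in unique(rec$confidence)) {
      tp <- sum(rec$confidence >= t & rec$tp)
      fp <- sum(rec$confidence >= t & !rec$tp)
      if (fp / nscan <= r) best <- max(best, tp / total_gt)
    }
    best
  })
  list(sensitivity = 100 * sens, average = mean(100 * sens))
}

# random small binary mask fixture
random_mask <- function(d, p = 0.3, spacing = c(1, 1, 1)) {
  ct_mask(array(stats::rbinom(prod(d), 1, p), d), spacing = spacing)
}

tiny_volume <- function(values, spacing = c(1, 1, 1)) {
  ct_volume(values, spacing = spacing)
}

# random per-group SGAM weights for C channels in G groups
random_sgam_weights <- function(C, G, kernel = 7L, sd = 0.3) {
  lapply(seq_len(G), function(g) list(
    pw_w = array(rnorm(C / G, sd = sd), c(C / G)),
    pw_b = rnorm(1, sd = sd),
    sp_w = array(rnorm(kernel^3, sd = sd), c(kernel, kernel, kernel)),
    sp_b = rnorm(1, sd = sd)))
}

make_proposal <- function(voxels, confidence, id = "scan", component = 1L) {
  structure(list(voxels = as.integer(voxels), confidence = confidence,
                 volume = length(voxels),
                 bbox = rbind(c(1, 1, 1), c(1, 1, 1)), id = id,
                 component = as.integer(component)),
            class = "detection_proposal")
}
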