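# Independent double-precision forward pass of the dense-block network,
# written directly from its definition (padded 3x3 convolutions, dense
# concatenation, leaky ReLU, stride-2 transitions, flatten, softmax
# cross-entropy with L2). Used to finite-difference the training loss as an
# oracle for the analytic gradients of the compiled implementation.

oracle_conv3 <- function(x, W, b, stride, slope) {
  d <- dim(x); H <- d[1]; Cin <- d[3]; N <- d[4]
  Ho <- if (stride == 1) H else H %/% 2
  xp <- array(0, c(H + 2, H + 2, Cin, N))
  xp[2:(H + 1), 2:(H + 1), , ] <- x
  Cout <- dim(W)[4]
  y <- array(0, c(Ho, Ho, Cout, N))
  for (co in seq_len(Cout)) {
    acc <- array(0, c(Ho, Ho, N))
    for (ki in 1:3) for (kj in 1:3) for (ci in seq_len(Cin)) {
      hi <- seq(ki, by = stride, length.out = Ho)
      wi <- seq(kj, by = stride, length.out = Ho)
      acc <- acc + xp[hi, wi, ci, , drop = FALSE][, , 1, ] * W[ki, kj, ci, co]
    }
    v <- acc + b[co]
    y[, , co, ] <- ifelse(v >= 0, v, slope * v)
  }
  y
}

oracle_cnn_loss <- function(weights, x, y0, slope, lambda) {
  N <- dim(x)[4]
  a <- x
  li <- 1
  for (blk in 1:3) {
    for (l in 1:3) {
      out <- oracle_conv3(a, weights$conv_w[[li]], weights$conv_b[[li]], 1, slope)
      grown <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(out)[3], N))
      grown[, , seq_len(dim(a)[3]), ] <- a
      grown[, , dim(a)[3] + seq_len(dim(out)[3]), ] <- out
      a <- grown
      li <- li + 1
    }
    a <- oracle_conv3(a, weights$conv_w[[li]], weights$conv_b[[li]], 2, slope)
    li <- li + 1
  }
  Fm <- matrix(a, nrow = prod(dim(a)[1:3]), ncol = N)
  logits <- t(weights$fc_w) %*% Fm + weights$fc_b
  ce <- 0
  for (n in seq_len(N)) {
    lg <- logits[, n] - max(logits[, n])
    p <- exp(lg) / sum(exp(lg))
    ce <- ce - log(max(p[y0[n] + 1], 1e-300))
  }
  l2 <- sum(vapply(weights$conv_w, function(w) sum(w^2), numeric(1))) +
    sum(weights$fc_w^2)
  ce / N + lambda * l2
}
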