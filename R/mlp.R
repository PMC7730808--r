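# Multi-layer perceptron: d -> hidden[1] -> hidden[2] -> 1, ReLU hidden
# units with inverted dropout, sigmoid output, binary cross-entropy, Adam.
# Pure matrix ops; deterministic under set.seed.

mlp_init <- function(d, hidden) {
  dims <- c(d, hidden, 1L)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

mlp_train <- function(X, y, hidden = c(100L, 50L), dropout = 0.5,
                      lr = 0.001, epochs = 100L, batch = 32L, seed = 1L) {
  set.seed(seed)
  n <- nrow(X)
  net <- mlp_init(ncol(X), hidden)
  nl <- length(net$W)
  adam <- list(mW = lapply(net$W, function(w) w * 0),
               vW = lapply(net$W, function(w) w * 0),
               mb = lapply(net$b, function(bb) bb * 0),
               vb = lapply(net$b, function(bb) bb * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  epoch_loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      B <- length(idx)
      # forward with inverted dropout on hidden activations
      acts <- vector("list", nl)
      masks <- vector("list", nl - 1L)
      a <- Xb
      for (l in seq_len(nl - 1L)) {
        z <- sweep(a %*% net$W[[l]], 2L, net$b[[l]], "+")
        h <- pmax(z, 0)
        if (dropout > 0) {
          m <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h))
          h <- h * m / (1 - dropout)
          masks[[l]] <- m
        }
        acts[[l]] <- list(input = a, relu = h, z = z)
        a <- h
      }
      zo <- sweep(a %*% net$W[[nl]], 2L, net$b[[nl]], "+")
      p <- 1 / (1 + exp(-zo))
      tot <- tot + mean(-(yb * log(pmax(p, 1e-15)) +
                          (1 - yb) * log(pmax(1 - p, 1e-15))))
      nb <- nb + 1L
      # backward
      dz <- (p - yb) / B
      grads_W <- vector("list", nl)
      grads_b <- vector("list", nl)
      grads_W[[nl]] <- crossprod(a, dz)
      grads_b[[nl]] <- colSums(dz)
      da <- dz %*% t(net$W[[nl]])
      for (l in rev(seq_len(nl - 1L))) {
        if (dropout > 0) da <- da * masks[[l]] / (1 - dropout)
        dzl <- da * (acts[[l]]$z > 0)
        grads_W[[l]] <- crossprod(acts[[l]]$input, dzl)
        grads_b[[l]] <- colSums(dzl)
        if (l > 1L) da <- dzl %*% t(net$W[[l]])
      }
      # Adam with bias correction
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (l in seq_len(nl)) {
        adam$mW[[l]] <- b1 * adam$mW[[l]] + (1 - b1) * grads_W[[l]]
        adam$vW[[l]] <- b2 * adam$vW[[l]] + (1 - b2) * grads_W[[l]]^2
        net$W[[l]] <- net$W[[l]] -
          lr * corr * adam$mW[[l]] / (sqrt(adam$vW[[l]]) + eps)
        adam$mb[[l]] <- b1 * adam$mb[[l]] + (1 - b1) * grads_b[[l]]
        adam$vb[[l]] <- b2 * adam$vb[[l]] + (1 - b2) * grads_b[[l]]^2
        net$b[[l]] <- net$b[[l]] -
          lr * corr * adam$mb[[l]] / (sqrt(adam$vb[[l]]) + eps)
      }
    }
    epoch_loss[ep] <- tot / nb
  }
  list(W = net$W, b = net$b, epoch_loss = epoch_loss)
}

mlp_forward <- function(fit, X) {
  nl <- length(fit$W)
  a <- X
  for (l in seq_len(nl - 1L))
    a <- pmax(sweep(a %*% fit$W[[l]], 2L, fit$b[[l]], "+"), 0)
  zo <- sweep(a %*% fit$W[[nl]], 2L, fit$b[[nl]], "+")
  as.numeric(1 / (1 + exp(-zo)))
}
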