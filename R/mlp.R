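# Minimal feed-forward neural network used as the ANN classifier: four
# hidden layers of configurable width, logistic hidden activations, a
# two-unit softmax output trained by full-batch gradient descent with
# momentum on the cross-entropy loss. Inputs are standardized with the
# training statistics. Initialization and training are driven entirely by
# the caller's RNG state, so results are reproducible under a seed.

mlp_init <- function(sizes) {
  W <- list(); b <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                  sd = 1 / sqrt(sizes[i])),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- rep(0, sizes[i + 1L])
  }
  list(W = W, b = b)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(net, x) {
  L <- length(net$W)
  a <- list(x)
  for (i in seq_len(L - 1L))
    a[[i + 1L]] <- sigmoid(sweep(a[[i]] %*% net$W[[i]], 2L, net$b[[i]], "+"))
  z <- sweep(a[[L]] %*% net$W[[L]], 2L, net$b[[L]], "+")
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  list(activations = a, probs = p)
}

mlp_train <- function(x, y, hidden, epochs = 200L, lr = 1,
                      momentum = 0.9) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd); scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  t_mat <- cbind(benign = y == "benign", malignant = y == "malignant") * 1
  sizes <- c(ncol(x), hidden, 2L)
  net <- mlp_init(sizes)
  L <- length(net$W)
  vW <- lapply(net$W, function(w) w * 0)
  vb <- lapply(net$b, function(b) b * 0)
  n <- nrow(xs)
  for (ep in seq_len(epochs)) {
    fw <- mlp_forward(net, xs)
    delta <- (fw$probs - t_mat) / n  # softmax + cross-entropy gradient
    for (i in L:1) {
      gW <- t(fw$activations[[i]]) %*% delta
      gb <- colSums(delta)
      vW[[i]] <- momentum * vW[[i]] - lr * gW
      vb[[i]] <- momentum * vb[[i]] - lr * gb
      if (i > 1L) {
        a <- fw$activations[[i]]
        delta <- (delta %*% t(net$W[[i]])) * a * (1 - a)
      }
      net$W[[i]] <- net$W[[i]] + vW[[i]]
      net$b[[i]] <- net$b[[i]] + vb[[i]]
    }
  }
  list(net = net, center = center, scale = scale)
}

mlp_predict <- function(model, x) {
  xs <- sweep(sweep(as.matrix(x), 2L, model$center), 2L, model$scale, "/")
  mlp_forward(model$net, xs)$probs[, 2L]
}
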