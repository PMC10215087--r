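# Independent oracles used across the test files. These deliberately avoid
# the package's own computation paths: counting is done by explicit
# per-layer enumeration, and the reference forward pass is a straight-line
# plain-R re-implementation of the two-stage explicit network.

# brute-force scalar count of one two-conv node, enumerating each layer
oracle_node_count <- function(a, k) {
  conv1_w <- 3 * 3 * a * k
  conv1_b <- k
  norm1 <- k + k
  conv2_w <- 3 * 3 * k * k
  conv2_b <- k
  norm2 <- k + k
  conv1_w + conv1_b + norm1 + conv2_w + conv2_b + norm2
}

oracle_total_count <- function(backbone, d, k, in_channels, classes) {
  s <- if (backbone == "E") d else d / 2
  total <- oracle_node_count(in_channels, k)
  for (i in seq_len(s)) total <- total + oracle_node_count(k * i, k)
  if (backbone != "E")
    for (i in seq_len(s)) total <- total + oracle_node_count(k * s, k)
  total + oracle_node_count(k, k) + (k * classes + classes)
}

# ---- straight-line reference forward pass (orientation L, backbone E,
# depth 2, width 1, single channel) ------------------------------------------

ref_conv3x3 <- function(x, w, b) {
  # x: H x W matrix; w: 3x3 matrix (indexed [kh, kw]); zero padding
  H <- nrow(x); W <- ncol(x)
  xp <- matrix(0, H + 2, W + 2)
  xp[2:(H + 1), 2:(W + 1)] <- x
  y <- matrix(0, H, W)
  for (i in 1:H)
    for (j in 1:W)
      y[i, j] <- sum(xp[i:(i + 2), j:(j + 2)] * w) + b
  y
}

ref_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  mu <- mean(x)
  va <- mean(x^2) - mu^2
  gamma * (x - mu) / sqrt(va + eps) + beta
}

ref_lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

# node with 1 input / 1 output channel, weights from the package node
ref_node_k1 <- function(x, p) {
  w1 <- matrix(p$conv1$w[, 1], 3, 3)
  h <- ref_lrelu(ref_instnorm(ref_conv3x3(x, w1, p$conv1$b[1]),
                              p$norm1$gamma[1], p$norm1$beta[1]))
  w2 <- matrix(p$conv2$w[, 1], 3, 3)
  ref_lrelu(ref_instnorm(ref_conv3x3(h, w2, p$conv2$b[1]),
                         p$norm2$gamma[1], p$norm2$beta[1]))
}

ref_maxpool2 <- function(x) {
  H <- nrow(x) / 2; W <- ncol(x) / 2
  y <- matrix(0, H, W)
  for (i in 1:H)
    for (j in 1:W)
      y[i, j] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  y
}

ref_bilinear2x <- function(x) {
  H <- nrow(x); W <- ncol(x)
  src <- function(o, n) {  # 1-based output index -> clamped source coords
    s <- ((o - 1) + 0.5) / 2 - 0.5
    s <- min(max(s, 0), n - 1)
    i0 <- floor(s)
    list(i0 = i0 + 1, i1 = min(i0 + 1, n - 1) + 1, f = s - i0)
  }
  y <- matrix(0, 2 * H, 2 * W)
  for (i in 1:(2 * H)) {
    a <- src(i, H)
    for (j in 1:(2 * W)) {
      b <- src(j, W)
      y[i, j] <- (1 - b$f) * ((1 - a$f) * x[a$i0, b$i0] + a$f * x[a$i1, b$i0]) +
        b$f * ((1 - a$f) * x[a$i0, b$i1] + a$f * x[a$i1, b$i1])
    }
  }
  y
}

# full reference trace of the explicit two-stage network: y1 = y0 + U(e1)
# + U(e2), with e1 = E1(D(y0)) and e2 = E2(D(y0), D(e1)), all at width 1.
ref_forward_LE2_k1 <- function(model, img) {
  x <- img[, , 1]
  y0 <- ref_node_k1(x, model$pre)
  d1 <- ref_maxpool2(y0)
  e1 <- ref_node_k1(d1, model$nodes[[1]])
  # stage 2 at divisor 4: concatenate D(y0) and D(e1); width 1 each ->
  # a 2-channel input, handled channel-by-channel against conv1's columns
  s2_in <- list(ref_maxpool2(ref_maxpool2(y0)), ref_maxpool2(e1))
  p <- model$nodes[[2]]
  w_y0 <- matrix(p$conv1$w[1:9, 1], 3, 3)
  w_e1 <- matrix(p$conv1$w[10:18, 1], 3, 3)
  c1 <- ref_conv3x3(s2_in[[1]], w_y0, 0) +
    ref_conv3x3(s2_in[[2]], w_e1, p$conv1$b[1])
  h <- ref_lrelu(ref_instnorm(c1, p$norm1$gamma[1], p$norm1$beta[1]))
  w2 <- matrix(p$conv2$w[, 1], 3, 3)
  e2 <- ref_lrelu(ref_instnorm(ref_conv3x3(h, w2, p$conv2$b[1]),
                               p$norm2$gamma[1], p$norm2$beta[1]))
  y1 <- y0 + ref_bilinear2x(e1) + ref_bilinear2x(ref_bilinear2x(e2))
  pp <- model$post
  post_h <- ref_node_k1(y1, pp$node)
  lapply(seq_along(pp$final$b), function(cl)
    post_h * pp$final$w[1, cl] + pp$final$b[cl])
}

# small deterministic dataset for smoke training tests
tiny_dataset <- function(n = 8, seed = 99, size = 32L, classes = 2L) {
  synth_generate(synth_spec(n_cases = n, image_size = c(size, size),
                            num_classes = classes, seed = seed))
}

# straight-line loss oracle: CE + negated mean foreground soft Dice
oracle_dice_ce <- function(logits, labels, eps = 1e-5) {
  d <- dim(logits)
  C <- d[3]
  p <- array(0, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      z <- logits[i, j, ]
      p[i, j, ] <- exp(z - max(z)) / sum(exp(z - max(z)))
    }
  ce <- 0
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      ce <- ce - log(p[i, j, labels[i, j] + 1])
  ce <- ce / (d[1] * d[2])
  dice <- numeric(C - 1)
  for (cl in seq_len(C - 1)) {
    t <- labels == cl
    inter <- sum(p[, , cl + 1][t])
    dice[cl] <- (2 * inter + eps) / (sum(p[, , cl + 1]) + sum(t) + eps)
  }
  list(ce = ce, loss = ce - mean(dice))
}
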