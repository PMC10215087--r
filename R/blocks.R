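# Network building blocks: two-conv stage subnetworks, pre-/post-processors,
# and the three resampling operators (max-pool down, bilinear up). Every
# layer has a forward that caches what its backward needs; tensors are R
# arrays with dim = c(H, W, C).

LRELU_SLOPE <- 0.01
NORM_EPS <- 1e-5

# ---- parameter constructors -------------------------------------------------

new_conv <- function(in_channels, out_channels, ksize = 3L) {
  stopifnot(in_channels >= 1L, out_channels >= 1L)
  fan_in <- ksize * ksize * in_channels
  # He initialization for the leaky rectifier
  sd <- sqrt(2 / ((1 + LRELU_SLOPE^2) * fan_in))
  list(w = matrix(stats::rnorm(fan_in * out_channels, sd = sd),
                  nrow = fan_in, ncol = out_channels),
       b = numeric(out_channels), k = as.integer(ksize))
}

new_norm <- function(channels) {
  list(gamma = rep(1, channels), beta = numeric(channels))
}

#' Create a two-convolution stage subnetwork
#'
#' Every stage node of the network is the same shape: a 3x3 convolution
#' `a -> k` and a 3x3 convolution `k -> k`, each followed by per-channel
#' instance normalization with learnable affine and a leaky rectifier.
#' Spatial size is preserved ("same" padding); the output always has `k`
#' channels regardless of `a`.
#'
#' @param in_channels Channels consumed (`a`).
#' @param out_channels Channels produced (`k`).
#' @return A parameter list of class `rkseg_node`.
#' @export
make_node <- function(in_channels, out_channels) {
  stopifnot(in_channels >= 1L, out_channels >= 1L)
  structure(list(conv1 = new_conv(in_channels, out_channels),
                 norm1 = new_norm(out_channels),
                 conv2 = new_conv(out_channels, out_channels),
                 norm2 = new_norm(out_channels)),
            class = "rkseg_node")
}

#' Create the pre-processor
#'
#' One two-conv node mapping the image modalities to the constant width `k`
#' at full resolution; the network performs no down-sampling before the
#' first stage, so the initial state keeps the input geometry.
#'
#' @param in_channels Image modalities.
#' @param width Node width `k`.
#' @export
make_pre <- function(in_channels, width) make_node(in_channels, width)

#' Create the post-processor
#'
#' `3x3,k / 3x3,k` (with normalization and nonlinearity) followed by a
#' `1x1,c` convolution that produces the class logits.
#'
#' @param width Node width `k`.
#' @param num_classes Classes including background.
#' @export
make_post <- function(width, num_classes) {
  structure(list(node = make_node(width, width),
                 final = new_conv(width, num_classes, ksize = 1L)),
            class = "rkseg_post")
}

# ---- layer forward/backward -------------------------------------------------

conv_fwd <- function(x, p) cpp_conv2d_fwd(x, p$w, p$b, p$k)

conv_bwd <- function(x, p, gy) cpp_conv2d_bwd(x, p$w, gy, p$k)

instnorm_fwd <- function(x, p) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu * mu
  istd <- 1 / sqrt(va + NORM_EPS)
  xhat <- (xm - rep(mu, each = n)) * rep(istd, each = n)
  y <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd)
}

instnorm_bwd <- function(cache, p, gy) {
  d <- dim(gy)
  n <- d[1] * d[2]
  gm <- matrix(gy, n, d[3])
  xhat <- cache$xhat
  ggamma <- colSums(gm * xhat)
  gbeta <- colSums(gm)
  # dL/dx = gamma * istd * (g - mean(g) - xhat * mean(g * xhat))
  gx <- (gm - rep(gbeta / n, each = n) - xhat * rep(ggamma / n, each = n)) *
    rep(p$gamma * cache$istd, each = n)
  dim(gx) <- d
  list(gx = gx, gp = list(gamma = ggamma, beta = gbeta))
}

lrelu_fwd <- function(x) {
  neg <- !is.na(x) & x < 0   # NA-safe: non-finite activations propagate
  x[neg] <- x[neg] * LRELU_SLOPE
  list(y = x, neg = neg)
}

lrelu_bwd <- function(cache, gy) {
  gy[cache$neg] <- gy[cache$neg] * LRELU_SLOPE
  gy
}

node_fwd <- function(x, p) {
  c1 <- conv_fwd(x, p$conv1)
  n1 <- instnorm_fwd(c1, p$norm1)
  a1 <- lrelu_fwd(n1$y)
  c2 <- conv_fwd(a1$y, p$conv2)
  n2 <- instnorm_fwd(c2, p$norm2)
  a2 <- lrelu_fwd(n2$y)
  list(y = a2$y,
       cache = list(x = x, c1 = c1, n1 = n1, a1 = a1, n2 = n2, a2 = a2))
}

node_bwd <- function(cache, p, gy) {
  g <- lrelu_bwd(cache$a2, gy)
  bn2 <- instnorm_bwd(cache$n2, p$norm2, g)
  bc2 <- conv_bwd(cache$a1$y, p$conv2, bn2$gx)
  g <- lrelu_bwd(cache$a1, bc2$gx)
  bn1 <- instnorm_bwd(cache$n1, p$norm1, g)
  bc1 <- conv_bwd(cache$x, p$conv1, bn1$gx)
  # gradient trees mirror the parameter trees exactly (incl. the 'k' marker)
  list(gx = bc1$gx,
       gp = list(conv1 = list(w = bc1$gw, b = bc1$gb, k = p$conv1$k),
                 norm1 = bn1$gp,
                 conv2 = list(w = bc2$gw, b = bc2$gb, k = p$conv2$k),
                 norm2 = bn2$gp))
}

# ---- resampling operators ---------------------------------------------------

pow2_steps <- function(from_divisor, to_divisor) {
  r <- to_divisor / from_divisor
  if (r <= 0)
    stop("scale divisors must be positive", call. = FALSE)
  n <- round(log2(r))
  if (!isTRUE(all.equal(2^n, r)))
    stop("scale divisors must be related by a power of two", call. = FALSE)
  as.integer(n)  # positive: down-sample; negative: up-sample
}

#' Down-sample a feature map by repeated 2x2 max-pooling
#'
#' The operator that moves the initial state and earlier increments to a
#' smaller stage scale. Each step halves both spatial axes with a stride-2
#' 2x2 max-pool; channels are untouched.
#'
#' @param x Array `(H, W, C)` with `H`, `W` divisible by `2^steps`.
#' @param steps Number of halvings (0 returns `x` unchanged).
#' @return Array `(H/2^steps, W/2^steps, C)`.
#' @export
downsample_max <- function(x, steps = 1L) {
  stopifnot(length(dim(x)) == 3L, steps >= 0L)
  for (i in seq_len(steps)) {
    d <- dim(x)
    if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
      stop(sprintf("spatial size %dx%d not divisible by 2", d[1], d[2]),
           call. = FALSE)
    x <- cpp_maxpool2_fwd(x)$y
  }
  x
}

#' Up-sample a feature map by repeated x2 bilinear interpolation
#'
#' The operator that returns a stage increment to full resolution (or to an
#' intermediate stage scale in the reversed orientation). Interpolation is
#' bilinear with non-aligned corners, applied as successive x2 steps;
#' channels are untouched and a constant map stays constant.
#'
#' @param x Array `(H, W, C)`.
#' @param steps Number of doublings (0 returns `x` unchanged).
#' @return Array `(H*2^steps, W*2^steps, C)`.
#' @export
upsample_bilinear <- function(x, steps = 1L) {
  stopifnot(length(dim(x)) == 3L, steps >= 0L)
  for (i in seq_len(steps)) x <- cpp_bilinear2x_fwd(x)
  x
}

# Differentiable resample between two scale divisors; caches per-step state.
resample_fwd <- function(x, from_divisor, to_divisor) {
  n <- pow2_steps(from_divisor, to_divisor)
  if (n == 0) return(list(y = x, kind = "id"))
  if (n > 0) {
    steps <- vector("list", n)
    for (i in seq_len(n)) {
      d <- dim(x)
      if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
        stop(sprintf("spatial size %dx%d not divisible by 2", d[1], d[2]),
             call. = FALSE)
      mp <- cpp_maxpool2_fwd(x)
      steps[[i]] <- list(amax = mp$amax, H = d[1], W = d[2])
      x <- mp$y
    }
    list(y = x, kind = "down", steps = steps)
  } else {
    sizes <- vector("list", -n)
    for (i in seq_len(-n)) {
      d <- dim(x)
      sizes[[i]] <- c(d[1], d[2])
      x <- cpp_bilinear2x_fwd(x)
    }
    list(y = x, kind = "up", sizes = sizes)
  }
}

resample_bwd <- function(cache, gy) {
  if (cache$kind == "id") return(gy)
  if (cache$kind == "down") {
    for (st in rev(cache$steps))
      gy <- cpp_maxpool2_bwd(st$amax, gy, st$H, st$W)
  } else {
    for (sz in rev(cache$sizes))
      gy <- cpp_bilinear2x_bwd(gy, sz[1], sz[2])
  }
  gy
}

# channel concatenation of (H, W, C_i) arrays; contiguous in this layout
concat_channels <- function(xs) {
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE),
        dim = c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3], 1))))
}

# ---- parameter-tree utilities ----------------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    attributes(out) <- attributes(a)
    out
  } else f(a)
}

tree_leaves <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_leaves), recursive = FALSE)
  else list(a)
}

tree_n_scalars <- function(a) {
  # 'k' kernel-size markers are metadata, not parameters
  count <- function(x, nm) {
    if (is.list(x)) sum(mapply(count, x, names2(x)))
    else if (identical(nm, "k")) 0L
    else length(x)
  }
  count(a, "")
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) rep("", length(x)) else nm
}

zeros_like <- function(a) {
  zl <- function(x, nm) {
    if (is.list(x)) {
      out <- Map(zl, x, names2(x))
      attributes(out) <- attributes(x)
      out
    } else if (identical(nm, "k")) x else x * 0
  }
  zl(a, "")
}

# a + scale * b over matching trees, skipping 'k' markers
tree_axpy <- function(a, b, scale = 1) {
  ax <- function(x, y, nm) {
    if (is.list(x)) {
      out <- Map(ax, x, y, names2(x))
      attributes(out) <- attributes(x)
      out
    } else if (identical(nm, "k")) x else x + scale * y
  }
  ax(a, b, "")
}
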