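node_in_channels <- function(model) {
  vapply(model$nodes, function(nd) nrow(nd$conv1$w) / 9, numeric(1))
}

test_that("stage node widths follow the concatenation arithmetic", {
  set.seed(1)
  m <- build_rkseg(rkseg_config("L", "E", 6, 32, 1, 2))
  expect_equal(node_in_channels(m), 32 * 1:6)
  mi <- build_rkseg(rkseg_config("L", "I", 6, 32, 1, 2))
  expect_equal(node_in_channels(mi), c(32, 64, 96, 96, 96, 96))
  mr <- build_rkseg(rkseg_config("R", "R", 4, 8, 1, 2))
  expect_equal(node_in_channels(mr), c(8, 16, 16, 16))
})

test_that("forward produces full-resolution logits for every variant", {
  set.seed(2)
  variants <- list(c("L", "E", 3), c("R", "E", 3), c("L", "I", 4),
                   c("R", "I", 4), c("L", "R", 4), c("R", "R", 4))
  img <- array(rnorm(32 * 32), c(32, 32, 1))
  for (v in variants) {
    m <- build_rkseg(rkseg_config(v[1], v[2], as.integer(v[3]), 4, 1, 3))
    lg <- rkseg_forward(m, img)
    expect_equal(dim(lg), c(32L, 32L, 3L))
    expect_true(all(is.finite(lg)))
  }
})

test_that("with all stage outputs zeroed the network is pre -> post exactly", {
  set.seed(3)
  for (v in list(c("L", "E", 3), c("R", "I", 4), c("L", "R", 4))) {
    m <- build_rkseg(rkseg_config(v[1], v[2], as.integer(v[3]), 4, 1, 2),
                     init_zero_stages = TRUE)
    img <- array(rnorm(32 * 32), c(32, 32, 1))
    lg <- rkseg_forward(m, img)
    # the RK update with every increment zero leaves y1 = y0
    y0 <- rksegnet:::node_fwd(img, m$pre)$y
    post_h <- rksegnet:::node_fwd(y0, m$post$node)$y
    expected <- rksegnet:::conv_fwd(post_h, m$post$final)
    expect_identical(lg, expected)   # exact tensor equality
  }
})

test_that("forward pass matches a straight-line reference trace (L/E, d=2, k=1)", {
  set.seed(4)
  cfg <- rkseg_config("L", "E", 2, 1, 1, 2)
  m <- build_rkseg(cfg)
  img <- array(rnorm(8 * 8), c(8, 8, 1))
  lg <- rkseg_forward(m, img)
  ref <- ref_forward_LE2_k1(m, img)
  expect_equal(lg[, , 1], ref[[1]], tolerance = 1e-12)
  expect_equal(lg[, , 2], ref[[2]], tolerance = 1e-12)
})

test_that("instantiated counts equal the closed form to the scalar", {
  set.seed(5)
  cfg <- rkseg_config("R", "E", 3, 32, 1, 3)
  m <- build_rkseg(cfg)
  rep <- count_parameters_instantiated(m)
  expect_identical(as.integer(rep$total), 111939L)
  expect_identical(as.integer(rep$total), as.integer(count_parameters(cfg)$total))
  expect_equal(rep$per_component[["pre_processor"]],
               count_parameters(cfg)$per_component[["pre_processor"]])
})

test_that("intermediate increment shapes follow the scale schedule", {
  set.seed(6)
  for (v in list(c("L", "E", 3), c("R", "E", 3), c("L", "I", 4))) {
    cfg <- rkseg_config(v[1], v[2], as.integer(v[3]), 4, 1, 2)
    m <- build_rkseg(cfg)
    fwd <- rkseg_forward(m, array(rnorm(32 * 32), c(32, 32, 1)),
                         keep_cache = TRUE)
    sched <- scale_schedule(cfg)
    s <- n_stages(cfg)
    e_div <- if (cfg$backbone == "E") sched$scale_divisor else
      sched$scale_divisor[s + seq_len(s)]
    for (i in seq_len(s))
      expect_equal(dim(fwd$cache$e[[i]]), c(32 / e_div[i], 32 / e_div[i], 4))
    if (cfg$backbone != "E")
      for (i in seq_len(s))
        expect_equal(dim(fwd$cache$x[[i]]),
                     c(32 / sched$scale_divisor[i], 32 / sched$scale_divisor[i], 4))
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  cfg <- rkseg_config("L", "E", 2, 2, 1, 2)
  m <- build_rkseg(cfg)
  img <- array(rnorm(16 * 16), c(16, 16, 1))
  lab <- matrix(sample(0:1, 256, TRUE), 16, 16)
  fwd <- rkseg_forward(m, img, keep_cache = TRUE)
  l <- dice_ce_loss(fwd$logits, lab, grad = TRUE)
  g <- rksegnet:::rkseg_backward(m, fwd$cache, l$grad[[1]])
  h <- 1e-6
  probes <- list(
    list(get = function(mm) mm$pre$conv1$w[3, 1],
         set = function(mm, v) { mm$pre$conv1$w[3, 1] <- v; mm },
         grad = g$pre$conv1$w[3, 1]),
    list(get = function(mm) mm$nodes[[2]]$conv1$w[5, 2],
         set = function(mm, v) { mm$nodes[[2]]$conv1$w[5, 2] <- v; mm },
         grad = g$nodes[[2]]$conv1$w[5, 2]),
    list(get = function(mm) mm$nodes[[1]]$norm2$gamma[1],
         set = function(mm, v) { mm$nodes[[1]]$norm2$gamma[1] <- v; mm },
         grad = g$nodes[[1]]$norm2$gamma[1]),
    list(get = function(mm) mm$post$final$w[2, 1],
         set = function(mm, v) { mm$post$final$w[2, 1] <- v; mm },
         grad = g$post$final$w[2, 1]),
    list(get = function(mm) mm$post$node$conv2$b[1],
         set = function(mm, v) { mm$post$node$conv2$b[1] <- v; mm },
         grad = g$post$node$conv2$b[1]))
  loss_of <- function(mm) dice_ce_loss(rkseg_forward(mm, img), lab)$loss
  for (p in probes) {
    v <- p$get(m)
    fd <- (loss_of(p$set(m, v + h)) - loss_of(p$set(m, v - h))) / (2 * h)
    expect_equal(p$grad, fd, tolerance = 1e-3)
  }
})

test_that("every parameter tensor receives gradient in all six variants", {
  set.seed(8)
  variants <- list(c("L", "E", 3), c("R", "E", 3), c("L", "I", 4),
                   c("R", "I", 4), c("L", "R", 4), c("R", "R", 4))
  for (v in variants) {
    cfg <- rkseg_config(v[1], v[2], as.integer(v[3]), 3, 1, 2)
    m <- build_rkseg(cfg)
    img <- array(rnorm(32 * 32), c(32, 32, 1))
    lab <- matrix(sample(0:1, 32 * 32, TRUE), 32, 32)
    fwd <- rkseg_forward(m, img, keep_cache = TRUE)
    l <- dice_ce_loss(fwd$logits, lab, grad = TRUE)
    g <- rksegnet:::rkseg_backward(m, fwd$cache, l$grad[[1]])
    check_tree <- function(p, where) {
      nms <- names(p)
      if (is.null(nms)) nms <- rep("", length(p))
      for (i in seq_along(p)) {
        if (is.list(p[[i]])) check_tree(p[[i]], paste0(where, "/", nms[i]))
        else if (!identical(nms[i], "k"))
          expect_true(any(p[[i]] != 0),
                      label = sprintf("%s/%s %s/%s nonzero grad", v[1], v[2],
                                      where, nms[i]))
      }
    }
    check_tree(list(pre = g$pre, nodes = g$nodes, post = g$post), "")
  }
})

test_that("padding policy pads odd inputs and rejects when told to", {
  set.seed(9)
  cfg <- rkseg_config("L", "E", 3, 4, 1, 2)
  m <- build_rkseg(cfg)
  lg <- rkseg_forward(m, array(rnorm(65 * 63), c(65, 63, 1)))
  expect_equal(dim(lg), c(65L, 63L, 2L))
  cfg_r <- rkseg_config("L", "E", 3, 4, 1, 2, pad_policy = "reject")
  m$cfg <- cfg_r
  expect_error(rkseg_forward(m, array(rnorm(65 * 63), c(65, 63, 1))),
               "not divisible")
  expect_error(rkseg_forward(m, array(rnorm(32 * 32 * 2), c(32, 32, 2))),
               "channels")
})
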