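# Assembly and execution of the six RKSeg variants.
#
# One forward pass is one time step of an s-stage Runge-Kutta method:
#   y1 = y0 + sum_i U(e_i)
# where y0 is the pre-processor output (the initial state), each increment
# e_i is produced by a stage subnetwork working at its own spatial scale,
# and U interpolates each increment back to full resolution. Backbone E
# feeds stage i with (y0, e_1, ..., e_{i-1}); backbones I and R first
# compute initial-value tensors x_i = X_i(y0, x_1, ..., x_{i-1}) for all
# stages, then the increments
#   I: e_i = I_i(y0, e_1, ..., e_{i-1}, x_{i+1}, ..., x_s)
#   R: e_i = R_i(y0, x_1, ..., x_{i-1}, x_{i+1}, ..., x_s)
# so every stage node consumes exactly s tensors of k channels. Every
# tensor entering a node is resampled to the node's scale: max-pooling when
# it comes from a larger scale, bilinear interpolation when it comes from a
# smaller one; y0 is always taken directly from full resolution.

# Wiring plan: evaluation order, scale divisors, and the sources of every
# stage node. Sources are (kind, idx) with kind in {"y0", "e", "x"}.
stage_plan <- function(cfg) {
  s <- n_stages(cfg)
  d <- cfg$depth
  sched <- scale_schedule(cfg)
  div <- sched$scale_divisor
  src_div <- function(kind, idx) {
    switch(kind,
           y0 = 1L,
           e = if (cfg$backbone == "E") div[idx] else div[s + idx],
           x = div[idx])
  }
  sources <- vector("list", d)
  for (j in seq_len(d)) {
    if (cfg$backbone == "E") {
      kinds <- c("y0", rep("e", j - 1L))
      idxs <- c(0L, seq_len(j - 1L))
    } else if (j <= s) {                       # X_j
      kinds <- c("y0", rep("x", j - 1L))
      idxs <- c(0L, seq_len(j - 1L))
    } else {                                   # increment node i = j - s
      i <- j - s
      if (cfg$backbone == "I") {
        kinds <- c("y0", rep("e", i - 1L), rep("x", s - i))
        idxs <- c(0L, seq_len(i - 1L), seq(i + 1L, length.out = s - i))
      } else {
        kinds <- c("y0", rep("x", s - 1L))
        idxs <- c(0L, setdiff(seq_len(s), i))
      }
    }
    sources[[j]] <- data.frame(
      kind = kinds, idx = idxs,
      from_div = mapply(src_div, kinds, idxs), row.names = NULL)
  }
  list(sched = sched, div = div, sources = sources, s = s, d = d)
}

#' Build an RKSeg model
#'
#' Instantiates the pre-processor, the `depth` stage nodes and the
#' post-processor for a configuration, with He-style weight initialization
#' (drawn from the current RNG state; seed beforehand for reproducibility).
#'
#' @param cfg An [rkseg_config()].
#' @param init_zero_stages If `TRUE`, the second convolution of every stage
#'   node is zero-initialized so all increments start at zero and the
#'   network begins as the identity map `y1 = y0` (residual-style start).
#' @return An object of class `rkseg_model`.
#' @examples
#' set.seed(1)
#' m <- build_rkseg(rkseg_config("L", "E", 3, 8, 1, 2))
#' count_parameters_instantiated(m)$total
#' @export
build_rkseg <- function(cfg, init_zero_stages = FALSE) {
  validate_config(cfg)
  plan <- stage_plan(cfg)
  k <- cfg$width
  nodes <- vector("list", cfg$depth)
  for (j in seq_len(cfg$depth)) {
    a <- k * nrow(plan$sources[[j]])
    nodes[[j]] <- make_node(a, k)
    if (init_zero_stages) {
      nodes[[j]]$conv2$w[] <- 0
      nodes[[j]]$conv2$b[] <- 0
    }
  }
  structure(list(cfg = cfg, plan = plan,
                 pre = make_pre(cfg$in_channels, k),
                 nodes = nodes,
                 post = make_post(k, cfg$num_classes)),
            class = "rkseg_model")
}

#' @export
print.rkseg_model <- function(x, ...) {
  print(x$cfg)
  sched <- x$plan$sched
  widths <- vapply(seq_len(x$cfg$depth),
                   function(j) x$cfg$width * nrow(x$plan$sources[[j]]), 1)
  cat("node  scale  in_channels -> out\n")
  for (j in seq_len(nrow(sched)))
    cat(sprintf("  %-4s 1/%-4d %d -> %d\n", sched$node[j],
                sched$scale_divisor[j], widths[j], x$cfg$width))
  cat(sprintf("parameters: %d (%.2f M)\n",
              count_parameters_instantiated(x)$total,
              count_parameters_instantiated(x)$total_millions_2dp))
  invisible(x)
}

# symmetric zero padding of (H, W, C) up to multiples of m
pad_image <- function(x, m) {
  d <- dim(x)
  ph <- (m - d[1] %% m) %% m
  pw <- (m - d[2] %% m) %% m
  if (ph == 0 && pw == 0)
    return(list(x = x, top = 0L, left = 0L, H = d[1], W = d[2]))
  top <- ph %/% 2L
  left <- pw %/% 2L
  out <- array(0, dim = c(d[1] + ph, d[2] + pw, d[3]))
  out[top + seq_len(d[1]), left + seq_len(d[2]), ] <- x
  list(x = out, top = top, left = left, H = d[1], W = d[2])
}

#' Run the segmentation forward pass
#'
#' Computes the full-resolution class logits for one image: pre-processor,
#' the Runge-Kutta stage sweep at descending (orientation `"L"`) or
#' ascending (`"R"`) scales, the increment sum `y1 = y0 + sum U(e_i)`, and
#' the post-processor. Odd-sized inputs are symmetrically zero-padded to
#' the next multiple of `2^depth` and the logits cropped back (under
#' `pad_policy = "pad_and_crop"`; otherwise rejected).
#'
#' @param model An [build_rkseg()] model.
#' @param image Array `(H, W, in_channels)`.
#' @param keep_cache Internal: retain intermediates for backpropagation.
#' @return Array `(H, W, num_classes)` of logits, or (with `keep_cache`)
#'   a list with `logits` and `cache`.
#' @export
rkseg_forward <- function(model, image, keep_cache = FALSE) {
  cfg <- model$cfg
  d <- dim(image)
  if (length(d) == 2L) { dim(image) <- c(d, 1L); d <- dim(image) }
  if (d[3] != cfg$in_channels)
    stop(sprintf("image has %d channels, config expects %d", d[3],
                 cfg$in_channels), call. = FALSE)
  m <- 2L^cfg$depth
  if ((d[1] %% m != 0L || d[2] %% m != 0L) && cfg$pad_policy == "reject")
    stop(sprintf("spatial size %dx%d not divisible by 2^depth = %d", d[1],
                 d[2], m), call. = FALSE)
  pad <- pad_image(image, m)

  plan <- model$plan
  pre <- node_fwd(pad$x, model$pre)
  y0 <- pre$y

  e <- vector("list", plan$s)
  x <- vector("list", plan$s)
  node_caches <- vector("list", plan$d)
  rs_caches <- vector("list", plan$d)
  for (j in seq_len(plan$d)) {
    src <- plan$sources[[j]]
    parts <- vector("list", nrow(src))
    rs <- vector("list", nrow(src))
    for (m_i in seq_len(nrow(src))) {
      t0 <- switch(src$kind[m_i], y0 = y0, e = e[[src$idx[m_i]]],
                   x = x[[src$idx[m_i]]])
      r <- resample_fwd(t0, src$from_div[m_i], plan$div[j])
      parts[[m_i]] <- r$y
      rs[[m_i]] <- r
    }
    nf <- node_fwd(concat_channels(parts), model$nodes[[j]])
    node_caches[[j]] <- nf$cache
    rs_caches[[j]] <- rs
    if (cfg$backbone == "E" || j > plan$s) {
      e[[if (cfg$backbone == "E") j else j - plan$s]] <- nf$y
    } else {
      x[[j]] <- nf$y
    }
  }

  e_div <- if (cfg$backbone == "E") plan$div else plan$div[plan$s + seq_len(plan$s)]
  up <- vector("list", plan$s)
  y1 <- y0
  for (i in seq_len(plan$s)) {
    u <- resample_fwd(e[[i]], e_div[i], 1L)
    up[[i]] <- u
    y1 <- y1 + u$y
  }

  postn <- node_fwd(y1, model$post$node)
  logits_full <- conv_fwd(postn$y, model$post$final)
  logits <- logits_full[pad$top + seq_len(pad$H), pad$left + seq_len(pad$W), ,
                        drop = FALSE]
  if (!keep_cache) return(logits)
  list(logits = logits,
       cache = list(pad = pad, pre = pre$cache, node_caches = node_caches,
                    rs_caches = rs_caches, up = up, postn = postn,
                    y0_dim = dim(y0), e = e, x = x))
}

# Backpropagation through one cached forward pass; returns the gradient
# tree (same shape as the model's parameter trees).
rkseg_backward <- function(model, cache, glogits) {
  cfg <- model$cfg
  plan <- model$plan
  pad <- cache$pad
  full_dim <- dim(cache$postn$cache$x)
  gl_full <- array(0, dim = c(full_dim[1], full_dim[2], cfg$num_classes))
  gl_full[pad$top + seq_len(pad$H), pad$left + seq_len(pad$W), ] <- glogits

  bfinal <- conv_bwd(cache$postn$cache$a2$y, model$post$final, gl_full)
  # note: postn cache's a2$y is the post-node output fed to the 1x1 conv
  bpost <- node_bwd(cache$postn$cache, model$post$node, bfinal$gx)
  g_y1 <- bpost$gx

  s <- plan$s
  g_y0 <- g_y1
  g_e <- vector("list", s)
  g_x <- vector("list", s)
  for (i in seq_len(s)) {
    g_e[[i]] <- resample_bwd(cache$up[[i]], g_y1)
    if (!is.null(cache$x[[i]]))
      g_x[[i]] <- array(0, dim = dim(cache$x[[i]]))
  }

  k <- cfg$width
  gnodes <- vector("list", plan$d)
  for (j in rev(seq_len(plan$d))) {
    if (cfg$backbone == "E" || j > s) {
      i <- if (cfg$backbone == "E") j else j - s
      gout <- g_e[[i]]
    } else {
      gout <- g_x[[j]]
    }
    nb <- node_bwd(cache$node_caches[[j]], model$nodes[[j]], gout)
    gnodes[[j]] <- nb$gp
    src <- plan$sources[[j]]
    for (m_i in seq_len(nrow(src))) {
      slice <- nb$gx[, , (m_i - 1L) * k + seq_len(k), drop = FALSE]
      g_src <- resample_bwd(cache$rs_caches[[j]][[m_i]], slice)
      kind <- src$kind[m_i]
      idx <- src$idx[m_i]
      if (kind == "y0") g_y0 <- g_y0 + g_src
      else if (kind == "e") g_e[[idx]] <- g_e[[idx]] + g_src
      else g_x[[idx]] <- g_x[[idx]] + g_src
    }
  }

  bpre <- node_bwd(cache$pre, model$pre, g_y0)
  list(pre = bpre$gp, nodes = gnodes,
       post = list(node = bpost$gp,
                   final = list(w = bfinal$gw, b = bfinal$gb,
                                k = model$post$final$k)))
}

#' Brute-force parameter count of an instantiated model
#'
#' Walks every weight array of a built model and counts its scalars,
#' grouped by component. Serves as the independent cross-check of
#' [count_parameters()]: the two must agree to the scalar for every valid
#' configuration.
#'
#' @param model An `rkseg_model`.
#' @return An `rkseg_param_report` (same shape as [count_parameters()]).
#' @export
count_parameters_instantiated <- function(model) {
  stopifnot(inherits(model, "rkseg_model"))
  comp <- c(pre_processor = tree_n_scalars(model$pre))
  stage_names <- paste0("stage_", model$plan$sched$node)
  for (j in seq_along(model$nodes))
    comp[stage_names[j]] <- tree_n_scalars(model$nodes[[j]])
  comp["post_processor"] <- tree_n_scalars(model$post)
  structure(list(total = sum(comp), per_component = comp,
                 total_millions_2dp = round_half_up(sum(comp) / 1e6, 2L)),
            class = "rkseg_param_report")
}

#' Predict label maps
#'
#' Argmax over the forward logits; padding (if any) is cropped before the
#' argmax so the output matches the input geometry exactly.
#'
#' @param model An `rkseg_model`.
#' @param images A single `(H, W, C)` array or a list of them (2D arrays are
#'   treated as single-channel).
#' @return An integer `(H, W)` label map (0-based classes), or a list of
#'   them.
#' @export
rkseg_predict <- function(model, images) {
  one <- function(img) {
    lg <- rkseg_forward(model, img)
    lab <- apply(lg, c(1, 2), which.max) - 1L
    storage.mode(lab) <- "integer"
    lab
  }
  if (is.list(images)) lapply(images, one) else one(images)
}
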