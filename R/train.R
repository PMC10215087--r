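# Training: minibatch SGD with Nesterov momentum on the Dice + CE loss,
# polynomial learning-rate decay, per-epoch logging and checkpoints.

#' Training configuration
#'
#' Defaults follow the nnU-Net-style recipe the architecture was designed
#' under: SGD with initial learning rate 0.01 and Nesterov momentum 0.99,
#' polynomial decay `lr0 * (1 - epoch/epochs)^0.9`, 150 epochs. Epoch count
#' and batch size are freely configurable (desk-scale runs in this package
#' use far fewer epochs).
#'
#' @param arch An [rkseg_config()].
#' @param lr0 Initial learning rate (> 0).
#' @param momentum Nesterov momentum coefficient.
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param schedule `"poly"` or `"constant"`.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param checkpoint_path,metrics_path Optional output files for the final
#'   checkpoint and the per-epoch metrics CSV.
#' @return A list of class `train_config`.
#' @export
train_config <- function(arch, lr0 = 0.01, momentum = 0.99, epochs = 150L,
                         batch_size = 8L, schedule = c("poly", "constant"),
                         seed = 0L, checkpoint_path = NULL,
                         metrics_path = NULL) {
  stopifnot(inherits(arch, "rkseg_config"), lr0 > 0, epochs >= 1L,
            batch_size >= 1L, momentum >= 0, momentum < 1)
  schedule <- match.arg(schedule)
  structure(list(arch = arch, lr0 = lr0, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), schedule = schedule,
                 seed = as.integer(seed), checkpoint_path = checkpoint_path,
                 metrics_path = metrics_path),
            class = "train_config")
}

model_params <- function(model) {
  list(pre = model$pre, nodes = model$nodes, post = model$post)
}

set_model_params <- function(model, p) {
  model$pre <- p$pre
  model$nodes <- p$nodes
  model$post <- p$post
  model
}

#' Train an RKSeg model
#'
#' Runs minibatch SGD with Nesterov momentum on the Dice + cross-entropy
#' loss. Fully seeded: the same configuration and seed reproduce the same
#' metrics log. Aborts with a diagnostic if the loss turns non-finite.
#'
#' @param cfg A [train_config()].
#' @param train_set,val_set Lists of samples (`image`, `label`); `val_set`
#'   may be `NULL`.
#' @param verbose Print a line per epoch.
#' @return A list of class `train_state`: the trained `model`, a `history`
#'   data frame (epoch, lr, train_loss, val_mean_dice), and `best_epoch`
#'   (highest validation Dice, or last epoch without validation).
#' @export
rkseg_train <- function(cfg, train_set, val_set = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), length(train_set) >= 1L)
  set.seed(cfg$seed)
  model <- build_rkseg(cfg$arch)
  velocity <- zeros_like(model_params(model))
  n <- length(train_set)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_mean_dice = numeric())
  best <- list(epoch = NA_integer_, dice = -Inf, params = NULL)

  for (epoch in seq_len(cfg$epochs)) {
    lr <- if (cfg$schedule == "poly")
      cfg$lr0 * (1 - (epoch - 1) / cfg$epochs)^0.9 else cfg$lr0
    order_idx <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- order_idx[start:min(start + cfg$batch_size - 1L, n)]
      fwd <- lapply(idx, function(i)
        rkseg_forward(model, train_set[[i]]$image, keep_cache = TRUE))
      loss <- dice_ce_loss(lapply(fwd, `[[`, "logits"),
                           lapply(idx, function(i) train_set[[i]]$label),
                           grad = TRUE)
      if (!is.finite(loss$loss))
        stop(sprintf(
          "non-finite loss at epoch %d (ce=%g, dice_term=%g); reduce lr0?",
          epoch, loss$ce, loss$dice_term), call. = FALSE)
      losses <- c(losses, loss$loss)
      grads <- NULL
      for (b in seq_along(idx)) {
        g <- rkseg_backward(model, fwd[[b]]$cache, loss$grad[[b]])
        grads <- if (is.null(grads)) g else tree_axpy(grads, g, 1)
      }
      # Nesterov: v <- mu v + g; step <- g + mu v; theta <- theta - lr step
      velocity <- tree_axpy(grads, velocity, cfg$momentum)
      step <- tree_axpy(grads, velocity, cfg$momentum)
      model <- set_model_params(
        model, tree_axpy(model_params(model), step, -lr))
    }
    val_dice <- NA_real_
    if (!is.null(val_set)) {
      val_dice <- evaluate_dataset(model, val_set)$mean
      if (val_dice > best$dice)
        best <- list(epoch = epoch, dice = val_dice,
                     params = model_params(model))
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      val_mean_dice = val_dice))
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %8.4f  val dice %s",
                      epoch, lr, mean(losses),
                      if (is.na(val_dice)) "-" else sprintf("%.4f", val_dice)))
  }
  if (is.null(val_set)) best <- list(epoch = cfg$epochs, dice = NA_real_,
                                     params = NULL)
  state <- structure(list(model = model, history = history,
                          best_epoch = best$epoch, best_dice = best$dice,
                          best_model = if (!is.null(best$params))
                            set_model_params(model, best$params) else model,
                          config = cfg),
                     class = "train_state")
  if (!is.null(cfg$checkpoint_path)) save_checkpoint(model,
                                                     cfg$checkpoint_path)
  if (!is.null(cfg$metrics_path))
    utils::write.csv(history, cfg$metrics_path, row.names = FALSE)
  state
}

#' @export
print.train_state <- function(x, ...) {
  h <- x$history
  cat(sprintf("trained %d epochs; final loss %.4f", nrow(h),
              h$train_loss[nrow(h)]))
  if (!all(is.na(h$val_mean_dice)))
    cat(sprintf("; best val dice %.4f (epoch %d)", x$best_dice,
                x$best_epoch))
  cat("\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the configuration as plain
#' key-values and every named weight array; loading reproduces the model
#' bitwise (`save -> load -> forward` equals the in-memory forward
#' exactly).
#'
#' @param model An `rkseg_model`.
#' @param path Destination file.
#' @return `path` invisibly (`save_checkpoint`); the model
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "rkseg_model"))
  saveRDS(list(format = "rkseg_checkpoint_v1",
               cfg = unclass(model$cfg),
               params = model_params(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "rkseg_checkpoint_v1"))
    stop("not an rkseg checkpoint", call. = FALSE)
  cfg <- do.call(rkseg_config, ck$cfg[c("orientation", "backbone", "depth",
                                        "width", "in_channels",
                                        "num_classes", "interpolation_mode",
                                        "norm_kind", "pad_policy")])
  model <- build_rkseg(cfg)
  set_model_params(model, ck$params)
}

#' Evaluate a model (or checkpoint) on a dataset
#'
#' Thin wrapper over [evaluate_dataset()] accepting a checkpoint path.
#'
#' @param model An `rkseg_model` or a checkpoint path.
#' @param dataset List of samples.
#' @return A `dice_report`.
#' @export
rkseg_evaluate <- function(model, dataset) evaluate_dataset(model, dataset)

#' Plot training curves
#'
#' Loss (and validation Dice when present) against epoch.
#'
#' @param state A `train_state`.
#' @return A ggplot object.
#' @export
plot_training_curves <- function(state) {
  h <- state$history
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch,
                                       y = .data$train_loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = "RKSeg training") +
    ggplot2::theme_minimal()
  if (!all(is.na(h$val_mean_dice)))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$val_mean_dice),
                                color = "darkorange", linetype = 2)
  p
}
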