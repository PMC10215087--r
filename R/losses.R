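# Training loss and evaluation metric.
#
# Loss convention: total = cross-entropy - mean soft Dice over foreground
# classes, so a perfect prediction drives the Dice term to -1 (and the CE
# term to its epsilon-limited minimum). The soft Dice is computed on
# softmax probabilities pooled over the whole batch per class, with a
# smoothing constant in numerator and denominator.

DICE_EPS <- 1e-5

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Symmetric, invariant to any common pixel
#' permutation, in `[0, 1]`. Two empty masks score 1 (the prediction is
#' exactly right).
#'
#' @param pred_mask,ref_mask Logical/0-1 arrays of equal shape.
#' @return A scalar in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
#' dice_coefficient(a, b)  # 2*1/(2+2) = 0.5
#' @export
dice_coefficient <- function(pred_mask, ref_mask) {
  if (!identical(dim(pred_mask), dim(ref_mask)))
    stop("mask shapes differ", call. = FALSE)
  p <- as.logical(pred_mask)
  r <- as.logical(ref_mask)
  sp <- sum(p); sr <- sum(r)
  if (sp + sr == 0) return(1)
  2 * sum(p & r) / (sp + sr)
}

# softmax over the class axis of an (H, W, C) logit array
softmax3 <- function(logits) {
  d <- dim(logits)
  z <- matrix(logits, d[1] * d[2], d[3])
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  dim(p) <- d
  p
}

#' Dice + cross-entropy segmentation loss
#'
#' The training criterion: pixel-averaged cross-entropy plus the negated
#' soft Dice, equally weighted (`loss = CE - mean_fg_dice`). Soft Dice uses
#' softmax probabilities aggregated per foreground class over the entire
#' batch; a smoothing constant `eps` in numerator and denominator keeps the
#' loss finite and differentiable when a class is absent.
#'
#' @param logits An `(H, W, C)` array or a list of them (a batch).
#' @param labels An integer `(H, W)` map with values in `0..C-1` (or a
#'   matching list).
#' @param eps Soft-Dice smoothing constant.
#' @param grad If `TRUE`, also return the gradient with respect to each
#'   logit array.
#' @return A list with `loss`, `ce`, `dice_term` (the negated mean soft
#'   Dice) and, when requested, `grad` (list parallel to the batch).
#' @export
dice_ce_loss <- function(logits, labels, eps = DICE_EPS, grad = FALSE) {
  if (!is.list(logits)) { logits <- list(logits); labels <- list(labels) }
  nb <- length(logits)
  C <- dim(logits[[1]])[3]
  fg <- seq_len(C - 1L) + 1L  # columns of classes 1..C-1 (background excluded)

  probs <- vector("list", nb)
  onehot <- vector("list", nb)
  n_pix_total <- 0L
  ce_sum <- 0
  inter <- numeric(C)  # per-class sum p*t over the batch
  psum <- numeric(C)
  tsum <- numeric(C)
  for (b in seq_len(nb)) {
    lg <- logits[[b]]
    lab <- labels[[b]]
    d <- dim(lg)
    if (any(lab < 0) || any(lab >= C))
      stop(sprintf("label out of range 0..%d", C - 1L), call. = FALSE)
    p <- softmax3(lg)
    n <- d[1] * d[2]
    pm <- matrix(p, n, C)
    t <- matrix(0, n, C)
    t[cbind(seq_len(n), as.integer(lab) + 1L)] <- 1
    ce_sum <- ce_sum + sum(-log(pmax(pm[t == 1], 1e-12)))
    inter <- inter + colSums(pm * t)
    psum <- psum + colSums(pm)
    tsum <- tsum + colSums(t)
    n_pix_total <- n_pix_total + n
    probs[[b]] <- pm
    onehot[[b]] <- t
  }
  ce <- ce_sum / n_pix_total
  num <- 2 * inter + eps
  den <- psum + tsum + eps
  dice_c <- num / den
  dice_term <- -mean(dice_c[fg])
  out <- list(loss = ce + dice_term, ce = ce, dice_term = dice_term,
              per_class_soft_dice = dice_c)
  if (!grad) return(out)

  # d(-mean_fg dice_c)/d p_c(px) = -(1/|fg|) (2 t - dice_c) / den_c
  gdice_coef_t <- numeric(C); gdice_coef_t[fg] <- -2 / (length(fg) * den[fg])
  gdice_coef_0 <- numeric(C); gdice_coef_0[fg] <- dice_c[fg] / (length(fg) * den[fg])
  out$grad <- vector("list", nb)
  for (b in seq_len(nb)) {
    pm <- probs[[b]]
    t <- onehot[[b]]
    gp <- -t / pmax(pm, 1e-12) / n_pix_total                     # CE part
    gp <- gp + t * rep(gdice_coef_t, each = nrow(pm)) +
      rep(gdice_coef_0, each = nrow(pm))                         # Dice part
    # chain through softmax: gz = p * (gp - rowSums(gp * p))
    gz <- pm * (gp - rowSums(gp * pm))
    d <- dim(logits[[b]])
    dim(gz) <- d
    out$grad[[b]] <- gz
  }
  out
}

#' Per-class Dice evaluation over a dataset
#'
#' Predicts every case (argmax over logits), computes the Dice coefficient
#' of every foreground class per case, averages per class over cases (each
#' case weighted equally), and reports the mean over foreground classes.
#'
#' @param model An `rkseg_model` (or path to a checkpoint readable by
#'   [load_checkpoint()]).
#' @param dataset A list of samples, each a list with `image` `(H, W, C)`
#'   and `label` `(H, W)`.
#' @return A list of class `dice_report`: `per_class` (named numeric),
#'   `mean`, `n_cases`, and `per_case` (a data frame, one row per case and
#'   class).
#' @export
evaluate_dataset <- function(model, dataset) {
  if (is.character(model)) model <- load_checkpoint(model)
  C <- model$cfg$num_classes
  fg <- seq_len(C - 1L)
  rows <- list()
  for (i in seq_along(dataset)) {
    smp <- dataset[[i]]
    if (!is.null(dim(smp$label)) && max(smp$label) >= C)
      stop("dataset contains labels outside the model's class range",
           call. = FALSE)
    pred <- rkseg_predict(model, smp$image)
    for (cl in fg) {
      rows[[length(rows) + 1L]] <- data.frame(
        case = if (!is.null(smp$case_id)) smp$case_id else i,
        class = cl,
        dice = dice_coefficient(pred == cl, smp$label == cl))
    }
  }
  per_case <- do.call(rbind, rows)
  per_class <- tapply(per_case$dice, per_case$class, mean)
  per_class <- stats::setNames(as.numeric(per_class),
                               paste0("class_", names(per_class)))
  structure(list(per_class = per_class, mean = mean(per_class),
                 n_cases = length(dataset), per_case = per_case),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice report over %d cases\n", x$n_cases))
  for (nm in names(x$per_class))
    cat(sprintf("  %-10s %.4f\n", nm, x$per_class[[nm]]))
  cat(sprintf("  mean       %.4f\n", x$mean))
  invisible(x)
}

#' Write a Dice report to JSON and CSV
#'
#' @param report A `dice_report`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_dice_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(per_class = as.list(report$per_class),
                              mean = report$mean, n_cases = report$n_cases),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(report$per_case, csv_path, row.names = FALSE)
  invisible(report)
}
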