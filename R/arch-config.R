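#' Architecture configuration for an RK segmentation network
#'
#' An RKSeg network computes one time step of an s-stage Runge--Kutta method,
#' with every stage evaluated at its own spatial scale. A configuration fixes
#' the six degrees of freedom of the family: the orientation (whether stages
#' run from large to small scale, `"L"`, or the reverse, `"R"`), the stage
#' wiring scheme or backbone (`"E"` explicit, `"I"` implicit with
#' initial-value stages, `"R"` reduced implicit), the down-sampling depth
#' `d` (number of halved scales, which equals the number of stage nodes),
#' the constant per-node channel width `k`, and the image channel/class
#' counts.
#'
#' For backbone `"E"` the number of RK stages `s` equals `d`; for backbones
#' `"I"` and `"R"` each stage owns two nodes (an initial-value node X and an
#' increment node I or R), so `d` must be even and `s = d/2`, with at least
#' two stages.
#'
#' @param orientation `"L"` (stages from large to small scale) or `"R"`
#'   (reversed).
#' @param backbone `"E"`, `"I"` or `"R"`.
#' @param depth Positive integer; number of down-sampled scales and stage
#'   nodes.
#' @param width Positive integer; output channels of every node (constant
#'   across scales).
#' @param in_channels Positive integer; image modalities.
#' @param num_classes Positive integer; segmentation classes including
#'   background.
#' @param interpolation_mode Up-sampling interpolation; only `"bilinear"`
#'   (non-aligned corners) is implemented.
#' @param norm_kind Normalization inside nodes; only per-channel
#'   `"instance"` normalization with learnable affine is implemented.
#' @param pad_policy `"pad_and_crop"` pads odd-sized inputs up to the next
#'   multiple of `2^depth` and crops the logits back; `"reject"` raises an
#'   error instead.
#' @return An object of class `rkseg_config`.
#' @examples
#' cfg <- rkseg_config("L", "E", depth = 6, width = 32,
#'                     in_channels = 1, num_classes = 2)
#' count_parameters(cfg)$total
#' @export
rkseg_config <- function(orientation = c("L", "R"),
                         backbone = c("E", "I", "R"),
                         depth,
                         width = 32L,
                         in_channels = 1L,
                         num_classes = 2L,
                         interpolation_mode = "bilinear",
                         norm_kind = "instance",
                         pad_policy = c("pad_and_crop", "reject")) {
  orientation <- match.arg(orientation)
  backbone <- match.arg(backbone)
  pad_policy <- match.arg(pad_policy)
  interpolation_mode <- match.arg(interpolation_mode, "bilinear")
  norm_kind <- match.arg(norm_kind, "instance")
  cfg <- structure(
    list(orientation = orientation, backbone = backbone,
         depth = as.integer(depth), width = as.integer(width),
         in_channels = as.integer(in_channels),
         num_classes = as.integer(num_classes),
         interpolation_mode = interpolation_mode, norm_kind = norm_kind,
         pad_policy = pad_policy),
    class = "rkseg_config")
  validate_config(cfg)
}

#' Validate an RKSeg configuration
#'
#' Checks positivity of all size fields and the backbone-specific stage
#' rules: backbones `"I"` and `"R"` update their stages alternately, so the
#' node count must be even and there must be at least two stages.
#'
#' @param cfg An `rkseg_config`.
#' @return `cfg`, unchanged, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "rkseg_config"))
  for (f in c("depth", "width", "in_channels", "num_classes")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L)
      stop(sprintf("'%s' must be a positive integer, got %s", f,
                   deparse(v)), call. = FALSE)
  }
  if (cfg$backbone %in% c("I", "R")) {
    if (cfg$depth %% 2L != 0L)
      stop("odd depth with alternating backbone: backbones 'I' and 'R' ",
           "pair each stage with an initial-value node, so depth must be even",
           call. = FALSE)
    if (cfg$depth %/% 2L < 2L)
      stop("backbones 'I' and 'R' update stages alternately and need at ",
           "least two stages (depth >= 4)", call. = FALSE)
  }
  cfg
}

#' Number of RK stages implied by a configuration
#'
#' @param cfg An `rkseg_config`.
#' @return `depth` for backbone `"E"`, `depth/2` for `"I"` and `"R"`.
#' @export
n_stages <- function(cfg) {
  if (cfg$backbone == "E") cfg$depth else cfg$depth %/% 2L
}

# Trainable scalars of one two-conv node a -> k: two 3x3 convs (a->k, k->k)
# with biases, plus two per-channel affine normalizations (gamma, beta).
node_param_count <- function(a, k) 9L * a * k + 9L * k * k + 2L * k + 4L * k

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Closed-form trainable-parameter count
#'
#' Counts every trainable scalar of the configured network analytically:
#' convolution weights, convolution biases, and the learnable affine pair of
#' each normalization layer (running statistics, having no gradients, are
#' excluded). The pre-processor is one two-conv node `in_channels -> k` at
#' full resolution; stage node i of backbone `"E"` consumes `k*i` channels;
#' for backbones `"I"`/`"R"` the X nodes consume `k*i` and the increment
#' nodes `k*s` channels; the post-processor is `3x3,k / 3x3,k / 1x1,c`.
#' Orientation changes only the geometry of the scales, never the widths,
#' so counts are orientation-independent.
#'
#' @param cfg An `rkseg_config`.
#' @return A list of class `rkseg_param_report` with `total` (integer),
#'   `per_component` (named integer vector: `pre_processor`, `stage_*`,
#'   `post_processor`) and `total_millions_2dp` (half-up rounding, the
#'   convention of the published tables).
#' @examples
#' # heart-task configuration, explicit backbone: 278,370 scalars = 0.28 M
#' count_parameters(rkseg_config("L", "E", 6, 32, 1, 2))$total_millions_2dp
#' @export
count_parameters <- function(cfg) {
  validate_config(cfg)
  k <- cfg$width
  s <- n_stages(cfg)
  comp <- c(pre_processor = node_param_count(cfg$in_channels, k))
  if (cfg$backbone == "E") {
    stage <- vapply(seq_len(s), function(i) node_param_count(k * i, k),
                    numeric(1))
    names(stage) <- paste0("stage_E", seq_len(s))
  } else {
    xn <- vapply(seq_len(s), function(i) node_param_count(k * i, k),
                 numeric(1))
    names(xn) <- paste0("stage_X", seq_len(s))
    inc <- rep(node_param_count(k * s, k), s)
    names(inc) <- paste0("stage_", cfg$backbone, seq_len(s))
    stage <- c(xn, inc)
  }
  comp <- c(comp, stage,
            post_processor = node_param_count(k, k) +
              k * cfg$num_classes + cfg$num_classes)
  structure(list(total = sum(comp), per_component = comp,
                 total_millions_2dp = round_half_up(sum(comp) / 1e6, 2L)),
            class = "rkseg_param_report")
}

#' @export
print.rkseg_param_report <- function(x, ...) {
  cat("RKSeg trainable-parameter report\n")
  cat(sprintf("  total: %d scalars (%.2f M)\n", x$total,
              x$total_millions_2dp))
  for (nm in names(x$per_component))
    cat(sprintf("  %-16s %10d\n", nm, as.integer(x$per_component[[nm]])))
  invisible(x)
}

#' Scale schedule of the stage nodes
#'
#' Orientation `"L"` runs the stage computations from large scale to small
#' scale: node j sits at scale divisor 2^j (spatial size divided by 2^j).
#' Orientation `"R"` reverses the sequence. For backbones `"I"`/`"R"` the X
#' nodes are enumerated before the increment nodes. The pre- and
#' post-processor always work at full resolution (divisor 1).
#'
#' @param cfg An `rkseg_config`.
#' @return A data frame with columns `node` and `scale_divisor`, one row per
#'   stage node in evaluation order.
#' @export
scale_schedule <- function(cfg) {
  validate_config(cfg)
  s <- n_stages(cfg)
  if (cfg$backbone == "E") {
    nodes <- paste0("E", seq_len(s))
  } else {
    nodes <- c(paste0("X", seq_len(s)), paste0(cfg$backbone, seq_len(s)))
  }
  div <- 2L^seq_len(cfg$depth)
  if (cfg$orientation == "R") div <- rev(div)
  data.frame(node = nodes, scale_divisor = div)
}

#' @export
print.rkseg_config <- function(x, ...) {
  cat(sprintf("RKSeg-%s / RKCNN-%s  depth=%d (s=%d stages)  k=%d  in=%d  classes=%d\n",
              x$orientation, x$backbone, x$depth, n_stages(x), x$width,
              x$in_channels, x$num_classes))
  invisible(x)
}
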