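# Deterministic synthetic 2D segmentation tasks.
#
# The generator emulates the shape of MSD-style 2D problems: compact
# foreground objects (ellipses, or blobs carved from smoothed noise) with
# class-specific mean intensity on a noisy background, 1-4 modalities, 2-4
# classes. It exists so every other module is testable without downloading
# imaging data; it does not emulate MRI/CT physics.

#' Specification of a synthetic segmentation dataset
#'
#' @param n_cases Number of cases to generate.
#' @param image_size `(H, W)`; keep both divisible by `2^depth` of the model
#'   under test.
#' @param in_channels Modalities, 1-4. Channels share the anatomy but have
#'   per-channel intensity scalings, like registered MR sequences.
#' @param num_classes Classes including background, 2-4.
#' @param objects_per_case Inclusive range of object count per case. The
#'   first `num_classes - 1` objects cycle through the foreground classes
#'   so every class is present in (nearly) every case.
#' @param object_kinds Subset of `"ellipse"` and `"blob"` (thresholded
#'   smoothed noise).
#' @param contrast Mean intensity of foreground class `l` above background,
#'   per unit class index (class `l` interior sits at `l * contrast`).
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_cases = 20L, image_size = c(64L, 64L),
                       in_channels = 1L, num_classes = 2L,
                       objects_per_case = NULL,
                       object_kinds = c("ellipse", "blob"),
                       contrast = 1, noise_sd = 0.1, seed = 0L) {
  stopifnot(n_cases >= 1L, length(image_size) == 2L, all(image_size >= 8L),
            in_channels >= 1L, in_channels <= 4L,
            num_classes >= 2L, num_classes <= 4L,
            contrast > 0, noise_sd >= 0)
  object_kinds <- match.arg(object_kinds, c("ellipse", "blob"),
                            several.ok = TRUE)
  if (is.null(objects_per_case))
    objects_per_case <- c(num_classes - 1L, num_classes + 1L)
  stopifnot(length(objects_per_case) == 2L, objects_per_case[1] >= 1L,
            objects_per_case[2] >= objects_per_case[1])
  structure(list(n_cases = as.integer(n_cases),
                 image_size = as.integer(image_size),
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 objects_per_case = as.integer(objects_per_case),
                 object_kinds = object_kinds,
                 contrast = contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# separable Gaussian blur, reflecting borders; kernel radius 3*sigma
blur2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kx <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kx <- kx / sum(kx)
  pad_reflect <- function(v, r) c(rev(v[seq_len(r)]), v,
                                  rev(v[length(v) - seq_len(r) + 1L]))
  conv1 <- function(v) {
    vp <- pad_reflect(v, r)
    stats::filter(vp, kx, sides = 2)[(r + 1L):(r + length(v))]
  }
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

ellipse_mask <- function(H, W, cy, cx, ry, rx, theta) {
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(theta) * yy + sin(theta) * xx
  v <- -sin(theta) * yy + cos(theta) * xx
  (u / ry)^2 + (v / rx)^2 <= 1
}

blob_mask <- function(H, W, cy, cx, radius) {
  field <- blur2d(matrix(stats::rnorm(H * W), H, W), sigma = radius / 3)
  disk <- ellipse_mask(H, W, cy, cx, 1.6 * radius, 1.6 * radius, 0)
  inside <- field[disk]
  if (length(inside) < 4L) return(disk)
  field >= stats::quantile(inside, 0.45) & disk
}

#' Generate a synthetic segmentation dataset
#'
#' Deterministic in the spec's seed (the caller's RNG state is saved and
#' restored). Object interiors get intensity `class * contrast` above the
#' zero background in channel 1, scaled per channel for multi-modal images,
#' before additive Gaussian noise.
#'
#' @param spec A [synth_spec()].
#' @return A list of samples; each has `image` `(H, W, C)`, `label`
#'   `(H, W)` integer matrix, and `case_id`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  if (min(H, W) < 16L && "blob" %in% spec$object_kinds)
    stop("image too small for blob objects", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(spec$seed)

  # fixed per-channel intensity scaling, emulating modality response
  chan_scale <- c(1, 0.8, 1.25, 0.6)[seq_len(spec$in_channels)]
  n_fg <- spec$num_classes - 1L
  samples <- vector("list", spec$n_cases)
  for (cs in seq_len(spec$n_cases)) {
    label <- matrix(0L, H, W)
    n_obj <- sample(seq(spec$objects_per_case[1], spec$objects_per_case[2]),
                    1L)
    for (o in seq_len(n_obj)) {
      cl <- if (o <= n_fg) o else sample(n_fg, 1L)
      kind <- sample(spec$object_kinds, 1L)
      rad <- stats::runif(1, 0.08, 0.18) * min(H, W)
      cy <- stats::runif(1, rad + 1, H - rad)
      cx <- stats::runif(1, rad + 1, W - rad)
      msk <- if (kind == "ellipse") {
        ellipse_mask(H, W, cy, cx, rad * stats::runif(1, 0.6, 1),
                     rad * stats::runif(1, 0.6, 1),
                     stats::runif(1, 0, pi))
      } else {
        blob_mask(H, W, cy, cx, rad)
      }
      label[msk] <- cl
    }
    intens <- matrix(spec$contrast * label, H, W)
    image <- array(0, dim = c(H, W, spec$in_channels))
    for (ch in seq_len(spec$in_channels))
      image[, , ch] <- intens * chan_scale[ch] +
        stats::rnorm(H * W, sd = spec$noise_sd)
    samples[[cs]] <- list(image = image, label = label,
                          case_id = sprintf("case_%04d", cs))
  }
  samples
}

# ---- MSD-style folder I/O ---------------------------------------------------

#' Write samples in the Medical Segmentation Decathlon folder layout
#'
#' Creates `imagesTr/` and `labelsTr/` under `root`, one NIfTI file per
#' channel with nnU-Net-style `_0000`, `_0001` modality suffixes, labels as
#' unsigned 8-bit, plus a `dataset.json` with `modality`, `labels` and
#' `numTraining`.
#'
#' @param samples Output of [synth_generate()].
#' @param root Destination directory (created if absent).
#' @return `root`, invisibly.
#' @export
write_msd_layout <- function(samples, root) {
  img_dir <- file.path(root, "imagesTr")
  lab_dir <- file.path(root, "labelsTr")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  n_chan <- dim(samples[[1]]$image)[3]
  n_classes <- max(vapply(samples, function(s) max(s$label), 0L)) + 1L
  for (s in samples) {
    for (ch in seq_len(n_chan)) {
      f <- file.path(img_dir, sprintf("%s_%04d.nii.gz", s$case_id, ch - 1L))
      RNifti::writeNifti(RNifti::asNifti(s$image[, , ch]), f)
    }
    lab <- s$label
    storage.mode(lab) <- "integer"
    RNifti::writeNifti(RNifti::asNifti(lab, datatype = "uint8"),
                       file.path(lab_dir, paste0(s$case_id, ".nii.gz")))
  }
  meta <- list(
    modality = stats::setNames(as.list(paste0("synthetic_", seq_len(n_chan))),
                               sprintf("%d", seq_len(n_chan) - 1L)),
    labels = stats::setNames(
      as.list(c("background", paste0("class_", seq_len(n_classes - 1L)))),
      sprintf("%d", seq_len(n_classes) - 1L)),
    numTraining = length(samples))
  jsonlite::write_json(meta, file.path(root, "dataset.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(root)
}

#' Read a dataset written in the MSD folder layout
#'
#' Inverse of [write_msd_layout()]: pairs every label file with its
#' modality-suffixed image files. Labels round-trip losslessly; images
#' round-trip within floating-point precision.
#'
#' @param root Directory holding `imagesTr`, `labelsTr`, `dataset.json`.
#' @return A list of samples (as from [synth_generate()]).
#' @export
read_msd_layout <- function(root) {
  img_dir <- file.path(root, "imagesTr")
  lab_dir <- file.path(root, "labelsTr")
  for (d in c(img_dir, lab_dir))
    if (!dir.exists(d))
      stop(sprintf("missing folder '%s' under '%s'", basename(d), root),
           call. = FALSE)
  lab_files <- sort(list.files(lab_dir, pattern = "\\.nii(\\.gz)?$"))
  if (length(lab_files) == 0L)
    stop("no label volumes found in labelsTr", call. = FALSE)
  samples <- vector("list", length(lab_files))
  for (i in seq_along(lab_files)) {
    case_id <- sub("\\.nii(\\.gz)?$", "", lab_files[i])
    chan_files <- sort(list.files(
      img_dir, pattern = paste0("^", case_id, "_[0-9]{4}\\.nii(\\.gz)?$")))
    if (length(chan_files) == 0L)
      stop(sprintf("no image channels found for case '%s'", case_id),
           call. = FALSE)
    lab <- as.array(RNifti::readNifti(file.path(lab_dir, lab_files[i])))
    lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
    chans <- lapply(chan_files, function(f)
      as.array(RNifti::readNifti(file.path(img_dir, f))))
    image <- array(0, dim = c(dim(lab), length(chans)))
    for (ch in seq_along(chans)) image[, , ch] <- chans[[ch]]
    samples[[i]] <- list(image = image, label = lab, case_id = case_id)
  }
  samples
}

#' Write/read samples as paired 8-bit PNG files
#'
#' A lighter dialect of the same pairing: `images/<case>.png` (1-4 channels,
#' intensities affinely mapped to 8-bit; lossy for images) and
#' `labels/<case>.png` (class index stored directly in the 8-bit channel;
#' lossless for up to 256 classes). The per-case intensity ranges are
#' stored in `png_meta.json` so images can be mapped back approximately.
#'
#' @param samples Output of [synth_generate()].
#' @param root Destination directory.
#' @return `root`, invisibly.
#' @export
write_png_layout <- function(samples, root) {
  img_dir <- file.path(root, "images")
  lab_dir <- file.path(root, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (s in samples) {
    img <- s$image
    lo <- min(img); hi <- max(img)
    scl <- if (hi > lo) (img - lo) / (hi - lo) else img * 0
    n_chan <- dim(img)[3]
    png_arr <- if (n_chan == 1L) scl[, , 1] else {
      # pad 2-channel to 3 (png supports 1, 2(GA), 3, 4); use zeros
      if (n_chan == 2L) {
        z <- array(0, dim = c(dim(img)[1:2], 3L))
        z[, , 1:2] <- scl
        z
      } else scl
    }
    png::writePNG(png_arr, file.path(img_dir, paste0(s$case_id, ".png")))
    png::writePNG(s$label / 255, file.path(lab_dir,
                                           paste0(s$case_id, ".png")))
    meta[[s$case_id]] <- list(lo = lo, hi = hi, n_channels = n_chan)
  }
  jsonlite::write_json(meta, file.path(root, "png_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(root)
}

#' @rdname write_png_layout
#' @export
read_png_layout <- function(root) {
  img_dir <- file.path(root, "images")
  lab_dir <- file.path(root, "labels")
  for (d in c(img_dir, lab_dir))
    if (!dir.exists(d))
      stop(sprintf("missing folder '%s' under '%s'", basename(d), root),
           call. = FALSE)
  meta <- jsonlite::read_json(file.path(root, "png_meta.json"))
  lab_files <- sort(list.files(lab_dir, pattern = "\\.png$"))
  samples <- vector("list", length(lab_files))
  for (i in seq_along(lab_files)) {
    case_id <- sub("\\.png$", "", lab_files[i])
    lab_raw <- png::readPNG(file.path(lab_dir, lab_files[i]))
    lab <- matrix(as.integer(round(lab_raw * 255)), nrow(lab_raw),
                  ncol(lab_raw))
    img_raw <- png::readPNG(file.path(img_dir, paste0(case_id, ".png")))
    m <- meta[[case_id]]
    if (length(dim(img_raw)) == 2L) dim(img_raw) <- c(dim(img_raw), 1L)
    img_raw <- img_raw[, , seq_len(m$n_channels), drop = FALSE]
    image <- img_raw * (m$hi - m$lo) + m$lo
    samples[[i]] <- list(image = image, label = lab, case_id = case_id)
  }
  samples
}
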