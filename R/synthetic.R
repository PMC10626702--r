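#' Class presets for synthetic lesion texture
#'
#' Each lesion class is modeled as a stationary Gaussian random field with a
#' class-specific mean intensity, standard deviation and isotropic
#' correlation length, blended into the background through a feathered
#' elliptical mask. The presets are fixed package constants, chosen so that
#' the three feature families can tell the classes apart:
#'
#' * `cyst` — homogeneous, low-contrast: a dark, smooth radiolucency
#'   (mean 70, sd 6, correlation length 3 px, soft border 2 px);
#' * `tumor` — high-variance, short-correlation: rough internal texture
#'   (mean 110, sd 30, correlation length 0.8 px, crisp border 1 px);
#' * `abscess` — intermediate and diffuse-bordered (mean 90, sd 15,
#'   correlation length 1.8 px, feathering 4 px);
#' * `normal` — no lesion drawn; the annotation center marks a background
#'   sampling point.
#'
#' @return named list of per-class parameter lists (`mean`, `sd`,
#'   `corr_len`, `softness`).
#' @export
lesion_presets <- function() list(
  cyst    = list(mean = 70,  sd = 6,  corr_len = 3,   softness = 2),
  tumor   = list(mean = 110, sd = 30, corr_len = 0.8, softness = 1),
  abscess = list(mean = 90,  sd = 15, corr_len = 1.8, softness = 4),
  normal  = NULL
)

#' Default background parameters
#'
#' The panoramic-like background is a smooth vertical brightness gradient
#' (dark at the top edge, brighter toward the jaw line) plus a gentle
#' horizontal sinusoid and i.i.d. Gaussian noise.
#'
#' @return list with `base`, `gradient_amplitude`, `horizontal_amplitude`,
#'   `noise_sd`.
#' @export
background_defaults <- function() list(
  base = 110, gradient_amplitude = 30, horizontal_amplitude = 8, noise_sd = 6
)

#' Stationary Gaussian random texture field
#'
#' White Gaussian noise convolved with a Gaussian kernel of standard
#' deviation `correlation_length` (reflect boundary), then rescaled
#' empirically to the requested mean and standard deviation, clipped to
#' `[0, 255]` and quantized to integers. `sd = 0` returns a constant field;
#' `correlation_length = 0` skips the smoothing (pure white noise). Uses the
#' current R RNG state — seed before calling for reproducibility.
#'
#' @param shape `(height, width)` in pixels, both positive.
#' @param mean_intensity target mean in `[0, 255]`.
#' @param sd target standard deviation (>= 0).
#' @param correlation_length isotropic correlation length in pixels (>= 0).
#' @return integer matrix in `[0, 255]`.
#' @export
texture_field <- function(shape, mean_intensity, sd, correlation_length = 0) {
  if (length(shape) != 2L || any(shape < 1)) stop("shape must be two positive integers")
  if (sd < 0) stop("sd must be >= 0")
  if (correlation_length < 0) stop("correlation_length must be >= 0")
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (sd == 0) return(clip_quantize(matrix(mean_intensity, h, w)))
  f <- matrix(stats::rnorm(h * w), h, w)
  if (correlation_length > 0) {
    k <- gaussian_kernel1d(correlation_length)
    f <- conv_sep(conv_sep(f, k, 1L), k, 2L)
  }
  s <- stats::sd(as.vector(f))
  z <- if (s > 0) (f - mean(f)) / s else f * 0
  clip_quantize(mean_intensity + sd * z)
}

#' Specify one synthetic lesion
#'
#' @param label one of `"cyst"`, `"tumor"`, `"abscess"`, `"normal"`.
#' @param center `(row, col)`, 1-based pixel coordinates.
#' @param semi_axes `(a, b)` ellipse semi-axes in pixels (each >= 5);
#'   ignored for `"normal"`.
#' @param texture_params optional override of the class preset: list with
#'   `mean`, `sd`, `corr_len`.
#' @param border_softness Gaussian edge feathering in pixels; default from
#'   the class preset.
#' @return list of class `"lesion_spec"`.
#' @export
lesion_spec <- function(label, center, semi_axes = c(12, 14),
                        texture_params = NULL, border_softness = NULL) {
  label <- match.arg(label, c("cyst", "tumor", "abscess", "normal"))
  preset <- lesion_presets()[[label]]
  if (label != "normal") {
    if (any(semi_axes < 5)) stop("semi_axes must each be >= 5 px")
    if (is.null(texture_params)) {
      texture_params <- preset[c("mean", "sd", "corr_len")]
    }
    if (is.null(border_softness)) border_softness <- preset$softness
  }
  structure(list(label = label, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 texture_params = texture_params,
                 border_softness = border_softness),
            class = "lesion_spec")
}

# smooth elliptical blending mask in [0, 1]: 1 well inside the ellipse,
# logistic falloff across the boundary with width ~ softness pixels
ellipse_mask <- function(h, w, center, semi_axes, softness) {
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt(((r - center[1]) / semi_axes[1])^2 + ((c_ - center[2]) / semi_axes[2])^2)
  if (softness <= 0) return((d <= 1) * 1.0)
  k <- min(semi_axes) / softness
  1 / (1 + exp((d - 1) * k))
}

#' Generate one synthetic radiograph with (at most) one lesion
#'
#' Background = vertical gradient + horizontal sinusoid + Gaussian noise;
#' lesion pixels are replaced by a [texture_field()] blended through the
#' feathered elliptical mask of [lesion_spec()]. A `"normal"` spec returns
#' the background untouched. Uses the current RNG state.
#'
#' @param image_shape `(H, W)`; default `c(400, 800)`.
#' @param spec a [lesion_spec()].
#' @param background list like [background_defaults()].
#' @return list with `image` (integer matrix) and `spec`.
#' @export
generate_image <- function(image_shape = c(400, 800), spec,
                           background = background_defaults()) {
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  if (h < 80L || w < 80L) stop("image must be at least 80x80 to admit a 40x40 ROI")
  vert <- background$base +
    background$gradient_amplitude * sin(pi * (seq_len(h) - 1) / (h - 1))
  horiz <- background$horizontal_amplitude * sin(2 * pi * (seq_len(w) - 1) / w)
  bg <- outer(vert, rep(1, w)) + outer(rep(1, h), horiz) +
    matrix(stats::rnorm(h * w, sd = background$noise_sd), h, w)
  bg <- clip_quantize(bg)
  if (spec$label == "normal") {
    return(list(image = bg, spec = spec))
  }
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  r0 <- spec$center[1]; c0 <- spec$center[2]
  if (r0 - a < 1 || r0 + a > h || c0 - b < 1 || c0 + b > w) {
    stop(sprintf(
      "lesion ellipse (center %.0f,%.0f semi-axes %.0f,%.0f) outside the %dx%d image",
      r0, c0, a, b, h, w))
  }
  tp <- spec$texture_params
  tex <- texture_field(c(h, w), tp$mean, tp$sd, tp$corr_len)
  alpha <- ellipse_mask(h, w, spec$center, spec$semi_axes, spec$border_softness)
  list(image = clip_quantize((1 - alpha) * bg + alpha * tex), spec = spec)
}

#' Configuration of a synthetic study
#'
#' Defaults follow the reference cohort's class distribution: 73 abscesses,
#' 52 cysts, 27 tumors and 40 normal radiographs. (The source reports both
#' these counts and a total of N = 172, which they do not sum to — the
#' counts are taken as authoritative, giving 192 images.)
#'
#' @param class_counts named non-negative integer vector over the four
#'   classes.
#' @param image_shape `(H, W)`, each >= 80.
#' @param background background parameter list.
#' @param seed study seed (integer).
#' @return list of class `"study_config"`.
#' @export
study_config <- function(class_counts = c(abscess = 73, cyst = 52,
                                          tumor = 27, normal = 40),
                         image_shape = c(400, 800),
                         background = background_defaults(),
                         seed = 1L) {
  if (is.null(names(class_counts)) ||
      !all(names(class_counts) %in% c("cyst", "tumor", "abscess", "normal"))) {
    stop("class_counts must be named with the four study classes")
  }
  if (any(class_counts < 0)) stop("class counts must be >= 0")
  if (any(image_shape < 80)) stop("image_shape must be at least 80x80")
  structure(list(class_counts = class_counts,
                 image_shape = as.integer(image_shape),
                 background = background, seed = as.integer(seed)),
            class = "study_config")
}

# per-image seed derived from the study seed; kept below 2^31
derive_seed <- function(seed, i) (as.numeric(seed) * 48271 + i * 9973) %% 2147483629

#' Generate a full synthetic study
#'
#' Emits exactly `sum(class_counts)` images in a deterministic class order
#' (abscess, cyst, tumor, normal blocks), each with its own derived seed, so
#' a fixed study seed reproduces the study bit for bit. Lesion centers and
#' semi-axes are drawn uniformly with margins guaranteeing both the ellipse
#' and the 40x40 ROI fit inside the image; semi-axes are uniform in
#' `[10, 16]` px so the lesion fills most of the ROI.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, each image is written as
#'   `<image_id>.png` and the annotations as `annotations.csv` (0-based
#'   center coordinates, columns `image_id,label,center_row,center_col`).
#' @return list with `images` (named list of integer matrices) and
#'   `annotations` (data frame with 1-based `center_row`, `center_col`).
#' @export
generate_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  counts <- config$class_counts
  labels <- rep(names(counts), times = counts)
  h <- config$image_shape[1]; w <- config$image_shape[2]
  margin <- 21L + 16L   # ROI half-window + max semi-axis
  images <- list()
  ann <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    set.seed(derive_seed(config$seed, i))
    lab <- labels[i]
    center <- c(round(stats::runif(1, margin, h - margin)),
                round(stats::runif(1, margin, w - margin)))
    id <- sprintf("img%03d_%s", i, lab)
    spec <- if (lab == "normal") {
      lesion_spec("normal", center)
    } else {
      lesion_spec(lab, center, semi_axes = round(stats::runif(2, 10, 16)))
    }
    gen <- generate_image(config$image_shape, spec, config$background)
    images[[id]] <- gen$image
    ann[[i]] <- data.frame(image_id = id, label = lab,
                           center_row = center[1], center_col = center[2],
                           stringsAsFactors = FALSE)
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(image_id = character(0), label = character(0),
               center_row = integer(0), center_col = integer(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(images)) {
      write_gray_png(images[[id]], file.path(out_dir, paste0(id, ".png")))
    }
    write_annotations(annotations, file.path(out_dir, "annotations.csv"))
  }
  list(images = images, annotations = annotations)
}

#' Read / write annotation tables
#'
#' On disk the center coordinates are 0-based (row-major pixel convention);
#' in memory they are 1-based like R matrices. These two functions perform
#' the conversion.
#'
#' @param ann annotation data frame with 1-based centers.
#' @param path CSV path.
#' @export
write_annotations <- function(ann, path) {
  out <- ann
  out$center_row <- out$center_row - 1L
  out$center_col <- out$center_col - 1L
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "label", "center_row", "center_col")
  if (!all(need %in% names(ann))) {
    stop("annotation CSV must have columns ", paste(need, collapse = ", "))
  }
  ann$center_row <- ann$center_row + 1L
  ann$center_col <- ann$center_col + 1L
  ann
}
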