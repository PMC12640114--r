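#' Stimulus degradation specifications
#'
#' A `degradation` describes one stimulus manipulation applied to every image
#' of a training epoch or a test battery: the identity (`"none"`), Gaussian
#' blur of a stated reference sigma, grayscale conversion, or a test-time hue
#' rotation. Blur sigmas are expressed at a 256-pixel reference resolution and
#' rescaled to the actual image width when applied, so the same nominal sigma
#' removes the same fraction of image detail at any resolution.
#'
#' @param kind One of `"none"`, `"blur"`, `"grayscale"`, `"hue_rotation"`.
#' @param sigma_ref Blur standard deviation in pixels at the 256-pixel
#'   reference resolution. Required (and only allowed) for `kind = "blur"`.
#' @param angle Hue rotation in degrees, taken modulo 360. Required (and only
#'   allowed) for `kind = "hue_rotation"`.
#' @return An object of class `degradation`.
#' @examples
#' degradation("blur", sigma_ref = 4)
#' degradation("none")
#' @export
degradation <- function(kind = c("none", "blur", "grayscale", "hue_rotation"),
                        sigma_ref = NULL, angle = NULL) {
  kind <- match.arg(kind)
  if (kind == "blur") {
    if (is.null(sigma_ref)) abort("`sigma_ref` is required for kind = 'blur'")
    if (!is.numeric(sigma_ref) || length(sigma_ref) != 1 || sigma_ref < 0)
      abort("`sigma_ref` must be a single non-negative number")
  } else if (!is.null(sigma_ref)) {
    abort("`sigma_ref` is only meaningful for kind = 'blur'")
  }
  if (kind == "hue_rotation") {
    if (is.null(angle)) abort("`angle` is required for kind = 'hue_rotation'")
    angle <- as.numeric(angle) %% 360
  } else if (!is.null(angle)) {
    abort("`angle` is only meaningful for kind = 'hue_rotation'")
  }
  structure(
    list(kind = kind,
         sigma_ref = if (kind == "blur") as.numeric(sigma_ref) else NULL,
         angle = if (kind == "hue_rotation") angle else NULL),
    class = "degradation"
  )
}

#' @export
format.degradation <- function(x, ...) {
  switch(x$kind,
    none = "none",
    blur = sprintf("blur(sigma_ref=%g)", x$sigma_ref),
    grayscale = "grayscale",
    hue_rotation = sprintf("hue_rotation(%g°)", x$angle)
  )
}

#' @export
print.degradation <- function(x, ...) {
  cat("<degradation> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize a degradation to JSON
#'
#' @param x A `degradation`.
#' @param json A JSON string such as `{"kind":"blur","sigma_ref":4}`.
#' @return `degradation_to_json()` a JSON string; `degradation_from_json()` a
#'   `degradation`.
#' @export
degradation_to_json <- function(x) {
  stopifnot(inherits(x, "degradation"))
  jsonlite::toJSON(x[!vapply(x, is.null, logical(1))], auto_unbox = TRUE)
}

#' @rdname degradation_to_json
#' @export
degradation_from_json <- function(json) {
  l <- jsonlite::fromJSON(json)
  degradation(l$kind, sigma_ref = l$sigma_ref, angle = l$angle)
}

check_raster <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    abort(sprintf("`%s` must be an H x W x 3 array", arg))
  invisible(image)
}

# 1-D Gaussian kernel truncated at 4 sigma, normalized to sum 1
gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded convolution matrix mapping a symmetric-padded signal of length
# n + 2r back to length n
conv_band_matrix <- function(n, kern) {
  r <- (length(kern) - 1L) / 2L
  M <- matrix(0, n, n + 2L * r)
  for (j in seq_along(kern)) M[cbind(seq_len(n), seq_len(n) + j - 1L)] <- kern[j]
  M
}

#' Gaussian blur with resolution-scaled sigma
#'
#' Convolves each channel with an isotropic Gaussian whose effective standard
#' deviation is `sigma_ref * width / ref_size`, so a nominal sigma stated at
#' the 256-pixel reference resolution degrades any image by the same relative
#' amount. The kernel is truncated at 4 effective sigma; boundaries are
#' handled by symmetric reflection; the result is clipped to [0, 1] on exit.
#' `sigma_ref = 0` returns the input unchanged.
#'
#' @param image An H x W x 3 array with values in [0, 1].
#' @param sigma_ref Non-negative blur sigma at the reference resolution.
#' @param ref_size Reference width in pixels (default 256).
#' @return A blurred raster of the same shape.
#' @export
gaussian_blur <- function(image, sigma_ref, ref_size = 256L) {
  check_raster(image)
  if (!is.numeric(sigma_ref) || length(sigma_ref) != 1 || is.na(sigma_ref) ||
      sigma_ref < 0)
    abort("`sigma_ref` must be a single non-negative number")
  if (sigma_ref == 0) return(image)
  d <- dim(image)
  sigma <- sigma_ref * d[2] / ref_size
  kern <- gaussian_kernel_1d(sigma)
  r <- (length(kern) - 1L) / 2L
  if (r >= d[1] || r >= d[2])
    abort("blur kernel radius exceeds image size")
  pr <- c(r:1, seq_len(d[1]), d[1]:(d[1] - r + 1L))
  pc <- c(r:1, seq_len(d[2]), d[2]:(d[2] - r + 1L))
  Kr <- conv_band_matrix(d[1], kern)
  Kc <- conv_band_matrix(d[2], kern)
  out <- image
  for (ch in 1:3) out[, , ch] <- Kr %*% image[pr, pc, ch] %*% t(Kc)
  pmin(pmax(out, 0), 1)
}

#' Grayscale conversion (BT.601 luminance)
#'
#' Computes per-pixel luminance with the ITU-R BT.601 coefficients
#' (0.299, 0.587, 0.114) and replicates it into all three channels, so tensor
#' shapes are unchanged across regimens. Idempotent.
#'
#' @param image An H x W x 3 array.
#' @return A raster of identical shape with equal channels.
#' @export
to_grayscale <- function(image) {
  check_raster(image)
  # already achromatic: return unchanged (makes idempotence exact)
  if (identical(image[, , 1], image[, , 2]) &&
      identical(image[, , 2], image[, , 3])) return(image)
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  array(c(y, y, y), dim = dim(image))
}

# float HSV -> RGB (base hsv() quantizes through 8-bit color strings)
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Hue rotation
#'
#' Shifts every pixel's hue by `angle` degrees (modulo 360) in a floating
#' point hue-saturation-value decomposition; saturation and value are
#' preserved. Used as a test-time perturbation probing reliance on specific
#' chromatic values.
#'
#' @param image An H x W x 3 array in [0, 1].
#' @param angle Rotation in degrees; any real value, taken modulo 360.
#' @return The hue-rotated raster.
#' @export
hue_rotate <- function(image, angle) {
  check_raster(image)
  angle <- as.numeric(angle) %% 360
  if (angle == 0) return(image)
  d <- dim(image)
  m <- matrix(image, ncol = 3)
  hsv <- rgb2hsv(t(m), maxColorValue = 1)
  rgb <- hsv_to_rgb((hsv[1, ] + angle / 360) %% 1, hsv[2, ], hsv[3, ])
  array(rgb, dim = d)
}

#' Apply a degradation specification to one raster
#'
#' Dispatches on `spec$kind`; `kind = "none"` is an exact identity.
#'
#' @param spec A [degradation()].
#' @param image An H x W x 3 array in [0, 1].
#' @param ref_size Blur reference resolution, passed to [gaussian_blur()].
#' @return The degraded raster.
#' @export
apply_degradation <- function(spec, image, ref_size = 256L) {
  stopifnot(inherits(spec, "degradation"))
  switch(spec$kind,
    none = image,
    blur = gaussian_blur(image, spec$sigma_ref, ref_size),
    grayscale = to_grayscale(image),
    hue_rotation = hue_rotate(image, spec$angle),
    abort(sprintf("unknown degradation kind '%s'", spec$kind))
  )
}

#' Preprocess a list of rasters into a model input batch
#'
#' Mirrors the restricted augmentation used for training: in train mode each
#' image receives a random crop position and an independent 0.5-probability
#' horizontal flip drawn from the caller's RNG stream; in eval mode a
#' deterministic center crop and no flip. All pixels are affinely rescaled
#' from [0, 1] to [-1, 1].
#'
#' @param images List of H x W x 3 arrays in [0, 1] (all the same shape).
#' @param train_mode Logical; random crop + flip when `TRUE`.
#' @param crop_size Side of the square crop; must be strictly smaller than or
#'   equal to the image side (strictly smaller for random crops to matter).
#' @return A `(crop_size, crop_size, 3, N)` numeric array in [-1, 1].
#' @export
preprocess_batch <- function(images, train_mode = FALSE, crop_size) {
  if (length(images) == 0) abort("`images` must be non-empty")
  d <- dim(images[[1]])
  if (crop_size > d[1] || crop_size > d[2])
    abort("`crop_size` must not exceed the image size")
  n <- length(images)
  out <- array(0, dim = c(crop_size, crop_size, 3L, n))
  max_off <- d[1] - crop_size
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (train_mode) {
      oy <- if (max_off > 0) sample.int(max_off + 1L, 1L) - 1L else 0L
      ox <- if (max_off > 0) sample.int(max_off + 1L, 1L) - 1L else 0L
      flip <- runif(1) < 0.5
    } else {
      oy <- ox <- max_off %/% 2L
      flip <- FALSE
    }
    crop <- img[oy + seq_len(crop_size), ox + seq_len(crop_size), , drop = FALSE]
    if (flip) crop <- crop[, crop_size:1, , drop = FALSE]
    out[, , , i] <- 2 * crop - 1
  }
  out
}

# cache key for precomputed degraded image lists
degradation_key <- function(spec) format(spec)

# degrade every image of a list once (used to cache per-phase training inputs)
degrade_images <- function(images, spec, ref_size = 256L) {
  if (spec$kind == "none") return(images)
  lapply(images, function(im) apply_degradation(spec, im, ref_size))
}
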