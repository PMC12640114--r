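#' Specification of a procedural labeled image set
#'
#' Describes a synthetic multi-class image set in which class identity is
#' carried redundantly by two cue families: a class-specific hue (removed by
#' grayscale conversion) and a class-specific band-pass texture frequency
#' (removed by Gaussian blur). Each image renders a class-specific procedural
#' shape, colored at the class hue and textured with band-pass filtered noise
#' in the class's frequency band, over a neutral noisy background. The set
#' stands in for large natural-image corpora at desk scale: both degradations
#' remove real, class-discriminative information.
#'
#' Defaults (10 classes, 200 train + 50 test images per class, 64 x 64
#' pixels) are sized so a full regimen grid trains on one CPU in minutes
#' while both cue families stay informative.
#'
#' @param n_classes Number of classes.
#' @param train_per_class,test_per_class Images per class and split.
#' @param image_size Square image side in pixels (>= 32).
#' @param hue_separation Degrees between adjacent class hue centers; defaults
#'   to equal spacing `360 / n_classes`.
#' @param hue_jitter_sd Per-image jitter (degrees, Gaussian) around the class
#'   hue center. A non-zero jitter makes hue an informative but noisy cue, so
#'   no single cue family suffices on its own — mirroring natural categories,
#'   where color is indicative rather than diagnostic. Class mean hues stay
#'   at their centers.
#' @param texture_freq_bands List of `c(low, high)` cycles/pixel pairs, one
#'   per class, each within (0, 0.5]. Default: narrow bands with centers
#'   equally spaced in [0.28, 0.48], high enough that blur at the reference
#'   severity suppresses them.
#' @param shape_families Character vector of procedural shape identifiers,
#'   one per class. The default recycles five families, so shape narrows the
#'   class down but cannot identify it alone.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (clipped to [0, 1]); discourages trivial memorization.
#' @param seed Integer seed; equal specs generate bitwise-equal sets.
#' @return An object of class `imageset_spec`.
#' @export
imageset_spec <- function(n_classes = 10L, train_per_class = 200L,
                          test_per_class = 50L, image_size = 64L,
                          hue_separation = 360 / n_classes,
                          hue_jitter_sd = 18,
                          texture_freq_bands = NULL,
                          shape_families = NULL,
                          noise_sd = 0.02, seed = 1L) {
  chk_count <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
      abort(sprintf("`%s` must be a positive integer >= %d", name, min))
  }
  chk_count(n_classes, "n_classes")
  chk_count(train_per_class, "train_per_class")
  chk_count(test_per_class, "test_per_class")
  chk_count(image_size, "image_size", min = 32L)
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (!is.numeric(hue_jitter_sd) || hue_jitter_sd < 0)
    abort("`hue_jitter_sd` must be >= 0")
  if (is.null(texture_freq_bands)) {
    # bands sit above the reference blur's pass band, so blurring removes
    # (not merely attenuates) the texture cue
    centers <- if (n_classes == 1) 0.38
               else seq(0.28, 0.48, length.out = n_classes)
    texture_freq_bands <- lapply(centers, function(c) c(c - 0.02, c + 0.02))
  }
  if (length(texture_freq_bands) != n_classes)
    abort("`texture_freq_bands` must have one (low, high) pair per class")
  for (b in texture_freq_bands)
    if (length(b) != 2 || b[1] <= 0 || b[2] > 0.5 || b[1] >= b[2])
      abort("`texture_freq_bands` entries must be (low, high) within (0, 0.5]")
  families <- c("blob", "tri", "square", "star5", "ring",
                "pent", "hex", "star3", "ellipse", "cross")
  if (is.null(shape_families))
    shape_families <- families[((seq_len(n_classes) - 1L) %% 5L) + 1L]
  if (length(shape_families) != n_classes)
    abort("`shape_families` must have length n_classes")
  structure(
    list(n_classes = as.integer(n_classes),
         train_per_class = as.integer(train_per_class),
         test_per_class = as.integer(test_per_class),
         image_size = as.integer(image_size),
         hue_separation = as.numeric(hue_separation),
         hue_jitter_sd = as.numeric(hue_jitter_sd),
         texture_freq_bands = texture_freq_bands,
         shape_families = shape_families,
         noise_sd = as.numeric(noise_sd),
         seed = as.integer(seed)),
    class = "imageset_spec"
  )
}

#' @export
print.imageset_spec <- function(x, ...) {
  cat(sprintf("<imageset_spec> %d classes, %d train + %d test per class, %dx%d px, seed %d\n",
              x$n_classes, x$train_per_class, x$test_per_class,
              x$image_size, x$image_size, x$seed))
  invisible(x)
}

new_imageset <- function(images, labels, split, n_classes, provenance) {
  set <- structure(
    list(images = images, labels = as.integer(labels), split = split,
         n_classes = as.integer(n_classes), provenance = provenance),
    class = "imageset"
  )
  validate_imageset(set)
}

#' Validate a labeled image set
#'
#' Asserts the container invariants: equal numbers of images and labels,
#' identical raster shapes, pixel values within [0, 1], and every class
#' represented at least once.
#'
#' @param set An `imageset`.
#' @return `set`, invisibly usable in pipes; errors on violation.
#' @export
validate_imageset <- function(set) {
  stopifnot(inherits(set, "imageset"))
  if (length(set$images) != length(set$labels))
    abort("images and labels differ in length")
  if (length(set$images) == 0) abort("image set is empty")
  d <- dim(set$images[[1]])
  for (im in set$images) {
    if (!identical(dim(im), d)) abort("rasters differ in shape")
  }
  rng <- range(vapply(set$images, function(im) c(min(im), max(im)),
                      numeric(2)))
  if (rng[1] < 0 || rng[2] > 1) abort("pixel values outside [0, 1]")
  if (!all(set$labels >= 0L & set$labels < set$n_classes))
    abort("labels outside [0, n_classes)")
  if (!setequal(unique(set$labels), 0:(set$n_classes - 1L)))
    abort("some class absent from the split")
  set
}

#' @export
print.imageset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<imageset> %s split: %d images (%dx%dx3), %d classes\n",
              x$split, length(x$images), d[1], d[2], x$n_classes))
  invisible(x)
}

# frequencies of an n-point DFT in cycles/sample
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

# band-pass filtered white noise, standardized to sd 1
bandpass_noise <- function(n, lo, hi) {
  z <- matrix(rnorm(n * n), n, n)
  f <- fft_freqs(n)
  fr <- sqrt(outer(f^2, f^2, "+"))
  mask <- fr >= lo & fr <= hi
  zt <- fft(z) * mask
  tex <- Re(fft(zt, inverse = TRUE)) / (n * n)
  s <- sd(as.vector(tex))
  if (s == 0) tex else tex / s
}

# radius-vs-angle boundary functions for the procedural shape families
shape_mask <- function(n, family, cx, cy, r0, rot) {
  xs <- (seq_len(n) - cx) / n
  ys <- (seq_len(n) - cy) / n
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  rad <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X) + rot
  kgon <- function(k) r0 * cos(pi / k) / cos(((th %% (2 * pi / k))) - pi / k)
  bound <- switch(family,
    blob    = r0 * (1 + 0.30 * sin(3 * th)),
    tri     = kgon(3),
    square  = kgon(4),
    pent    = kgon(5),
    hex     = kgon(6),
    star3   = r0 * (1 + 0.40 * cos(3 * th)),
    star5   = r0 * (1 + 0.35 * cos(5 * th)),
    ellipse = r0 / sqrt((cos(th) / 1.25)^2 + (sin(th) / 0.8)^2),
    cross   = NULL,
    ring    = NULL,
    abort(sprintf("unknown shape family '%s'", family))
  )
  if (family == "cross") {
    w <- r0 * 0.35
    Xr <- X * cos(rot) + Y * sin(rot)
    Yr <- -X * sin(rot) + Y * cos(rot)
    (abs(Xr) < w & abs(Yr) < r0) | (abs(Yr) < w & abs(Xr) < r0)
  } else if (family == "ring") {
    rad <= r0 & rad >= 0.45 * r0
  } else {
    rad <= bound
  }
}

render_class_image <- function(n, hue_deg, hue_jitter_sd, band, family,
                               noise_sd) {
  # jittered placement, scale, orientation and hue per image
  cx <- n / 2 + runif(1, -0.08, 0.08) * n
  cy <- n / 2 + runif(1, -0.08, 0.08) * n
  r0 <- runif(1, 0.24, 0.32)
  rot <- runif(1, 0, 2 * pi)
  hue <- (hue_deg + rnorm(1, 0, hue_jitter_sd)) %% 360
  mask <- shape_mask(n, family, cx, cy, r0, rot)
  tex <- bandpass_noise(n, band[1], band[2])
  v <- pmin(pmax(0.58 + 0.28 * tex, 0), 1)
  rgb <- hsv_to_rgb(rep(hue / 360, n * n), rep(0.65, n * n), as.vector(v))
  img <- array(0.5, dim = c(n, n, 3))
  mv <- as.vector(mask)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mv] <- rgb[mv, ch]
    img[, , ch] <- plane
  }
  if (noise_sd > 0) img <- img + array(rnorm(n * n * 3, 0, noise_sd), dim(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic labeled image set
#'
#' Draws the train and the test split from the same generative process with
#' disjoint random draws, deterministically for a fixed `spec$seed`.
#'
#' @param spec An [imageset_spec()].
#' @return A list with elements `train` and `test`, each an `imageset`.
#' @examples
#' sets <- generate_dataset(imageset_spec(n_classes = 2, train_per_class = 4,
#'                                        test_per_class = 2, seed = 7))
#' length(sets$train$images)  # 8
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "imageset_spec"))
  set.seed(spec$seed)
  hue0 <- 10  # fixed global offset so class 0 is not exactly red
  hues <- (hue0 + (0:(spec$n_classes - 1)) * spec$hue_separation) %% 360
  gen_split <- function(per_class, split) {
    images <- vector("list", per_class * spec$n_classes)
    labels <- integer(per_class * spec$n_classes)
    i <- 1L
    for (cl in 0:(spec$n_classes - 1L)) {
      for (j in seq_len(per_class)) {
        images[[i]] <- render_class_image(
          spec$image_size, hues[cl + 1L], spec$hue_jitter_sd,
          spec$texture_freq_bands[[cl + 1L]],
          spec$shape_families[cl + 1L], spec$noise_sd)
        labels[i] <- cl
        i <- i + 1L
      }
    }
    new_imageset(images, labels, split, spec$n_classes, spec)
  }
  list(train = gen_split(spec$train_per_class, "train"),
       test = gen_split(spec$test_per_class, "test"))
}

# mean chromatic vector of one raster: per-pixel residual orthogonal to the
# achromatic (equal-channel) axis, averaged over pixels
mean_chroma_vector <- function(image) {
  m <- matrix(image, ncol = 3)
  colMeans(m - rowMeans(m))
}

# radial power centroid of the luminance plane over f >= f_min cycles/pixel
# (very low frequencies excluded so the shape envelope does not dominate)
image_spectral_centroid <- function(image, f_min = 0.05) {
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  y <- y - mean(y)
  P <- Mod(fft(y))^2
  f <- fft_freqs(nrow(y))
  fr <- sqrt(outer(fft_freqs(nrow(y))^2, fft_freqs(ncol(y))^2, "+"))
  keep <- fr >= f_min
  if (sum(P[keep]) == 0) return(0)
  sum(P[keep] * fr[keep]) / sum(P[keep])
  }

#' Cue diagnostics for a labeled image set
#'
#' Confirms that both class cue families are separated, so grayscale and blur
#' each remove real information. Per class the report gives the mean
#' chromatic vector (and its hue angle in the opponent plane) and the mean
#' spectral centroid of the luminance plane. Chromatic separation is the mean
#' pairwise Euclidean distance between class mean chroma vectors; texture
#' separation the mean pairwise absolute difference between class spectral
#' centroids.
#'
#' @param set An `imageset`.
#' @return A list of class `cue_diagnostics`: `per_class` (tibble),
#'   `chromatic_separation`, `texture_separation`, `separation_defined`
#'   (FALSE, with NA separations, for a single-class set).
#' @export
cue_diagnostics <- function(set) {
  stopifnot(inherits(set, "imageset"))
  if (length(set$images) == 0) abort("empty image set")
  classes <- sort(unique(set$labels))
  rows <- lapply(classes, function(cl) {
    idx <- which(set$labels == cl)
    ch <- t(vapply(set$images[idx], mean_chroma_vector, numeric(3)))
    cv <- colMeans(ch)
    # opponent-plane hue angle of the class mean chroma vector
    o1 <- (cv[1] - cv[2]) / sqrt(2)
    o2 <- (cv[1] + cv[2] - 2 * cv[3]) / sqrt(6)
    tibble(
      class = cl,
      chroma_r = cv[1], chroma_g = cv[2], chroma_b = cv[3],
      chroma_magnitude = sqrt(sum(cv^2)),
      hue_angle = (atan2(o2, o1) * 180 / pi) %% 360,
      sf_centroid = mean(vapply(set$images[idx], image_spectral_centroid,
                                numeric(1)))
    )
  })
  per_class <- bind_rows(rows)
  if (length(classes) < 2) {
    chrom <- NA_real_; texs <- NA_real_; defined <- FALSE
  } else {
    cm <- as.matrix(per_class[, c("chroma_r", "chroma_g", "chroma_b")])
    dd <- as.matrix(stats::dist(cm))
    chrom <- mean(dd[upper.tri(dd)])
    sc <- per_class$sf_centroid
    ds <- abs(outer(sc, sc, "-"))
    texs <- mean(ds[upper.tri(ds)])
    defined <- TRUE
  }
  structure(list(per_class = per_class,
                 chromatic_separation = chrom,
                 texture_separation = texs,
                 separation_defined = defined),
            class = "cue_diagnostics")
}

#' @export
print.cue_diagnostics <- function(x, ...) {
  cat("<cue_diagnostics>\n")
  if (x$separation_defined) {
    cat(sprintf("  chromatic separation: %.4f\n", x$chromatic_separation))
    cat(sprintf("  texture separation:   %.4f cycles/pixel\n",
                x$texture_separation))
  } else {
    cat("  separations undefined (single-class set)\n")
  }
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.cue_diagnostics <- function(x, ...) x$per_class

#' Persist / load a labeled image set as PNG files plus a CSV manifest
#'
#' `write_imageset()` writes one PNG per image, a `manifest.csv` with columns
#' `filename`, `label`, `split`, and (for generated sets) a `spec.json`
#' sidecar. `read_imageset()` loads any directory obeying the same manifest
#' schema, including user-supplied real images, selecting one split.
#'
#' @param set An `imageset`.
#' @param dir Directory to write to / read from (created if needed).
#' @param split Which split to load.
#' @return `write_imageset()` the directory, invisibly; `read_imageset()` an
#'   `imageset`.
#' @export
write_imageset <- function(set, dir) {
  stopifnot(inherits(set, "imageset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fns <- sprintf("%s_%05d_class%02d.png", set$split, seq_along(set$images),
                 set$labels)
  for (i in seq_along(set$images))
    png::writePNG(set$images[[i]], file.path(dir, fns[i]))
  manifest_path <- file.path(dir, "manifest.csv")
  man <- tibble(filename = fns, label = set$labels, split = set$split)
  if (file.exists(manifest_path)) {
    old <- as_tibble(read.csv(manifest_path, stringsAsFactors = FALSE))
    man <- bind_rows(old[old$split != set$split, ], man)
  }
  write.csv(man, manifest_path, row.names = FALSE)
  if (inherits(set$provenance, "imageset_spec")) {
    prov <- set$provenance
    prov$texture_freq_bands <- lapply(prov$texture_freq_bands, as.numeric)
    jsonlite::write_json(unclass(prov), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_imageset
#' @export
read_imageset <- function(dir, split = c("train", "test")) {
  split <- match.arg(split)
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) abort("no manifest.csv in directory")
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  man <- man[man$split == split, ]
  if (nrow(man) == 0) abort(sprintf("no '%s' rows in manifest", split))
  images <- lapply(file.path(dir, man$filename), function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
    if (dim(im)[3] == 4) im <- im[, , 1:3]
    im
  })
  new_imageset(images, man$label, split, max(man$label) + 1L, dir)
}
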