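# Deterministic generator of lesion-like segmentation fixtures.
#
# Images emulate the qualitative look of ultrasound/dermoscopy lesion data:
# a smooth background intensity field carrying multiplicative Rayleigh-like
# speckle, with one or more blurred, boundary-perturbed elliptical lesions
# shifted in contrast against the background. Every sample is a pure
# function of (seed, index), so fixtures never need to ship with the
# package. No claim of physical fidelity is made; see the methods vignette
# for what these fixtures do and do not exercise.

#' Configuration of the synthetic lesion generator
#'
#' @param n_images number of images in the dataset.
#' @param image_size integer length-2, height and width.
#' @param seed integer; together with the image index it fully determines
#'   every sample.
#' @param lesions_per_image integer range (min, max) of lesion counts.
#' @param radius_range lesion radius range as a fraction of `min(H, W)`.
#' @param contrast foreground-background intensity gap in `[0, 1]`; 0 makes
#'   the lesions invisible.
#' @param noise_sigma relative amplitude of the multiplicative speckle.
#' @param blur_sigma Gaussian blur (pixels) of the lesion boundary.
#' @param channels 1 (grayscale) or 3 (RGB with mild channel tints).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 16, image_size = c(64, 64), seed = 1,
                             lesions_per_image = c(1, 2),
                             radius_range = c(0.12, 0.3), contrast = 0.35,
                             noise_sigma = 0.15, blur_sigma = 1.5,
                             channels = 1) {
  if (n_images < 0) stop("n_images must be non-negative")
  if (length(image_size) != 2 || any(image_size < 8))
    stop("image_size must be two values of at least 8")
  if (length(lesions_per_image) != 2 || lesions_per_image[1] > lesions_per_image[2] ||
      lesions_per_image[1] < 0)
    stop("lesions_per_image must be a non-decreasing non-negative range")
  if (length(radius_range) != 2 || radius_range[1] <= 0 ||
      radius_range[1] > radius_range[2])
    stop("radius_range must be a positive non-decreasing range")
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]")
  if (!channels %in% c(1, 3)) stop("channels must be 1 or 3")
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 lesions_per_image = as.integer(lesions_per_image),
                 radius_range = radius_range, contrast = contrast,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 channels = as.integer(channels)),
            class = "synthetic_config")
}

# run expr with the RNG seeded to s, restoring the caller's RNG state
with_seed <- function(s, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(s)
  force(expr)
}

sample_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

gblur2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

#' Generate one synthetic lesion sample
#'
#' Fully deterministic in `(cfg$seed, index)`: the lesion count, centres,
#' radii, eccentricities and low-frequency boundary perturbations, the
#' background field and the speckle are all drawn from a stream seeded by
#' the pair, so the same call always returns a bit-identical sample.
#'
#' @param cfg a [synthetic_config()].
#' @param index 1-based sample index.
#' @return a `segmentation_sample`: list with `image` (`H x W x channels`
#'   array of 8-bit-quantised intensities in `[0, 1]`), `mask` (binary
#'   `H x W` matrix) and `id`.
#' @export
generate_sample <- function(cfg, index) {
  stopifnot(inherits(cfg, "synthetic_config"))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  with_seed(sample_seed(cfg$seed, index), {
    # lesion mask: union of boundary-perturbed ellipses
    n_les <- if (cfg$lesions_per_image[1] == cfg$lesions_per_image[2])
      cfg$lesions_per_image[1]
    else sample(cfg$lesions_per_image[1]:cfg$lesions_per_image[2], 1)
    mask <- matrix(0, H, W)
    rr <- matrix(rep(seq_len(H), W), H, W)
    cc <- matrix(rep(seq_len(W), each = H), H, W)
    for (l in seq_len(n_les)) {
      r0 <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2]) * min(H, W)
      ecc <- stats::runif(1, 0.6, 1)
      th <- stats::runif(1, 0, pi)
      cy <- stats::runif(1, 0.2 * H, 0.8 * H)
      cx <- stats::runif(1, 0.2 * W, 0.8 * W)
      ak <- stats::rnorm(3, 0, 0.06)
      ph <- stats::runif(3, 0, 2 * pi)
      dy <- rr - cy; dx <- cc - cx
      # rotate into the ellipse frame
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      rho <- sqrt((u / r0)^2 + (v / (r0 * ecc))^2)
      phi <- atan2(v, u)
      bound <- 1 + ak[1] * cos(2 * phi + ph[1]) + ak[2] * cos(3 * phi + ph[2]) +
        ak[3] * cos(4 * phi + ph[3])
      mask[rho <= bound] <- 1
    }
    # background: smooth random field with multiplicative Rayleigh speckle
    field <- gblur2(matrix(stats::rnorm(H * W), H, W), sigma = min(H, W) / 10)
    field <- 0.45 + 0.1 * field / max(stats::sd(field), 1e-8)
    ray <- sqrt(stats::rnorm(H * W)^2 + stats::rnorm(H * W)^2) / sqrt(pi / 2)
    speckle <- 1 + cfg$noise_sigma * (matrix(ray, H, W) - 1)
    fg <- gblur2(mask, cfg$blur_sigma)
    base <- (field + cfg$contrast * fg) * speckle
    img <- if (cfg$channels == 1) {
      array(quantize8(base), c(H, W, 1))
    } else {
      tint <- 1 + stats::runif(3, -0.08, 0.08)
      array(quantize8(c(base * tint[1], base * tint[2], base * tint[3])),
            c(H, W, 3))
    }
    structure(list(image = img, mask = mask,
                   id = sprintf("syn%06d", as.integer(index))),
              class = "segmentation_sample")
  })
}

#' Generate a full synthetic dataset in memory
#'
#' @param cfg a [synthetic_config()].
#' @return list of `segmentation_sample` objects of length `cfg$n_images`.
#' @export
generate_dataset <- function(cfg) {
  lapply(seq_len(cfg$n_images), function(i) generate_sample(cfg, i))
}

#' Write a dataset as paired PNGs
#'
#' Layout: `<dir>/images/<id>.png` and `<dir>/masks/<id>.png` with matching
#' stems; masks are stored as 0/255. When called with a config, the dataset
#' is generated first; the generator config is serialised alongside as
#' `config.yaml` for provenance.
#'
#' @param x a [synthetic_config()] or a list of `segmentation_sample`s.
#' @param out_dir output directory.
#' @return invisibly, the vector of sample ids written.
#' @export
write_dataset <- function(x, out_dir) {
  cfg <- NULL
  if (inherits(x, "synthetic_config")) {
    cfg <- x
    x <- generate_dataset(x)
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in x) {
    img <- s$image
    if (dim(img)[3] == 1) dim(img) <- dim(img)[1:2]
    png::writePNG(img, file.path(out_dir, "images", paste0(s$id, ".png")))
    png::writePNG(s$mask, file.path(out_dir, "masks", paste0(s$id, ".png")))
  }
  if (!is.null(cfg))
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(vapply(x, function(s) s$id, character(1)))
}

#' Read a paired-PNG dataset
#'
#' Inverse of [write_dataset()]: masks are mapped 255 -> 1 and must be
#' strictly 0/255 (a mask holding any other value is a validation error
#' naming the file). Images missing their mask are skipped with a warning
#' and listed in the `errors` attribute of the result.
#'
#' @param dir dataset directory containing `images/` and `masks/`.
#' @return list of `segmentation_sample`s, with an `errors` attribute
#'   (character vector of problems, empty when the directory is clean).
#' @export
read_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$"))
  out <- list()
  errors <- character(0)
  for (f in imgs) {
    id <- sub("\\.png$", "", f)
    mf <- file.path(dir, "masks", f)
    if (!file.exists(mf)) {
      errors <- c(errors, sprintf("missing mask for image '%s'", f))
      warning(sprintf("skipping '%s': no matching mask", f), call. = FALSE)
      next
    }
    img <- png::readPNG(file.path(dir, "images", f))
    if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1)
    if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    m <- png::readPNG(mf)
    if (length(dim(m)) == 3) m <- m[, , 1]
    mv <- round(m * 255)
    if (!all(mv %in% c(0, 255)))
      stop(sprintf("mask '%s' is not binary: contains value(s) %s", mf,
                   paste(utils::head(setdiff(sort(unique(mv)), c(0, 255)), 3),
                         collapse = ", ")))
    out[[length(out) + 1]] <- structure(
      list(image = img, mask = (mv == 255) * 1, id = id),
      class = "segmentation_sample")
  }
  attr(out, "errors") <- errors
  out
}

# -- augmentation ------------------------------------------------------------

#' Augmentation configuration
#'
#' All ranges default to the identity; [augment()] with a default config
#' returns its input unchanged.
#'
#' @param rotate rotation range in degrees (draws uniformly; exact array
#'   rotation is used for multiples of 90).
#' @param brightness multiplicative brightness jitter range.
#' @param hue hue shift range (fraction of the hue circle; 3-channel images
#'   only).
#' @param crop minimum retained fraction of each spatial dimension for the
#'   random crop; the crop is resized back to the original size. Must be in
#'   `(0, 1]`.
#' @return an `aug_config` object.
#' @export
aug_config <- function(rotate = c(0, 0), brightness = c(1, 1), hue = c(0, 0),
                       crop = 1) {
  if (crop <= 0 || crop > 1) stop("crop fraction must be in (0, 1]")
  structure(list(rotate = rotate, brightness = brightness, hue = hue,
                 crop = crop), class = "aug_config")
}

rot90k <- function(m, k) {   # exact right-angle rotation, counter-clockwise
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE][, , drop = FALSE]
  m
}

eb_rotate <- function(m, angle, nearest = FALSE) {
  im <- EBImage::rotate(EBImage::Image(m), angle,
                        filter = if (nearest) "none" else "bilinear",
                        output.dim = dim(m), bg.col = 0)
  as.matrix(EBImage::imageData(im))
}

eb_resize <- function(m, H, W, nearest = FALSE) {
  im <- EBImage::resize(EBImage::Image(m), w = H, h = W,
                        filter = if (nearest) "none" else "bilinear")
  as.matrix(EBImage::imageData(im))
}

apply_chan <- function(img, f) {
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- f(img[, , ch])
  out
}

#' Augment a segmentation sample
#'
#' Applies, in order: joint rotation of image and mask (nearest-neighbour
#' resampling for the mask, so it stays strictly binary; exact array
#' rotation for multiples of 90 degrees), hue and brightness jitter
#' (image only), and a joint random crop resized back to the original
#' size. All draws come from the R RNG; pass `seed` for reproducibility.
#'
#' @param sample a `segmentation_sample`.
#' @param cfg an [aug_config()].
#' @param seed optional integer seed for the jitter draws.
#' @return an augmented `segmentation_sample`; the mask remains 0/1 and the
#'   image keeps its size.
#' @export
augment <- function(sample, cfg = aug_config(), seed = NULL) {
  stopifnot(inherits(cfg, "aug_config"))
  run <- function() {
    img <- sample$image; mask <- sample$mask
    H <- nrow(mask); W <- ncol(mask)
    # rotation
    ang <- stats::runif(1, cfg$rotate[1], cfg$rotate[2])
    if (ang != 0) {
      if (ang %% 90 == 0 && H == W) {
        k <- as.integer(ang / 90)
        img <- apply_chan(img, function(m) rot90k(m, k))
        mask <- rot90k(mask, k)
      } else {
        img <- apply_chan(img, function(m) eb_rotate(m, ang))
        mask <- eb_rotate(mask, ang, nearest = TRUE)
      }
    }
    # brightness / hue (image only)
    br <- stats::runif(1, cfg$brightness[1], cfg$brightness[2])
    if (br != 1) img <- pmin(pmax(img * br, 0), 1)
    hs <- stats::runif(1, cfg$hue[1], cfg$hue[2])
    if (hs != 0 && dim(img)[3] == 3) {
      rgb <- matrix(aperm(img, c(3, 1, 2)), 3)
      hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
      hsv[1, ] <- (hsv[1, ] + hs) %% 1
      col <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
      rgb2 <- grDevices::col2rgb(col) / 255
      img <- aperm(array(rgb2, c(3, H, W)), c(2, 3, 1))
    }
    # random crop, resized back
    if (cfg$crop < 1) {
      fh <- stats::runif(1, cfg$crop, 1)
      fw <- stats::runif(1, cfg$crop, 1)
      ch <- max(2L, floor(fh * H)); cw <- max(2L, floor(fw * W))
      if (ch > H || cw > W) stop("crop larger than image")
      oy <- sample.int(H - ch + 1L, 1); ox <- sample.int(W - cw + 1L, 1)
      if (ch < H || cw < W) {
        cr <- function(m) m[oy:(oy + ch - 1L), ox:(ox + cw - 1L), drop = FALSE]
        img <- apply_chan_resize(img, cr, H, W)
        mask <- eb_resize(cr(mask), H, W, nearest = TRUE)
      }
    }
    mask <- (mask > 0.5) * 1
    structure(list(image = img, mask = mask, id = sample$id),
              class = "segmentation_sample")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

apply_chan_resize <- function(img, cr, H, W) {
  C <- dim(img)[3]
  out <- array(0, c(H, W, C))
  for (ch in seq_len(C)) out[, , ch] <- eb_resize(cr(img[, , ch]), H, W)
  pmin(pmax(out, 0), 1)
}
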