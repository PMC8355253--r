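#' Specify a synthetic slide
#'
#' Describes one synthetic whole-slide image: a textured background carrying a
#' small number of elliptical lesions whose exact pixel support is returned as
#' the ground-truth mask.  Real gigapixel slides of this kind hold sparse
#' regions of interest that can be orders of magnitude smaller than the slide;
#' the generator reproduces that regime at desk scale with every pixel's label
#' known by construction.
#'
#' Lesions are drawn in a designated image channel whose background level is
#' exactly zero by default, so lesion evidence is separated from background by
#' a closed-form margin.  Under average downsampling any block that contains at
#' least one lesion pixel keeps a strictly positive value in that channel,
#' which is what makes exact cascade-versus-dense equivalence checks possible
#' (see [make_threshold_oracle()]).
#'
#' @param width,height Slide dimensions in pixels.
#' @param n_lesions Number of elliptical lesions (>= 0).
#' @param lesion_axis_range Length-2 numeric, minimum and maximum ellipse
#'   semi-axis in pixels.
#' @param lesion_intensity Length-2 numeric range; each lesion's value in the
#'   lesion channel is drawn uniformly from it.  Keep the lower end well above
#'   zero so lesions survive 8-bit quantization after deep downsampling.
#' @param lesion_channel Index of the channel carrying lesion signal.
#' @param background_mean,background_amplitude Per-channel mean and half-range
#'   of the smoothed background noise; the lesion channel defaults to zero
#'   background so the lesion margin is exact.
#' @param background_grain Spacing in pixels of the noise lattice that is
#'   bilinearly interpolated to produce the smooth background texture.
#' @param rotate Should ellipses be randomly rotated?
#' @param sparsity_ceiling Warn if the lesion pixel fraction exceeds this.
#' @param min_size Minimum slide side in pixels (one tile of the consuming
#'   pyramid).
#' @param seed Integer RNG seed; identical specs produce bit-identical slides.
#' @return A `slide_spec` object (a named list).
#' @seealso [generate_slide()], [generate_dataset()]
#' @export
slide_spec <- function(width = 4096, height = 4096, n_lesions = 3,
                       lesion_axis_range = c(40, 80),
                       lesion_intensity = c(0.85, 0.95),
                       lesion_channel = 2,
                       background_mean = c(0.75, 0, 0.65),
                       background_amplitude = c(0.12, 0, 0.12),
                       background_grain = 64,
                       rotate = TRUE,
                       sparsity_ceiling = 0.01,
                       min_size = 512,
                       seed = 1L) {
  check_number(width, "width", min = 1)
  check_number(height, "height", min = 1)
  check_number(n_lesions, "n_lesions", min = 0)
  if (width < min_size || height < min_size) {
    abort(sprintf(
      "Slide dimensions %dx%d are below the minimum size %dx%d (one tile).",
      as.integer(width), as.integer(height), as.integer(min_size),
      as.integer(min_size)))
  }
  if (length(lesion_axis_range) != 2 || lesion_axis_range[1] < 1 ||
      diff(lesion_axis_range) < 0) {
    abort("`lesion_axis_range` must be (min, max) with min >= 1.")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_lesions = as.integer(n_lesions),
         lesion_axis_range = lesion_axis_range,
         lesion_intensity = lesion_intensity,
         lesion_channel = as.integer(lesion_channel),
         background_mean = background_mean,
         background_amplitude = background_amplitude,
         background_grain = background_grain,
         rotate = isTRUE(rotate),
         sparsity_ceiling = sparsity_ceiling,
         min_size = as.integer(min_size),
         seed = as.integer(seed)),
    class = "slide_spec")
}

#' @export
print.slide_spec <- function(x, ...) {
  cat(sprintf("<slide_spec> %dx%d px, %d lesion(s), axes [%g, %g], seed %d\n",
              x$width, x$height, x$n_lesions,
              x$lesion_axis_range[1], x$lesion_axis_range[2], x$seed))
  invisible(x)
}

# One channel of smoothed background texture.  Knots are pre-drawn so the
# channel loop can run after lesion parameters without disturbing RNG order.
render_background_plane <- function(spec, knots) {
  if (is.null(knots)) return(matrix(0, spec$height, spec$width))
  plane <- bilinear_resize(knots, spec$height, spec$width)
  if (min(knots) < 0 || max(knots) > 1) plane <- pmin(pmax(plane, 0), 1)
  plane
}

draw_background_knots <- function(spec) {
  kn_h <- max(2, ceiling(spec$height / spec$background_grain) + 1)
  kn_w <- max(2, ceiling(spec$width / spec$background_grain) + 1)
  purrr::map(1:3, function(ch) {
    amp <- spec$background_amplitude[ch]
    mu <- spec$background_mean[ch]
    if (amp == 0 && mu == 0) return(NULL)
    matrix(runif(kn_h * kn_w, mu - amp, mu + amp), kn_h, kn_w)
  })
}

draw_lesion_params <- function(spec) {
  r <- spec$lesion_axis_range
  purrr::map_dfr(seq_len(spec$n_lesions), function(k) {
    a <- runif(1, r[1], r[2])
    b <- runif(1, r[1], r[2])
    theta <- if (spec$rotate) runif(1, 0, pi) else 0
    margin <- ceiling(max(a, b)) + 1
    if (spec$width - 2 * margin < 1 || spec$height - 2 * margin < 1) {
      abort(sprintf(
        "A lesion with semi-axes up to %.0f px cannot fit inside a %dx%d slide.",
        max(a, b), spec$width, spec$height))
    }
    tibble(lesion = k, a = a, b = b, theta = theta,
           cx = runif(1, margin + 1, spec$width - margin),
           cy = runif(1, margin + 1, spec$height - margin),
           intensity = runif(1, spec$lesion_intensity[1],
                             spec$lesion_intensity[2]))
  })
}

# Exact rasterization on pixel centers: pixel (row y, col x) is lesion iff the
# point (x, y) satisfies the rotated-ellipse inequality.
rasterize_ellipse <- function(les, width, height) {
  r <- max(les$a, les$b)
  x0 <- max(1L, floor(les$cx - r)); x1 <- min(width, ceiling(les$cx + r))
  y0 <- max(1L, floor(les$cy - r)); y1 <- min(height, ceiling(les$cy + r))
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - les$cx, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - les$cy, length(ys), length(xs))
  u <- (dx * cos(les$theta) + dy * sin(les$theta)) / les$a
  v <- (-dx * sin(les$theta) + dy * cos(les$theta)) / les$b
  list(rows = ys, cols = xs, inside = (u^2 + v^2) <= 1)
}

#' Generate a synthetic slide
#'
#' Renders the slide described by a [slide_spec()]: smoothed-noise background,
#' elliptical lesions composited into the lesion channel, and a binary
#' ground-truth mask that marks exactly the union of lesion supports.  Pixel
#' values are snapped to the 8-bit grid so file round trips are lossless.
#'
#' @param spec A [slide_spec()].
#' @return A `synthetic_slide`: list with `image` (height x width x 3 array in
#'   \code{[0, 1]}), `gt_mask` (integer 0/1 matrix), `spec`, and `lesions`
#'   (tibble of drawn ellipse parameters: semi-axes `a`, `b`, rotation
#'   `theta`, center `cx`, `cy`, `intensity`).
#' @examples
#' slide <- generate_slide(slide_spec(512, 512, n_lesions = 1, seed = 7))
#' sum(slide$gt_mask)
#' @export
generate_slide <- function(spec) {
  if (!inherits(spec, "slide_spec")) abort("`spec` must be a `slide_spec`.")
  withr::with_seed(spec$seed, {
    knots <- draw_background_knots(spec)
    mask <- matrix(0L, spec$height, spec$width)
    params <- tibble(lesion = integer(), a = double(), b = double(),
                     theta = double(), cx = double(), cy = double(),
                     intensity = double())
    rasters <- list()
    if (spec$n_lesions > 0) {
      params <- draw_lesion_params(spec)
      rasters <- purrr::map(seq_len(nrow(params)), function(k) {
        rasterize_ellipse(params[k, ], spec$width, spec$height)
      })
      for (ras in rasters) {
        sub <- mask[ras$rows, ras$cols]
        sub[ras$inside] <- 1L
        mask[ras$rows, ras$cols] <- sub
      }
    }
    # channels are rendered one at a time to bound peak memory on large slides
    img <- array(0, c(spec$height, spec$width, 3))
    for (ch in 1:3) {
      plane <- render_background_plane(spec, knots[[ch]])
      for (k in seq_along(rasters)) {
        ras <- rasters[[k]]
        sub <- plane[ras$rows, ras$cols]
        if (ch == spec$lesion_channel) {
          sub[ras$inside] <- params$intensity[k]
        } else {
          # darken the other channels so lesions are visible in renderings
          sub[ras$inside] <- sub[ras$inside] * 0.55
        }
        plane[ras$rows, ras$cols] <- sub
      }
      img[, , ch] <- quantize8(plane)
      rm(plane)
    }
    frac <- sum(mask) / (spec$width * spec$height)
    if (frac > spec$sparsity_ceiling) {
      warning(sprintf(
        "Lesion pixel fraction %.4f exceeds the sparsity ceiling %.4f.",
        frac, spec$sparsity_ceiling), call. = FALSE)
    }
    structure(list(image = img, gt_mask = mask, spec = spec,
                   lesions = params),
              class = "synthetic_slide")
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf(
    "<synthetic_slide> %dx%d px, %d lesion(s), %d lesion px (%.3f%%)\n",
    x$spec$width, x$spec$height, x$spec$n_lesions, sum(x$gt_mask),
    100 * sum(x$gt_mask) / length(x$gt_mask)))
  invisible(x)
}

#' Generate a reproducible synthetic dataset with a train/test split
#'
#' Draws `n_slides` slide specifications from a template, assigning each slide
#' its own RNG substream (root seed plus slide counter) so any slide can be
#' re-generated independently, and randomly splits slides into training and
#' testing sets at a fixed ratio.  With 143 slides and the default 68% ratio
#' the split is 97 training / 46 testing slides.
#'
#' @param n_slides Number of slides (>= 1).
#' @param template A [slide_spec()] used for every slide (only the seed
#'   varies between slides).
#' @param seed Root seed governing both the per-slide substreams and the split.
#' @param train_frac Fraction assigned to the training split; the training
#'   count is `round(train_frac * n_slides)`.
#' @param dir Optional directory; when given, slides and masks are written as
#'   PNG files and the manifest as `manifest.csv`.
#' @return A `wsi_dataset`: list with `manifest` (tibble: slide_id, width,
#'   height, n_lesions, seed, split, path, mask_path) and `specs` (named list
#'   of per-slide [slide_spec()]s).
#' @export
generate_dataset <- function(n_slides, template = slide_spec(), seed = 1L,
                             train_frac = 0.68, dir = NULL) {
  check_number(n_slides, "n_slides", min = 1)
  n_slides <- as.integer(n_slides)
  n_train <- as.integer(round(train_frac * n_slides))
  specs <- purrr::map(seq_len(n_slides), function(k) {
    s <- template
    s$seed <- as.integer(seed + k)
    s
  })
  names(specs) <- sprintf("slide_%03d", seq_len(n_slides))
  split <- withr::with_seed(as.integer(seed), {
    out <- rep("test", n_slides)
    out[sample.int(n_slides, n_train)] <- "train"
    out
  })
  manifest <- tibble(
    slide_id = names(specs),
    width = template$width, height = template$height,
    n_lesions = template$n_lesions,
    seed = purrr::map_int(specs, "seed"),
    split = split,
    path = NA_character_, mask_path = NA_character_)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- file.path(dir, paste0(manifest$slide_id, ".png"))
    manifest$mask_path <- file.path(dir, paste0(manifest$slide_id, "_mask.png"))
    for (k in seq_len(n_slides)) {
      slide <- generate_slide(specs[[k]])
      write_image(slide$image, manifest$path[k])
      write_mask(slide$gt_mask, manifest$mask_path[k])
    }
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  }
  structure(list(manifest = manifest, specs = specs), class = "wsi_dataset")
}

#' @export
print.wsi_dataset <- function(x, ...) {
  cat(sprintf("<wsi_dataset> %d slides (%d train / %d test)\n",
              nrow(x$manifest), sum(x$manifest$split == "train"),
              sum(x$manifest$split == "test")))
  invisible(x)
}

#' Read and write slide images and masks
#'
#' Slides are stored as 8-bit RGB PNG (or TIFF when the path ends in
#' `.tif`/`.tiff`); masks as single-channel PNG/TIFF with 0 = background and
#' 255 = lesion.
#'
#' @param img Height x width x 3 array in \code{[0, 1]}.
#' @param mask Integer 0/1 matrix.
#' @param path Output file path.
#' @return `write_*` return `path` invisibly; `read_image()` returns an array,
#'   `read_mask()` an integer 0/1 matrix.
#' @export
write_image <- function(img, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Package `tiff` is required to write TIFF files.")
    }
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  write_image(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Package `tiff` is required to read TIFF files.")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' @rdname write_image
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  as_binary_mask((m >= 0.5) * 1L)
}
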