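#' Architecture of the single-stream FCN-32s tile segmenter
#'
#' Describes the modified VGG16-backbone fully convolutional network used as
#' the per-level tile segmenter: a 100-pixel-padded first 3x3 convolution,
#' five conv blocks each followed by ceil-mode 2x2/2 max pooling, a 7x7
#' "fc6" convolution, 1x1 "fc7", a 3-plane score layer, one 32x-stride
#' kernel-64 transposed convolution for upsampling, and a symmetric center
#' crop back to the input size.  The 3 score planes are read as (background,
#' lesion, ignore) with the lesion plane defining the probability map.
#'
#' @param input_size Nominal training tile side in pixels.
#' @return An `fcn32s_spec` object.
#' @seealso [trace_shapes()]
#' @export
fcn32s_spec <- function(input_size = 512) {
  structure(list(
    input_size = as.integer(input_size),
    conv_blocks = list(c(64, 64), c(128, 128), c(256, 256, 256),
                       c(512, 512, 512), c(512, 512, 512)),
    first_pad = 100L, conv_pad = 1L, conv_kernel = 3L,
    pool_kernel = 2L, pool_stride = 2L,
    fc6_kernel = 7L, fc6_width = 4096L, fc7_width = 4096L,
    n_classes = 3L,
    upsample_stride = 32L, upsample_kernel = 64L),
    class = "fcn32s_spec")
}

#' Spatial-dimension trace of the FCN-32s
#'
#' Walks the network layer by layer and reports each layer's output spatial
#' size, using the standard convolution arithmetic: pad-100 first conv and
#' pad-1 3x3 convs (`out = in + 2p - 2`), ceil-mode 2x2/2 pooling
#' (`out = ceiling(in / 2)`), valid 7x7 fc6 (`out = in - 6`), 1x1 fc7, a
#' stride-32 kernel-64 transposed convolution (`out = (in - 1) * 32 + 64`)
#' and the final symmetric center crop to the input size.  For a 512 x 512
#' input this yields Conv1_2 = 710, pool outputs 355/178/89/45/23, Drop7 = 17,
#' Upsampled = 576 and Output = 512.
#'
#' @param spec An [fcn32s_spec()].
#' @param input_hw Input spatial size, length-1 or length-2 integer.
#' @return A tibble with `layer`, `height`, `width`, `channels`.
#' @examples
#' trace_shapes(fcn32s_spec(), 512)
#' @export
trace_shapes <- function(spec = fcn32s_spec(), input_hw = spec$input_size) {
  if (!inherits(spec, "fcn32s_spec")) abort("`spec` must be an `fcn32s_spec`.")
  hw <- as.integer(rep(input_hw, length.out = 2))
  if (any(hw < 1)) abort("`input_hw` must be positive.")
  rows <- list(tibble(layer = "Input", height = hw[1], width = hw[2],
                      channels = 3L))
  add <- function(layer, hw, ch) {
    rows[[length(rows) + 1]] <<- tibble(layer = layer, height = hw[1],
                                        width = hw[2], channels = as.integer(ch))
  }
  cur <- hw
  for (b in seq_along(spec$conv_blocks)) {
    widths <- spec$conv_blocks[[b]]
    for (k in seq_along(widths)) {
      pad <- if (b == 1 && k == 1) spec$first_pad else spec$conv_pad
      cur <- cur + 2L * pad - (spec$conv_kernel - 1L)
      add(sprintf("Conv%d_%d", b, k), cur, widths[k])
    }
    cur <- as.integer(ceiling(cur / spec$pool_stride))
    add(sprintf("Pool%d", b), cur, widths[length(widths)])
  }
  if (any(cur < spec$fc6_kernel)) {
    abort(sprintf(
      "Input %dx%d is too small: the feature map reaching fc6 (%dx%d) is smaller than its %dx%d kernel.",
      hw[1], hw[2], cur[1], cur[2], spec$fc6_kernel, spec$fc6_kernel))
  }
  cur <- cur - (spec$fc6_kernel - 1L)
  add("Fc6", cur, spec$fc6_width)
  add("Drop6", cur, spec$fc6_width)
  add("Fc7", cur, spec$fc7_width)
  add("Drop7", cur, spec$fc7_width)
  add("Score", cur, spec$n_classes)
  cur <- (cur - 1L) * spec$upsample_stride + spec$upsample_kernel
  add("Upsampled", cur, spec$n_classes)
  if (any(cur < hw)) {
    abort("Upsampled map is smaller than the input; cannot center-crop.")
  }
  add("Output", hw, spec$n_classes)
  dplyr::bind_rows(rows)
}

#' Training configuration
#'
#' Defaults follow the classic FCN recipe: plain stochastic gradient descent
#' on a *summed* (unnormalized) per-pixel cross-entropy with learning rate
#' 1e-10, dropout 0.5 and weight decay 5e-4.  For desk-scale experiments a
#' `loss_scale = "normalized"` mode (mean per-pixel cross-entropy) with a
#' correspondingly larger learning rate converges in a few hundred steps.
#'
#' @param learning_rate SGD step size (>= 0).
#' @param dropout Dropout probability on the pooled features, in \[0, 1).
#' @param weight_decay L2 penalty coefficient.
#' @param epochs Passes over the training tiles.
#' @param loss_scale `"summed"` (classic recipe) or `"normalized"`.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-10, dropout = 0.5,
                         weight_decay = 5e-4, epochs = 10,
                         loss_scale = c("summed", "normalized"), seed = 1L) {
  check_number(learning_rate, "learning_rate", min = 0)
  check_number(weight_decay, "weight_decay", min = 0)
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 loss_scale = match.arg(loss_scale), seed = as.integer(seed)),
            class = "train_config")
}

# ---- reduced-width trainable network -------------------------------------

tile_pixels <- function(tile) {
  if (inherits(tile, "wsi_tile")) tile <- tile$pixels
  if (is.matrix(tile)) tile <- array(tile, c(dim(tile), 1))
  tile
}

im2col3 <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]; ch <- dim(img)[3]
  pad <- array(0, c(h + 2, w + 2, ch))
  pad[2:(h + 1), 2:(w + 1), ] <- img
  cols <- matrix(0, h * w, 9 * ch)
  k <- 0
  for (c_ in seq_len(ch)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        k <- k + 1
        cols[, k] <- as.vector(pad[dy + seq_len(h), dx + seq_len(w), c_])
      }
    }
  }
  cols
}

#' Build a trainable reduced-width FCN-32s tile segmenter
#'
#' A single-stream, 32x-stride fully convolutional segmenter at a width that
#' trains in minutes on a CPU: one 3x3 pad-1 convolution (3 -> `width`
#' channels) with ReLU, a stride-32 average-pooling downsampling path, a 1x1
#' score convolution producing 3 planes (background / lesion / ignore), fixed
#' bilinear 32x upsampling back to the tile size, and a softmax whose lesion
#' plane is the probability map.  Average pooling makes the coarse score track
#' lesion *coverage*, so the upsampled 0.5-level set follows the true lesion
#' boundary.  Weights are seeded-random unless a checkpoint file is supplied.
#'
#' @param spec An [fcn32s_spec()] (records the reference architecture the
#'   variant reduces; its class count is honored).
#' @param config A [train_config()]; its seed initializes the weights.
#' @param width Feature channels of the reduced variant.
#' @param weights_file Optional RDS checkpoint written by [save_segmenter()].
#' @return An `fcn32s` model honoring the segmenter contract: `predict(model,
#'   tile)` returns a probability map of the tile's spatial size with values
#'   in \[0, 1\].
#' @export
build_fcn32s <- function(spec = fcn32s_spec(), config = train_config(),
                         width = 8, weights_file = NULL) {
  width <- as.integer(check_number(width, "width", min = 1))
  model <- structure(list(spec = spec, config = config, width = width,
                          stride = 32L, n_classes = spec$n_classes),
                     class = c("fcn32s", "wsi_segmenter"))
  if (is.null(weights_file)) {
    model <- withr::with_seed(config$seed, {
      model$W1 <- matrix(rnorm(27 * width, sd = 0.1), 27, width)
      model$b1 <- rep(0, width)
      model$W2 <- matrix(rnorm(width * spec$n_classes, sd = 0.1), width,
                         spec$n_classes)
      model$b2 <- rep(0, spec$n_classes)
      model
    })
  } else {
    w <- tryCatch(readRDS(weights_file), error = function(e) NULL)
    ok <- is.list(w) && all(c("W1", "b1", "W2", "b2") %in% names(w)) &&
      is.matrix(w$W1) && nrow(w$W1) == 27 &&
      is.matrix(w$W2) && ncol(w$W2) == spec$n_classes &&
      ncol(w$W1) == nrow(w$W2)
    if (!ok) abort(sprintf("Malformed weight file: %s", weights_file))
    model$width <- ncol(w$W1)
    model[c("W1", "b1", "W2", "b2")] <- w[c("W1", "b1", "W2", "b2")]
  }
  model
}

#' Save a trained segmenter checkpoint
#'
#' @param model An `fcn32s` model.
#' @param path Output RDS path.
#' @export
save_segmenter <- function(model, path) {
  saveRDS(model[c("W1", "b1", "W2", "b2")], path)
  invisible(path)
}

#' @export
print.fcn32s <- function(x, ...) {
  cat(sprintf("<fcn32s> reduced width %d, stride %d, %d score planes\n",
              x$width, x$stride, x$n_classes))
  invisible(x)
}

fcn_forward <- function(model, img, dropout_mask = NULL) {
  h <- dim(img)[1]; w <- dim(img)[2]
  s <- model$stride
  hp <- as.integer(ceiling(h / s) * s)
  wp <- as.integer(ceiling(w / s) * s)
  if (hp != h || wp != w) {
    padded <- array(0, c(hp, wp, dim(img)[3]))
    padded[seq_len(h), seq_len(w), ] <- img
    img <- padded
  }
  X <- im2col3(img)
  A <- sweep(X %*% model$W1, 2, model$b1, "+")
  Fmat <- A * (A > 0)
  hc <- hp %/% s; wc <- wp %/% s
  cell <- as.vector(matrix(
    rep(seq_len(hc), each = s, length.out = hp), hp, wp) +
      hc * (matrix(rep(seq_len(wc) - 1L, each = s, length.out = wp),
                   hp, wp, byrow = TRUE)))
  P <- rowsum(Fmat, cell, reorder = TRUE) / (s * s)
  if (!is.null(dropout_mask)) P <- P * dropout_mask
  S <- sweep(P %*% model$W2, 2, model$b2, "+")
  up <- array(0, c(h, w, model$n_classes))
  for (k in seq_len(model$n_classes)) {
    up[, , k] <- bilinear_resize(matrix(S[, k], hc, wc), hp, wp)[seq_len(h),
                                                                 seq_len(w)]
  }
  m <- up[, , 1]
  for (k in 2:model$n_classes) m <- pmax(m, up[, , k])
  ex <- exp(up - as.vector(m))
  denom <- ex[, , 1]
  for (k in 2:model$n_classes) denom <- denom + ex[, , k]
  list(X = X, A = A, P = P, cell = cell, hc = hc, wc = wc, hp = hp, wp = wp,
       h = h, w = w, up = up, prob = ex / as.vector(denom))
}

#' @export
predict.fcn32s <- function(object, tile, ...) {
  fw <- fcn_forward(object, tile_pixels(tile))
  fw$prob[, , 2]
}

#' Train a segmenter with seeded stochastic gradient descent
#'
#' Plain SGD on the per-pixel cross-entropy between the softmax score planes
#' and binary lesion masks, with dropout on the pooled features and L2 weight
#' decay.  Supports the sparse-annotation regime in which the labeled tiles
#' are a tiny fraction of all slide tiles.  Runs are bit-reproducible given
#' the configuration seed; a zero learning rate leaves parameters unchanged.
#'
#' @param model An `fcn32s` model from [build_fcn32s()].
#' @param tiles List of tiles (arrays or `wsi_tile`s).
#' @param masks List of matching binary 0/1 matrices (1 = lesion).
#' @param config A [train_config()].
#' @return List with `model` (trained) and `history`, a tibble of per-step
#'   mean cross-entropy (`epoch`, `step`, `loss`).
#' @export
train_segmenter <- function(model, tiles, masks, config = model$config) {
  if (length(tiles) == 0) abort("Empty training set: need >= 1 labeled tile.")
  if (length(tiles) != length(masks)) {
    abort("`tiles` and `masks` must have equal length.")
  }
  masks <- purrr::imap(masks, ~ as_binary_mask(.x, paste0("masks[[", .y, "]]")))
  lr <- config$learning_rate
  wd <- config$weight_decay
  history <- list()
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(tiles))
      for (s_i in seq_along(ord)) {
        idx <- ord[s_i]
        img <- tile_pixels(tiles[[idx]])
        y <- masks[[idx]]
        drop_mask <- NULL
        fw0 <- NULL
        if (config$dropout > 0) {
          # mask drawn on the pooled feature grid, inverted-scale convention
          hc <- ceiling(dim(img)[1] / model$stride)
          wc <- ceiling(dim(img)[2] / model$stride)
          drop_mask <- matrix(
            (runif(hc * wc * model$width) >= config$dropout) /
              (1 - config$dropout), hc * wc, model$width)
        }
        fw <- fcn_forward(model, img, dropout_mask = drop_mask)
        n_px <- fw$h * fw$w
        lab <- y + 1L  # 1 = background plane, 2 = lesion plane
        p_lab <- ifelse(lab == 1L, fw$prob[, , 1], fw$prob[, , 2])
        loss <- -mean(log(pmax(p_lab, 1e-12)))
        history[[length(history) + 1]] <- tibble(epoch = ep, step = s_i,
                                                 loss = loss)
        scale <- if (config$loss_scale == "normalized") 1 / n_px else 1
        G <- array(0, c(fw$h, fw$w, model$n_classes))
        for (k in seq_len(model$n_classes)) {
          G[, , k] <- (fw$prob[, , k] - (lab == k)) * scale
        }
        Gc <- matrix(0, fw$hc * fw$wc, model$n_classes)
        for (k in seq_len(model$n_classes)) {
          gpad <- matrix(0, fw$hp, fw$wp)
          gpad[seq_len(fw$h), seq_len(fw$w)] <- G[, , k]
          Gc[, k] <- as.vector(bilinear_resize_t(gpad, fw$hc, fw$wc))
        }
        dW2 <- crossprod(fw$P, Gc)
        db2 <- colSums(Gc)
        dP <- Gc %*% t(model$W2)
        if (!is.null(drop_mask)) dP <- dP * drop_mask
        dF <- dP[fw$cell, , drop = FALSE] / (model$stride^2)
        dA <- dF * (fw$A > 0)
        dW1 <- crossprod(fw$X, dA)
        db1 <- colSums(dA)
        model$W1 <- model$W1 - lr * (dW1 + wd * model$W1)
        model$b1 <- model$b1 - lr * db1
        model$W2 <- model$W2 - lr * (dW2 + wd * model$W2)
        model$b2 <- model$b2 - lr * db2
      }
    }
  })
  list(model = model, history = dplyr::bind_rows(history))
}

# ---- closed-form oracle segmenters ---------------------------------------

#' Closed-form threshold segmenter (test oracle)
#'
#' Predicts probability 1 where the designated channel reaches the cutoff and
#' 0 elsewhere.  On synthetic slides whose lesion signal lives in a dedicated
#' zero-background channel, the same oracle applied to any average-downsampled
#' level detects every block containing lesion signal, which gives the cascade
#' the exact coarse-covers-fine property used in equivalence tests.
#'
#' @param channel Channel index carrying lesion signal.
#' @param cutoff Threshold; a cutoff at or below the channel minimum yields an
#'   all-ones map.
#' @param level Optional level tag (informational).
#' @return A `threshold_segmenter` honoring the segmenter contract.
#' @export
make_threshold_oracle <- function(channel = 2, cutoff = 0.002, level = NULL) {
  structure(list(channel = as.integer(channel), cutoff = cutoff,
                 level = level),
            class = c("threshold_segmenter", "wsi_segmenter"))
}

#' @export
predict.threshold_segmenter <- function(object, tile, ...) {
  px <- tile_pixels(tile)
  ch <- min(object$channel, dim(px)[3])
  (px[, , ch] >= object$cutoff) * 1
}

#' Identity-channel segmenter
#'
#' Reads the designated channel's pixel value directly as the lesion
#' probability — a continuous closed-form segmenter useful for studying how
#' the attention threshold `alpha` shapes selection and masks.
#'
#' @inheritParams make_threshold_oracle
#' @return A `channel_prob_segmenter` honoring the segmenter contract.
#' @export
channel_prob_segmenter <- function(channel = 2, level = NULL) {
  structure(list(channel = as.integer(channel), level = level),
            class = c("channel_prob_segmenter", "wsi_segmenter"))
}

#' @export
predict.channel_prob_segmenter <- function(object, tile, ...) {
  px <- tile_pixels(tile)
  pmin(pmax(px[, , min(object$channel, dim(px)[3])], 0), 1)
}

#' Constant-probability segmenter (degenerate test model)
#'
#' @param value Probability assigned to every pixel.
#' @return A `constant_segmenter` honoring the segmenter contract.
#' @export
constant_segmenter <- function(value) {
  check_number(value, "value", min = 0, max = 1)
  structure(list(value = value),
            class = c("constant_segmenter", "wsi_segmenter"))
}

#' @export
predict.constant_segmenter <- function(object, tile, ...) {
  px <- tile_pixels(tile)
  matrix(object$value, dim(px)[1], dim(px)[2])
}
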