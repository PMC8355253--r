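#' Configure the coarse-to-fine cascade
#'
#' The cascade scores every tile at the coarsest level, thresholds the
#' per-pixel probabilities at `alpha` to build a binary attention map, and at
#' each finer level processes only the tiles selected by the previous level's
#' attention.  Attention can be kept per tile (the literal selection rule: an
#' active coarse tile selects all of its `2^(2z)` child tiles) or refined to
#' `2^z x 2^z` sub-tile attention units, each gating exactly one child tile
#' (16 units per tile for z = 2).
#'
#' @param alpha Probability threshold in \[0, 1\] (default 0.5); a pixel
#'   counts as lesion evidence when its probability is `>= alpha` (inclusive).
#' @param granularity `"per_unit"` (default) or `"per_tile"`.
#' @param alpha_per_level Optional numeric vector overriding `alpha` level by
#'   level (element `l` applies at level `l`).
#' @return A `cascade_config` object.
#' @export
cascade_config <- function(alpha = 0.5,
                           granularity = c("per_unit", "per_tile"),
                           alpha_per_level = NULL) {
  check_number(alpha, "alpha", min = 0, max = 1)
  if (!is.null(alpha_per_level) &&
      any(alpha_per_level < 0 | alpha_per_level > 1)) {
    abort("`alpha_per_level` entries must be in [0, 1].")
  }
  structure(list(alpha = alpha, granularity = match.arg(granularity),
                 alpha_per_level = alpha_per_level),
            class = "cascade_config")
}

level_alpha <- function(config, level) {
  if (!is.null(config$alpha_per_level) &&
      length(config$alpha_per_level) >= level) {
    config$alpha_per_level[level]
  } else {
    config$alpha
  }
}

#' Run a segmenter over a set of tiles
#'
#' Applies one level's model to each tile and returns per-tile probability
#' maps.  All tiles must share one level; each map keeps the tile's valid
#' (non-padded) extent so padded pixels never contribute to attention maxima
#' or to the assembled mask.
#'
#' @param tiles List of `wsi_tile`s from one level (may be empty).
#' @param model A segmenter: `predict(model, tile)` must return a matrix of
#'   the tile's spatial size with values in \[0, 1\].
#' @return List of `prob_map`s (`values`, `index`, `valid`).
#' @export
infer_level <- function(tiles, model) {
  if (length(tiles) == 0) return(list())
  lv <- unique(purrr::map_dbl(tiles, ~ .x$index[["level"]]))
  if (length(lv) != 1) {
    abort(sprintf("All tiles must share one level; got levels %s.",
                  paste(lv, collapse = ", ")))
  }
  purrr::map(tiles, make_prob_map_checked, model = model)
}

make_prob_map_checked <- function(tl, model) {
  p <- predict(model, tl)
  if (min(p) < 0 || max(p) > 1) {
    abort("Model output violates the segmenter contract: values outside [0, 1].")
  }
  structure(list(values = p, index = tl$index, valid = tl$valid),
            class = "prob_map")
}

# Tile-streaming inference: tiles are extracted, scored and discarded one at
# a time so whole-level tile sets are never resident for large slides.
infer_indices <- function(pyramid, level, idx, model) {
  purrr::pmap(idx, function(i, j) {
    make_prob_map_checked(get_tile(pyramid, level, i, j), model)
  })
}

unit_max <- function(vals, valid, units) {
  ts <- nrow(vals)
  us <- ts %/% units
  if (valid[1] < ts || valid[2] < ts) {
    if (valid[1] < ts) vals[(valid[1] + 1):ts, ] <- -Inf
    if (valid[2] < ts) vals[, (valid[2] + 1):ts] <- -Inf
  }
  arr <- array(vals, c(us, units, us, units))
  apply(arr, c(2, 4), max)
}

#' Compute a binary attention map from probability maps
#'
#' Implements the thresholding rule: an attention cell is set to 1 when any
#' of its valid pixels has probability greater than or equal to `alpha`
#' (inclusive at the boundary).  In `per_tile` mode the cell is the whole
#' tile; in `per_unit` mode each tile contributes a `2^z x 2^z` block of
#' attention units, each thresholded over its own sub-region.  Tiles without
#' a probability map (not processed at this level) stay 0.
#'
#' @param prob_maps List of `prob_map`s from [infer_level()] (one level).
#' @param pyramid The [build_pyramid()] result the maps came from.
#' @param config A [cascade_config()].
#' @return An `attention_map`: list with `level`, `mode`, `grid` (binary
#'   matrix over tiles, or over units for `per_unit`), `units_per_tile_axis`.
#' @export
compute_attention <- function(prob_maps, pyramid, config = cascade_config()) {
  if (length(prob_maps) == 0) abort("Need at least one probability map.")
  level <- prob_maps[[1]]$index[["level"]]
  g <- pyramid$grid[pyramid$grid$level == level, ]
  z <- pyramid$config$zoom_step
  alpha <- level_alpha(config, level)
  if (config$granularity == "per_tile") {
    grid <- matrix(0L, g$n_rows, g$n_cols)
    for (pm in prob_maps) {
      v <- pm$values[seq_len(pm$valid[1]), seq_len(pm$valid[2]), drop = FALSE]
      grid[pm$index[["i"]] + 1, pm$index[["j"]] + 1] <-
        as.integer(max(v) >= alpha)
    }
    units <- 1L
  } else {
    units <- as.integer(2^z)
    if (pyramid$config$tile_size %% units != 0) {
      abort("`tile_size` must be divisible by 2^z for per-unit attention.")
    }
    grid <- matrix(0L, g$n_rows * units, g$n_cols * units)
    for (pm in prob_maps) {
      um <- unit_max(pm$values, pm$valid, units)
      rows <- pm$index[["i"]] * units + seq_len(units)
      cols <- pm$index[["j"]] * units + seq_len(units)
      grid[rows, cols] <- as.integer(um >= alpha)
    }
  }
  structure(list(level = level, mode = config$granularity, grid = grid,
                 units_per_tile_axis = units, zoom_step = z),
            class = "attention_map")
}

#' Select tiles at the next finer level from a coarse attention map
#'
#' In `per_tile` mode, tile `(l, i, j)` is selected when the attention cell at
#' `(l - 1, floor(i / 2^z), floor(j / 2^z))` is 1 (each active coarse tile
#' selects up to `2^(2z)` children).  In `per_unit` mode the unit index space
#' at level `l - 1` coincides with the tile index space at level `l`, so tile
#' `(l, i, j)` is selected exactly when unit `(i, j)` is active.
#'
#' @param attention An [compute_attention()] result for level `l - 1`.
#' @param pyramid The pyramid providing the level-`l` grid.
#' @return A tibble of selected 0-based tile indices `i`, `j` at level
#'   `attention$level + 1`.
#' @export
select_tiles <- function(attention, pyramid) {
  level <- attention$level + 1L
  if (level > pyramid$config$num_levels) {
    abort("Attention is already at the finest level; nothing to select.")
  }
  g <- pyramid$grid[pyramid$grid$level == level, ]
  idx <- tidyr::expand_grid(i = seq_len(g$n_rows) - 1L,
                            j = seq_len(g$n_cols) - 1L)
  f <- 2L^attention$zoom_step
  if (attention$mode == "per_tile") {
    if (nrow(attention$grid) * f < g$n_rows ||
        ncol(attention$grid) * f < g$n_cols) {
      abort("Attention grid does not cover the finer tile grid.")
    }
    keep <- attention$grid[cbind(floor(idx$i / f) + 1, floor(idx$j / f) + 1)] == 1L
  } else {
    if (nrow(attention$grid) < g$n_rows || ncol(attention$grid) < g$n_cols) {
      abort("Attention unit grid does not cover the finer tile grid.")
    }
    keep <- attention$grid[cbind(idx$i + 1, idx$j + 1)] == 1L
  }
  idx[keep, ]
}

#' Assemble a slide-level binary mask from selected finest-level tiles
#'
#' Pixel-level thresholding and stitching: a pixel is 1 iff it lies in the
#' valid region of a selected finest-level tile and its probability is
#' `>= alpha`; everything outside selected tiles (and all padding) is 0.
#' Tiles are non-overlapping by construction; duplicated tile claims error.
#'
#' @param prob_maps List of `prob_map`s for the selected finest-level tiles.
#' @param dims Slide dimensions `c(height, width)` at the finest level.
#' @param tile_size Tile side in pixels.
#' @param alpha Threshold in \[0, 1\].
#' @return Integer 0/1 matrix of `dims`.
#' @export
assemble_mask <- function(prob_maps, dims, tile_size, alpha = 0.5) {
  mask <- matrix(0L, dims[1], dims[2])
  if (length(prob_maps) == 0) return(mask)
  keys <- purrr::map_chr(prob_maps,
                         ~ paste(.x$index[["i"]], .x$index[["j"]], sep = "_"))
  if (anyDuplicated(keys)) {
    abort("Overlapping tile claims: the same tile index appears twice.")
  }
  for (pm in prob_maps) {
    i <- pm$index[["i"]]; j <- pm$index[["j"]]
    rows <- (i * tile_size + 1):(i * tile_size + pm$valid[1])
    cols <- (j * tile_size + 1):(j * tile_size + pm$valid[2])
    v <- pm$values[seq_len(pm$valid[1]), seq_len(pm$valid[2]), drop = FALSE]
    mask[rows, cols] <- (v >= alpha) * 1L
  }
  mask
}

#' Run the full coarse-to-fine cascade over a pyramid
#'
#' Level 1 (coarsest) is processed exhaustively; its attention map selects the
#' level-2 tiles, and so on down to the finest level N, whose selected tiles
#' are thresholded and stitched into the final lesion mask.  Background
#' regions rejected at coarse levels are never touched again, which is where
#' the speed-up over exhaustive dense inference comes from.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param models List of N segmenters, element `l` serving level `l`.
#' @param config A [cascade_config()].
#' @return A `cascade_result`: `mask` (integer 0/1 matrix at finest-level
#'   resolution), `selection` (tibble: level, tiles_total, tiles_processed),
#'   `selected` (tibble of processed tile indices per level), `config`.
#' @examples
#' slide <- generate_slide(slide_spec(1024, 1024, n_lesions = 1, seed = 3))
#' pyr <- build_pyramid(slide$image, pyramid_config(512, num_levels = 2))
#' oracle <- make_threshold_oracle()
#' res <- run_cascade(pyr, list(oracle, oracle))
#' tidy(res)
#' @export
run_cascade <- function(pyramid, models, config = cascade_config()) {
  n <- pyramid$config$num_levels
  if (length(models) != n) {
    abort(sprintf("Need one model per level: %d level(s) but %d model(s).",
                  n, length(models)))
  }
  ts <- pyramid$config$tile_size
  counts <- list()
  selected <- list()
  idx <- all_tile_indices(pyramid, 1L)
  for (l in seq_len(n)) {
    g <- pyramid$grid[pyramid$grid$level == l, ]
    maps <- infer_indices(pyramid, l, idx, models[[l]])
    counts[[l]] <- tibble(level = l, tiles_total = g$n_tiles,
                          tiles_processed = nrow(idx))
    selected[[l]] <- dplyr::mutate(idx, level = l, .before = 1)
    if (l < n) {
      if (length(maps) == 0) {
        idx <- idx[0, ]
        next
      }
      att <- compute_attention(maps, pyramid, config)
      idx <- select_tiles(att, pyramid)
    } else {
      mask <- assemble_mask(maps, c(g$height, g$width), ts,
                            level_alpha(config, n))
    }
  }
  if (!exists("mask", inherits = FALSE)) {
    g <- pyramid$grid[pyramid$grid$level == n, ]
    mask <- matrix(0L, g$height, g$width)
    counts[[n]] <- tibble(level = n, tiles_total = g$n_tiles,
                          tiles_processed = 0L)
  }
  structure(list(mask = mask,
                 selection = dplyr::bind_rows(counts),
                 selected = dplyr::bind_rows(selected),
                 config = config),
            class = "cascade_result")
}

#' Exhaustive dense inference at the finest level
#'
#' Processes every finest-level tile with the finest-level model and
#' thresholds at `alpha` — the dense baseline the cascade is compared
#' against.
#'
#' @inheritParams run_cascade
#' @param model The finest-level segmenter.
#' @param alpha Threshold in \[0, 1\].
#' @return Integer 0/1 mask at finest-level resolution.
#' @export
segment_dense <- function(pyramid, model, alpha = 0.5) {
  n <- pyramid$config$num_levels
  g <- pyramid$grid[pyramid$grid$level == n, ]
  idx <- all_tile_indices(pyramid, n)
  ts <- pyramid$config$tile_size
  mask <- matrix(0L, g$height, g$width)
  # incremental thresholding keeps one tile resident at a time
  for (r in seq_len(nrow(idx))) {
    pm <- make_prob_map_checked(get_tile(pyramid, n, idx$i[r], idx$j[r]),
                                model)
    rows <- (idx$i[r] * ts + 1):(idx$i[r] * ts + pm$valid[1])
    cols <- (idx$j[r] * ts + 1):(idx$j[r] * ts + pm$valid[2])
    v <- pm$values[seq_len(pm$valid[1]), seq_len(pm$valid[2]), drop = FALSE]
    mask[rows, cols] <- (v >= alpha) * 1L
  }
  mask
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> %d positive px (%.4f%%)\n",
              sum(x$mask), 100 * mean(x$mask)))
  print(x$selection)
  invisible(x)
}

#' @rdname run_cascade
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cascade_result <- function(x, ...) {
  dplyr::mutate(x$selection,
                fraction_processed = .data$tiles_processed / .data$tiles_total)
}

#' @rdname run_cascade
#' @exportS3Method generics::glance
glance.cascade_result <- function(x, ...) {
  tibble(levels = nrow(x$selection),
         tiles_total = sum(x$selection$tiles_total),
         tiles_processed = sum(x$selection$tiles_processed),
         positive_pixels = sum(x$mask),
         positive_fraction = mean(x$mask))
}

#' Write a segmentation mask or render a tinted overlay
#'
#' @param mask Integer 0/1 matrix.
#' @param image Slide raster to tint.
#' @param path Output PNG path.
#' @param color Overlay color for lesion pixels.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(mask, image, path, color = c(1, 1, 0)) {
  out <- image
  sel <- mask == 1L
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[sel] <- 0.5 * plane[sel] + 0.5 * color[ch]
    out[, , ch] <- plane
  }
  png::writePNG(out, path)
  invisible(path)
}
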