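#' Configure a tile pyramid
#'
#' A slide is decomposed into `num_levels` resolution levels; level
#' `num_levels` is the full-resolution raster and each coarser level is the
#' next level downsampled by `2^zoom_step` per axis (area averaging).  Every
#' level is cut into non-overlapping `tile_size` x `tile_size` tiles, border
#' tiles zero-padded with their true extent recorded.
#'
#' @param tile_size Tile side in pixels (default 512).
#' @param num_levels Number of pyramid levels N >= 1 (level 1 = coarsest).
#' @param zoom_step Integer z >= 1; consecutive levels differ by a linear
#'   scale factor of `2^z` (default 2, i.e. 4x), so one coarse tile footprint
#'   covers `2^(2z)` tiles at the next finer level.
#' @param quantize Snap downsampled levels to the 8-bit grid (default `TRUE`);
#'   this emulates 8-bit slide data and makes the PNG tile store lossless.
#' @return A `pyramid_config` object.
#' @export
pyramid_config <- function(tile_size = 512, num_levels = 3, zoom_step = 2,
                           quantize = TRUE) {
  check_number(tile_size, "tile_size", min = 1)
  check_number(num_levels, "num_levels", min = 1)
  check_number(zoom_step, "zoom_step", min = 1)
  structure(list(tile_size = as.integer(tile_size),
                 num_levels = as.integer(num_levels),
                 zoom_step = as.integer(zoom_step),
                 quantize = isTRUE(quantize)),
            class = "pyramid_config")
}

#' @export
print.pyramid_config <- function(x, ...) {
  cat(sprintf("<pyramid_config> tile %d px, N = %d levels, z = %d (%dx/level)\n",
              x$tile_size, x$num_levels, x$zoom_step, 2^x$zoom_step))
  invisible(x)
}

#' Build a tile pyramid from a slide raster
#'
#' @param image Full-resolution slide: a height x width x channels array or a
#'   matrix, values in \code{[0, 1]}.
#' @param config A [pyramid_config()].
#' @return A `tile_pyramid`: list with `config`, `levels` (list of rasters,
#'   element `l` being level `l`), and `grid`, a tibble with one row per level
#'   (`level`, `height`, `width`, `n_rows`, `n_cols`, `n_tiles`).
#' @examples
#' pyr <- build_pyramid(array(runif(64 * 64 * 3), c(64, 64, 3)),
#'                      pyramid_config(tile_size = 32, num_levels = 2))
#' pyr$grid
#' @export
build_pyramid <- function(image, config = pyramid_config()) {
  if (!inherits(config, "pyramid_config")) {
    abort("`config` must be a `pyramid_config`.")
  }
  dm <- dim(image)
  if (is.null(dm) || dm[1] < 1 || dm[2] < 1 || length(image) == 0) {
    abort("`image` must be a non-empty matrix or array.")
  }
  f <- 2^config$zoom_step
  levels <- vector("list", config$num_levels)
  levels[[config$num_levels]] <- image
  if (config$num_levels > 1) {
    for (l in (config$num_levels - 1):1) {
      d <- block_mean_image(levels[[l + 1]], f)
      if (config$quantize) d <- quantize8(d)
      levels[[l]] <- d
    }
  }
  grid <- purrr::map_dfr(seq_len(config$num_levels), function(l) {
    dl <- dim(levels[[l]])
    tibble(level = l, height = dl[1], width = dl[2],
           n_rows = ceiling(dl[1] / config$tile_size),
           n_cols = ceiling(dl[2] / config$tile_size))
  })
  grid$n_tiles <- grid$n_rows * grid$n_cols
  structure(list(config = config, levels = levels, grid = grid),
            class = "tile_pyramid")
}

#' @export
print.tile_pyramid <- function(x, ...) {
  cat(sprintf("<tile_pyramid> %d level(s), tile %d px\n",
              x$config$num_levels, x$config$tile_size))
  print(x$grid)
  invisible(x)
}

#' Tile grid dimensions for an arbitrary level size
#'
#' Closed-form ceiling-division bookkeeping: a level of `height` x `width`
#' pixels cut into `tile_size` tiles has `ceiling(height / tile_size)` rows of
#' tiles and `ceiling(width / tile_size)` columns.
#'
#' @param height,width Level dimensions in pixels.
#' @param tile_size Tile side in pixels.
#' @return A tibble with `n_rows`, `n_cols`, `n_tiles`.
#' @examples
#' tile_grid_dims(41546, 91257, 512)  # 82 x 179 = 14678 tiles
#' @export
tile_grid_dims <- function(height, width, tile_size = 512) {
  nr <- ceiling(height / tile_size)
  nc <- ceiling(width / tile_size)
  tibble(n_rows = nr, n_cols = nc, n_tiles = nr * nc)
}

level_raster <- function(pyramid, level) {
  if (level < 1 || level > pyramid$config$num_levels) {
    abort(sprintf("`level` must be in 1..%d.", pyramid$config$num_levels))
  }
  pyramid$levels[[level]]
}

#' Extract one tile from a pyramid
#'
#' Tiles are indexed 0-based, row-major, with half-open pixel footprints
#' `[i * tile_size, min((i + 1) * tile_size, height))`.  Border tiles are
#' zero-padded to the full tile size; `valid` records the unpadded extent.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param level Level (1 = coarsest).
#' @param i,j 0-based tile row and column.
#' @return A `wsi_tile`: list with `index` (level, i, j), `pixels`
#'   (tile_size x tile_size x channels array) and `valid` = c(height, width)
#'   of real content.
#' @export
get_tile <- function(pyramid, level, i, j) {
  g <- pyramid$grid[pyramid$grid$level == level, ]
  if (nrow(g) == 0) {
    abort(sprintf("`level` must be in 1..%d.", pyramid$config$num_levels))
  }
  if (i < 0 || i >= g$n_rows || j < 0 || j >= g$n_cols) {
    abort(sprintf(
      "Tile (%d, %d) is outside the level-%d grid of %d x %d tiles.",
      i, j, level, g$n_rows, g$n_cols))
  }
  ts <- pyramid$config$tile_size
  ras <- pyramid$levels[[level]]
  rows <- (i * ts + 1):min((i + 1) * ts, g$height)
  cols <- (j * ts + 1):min((j + 1) * ts, g$width)
  nch <- if (length(dim(ras)) == 3) dim(ras)[3] else 1L
  px <- array(0, c(ts, ts, nch))
  if (length(dim(ras)) == 3) {
    px[seq_along(rows), seq_along(cols), ] <- ras[rows, cols, , drop = FALSE]
  } else {
    px[seq_along(rows), seq_along(cols), 1] <- ras[rows, cols]
  }
  structure(list(index = c(level = level, i = i, j = j), pixels = px,
                 valid = c(length(rows), length(cols))),
            class = "wsi_tile")
}

all_tile_indices <- function(pyramid, level) {
  g <- pyramid$grid[pyramid$grid$level == level, ]
  tidyr::expand_grid(i = seq_len(g$n_rows) - 1L, j = seq_len(g$n_cols) - 1L)
}

#' Map a coarse tile to its child tiles at the next finer level
#'
#' A tile at level `l` covers up to `2^(2z)` tiles at level `l + 1`: the
#' children are all indices `(i', j')` with `floor(i' / 2^z) = i` and
#' `floor(j' / 2^z) = j`, clipped to the finer grid (border tiles of ragged
#' grids have fewer children).
#'
#' @inheritParams get_tile
#' @return A tibble of 0-based child indices `i`, `j` at level `level + 1`.
#' @export
child_indices <- function(pyramid, level, i, j) {
  if (level >= pyramid$config$num_levels) {
    abort("Tiles at the finest level have no children.")
  }
  g <- pyramid$grid[pyramid$grid$level == level + 1, ]
  f <- 2^pyramid$config$zoom_step
  rows <- (i * f):min((i + 1) * f - 1, g$n_rows - 1)
  cols <- (j * f):min((j + 1) * f - 1, g$n_cols - 1)
  rows <- rows[rows >= 0 & rows < g$n_rows]
  cols <- cols[cols >= 0 & cols < g$n_cols]
  tidyr::expand_grid(i = as.integer(rows), j = as.integer(cols))
}

#' Parent tile of a fine-level tile
#'
#' The inverse of [child_indices()]: tile `(l, i, j)` maps to
#' `(l - 1, floor(i / 2^z), floor(j / 2^z))`.
#'
#' @inheritParams get_tile
#' @return Named integer vector `c(level, i, j)` at level `level - 1`.
#' @export
parent_index <- function(pyramid, level, i, j) {
  if (level <= 1) abort("Level-1 tiles have no parent.")
  f <- 2^pyramid$config$zoom_step
  c(level = as.integer(level) - 1L, i = as.integer(floor(i / f)),
    j = as.integer(floor(j / f)))
}

#' Reassemble a level raster from its tiles
#'
#' Stitches every tile of a level, cropped to its valid region, back into the
#' level raster.  Used to verify that tiling is lossless.
#'
#' @inheritParams get_tile
#' @return The level raster.
#' @export
reassemble_level <- function(pyramid, level) {
  g <- pyramid$grid[pyramid$grid$level == level, ]
  ts <- pyramid$config$tile_size
  ref <- pyramid$levels[[level]]
  nch <- if (length(dim(ref)) == 3) dim(ref)[3] else 1L
  out <- array(0, c(g$height, g$width, nch))
  for (i in seq_len(g$n_rows) - 1L) {
    for (j in seq_len(g$n_cols) - 1L) {
      tl <- get_tile(pyramid, level, i, j)
      rows <- (i * ts + 1):(i * ts + tl$valid[1])
      cols <- (j * ts + 1):(j * ts + tl$valid[2])
      out[rows, cols, ] <- tl$pixels[seq_len(tl$valid[1]),
                                     seq_len(tl$valid[2]), , drop = FALSE]
    }
  }
  if (length(dim(ref)) == 2) out <- out[, , 1] else out
}

#' Write and read a directory-based tile store
#'
#' The store holds `level_{l}/tile_{i}_{j}.png` files plus a JSON descriptor
#' with the pyramid geometry.  With the default 8-bit quantization the round
#' trip is bit-exact.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param dir Store directory.
#' @return `write_pyramid()` returns `dir` invisibly; `read_pyramid()` returns
#'   a `tile_pyramid`.
#' @export
write_pyramid <- function(pyramid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- pyramid$config
  dims <- purrr::map(pyramid$levels, dim)
  desc <- list(tile_size = cfg$tile_size, num_levels = cfg$num_levels,
               zoom_step = cfg$zoom_step, quantize = cfg$quantize,
               level_heights = purrr::map_int(dims, 1),
               level_widths = purrr::map_int(dims, 2),
               channels = purrr::map_int(dims, ~ if (length(.x) == 3) .x[3]
                                         else 1L))
  jsonlite::write_json(desc, file.path(dir, "pyramid.json"), auto_unbox = TRUE)
  for (l in seq_len(cfg$num_levels)) {
    ldir <- file.path(dir, sprintf("level_%d", l))
    dir.create(ldir, showWarnings = FALSE)
    g <- pyramid$grid[pyramid$grid$level == l, ]
    for (i in seq_len(g$n_rows) - 1L) {
      for (j in seq_len(g$n_cols) - 1L) {
        tl <- get_tile(pyramid, l, i, j)
        px <- tl$pixels[seq_len(tl$valid[1]), seq_len(tl$valid[2]), ,
                        drop = FALSE]
        if (dim(px)[3] == 1) px <- px[, , 1]
        png::writePNG(px, file.path(ldir, sprintf("tile_%d_%d.png", i, j)))
      }
    }
  }
  invisible(dir)
}

#' @rdname write_pyramid
#' @export
read_pyramid <- function(dir) {
  desc <- jsonlite::read_json(file.path(dir, "pyramid.json"),
                              simplifyVector = TRUE)
  cfg <- pyramid_config(desc$tile_size, desc$num_levels, desc$zoom_step,
                        desc$quantize)
  ts <- cfg$tile_size
  levels <- purrr::map(seq_len(cfg$num_levels), function(l) {
    dm <- c(desc$level_heights[l], desc$level_widths[l])
    nch <- desc$channels[l]
    out <- array(0, c(dm[1], dm[2], nch))
    for (i in seq_len(ceiling(dm[1] / ts)) - 1L) {
      for (j in seq_len(ceiling(dm[2] / ts)) - 1L) {
        px <- png::readPNG(file.path(dir, sprintf("level_%d", l),
                                     sprintf("tile_%d_%d.png", i, j)))
        if (length(dim(px)) == 2) px <- array(px, c(dim(px), 1))
        rows <- (i * ts + 1):(i * ts + dim(px)[1])
        cols <- (j * ts + 1):(j * ts + dim(px)[2])
        out[rows, cols, ] <- px
      }
    }
    if (nch == 1) out[, , 1] else out
  })
  grid <- purrr::map_dfr(seq_len(cfg$num_levels), function(l) {
    dl <- dim(levels[[l]]) %||% c(length(levels[[l]]), 1)
    tibble(level = l, height = dl[1], width = dl[2],
           n_rows = ceiling(dl[1] / ts), n_cols = ceiling(dl[2] / ts))
  })
  grid$n_tiles <- grid$n_rows * grid$n_cols
  structure(list(config = cfg, levels = levels, grid = grid),
            class = "tile_pyramid")
}
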