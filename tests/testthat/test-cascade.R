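make_prob_map <- function(values, level, i, j, valid = dim(values)) {
  structure(list(values = values, index = c(level = level, i = i, j = j),
                 valid = as.integer(valid)),
            class = "prob_map")
}

test_that("attention thresholding matches brute-force per-cell maxima", {
  set.seed(4)
  s <- small_slide(512, 512, n_lesions = 1, seed = 2)
  pyr <- build_pyramid(s$image, pyramid_config(512, num_levels = 1))
  for (rep in 1:5) {
    vals <- matrix(runif(512 * 512), 512, 512)
    valid <- c(sample(c(512L, 400L), 1), sample(c(512L, 380L), 1))
    pm <- make_prob_map(vals, 1, 0, 0, valid)
    alpha <- runif(1, 0.3, 0.9)
    att <- compute_attention(list(pm), pyr,
                             cascade_config(alpha, "per_unit"))
    expect_identical(att$grid, oracle_attention(vals, valid, 4, alpha))
    att_t <- compute_attention(list(pm), pyr,
                               cascade_config(alpha, "per_tile"))
    v <- vals[seq_len(valid[1]), seq_len(valid[2])]
    expect_identical(att_t$grid[1, 1], as.integer(max(v) >= alpha))
  }
})

test_that("the alpha boundary is inclusive and localizes to the right unit", {
  s <- small_slide(512, 512, n_lesions = 0, seed = 2)
  pyr <- build_pyramid(s$image, pyramid_config(512, num_levels = 1))
  vals <- matrix(0, 512, 512)
  vals[200, 300] <- 0.5  # exactly alpha; unit row 2, col 3 (1-based)
  att <- compute_attention(list(make_prob_map(vals, 1, 0, 0)), pyr,
                           cascade_config(alpha = 0.5, "per_unit"))
  expected <- matrix(0L, 4, 4)
  expected[2, 3] <- 1L
  expect_identical(att$grid, expected)
  just_below <- compute_attention(
    list(make_prob_map(vals * 0.999, 1, 0, 0)), pyr,
    cascade_config(alpha = 0.5, "per_unit"))
  expect_identical(sum(just_below$grid), 0L)
  expect_identical(sum(att$grid), 1L)
  expect_error(cascade_config(alpha = 1.5), "alpha")
})

test_that("all-zero probabilities yield no attention and an empty selection", {
  s <- small_slide(512, 512, n_lesions = 0, seed = 6)
  pyr <- build_pyramid(s$image, pyramid_config(256, num_levels = 2))
  tiles <- purrr::pmap(wsicascade:::all_tile_indices(pyr, 1),
                       function(i, j) get_tile(pyr, 1, i, j))
  maps <- infer_level(tiles, constant_segmenter(0))
  att <- compute_attention(maps, pyr, cascade_config())
  expect_identical(sum(att$grid), 0L)
  expect_identical(nrow(select_tiles(att, pyr)), 0L)
})

test_that("per-tile selection expands each active cell to <= 2^(2z) children", {
  pyr <- fake_pyramid(3, 3, tile_size = 16, zoom_step = 2)
  att <- structure(list(level = 1L, mode = "per_tile",
                        grid = matrix(0L, 3, 3), units_per_tile_axis = 1L,
                        zoom_step = 2L),
                   class = "attention_map")
  att$grid[1, 1] <- 1L
  sel <- select_tiles(att, pyr)
  expect_identical(nrow(sel), 16L)
  expect_true(all(sel$i <= 3 & sel$j <= 3))
  # geometric footprint oracle for random per-unit attention
  att_u <- structure(list(level = 1L, mode = "per_unit",
                          grid = matrix(rbinom(144, 1, 0.3), 12, 12),
                          units_per_tile_axis = 4L, zoom_step = 2L),
                     class = "attention_map")
  sel_u <- select_tiles(att_u, pyr)
  manual <- which(att_u$grid == 1L, arr.ind = TRUE)
  expect_identical(nrow(sel_u), nrow(manual))
  expect_setequal(paste(sel_u$i, sel_u$j),
                  paste(manual[, 1] - 1L, manual[, 2] - 1L))
})

test_that("degenerate cascades: all-zero and all-one models", {
  s <- small_slide(1024, 1024, n_lesions = 1, seed = 8)
  pyr <- build_pyramid(s$image, pyramid_config(512, num_levels = 2))
  zeros <- rep(list(constant_segmenter(0)), 2)
  res0 <- run_cascade(pyr, zeros)
  expect_identical(sum(res0$mask), 0L)
  expect_identical(res0$selection$tiles_processed, c(1L, 0L))

  ones <- rep(list(constant_segmenter(1)), 2)
  res1 <- run_cascade(pyr, ones)
  expect_identical(mean(res1$mask), 1)
  expect_identical(res1$selection$tiles_processed,
                   as.integer(res1$selection$tiles_total))
  expect_identical(res1$mask, segment_dense(pyr, constant_segmenter(1)))
})

test_that("cascade equals dense inference with oracle models, doing less work", {
  oracle <- make_threshold_oracle()
  for (sd in 1:3) {
    s <- small_slide(1536, 1280, n_lesions = 2, seed = 40 + sd)
    pyr <- build_pyramid(s$image, pyramid_config(512, num_levels = 3))
    res <- run_cascade(pyr, rep(list(oracle), 3))
    dense <- segment_dense(pyr, oracle)
    expect_identical(res$mask, dense)
    expect_identical(res$mask, s$gt_mask)
    n_level <- res$selection[res$selection$level == 3, ]
    expect_lt(n_level$tiles_processed, n_level$tiles_total)
  }
})

test_that("per_tile and per_unit agree on the mask; per_unit does less work", {
  oracle <- make_threshold_oracle()
  s <- small_slide(2048, 2048, n_lesions = 2, seed = 51)
  pyr <- build_pyramid(s$image, pyramid_config(512, num_levels = 2))
  res_u <- run_cascade(pyr, rep(list(oracle), 2),
                       cascade_config(granularity = "per_unit"))
  res_t <- run_cascade(pyr, rep(list(oracle), 2),
                       cascade_config(granularity = "per_tile"))
  expect_identical(res_u$mask, res_t$mask)
  expect_lte(sum(res_u$selection$tiles_processed),
             sum(res_t$selection$tiles_processed))
})

test_that("attention, selection and mask are monotone in alpha", {
  s <- small_slide(1024, 1024, n_lesions = 2, seed = 61)
  pyr <- build_pyramid(s$image, pyramid_config(512, num_levels = 2))
  model <- channel_prob_segmenter(2)
  alphas <- c(0.3, 0.5, 0.9)
  runs <- purrr::map(alphas, function(a) {
    run_cascade(pyr, rep(list(model), 2), cascade_config(alpha = a))
  })
  for (k in 1:2) {
    m_lo <- runs[[k]]$mask
    m_hi <- runs[[k + 1]]$mask
    expect_true(all(m_lo[m_hi == 1L] == 1L))  # mask(a2) subset mask(a1)
    sel_lo <- dplyr::filter(runs[[k]]$selected, level == 2)
    sel_hi <- dplyr::filter(runs[[k + 1]]$selected, level == 2)
    expect_true(all(paste(sel_hi$i, sel_hi$j) %in%
                      paste(sel_lo$i, sel_lo$j)))
  }
})

test_that("every positive pixel lies inside a selected finest-level tile", {
  s <- small_slide(1536, 1024, n_lesions = 2, seed = 71)
  pyr <- build_pyramid(s$image, pyramid_config(512, num_levels = 3))
  res <- run_cascade(pyr, rep(list(make_threshold_oracle()), 3))
  pos <- which(res$mask == 1L, arr.ind = TRUE)
  tile_of <- unique(tibble::tibble(i = (pos[, 1] - 1L) %/% 512L,
                                   j = (pos[, 2] - 1L) %/% 512L))
  sel <- dplyr::filter(res$selected, level == 3)
  expect_true(all(paste(tile_of$i, tile_of$j) %in% paste(sel$i, sel$j)))
})

test_that("mask assembly matches brute-force thresholding and stitching", {
  set.seed(12)
  maps <- list(
    make_prob_map(matrix(runif(64 * 64), 64, 64), 1, 0, 0),
    make_prob_map(matrix(runif(64 * 64), 64, 64), 1, 0, 1, valid = c(64, 40)))
  mask <- assemble_mask(maps, c(64, 104), 64, alpha = 0.5)
  manual <- matrix(0L, 64, 104)
  manual[1:64, 1:64] <- (maps[[1]]$values >= 0.5) * 1L
  manual[1:64, 65:104] <- (maps[[2]]$values[, 1:40] >= 0.5) * 1L
  expect_identical(mask, manual)
  expect_identical(assemble_mask(list(), c(32, 32), 16), matrix(0L, 32, 32))
  expect_error(assemble_mask(c(maps, maps[1]), c(64, 104), 64),
               "Overlapping tile claims")
})

test_that("cascade input contracts are enforced", {
  s <- small_slide(1024, 512, n_lesions = 1, seed = 81)
  pyr <- build_pyramid(s$image, pyramid_config(512, num_levels = 2))
  expect_error(run_cascade(pyr, list(constant_segmenter(0))),
               "one model per level")
  t1 <- get_tile(pyr, 1, 0, 0)
  t2 <- get_tile(pyr, 2, 0, 0)
  expect_error(infer_level(list(t1, t2), constant_segmenter(0)),
               "share one level")
  expect_identical(infer_level(list(), constant_segmenter(0)), list())
})
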