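# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths.

# Layer-by-layer spatial-size simulator from first principles of convolution
# arithmetic: conv/pool output = floor((in + 2p - k) / s) + 1, with ceil-mode
# pooling using ceiling instead of floor.
oracle_fcn_trace <- function(s) {
  conv <- function(s, k, p) floor((s + 2 * p - k) / 1) + 1
  pool <- function(s) ceiling((s - 2) / 2) + 1
  sizes <- c(Input = s)
  s <- conv(s, 3, 100); sizes["Conv1_1"] <- s
  s <- conv(s, 3, 1); sizes["Conv1_2"] <- s
  s <- pool(s); sizes["Pool1"] <- s
  for (b in 2:5) {
    for (k in seq_len(if (b <= 2) 2 else 3)) {
      s <- conv(s, 3, 1)
      sizes[sprintf("Conv%d_%d", b, k)] <- s
    }
    s <- pool(s); sizes[sprintf("Pool%d", b)] <- s
  }
  s <- floor((s - 7)) + 1; sizes["Fc6"] <- s
  sizes["Fc7"] <- s
  s <- (s - 1) * 32 + 64; sizes["Upsampled"] <- s
  sizes
}

# Point-in-ellipse rasterization over the full pixel grid (no bounding boxes,
# no shared code with the generator's renderer).
oracle_ellipse_mask <- function(lesions, width, height) {
  m <- matrix(0L, height, width)
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  for (k in seq_len(nrow(lesions))) {
    le <- lesions[k, ]
    dx <- xs - le$cx
    dy <- ys - le$cy
    u <- (dx * cos(le$theta) + dy * sin(le$theta)) / le$a
    v <- (-dx * sin(le$theta) + dy * cos(le$theta)) / le$b
    m[u^2 + v^2 <= 1] <- 1L
  }
  m
}

# Per-cell maxima thresholding with explicit loops.
oracle_attention <- function(values, valid, units, alpha) {
  ts <- nrow(values)
  us <- ts %/% units
  out <- matrix(0L, units, units)
  for (a in seq_len(units)) {
    for (b in seq_len(units)) {
      rows <- ((a - 1) * us + 1):(a * us)
      cols <- ((b - 1) * us + 1):(b * us)
      rows <- rows[rows <= valid[1]]
      cols <- cols[cols <= valid[2]]
      if (length(rows) && length(cols)) {
        out[a, b] <- as.integer(max(values[rows, cols]) >= alpha)
      }
    }
  }
  out
}

# Per-pixel confusion tally with explicit loops (small masks only).
oracle_confusion <- function(pred, gt) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1
      if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1
      if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1
      if (pred[i, j] == 0 && gt[i, j] == 1) fn <- fn + 1
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Textbook pooled-MSE pairwise t comparisons, written directly from the
# one-way ANOVA definitions.
oracle_lsd <- function(values, groups, conf_level = 0.95) {
  lv <- unique(groups)
  k <- length(lv)
  n_total <- length(values)
  sse <- 0
  for (g in lv) {
    v <- values[groups == g]
    sse <- sse + sum((v - mean(v))^2)
  }
  df <- n_total - k
  mse <- sse / df
  res <- list()
  cmb <- utils::combn(lv, 2)
  for (p in seq_len(ncol(cmb))) {
    a <- cmb[1, p]; b <- cmb[2, p]
    na <- sum(groups == a); nb <- sum(groups == b)
    d <- mean(values[groups == a]) - mean(values[groups == b])
    se <- sqrt(mse * (1 / na + 1 / nb))
    tt <- if (se == 0) 0 else d / se
    tc <- qt(1 - (1 - conf_level) / 2, df)
    res[[p]] <- data.frame(method_i = a, method_j = b, mean_difference = d,
                           std_error = se, p_value = 2 * pt(-abs(tt), df),
                           ci_low = d - tc * se, ci_high = d + tc * se)
  }
  do.call(rbind, res)
}

# Minimal pyramid stand-in carrying only the geometry select_tiles() and
# child-index arithmetic need (no rasters), for exhaustive grid sweeps.
fake_pyramid <- function(n_rows1, n_cols1, tile_size = 16, zoom_step = 2,
                         num_levels = 2) {
  f <- 2^zoom_step
  grid <- tibble::tibble(
    level = 1:2,
    height = c(n_rows1 * tile_size, n_rows1 * tile_size * f),
    width = c(n_cols1 * tile_size, n_cols1 * tile_size * f),
    n_rows = c(n_rows1, n_rows1 * f),
    n_cols = c(n_cols1, n_cols1 * f))
  grid$n_tiles <- grid$n_rows * grid$n_cols
  structure(list(config = pyramid_config(tile_size, num_levels, zoom_step),
                 levels = NULL, grid = grid),
            class = "tile_pyramid")
}

small_slide <- function(width = 1024, height = 1024, n_lesions = 2, seed = 5,
                        axes = c(40, 80)) {
  suppressWarnings(generate_slide(slide_spec(
    width, height, n_lesions = n_lesions, lesion_axis_range = axes,
    sparsity_ceiling = 1, seed = seed)))
}
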