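# hand-built image set: class c shows a bright 4x4 block at a class-specific
# location on a dark background, plus pixel noise
block_image_set <- function(n_per_class, n_classes = 3, side = 12, seed = 1,
                            provenance = list(nonsq = "a", sq = "b"),
                            prefix = "s") {
  set.seed(seed)
  n <- n_per_class * n_classes
  px <- array(0L, dim = c(n, side, side))
  labels <- character(n)
  for (i in seq_len(n)) {
    cl <- (i - 1) %% n_classes + 1
    img <- matrix(sample(0:60, side * side, TRUE), side, side)
    rows <- (cl - 1) * 4 + 1:4
    img[rows, 5:8] <- sample(200:255, 16, TRUE)
    px[i, , ] <- img
    labels[i] <- paste0("class", cl)
  }
  list(images = structure(list(pixels = px,
                               sample_ids = sprintf("%s%03d", prefix, seq_len(n)),
                               grid_shape = c(side, side),
                               provenance = provenance),
                          class = "MethylationImageSet"),
       labels = labels)
}

test_that("patchify tiles losslessly into row-major flattened patches", {
  img <- to_uint8_grayscale(matrix(runif(68 * 68), 68, 68), sample_id = "x")
  p <- patchify(img, 4)
  expect_equal(dim(p), c(289L, 48L))
  expect_equal(unpatchify(p, c(68, 68, 3), 4), img$pixels, ignore_attr = TRUE)
  cst <- patchify(to_uint8_grayscale(matrix(0.5, 8, 8)), 4)
  expect_true(all(apply(cst, 2, function(col) length(unique(col)) == 1)))
  expect_error(patchify(to_uint8_grayscale(matrix(0.5, 9, 9)), 4), "divisible")
})

test_that("config validation enforces the geometry contracts", {
  expect_error(vit_config(image_size = 66), "divisible")
  expect_error(vit_config(block_mlp_units = c(512, 128)), "projection_dim")
  expect_error(vit_config(epochs = 0), "epochs")
  cfg <- vit_config()
  expect_equal(cfg$n_tokens, 289L)
})

test_that("parameter count matches an independent layer-by-layer tally", {
  cfg <- vit_config()
  P <- 289; D <- 256; d_in <- 48; u1 <- 512; u2 <- 256
  h1 <- 1024; h2 <- 512; C <- 18; B <- 8
  tally <- (d_in * D + D) + P * D +
    B * (2 * D + 4 * (D * D + D) + 2 * D +
           (D * u1 + u1) + (u1 * u2 + u2)) +
    2 * D +
    (P * D * h1 + h1) + (h1 * h2 + h2) + (h2 * C + C)
  expect_equal(vit_parameter_count(cfg), tally)
})

test_that("forward passes are normalized, seeded builds identical", {
  cfg <- vit_config(image_size = 12, patch_size = 4, n_blocks = 2, n_heads = 2,
                    projection_dim = 16, block_mlp_units = c(24, 16),
                    head_mlp_units = c(20, 12), n_classes = 4, dropout = 0,
                    seed = 5)
  m1 <- build_vit(cfg); m2 <- build_vit(cfg)
  expect_identical(m1$params, m2$params)
  set <- block_image_set(2, 3, side = 12, seed = 2)
  probs <- methylCUP:::vit_forward(m1$params, cfg,
    methylCUP:::image_set_to_patches(set$images, cfg))$probs
  expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-6)
  expect_true(all(probs >= 0))
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- vit_config(image_size = 8, patch_size = 4, n_blocks = 2, n_heads = 2,
                    projection_dim = 8, block_mlp_units = c(12, 8),
                    head_mlp_units = c(10, 6), n_classes = 3, dropout = 0,
                    seed = 42)
  m <- build_vit(cfg)
  set.seed(9)
  X <- array(runif(3 * cfg$n_tokens * 48), dim = c(3, cfg$n_tokens, 48))
  y <- c(1L, 3L, 2L)
  loss_fn <- function(params)
    methylCUP:::cross_entropy(methylCUP:::vit_forward(params, cfg, X)$probs, y)
  fw <- methylCUP:::vit_forward(m$params, cfg, X, keep_cache = TRUE)
  dlogits <- fw$probs
  dlogits[cbind(1:3, y)] <- dlogits[cbind(1:3, y)] - 1
  dlogits <- dlogits / 3
  gr <- methylCUP:::vit_backward(m$params, cfg, fw$cache, dlogits)
  eps <- 1e-5
  set.seed(1)
  for (nm in names(m$params)) {
    for (i in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d] = %g", nm, i, gr[[nm]][i]))
    }
  }
})

test_that("training separates block-structured classes and logs a sane history", {
  cfg <- vit_config_scaled(image_size = 12, n_classes = 3, seed = 7)
  set <- block_image_set(20, 3, side = 12, seed = 3)
  val <- block_image_set(6, 3, side = 12, seed = 4, prefix = "v")
  m <- train_vit(build_vit(cfg), set$images, set$labels, val$images, val$labels)
  expect_equal(nrow(m$history), 5L)
  expect_gt(m$history$train_acc[5], 0.95)
  # descent sanity over 3 seeds: first-epoch loss below the untrained loss
  for (sd in 1:3) {
    cfg_s <- vit_config_scaled(image_size = 12, n_classes = 3, seed = 20 + sd)
    tr <- block_image_set(10, 3, side = 12, seed = 30 + sd)
    va <- block_image_set(3, 3, side = 12, seed = 40 + sd, prefix = "v")
    m0 <- build_vit(cfg_s)
    X <- methylCUP:::image_set_to_patches(tr$images, cfg_s)
    y <- match(tr$labels, sort(unique(tr$labels)))
    untrained <- methylCUP:::cross_entropy(
      methylCUP:::vit_forward(m0$params, cfg_s, X)$probs, y)
    mt <- train_vit(m0, tr$images, tr$labels, va$images, va$labels)
    expect_lte(mt$history$train_loss[1], untrained * 1.05)
  }
})

test_that("prediction is deterministic, shape-stable and order-equivariant", {
  cfg <- vit_config_scaled(image_size = 12, n_classes = 3, seed = 7)
  set <- block_image_set(8, 3, side = 12, seed = 3)
  val <- block_image_set(3, 3, side = 12, seed = 4, prefix = "v")
  m <- train_vit(build_vit(cfg), set$images, set$labels, val$images, val$labels)
  p1 <- predict_vit(m, val$images)
  p2 <- predict_vit(m, val$images)
  expect_identical(p1$probabilities, p2$probabilities)
  expect_equal(dim(p1$probabilities), c(9L, 3L))
  expect_equal(rowSums(p1$probabilities), rep(1, 9), tolerance = 1e-6,
               ignore_attr = TRUE)
  # permuting the batch permutes the outputs identically
  perm <- c(5, 1, 9, 2, 7, 3, 8, 4, 6)
  permuted <- val$images
  permuted$pixels <- val$images$pixels[perm, , , drop = FALSE]
  permuted$sample_ids <- val$images$sample_ids[perm]
  pp <- predict_vit(m, permuted)
  expect_equal(pp$probabilities, p1$probabilities[perm, ], tolerance = 1e-9)
})

test_that("a model refuses images rendered under a different assignment", {
  cfg <- vit_config_scaled(image_size = 12, n_classes = 3, seed = 7)
  set <- block_image_set(8, 3, side = 12, seed = 3)
  val <- block_image_set(3, 3, side = 12, seed = 4, prefix = "v")
  m <- train_vit(build_vit(cfg), set$images, set$labels, val$images, val$labels)
  foreign <- val$images
  foreign$provenance <- list(nonsq = "other", sq = "b")
  expect_error(predict_vit(m, foreign), "different probe-to-pixel assignment")
  expect_silent(predict_vit(m, foreign, check_provenance = FALSE))
})

test_that("attention rows are stochastic and frozen-uniform attention is flat", {
  cfg <- vit_config(image_size = 12, patch_size = 4, n_blocks = 2, n_heads = 2,
                    projection_dim = 16, block_mlp_units = c(24, 16),
                    head_mlp_units = c(20, 12), n_classes = 3, dropout = 0,
                    seed = 11)
  m <- build_vit(cfg)
  set <- block_image_set(1, 3, side = 12, seed = 6)
  X <- methylCUP:::image_set_to_patches(set$images, cfg)
  fw <- methylCUP:::vit_forward(m$params, cfg, X[1, , , drop = FALSE])
  for (A in fw$attn_last[[1]])
    expect_equal(rowSums(A), rep(1, cfg$n_tokens), tolerance = 1e-6)

  att <- extract_attention(m, get_image(set$images, set$images$sample_ids[1]))
  expect_equal(dim(att$mean_map), c(12L, 12L))
  expect_true(all(att$mean_map >= 0 & att$mean_map <= 1))
  expect_equal(sum(att$grid), 1, tolerance = 1e-9)

  # zero the final block's query/key projections: attention becomes uniform
  m$params$b2_Wq[] <- 0; m$params$b2_bq[] <- 0
  m$params$b2_Wk[] <- 0; m$params$b2_bk[] <- 0
  att_u <- extract_attention(m, get_image(set$images, set$images$sample_ids[1]))
  expect_equal(as.vector(att_u$grid), rep(1 / 9, 9), tolerance = 1e-12)
})
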