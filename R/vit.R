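#' Vision-transformer configuration
#'
#' Geometry and training hyper-parameters of the methylation-image
#' classifier. Defaults follow the full-scale model: 68 x 68 inputs cut into
#' 4 x 4 patches (17 x 17 = 289 tokens), 8 pre-norm transformer blocks with
#' 4 attention heads at projection dimension 256, block MLP 512 -> 256 with
#' GELU, all-token flatten into a 1024 -> 512 head, softmax output; AdamW,
#' batch size 100, 14 epochs, learning rate 1e-4. Dropout 0.1 and weight
#' decay 1e-4 are applied in attention and the MLPs.
#'
#' @param image_size Side length of the square input image.
#' @param patch_size Patch side; must divide `image_size`.
#' @param n_blocks Number of transformer encoder blocks.
#' @param n_heads Attention heads; must divide `projection_dim`.
#' @param projection_dim Token embedding width.
#' @param block_mlp_units Two integers; the second must equal
#'   `projection_dim` so the residual connection is well-formed.
#' @param head_mlp_units Two integers for the classification head.
#' @param n_classes Number of origin classes.
#' @param batch_size,epochs,learning_rate,weight_decay AdamW training
#'   parameters.
#' @param dropout Dropout rate in attention weights and MLPs (0 disables).
#' @param seed Integer seed for initialisation and batch shuffling.
#' @return A `ViTConfig` list.
#' @export
vit_config <- function(image_size = 68L, patch_size = 4L, n_blocks = 8L,
                       n_heads = 4L, projection_dim = 256L,
                       block_mlp_units = c(512L, 256L),
                       head_mlp_units = c(1024L, 512L), n_classes = 18L,
                       batch_size = 100L, epochs = 14L,
                       learning_rate = 1e-4, weight_decay = 1e-4,
                       dropout = 0.1, seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              patch_size = as.integer(patch_size),
              n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
              projection_dim = as.integer(projection_dim),
              block_mlp_units = as.integer(block_mlp_units),
              head_mlp_units = as.integer(head_mlp_units),
              n_classes = as.integer(n_classes),
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              learning_rate = learning_rate, weight_decay = weight_decay,
              dropout = dropout, seed = as.integer(seed))
  if (cfg$image_size %% cfg$patch_size != 0L)
    stopf("image_size (%d) must be divisible by patch_size (%d)",
          cfg$image_size, cfg$patch_size)
  if (cfg$projection_dim %% cfg$n_heads != 0L)
    stopf("projection_dim must be divisible by n_heads")
  if (length(cfg$block_mlp_units) != 2L ||
      cfg$block_mlp_units[2L] != cfg$projection_dim)
    stopf("block_mlp_units must be length 2 with the second equal to projection_dim")
  if (length(cfg$head_mlp_units) != 2L) stopf("head_mlp_units must be length 2")
  if (cfg$epochs < 1L) stopf("'epochs' must be >= 1")
  if (cfg$batch_size < 1L) stopf("'batch_size' must be >= 1")
  if (cfg$n_classes < 2L) stopf("'n_classes' must be >= 2")
  cfg$n_tokens <- (cfg$image_size %/% cfg$patch_size)^2L
  structure(cfg, class = "ViTConfig")
}

#' Desk-scale training configuration
#'
#' A reduced transformer (2 blocks, 5 epochs, narrower projections, a larger
#' learning rate, no dropout) for CPU-scale experiments on small synthetic
#' cohorts; the geometry adapts to the image size.
#'
#' @param image_size Side of the (square) merged image.
#' @param n_classes Number of classes.
#' @param seed Seed.
#' @param ... Overrides forwarded to [vit_config()].
#' @return A `ViTConfig`.
#' @export
vit_config_scaled <- function(image_size, n_classes, seed = 1L, ...) {
  vit_config(image_size = image_size, patch_size = 4L, n_blocks = 2L,
             n_heads = 4L, projection_dim = 64L,
             block_mlp_units = c(128L, 64L), head_mlp_units = c(128L, 64L),
             n_classes = n_classes, batch_size = 16L, epochs = 5L,
             learning_rate = 3e-3, weight_decay = 1e-4, dropout = 0,
             seed = seed, ...)
}

#' Cut an image into flattened patches
#'
#' Tiles the image exactly with `patch_size` x `patch_size` patches in
#' row-major patch order; each patch is flattened (including the three
#' channels) into a vector of length `patch_size^2 * 3`. Lossless:
#' [unpatchify()] inverts it.
#'
#' @param image A `MethylationImage` (or an H x W x 3 array).
#' @param patch_size Patch side; must divide both image dimensions.
#' @return Matrix of `n_patches` rows and `patch_size^2 * 3` columns.
#' @export
patchify <- function(image, patch_size = 4L) {
  px <- if (inherits(image, "MethylationImage")) image$pixels else image
  stopifnot(length(dim(px)) == 3L)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  if (H %% patch_size != 0L || W %% patch_size != 0L)
    stopf("image %dx%d not divisible by patch size %d", H, W, patch_size)
  gr <- H %/% patch_size; gc <- W %/% patch_size
  out <- matrix(0, gr * gc, patch_size^2 * dim(px)[3L])
  k <- 0L
  for (pr in seq_len(gr)) {
    rows <- (pr - 1L) * patch_size + seq_len(patch_size)
    for (pc in seq_len(gc)) {
      cols <- (pc - 1L) * patch_size + seq_len(patch_size)
      k <- k + 1L
      out[k, ] <- as.vector(px[rows, cols, ])
    }
  }
  out
}

#' @rdname patchify
#' @param patches Matrix from [patchify()].
#' @param image_shape Original `c(H, W, channels)`.
#' @return The reassembled array.
#' @export
unpatchify <- function(patches, image_shape, patch_size = 4L) {
  H <- image_shape[1L]; W <- image_shape[2L]; C <- image_shape[3L]
  gr <- H %/% patch_size; gc <- W %/% patch_size
  px <- array(0, dim = image_shape)
  k <- 0L
  for (pr in seq_len(gr)) {
    rows <- (pr - 1L) * patch_size + seq_len(patch_size)
    for (pc in seq_len(gc)) {
      cols <- (pc - 1L) * patch_size + seq_len(patch_size)
      k <- k + 1L
      px[rows, cols, ] <- array(patches[k, ], dim = c(patch_size, patch_size, C))
    }
  }
  px
}

## ---- internal neural-net primitives ---------------------------------------

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

layernorm_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2L, g, `*`)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

# dropout with inverted scaling; returns mask (or NULL when inactive)
dropout_mask <- function(dim_, rate, training) {
  if (!training || rate <= 0) return(NULL)
  mask <- array(runif(prod(dim_)) >= rate, dim = dim_) / (1 - rate)
  mask
}

init_mat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, 0, sd), nr, nc)

## ---- model construction ----------------------------------------------------

#' Build an untrained vision transformer
#'
#' Allocates and seeds all parameters for the architecture described by the
#' config: linear patch projection plus learned position embeddings, pre-norm
#' transformer blocks (multi-head self-attention and a GELU MLP, each behind
#' a residual connection), a final layer norm, then an all-token flatten into
#' the GELU head MLP and a softmax output layer. Two builds with the same
#' seed have identical initial parameters.
#'
#' @param config A [vit_config()].
#' @return A `ViTModel` list: `params`, `config`, `label_order` (NULL until
#'   trained), `history`, `provenance`.
#' @export
build_vit <- function(config) {
  stopifnot(inherits(config, "ViTConfig"))
  set.seed(config$seed)
  D <- config$projection_dim; P <- config$n_tokens
  d_in <- config$patch_size^2 * 3L
  u <- config$block_mlp_units; h <- config$head_mlp_units
  p <- list(emb_W = init_mat(d_in, D), emb_b = numeric(D),
            pos_E = init_mat(P, D))
  for (i in seq_len(config$n_blocks)) {
    p[[sprintf("b%d_ln1_g", i)]] <- rep(1, D)
    p[[sprintf("b%d_ln1_b", i)]] <- numeric(D)
    for (nm in c("q", "k", "v", "o")) {
      p[[sprintf("b%d_W%s", i, nm)]] <- init_mat(D, D)
      p[[sprintf("b%d_b%s", i, nm)]] <- numeric(D)
    }
    p[[sprintf("b%d_ln2_g", i)]] <- rep(1, D)
    p[[sprintf("b%d_ln2_b", i)]] <- numeric(D)
    p[[sprintf("b%d_W1", i)]] <- init_mat(D, u[1L])
    p[[sprintf("b%d_b1", i)]] <- numeric(u[1L])
    p[[sprintf("b%d_W2", i)]] <- init_mat(u[1L], u[2L])
    p[[sprintf("b%d_b2", i)]] <- numeric(u[2L])
  }
  p$lnf_g <- rep(1, D); p$lnf_b <- numeric(D)
  p$head_W1 <- init_mat(P * D, h[1L]); p$head_b1 <- numeric(h[1L])
  p$head_W2 <- init_mat(h[1L], h[2L]); p$head_b2 <- numeric(h[2L])
  p$out_W <- init_mat(h[2L], config$n_classes)
  p$out_b <- numeric(config$n_classes)
  structure(list(params = p, config = config, label_order = NULL,
                 history = NULL, provenance = NULL),
            class = "ViTModel")
}

#' Total number of trainable parameters
#' @param model A `ViTModel` or a `ViTConfig`.
#' @return Integer count.
#' @export
vit_parameter_count <- function(model) {
  if (inherits(model, "ViTConfig")) model <- build_vit(model)
  sum(vapply(model$params, length, numeric(1)))
}

# forward pass over a batch.
# X: b x P x d_in array of patch vectors scaled to [0,1].
# Returns probs (b x C) and, if keep_cache, everything backward needs.
vit_forward <- function(params, config, X, training = FALSE,
                        keep_cache = FALSE) {
  b <- dim(X)[1L]; P <- config$n_tokens; D <- config$projection_dim
  nh <- config$n_heads; dh <- D %/% nh
  Xt <- matrix(aperm(X, c(2L, 1L, 3L)), b * P, dim(X)[3L])  # sample-major tokens
  tok_idx <- rep(seq_len(P), b)
  H <- Xt %*% params$emb_W +
    rep(params$emb_b, each = b * P) + params$pos_E[tok_idx, ]
  cache <- if (keep_cache) list(Xt = Xt, tok_idx = tok_idx, blocks = list())
  attn_last <- NULL
  rows_of <- function(s) (s - 1L) * P + seq_len(P)
  for (i in seq_len(config$n_blocks)) {
    pfx <- function(nm) params[[sprintf("b%d_%s", i, nm)]]
    ln1 <- layernorm_fwd(H, pfx("ln1_g"), pfx("ln1_b"))
    Q <- ln1$y %*% pfx("Wq") + rep(pfx("bq"), each = b * P)
    K <- ln1$y %*% pfx("Wk") + rep(pfx("bk"), each = b * P)
    V <- ln1$y %*% pfx("Wv") + rep(pfx("bv"), each = b * P)
    O <- matrix(0, b * P, D)
    A_store <- if (keep_cache || i == config$n_blocks) vector("list", b)
    M_store <- if (keep_cache) vector("list", b)
    for (s in seq_len(b)) {
      rs <- rows_of(s)
      A_heads <- vector("list", nh); M_heads <- vector("list", nh)
      for (hh in seq_len(nh)) {
        cs <- (hh - 1L) * dh + seq_len(dh)
        S <- (Q[rs, cs, drop = FALSE] %*% t(K[rs, cs, drop = FALSE])) / sqrt(dh)
        A <- softmax_rows(S)
        M <- dropout_mask(dim(A), config$dropout, training)
        Ad <- if (is.null(M)) A else A * M
        O[rs, cs] <- Ad %*% V[rs, cs, drop = FALSE]
        A_heads[[hh]] <- A
        M_heads[hh] <- list(M)          # [[<- would drop a NULL mask
      }
      if (!is.null(A_store)) A_store[[s]] <- A_heads
      if (keep_cache) M_store[[s]] <- M_heads
    }
    Oo <- O %*% pfx("Wo") + rep(pfx("bo"), each = b * P)
    Mo <- dropout_mask(dim(Oo), config$dropout, training)
    if (!is.null(Mo)) Oo <- Oo * Mo
    H1 <- H + Oo
    ln2 <- layernorm_fwd(H1, pfx("ln2_g"), pfx("ln2_b"))
    Z1 <- ln2$y %*% pfx("W1") + rep(pfx("b1"), each = b * P)
    G <- gelu(Z1)
    Mg <- dropout_mask(dim(G), config$dropout, training)
    Gd <- if (is.null(Mg)) G else G * Mg
    Z2 <- Gd %*% pfx("W2") + rep(pfx("b2"), each = b * P)
    Mz <- dropout_mask(dim(Z2), config$dropout, training)
    if (!is.null(Mz)) Z2 <- Z2 * Mz
    Hnew <- H1 + Z2
    if (keep_cache)
      cache$blocks[[i]] <- list(H = H, ln1 = ln1, Q = Q, K = K, V = V, O = O,
                                A = A_store, M = M_store, Mo = Mo, H1 = H1,
                                ln2 = ln2, Z1 = Z1, G = G, Mg = Mg, Mz = Mz)
    if (i == config$n_blocks) attn_last <- A_store
    H <- Hnew
  }
  lnf <- layernorm_fwd(H, params$lnf_g, params$lnf_b)
  Fm <- matrix(0, b, P * D)            # per-sample all-token flatten
  for (s in seq_len(b)) Fm[s, ] <- as.vector(t(lnf$y[rows_of(s), , drop = FALSE]))
  Mf <- dropout_mask(dim(Fm), config$dropout, training)
  Fd <- if (is.null(Mf)) Fm else Fm * Mf
  Z1h <- Fd %*% params$head_W1 + rep(params$head_b1, each = b)
  G1h <- gelu(Z1h)
  M1h <- dropout_mask(dim(G1h), config$dropout, training)
  G1d <- if (is.null(M1h)) G1h else G1h * M1h
  Z2h <- G1d %*% params$head_W2 + rep(params$head_b2, each = b)
  G2h <- gelu(Z2h)
  logits <- G2h %*% params$out_W + rep(params$out_b, each = b)
  probs <- softmax_rows(logits)
  if (keep_cache) {
    cache <- c(cache, list(Hfinal = H, lnf = lnf, Fm = Fm, Mf = Mf,
                           Z1h = Z1h, G1h = G1h, M1h = M1h, Z2h = Z2h,
                           G2h = G2h, probs = probs, b = b))
  }
  list(probs = probs, cache = cache, attn_last = attn_last)
}

# backward pass; dlogits = dLoss/dlogits (b x C). Returns gradient list
# matching params' names/shapes.
vit_backward <- function(params, config, cache, dlogits) {
  b <- cache$b; P <- config$n_tokens; D <- config$projection_dim
  nh <- config$n_heads; dh <- D %/% nh
  g <- list()
  rows_of <- function(s) (s - 1L) * P + seq_len(P)

  g$out_W <- t(cache$G2h) %*% dlogits
  g$out_b <- colSums(dlogits)
  dG2h <- dlogits %*% t(params$out_W)
  dZ2h <- dG2h * gelu_grad(cache$Z2h)
  G1d <- if (is.null(cache$M1h)) cache$G1h else cache$G1h * cache$M1h
  g$head_W2 <- t(G1d) %*% dZ2h
  g$head_b2 <- colSums(dZ2h)
  dG1d <- dZ2h %*% t(params$head_W2)
  dG1h <- if (is.null(cache$M1h)) dG1d else dG1d * cache$M1h
  dZ1h <- dG1h * gelu_grad(cache$Z1h)
  Fd <- if (is.null(cache$Mf)) cache$Fm else cache$Fm * cache$Mf
  g$head_W1 <- t(Fd) %*% dZ1h
  g$head_b1 <- colSums(dZ1h)
  dFd <- dZ1h %*% t(params$head_W1)
  dFm <- if (is.null(cache$Mf)) dFd else dFd * cache$Mf
  dLnfY <- matrix(0, b * P, D)
  for (s in seq_len(b)) dLnfY[rows_of(s), ] <- matrix(dFm[s, ], P, D, byrow = TRUE)
  bw <- layernorm_bwd(dLnfY, cache$lnf, params$lnf_g)
  g$lnf_g <- bw$dg; g$lnf_b <- bw$db
  dH <- bw$dx

  for (i in rev(seq_len(config$n_blocks))) {
    bl <- cache$blocks[[i]]
    pfx <- function(nm) params[[sprintf("b%d_%s", i, nm)]]
    nm_ <- function(nm) sprintf("b%d_%s", i, nm)
    # MLP branch
    dZ2 <- if (is.null(bl$Mz)) dH else dH * bl$Mz
    Gd <- if (is.null(bl$Mg)) bl$G else bl$G * bl$Mg
    g[[nm_("W2")]] <- t(Gd) %*% dZ2
    g[[nm_("b2")]] <- colSums(dZ2)
    dGd <- dZ2 %*% t(pfx("W2"))
    dG <- if (is.null(bl$Mg)) dGd else dGd * bl$Mg
    dZ1 <- dG * gelu_grad(bl$Z1)
    g[[nm_("W1")]] <- t(bl$ln2$y) %*% dZ1
    g[[nm_("b1")]] <- colSums(dZ1)
    dLn2Y <- dZ1 %*% t(pfx("W1"))
    bw2 <- layernorm_bwd(dLn2Y, bl$ln2, pfx("ln2_g"))
    g[[nm_("ln2_g")]] <- bw2$dg; g[[nm_("ln2_b")]] <- bw2$db
    dH1 <- dH + bw2$dx
    # attention branch
    dOo <- if (is.null(bl$Mo)) dH1 else dH1 * bl$Mo
    g[[nm_("Wo")]] <- t(bl$O) %*% dOo
    g[[nm_("bo")]] <- colSums(dOo)
    dO <- dOo %*% t(pfx("Wo"))
    dQ <- matrix(0, b * P, D); dK <- matrix(0, b * P, D); dV <- matrix(0, b * P, D)
    for (s in seq_len(b)) {
      rs <- rows_of(s)
      for (hh in seq_len(nh)) {
        cs <- (hh - 1L) * dh + seq_len(dh)
        A <- bl$A[[s]][[hh]]; M <- bl$M[[s]][[hh]]
        Ad <- if (is.null(M)) A else A * M
        dOh <- dO[rs, cs, drop = FALSE]
        Vh <- bl$V[rs, cs, drop = FALSE]
        dAd <- dOh %*% t(Vh)
        dV[rs, cs] <- t(Ad) %*% dOh
        dA <- if (is.null(M)) dAd else dAd * M
        dS <- A * (dA - rowSums(dA * A))
        dQ[rs, cs] <- dS %*% bl$K[rs, cs, drop = FALSE] / sqrt(dh)
        dK[rs, cs] <- t(dS) %*% bl$Q[rs, cs, drop = FALSE] / sqrt(dh)
      }
    }
    y1 <- bl$ln1$y
    g[[nm_("Wq")]] <- t(y1) %*% dQ; g[[nm_("bq")]] <- colSums(dQ)
    g[[nm_("Wk")]] <- t(y1) %*% dK; g[[nm_("bk")]] <- colSums(dK)
    g[[nm_("Wv")]] <- t(y1) %*% dV; g[[nm_("bv")]] <- colSums(dV)
    dLn1Y <- dQ %*% t(pfx("Wq")) + dK %*% t(pfx("Wk")) + dV %*% t(pfx("Wv"))
    bw1 <- layernorm_bwd(dLn1Y, bl$ln1, pfx("ln1_g"))
    g[[nm_("ln1_g")]] <- bw1$dg; g[[nm_("ln1_b")]] <- bw1$db
    dH <- dH1 + bw1$dx
  }
  g$emb_W <- t(cache$Xt) %*% dH
  g$emb_b <- colSums(dH)
  dPos <- rowsum(dH, cache$tok_idx)
  g$pos_E <- as.matrix(dPos)
  g
}

## ---- training and inference ------------------------------------------------

# image set -> b x P x d_in patch array scaled to [0,1]
image_set_to_patches <- function(image_set, config) {
  if (image_set$grid_shape[1L] != config$image_size ||
      image_set$grid_shape[2L] != config$image_size)
    stopf("image geometry %dx%d does not match config image_size %d",
          image_set$grid_shape[1L], image_set$grid_shape[2L], config$image_size)
  n <- length(image_set$sample_ids)
  d_in <- config$patch_size^2 * 3L
  X <- array(0, dim = c(n, config$n_tokens, d_in))
  for (k in seq_len(n)) {
    ch <- image_set$pixels[k, , ] / 255
    X[k, , ] <- patchify(array(ch, dim = c(dim(ch), 3L)), config$patch_size)
  }
  X
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)))
}

#' Train the vision transformer
#'
#' Minimises categorical cross-entropy with AdamW over the configured number
#' of epochs, recording per-epoch loss and accuracy on the training and
#' validation sets and retaining the parameters of the epoch with the best
#' validation accuracy. Runs are reproducible for a fixed config seed. The
#' model records the image stack's assignment provenance and later refuses
#' to predict images rendered under a different assignment.
#'
#' @param model A `ViTModel` from [build_vit()].
#' @param image_set,labels Training `MethylationImageSet` and a character
#'   vector of class labels aligned to its `sample_ids`.
#' @param val_image_set,val_labels Validation stack and labels (disjoint
#'   from training).
#' @param verbose Print per-epoch progress.
#' @return The trained `ViTModel` with `label_order`, `history` and
#'   `provenance` filled in.
#' @export
train_vit <- function(model, image_set, labels, val_image_set, val_labels,
                      verbose = FALSE) {
  stopifnot(inherits(model, "ViTModel"))
  config <- model$config
  if (length(labels) != length(image_set$sample_ids))
    stopf("labels must align with the image set")
  if (length(intersect(image_set$sample_ids, val_image_set$sample_ids)))
    stopf("training and validation sets overlap")
  label_order <- sort(unique(labels))
  if (length(label_order) > config$n_classes)
    stopf("%d classes in labels exceed config n_classes = %d",
          length(label_order), config$n_classes)
  if (length(setdiff(unique(val_labels), label_order)))
    warnf("validation classes absent from training: %s",
          paste(setdiff(unique(val_labels), label_order), collapse = ", "))
  if (length(label_order) < config$n_classes)
    label_order <- c(label_order,
                     sprintf(".unused%02d", seq_len(config$n_classes - length(label_order))))
  y <- match(labels, label_order)
  yv <- match(val_labels, label_order)

  X <- image_set_to_patches(image_set, config)
  Xv <- image_set_to_patches(val_image_set, config)
  n <- dim(X)[1L]
  params <- model$params
  mstate <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  vstate <- mstate
  decay_set <- names(params)[vapply(params, is.matrix, logical(1))]
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(acc = -Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    idx <- sample(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[bi, , , drop = FALSE]
      fw <- vit_forward(params, config, Xb, training = TRUE, keep_cache = TRUE)
      pb <- fw$probs
      ep_loss <- ep_loss + cross_entropy(pb, y[bi]) * length(bi)
      ep_correct <- ep_correct + sum(max.col(pb, ties.method = "first") == y[bi])
      dlogits <- pb
      dlogits[cbind(seq_along(bi), y[bi])] <-
        dlogits[cbind(seq_along(bi), y[bi])] - 1
      dlogits <- dlogits / length(bi)
      grads <- vit_backward(params, config, fw$cache, dlogits)
      step <- step + 1L
      b1t <- 1 - beta1^step; b2t <- 1 - beta2^step
      for (nm in names(params)) {
        gr <- grads[[nm]]
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gr
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gr * gr
        upd <- (mstate[[nm]] / b1t) / (sqrt(vstate[[nm]] / b2t) + eps)
        if (nm %in% decay_set) upd <- upd + config$weight_decay * params[[nm]]
        params[[nm]] <- params[[nm]] - config$learning_rate * upd
      }
    }
    fv <- vit_forward(params, config, Xv, training = FALSE)
    val_loss <- cross_entropy(fv$probs, yv)
    val_acc <- mean(max.col(fv$probs, ties.method = "first") == yv)
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = val_loss, val_acc = val_acc))
    if (val_acc > best$acc) best <- list(acc = val_acc, params = params, epoch = ep)
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
                      ep, ep_loss / n, ep_correct / n, val_loss, val_acc))
  }
  model$params <- best$params
  model$label_order <- label_order
  model$history <- hist
  model$best_epoch <- best$epoch
  model$provenance <- image_set$provenance
  model
}

#' Predict origin classes for methylation images
#'
#' Deterministic inference: per-sample class probabilities (summing to 1)
#' and the argmax class, ties broken by `label_order` position. Refuses an
#' image set whose probe-to-pixel assignment fingerprint differs from the
#' one the model was trained on.
#'
#' @param model A trained `ViTModel`.
#' @param image_set A `MethylationImageSet`.
#' @param check_provenance Set `FALSE` to bypass the assignment guard.
#' @return List: `probabilities` (matrix, samples x classes, columns in
#'   `label_order`), `classes` (named character vector).
#' @export
predict_vit <- function(model, image_set, check_provenance = TRUE) {
  stopifnot(inherits(model, "ViTModel"))
  if (is.null(model$label_order)) stopf("model has not been trained")
  if (check_provenance && !is.null(model$provenance)) {
    same <- identical(model$provenance$nonsq, image_set$provenance$nonsq) &&
      identical(model$provenance$sq, image_set$provenance$sq)
    if (!same)
      stopf("image set was rendered under a different probe-to-pixel assignment than the model was trained on")
  }
  X <- image_set_to_patches(image_set, model$config)
  probs <- matrix(0, dim(X)[1L], model$config$n_classes)
  bs <- model$config$batch_size
  for (start in seq(1L, dim(X)[1L], by = bs)) {
    bi <- start:min(start + bs - 1L, dim(X)[1L])
    probs[bi, ] <- vit_forward(model$params, model$config,
                               X[bi, , , drop = FALSE])$probs
  }
  colnames(probs) <- model$label_order
  rownames(probs) <- image_set$sample_ids
  cls <- model$label_order[max.col(probs, ties.method = "first")]
  names(cls) <- image_set$sample_ids
  list(probabilities = probs, classes = cls)
}

#' Final-layer attention map for one image
#'
#' Runs a forward pass and aggregates the final encoder block's attention:
#' per head, the softmax attention rows (each summing to 1) are averaged
#' over query tokens, giving the mean attention received by each key token;
#' heads are then averaged and the token vector reshaped to the patch grid.
#' `mean_map` is the grid upsampled (nearest-neighbour) to the input image
#' size for overlay.
#'
#' @param model A `ViTModel` (trained or freshly built).
#' @param image A `MethylationImage` matching the model geometry.
#' @return An `AttentionMap`: list(sample_id, per_head (list of grid
#'   matrices), grid (mean over heads), mean_map (image-sized matrix)).
#' @export
extract_attention <- function(model, image) {
  stopifnot(inherits(model, "ViTModel"))
  config <- model$config
  px <- image$pixels / 255
  X <- array(0, dim = c(1L, config$n_tokens, config$patch_size^2 * 3L))
  X[1L, , ] <- patchify(array(px, dim = dim(image$pixels)), config$patch_size)
  fw <- vit_forward(model$params, config, X)
  heads <- fw$attn_last[[1L]]
  side <- config$image_size %/% config$patch_size
  per_head <- lapply(heads, function(A) {
    matrix(colMeans(A), side, side, byrow = TRUE)
  })
  grid <- Reduce(`+`, per_head) / length(per_head)
  mean_map <- resize_image(grid, c(config$image_size, config$image_size),
                           method = "nearest")
  structure(list(sample_id = image$sample_id, per_head = per_head,
                 grid = grid, mean_map = mean_map),
            class = "AttentionMap")
}
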