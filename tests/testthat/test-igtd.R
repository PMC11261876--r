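test_that("feature rank matrices match a brute-force sort of pair distances", {
  bm <- random_beta_matrix(10, 6, seed = 31)
  fr <- feature_rank_matrix(bm)
  d <- as.matrix(dist(bm$values))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  r <- rank(d[upper.tri(d)])
  oracle <- matrix(0, 10, 10)
  for (k in seq_len(nrow(pairs))) {
    oracle[pairs[k, 1], pairs[k, 2]] <- r[k]
    oracle[pairs[k, 2], pairs[k, 1]] <- r[k]
  }
  expect_equal(fr$ranks, oracle)
  expect_true(isSymmetric(fr$ranks))
  expect_true(all(diag(fr$ranks) == 0))

  two <- feature_rank_matrix(random_beta_matrix(2, 5, seed = 1))
  expect_equal(two$ranks[1, 2], 1)
  # three probes at mutual equal distance share the average rank 2
  v <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1) * 0.9, 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  eq <- feature_rank_matrix(BetaMatrix(v))
  expect_true(all(eq$ranks[upper.tri(eq$ranks)] == 2))
  expect_error(feature_rank_matrix(random_beta_matrix(1, 5, seed = 1)),
               "at least 2")
})

test_that("pixel rank matrices reflect grid geometry", {
  expect_equal(pixel_rank_matrix(c(1, 2))$ranks[1, 2], 1)
  g22 <- pixel_rank_matrix(c(2, 2))$ranks
  # the two diagonal pairs share the largest (tied) rank
  expect_equal(g22[1, 4], g22[2, 3])
  expect_equal(g22[1, 4], max(g22))
  g44 <- pixel_rank_matrix(c(4, 4))
  cells <- cbind((0:15) %/% 4, (0:15) %% 4)
  d <- as.matrix(dist(cells))
  r <- rank(d[upper.tri(d)])
  oracle <- matrix(0, 16, 16)
  oracle[upper.tri(oracle)] <- r
  oracle <- oracle + t(oracle)
  expect_equal(g44$ranks, oracle)
})

test_that("assignment error matches a double-loop oracle and its symmetries", {
  set.seed(41)
  bm <- random_beta_matrix(6, 8, seed = 41)
  fr <- feature_rank_matrix(bm)
  pr <- pixel_rank_matrix(c(2, 3))
  for (rep in 1:5) {
    ord <- sample(6)
    expect_equal(assignment_error(fr, pr, ord),
                 oracle_assignment_error(fr$ranks, pr$ranks, ord))
  }
  expect_equal(assignment_error(pr, pr, 1:6), 0)
  # relabeling both matrices by the same permutation leaves the error fixed
  perm <- sample(6)
  fr2 <- fr; fr2$ranks <- fr$ranks[perm, perm]
  ord <- sample(6)
  expect_equal(assignment_error(fr2, pr, match(ord, perm)),
               assignment_error(fr, pr, ord))
  expect_error(assignment_error(fr, pixel_rank_matrix(c(2, 2)), 1:4), "sizes differ")
  expect_error(assignment_error(fr, pr, c(1, 1, 2, 3, 4, 5)), "permutation")
})

test_that("optimization reaches the exhaustive optimum on tiny instances", {
  for (sd in c(5, 7, 11)) {
    set.seed(sd)
    shape <- list(c(2, 2), c(2, 3), c(2, 4))[[sample(3, 1)]]
    n <- prod(shape)
    bm <- random_beta_matrix(n, 10, seed = sd)
    fr <- feature_rank_matrix(bm)
    pr <- pixel_rank_matrix(shape)
    a <- igtd_optimize(fr, pr, n_iterations = 300, seed = sd)
    best <- min(vapply(all_perms(seq_len(n)),
                       function(p) assignment_error(fr, pr, p), numeric(1)))
    expect_lte(a$final_error, best * 1.1 + 1e-9)
    expect_equal(assignment_error(fr, pr, a$order), a$final_error)
  }
})

test_that("a perfectly matched instance is a fixed point at error zero", {
  pr <- pixel_rank_matrix(c(3, 3))
  fr <- structure(list(ranks = pr$ranks, size = 9, grid_shape = NULL,
                       probe_ids = sprintf("p%d", 1:9)), class = "RankMatrix")
  a <- igtd_optimize(fr, pr, n_iterations = 50, seed = 1, restarts = 0)
  expect_equal(a$order, 1:9)
  expect_true(all(a$error_trajectory == 0))
})

test_that("error trajectories never increase and orders stay bijective", {
  for (sd in 1:20) {
    set.seed(300 + sd)
    n <- 2L * sample(3:10, 1)
    bm <- random_beta_matrix(n, 5, seed = 200 + sd)
    fr <- feature_rank_matrix(bm)
    pr <- pixel_rank_matrix(c(2L, n %/% 2L))
    a <- igtd_optimize(fr, pr, n_iterations = 100, seed = sd, restarts = 3)
    expect_true(all(diff(a$error_trajectory) <= 1e-9))
    expect_setequal(a$order, seq_len(n))
    expect_lte(a$final_error, a$initial_error)
  }
})

test_that("block-structured panels land correlated probes on nearby pixels", {
  # 4 blocks of 9 highly correlated probes; after optimisation the mean
  # within-block pixel distance should beat random placement
  set.seed(77)
  n_block <- 4; per <- 9; n <- n_block * per
  base <- matrix(runif(n_block * 30), n_block, 30)
  v <- base[rep(seq_len(n_block), each = per), ] +
    matrix(rnorm(n * 30, 0, 0.01), n, 30)
  v <- pmin(pmax(v, 0), 1)
  dimnames(v) <- list(sprintf("p%02d", 1:n), sprintf("s%d", 1:30))
  fr <- feature_rank_matrix(BetaMatrix(v))
  pr <- pixel_rank_matrix(c(6, 6))
  a <- igtd_optimize(fr, pr, n_iterations = 500, seed = 3)
  coords <- cbind((seq_len(36) - 1) %/% 6, (seq_len(36) - 1) %% 6)
  block_of <- rep(seq_len(n_block), each = per)
  mean_within <- function(ord) {
    cell_block <- block_of[ord]
    mean(sapply(seq_len(n_block), function(b) {
      cc <- coords[cell_block == b, , drop = FALSE]
      mean(dist(cc))
    }))
  }
  opt <- mean_within(a$order)
  set.seed(5)
  rnd <- replicate(100, mean_within(sample(36)))
  expect_lt(opt, min(mean(rnd), quantile(rnd, 0.05)))
})

test_that("assignments serialize to JSON and read back consistently", {
  bm <- random_beta_matrix(12, 8, seed = 51)
  a <- igtd_optimize(feature_rank_matrix(bm), pixel_rank_matrix(c(4, 3)),
                     n_iterations = 100, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_assignment(a, tmp)
  back <- read_assignment(tmp)
  expect_equal(back$order, a$order)
  expect_equal(back$probe_ids, a$probe_ids)
  expect_equal(back$grid_shape, a$grid_shape)
  expect_equal(back$final_error, a$final_error)
})

test_that("the squared error variant optimises its own objective", {
  bm <- random_beta_matrix(8, 6, seed = 87)
  fr <- feature_rank_matrix(bm)
  pr <- pixel_rank_matrix(c(2, 4))
  set.seed(88)
  ord <- sample(8)
  oracle_sq <- 0
  for (i in 1:7) for (j in (i + 1):8)
    oracle_sq <- oracle_sq + (fr$ranks[ord[i], ord[j]] - pr$ranks[i, j])^2
  expect_equal(assignment_error(fr, pr, ord, variant = "squared"), oracle_sq)
  a <- igtd_optimize(fr, pr, n_iterations = 150, seed = 4, variant = "squared")
  expect_true(all(diff(a$error_trajectory) <= 1e-9))
  expect_equal(assignment_error(fr, pr, a$order, variant = "squared"),
               a$final_error)
  # each variant is at least as good as the other's order on its own objective
  b <- igtd_optimize(fr, pr, n_iterations = 150, seed = 4)
  expect_lte(a$final_error,
             assignment_error(fr, pr, b$order, variant = "squared") + 1e-9)
})
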