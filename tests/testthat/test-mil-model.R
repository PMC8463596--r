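
tiny_cfg <- function() model_config(input_size = 16, h = 2, w = 2, C = 8, L = 4)

rand_image <- function(seed, size = 16) {
  set.seed(seed)
  array(rnorm(size * size * 3, 0, 0.5), c(size, size, 3))
}

test_that("model_config validates geometry and pooling fraction", {
  expect_s3_class(model_config(), "model_config")
  expect_error(model_config(input_size = 60, h = 4), "power of 2")
  expect_error(model_config(t = 0), "pooling fraction")
  expect_error(model_config(t = 1.2), "pooling fraction")
  expect_error(model_config(h = 4, w = 8), "square")
})

test_that("feature extraction honors the configured output shape", {
  cfg <- model_config(input_size = 64, h = 4, w = 4, C = 32, L = 16)
  w <- init_weights(cfg, seed = 1)
  img <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  f <- extract_features(img, cfg, w)
  expect_equal(dim(f), c(4, 4, 32))
  expect_identical(f, extract_features(img, cfg, w))  # deterministic
  expect_error(extract_features(array(0, c(32, 32, 3)), cfg, w),
               "expected 64 x 64 x 3")
  # constant input gives a spatially constant map (zero-padding aside, an
  # all-zero image activates only biases, which are constant per channel)
  f0 <- extract_features(array(0, c(64, 64, 3)), cfg, w)
  expect_true(all(apply(f0, 3, function(ch) diff(range(ch))) < 1e-12))
})

test_that("saliency head is a sigmoid 1x1 convolution", {
  cfg <- tiny_cfg()
  w <- init_weights(cfg, seed = 2)
  f <- extract_features(rand_image(1), cfg, w)
  s <- compute_saliency(f, w$head)
  expect_s3_class(s, "saliency_pair")
  expect_true(all(s$benign > 0 & s$benign < 1))
  expect_true(all(s$malignant > 0 & s$malignant < 1))
  # zero features and zero head give exactly 0.5 everywhere
  zero_head <- list(W = matrix(0, cfg$C, 2), b = c(0, 0))
  s0 <- compute_saliency(array(0, dim(f)), zero_head)
  expect_true(all(s0$benign == 0.5) && all(s0$malignant == 0.5))
  # monotone in the pre-activation: raising one head weight with positive
  # feature raises the matching map cell
  fpos <- array(abs(rnorm(prod(dim(f)))) + 0.1, dim(f))
  w2 <- w$head
  w2$W[1, 2] <- w2$W[1, 2] + 1
  expect_true(all(compute_saliency(fpos, w2)$malignant >
                  compute_saliency(fpos, w$head)$malignant))
  expect_error(compute_saliency(f * NA, w$head), "non-finite")
})

test_that("global max pooling matches the exhaustive loop oracle", {
  set.seed(3)
  f <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  v <- global_max_pool(f)
  ref <- numeric(6)
  for (c in 1:6) {
    best <- -Inf
    for (i in 1:4) for (j in 1:4) best <- max(best, f[i, j, c])
    ref[c] <- best
  }
  expect_equal(v, ref)
  expect_equal(global_max_pool(array(2.5, c(3, 3, 4))), rep(2.5, 4))
  spike <- array(0, c(3, 3, 2)); spike[2, 3, 1] <- 7; spike[1, 1, 2] <- -1
  expect_equal(global_max_pool(spike), c(7, 0))
})

test_that("gated attention matches the direct formula and normalizes", {
  cfg <- tiny_cfg()
  w <- init_weights(cfg, seed = 4)
  set.seed(5)
  vecs <- lapply(1:3, function(i) rnorm(cfg$C))
  alpha <- gated_attention(vecs, w$attn)
  expect_equal(colSums(alpha), c(benign = 1, malignant = 1), tolerance = 1e-12)
  ref <- gated_attention_oracle(vecs, w$attn)
  expect_equal(unname(alpha), unname(ref), tolerance = 1e-12)
  # singleton and symmetric cases
  expect_equal(unname(gated_attention(vecs[1], w$attn)),
               matrix(1, 1, 2), tolerance = 1e-12)
  same <- gated_attention(vecs[c(1, 1, 1, 1)], w$attn)
  expect_equal(unname(same), matrix(0.25, 4, 2), tolerance = 1e-12)
  expect_error(gated_attention(list(), w$attn), "empty")
  expect_error(gated_attention(list(rnorm(3)), w$attn), "width")
})

test_that("top_t_pool equals the sort oracle on all small grids", {
  ts <- c(NA, 0.1, 0.25, 0.5, 1.0)  # NA replaced by 1/(h*w) per grid
  set.seed(6)
  for (side in 2:8) {
    for (rep in 1:3) {
      g <- matrix(runif(side * side), side, side)
      for (t in ts) {
        tt <- if (is.na(t)) 1 / (side * side) else t
        expect_identical(top_t_pool(g, tt), top_t_sort_oracle(g, tt))
      }
    }
  }
  expect_equal(top_t_pool(matrix(c(0.1, 0.3, 0.9, 0.5), 2, 2), 0.25), 0.9)
  g <- matrix(runif(16), 4, 4)
  expect_equal(top_t_pool(g, 1.0), mean(g))
  expect_equal(top_t_pool(matrix(0.42, 3, 3), 0.3), 0.42)
  expect_error(top_t_pool(g, 0), "pooling fraction")
  expect_error(top_t_pool(g, 1.01), "pooling fraction")
})

test_that("top_t_pool is non-increasing as the pool grows", {
  set.seed(7)
  g <- matrix(runif(64), 8, 8)
  vals <- vapply(1:64, function(n) top_t_pool(g, n / 64), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("image-level predictions pool each map independently", {
  s <- structure(list(benign = matrix(0, 3, 3),
                      malignant = matrix(runif(9), 3, 3)),
                 class = "saliency_pair")
  p <- image_level_pred(s, 0.25)
  expect_equal(p[["benign"]], 0)
  expect_equal(p[["malignant"]], top_t_sort_oracle(s$malignant, 0.25))
  s$benign <- s$malignant
  p2 <- image_level_pred(s, 0.4)
  expect_equal(p2[["benign"]], p2[["malignant"]])
})

test_that("breast_pred is the attention-weighted convex combination", {
  preds <- cbind(c(0.2, 0.8), c(0, 1))
  att <- cbind(c(0.5, 0.5), c(0.25, 0.75))
  bp <- breast_pred(preds, att)
  expect_equal(bp$y_b, 0.5)
  expect_equal(bp$y_m, 0.75)
  # constant image predictions are preserved; outputs stay inside the hull
  same <- breast_pred(cbind(rep(0.3, 4), rep(0.6, 4)),
                      cbind(rep(0.25, 4), rep(0.25, 4)))
  expect_equal(same$y_b, 0.3)
  expect_equal(same$y_m, 0.6)
  expect_error(breast_pred(preds, att[1, , drop = FALSE]), "mismatch")
  expect_error(breast_pred(preds, cbind(c(0.7, 0.5), c(0.25, 0.75))),
               "sum to 1")
})

test_that("forward pass is permutation- and duplication-invariant", {
  cfg <- tiny_cfg()
  m <- mil_model(cfg, seed = 8)
  imgs <- lapply(1:4, rand_image)
  p <- mil_forward(imgs, m)
  expect_true(p$y_b >= 0 && p$y_b <= 1 && p$y_m >= 0 && p$y_m <= 1)
  expect_equal(unname(colSums(p$attention)), c(1, 1), tolerance = 1e-6)
  set.seed(9)
  for (rep in 1:3) {
    perm <- sample(4)
    pp <- mil_forward(imgs[perm], m)
    expect_equal(pp$y_b, p$y_b, tolerance = 1e-5)
    expect_equal(pp$y_m, p$y_m, tolerance = 1e-5)
  }
  dup <- mil_forward(c(imgs, imgs), m)
  expect_equal(dup$y_b, p$y_b, tolerance = 1e-5)
  expect_equal(dup$y_m, p$y_m, tolerance = 1e-5)
  # K = 1 reduces to the image-level prediction
  one <- mil_forward(imgs[1], m)
  expect_equal(unname(one$attention[1, ]), c(1, 1), tolerance = 1e-12)
  expect_equal(one$y_m, unname(one$image_preds[1, 2]))
  expect_error(mil_forward(list(), m), "empty")
})

test_that("saliency regularizer sums absolute values over both maps", {
  z <- structure(list(benign = matrix(0, 2, 2), malignant = matrix(0, 2, 2)),
                 class = "saliency_pair")
  expect_equal(saliency_reg(z), 0)
  z$malignant[1, 2] <- 0.5
  expect_equal(saliency_reg(z), 0.5)
  set.seed(10)
  pos <- structure(list(benign = matrix(runif(4), 2, 2),
                        malignant = matrix(runif(4), 2, 2)),
                   class = "saliency_pair")
  expect_equal(saliency_reg(pos), sum(pos$benign) + sum(pos$malignant))
})

test_that("total loss is finite, nonnegative and linear in beta", {
  cfg <- tiny_cfg()
  m <- mil_model(cfg, seed = 11)
  imgs <- lapply(5:7, rand_image)
  p <- mil_forward(imgs, m)
  y <- c(y_b = 1, y_m = 0)
  l0 <- total_loss(y, p, p$saliency, beta = 0)
  l1 <- total_loss(y, p, p$saliency, beta = 1)
  expect_gte(l0, 0)
  expect_equal(l1 - l0, sum(vapply(p$saliency, saliency_reg, numeric(1))),
               tolerance = 1e-10)
  # perfect prediction at beta 0 gives (numerically) zero loss
  perfect <- structure(list(y_b = 1, y_m = 0), class = "breast_prediction")
  expect_lt(total_loss(y, perfect, list(), beta = 0), 1e-6)
  expect_error(total_loss(c(y_b = 0.5, y_m = 0), p, p$saliency, 0), "binary")
  expect_error(total_loss(y, p, p$saliency, -1), "beta")
})

test_that("analytic gradient matches central finite differences", {
  cfg <- tiny_cfg()
  m <- mil_model(cfg, seed = 12)
  set.seed(13)
  imgs <- lapply(1:2, function(i) array(rnorm(16 * 16 * 3, 0, 0.5),
                                        c(16, 16, 3)))
  y <- c(y_b = 0, y_m = 1)
  beta <- 0.02
  lg <- mil_loss_grad(imgs, y, m, beta)
  expect_equal(lg$loss, total_loss(y, mil_forward(imgs, m),
                                   mil_forward(imgs, m)$saliency, beta),
               tolerance = 1e-10)
  theta <- unlist(m$weights)
  gan <- unlist(lg$grads)
  idx <- sort(sample(length(theta), 250))
  h <- 1e-5
  loss_at <- function(tvec) {
    mm <- m
    mm$weights <- sonomil:::relist_like_(tvec, m$weights)
    mil_loss_grad(imgs, y, mm, beta)$loss
  }
  gfd <- vapply(idx, function(j) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (loss_at(tp) - loss_at(tm)) / (2 * h)
  }, numeric(1))
  rel <- sqrt(sum((gfd - gan[idx])^2)) / max(1e-8, sqrt(sum(gfd^2)))
  expect_lt(rel, 1e-4)
})
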