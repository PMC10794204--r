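# The engine is verified against finite differences: double-precision tail
# ops exactly (tight tolerance), the float32 encoder path loosely (single
# precision limits the agreement).

test_that("double-precision tail ops match central finite differences", {
  set.seed(1)
  B <- 5L
  x0 <- matrix(runif(B * 12, 0.2, 0.8), B)
  tgt <- matrix(runif(B * 12), B)
  y <- sample(0:2, B, replace = TRUE)

  loss_at <- function(x) {
    tp <- ad_tape()
    a <- ad_leaf(tp, x)
    kp <- ad_orth(tp, a)
    mse <- ad_mse(tp, kp, tgt)
    vhs <- ad_vhs(tp, kp)
    lg <- ad_softvhs_logits(tp, vhs, c(7.35, 9.1, 11.5), 2)
    ce <- ad_ce(tp, lg, y)
    ad_axpby(tp, ce, mse, 1, 0.5)
  }
  # backprop gradients
  tpg <- ad_tape()
  a <- ad_leaf(tpg, x0)
  kp <- ad_orth(tpg, a)
  mse <- ad_mse(tpg, kp, tgt)
  vhs <- ad_vhs(tpg, kp)
  lg <- ad_softvhs_logits(tpg, vhs, c(7.35, 9.1, 11.5), 2)
  ce <- ad_ce(tpg, lg, y)
  loss <- ad_axpby(tpg, ce, mse, 1, 0.5)
  ad_backward(tpg, loss)
  g <- a$grad

  h <- 1e-6
  for (idx in sample(length(x0), 20)) {
    xp <- x0; xp[idx] <- xp[idx] + h
    xm <- x0; xm[idx] <- xm[idx] - h
    fd <- (loss_at(xp)$val - loss_at(xm)$val) / (2 * h)
    expect_equal(g[idx], fd, tolerance = 1e-5)
  }
})

test_that("float32 encoder gradients agree with finite differences", {
  set.seed(2)
  model <- rvt_model(tiny_config(), seed = 3)
  B <- 2L
  S <- model$config$input_size
  X <- random_pixel_batch(B, S)
  y <- c(0L, 2L)
  tgt <- matrix(runif(B * 12), B)

  fw <- rvt_forward(model, X, B)
  ce <- ad_ce(fw$tape, fw$logits, y)
  mse <- ad_mse(fw$tape, fw$keypoints, tgt)
  loss <- ad_axpby(fw$tape, ce, mse, 1, 1)
  ad_backward(fw$tape, loss)

  loss_with <- function(nm, idx, delta) {
    m2 <- model
    m2$params[[nm]][idx] <- m2$params[[nm]][idx] + delta
    fw <- rvt_forward(m2, X, B)
    ce <- ad_ce(fw$tape, fw$logits, y)
    mse <- ad_mse(fw$tape, fw$keypoints, tgt)
    ad_axpby(fw$tape, ce, mse, 1, 1)$val
  }

  set.seed(4)
  checked <- 0L
  for (nm in c("s1.pe.W", "s1.b1.Wq", "s1.b1.abias", "s1.b1.W1", "s1.pos",
               "s2.b1.Ws", "ff.lowW", "head.Wkp", "head.Wcls",
               "s1.b1.ln1g")) {
    g <- fw$params[[nm]]$grad
    idx <- which(abs(g) == max(abs(g)))[1]   # strongest entry: best s/n
    h <- 5e-3
    fd <- (loss_with(nm, idx, h) - loss_with(nm, idx, -h)) / (2 * h)
    if (abs(fd) > 1e-4) {
      expect_equal(g[idx], fd, tolerance = 0.05,
                   info = paste("param", nm))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 6L)
})

test_that("attention softmax rows sum to one and match a hand computation", {
  set.seed(5)
  q <- f32_new(matrix(rnorm(1 * 2), 1, 2))
  kv <- matrix(rnorm(3 * 2), 3, 2)
  k <- f32_new(kv)
  v <- f32_new(kv)
  out <- f32_attention(q, k, v, 1L, 1L, 2L)
  A <- f32_get(out$attn)
  expect_equal(sum(A), 1, tolerance = 1e-6)
  # hand computation: softmax(q k' / sqrt(2)) v
  qv <- f32_get(q)
  s <- as.numeric(qv %*% t(kv)) / sqrt(2)
  w <- exp(s - max(s)); w <- w / sum(w)
  expect_equal(as.numeric(f32_get(out$val)), as.numeric(w %*% kv),
               tolerance = 1e-5)

  # batched, with spatial-reduction shapes: rows of every map sum to 1
  model <- rvt_model(tiny_config(), seed = 1)
  B <- 3L
  X <- random_pixel_batch(B, model$config$input_size)
  fw <- rvt_forward(model, X, B)
  att_nodes <- Filter(function(nd) !is.null(nd$attn),
                      fw$tape$nodes[seq_len(fw$tape$n)])
  expect_gte(length(att_nodes), 2L)
  for (nd in att_nodes) {
    A <- f32_get(nd$attn)
    Nk <- nrow(A) / (nrow(f32_get(nd$val)) / B)
    for (j in seq_len(ncol(A))) {
      rs <- rowSums(matrix(A[, j], ncol = Nk))
      expect_true(all(abs(rs - 1) < 1e-5))
    }
  }
})

test_that("spatial reduction has the contracted shapes and linearity", {
  # 8x8 grid, R=2, C=16 -> 16 tokens of (R^2 C) = 64 gathered channels
  idx <- idx_patch(8L, 2L, 1L)
  expect_equal(dim(idx), c(16L, 4L))
  x <- f32_new(matrix(rnorm(64 * 16), 64, 16))
  gath <- f32_gather_cbind(x, idx)
  expect_equal(f32_dims(gath), c(16L, 64L))
  W <- matrix(rnorm(64 * 16, 0, 0.1), 64, 16)
  proj <- f32_gemm(gath, W)
  expect_equal(f32_dims(proj), c(16L, 16L))
  # R=1 keeps the token count
  idx1 <- idx_patch(8L, 1L, 1L)
  expect_equal(nrow(idx1), 64L)
  # all-zero input gives an all-zero bias-free projection
  z <- f32_new(matrix(0, 64, 16))
  pz <- f32_gemm(f32_gather_cbind(z, idx), W)
  expect_true(all(f32_get(pz) == 0))
})

test_that("gather/scatter, pool and interp backward are adjoint-consistent", {
  # <A x, y> = <x, A' y> for the linear ops, the defining adjoint property
  set.seed(6)
  idx <- idx_conv3(4L, 2L)
  x <- matrix(rnorm(32 * 3), 32, 3)
  y <- matrix(rnorm(32 * 27), 32, 27)
  Ax <- f32_get(f32_gather_cbind(f32_new(x), idx))
  Aty <- f32_get(f32_gather_bwd(f32_new(y), idx, 32L, 3L))
  expect_equal(sum(Ax * y), sum(x * Aty), tolerance = 1e-4)

  xp <- matrix(rnorm(24 * 5), 24, 5)
  yp <- matrix(rnorm(2 * 5), 2, 5)
  Px <- f32_get(f32_mean_pool(f32_new(xp), 2L, 12L))
  Pty <- f32_get(f32_mean_pool_bwd(f32_new(yp), 2L, 12L))
  expect_equal(sum(Px * yp), sum(xp * Pty), tolerance = 1e-4)

  U <- kronecker(bilinear_matrix_1d(4, 2), bilinear_matrix_1d(4, 2))
  xi <- matrix(rnorm(2 * 4 * 3), 8, 3)
  yi <- matrix(rnorm(2 * 16 * 3), 32, 3)
  Uf <- f32_new(U)
  Ux <- f32_get(f32_interp(f32_new(xi), Uf, 2L))
  Uty <- f32_get(f32_interp_bwd(f32_new(yi), Uf, 2L))
  expect_equal(sum(Ux * yi), sum(xi * Uty), tolerance = 1e-4)
})

test_that("orthogonal layer node matches the geometry oracle and its slope gradient", {
  set.seed(7)
  # oracle equivalence on random 12-vectors
  for (i in 1:200) {
    v <- runif(12)
    tp <- ad_tape()
    nd <- ad_orth(tp, ad_leaf(tp, matrix(v, 1)))
    expect_equal(as.numeric(nd$val),
                 unname(kp_flatten(orthogonalize(kp_unflatten(v, validate = FALSE)))),
                 tolerance = 1e-12)
  }
  # d(y4_hat)/d(x4) equals the slope s, by finite differences
  v <- c(0.1, 0.2, 0.5, 0.9, 0.3, 0.6, 0.7, 0.4, 0.1, 0.9, 0.9, 0.9)
  s_true <- -(v[1] - v[3]) / (v[2] - v[4])
  h <- 1e-7
  vp <- v; vp[7] <- vp[7] + h
  vm <- v; vm[7] <- vm[7] - h
  o <- function(w) {
    tp <- ad_tape()
    as.numeric(ad_orth(tp, ad_leaf(tp, matrix(w, 1)))$val)[8]
  }
  expect_equal((o(vp) - o(vm)) / (2 * h), s_true, tolerance = 1e-6)
  # and backprop agrees
  tp <- ad_tape()
  a <- ad_leaf(tp, matrix(v, 1))
  nd <- ad_orth(tp, a)
  ms <- ad_mse(tp, nd, matrix(0, 1, 12))
  ad_backward(tp, ms)
  loss_of <- function(w) {
    tp <- ad_tape()
    nd <- ad_orth(tp, ad_leaf(tp, matrix(w, 1)))
    mean((nd$val - 0)^2)
  }
  fd <- (loss_of(vp) - loss_of(vm)) / (2 * h)
  expect_equal(a$grad[7], fd, tolerance = 1e-4)
})
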