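# Minimal tape-based reverse-mode automatic differentiation over base-R
# matrices. All activations are dense matrices; a "tape" records nodes in
# creation order and backward() replays it in reverse. Heavy lifting is done
# by BLAS through %*% / crossprod / tcrossprod, so the engine is fast enough
# for the desk-scale transformer while staying dependency-free.
#
# Conventions:
#   * token sequences are stacked image-major: a batch of B images with N
#     tokens of C channels is a (B*N) x C matrix, image b occupying rows
#     ((b-1)N+1):(bN), tokens in row-major grid order ((y-1)*W + x);
#   * every op takes the tape first and returns a new node;
#   * node$grad accumulates d(loss)/d(node$val) during backward().

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tp, val, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes))
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd$id <- tp$n
  nd
}

ad_leaf <- function(tp, val) ad_node(tp, val)

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# run reverse-mode accumulation from `root` (grad seeded with 1)
ad_backward <- function(tp, root) {
  root$grad <- if (length(root$val) == 1L) 1 else {
    g <- root$val; g[] <- 1; g
  }
  for (i in seq(root$id, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd) && !is.null(nd$grad) && !is.null(nd$backward))
      nd$backward(nd)
  }
  invisible(NULL)
}

## ---- elementary ops --------------------------------------------------------

ad_mm <- function(tp, a, b) {
  ad_node(tp, a$val %*% b$val, list(a, b), function(nd) {
    g <- nd$grad
    ad_accum(a, tcrossprod(g, b$val))
    ad_accum(b, crossprod(a$val, g))
  })
}

ad_add <- function(tp, a, b) {
  ad_node(tp, a$val + b$val, list(a, b), function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, nd$grad)
  })
}

# add a length-C bias row-vector (param stored as 1 x C matrix) to each row
ad_bias <- function(tp, a, b) {
  bv <- as.numeric(b$val)
  ad_node(tp, a$val + rep(bv, each = nrow(a$val)), list(a, b), function(nd) {
    g <- nd$grad
    ad_accum(a, g)
    ad_accum(b, matrix(colSums(g), 1L))
  })
}

# add an N x C positional table to a (B*N) x C stacked sequence
ad_posadd <- function(tp, a, p, B) {
  N <- nrow(p$val)
  grp <- rep(seq_len(N), times = B)
  ad_node(tp, a$val + p$val[grp, , drop = FALSE], list(a, p), function(nd) {
    g <- nd$grad
    ad_accum(a, g)
    ad_accum(p, rowsum(g, grp, reorder = TRUE))
  })
}

ad_scale <- function(tp, a, k) {
  ad_node(tp, a$val * k, list(a), function(nd) ad_accum(a, nd$grad * k))
}

ad_gelu <- function(tp, a) {
  x <- a$val
  ad_node(tp, x * stats::pnorm(x), list(a), function(nd) {
    ad_accum(a, nd$grad * (stats::pnorm(x) + x * stats::dnorm(x)))
  })
}

ad_sigmoid <- function(tp, a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(tp, s, list(a), function(nd) ad_accum(a, nd$grad * s * (1 - s)))
}

# row-wise layer normalization with learned gain/bias (1 x C params)
ad_layernorm <- function(tp, a, gain, bias, eps = 1e-5) {
  x <- a$val
  C <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  gv <- as.numeric(gain$val)
  bv <- as.numeric(bias$val)
  n <- nrow(x)
  val <- xhat * rep(gv, each = n) + rep(bv, each = n)
  ad_node(tp, val, list(a, gain, bias), function(nd) {
    g <- nd$grad
    ad_accum(gain, matrix(colSums(g * xhat), 1L))
    ad_accum(bias, matrix(colSums(g), 1L))
    dxhat <- g * rep(gv, each = n)
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    ad_accum(a, dx)
  })
}

## ---- structural ops --------------------------------------------------------

# Gather-and-concatenate: for each of K kernel offsets, pick rows of `a` by
# idx[, k] (NA = zero row, used for conv zero-padding) and cbind the K blocks.
# This single primitive implements im2col for convolutions, non-overlapping
# patch embedding, and the R x R neighborhood grouping of spatial reduction.
# Within a fixed offset k the picked rows are distinct, so backward may
# scatter-add block-wise without index collisions.
ad_gather_cbind <- function(tp, a, idx) {
  C <- ncol(a$val)
  K <- ncol(idx)
  Nout <- nrow(idx)
  val <- matrix(0, Nout, K * C)
  for (k in seq_len(K)) {
    rows <- idx[, k]
    ok <- !is.na(rows)
    val[ok, ((k - 1L) * C + 1L):(k * C)] <- a$val[rows[ok], , drop = FALSE]
  }
  ad_node(tp, val, list(a), function(nd) {
    g <- nd$grad
    ga <- matrix(0, nrow(a$val), C)
    for (k in seq_len(K)) {
      rows <- idx[, k]
      ok <- !is.na(rows)
      r <- rows[ok]
      ga[r, ] <- ga[r, , drop = FALSE] +
        g[ok, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    }
    ad_accum(a, ga)
  })
}

ad_cbind2 <- function(tp, a, b) {
  Ca <- ncol(a$val)
  ad_node(tp, cbind(a$val, b$val), list(a, b), function(nd) {
    g <- nd$grad
    ad_accum(a, g[, seq_len(Ca), drop = FALSE])
    ad_accum(b, g[, -seq_len(Ca), drop = FALSE])
  })
}

# global average pool over tokens: (B*N) x C -> B x C
ad_mean_pool <- function(tp, a, B, N) {
  grp <- rep(seq_len(B), each = N)
  ad_node(tp, rowsum(a$val, grp, reorder = TRUE) / N, list(a), function(nd) {
    ad_accum(a, nd$grad[grp, , drop = FALSE] / N)
  })
}

# apply a fixed (Nout x Nin) interpolation matrix per image (bilinear upsample)
ad_interp <- function(tp, a, U, B) {
  Nin <- ncol(U)
  Nout <- nrow(U)
  C <- ncol(a$val)
  val <- matrix(0, B * Nout, C)
  for (b in seq_len(B)) {
    val[((b - 1L) * Nout + 1L):(b * Nout), ] <-
      U %*% a$val[((b - 1L) * Nin + 1L):(b * Nin), , drop = FALSE]
  }
  ad_node(tp, val, list(a), function(nd) {
    g <- nd$grad
    ga <- matrix(0, B * Nin, C)
    for (b in seq_len(B)) {
      ga[((b - 1L) * Nin + 1L):(b * Nin), ] <-
        crossprod(U, g[((b - 1L) * Nout + 1L):(b * Nout), , drop = FALSE])
    }
    ad_accum(a, ga)
  })
}

## ---- attention -------------------------------------------------------------

row_softmax <- function(s) {
  s <- exp(s - apply(s, 1L, max))
  s / rowSums(s)
}

# Multi-head scaled-dot-product attention with optional learned relative bias.
# q: (B*Nq) x (H*dh); k, v: (B*Nk) x (H*dh). bias (optional): n_off x H param
# indexed by bias_idx, an Nq x Nk integer matrix of offset codes shared by
# all images. Per head: SoftMax(Q K' / sqrt(dh) + B) V.
ad_attention <- function(tp, q, k, v, B, H, dh, bias = NULL, bias_idx = NULL) {
  Nq <- nrow(q$val) / B
  Nk <- nrow(k$val) / B
  scale <- 1 / sqrt(dh)
  val <- matrix(0, B * Nq, H * dh)
  A <- vector("list", B * H)
  bmats <- NULL
  if (!is.null(bias)) {
    bmats <- lapply(seq_len(H), function(h)
      matrix(bias$val[bias_idx, h], Nq, Nk))
  }
  for (b in seq_len(B)) {
    rq <- ((b - 1L) * Nq + 1L):(b * Nq)
    rk <- ((b - 1L) * Nk + 1L):(b * Nk)
    for (h in seq_len(H)) {
      ch <- ((h - 1L) * dh + 1L):(h * dh)
      Qi <- q$val[rq, ch, drop = FALSE]
      Ki <- k$val[rk, ch, drop = FALSE]
      S <- tcrossprod(Qi, Ki) * scale
      if (!is.null(bmats)) S <- S + bmats[[h]]
      Ai <- row_softmax(S)
      A[[(b - 1L) * H + h]] <- Ai
      val[rq, ch] <- Ai %*% v$val[rk, ch, drop = FALSE]
    }
  }
  parents <- c(list(q, k, v), if (!is.null(bias)) list(bias))
  nd <- ad_node(tp, val, parents, function(nd) {
    g <- nd$grad
    gq <- matrix(0, nrow(q$val), ncol(q$val))
    gk <- matrix(0, nrow(k$val), ncol(k$val))
    gv <- matrix(0, nrow(v$val), ncol(v$val))
    gb <- if (!is.null(bias)) matrix(0, nrow(bias$val), H)
    idxv <- if (!is.null(bias)) as.vector(bias_idx)
    for (b in seq_len(B)) {
      rq <- ((b - 1L) * Nq + 1L):(b * Nq)
      rk <- ((b - 1L) * Nk + 1L):(b * Nk)
      for (h in seq_len(H)) {
        ch <- ((h - 1L) * dh + 1L):(h * dh)
        Ai <- A[[(b - 1L) * H + h]]
        gO <- g[rq, ch, drop = FALSE]
        Vi <- v$val[rk, ch, drop = FALSE]
        gv[rk, ch] <- gv[rk, ch, drop = FALSE] + crossprod(Ai, gO)
        dA <- tcrossprod(gO, Vi)
        dS <- Ai * (dA - rowSums(Ai * dA))
        gq[rq, ch] <- gq[rq, ch, drop = FALSE] +
          (dS %*% k$val[rk, ch, drop = FALSE]) * scale
        gk[rk, ch] <- gk[rk, ch, drop = FALSE] +
          crossprod(dS, q$val[rq, ch, drop = FALSE]) * scale
        if (!is.null(bias))
          gb[, h] <- gb[, h] +
            as.numeric(rowsum(as.vector(dS), idxv, reorder = TRUE))
      }
    }
    ad_accum(q, gq)
    ad_accum(k, gk)
    ad_accum(v, gv)
    if (!is.null(bias)) ad_accum(bias, gb)
  })
  attr(nd, "attn") <- NULL
  nd$attn <- A       # kept for inspection/tests (softmax rows sum to one)
  nd
}

## ---- the orthogonal layer --------------------------------------------------

# Differentiable perpendicularity projection on a B x 12 batch of flattened
# keypoints (Ax,Ay,Bx,By,Cx,Cy,Dx,Dy,Ex,Ey,Fx,Fy). Rows with |y1 - y2| >= eps
# replace Dy by s*(x4 - x3) + y3 with s = -(x1 - x2)/(y1 - y2); degenerate
# rows (long axis horizontal) replace Dx by Cx instead. Gradients flow to all
# contributing coordinates.
ad_orth <- function(tp, a, eps = 1e-6) {
  x <- a$val
  x1 <- x[, 1L]; y1 <- x[, 2L]; x2 <- x[, 3L]; y2 <- x[, 4L]
  x3 <- x[, 5L]; y3 <- x[, 6L]; x4 <- x[, 7L]
  dy <- y1 - y2
  m <- abs(dy) >= eps
  s <- ifelse(m, -(x1 - x2) / ifelse(m, dy, 1), 0)
  val <- x
  val[m, 8L] <- s[m] * (x4[m] - x3[m]) + y3[m]
  val[!m, 7L] <- x3[!m]
  ad_node(tp, val, list(a), function(nd) {
    g <- nd$grad
    ga <- g
    if (any(m)) {
      g8 <- g[m, 8L]
      sm <- s[m]; dym <- dy[m]
      dx12 <- (x1 - x2)[m]
      ds <- g8 * (x4[m] - x3[m])
      ga[m, 8L] <- 0                             # original y4 discarded
      ga[m, 7L] <- ga[m, 7L] + g8 * sm           # x4
      ga[m, 5L] <- ga[m, 5L] - g8 * sm           # x3
      ga[m, 6L] <- ga[m, 6L] + g8                # y3
      ga[m, 1L] <- ga[m, 1L] - ds / dym          # x1
      ga[m, 3L] <- ga[m, 3L] + ds / dym          # x2
      ga[m, 2L] <- ga[m, 2L] + ds * dx12 / dym^2 # y1
      ga[m, 4L] <- ga[m, 4L] - ds * dx12 / dym^2 # y2
    }
    if (any(!m)) {
      g7 <- g[!m, 7L]
      ga[!m, 7L] <- 0                            # original x4 discarded
      ga[!m, 5L] <- ga[!m, 5L] + g7              # x3
    }
    ad_accum(a, ga)
  })
}

## ---- losses ----------------------------------------------------------------

# mean cross-entropy of integer classes y (0-based) under row logits,
# in log-sum-exp form so forward value and backward gradient agree exactly
# for arbitrarily extreme logits
ad_ce <- function(tp, logits, y) {
  L <- logits$val
  n <- nrow(L)
  mx <- apply(L, 1L, max)
  lse <- mx + log(rowSums(exp(L - mx)))
  iy <- cbind(seq_len(n), y + 1L)
  val <- mean(lse - L[iy])
  P <- exp(L - lse)
  ad_node(tp, val, list(logits), function(nd) {
    Y <- matrix(0, n, ncol(L))
    Y[iy] <- 1
    ad_accum(logits, nd$grad * (P - Y) / n)
  })
}

# mean squared error over all entries
ad_mse <- function(tp, pred, target) {
  d <- pred$val - target
  val <- mean(d * d)
  ad_node(tp, val, list(pred), function(nd) {
    ad_accum(pred, nd$grad * 2 * d / length(d))
  })
}

# weighted sum of two scalar nodes: wa*a + wb*b
ad_axpby <- function(tp, a, b, wa, wb) {
  ad_node(tp, wa * a$val + wb * b$val, list(a, b), function(nd) {
    ad_accum(a, nd$grad * wa)
    ad_accum(b, nd$grad * wb)
  })
}

## ---- differentiable VHS (soft class logits from geometry) ------------------

# per-row VHS from a B x 12 keypoint matrix (any consistent units; the score
# is scale-free). Returns a B x 1 node.
ad_vhs <- function(tp, a, factor = 6, eps = 1e-9) {
  x <- a$val
  seglen <- function(c1, c2) {
    dx <- x[, c1[1]] - x[, c2[1]]
    dy <- x[, c1[2]] - x[, c2[2]]
    sqrt(dx * dx + dy * dy)
  }
  ab <- seglen(c(1L, 2L), c(3L, 4L))
  cd <- seglen(c(5L, 6L), c(7L, 8L))
  ef <- pmax(seglen(c(9L, 10L), c(11L, 12L)), eps)
  val <- matrix(factor * (ab + cd) / ef, ncol = 1L)
  ad_node(tp, val, list(a), function(nd) {
    g <- as.numeric(nd$grad)
    ga <- matrix(0, nrow(x), 12L)
    addseg <- function(c1, c2, len, w) {
      len <- pmax(len, eps)
      ux <- (x[, c1[1]] - x[, c2[1]]) / len
      uy <- (x[, c1[2]] - x[, c2[2]]) / len
      ga[, c1[1]] <<- ga[, c1[1]] + w * ux
      ga[, c1[2]] <<- ga[, c1[2]] + w * uy
      ga[, c2[1]] <<- ga[, c2[1]] - w * ux
      ga[, c2[2]] <<- ga[, c2[2]] - w * uy
    }
    addseg(c(1L, 2L), c(3L, 4L), ab, g * factor / ef)
    addseg(c(5L, 6L), c(7L, 8L), cd, g * factor / ef)
    addseg(c(9L, 10L), c(11L, 12L), ef, -g * factor * (ab + cd) / ef^2)
    ad_accum(a, ga)
  })
}

# class logits derived from geometry alone: negative squared distance of the
# predicted VHS to each class-interval midpoint over a temperature
ad_softvhs_logits <- function(tp, vhs, midpoints, temperature = 1) {
  v <- as.numeric(vhs$val)
  val <- -outer(v, midpoints, function(a, b) (a - b)^2) / temperature
  ad_node(tp, val, list(vhs), function(nd) {
    g <- nd$grad
    dv <- rowSums(g * (-2 * outer(v, midpoints, "-") / temperature))
    ad_accum(vhs, matrix(dv, ncol = 1L))
  })
}
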