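# Float32 node layer over the compiled kernels in src/ops.cpp.
#
# These ops live on the same tape as the double-precision ops of
# autodiff.R. Activation nodes carry an external pointer to an arma::fmat
# (kind "f"); parameter leaves stay double R matrices (kind "d", master
# weights), are converted at the kernel boundary, and receive
# double-precision gradients. adf_to_double() bridges a float activation
# into the double-precision tail of the graph (orthogonal layer, VHS,
# losses), which keeps the geometric contracts at 1e-9 while the heavy
# encoder runs single-precision BLAS.

adf_leaf <- function(tp, m) {
  nd <- ad_node(tp, f32_new_arena(m))
  nd$kind <- "f"
  nd
}

ad_param <- function(tp, m) {
  nd <- ad_node(tp, m)
  nd$kind <- "d"
  nd
}

# Accumulate a float gradient. `share = TRUE` means g is uniquely owned by
# this consumer (fresh backward output, or the only alias of a pass-through
# gradient) and may be stored without copying; pass share = FALSE for any
# additional alias of the same tensor so in-place accumulation cannot
# corrupt a sibling.
adf_accum <- function(nd, g, share = TRUE) {
  if (is.null(nd$grad)) {
    nd$grad <- if (share) g else f32_scale(g, 1)
  } else {
    f32_add_inplace(nd$grad, g)
  }
  invisible(NULL)
}

# accumulate a double (parameter) gradient
adp_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

adf_gemm <- function(tp, a, w) {
  nd <- ad_node(tp, f32_gemm(a$val, w$val), list(a, w), function(nd) {
    g <- nd$grad
    adf_accum(a, f32_gemm(g, w$val, FALSE, TRUE))
    adp_accum(w, f32_gemm_d(a$val, g, TRUE, FALSE))
  })
  nd$kind <- "f"
  nd
}

# fused fully connected layer x %*% W + b (one node, one output tensor)
adf_linear <- function(tp, a, w, b) {
  nd <- ad_node(tp, f32_linear(a$val, w$val, b$val), list(a, w, b),
                function(nd) {
    g <- nd$grad
    adf_accum(a, f32_gemm(g, w$val, FALSE, TRUE))
    adp_accum(w, f32_gemm_d(a$val, g, TRUE, FALSE))
    adp_accum(b, f32_colsums(g))
  })
  nd$kind <- "f"
  nd
}

adf_bias <- function(tp, a, b) {
  nd <- ad_node(tp, f32_bias_add(a$val, b$val), list(a, b), function(nd) {
    g <- nd$grad
    adf_accum(a, g)
    adp_accum(b, f32_colsums(g))
  })
  nd$kind <- "f"
  nd
}

adf_add <- function(tp, a, b) {
  nd <- ad_node(tp, f32_add(a$val, b$val), list(a, b), function(nd) {
    adf_accum(a, nd$grad)
    adf_accum(b, nd$grad, share = FALSE)
  })
  nd$kind <- "f"
  nd
}

adf_posadd <- function(tp, a, p, B) {
  N <- nrow(p$val)
  nd <- ad_node(tp, f32_posadd(a$val, p$val, B), list(a, p), function(nd) {
    g <- nd$grad
    adf_accum(a, g)
    adp_accum(p, f32_posadd_bwd(g, N, B))
  })
  nd$kind <- "f"
  nd
}

adf_gelu <- function(tp, a) {
  nd <- ad_node(tp, f32_gelu(a$val), list(a), function(nd) {
    adf_accum(a, f32_gelu_bwd(a$val, nd$grad))
  })
  nd$kind <- "f"
  nd
}

adf_layernorm <- function(tp, a, gain, bias, eps = 1e-5) {
  fw <- f32_layernorm(a$val, gain$val, bias$val, eps)
  nd <- ad_node(tp, fw$val, list(a, gain, bias), function(nd) {
    bw <- f32_layernorm_bwd(nd$grad, fw$xhat, fw$inv, gain$val)
    adf_accum(a, bw$dx)
    adp_accum(gain, bw$dgain)
    adp_accum(bias, bw$dbias)
  })
  nd$kind <- "f"
  nd
}

adf_gather_cbind <- function(tp, a, idx) {
  nin <- f32_dims(a$val)[1]
  C <- f32_dims(a$val)[2]
  nd <- ad_node(tp, f32_gather_cbind(a$val, idx), list(a), function(nd) {
    adf_accum(a, f32_gather_bwd(nd$grad, idx, nin, C))
  })
  nd$kind <- "f"
  nd
}

adf_cbind2 <- function(tp, a, b) {
  Ca <- f32_dims(a$val)[2]
  Cb <- f32_dims(b$val)[2]
  nd <- ad_node(tp, f32_cbind2(a$val, b$val), list(a, b), function(nd) {
    adf_accum(a, f32_cols(nd$grad, 1L, Ca))
    adf_accum(b, f32_cols(nd$grad, Ca + 1L, Ca + Cb))
  })
  nd$kind <- "f"
  nd
}

adf_mean_pool <- function(tp, a, B, N) {
  nd <- ad_node(tp, f32_mean_pool(a$val, B, N), list(a), function(nd) {
    adf_accum(a, f32_mean_pool_bwd(nd$grad, B, N))
  })
  nd$kind <- "f"
  nd
}

# U may be a double matrix or a persistent f32 pointer (cached by the model)
adf_interp <- function(tp, a, U, B) {
  nd <- ad_node(tp, f32_interp(a$val, U, B), list(a), function(nd) {
    adf_accum(a, f32_interp_bwd(nd$grad, U, B))
  })
  nd$kind <- "f"
  nd
}

adf_attention <- function(tp, q, k, v, B, H, dh, bias = NULL,
                          bias_idx = NULL) {
  fw <- if (is.null(bias)) {
    f32_attention(q$val, k$val, v$val, B, H, dh)
  } else {
    f32_attention(q$val, k$val, v$val, B, H, dh, bias$val, bias_idx)
  }
  parents <- c(list(q, k, v), if (!is.null(bias)) list(bias))
  nd <- ad_node(tp, fw$val, parents, function(nd) {
    bw <- if (is.null(bias)) {
      f32_attention_bwd(nd$grad, q$val, k$val, v$val, fw$attn, B, H, dh)
    } else {
      f32_attention_bwd(nd$grad, q$val, k$val, v$val, fw$attn, B, H, dh,
                        bias_idx, nrow(bias$val))
    }
    adf_accum(q, bw$dq)
    adf_accum(k, bw$dk)
    adf_accum(v, bw$dv)
    if (!is.null(bias)) adp_accum(bias, bw$dbias)
  })
  nd$kind <- "f"
  nd$attn <- fw$attn
  nd
}

# bridge: float activation -> double matrix node
adf_to_double <- function(tp, a) {
  nd <- ad_node(tp, f32_get(a$val), list(a), function(nd) {
    adf_accum(a, f32_new_arena(nd$grad))
  })
  nd$kind <- "d"
  nd
}
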