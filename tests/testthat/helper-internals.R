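# White-box tests exercise the internal autodiff engine and kernel wrappers
# directly; bind them here so the suite also runs in harnesses that do not
# parent the test environment on the package namespace.
for (.nm in c(
  "ad_tape", "ad_leaf", "ad_node", "ad_backward", "ad_mm", "ad_add",
  "ad_bias", "ad_orth", "ad_mse", "ad_ce", "ad_axpby", "ad_vhs",
  "ad_softvhs_logits", "ad_gelu", "ad_sigmoid", "row_softmax",
  "rvt_forward", "rvt_grids", "idx_patch", "idx_conv3",
  "bilinear_matrix_1d", "rel_bias_index", "kp_axes_dot",
  "kp_axes_abs_cos",
  "f32_new", "f32_new_arena", "f32_get", "f32_dims", "f32_gemm",
  "f32_attention", "f32_attention_bwd", "f32_gather_cbind",
  "f32_gather_bwd", "f32_mean_pool", "f32_mean_pool_bwd", "f32_interp",
  "f32_interp_bwd", "f32_linear", "f32_layernorm", "f32_layernorm_bwd",
  "arena_reset")) {
  assign(.nm, utils::getFromNamespace(.nm, "vhsnet"))
}
rm(.nm)
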