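# Tiny model/generator settings used across tests: small enough that a
# forward+backward pass takes milliseconds.
tiny_config <- function(...) {
  rvt_config("desk", input_size = 32L, patch_sizes = c(4L, 2L),
             dims = c(8L, 16L), heads = c(1L, 2L), sr_ratios = c(2L, 2L),
             depths = c(1L, 1L), fusion_channels = 8L, head_hidden = 16L,
             ...)
}

tiny_generator <- function(...) generator_config(image_size = 48L, ...)

# random image batch as the stacked pixel matrix the encoder consumes
random_pixel_batch <- function(B, S) {
  matrix(stats::runif(B * S * S * 3), ncol = 3L)
}

# numeric loss as a function of one parameter entry, for finite differences
fd_loss <- function(model, X, B, y, tgt, gamma = 0.01) {
  function() {
    fw <- rvt_forward(model, X, B)
    ce <- ad_ce(fw$tape, fw$logits, y)
    mse <- ad_mse(fw$tape, fw$keypoints, tgt)
    ad_axpby(fw$tape, ce, mse, 1, gamma)
  }
}
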