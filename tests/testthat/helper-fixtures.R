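# Shared fixtures: all tiny, generated in code.

tiny_net_config <- function(n_bands = 12, n_classes = 3, model_dim = 2,
                            state_dim = 3) {
  mbnet_config(n_bands = n_bands, n_classes = n_classes,
               model_dim = model_dim, state_dim = state_dim)
}

tiny_dataset <- function(n_per_class = 12, n_bands = 16, n_classes = 3,
                         noise_sd = 0.02, seed = 7) {
  cfg <- synthetic_config(
    n_bands = n_bands, n_classes = n_classes,
    class_labels = paste0(seq(50, by = 50, length.out = n_classes), " °C"),
    samples_per_class = n_per_class,
    dip_depth_by_class = seq(0.3, 0.05, length.out = n_classes),
    nir_amp_by_class = seq(0.02, 0.12, length.out = n_classes),
    noise_sd = noise_sd, illum_scale_sd = 0.05, seed = seed)
  generate_spectra(cfg)
}

# training loss of a network on a fixed batch (used by gradient checks)
net_loss <- function(params, Yin, y, variant = "bidirectional") {
  f <- specmamba:::.mbnet_forward_full(Yin, params, variant, TRUE, FALSE)
  specmamba:::.cross_entropy(specmamba:::.softmax(f$logits), y)
}
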