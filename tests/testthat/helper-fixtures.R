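# Small fixtures shared across test files. Everything is generated in code;
# dimensions are kept tiny so unit tests stay fast. The desk-scale
# experiment fixtures used by the acceptance properties live in
# helper-experiments.R.

tiny_spec <- function(seed = 1, shift = 0, n_bands = 20L, ...) {
  synthetic_spec(n_classes = 4L, n_bands = n_bands, shift_magnitude = shift,
                 spatial_shape = c(8L, 10L), seed = seed, ...)
}

tiny_data <- function(seed = 1, shift = 0, n_per_class = 12L, ...) {
  generate_dataset(tiny_spec(seed = seed, shift = shift, ...), n_per_class)
}

tiny_model <- function(data, seed = 1, ...) {
  man <- data$manifest
  build_model(n_classes = length(attr(man, "class_names")),
              n_bands = attr(man, "band_count"),
              input_shape = dim(data$cubes[[1]]$values)[1:2],
              feature_dim = 8L, conv_channels = 4L, n_blocks = 2L,
              branch_hidden = 12L, head_hidden = 6L, seed = seed, ...)
}

tiny_config <- function(epochs = 5L, seed = 1, ...) {
  train_config(batch_size = 32L, epochs = epochs, seed = seed,
               log_target_accuracy = FALSE, ...)
}

# random cube with an off-centre rectangular support, handy for padding tests
rect_cube <- function(rows = 5L, cols = 7L, bands = 3L, id = "seed",
                      seed = 99L) {
  v <- array(0, c(rows, cols, bands))
  set.seed(seed)
  v[] <- runif(length(v), 0.1, 0.9)
  seed_cube(v, variety = 0L, domain = "source", sample_id = id)
}
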