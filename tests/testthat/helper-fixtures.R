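# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

tiny_system <- function() {
  fixture("sys32", function()
    build_shearlet_system(shearlet_config(32, n_scales = 1,
                                          shear_counts = 5)))
}

small_system64 <- function() {
  fixture("sys64", function()
    build_shearlet_system(shearlet_config(64, n_scales = 2)))
}

# circular shift of a matrix by (dr, dc)
circshift <- function(m, dr, dc) {
  n <- nrow(m)
  m[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(ncol(m)) - 1 - dc) %%
                                         ncol(m)) + 1]
}

# brute-force circular convolution of image with kernel h (both M x M):
# out(m) = sum_x I(x) h(m - x), indices circular, 1-based
brute_circular_conv <- function(image, h) {
  M <- nrow(image)
  out <- matrix(0, M, M)
  for (m1 in seq_len(M)) {
    for (m2 in seq_len(M)) {
      hs <- h[((m1 - seq_len(M)) %% M) + 1, ((m2 - seq_len(M)) %% M) + 1]
      out[m1, m2] <- sum(image * hs)
    }
  }
  out
}

# small deterministic phantom set for classifier tests
tiny_phantoms <- function(n = 12, n_orientations = 4L) {
  cfg <- phantom_config(image_size = 64, n_small = c(2, 4),
                        n_orientations = n_orientations)
  lapply(seq_len(n), function(i) sample_head_phantom(cfg, seed = 5000 + i))
}

# wavefront set from a triple matrix for concise test construction
wf_from <- function(triples, dims = c(32, 32), n = 8) {
  wavefront_set(data.frame(row = triples[, 1], col = triples[, 2],
                           bin = triples[, 3]), dims, n)
}

# an ensemble whose binary models output a constant probability (~0 or ~1);
# exercises the prediction plumbing without training
constant_ensemble <- function(system, n_orientations = 4L, edge_on = TRUE,
                              orientations_on = TRUE) {
  M <- system$config$image_size
  spec <- cnn_spec(c(21, 21, system$L), channels = c(2L, 2L),
                   dense_width = 4L)
  make <- function(on) {
    params <- shearwf:::cnn_init(spec, seed = 1)
    params$dense2$W[] <- 0
    params$dense2$b[] <- if (on) 20 else -20
    structure(list(params = params, spec = spec,
                   config = train_config(epochs = 0L), history = NULL),
              class = "cnn_model")
  }
  structure(
    list(orientation_models = lapply(seq_len(n_orientations),
                                     function(i) make(orientations_on)),
         edge_model = make(edge_on),
         tau_edge = 0.5, tau_orientation = rep(0.5, n_orientations),
         n_orientations = n_orientations, image_size = M,
         system_config = system$config,
         train_config = train_config(epochs = 0L),
         channels = c(2L, 2L), dense_width = 4L),
    class = "wf_ensemble")
}
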