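# Shared fixture builders; everything is generated in code under fixed seeds.

random_cube <- function(d = 5L, h = 4L, w = 3L, seed = 1L, wl = NULL) {
  set.seed(seed)
  if (is.null(wl)) wl <- seq(400, 1000, length.out = d)
  hypercube(array(runif(d * h * w), dim = c(d, h, w)), wl)
}

# tiny, strongly separable labeled dataset for optimization tests
separable_spec <- function(n_classes = 2L, seeds_per_class = 10L, seed = 1L) {
  # windows wide enough to span several bands at 16-band resolution
  synthetic_spec(n_classes = n_classes, seeds_per_class = seeds_per_class,
                 bands = 16L, seed_patch = 16L, amplitude = 0.3,
                 windows = list(c(525, 100), c(650, 150)),
                 intensity_jitter_sd = 0.05, noise_sd = 0.02, rng_seed = seed)
}

# labels-only samples for split tests
label_samples <- function(labels) {
  lapply(labels, function(l) list(cube = NULL, label = l))
}

# intersection-over-union of two binary masks
mask_iou <- function(a, b) {
  sum(a & b) / sum(a | b)
}
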