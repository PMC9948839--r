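# Small reproducible fixtures shared across the suite.

small_phantom <- function(shape = 24, seed = 1, noise = 0.1,
                          means = c(0, 1, 1)) {
  make_phantom(phantom_spec(shape = rep(shape, 3), tissue_means = means,
                            noise_sigma = noise, rng_seed = seed))
}

# phantom with the protrusion merged into label 1 (single binary structure)
binary_phantom <- function(shape = 24, seed = 1, noise = 0.1) {
  v <- small_phantom(shape, seed, noise)
  v$labels[v$labels == 2L] <- 1L
  v
}

# perfect segmenter for a noiseless binary phantom: thresholding the class
# intensity reproduces the ground-truth labels exactly at the identity and
# up to boundary interpolation after rotation
oracle_segmenter <- function() {
  segmenter(function(image, scheme = NULL) {
    out <- array(0L, dim(image)[1:3])
    out[image > 0.5] <- 1L
    out
  }, id = "oracle")
}

background_segmenter <- function() {
  segmenter(function(image, scheme = NULL) array(0L, dim(image)[1:3]),
            id = "constant-background")
}

random_mask <- function(dims, p = 0.3) {
  array(stats::runif(prod(dims)) < p, dims)
}
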