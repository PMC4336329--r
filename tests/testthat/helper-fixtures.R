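# Shared fixtures built in code.

# A tiny hand-made library with explicit fingerprints and activities.
toy_library <- function() {
  fps <- list(
    A = chemfp(c(0, 1, 2), 16), B = chemfp(c(0, 1, 2), 16),
    C = chemfp(c(0, 1, 3), 16), D = chemfp(c(8, 9, 10), 16),
    E = chemfp(c(12, 13), 16))
  lib <- data.frame(id = names(fps),
                    inhib_10uM = c(90, 85, 40, 10, 60),
                    inhib_1uM = c(60, 50, 20, 0, 30),
                    stringsAsFactors = FALSE)
  lib$fingerprint <- unname(fps)
  class(lib) <- c("compound_library", "data.frame")
  lib
}

# Random fingerprints for property tests.
random_fps <- function(n, n_bits = 64, density = 0.2, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    chemfp(which(runif(n_bits) < density) - 1L, n_bits)))
}

random_fp_library <- function(n, n_bits = 64, density = 0.2, seed = 1) {
  lib <- data.frame(id = sprintf("R%03d", seq_len(n)),
                    inhib_10uM = withr::with_seed(seed + 1, runif(n, -10, 100)),
                    stringsAsFactors = FALSE)
  lib$fingerprint <- random_fps(n, n_bits, density, seed)
  class(lib) <- c("compound_library", "data.frame")
  lib
}

# Random graph as a structure_network plus activities, for oracle tests.
random_network <- function(n, p = 0.2, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n))
    pairs <- t(combn(n, 2))
    sel <- runif(nrow(pairs)) < p
    structure_network(ids, cbind(ids[pairs[sel, 1]], ids[pairs[sel, 2]]))
  })
}

# Brute-force ChC oracle: count pairs and internal edges by full scan.
chc_oracle <- function(network, activities, t) {
  above <- names(activities)[activities > t]
  n_t <- length(above)
  if (n_t < 2) return(NA_real_)
  e <- 0
  if (nrow(network$edges))
    for (k in seq_len(nrow(network$edges)))
      e <- e + (network$edges[k, 1] %in% above && network$edges[k, 2] %in% above)
  2 * e / (n_t * (n_t - 1))
}
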