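# linearly separable 4096-d fixture: two Gaussian clusters, margin ~10 sd
separable_fixture <- function(n_per_class = 120, seed = 21) {
  withr::with_seed(seed, {
    dir <- rnorm(4096); dir <- dir / sqrt(sum(dir^2))
    x <- matrix(rnorm(2 * n_per_class * 4096, sd = 1), 2 * n_per_class)
    y <- rep(c("a", "b"), each = n_per_class)
    x[y == "a", ] <- x[y == "a", ] + matrix(10 * dir, n_per_class, 4096,
                                            byrow = TRUE)
    list(x = x, y = factor(y),
         wells = rep(rep(c("w1", "w2", "w3"), length.out = n_per_class), 2))
  })
}

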