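# Worked 2D example: two classes of two points each, separated along x
# and spread along y. Scatter matrices are hand-computable.
four_point_data <- function() {
  tibble::tibble(
    x = c(0, 0, 4, 4),
    y = c(0, 2, 0, 2),
    class = c(1, 1, 2, 2)
  )
}

# Two-class Gaussian dataset with means +/- delta/2 on every dimension.
gaussian_two_class <- function(n, d, delta = 1, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  cls <- rep(c(0, 1), times = c(half, n - half))
  X <- matrix(stats::rnorm(n * d, mean = (cls - 0.5) * delta), nrow = n)
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- paste0("f", seq_len(d))
  out$class <- cls
  out
}

# Exhaustive minimum of a fitness over all masks of n_dims bits.
exhaustive_optimum <- function(fitness, n_dims) {
  masks <- as.matrix(expand.grid(rep(list(0:1), n_dims)))
  min(apply(masks, 1, fitness))
}
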