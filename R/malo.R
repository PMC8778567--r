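#' Configuration for the binary modified ant lion optimizer
#'
#' Bundles and validates all tunable parameters of [run_malo()]. The
#' optimizer searches over bit-masks of length `n_dims`, minimizing a
#' user-supplied fitness. Ants perform bounded random walks around
#' roulette-selected ant lions and around the elite; the walk bounds
#' shrink over iterations (exploitation), a Levy-flight step adds
#' occasional long jumps (escape from local optima), and a per-bit
#' crossover combines the two binarized walks into the new ant.
#'
#' @param n_dims Length of the binary mask being optimized.
#' @param n_ants Colony size (at least 2).
#' @param max_iters Number of iterations `K`.
#' @param levy_alpha Step-size multiplier of the Levy perturbation;
#'   the canonical setting is 1.
#' @param levy_exponent Stability exponent of the Levy step, in (0, 2].
#' @param crossover_rate Per-bit probability of inheriting from the
#'   roulette-walk parent rather than the elite-walk parent.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param walk_lower,walk_upper Base per-dimension walk bounds before
#'   iteration shrinking. Scalars are recycled to `n_dims`.
#'
#' @return An object of class `malo_config` (a named list).
#' @examples
#' malo_config(n_dims = 8, n_ants = 10, max_iters = 20, seed = 1)
#' @export
malo_config <- function(n_dims, n_ants = 20, max_iters = 100,
                        levy_alpha = 1, levy_exponent = 1.5,
                        crossover_rate = 0.5, seed = 1,
                        walk_lower = -1, walk_upper = 1) {
  stopifnot(
    is.numeric(n_dims), length(n_dims) == 1, n_dims >= 1,
    is.numeric(n_ants), length(n_ants) == 1, n_ants >= 2,
    is.numeric(max_iters), length(max_iters) == 1, max_iters >= 1,
    is.numeric(levy_alpha), levy_alpha >= 0,
    is.numeric(levy_exponent), levy_exponent > 0, levy_exponent <= 2,
    is.numeric(crossover_rate), crossover_rate >= 0, crossover_rate <= 1,
    is.numeric(seed), length(seed) == 1
  )
  walk_lower <- rep_len(walk_lower, n_dims)
  walk_upper <- rep_len(walk_upper, n_dims)
  if (!all(is.finite(walk_lower)) || !all(is.finite(walk_upper)) ||
      any(walk_lower >= walk_upper)) {
    stop("walk bounds must be finite with lower < upper in every dimension",
         call. = FALSE)
  }
  structure(
    list(
      n_dims = as.integer(n_dims), n_ants = as.integer(n_ants),
      max_iters = as.integer(max_iters), levy_alpha = levy_alpha,
      levy_exponent = levy_exponent, crossover_rate = crossover_rate,
      seed = as.integer(seed), walk_lower = walk_lower,
      walk_upper = walk_upper
    ),
    class = "malo_config"
  )
}

#' Stochastic step function of the ant random walk
#'
#' Maps a uniform draw to a step indicator: 1 when `rdm > 0.5`, else 0.
#' Ants in the colony walk by taking steps of `2 * stochastic_step(r) - 1`,
#' i.e. +1 or -1 with equal probability.
#'
#' @param rdm Numeric vector of values in \[0, 1\].
#' @return Integer vector of 0/1 indicators.
#' @examples
#' stochastic_step(c(0.7, 0.5, 0))
#' @export
stochastic_step <- function(rdm) {
  if (!is.numeric(rdm) || anyNA(rdm) || any(rdm < 0 | rdm > 1)) {
    stop("`rdm` must be numeric in [0, 1]", call. = FALSE)
  }
  as.integer(rdm > 0.5)
}

#' Unbounded ant random walk
#'
#' Cumulative sum of +/-1 steps, starting at 0, so the path has length
#' `n_steps + 1`. The underlying uniforms may be supplied explicitly
#' (mainly for testing); by default they come from the session RNG.
#'
#' @param n_steps Number of steps (at least 1).
#' @param rdm Optional vector of `n_steps` uniforms driving the walk.
#' @return Numeric vector: the walk path, `path[1] == 0`.
#' @examples
#' random_walk(4, rdm = c(0.9, 0.8, 0.7, 0.6)) # 0 1 2 3 4
#' @export
random_walk <- function(n_steps, rdm = stats::runif(n_steps)) {
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 1) {
    stop("`n_steps` must be a single integer >= 1", call. = FALSE)
  }
  if (length(rdm) != n_steps) {
    stop("`rdm` must have length `n_steps`", call. = FALSE)
  }
  c(0, cumsum(2L * stochastic_step(rdm) - 1L))
}

#' Shrinking trap bounds
#'
#' As iterations progress the admissible walk radius contracts, shifting
#' the search from exploration to exploitation. The shrink ratio is
#' `J = 10^omega * k / K`, with `omega` stepping through
#' 2, 3, 4, 5, 6 as `k` passes 0.1, 0.5, 0.75, 0.9 and 0.95 of `K`.
#' Before `k > 0.1 K` no shrinking is applied (`J = 1`).
#'
#' @param k Current iteration, in `1..K`.
#' @param K Maximum number of iterations.
#' @param base_lower,base_upper Unshrunk per-dimension bounds.
#' @return A list with elements `r` (lower), `t` (upper), `J`, `omega`.
#' @examples
#' shrink_bounds(76, 100, -1, 1)$omega # 4
#' @export
shrink_bounds <- function(k, K, base_lower, base_upper) {
  if (!is.numeric(k) || !is.numeric(K) || length(k) != 1 || length(K) != 1 ||
      k < 1 || k > K) {
    stop("`k` must lie in 1..K", call. = FALSE)
  }
  ratio <- k / K
  omega <- if (ratio > 0.95) 6L else if (ratio > 0.9) 5L else
    if (ratio > 0.75) 4L else if (ratio > 0.5) 3L else
    if (ratio > 0.1) 2L else 1L
  J <- if (ratio > 0.1) 10^omega * ratio else 1
  list(r = base_lower / J, t = base_upper / J, J = J, omega = omega)
}

#' Min-max normalization of a walk into trap bounds
#'
#' Affinely maps the observed range of a walk onto the current bounds
#' `[r, t]`, keeping the ant inside the (possibly shrunken) trap. A
#' zero-range (constant) walk maps to the bound midpoint.
#'
#' @param walk Numeric walk path.
#' @param r,t Scalar lower/upper bound for this dimension.
#' @return Numeric vector in `[r, t]`, same length as `walk`.
#' @examples
#' normalize_walk(c(0, 1, 2), r = 0, t = 1) # 0 0.5 1
#' @export
normalize_walk <- function(walk, r, t) {
  if (length(walk) == 0) stop("`walk` must be nonempty", call. = FALSE)
  lo <- min(walk)
  hi <- max(walk)
  if (hi == lo) {
    return(rep((r + t) / 2, length(walk)))
  }
  (walk - lo) * (t - r) / (hi - lo) + r
}

# Mantegna construction of a symmetric Levy-stable step of exponent
# lambda: u / |v|^(1/lambda) with u ~ N(0, sigma_u^2), v ~ N(0, 1).
mantegna_sigma <- function(lambda) {
  (gamma(1 + lambda) * sin(pi * lambda / 2) /
     (gamma((1 + lambda) / 2) * lambda * 2^((lambda - 1) / 2)))^(1 / lambda)
}

#' Levy-flight perturbation of a position
#'
#' Adds `alpha * L` elementwise, where `L` is a heavy-tailed Levy-stable
#' step of exponent `lambda` drawn per dimension via the Mantegna
#' algorithm. Occasional long jumps let the colony escape local optima.
#'
#' @param position Finite numeric vector.
#' @param alpha Nonnegative step-size multiplier (0 returns the input).
#' @param lambda Stability exponent in (0, 2].
#' @return Numeric vector, same length as `position`.
#' @examples
#' levy_step(c(0, 0), alpha = 0) # unchanged
#' @export
levy_step <- function(position, alpha = 1, lambda = 1.5) {
  if (!is.numeric(position) || !all(is.finite(position))) {
    stop("`position` must be finite numeric", call. = FALSE)
  }
  stopifnot(alpha >= 0, lambda > 0, lambda <= 2)
  if (alpha == 0) {
    return(position)
  }
  n <- length(position)
  u <- stats::rnorm(n, sd = mantegna_sigma(lambda))
  v <- stats::rnorm(n)
  position + alpha * u / abs(v)^(1 / lambda)
}

#' Binary coding of a continuous position
#'
#' Each coordinate becomes 1 with probability `|tanh(position_j)|`:
#' a uniform draw `rdm_j` is compared against the transfer function, so
#' positions far from 0 are almost surely coded 1 and a coordinate at
#' exactly 0 is always coded 0.
#'
#' @param position Finite numeric vector.
#' @param rdm Optional uniforms (testing hook); defaults to fresh draws.
#' @return Integer 0/1 vector.
#' @examples
#' binarize(c(0, 50), rdm = c(0.5, 0.5)) # 0 1
#' @export
binarize <- function(position, rdm = stats::runif(length(position))) {
  if (!is.numeric(position) || !all(is.finite(position))) {
    stop("`position` must be finite numeric", call. = FALSE)
  }
  as.integer(rdm < abs(tanh(position)))
}

#' Roulette-wheel selection for minimization
#'
#' Selection probability is proportional to `(max(f) - f_i) + 1e-12`,
#' renormalized: lower fitness means strictly higher selection
#' probability, while the worst candidate remains (barely) selectable.
#'
#' @param fitnesses Finite numeric vector, smaller is better.
#' @return A single selected index.
#' @export
roulette_select <- function(fitnesses) {
  if (length(fitnesses) == 0) {
    stop("`fitnesses` must be nonempty", call. = FALSE)
  }
  if (!all(is.finite(fitnesses))) {
    stop("`fitnesses` must be finite", call. = FALSE)
  }
  if (length(fitnesses) == 1) {
    return(1L)
  }
  w <- (max(fitnesses) - fitnesses) + 1e-12
  sample.int(length(fitnesses), 1L, prob = w / sum(w))
}

#' Per-bit uniform crossover
#'
#' Each child bit comes from `walk_a` with probability `rate`, else
#' from `walk_b`; every locus therefore stays within the parental
#' alleles.
#'
#' @param walk_a,walk_b Binary vectors of equal length.
#' @param rate Probability of inheriting from `walk_a` per bit.
#' @param rdm Optional uniforms (testing hook).
#' @return Integer 0/1 vector.
#' @export
crossover <- function(walk_a, walk_b, rate = 0.5,
                      rdm = stats::runif(length(walk_a))) {
  if (length(walk_a) != length(walk_b)) {
    stop("parent vectors must have equal length", call. = FALSE)
  }
  as.integer(ifelse(rdm < rate, walk_a, walk_b))
}

# One normalized walk position per dimension: walk K steps, map the
# path into the shrunk bounds shifted around `center`, take step k.
walk_position <- function(n_dims, K, k, bounds, center) {
  steps <- matrix(2L * (stats::runif(K * n_dims) > 0.5) - 1L, nrow = K)
  paths <- rbind(0, apply(steps, 2, cumsum))
  lo <- apply(paths, 2, min)
  hi <- apply(paths, 2, max)
  r <- center + bounds$r
  t <- center + bounds$t
  pos <- ifelse(hi == lo, (r + t) / 2,
                (paths[k + 1L, ] - lo) * (t - r) / (hi - lo) + r)
  as.numeric(pos)
}

#' Run the binary modified ant lion optimizer
#'
#' Minimizes `fitness` over bit-masks of length `config$n_dims`. Each
#' iteration, every ant takes a bounded random walk around a
#' roulette-selected ant lion and another around the elite, both walks
#' are Levy-perturbed and binarized through the tanh transfer function,
#' and a per-bit crossover of the two binary walks forms the new ant.
#' An ant lion is replaced by an ant that strictly beats it; the elite
#' (best ant lion so far) is retained across iterations, so the elite
#' fitness trace is non-increasing.
#'
#' @param fitness Function mapping an integer 0/1 vector of length
#'   `n_dims` to a finite scalar; smaller is better. It must be defined
#'   for the all-zeros mask (return a finite worst-case penalty there).
#' @param config A [malo_config()].
#' @return An object of class `malo_result`: list with `best_mask`,
#'   `best_fitness`, `elite_history` (length `max_iters`,
#'   non-increasing), `evaluations`, and the `config`.
#' @examples
#' target <- c(1L, 0L, 1L, 1L, 0L)
#' res <- run_malo(function(m) sum(m != target),
#'                 malo_config(5, n_ants = 10, max_iters = 30, seed = 1))
#' res$best_mask
#' @export
run_malo <- function(fitness, config) {
  stopifnot(inherits(config, "malo_config"), is.function(fitness))
  n <- config$n_dims
  K <- config$max_iters
  n_ants <- config$n_ants
  bnd <- list(r = config$walk_lower, t = config$walk_upper)

  eval_fit <- function(mask) {
    f <- fitness(mask)
    if (!is.numeric(f) || length(f) != 1 || !is.finite(f)) {
      stop("fitness returned a non-finite value for mask [",
           paste(mask, collapse = ""), "]", call. = FALSE)
    }
    f
  }

  set.seed(config$seed)
  antlions <- matrix(as.integer(stats::runif(n_ants * n) > 0.5),
                     nrow = n_ants)
  al_fit <- apply(antlions, 1, eval_fit)
  evaluations <- n_ants
  elite_idx <- which.min(al_fit)
  elite <- antlions[elite_idx, ]
  elite_fit <- al_fit[elite_idx]
  elite_history <- numeric(K)

  for (k in seq_len(K)) {
    b <- shrink_bounds(k, K, config$walk_lower, config$walk_upper)
    for (i in seq_len(n_ants)) {
      sel <- roulette_select(al_fit)
      pos_p <- walk_position(n, K, k, b, center = antlions[sel, ])
      pos_c <- walk_position(n, K, k, b, center = elite)
      # Levy flight acts as local search around the global best only;
      # the roulette walk stays a plain trapped random walk
      pos_c <- levy_step(pos_c, config$levy_alpha, config$levy_exponent)
      ant <- crossover(binarize(pos_p), binarize(pos_c),
                       config$crossover_rate)
      f <- eval_fit(ant)
      evaluations <- evaluations + 1L
      if (f < al_fit[sel]) {
        antlions[sel, ] <- ant
        al_fit[sel] <- f
      }
    }
    m <- which.min(al_fit)
    if (al_fit[m] < elite_fit) {
      elite_fit <- al_fit[m]
      elite <- antlions[m, ]
    }
    elite_history[k] <- elite_fit
  }

  structure(
    list(best_mask = as.integer(elite), best_fitness = elite_fit,
         elite_history = elite_history, evaluations = evaluations,
         config = config),
    class = "malo_result"
  )
}

#' @export
print.malo_result <- function(x, ...) {
  cat("Binary MALO result\n")
  cat("  dims:", x$config$n_dims, " ants:", x$config$n_ants,
      " iters:", x$config$max_iters, "\n")
  cat("  best mask:", paste(x$best_mask, collapse = ""), "\n")
  cat("  best fitness:", format(x$best_fitness), "\n")
  cat("  fitness evaluations:", x$evaluations, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the elite trace of a MALO run
#'
#' @param x A `malo_result`.
#' @param ... Unused.
#' @return A tibble with columns `iteration` and `elite_fitness`.
#' @method tidy malo_result
#' @export
tidy.malo_result <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$elite_history),
    elite_fitness = x$elite_history
  )
}

#' One-row summary of a MALO run
#'
#' @param x A `malo_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance malo_result
#' @export
glance.malo_result <- function(x, ...) {
  tibble::tibble(
    n_dims = x$config$n_dims,
    n_ants = x$config$n_ants,
    max_iters = x$config$max_iters,
    best_fitness = x$best_fitness,
    n_selected = sum(x$best_mask),
    evaluations = x$evaluations
  )
}

#' Convergence plot for a MALO run
#'
#' @param object A `malo_result`.
#' @param ... Unused.
#' @return A ggplot of elite fitness against iteration.
#' @method autoplot malo_result
#' @export
autoplot.malo_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration,
                               y = .data$elite_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Elite fitness",
                  title = "MALO convergence") +
    ggplot2::theme_minimal()
}
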