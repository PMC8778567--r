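test_that("scatter matrices reproduce the worked four-point example", {
  sc <- scatter_matrices(four_point_data())
  expect_equal(unname(sc$grand_mean), c(2, 1))
  expect_equal(unname(sc$between), matrix(c(16, 0, 0, 0), 2))
  expect_equal(unname(sc$within), matrix(c(0, 0, 0, 4), 2))
})

test_that("degenerate class layouts zero the right scatter matrix", {
  # one sample per class: every class scatter vanishes
  d <- tibble::tibble(a = c(1, 5), b = c(2, -1), class = c(1, 2))
  expect_equal(unname(scatter_matrices(d)$within), matrix(0, 2, 2))
  # identical class means: no between-class scatter
  d2 <- tibble::tibble(a = c(0, 2, 0, 2), b = c(1, 3, 1, 3),
                       class = c(1, 1, 2, 2))
  expect_equal(unname(scatter_matrices(d2)$between), matrix(0, 2, 2))
})

test_that("between plus within equals the total scatter", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(20:60, 1)
    p <- sample(2:6, 1)
    d <- gaussian_two_class(n, p, delta = stats::runif(1, 0, 2), seed = s)
    sc <- scatter_matrices(d)
    X <- as.matrix(d[, seq_len(p)])
    total <- crossprod(sweep(X, 2, colMeans(X)))
    expect_lt(norm(sc$between + sc$within - total, "F") /
                max(norm(total, "F"), 1e-12), 1e-8)
  }
})

test_that("fisher criterion evaluates the determinant ratio", {
  sc <- scatter_matrices(four_point_data())
  # ridge-dominated denominator on the worked example
  expect_equal(fisher_criterion(c(1, 0), sc, ridge = 1e-6), 16 / 1e-6,
               tolerance = 1e-9)
  # scaling a single direction cancels in the ratio
  v <- c(0.6, 0.8)
  expect_equal(fisher_criterion(v, sc, ridge = 0.1),
               fisher_criterion(2 * v, sc, ridge = 0.1))
  # coincident class means give zero for any direction
  d2 <- tibble::tibble(a = c(0, 2, 0, 2), b = c(1, 3, 1, 3),
                       class = c(1, 1, 2, 2))
  expect_equal(fisher_criterion(c(1, 1), scatter_matrices(d2), ridge = 1e-6),
               0)
  expect_error(fisher_criterion(c(1, 0), sc, ridge = 0), "singular")
})

test_that("two-class fit matches the closed-form discriminant", {
  for (s in 1:10) {
    d <- gaussian_two_class(200, 6, delta = 1, seed = s)
    fit <- fisher_lda(d)
    sc <- fit$scatter
    W <- sc$within + diag(fit$ridge, 6)
    closed <- solve(W, sc$class_means[1, ] - sc$class_means[2, ])
    cosang <- abs(sum(fit$projection[, 1] * closed) /
                    sqrt(sum(closed^2)))
    expect_gte(cosang, 1 - 1e-6)
  }
})

test_that("generalized eigenpairs satisfy their defining equation", {
  d <- simulate_cleveland(n_samples = 150, missing_rate = 0, seed = 3)
  fit <- fisher_lda(d)
  B <- fit$scatter$between
  W <- fit$scatter$within + diag(fit$ridge, nrow(B))
  for (j in seq_len(fit$d)) {
    y <- fit$projection[, j]
    res <- sqrt(sum((B %*% y - fit$eigenvalues[j] * (W %*% y))^2)) /
      sqrt(sum(y^2))
    expect_lt(res / max(1, norm(B, "F")), 1e-6)
  }
  expect_true(all(diff(fit$eigenvalues) <= 1e-8))
})

test_that("three separated blobs keep exactly two discriminants", {
  set.seed(10)
  n <- 60
  centers <- matrix(c(0, 0, 0, 0, 0,
                      10, 0, 0, 0, 0,
                      0, 10, 0, 0, 0), nrow = 3, byrow = TRUE)
  X <- centers[rep(1:3, each = n), ] + matrix(stats::rnorm(3 * n * 5), ncol = 5)
  d <- tibble::as_tibble(as.data.frame(X))
  d$class <- rep(1:3, each = n)
  fit <- fisher_lda(d)
  expect_identical(fit$d, 2L)
})

test_that("the fitted direction beats random directions on the criterion", {
  for (s in 1:5) {
    d <- gaussian_two_class(80, 4, delta = 1.2, seed = 100 + s)
    fit <- fisher_lda(d)
    crit_fit <- fisher_criterion(fit$projection[, 1, drop = FALSE],
                                 fit$scatter, ridge = fit$ridge)
    set.seed(s)
    V <- matrix(stats::rnorm(4 * 1000), nrow = 4)
    V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
    B <- fit$scatter$between
    W <- fit$scatter$within + diag(fit$ridge, 4)
    crits <- colSums(V * (B %*% V)) / colSums(V * (W %*% V))
    expect_gte(crit_fit, max(crits) - 1e-10)
  }
})

test_that("projection is linear and matches stored centroids", {
  d <- four_point_data()
  fit <- fisher_lda(d)
  # between-class scatter lies along x, so LD1 is the x axis
  expect_equal(unname(as.matrix(lda_project(fit, d))[, 1]), c(0, 0, 4, 4))
  means <- dplyr::summarise(d, dplyr::across(c(x, y), mean),
                            .by = class)
  proj_means <- as.matrix(lda_project(fit, means[, c("x", "y")]))
  expect_equal(unname(proj_means), unname(fit$centroids),
               tolerance = 1e-10)
  expect_error(lda_project(fit, tibble::tibble(x = 1)), "lacks feature")
})

test_that("prediction is nearest projected centroid with low-index ties", {
  d <- gaussian_two_class(500, 2, delta = 6, seed = 20)
  fit <- fisher_lda(d)
  # class means classify to themselves
  m0 <- dplyr::filter(d, class == 0) |>
    dplyr::summarise(dplyr::across(c(f1, f2), mean))
  expect_equal(as.character(predict(fit, m0)), "0")
  # training accuracy at 6-sigma separation is essentially perfect
  acc <- mean(predict(fit, d) == d$class)
  expect_gte(acc, 0.99)
  # exact midpoint between centroids resolves to the lower class index
  cent <- fit$centroids
  mid <- (cent[1, 1] + cent[2, 1]) / 2
  v <- fit$projection[, 1]
  x_mid <- mid * v / sum(v^2) # a point projecting exactly onto the midpoint
  expect_equal(as.character(predict(fit, matrix(x_mid, nrow = 1))), "0")
})

test_that("translation of all samples changes nothing that matters", {
  d <- gaussian_two_class(120, 3, delta = 1.5, seed = 30)
  fit <- fisher_lda(d)
  shifted <- d
  for (j in 1:3) shifted[[j]] <- shifted[[j]] + c(5, -2, 11)[j]
  fit2 <- fisher_lda(shifted)
  expect_equal(fit$eigenvalues, fit2$eigenvalues, tolerance = 1e-8)
  expect_equal(predict(fit, d), predict(fit2, shifted))
})

test_that("labels agree with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  agree <- vapply(1:20, function(s) {
    d <- gaussian_two_class(150, 4, delta = 1.5, seed = 200 + s)
    fit <- fisher_lda(d)
    ref <- MASS::lda(class ~ ., data = d)
    mean(predict(fit, d) == predict(ref, d)$class)
  }, numeric(1))
  expect_true(all(agree >= 0.99))
})

test_that("lda tidiers and plots expose the fitted structure", {
  d <- gaussian_two_class(80, 3, delta = 1, seed = 40)
  fit <- fisher_lda(d)
  td <- tidy(fit)
  expect_named(td, c("term", "direction", "loading"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$n_directions, 1L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("input validation guards the model surface", {
  expect_error(fisher_lda(tibble::tibble(a = 1:4, class = 1)), "2 classes")
  d <- tibble::tibble(a = c(1, NA, 3, 4), class = c(1, 1, 2, 2))
  expect_error(fisher_lda(d), "missing")
  d2 <- tibble::tibble(a = c(1, 2, 3), class = c(1, 2, 3))
  expect_error(fisher_lda(d2), "more samples than classes")
})
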