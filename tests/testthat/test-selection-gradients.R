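test_that("standardization centers, scales by sample SD, and is idempotent", {
  z <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- standardize_traits(z)
  expect_equal(s[, "a"], c(-1, 0, 1))   # sd(1,2,3) = 1
  expect_equal(unname(colMeans(s)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(standardize_traits(s)), unname(s), tolerance = 1e-12)
  expect_equal(cor(s), cor(z), tolerance = 1e-12)
  expect_error(standardize_traits(cbind(a = c(1, 1, 1), b = 1:3)),
               "zero-variance.*a")
})

test_that("relative fitness has mean one per episode and mirrors the study counts", {
  raw <- c(rep(0, 255), rep(1, 245))
  w <- relative_fitness(raw)
  expect_equal(unique(w[raw == 1]), 500 / 245)
  expect_equal(mean(w), 1, tolerance = 1e-12)
  expect_equal(relative_fitness(rep(3.2, 10)), rep(1, 10))
  expect_error(relative_fitness(rep(0, 5)), "all-zero")
  expect_error(relative_fitness(c(-1, 2)), "non-negative")
  # per-episode grouping
  w2 <- relative_fitness(c(0, 2, 1, 3), episode = c("a", "a", "b", "b"))
  expect_equal(as.vector(tapply(w2, c("a", "a", "b", "b"), mean)),
               c(1, 1), tolerance = 1e-12)
})

test_that("exact linear and quadratic surfaces are recovered with the doubling rule", {
  set.seed(2)
  z <- standardize_traits(matrix(rnorm(200), 100, 2,
                                 dimnames = list(NULL, c("z1", "z2"))))
  # w = 1 + 0.3 z1 exactly
  lin <- suppressWarnings(linear_gradients(z, 1 + 0.3 * z[, 1]))
  expect_equal(unname(lin$beta), c(0.3, 0), tolerance = 1e-12)
  # w = z1^2: quadratic coefficient 1, reported doubled
  quad <- suppressWarnings(quadratic_gradients(z, z[, 1]^2))
  expect_equal(quad$gamma["z1", "z1"], 2, tolerance = 1e-10)
  # w = z1 z2: pure correlational selection
  quad2 <- suppressWarnings(quadratic_gradients(z, z[, 1] * z[, 2]))
  expect_equal(quad2$gamma["z1", "z2"], 1, tolerance = 1e-10)
  expect_equal(quad2$gamma["z1", "z1"], 0, tolerance = 1e-10)
  expect_true(isSymmetric(quad2$gamma))
})

test_that("beta equals cov(w, z) for orthonormal traits", {
  set.seed(3)
  n <- 80
  raw <- matrix(rnorm(n * 3), n, 3)
  q <- qr.Q(qr(scale(raw, scale = FALSE))) * sqrt(n - 1)  # crossprod/(n-1) = I
  colnames(q) <- paste0("z", 1:3)
  w <- 1 + rnorm(n, sd = 0.3)
  b <- linear_gradients(q, w)$beta
  expect_equal(unname(b), unname(cov(w, q)[1, ]), tolerance = 1e-10)
})

test_that("OLS gradients equal a normal-equations oracle", {
  set.seed(4)
  z <- standardize_traits(matrix(rnorm(60 * 3), 60, 3,
                                 dimnames = list(NULL, paste0("z", 1:3))))
  w <- relative_fitness(rpois(60, 4))
  b <- linear_gradients(z, w)$beta
  X <- cbind(1, z)
  expect_equal(unname(b), unname(solve(crossprod(X), crossprod(X, w))[-1]),
               tolerance = 1e-9)
  d <- shapeselect:::quadratic_design(z)
  X2 <- cbind(1, d$X)
  co <- solve(crossprod(X2), crossprod(X2, w))[-1]
  g <- quadratic_gradients(z, w)$gamma
  expect_equal(unname(diag(g)), unname(2 * co[d$idx_sq]), tolerance = 1e-9)
  expect_equal(g[1, 2], unname(co[d$idx_cp[1]]), tolerance = 1e-9)
})

test_that("estimates are invariant to specimen order and error on bad designs", {
  set.seed(5)
  z <- std_traits(50, p = 3, seed = 5)
  w <- relative_fitness(rbinom(50, 1, 0.5))
  ord <- sample(50)
  expect_equal(linear_gradients(z, w)$beta,
               linear_gradients(z[ord, ], w[ord])$beta, tolerance = 1e-12)
  zz <- cbind(z, dup = z[, 1])
  expect_error(linear_gradients(zz, w), "collinear")
  expect_error(quadratic_gradients(z[1:8, ], w[1:8]), "need n >")
})

test_that("planted gradients are recovered within 3 SE at moderate n", {
  set.seed(6)
  n <- 2000
  z <- std_traits(n, p = 5, seed = 6)
  beta <- c(-0.1, 0.2, 0, 0, 0.05)
  gamma <- diag(c(-0.2, -0.2, 0, 0, 0))
  gamma[1, 2] <- gamma[2, 1] <- 0.1
  eta <- shapeselect:::selection_surface_eta(z, beta, gamma)
  w <- 1 - sum(diag(gamma)) / 2 + eta + rnorm(n, sd = 0.5)
  lin <- linear_gradients(z, w)
  expect_true(all(abs(lin$beta - beta) < 3 * lin$se))
  quad <- quadratic_gradients(z, w)
  expect_true(all(abs(quad$gamma - gamma) < 3 * quad$gamma_se))
})

test_that("permutation p-values are deterministic, floored, and capped", {
  set.seed(7)
  n <- 300
  z <- std_traits(n, p = 2, seed = 7)
  w_null <- relative_fitness(rpois(n, 3))
  p1 <- permutation_test(z, w_null, "first", n_perm = 199, seed = 42)
  p2 <- permutation_test(z, w_null, "first", n_perm = 199, seed = 42)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  # overwhelming planted effect: p hits the add-one floor
  w_strong <- 1 + 1.0 * z[, 1] + rnorm(n, sd = 0.1)
  p <- permutation_test(z, w_strong, "first", n_perm = 1999, seed = 1)
  expect_equal(unname(p[1]), 2 / 2000)
  # second-order run returns the gamma layout
  ps <- permutation_test(z, w_null, "second", n_perm = 99, seed = 3)
  expect_true(isSymmetric(ps$p_gamma))
  expect_equal(dim(ps$p_gamma), c(2L, 2L))
})

test_that("the full episode wrapper produces a coherent gradient_estimates object", {
  tr <- synthetic_truth()
  z <- std_traits(400, p = 5, seed = 9)
  fit <- gen_fitness(z, tr$episodes$mating, seed = 11)
  est <- selection_gradients(z, fit, n_perm = 199, seed = 2,
                             standardize = FALSE)
  expect_s3_class(est, "gradient_estimates")
  expect_true(isSymmetric(est$gamma))
  expect_equal(dim(est$p_gamma), c(5L, 5L))
  expect_true(all(est$p_beta > 0 & est$p_beta <= 1))
  expect_equal(est$n, 400L)
  expect_output(print(est), "selection gradients")
  f <- withr::local_tempfile(fileext = ".csv")
  write_gradient_table(est, f)
  expect_equal(nrow(utils::read.csv(f, check.names = FALSE)), 5L)
})
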