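test_that("identical episodes produce zero F for every block", {
  z <- std_traits(120, p = 3, seed = 20)
  set.seed(20)
  w <- relative_fitness(rpois(120, 5))
  cmp <- sequential_model_comparison(z, w, z, w)
  expect_equal(cmp$blocks$F, rep(0, 3), tolerance = 1e-10)
  expect_equal(cmp$per_trait_quadratic$F, rep(0, 3), tolerance = 1e-10)
})

test_that("df bookkeeping matches the sequential design for n = 1008, p = 5", {
  z1 <- std_traits(500, p = 5, seed = 21)
  z2 <- std_traits(508, p = 5, seed = 22)
  set.seed(23)
  w1 <- relative_fitness(rbinom(500, 1, 0.5))
  w2 <- relative_fitness(rpois(508, 6))
  cmp <- sequential_model_comparison(z1, w1, z2, w2)
  expect_equal(cmp$blocks$df1, c(5, 5, 10))
  expect_equal(cmp$blocks$df2, c(996, 986, 966))
  expect_equal(cmp$per_trait_quadratic$df1, rep(1, 5))
  expect_equal(cmp$per_trait_quadratic$df2, rep(986, 5))
  expect_equal(cmp$n, 1008L)
  # swap invariance
  swp <- sequential_model_comparison(z2, w2, z1, w1)
  expect_equal(swp$blocks$F, cmp$blocks$F, tolerance = 1e-10)
})

test_that("partial F equals R's own nested-model anova on a small instance", {
  set.seed(24)
  n1 <- 60; n2 <- 70
  z1 <- std_traits(n1, p = 2, seed = 25)
  z2 <- std_traits(n2, p = 2, seed = 26)
  w1 <- relative_fitness(rpois(n1, 4))
  w2 <- relative_fitness(rpois(n2, 4))
  cmp <- sequential_model_comparison(z1, w1, z2, w2)

  dat <- data.frame(w = c(w1, w2), ep = rep(c(0, 1), c(n1, n2)),
                    rbind(z1, z2))
  nm <- colnames(z1)
  lin <- paste(nm, collapse = " + ")
  f_red <- stats::as.formula(paste("w ~ ep +", lin))
  f_full <- stats::as.formula(paste("w ~ ep +", lin, "+",
                                    paste0("ep:", nm, collapse = " + ")))
  a <- stats::anova(stats::lm(f_red, dat), stats::lm(f_full, dat))
  expect_equal(cmp$blocks$F[1], a$F[2], tolerance = 1e-9)
  expect_equal(cmp$blocks$p[1], a$`Pr(>F)`[2], tolerance = 1e-9)

  # quadratic block against the explicit-SSE oracle
  sq1 <- z1^2; sq2 <- z2^2
  X_red <- cbind(1, dat$ep, rbind(z1, z2), rbind(z1, z2) * dat$ep,
                 rbind(sq1, sq2))
  X_full <- cbind(X_red, rbind(sq1, sq2) * dat$ep)
  sse <- function(X) sum(stats::lm.fit(X, dat$w)$residuals^2)
  Fq <- ((sse(X_red) - sse(X_full)) / 2) /
    (sse(X_full) / (nrow(dat) - ncol(X_full)))
  expect_equal(cmp$blocks$F[2], Fq, tolerance = 1e-9)
})

test_that("a planted quadratic difference is detected and the linear block stays at level", {
  n_rep <- 30
  hit_q <- 0
  set.seed(27)
  for (r in seq_len(n_rep)) {
    z1 <- standardize_traits(matrix(rnorm(500 * 3), 500, 3,
                                    dimnames = list(NULL, paste0("z", 1:3))))
    z2 <- standardize_traits(matrix(rnorm(500 * 3), 500, 3,
                                    dimnames = list(NULL, paste0("z", 1:3))))
    g1 <- diag(c(0, 0, 0)); g2 <- diag(c(0.4, 0, 0))
    w1 <- 1 + shapeselect:::selection_surface_eta(z1, rep(0, 3), g1) -
      sum(diag(g1)) / 2 + rnorm(500, sd = 0.5)
    w2 <- 1 + shapeselect:::selection_surface_eta(z2, rep(0, 3), g2) -
      sum(diag(g2)) / 2 + rnorm(500, sd = 0.5)
    cmp <- sequential_model_comparison(z1, w1, z2, w2)
    hit_q <- hit_q + (cmp$blocks$p[2] < 0.05)
  }
  expect_gte(hit_q / n_rep, 0.8)

  # level of the linear block under a shared null, 200 replicates
  set.seed(28)
  rej <- 0
  for (r in 1:200) {
    z1 <- standardize_traits(matrix(rnorm(200 * 2), 200, 2,
                                    dimnames = list(NULL, c("z1", "z2"))))
    z2 <- standardize_traits(matrix(rnorm(200 * 2), 200, 2,
                                    dimnames = list(NULL, c("z1", "z2"))))
    cmp <- sequential_model_comparison(z1, 1 + rnorm(200, sd = 0.5),
                                       z2, 1 + rnorm(200, sd = 0.5))
    rej <- rej + (cmp$blocks$p[1] < 0.05)
  }
  # binomial 95% band around 0.05 for 200 draws
  expect_gte(rej / 200, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lte(rej / 200, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("episode-label permutation p-values are available and sane", {
  z1 <- std_traits(100, p = 2, seed = 30)
  z2 <- std_traits(100, p = 2, seed = 31)
  set.seed(32)
  w1 <- 1 + rnorm(100, sd = 0.4)
  w2 <- 1 + rnorm(100, sd = 0.4)
  cmp <- sequential_model_comparison(z1, w1, z2, w2, permute_p = TRUE,
                                     n_perm = 199, seed = 9)
  expect_true(all(cmp$blocks$p_perm > 0 & cmp$blocks$p_perm <= 1))
  expect_error(sequential_model_comparison(z1, w1, std_traits(100, 3), w2),
               "same trait set")
})
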