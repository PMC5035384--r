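test_that("centroid size has its closed form and invariances", {
  sq <- square_config()
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(3.7 * sq), 3.7 * sqrt(2))
  expect_equal(centroid_size(sweep(sq, 2, c(10, -3), "+")), sqrt(2))
  set.seed(1)
  cfg <- matrix(rnorm(20), 10, 2)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  expect_equal(centroid_size(cfg %*% R), centroid_size(cfg))
  expect_error(centroid_size(matrix(1, 5, 2)), "coincident")
})

test_that("GPA aligns similarity-transformed copies of one shape exactly", {
  set.seed(7)
  base <- default_outline(15)
  coords <- array(0, c(15, 2, 6))
  for (i in 1:6) coords[, , i] <- rand_similarity(base)
  al <- gpa_align(landmark_set(coords))
  expect_lt(gpa_objective(al), 1e-10)
  # mean deviation from consensus is the zero vector by construction
  expect_equal(apply(al$aligned, c(1, 2), mean), al$consensus)
  expect_equal(centroid_size(al$consensus), 1)
  expect_true(all(al$centroid_sizes > 0))
})

test_that("alignment is invariant to pre-transforming any input specimen", {
  tr <- small_truth()
  g <- gen_specimens(tr, 8, seed = 11)
  al1 <- gpa_align(g$landmarks, g$sliders)
  coords2 <- g$landmarks$coords
  set.seed(99)
  coords2[, , 3] <- rand_similarity(coords2[, , 3])
  coords2[, , 7] <- rand_similarity(coords2[, , 7])
  al2 <- gpa_align(landmark_set(coords2, ids = g$landmarks$ids), g$sliders)
  expect_equal(al1$aligned, al2$aligned, tolerance = 1e-8)
  expect_equal(al1$consensus, al2$consensus, tolerance = 1e-8)
})

test_that("classical GPA matches a brute-force rotation-search oracle on 3 specimens", {
  set.seed(5)
  coords <- array(rnorm(10 * 2 * 3, sd = 0.04), c(10, 2, 3)) +
    array(default_outline(10), c(10, 2, 3))
  al <- gpa_align(landmark_set(coords))

  # oracle: centered unit-size configs, rotations parameterized by angles;
  # minimize summed squared deviation from the mean shape numerically
  cs <- function(m) m / sqrt(sum(scale(m, scale = FALSE)^2))
  base <- lapply(1:3, function(i) {
    m <- scale(coords[, , i], scale = FALSE)
    attr(m, "scaled:center") <- NULL
    cs(m)
  })
  obj <- function(th) {
    rot <- lapply(1:3, function(i) {
      R <- matrix(c(cos(th[i]), sin(th[i]), -sin(th[i]), cos(th[i])), 2, 2)
      base[[i]] %*% R
    })
    mn <- Reduce(`+`, rot) / 3
    sum(vapply(rot, function(m) sum((m - mn)^2), 0))
  }
  oracle <- stats::optim(c(0, 0.1, -0.1), obj, method = "BFGS",
                         control = list(reltol = 1e-14))
  # recover the package's rotation angles (polar factor of the cross
  # product) and evaluate them under the oracle's objective: both should
  # sit at the same global minimum
  package_obj <- obj(vapply(1:3, function(i) {
    s <- svd(crossprod(base[[i]], al$aligned[, , i]))
    R <- s$u %*% t(s$v)
    atan2(R[2, 1], R[1, 1])
  }, 0))
  expect_equal(package_obj, oracle$value, tolerance = 1e-7)
})

test_that("pairwise alignment agrees with vegan's Procrustes rotation", {
  skip_if_not_installed("vegan")
  set.seed(3)
  A <- default_outline(12) + matrix(rnorm(24, sd = 0.05), 12, 2)
  B <- default_outline(12) + matrix(rnorm(24, sd = 0.05), 12, 2)
  al <- gpa_align(landmark_set(array(c(A, B), c(12, 2, 2))))
  d_pkg <- sum((al$aligned[, , 1] - al$aligned[, , 2])^2)
  # for two centered equal-size shapes the GPA residual equals the optimal
  # pairwise (rotation-only) Procrustes residual, which vegan computes
  # independently
  v <- vegan::procrustes(al$aligned[, , 1], al$aligned[, , 2],
                         scale = FALSE, symmetric = FALSE)
  expect_equal(d_pkg, sum((v$Yrot - v$X)^2), tolerance = 1e-8)
})

test_that("sliding semilandmarks never increases total bending energy", {
  tr <- synthetic_truth()
  set.seed(21)
  n <- 12
  coords <- array(0, c(29, 2, n))
  for (i in seq_len(n)) {
    v <- c(tr$consensus[, 1], tr$consensus[, 2]) +
      tr$axes %*% (tr$axis_sd * rnorm(8))
    cfg <- cbind(v[1:29], v[30:58])
    # perturb semilandmark spacing tangentially (digitizing unevenness)
    sl <- tr$sliders$slider
    tang <- tr$consensus[tr$sliders$after, ] - tr$consensus[tr$sliders$before, ]
    tang <- tang / sqrt(rowSums(tang^2))
    cfg[sl, ] <- cfg[sl, ] + tang * rnorm(26, sd = 0.01)
    coords[, , i] <- rand_similarity(cfg)
  }
  lm <- landmark_set(coords)
  al_raw <- gpa_align(lm)
  al_slid <- gpa_align(lm, tr$sliders)
  be_total <- function(al) sum(vapply(seq_len(n), function(i)
    bending_energy(al$consensus, al$aligned[, , i]), 0))
  expect_lt(be_total(al_slid), be_total(al_raw))
})

test_that("relative warps span at most 2k-4 dimensions and conserve variance", {
  tr <- synthetic_truth()
  g <- gen_specimens(tr, 60, seed = 2)
  al <- gpa_align(g$landmarks, g$sliders)
  rw <- relative_warps(al)
  expect_equal(ncol(rw$scores), 54L)  # 2 * 29 - 4
  expect_equal(unname(colMeans(rw$scores)), rep(0, 54), tolerance = 1e-12)
  expect_true(all(diff(rw$pct_variance) <= 1e-12))
  expect_lte(sum(rw$pct_variance), 100 + 1e-8)
  # eigenvalue sum equals the total variance of the aligned coordinates
  # 4 similarity dimensions are removed only to first order, so a sliver of
  # variance sits outside the 2k-4 retained components
  X <- t(apply(al$aligned, 3, function(m) c(m[, 1], m[, 2])))
  expect_equal(sum(rw$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-6)
  expect_lte(sum(rw$eigenvalues), sum(apply(X, 2, var)) * (1 + 1e-12))
})

test_that("a single planted shape axis is recovered as RW1", {
  tr0 <- synthetic_truth(axis_sd = c(0.01, 0, 0), noise_sd = 0)
  g <- gen_specimens(tr0, 40, seed = 5)
  al <- gpa_align(g$landmarks, g$sliders)
  rw <- relative_warps(al)
  expect_gte(rw$pct_variance[1], 99)
  # the consensus frame sits at an arbitrary rotation from the generator's
  # reference; rotate the planted axis into it before comparing directions
  R <- shapeselect:::proper_rotation(tr0$consensus, al$consensus)
  ax <- matrix(tr0$axes[, 1], ncol = 2) %*% R
  expect_gt(abs(sum(rw$loadings[, 1] * c(ax))), 0.99)
  expect_gt(abs(cor(rw$scores[, 1], g$true_scores[, 1])), 0.999)
})

test_that("shape_at_score is linear, symmetric, and projection-consistent", {
  tr <- small_truth()
  g <- gen_specimens(tr, 20, seed = 9)
  al <- gpa_align(g$landmarks, g$sliders)
  rw <- relative_warps(al)
  cons_vec <- rw$center
  at0 <- shape_at_score(rw, 1, 0)
  expect_equal(c(at0[, 1], at0[, 2]), unname(cons_vec))
  s <- 0.03
  up <- shape_at_score(rw, 2, s); dn <- shape_at_score(rw, 2, -s)
  expect_equal(up + dn, 2 * at0)
  # projecting the synthesized shape back recovers the score
  v <- c(up[, 1], up[, 2]) - cons_vec
  expect_equal(sum(v * rw$loadings[, 2]), s, tolerance = 1e-8)
  expect_error(shape_at_score(rw, 99, 1), "component")
})

test_that("TPS deformation grids interpolate exactly and detect affine maps", {
  ref <- default_outline(14)
  g_id <- tps_deformation_grid(ref, ref)
  expect_lt(max(abs(g_id$warped - g_id$grid)), 1e-10)

  aff <- ref %*% matrix(c(1.2, 0.3, -0.1, 0.9), 2, 2) +
    matrix(c(0.5, -0.2), 14, 2, byrow = TRUE)
  g_aff <- tps_deformation_grid(ref, aff)
  expect_lt(abs(g_aff$bending_energy), 1e-8)

  set.seed(8)
  tgt <- ref + matrix(rnorm(28, sd = 0.05), 14, 2)
  g <- tps_deformation_grid(ref, tgt)
  expect_equal(g$warp(ref), tgt, tolerance = 1e-9)
  expect_gt(g$bending_energy, 0)
  expect_error(tps_deformation_grid(rbind(ref, ref[1, ]),
                                    rbind(tgt, tgt[1, ])), "coincident")
})
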