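#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard geometric-morphometric size measure. It is
#' invariant to translation and rotation and scales linearly with the
#' configuration.
#'
#' @param config numeric `k x 2` matrix of landmark coordinates.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  stopifnot(ncol(config) == 2L, nrow(config) >= 3L)
  cs <- sqrt(sum(scale(config, scale = FALSE)^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincident")
  cs
}

# Center a configuration and scale to unit centroid size.
center_scale <- function(config) {
  cc <- sweep(config, 2, colMeans(config))
  cc / sqrt(sum(cc^2))
}

# Optimal proper rotation R (2x2) minimizing ||A %*% R - B||_F.
# Reflections are disallowed: specimens are digitized consistently oriented.
proper_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Thin-plate-spline bending-energy matrix of a reference configuration
#'
#' Returns the `k x k` matrix `L_k` such that for target heights `h` (one
#' coordinate of a target configuration), `t(h) %*% L_k %*% h` is the bending
#' energy of the thin-plate spline mapping the reference onto those heights.
#' Affine displacements are in its null space.
#'
#' @param ref `k x 2` reference configuration.
#' @return `k x k` symmetric positive semi-definite matrix.
#' @export
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  L <- tps_system(ref)
  Li <- solve(L)[seq_len(k), seq_len(k)]
  (Li + t(Li)) / 2
}

# TPS kernel U(r) = r^2 log(r^2), with U(0) = 0.
tps_U <- function(r2) ifelse(r2 > 0, r2 * log(r2), 0)

# Full (k+3) x (k+3) TPS system matrix [[K, P], [P', 0]] for a reference.
tps_system <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  if (any(d2[upper.tri(d2)] == 0))
    stop("singular thin-plate-spline system: coincident reference landmarks")
  K <- tps_U(d2)
  P <- cbind(1, ref)
  rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
}

#' Bending energy of a reference-to-target deformation
#'
#' @param ref,target `k x 2` configurations sharing landmark order.
#' @return Non-negative scalar (sums the x and y components).
#' @export
bending_energy <- function(ref, target) {
  Lk <- bending_energy_matrix(ref)
  sum(target[, 1] %*% Lk %*% target[, 1],
      target[, 2] %*% Lk %*% target[, 2])
}

# One sliding pass: move each semilandmark along its tangent direction to
# minimize bending energy relative to the reference (consensus). Tangents are
# chords between the slider's neighbors, taken from the specimen itself.
slide_one <- function(config, ref_Lk, sliders) {
  k <- nrow(config)
  m <- nrow(sliders)
  if (m == 0L) return(config)
  Tx <- config[sliders$after, 1] - config[sliders$before, 1]
  Ty <- config[sliders$after, 2] - config[sliders$before, 2]
  len <- sqrt(Tx^2 + Ty^2)
  len[len == 0] <- 1
  Tx <- Tx / len; Ty <- Ty / len
  # U maps slide amounts to coordinate displacements, one column per slider
  Ux <- matrix(0, k, m); Uy <- matrix(0, k, m)
  Ux[cbind(sliders$slider, seq_len(m))] <- Tx
  Uy[cbind(sliders$slider, seq_len(m))] <- Ty
  LUx <- ref_Lk %*% Ux; LUy <- ref_Lk %*% Uy
  A <- crossprod(Ux, LUx) + crossprod(Uy, LUy)
  b <- crossprod(LUx, config[, 1]) + crossprod(LUy, config[, 2])
  s <- tryCatch(solve(A + diag(1e-12, m), -b),
                error = function(e) rep(0, m))
  out <- config
  out[sliders$slider, 1] <- out[sliders$slider, 1] + s * Tx
  out[sliders$slider, 2] <- out[sliders$slider, 2] + s * Ty
  out
}

#' Generalized Procrustes alignment with optional sliding semilandmarks
#'
#' Iteratively centers every specimen, scales it to unit centroid size, and
#' rotates it (proper rotations only) onto the running consensus until the
#' consensus stabilizes. When a slider table is supplied, sliding passes are
#' interleaved with re-superimposition: each semilandmark moves along the
#' chord between its neighboring landmarks so as to minimize the
#' thin-plate-spline bending energy of the specimen relative to the
#' consensus, which removes arbitrary spacing variation along the outline.
#' On return the aligned configurations are jointly rescaled so that their
#' mean (the consensus) has exactly unit centroid size, making the consensus
#' the exact mean of the aligned sample.
#'
#' @param x a [landmark_set] or `k x 2 x n` array.
#' @param sliders optional `slider_table` (see [read_sliders()]).
#' @param tol relative consensus-change convergence tolerance.
#' @param max_iter iteration cap for the superimposition loop.
#' @param slide_cycles maximum GPA/slide alternations.
#' @param slide_tol relative change below which sliding stops.
#' @return An `aligned_shapes` object: `aligned` (`k x 2 x n`), `consensus`
#'   (`k x 2`, centered, unit centroid size), `centroid_sizes` (original CS
#'   per specimen, digitizer units), `ids`, `iterations`, `slid`.
#' @export
gpa_align <- function(x, sliders = NULL, tol = 1e-8, max_iter = 100,
                      slide_cycles = 5, slide_tol = 1e-6) {
  if (inherits(x, "landmark_set")) {
    coords <- x$coords; ids <- x$ids
  } else {
    coords <- x; ids <- dimnames(x)[[3]]
  }
  k <- dim(coords)[1]; n <- dim(coords)[3]
  if (n < 1L) stop("no specimens to align")
  if (!is.null(sliders) && nrow(sliders) &&
      (max(unlist(sliders[c("before", "slider", "after")])) > k))
    stop("slider table references landmark beyond k = ", k)
  cs <- apply(coords, 3, centroid_size)
  aligned <- array(0, dim(coords))
  for (i in seq_len(n)) aligned[, , i] <- center_scale(coords[, , i])

  superimpose <- function(aligned) {
    consensus <- center_scale(aligned[, , 1])
    iter <- 0L
    repeat {
      iter <- iter + 1L
      for (i in seq_len(n))
        aligned[, , i] <- aligned[, , i] %*%
          proper_rotation(aligned[, , i], consensus)
      new_cons <- center_scale(apply(aligned, c(1, 2), mean))
      delta <- sqrt(sum((new_cons - consensus)^2))
      consensus <- new_cons
      if (delta < tol) break
      if (iter >= max_iter)
        stop("GPA failed to converge in ", max_iter,
             " iterations (last consensus change ", signif(delta, 3), ")")
    }
    list(aligned = aligned, consensus = consensus, iter = iter)
  }

  fit <- superimpose(aligned)
  slid <- FALSE
  if (!is.null(sliders) && nrow(sliders) > 0L) {
    slid <- TRUE
    prev_be <- Inf
    for (cyc in seq_len(slide_cycles)) {
      Lk <- bending_energy_matrix(fit$consensus)
      for (i in seq_len(n))
        fit$aligned[, , i] <- slide_one(fit$aligned[, , i], Lk, sliders)
      # sliding changed the shapes: re-normalize and re-superimpose
      for (i in seq_len(n))
        fit$aligned[, , i] <- center_scale(fit$aligned[, , i])
      fit <- superimpose(fit$aligned)
      be <- sum(vapply(seq_len(n), function(i)
        bending_energy(fit$consensus, fit$aligned[, , i]), 0))
      if (is.finite(prev_be) && prev_be - be < slide_tol * max(prev_be, 1e-12)) break
      prev_be <- be
    }
  }
  # exact-mean normalization: consensus := mean of aligned, unit CS
  cons_raw <- apply(fit$aligned, c(1, 2), mean)
  f <- sqrt(sum(scale(cons_raw, scale = FALSE)^2))
  ctr <- colMeans(cons_raw)
  for (i in seq_len(n))
    fit$aligned[, , i] <- sweep(fit$aligned[, , i], 2, ctr) / f
  consensus <- sweep(cons_raw, 2, ctr) / f
  dimnames(consensus) <- list(NULL, c("x", "y"))
  dimnames(fit$aligned) <- list(NULL, c("x", "y"), ids)
  structure(list(aligned = fit$aligned, consensus = consensus,
                 centroid_sizes = stats::setNames(cs, ids), ids = ids,
                 iterations = fit$iter, slid = slid),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("aligned_shapes:", dim(x$aligned)[3], "specimens,",
      dim(x$aligned)[1], "landmarks",
      if (x$slid) "(semilandmarks slid)" else "", "\n")
  invisible(x)
}

#' Relative warps (principal components of aligned shape coordinates)
#'
#' With the weighting exponent at zero and the uniform component retained,
#' relative warps are the principal components of the Procrustes-aligned
#' coordinates about the consensus; scores are the shape variables used as
#' traits downstream. Component signs are fixed deterministically by making
#' each component's largest-magnitude loading positive. Two-dimensional
#' alignment removes 4 degrees of freedom, so at most `2k - 4` components are
#' non-degenerate.
#'
#' @param aligned an `aligned_shapes` object from [gpa_align()].
#' @return A `shape_scores` object: `scores` (n x r), `eigenvalues`,
#'   `pct_variance`, `loadings` (2k x r, x-block then y-block), `consensus`,
#'   `center`, `k`.
#' @export
relative_warps <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  n <- dim(aligned$aligned)[3]
  k <- dim(aligned$aligned)[1]
  if (n < 3L) stop("relative warps require at least 3 specimens")
  X <- t(apply(aligned$aligned, 3, function(m) c(m[, 1], m[, 2])))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  r <- min(2L * k - 4L, n - 1L)
  sv <- svd(Xc, nu = 0, nv = r)
  ev <- (sv$d^2 / (n - 1))[seq_len(r)]
  load <- sv$v
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(r)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  scores <- Xc %*% load
  colnames(scores) <- colnames(load) <- paste0("RW", seq_len(r))
  rownames(scores) <- aligned$ids
  structure(list(scores = scores, eigenvalues = ev,
                 pct_variance = 100 * ev / sum(ev),
                 loadings = load, consensus = aligned$consensus,
                 center = ctr, k = k),
            class = "shape_scores")
}

#' @export
print.shape_scores <- function(x, ...) {
  cat("shape_scores:", nrow(x$scores), "specimens,",
      ncol(x$scores), "relative warps\n")
  p <- x$pct_variance[seq_len(min(3, length(x$pct_variance)))]
  cat("  leading % variance:", paste(sprintf("%.2f", p), collapse = ", "), "\n")
  invisible(x)
}

#' Synthesize the shape configuration at a given relative-warp score
#'
#' Reconstructs `consensus + score * loading` as a `k x 2` configuration —
#' the construction behind positive/negative-score deformation insets.
#'
#' @param rw a `shape_scores` object.
#' @param component relative-warp index.
#' @param score score value along that component.
#' @return `k x 2` configuration.
#' @export
shape_at_score <- function(rw, component, score) {
  r <- ncol(rw$scores)
  if (component < 1L || component > r)
    stop("component must be in [1, ", r, "]")
  v <- rw$center + score * rw$loadings[, component]
  k <- rw$k
  cbind(x = v[seq_len(k)], y = v[k + seq_len(k)])
}

#' Thin-plate-spline deformation grid between two configurations
#'
#' Fits the interpolating thin-plate spline carrying the reference landmarks
#' exactly onto the target landmarks and evaluates it on a rectangular grid —
#' the classical deformation-grid visualization of a shape change.
#'
#' @param ref `k x 2` reference (usually the consensus).
#' @param target `k x 2` target configuration.
#' @param n_grid grid lines per axis.
#' @param expand fractional bounding-box expansion.
#' @return A `tps_grid` object: `grid` (original grid points), `warped`
#'   (their images), `nx`, `ny`, `bending_energy` (of the non-affine part),
#'   and the spline coefficients.
#' @export
tps_deformation_grid <- function(ref, target, n_grid = 24, expand = 0.1) {
  ref <- as.matrix(ref); target <- as.matrix(target)
  stopifnot(nrow(ref) == nrow(target), ncol(ref) == 2L, ncol(target) == 2L)
  k <- nrow(ref)
  L <- tps_system(ref)
  sol <- solve(L, rbind(target, matrix(0, 3, 2)))
  W <- sol[seq_len(k), , drop = FALSE]        # non-affine coefficients
  A <- sol[k + 1:3, , drop = FALSE]           # affine part
  be <- sum(diag(t(W) %*% tps_U(as.matrix(stats::dist(ref))^2) %*% W))
  rx <- range(ref[, 1]); ry <- range(ref[, 2])
  ex <- expand * diff(rx); ey <- expand * diff(ry)
  gx <- seq(rx[1] - ex, rx[2] + ex, length.out = n_grid)
  gy <- seq(ry[1] - ey, ry[2] + ey, length.out = n_grid)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  warp_fun <- function(pts) {
    d2 <- outer(rowSums(pts^2), rowSums(ref^2), "+") - 2 * pts %*% t(ref)
    d2[d2 < 0] <- 0
    cbind(1, pts) %*% A + tps_U(d2) %*% W
  }
  structure(list(grid = grid, warped = warp_fun(grid),
                 nx = n_grid, ny = n_grid, bending_energy = be,
                 coefficients = list(W = W, A = A), ref = ref,
                 target = target, warp = warp_fun),
            class = "tps_grid")
}

#' @export
plot.tps_grid <- function(x, ...) {
  w <- x$warped
  plot(w, type = "n", asp = 1, xlab = "", ylab = "", axes = FALSE, ...)
  for (i in seq_len(x$ny))
    graphics::lines(w[(i - 1) * x$nx + seq_len(x$nx), ], col = "grey60")
  for (j in seq_len(x$nx))
    graphics::lines(w[j + x$nx * (seq_len(x$ny) - 1), ], col = "grey60")
  graphics::points(x$target, pch = 19, cex = 0.6)
  invisible(x)
}
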