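#' Penalized thin-plate-spline fitness surface over two canonical axes
#'
#' Fits relative fitness as a smooth function of two predictors (typically a
#' pair of canonical-axis scores) by a penalized thin-plate spline with
#' knots at the data points, minimizing
#' `sum_i m_i (w_i - f(x_i))^2 + n * lambda * J(f)` where `J` is the
#' bending-energy penalty and `m_i` the multiplicity of duplicate predictor
#' points (duplicates are aggregated by averaging their fitness). At
#' `lambda = 0` the spline interpolates the (aggregated) data exactly; as
#' `lambda` grows the fit tends to the least-squares plane. With
#' `smoothing = "gcv"` the penalty is chosen on a 40-point log-spaced grid
#' (1e-6 to 1e3 times a data-scale normalization) by minimizing the
#' generalized cross-validation score `GCV = n * RSS / (n - tr(H))^2`.
#' Surfaces fitted this way are descriptive visualizations of the selection
#' surface; no inference is drawn from them.
#'
#' @param x numeric `n x 2` predictor matrix (e.g. two canonical scores).
#' @param w fitness values (length n).
#' @param smoothing `"gcv"` or a non-negative numeric penalty.
#' @param n_grid evaluation-grid lines per axis.
#' @param expand fractional bounding-box expansion for the grid.
#' @return A `smooth_surface`: `knots`, `coef` (spline + affine),
#'   `lambda`, `gcv` (data.frame over the search grid, when searched),
#'   `grid` (list `x`, `y`, `z`), `fitted` (at the knots), and a `predict`
#'   closure.
#' @export
fit_tps_surface <- function(x, w, smoothing = "gcv", n_grid = 30,
                            expand = 0.05) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2L, nrow(x) == length(w))
  n_all <- nrow(x)
  if (n_all < 6L) stop("need at least 6 observations for a surface")
  # aggregate duplicate predictor points with multiplicity weights
  key <- paste(x[, 1], x[, 2], sep = "\r")
  grp <- match(key, unique(key))
  nu <- max(grp)
  knots <- x[!duplicated(grp), , drop = FALSE]
  m <- as.vector(table(grp))
  ybar <- as.vector(tapply(w, grp, mean))
  if (nu < 4L || qr(cbind(1, knots))$rank < 3L)
    stop("predictor points are collinear; surface is singular")
  d2 <- as.matrix(stats::dist(knots))^2
  K <- tps_U(d2)
  P <- cbind(1, knots)
  Winv <- diag(1 / m, nu)

  kscale <- mean(abs(K)) + 1e-300
  solve_at <- function(lam) {
    nl <- n_all * lam
    if (nl <= 1e4 * kscale) {
      A <- rbind(cbind(K + nl * Winv, P), cbind(t(P), matrix(0, 3, 3)))
      Ainv <- solve(A)
      cS <- (Ainv %*% c(ybar, 0, 0, 0))[seq_len(nu)]
      d <- (Ainv %*% c(ybar, 0, 0, 0))[nu + 1:3]
      B <- cbind(K, P)
    } else {
      # scaled variables u = n*lambda*c keep the system well conditioned
      # as the penalty grows and the fit tends to the least-squares plane
      A <- rbind(cbind(K / nl + Winv, P), cbind(t(P), matrix(0, 3, 3)))
      Ainv <- solve(A)
      u <- (Ainv %*% c(ybar, 0, 0, 0))[seq_len(nu)]
      cS <- u / nl
      d <- (Ainv %*% c(ybar, 0, 0, 0))[nu + 1:3]
      B <- cbind(K / nl, P)
    }
    fitted <- as.vector(K %*% cS + P %*% d)
    # hat matrix: fitted = B %*% Ainv[, 1:nu] %*% ybar
    H <- B %*% Ainv[, seq_len(nu), drop = FALSE]
    rss <- sum(m * (ybar - fitted)^2)
    edf <- sum(diag(H))  # trace of the smoother on the aggregated data
    gcv <- n_all * rss / (n_all - min(edf, n_all - 1e-8))^2
    list(sol = c(cS, d), fitted = fitted, rss = rss, edf = edf, gcv = gcv)
  }

  gcv_tab <- NULL
  if (identical(smoothing, "gcv")) {
    scale0 <- mean(abs(K))
    grid_l <- scale0 * 10^seq(-6, 3, length.out = 40)
    fits <- lapply(grid_l, solve_at)
    gcv_tab <- data.frame(lambda = grid_l,
                          gcv = vapply(fits, `[[`, 0, "gcv"),
                          edf = vapply(fits, `[[`, 0, "edf"))
    best <- which.min(gcv_tab$gcv)
    lambda <- grid_l[best]
    f <- fits[[best]]
  } else {
    lambda <- as.numeric(smoothing)
    if (is.na(lambda) || lambda < 0) stop("smoothing must be 'gcv' or >= 0")
    f <- solve_at(lambda)
  }

  cS <- f$sol[seq_len(nu)]
  cA <- f$sol[nu + 1:3]
  predict_fun <- function(pts) {
    pts <- as.matrix(pts)
    D2 <- outer(rowSums(pts^2), rowSums(knots^2), "+") - 2 * pts %*% t(knots)
    D2[D2 < 0] <- 0
    as.vector(tps_U(D2) %*% cS + cbind(1, pts) %*% cA)
  }
  rx <- range(knots[, 1]); ry <- range(knots[, 2])
  gx <- seq(rx[1] - expand * diff(rx), rx[2] + expand * diff(rx),
            length.out = n_grid)
  gy <- seq(ry[1] - expand * diff(ry), ry[2] + expand * diff(ry),
            length.out = n_grid)
  z <- matrix(predict_fun(as.matrix(expand.grid(gx, gy))), n_grid, n_grid)
  structure(list(knots = knots, weights = m, y = ybar,
                 coef = list(spline = cS, affine = cA), lambda = lambda,
                 gcv = gcv_tab, edf = f$edf, fitted = f$fitted,
                 grid = list(x = gx, y = gy, z = z), predict = predict_fun,
                 n = n_all),
            class = "smooth_surface")
}

#' @export
print.smooth_surface <- function(x, ...) {
  cat("smooth_surface:", x$n, "points,", nrow(x$knots), "knots, lambda =",
      signif(x$lambda, 4), ", edf =", round(x$edf, 2), "\n")
  invisible(x)
}

#' Predict from a fitted thin-plate-spline surface
#' @param object a `smooth_surface`.
#' @param newdata `m x 2` matrix of predictor points.
#' @param ... ignored.
#' @return Numeric vector of surface heights.
#' @export
predict.smooth_surface <- function(object, newdata, ...) {
  object$predict(newdata)
}

#' Perspective plot of a fitted fitness surface
#'
#' Writes a perspective-view rendering of the surface grid to an image file
#' (PNG or PDF, chosen by extension).
#'
#' @param s a `smooth_surface`.
#' @param file output path ending in `.png` or `.pdf`.
#' @param theta,phi viewing angles passed to [graphics::persp()].
#' @param xlab,ylab,zlab axis labels.
#' @return `file`, invisibly.
#' @export
surface_plot <- function(s, file, theta = -35, phi = 25,
                         xlab = "axis 1", ylab = "axis 2",
                         zlab = "relative fitness") {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") grDevices::png(file, width = 800, height = 700)
  else if (ext == "pdf") grDevices::pdf(file, width = 7, height = 6)
  else stop("unsupported image format: .", ext)
  on.exit(grDevices::dev.off())
  graphics::persp(s$grid$x, s$grid$y, s$grid$z, theta = theta, phi = phi,
                  xlab = xlab, ylab = ylab, zlab = zlab,
                  ticktype = "detailed", col = "lightsteelblue",
                  shade = 0.4, border = NA)
  invisible(file)
}
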