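#' Standardize a trait matrix to zero mean and unit variance
#'
#' Lande-Arnold gradients are defined on standardized traits. Columns are
#' centered and scaled by the sample standard deviation (n - 1 denominator).
#'
#' @param z numeric matrix or data.frame of traits (columns = traits).
#' @return Numeric matrix with attribute `standardized = TRUE`.
#' @export
standardize_traits <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("standardization requires at least 2 specimens")
  sds <- apply(z, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(z)[sds == 0]
    stop("zero-variance trait(s): ",
         paste(if (is.null(nm)) which(sds == 0) else nm, collapse = ", "))
  }
  out <- scale(z)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  out
}

#' Relative fitness within a selection episode
#'
#' Divides raw fitness by its (episode) mean so that mean relative fitness is
#' one, the scale on which selection gradients are regression coefficients.
#'
#' @param fitness non-negative numeric vector (binary mating success or
#'   offspring counts).
#' @param episode optional grouping vector; relativization is done within
#'   each group.
#' @return Numeric vector of relative fitness, mean one within episode.
#' @export
relative_fitness <- function(fitness, episode = NULL) {
  if (any(fitness < 0)) stop("fitness must be non-negative")
  if (is.null(episode)) episode <- rep(1L, length(fitness))
  out <- numeric(length(fitness))
  for (g in unique(episode)) {
    i <- episode == g
    m <- mean(fitness[i])
    if (m <= 0) stop("episode '", g, "': all-zero fitness, cannot relativize")
    out[i] <- fitness[i] / m
  }
  out
}

# Second-order design matrix: linear terms, squared terms, pairwise products.
# Returns the matrix (no intercept) plus index maps back into beta/gamma.
quadratic_design <- function(z) {
  z <- as.matrix(z)
  p <- ncol(z)
  nm <- colnames(z)
  if (is.null(nm)) nm <- paste0("z", seq_len(p))
  sq <- z^2
  colnames(sq) <- paste0(nm, "^2")
  if (p > 1L) {
    pairs <- utils::combn(p, 2)
    cp <- z[, pairs[1, ], drop = FALSE] * z[, pairs[2, ], drop = FALSE]
    colnames(cp) <- paste0(nm[pairs[1, ]], ":", nm[pairs[2, ]])
  } else {
    pairs <- matrix(integer(), 2, 0)
    cp <- matrix(numeric(nrow(z)), nrow(z), 0)
  }
  list(X = cbind(z, sq, cp), p = p, names = nm, pairs = pairs,
       idx_lin = seq_len(p), idx_sq = p + seq_len(p),
       idx_cp = 2L * p + seq_len(ncol(pairs)))
}

check_lande_arnold_inputs <- function(z, w) {
  z <- as.matrix(z)
  if (nrow(z) != length(w)) stop("traits and fitness differ in length")
  if (qr(cbind(1, z))$rank < ncol(z) + 1L)
    stop("rank-deficient trait design: collinear traits")
  z
}

#' Linear (directional) selection gradients
#'
#' Fits the first-order Lande-Arnold regression of relative fitness on
#' standardized traits by ordinary least squares. Directional gradients are
#' taken from this model (not from the second-order model).
#'
#' @param z standardized trait matrix.
#' @param w relative fitness vector.
#' @return List with `beta`, `se`, `fit` (the `lm` object), `n`.
#' @export
linear_gradients <- function(z, w) {
  z <- check_lande_arnold_inputs(z, w)
  if (nrow(z) <= ncol(z) + 1L) stop("need n > p + 1 observations")
  fit <- stats::lm(w ~ z)
  cf <- summary(fit)$coefficients
  nm <- colnames(z)
  if (is.null(nm)) nm <- paste0("z", seq_len(ncol(z)))
  list(beta = stats::setNames(cf[-1, 1], nm),
       se = stats::setNames(cf[-1, 2], nm), fit = fit, n = nrow(z))
}

#' Quadratic and correlational selection gradients
#'
#' Fits the full second-order Lande-Arnold regression (all linear, squared
#' and pairwise-product terms simultaneously). Quadratic gradients are twice
#' the squared-term coefficients — the fitted surface is
#' `w = a + beta'z + z'Gz/2`, so the raw squared-term coefficient
#' underestimates stabilizing/disruptive selection by half. The returned
#' `gamma` matrix has the doubled coefficients on the diagonal and the
#' product-term coefficients off the diagonal, and is symmetric.
#'
#' @param z standardized trait matrix.
#' @param w relative fitness vector.
#' @return List with `gamma` (p x p symmetric), `gamma_se` (same layout),
#'   `beta2` (linear coefficients of the second-order model), `fit`, `n`.
#' @export
quadratic_gradients <- function(z, w) {
  z <- check_lande_arnold_inputs(z, w)
  d <- quadratic_design(z)
  p <- d$p
  if (nrow(z) <= 1L + p + p * (p + 1L) / 2L)
    stop("need n > 1 + p + p(p+1)/2 observations for the full quadratic model")
  fit <- stats::lm(w ~ d$X)
  cf <- summary(fit)$coefficients
  co <- cf[-1, 1]; se <- cf[-1, 2]
  gamma <- diag(2 * co[d$idx_sq], p)
  gamma_se <- diag(2 * se[d$idx_sq], p)
  if (ncol(d$pairs)) {
    for (j in seq_len(ncol(d$pairs))) {
      a <- d$pairs[1, j]; b <- d$pairs[2, j]
      gamma[a, b] <- gamma[b, a] <- co[d$idx_cp[j]]
      gamma_se[a, b] <- gamma_se[b, a] <- se[d$idx_cp[j]]
    }
  }
  dimnames(gamma) <- dimnames(gamma_se) <- list(d$names, d$names)
  list(gamma = gamma, gamma_se = gamma_se,
       beta2 = stats::setNames(co[d$idx_lin], d$names),
       beta2_se = stats::setNames(se[d$idx_lin], d$names),
       fit = fit, n = nrow(z))
}

# Shared permutation engine: observed coefficients vs coefficients refit on
# fitness shuffled across individuals, vectorized through one QR of the fixed
# design. Two-tailed p per coefficient with the add-one correction
# p = min(1, 2 * min((#le + 1), (#ge + 1)) / (N + 1)).
permute_coef_pvalues <- function(X, w, n_perm, seed = NULL, chunk = 2000L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  qr_X <- qr(cbind(1, X))
  obs <- qr.coef(qr_X, w)[-1]
  n_le <- n_ge <- numeric(length(obs))
  done <- 0L
  while (done < n_perm) {
    nb <- min(chunk, n_perm - done)
    W <- matrix(w[as.vector(vapply(seq_len(nb), function(...) sample.int(n),
                                   integer(n)))], n, nb)
    B <- qr.coef(qr_X, W)[-1, , drop = FALSE]
    n_le <- n_le + rowSums(B <= obs)
    n_ge <- n_ge + rowSums(B >= obs)
    done <- done + nb
  }
  p <- 2 * pmin(n_le + 1, n_ge + 1) / (n_perm + 1)
  stats::setNames(pmin(p, 1), names(obs))
}

#' Permutation test for selection-gradient coefficients
#'
#' Fitness values are randomly shuffled across individuals, breaking any
#' trait-fitness association, and the regression refit; the two-tailed
#' p-value for each coefficient compares the observed estimate with the
#' permutation distribution, using the add-one small-sample correction so
#' p = 0 is impossible. Traits are standardized once on the full sample
#' before any permutation; only fitness is shuffled. First- and second-order
#' models are tested in separate runs.
#'
#' @param z standardized trait matrix.
#' @param w relative fitness.
#' @param order `"first"` (directional model) or `"second"` (full quadratic
#'   model).
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed for reproducibility.
#' @return For `"first"`: named vector `p_beta`. For `"second"`: list with
#'   `p_gamma` (p x p, diagonal = squared-term p, off-diagonal =
#'   product-term p) and `p_linear2`.
#' @export
permutation_test <- function(z, w, order = c("first", "second"),
                             n_perm = 9999, seed = NULL) {
  order <- match.arg(order)
  z <- check_lande_arnold_inputs(z, w)
  if (order == "first")
    return(permute_coef_pvalues(z, w, n_perm, seed))
  d <- quadratic_design(z)
  pv <- permute_coef_pvalues(d$X, w, n_perm, seed)
  p <- d$p
  p_gamma <- diag(pv[d$idx_sq], p)
  if (ncol(d$pairs))
    for (j in seq_len(ncol(d$pairs))) {
      a <- d$pairs[1, j]; b <- d$pairs[2, j]
      p_gamma[a, b] <- p_gamma[b, a] <- pv[d$idx_cp[j]]
    }
  dimnames(p_gamma) <- list(d$names, d$names)
  list(p_gamma = p_gamma, p_linear2 = stats::setNames(pv[d$idx_lin], d$names))
}

#' Full Lande-Arnold selection-gradient analysis for one episode
#'
#' Standardizes traits, relativizes fitness, estimates directional gradients
#' from the first-order model and quadratic/correlational gradients from the
#' full second-order model, and attaches permutation p-values from separate
#' randomizations of the two models. Ordinary least squares is used even for
#' binary mating fitness (gradients retain their evolutionary interpretation
#' on the relative-fitness scale); inference comes from the permutations, not
#' the Gaussian standard errors.
#'
#' @param traits trait matrix or data.frame (unstandardized is fine; set
#'   `standardize = FALSE` if already standardized).
#' @param fitness raw fitness vector (binary or counts).
#' @param n_perm permutations per model.
#' @param seed RNG seed.
#' @param standardize,relativize whether to transform inputs.
#' @return A `gradient_estimates` object with `beta`, `beta_se`, `gamma`,
#'   `gamma_se`, `p_beta`, `p_gamma`, `n`, plus the transformed `z` and `w`.
#' @export
selection_gradients <- function(traits, fitness, n_perm = 9999, seed = NULL,
                                standardize = TRUE, relativize = TRUE) {
  z <- if (standardize) standardize_traits(traits) else as.matrix(traits)
  w <- if (relativize) relative_fitness(fitness) else fitness
  lin <- linear_gradients(z, w)
  quad <- quadratic_gradients(z, w)
  p_beta <- permutation_test(z, w, "first", n_perm = n_perm, seed = seed)
  p2 <- permutation_test(z, w, "second", n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  structure(list(beta = lin$beta, beta_se = lin$se,
                 gamma = quad$gamma, gamma_se = quad$gamma_se,
                 beta2 = quad$beta2, p_beta = p_beta, p_gamma = p2$p_gamma,
                 n = lin$n, n_perm = n_perm, z = z, w = w),
            class = "gradient_estimates")
}

sig_star <- function(p) ifelse(p < 0.001, "***",
                        ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))

#' @export
print.gradient_estimates <- function(x, digits = 3, ...) {
  cat("Lande-Arnold selection gradients (n =", x$n, ",",
      x$n_perm, "permutations)\n\n")
  p <- length(x$beta)
  tab <- data.frame(beta = sprintf("%.*f%s", digits, x$beta, sig_star(x$p_beta)))
  g <- matrix("", p, p, dimnames = dimnames(x$gamma))
  for (i in seq_len(p)) for (j in seq_len(i))
    g[i, j] <- sprintf("%.*f%s", digits, x$gamma[i, j], sig_star(x$p_gamma[i, j]))
  tab <- cbind(tab, g)
  rownames(tab) <- names(x$beta)
  print(tab)
  invisible(x)
}

#' Export a gradient table (beta column + lower-triangle gamma)
#'
#' @param x a `gradient_estimates` object.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_gradient_table <- function(x, file) {
  p <- length(x$beta)
  g <- x$gamma
  g[upper.tri(g)] <- NA
  df <- data.frame(trait = names(x$beta), beta = x$beta, p_beta = x$p_beta,
                   g, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
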