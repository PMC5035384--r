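#' Sequential model building: does selection differ between episodes?
#'
#' Pools two selection episodes (each already standardized and relativized
#' within episode) with an episode indicator and asks, block by block,
#' whether the selection surface differs between them. Blocks are cumulative:
#' linear episode-interaction terms are tested against the pooled linear
#' model; quadratic interactions are tested with all linear terms (and their
#' interactions) retained; correlational interactions with linear and
#' quadratic blocks retained. Each block's partial F compares the model with
#' episode-by-term interactions for that block against the nested model
#' without them:
#' `F = ((SSE_reduced - SSE_full) / d_num) / (SSE_full / d_den)`.
#' A per-trait breakdown of the quadratic block drops one squared-term
#' interaction at a time from the quadratic-block full model.
#'
#' @param traits1,traits2 standardized trait matrices for the two episodes
#'   (same columns, standardized within episode).
#' @param w1,w2 relative fitness within each episode.
#' @param permute_p if `TRUE`, p-values are additionally computed by
#'   shuffling episode labels (`n_perm` relabelings) instead of relying on
#'   the F distribution alone.
#' @param n_perm relabelings when `permute_p = TRUE`.
#' @param seed RNG seed for the relabeling option.
#' @return A `comparison_result`: data.frame `blocks` (block, F, df1, df2,
#'   p), data.frame `per_trait_quadratic`, and `n` (pooled).
#' @export
sequential_model_comparison <- function(traits1, w1, traits2, w2,
                                        permute_p = FALSE, n_perm = 999,
                                        seed = NULL) {
  z1 <- as.matrix(traits1); z2 <- as.matrix(traits2)
  if (ncol(z1) != ncol(z2) ||
      !identical(colnames(z1), colnames(z2)))
    stop("episodes must share the same trait set")
  z <- rbind(z1, z2)
  w <- c(w1, w2)
  ep <- rep(c(0, 1), c(nrow(z1), nrow(z2)))
  n <- nrow(z)
  d <- quadratic_design(z)
  lin <- d$X[, d$idx_lin, drop = FALSE]
  sq <- d$X[, d$idx_sq, drop = FALSE]
  cp <- d$X[, d$idx_cp, drop = FALSE]
  p <- d$p
  if (n <= 2 + 4 * p + 2 * ncol(cp))
    stop("insufficient pooled sample size for the correlational block")

  sse <- function(X) {
    f <- stats::lm.fit(cbind(1, X), w)
    sum(f$residuals^2)
  }
  partial_f <- function(X_red, X_full, d_num) {
    s_r <- sse(X_red); s_f <- sse(X_full)
    d_den <- n - (ncol(X_full) + 1L)
    f <- ((s_r - s_f) / d_num) / (s_f / d_den)
    c(F = max(f, 0), df1 = d_num, df2 = d_den,
      p = stats::pf(max(f, 0), d_num, d_den, lower.tail = FALSE))
  }

  X_L_red <- cbind(ep, lin)
  X_L_full <- cbind(X_L_red, lin * ep)
  X_Q_red <- cbind(X_L_full, sq)
  X_Q_full <- cbind(X_Q_red, sq * ep)
  X_C_red <- cbind(X_Q_full, cp)
  X_C_full <- cbind(X_C_red, cp * ep)

  blocks <- rbind(linear = partial_f(X_L_red, X_L_full, p),
                  quadratic = partial_f(X_Q_red, X_Q_full, p),
                  correlational = partial_f(X_C_red, X_C_full, ncol(cp)))
  blocks <- data.frame(block = rownames(blocks), blocks, row.names = NULL)

  # per-trait quadratic interactions by single-term deletion
  per_trait <- t(vapply(seq_len(p), function(j) {
    partial_f(cbind(X_Q_red, (sq * ep)[, -j, drop = FALSE]), X_Q_full, 1L)
  }, c(F = 0, df1 = 0, df2 = 0, p = 0)))
  per_trait <- data.frame(trait = d$names, per_trait, row.names = NULL)

  if (permute_p) {
    if (!is.null(seed)) set.seed(seed)
    hits <- matrix(0, n_perm, 3)
    for (b in seq_len(n_perm)) {
      eb <- ep[sample.int(n)]
      fb <- c(partial_f(cbind(eb, lin), cbind(eb, lin, lin * eb), p)["F"],
              partial_f(cbind(eb, lin, lin * eb, sq),
                        cbind(eb, lin, lin * eb, sq, sq * eb), p)["F"],
              partial_f(cbind(eb, lin, lin * eb, sq, sq * eb, cp),
                        cbind(eb, lin, lin * eb, sq, sq * eb, cp, cp * eb),
                        ncol(cp))["F"])
      hits[b, ] <- fb >= blocks$F
    }
    blocks$p_perm <- (colSums(hits) + 1) / (n_perm + 1)
  }

  structure(list(blocks = blocks, per_trait_quadratic = per_trait, n = n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Sequential model comparison of selection episodes (pooled n =",
      x$n, ")\n\n")
  b <- x$blocks
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-13s F[%d,%d] = %.3f, P = %.3f\n", b$block[i],
                b$df1[i], b$df2[i], b$F[i], b$p[i]))
  cat("\nPer-trait quadratic differences:\n")
  pt <- x$per_trait_quadratic
  for (i in seq_len(nrow(pt)))
    cat(sprintf("  %-6s F[%d,%d] = %.3f, P = %.3f\n", pt$trait[i],
                pt$df1[i], pt$df2[i], pt$F[i], pt$p[i]))
  invisible(x)
}
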