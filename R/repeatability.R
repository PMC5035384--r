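#' ANOVA-based repeatability (intraclass correlation) of a measurement
#'
#' One-way ANOVA repeatability for a balanced design with `n` subjects each
#' measured `m` times (e.g. two independent digitizations of the same
#' specimen): `R = (MSB - MSW) / (MSB + (m - 1) * MSW)`, the proportion of
#' variance among measurements attributable to differences among subjects.
#' The 95% confidence interval is the exact F-distribution interval for the
#' balanced one-way design. Negative point estimates (possible when the
#' subject effect is absent) are reported as computed, not truncated: the
#' variance-component estimator is unbiased and truncation would bias
#' simulation averages.
#'
#' @param value numeric vector of measurements.
#' @param subject subject identifier, same length as `value`.
#' @param conf confidence level.
#' @return A `repeatability_estimate`: `R`, `ci` (length 2), `n_subjects`,
#'   `m` (measurements per subject), `MSB`, `MSW`.
#' @export
icc_repeatability <- function(value, subject, conf = 0.95) {
  stopifnot(length(value) == length(subject))
  subject <- as.factor(subject)
  cnt <- table(subject)
  if (length(cnt) < 2L) stop("need at least 2 subjects")
  if (any(cnt < 2L)) stop("every subject needs >= 2 measurements")
  if (length(unique(cnt)) > 1L)
    stop("unbalanced design: measurements per subject differ")
  m <- as.integer(cnt[1])
  n <- length(cnt)
  if (stats::var(value) == 0) stop("zero total variance in measurements")
  fit <- stats::aov(value ~ subject)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  if (msw == 0) {
    R <- 1; ci <- c(1, 1)
  } else {
    R <- (msb - msw) / (msb + (m - 1) * msw)
    alpha <- 1 - conf
    Fobs <- msb / msw
    df1 <- n - 1L; df2 <- n * (m - 1L)
    FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((FL - 1) / (FL + m - 1), (FU - 1) / (FU + m - 1))
  }
  structure(list(R = R, ci = ci, conf = conf, n_subjects = n, m = m,
                 MSB = msb, MSW = msw),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("Repeatability R = %.*f, %d%% CI = (%.*f, %.*f), %d subjects x %d\n",
              digits, x$R, round(100 * x$conf), digits, x$ci[1], digits,
              x$ci[2], x$n_subjects, x$m))
  invisible(x)
}

#' Repeatability of a set of traits from a two-digitization table
#'
#' @param df data.frame with columns `subject_id` plus one column per trait;
#'   one row per measurement.
#' @param traits character vector of trait column names.
#' @return data.frame with one row per trait: `R`, `lower`, `upper`.
#' @export
repeatability_table <- function(df, traits) {
  out <- lapply(traits, function(tr)
    icc_repeatability(df[[tr]], df$subject_id))
  data.frame(trait = traits,
             R = vapply(out, `[[`, 0, "R"),
             lower = vapply(out, function(o) o$ci[1], 0),
             upper = vapply(out, function(o) o$ci[2], 0))
}
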