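# Shared fixtures: all synthetic, built in code.

square_config <- function() {
  cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
}

# random similarity transform (proper rotation + scale + translation)
rand_similarity <- function(config, angle = stats::runif(1, 0, 2 * pi),
                            s = stats::runif(1, 0.5, 3),
                            shift = stats::runif(2, -10, 10)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(s * config %*% R, 2, shift, "+")
}

# small truth for fast pipeline-level tests
small_truth <- function(...) {
  synthetic_truth(k = 13, fixed = c(1, 6, 7), ...)
}

# standardized 5-trait matrix, deterministic given seed
std_traits <- function(n, p = 5, seed = 1) {
  set.seed(seed)
  nm <- c("PW", "CS", if (p > 2) paste0("RW", seq_len(p - 2)))[seq_len(p)]
  z <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, nm))
  standardize_traits(z)
}

gpa_objective <- function(al) {
  sum(apply(al$aligned, 3, function(m) sum((m - al$consensus)^2)))
}
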