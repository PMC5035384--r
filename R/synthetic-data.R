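#' Reference aedeagus-like outline for the synthetic generator
#'
#' A closed, tapered outline sampled at `k` points, standing in for the
#' digitized genital outline: an elongated body with a narrow anterior tip.
#' Returned centered with unit centroid size.
#'
#' @param k number of landmarks.
#' @return `k x 2` configuration.
#' @export
default_outline <- function(k = 29) {
  t <- 2 * pi * (seq_len(k) - 1) / k
  x <- cos(t)
  y <- 0.35 * sin(t) * (1 + 0.35 * cos(t))
  center_scale(cbind(x = x, y = y))
}

# Smooth deformation fields, normal to the outline, orthonormalized against
# the similarity transforms (translation x/y, scaling, rotation) of the
# reference so the planted axes are pure shape variation. When a slider
# table is given the fields are first passed through the slide-invariant
# projector P = I - U (U'LU)^-1 U'L (U = tangential slide directions at the
# semilandmarks, L = bending-energy metric of the reference): deviations in
# range(P) are untouched by bending-energy sliding, so planted variation
# survives the semilandmark treatment instead of being obliquely projected
# by it. Deterministic.
shape_axis_basis <- function(ref, n_axes = 3, sliders = NULL) {
  k <- nrow(ref)
  t <- 2 * pi * (seq_len(k) - 1) / k
  nb <- c(k, seq_len(k - 1)); na <- c(seq_len(k - 1) + 1, 1)
  tang <- ref[na, ] - ref[nb, ]
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(-tang[, 2], tang[, 1])            # outline normals
  sim <- cbind(c(rep(1, k), rep(0, k)),          # translate x
               c(rep(0, k), rep(1, k)),          # translate y
               c(ref[, 1], ref[, 2]),            # scale
               c(-ref[, 2], ref[, 1]))           # rotate
  amp <- cbind(sin(t),                           # mid-section thickness
               cos(2 * t),                       # tip vs mid width balance
               sin(3 * t),                       # posterior-section length
               cos(4 * t), sin(5 * t), cos(6 * t), sin(7 * t),
               cos(8 * t), sin(9 * t), cos(10 * t))
  fields <- apply(amp, 2, function(a) c(a * nrm[, 1], a * nrm[, 2]))
  if (!is.null(sliders) && nrow(sliders) > 0L) {
    m <- nrow(sliders)
    st <- ref[sliders$after, ] - ref[sliders$before, ]
    st <- st / sqrt(rowSums(st^2))
    U <- matrix(0, 2L * k, m)
    U[cbind(sliders$slider, seq_len(m))] <- st[, 1]
    U[cbind(k + sliders$slider, seq_len(m))] <- st[, 2]
    Lk <- bending_energy_matrix(ref)
    L2U <- rbind(Lk %*% U[seq_len(k), ], Lk %*% U[k + seq_len(k), ])
    fields <- fields - U %*% solve(crossprod(U, L2U), crossprod(L2U, fields))
  }
  q <- qr.Q(qr(cbind(sim, fields)))
  axes <- q[, 4 + seq_len(n_axes), drop = FALSE]
  colnames(axes) <- paste0("axis", seq_len(n_axes))
  axes
}

#' Ground-truth parameters for the synthetic study generator
#'
#' Bundles everything the generator needs to emulate a two-episode selection
#' study on genital shape: a reference outline with fixed landmarks and
#' sliding semilandmarks, a low-rank shape covariance (eight planted axes;
#' the leading three put roughly 65%, 11% and 7% of shape variance on the
#' first three relative warps — cumulatively just over 80% — while five
#' minor axes carry the residual spread) plus a small isotropic digitizing
#' noise, a body-size
#' distribution weakly correlated with genital size, and per-episode
#' selection surfaces. Episode defaults mirror the emulated design: a
#' mating episode of 500 trials with a 49% success rate (binary fitness from
#' a logistic individual selection surface) and a fertilization episode of
#' 508 trials with ~20% zero-offspring females and counts bounded by 1-80
#' (zero-inflated bounded negative binomial with log-linked mean). The
#' default selection surfaces are the published gradient tables from
#' [example_gradients()].
#'
#' @param k landmarks per outline.
#' @param fixed indices of the fixed landmarks (the rest slide).
#' @param axis_sd standard deviations of the three planted shape axes
#'   (Procrustes units).
#' @param noise_sd isotropic digitizing noise per coordinate (Procrustes
#'   units).
#' @param cs_meanlog,cs_sdlog log-normal genital centroid-size distribution
#'   (mm; genitalia are canalized, hence the small spread).
#' @param pw_mean,pw_sd pronotum-width distribution (mm).
#' @param pw_cs_cor correlation between pronotum width and log centroid
#'   size.
#' @param episodes named list of per-episode settings; see Details in the
#'   package vignette. Each episode has `n`, `model` (one of
#'   `"binary-logistic"`, `"zero-inflated-count"`, `"gaussian"`), `beta`,
#'   `gamma`, and model-specific fields (`rate`; `zero_prob`, `count_mu`,
#'   `count_disp`, `count_max`; `sigma`).
#' @return A `synthetic_truth` object (validated list).
#' @export
synthetic_truth <- function(k = 29, fixed = c(1, 16, 17),
                            axis_sd = sqrt(2e-3 * c(0.653, 0.114, 0.067,
                                                    0.060, 0.042, 0.030,
                                                    0.020, 0.014)),
                            noise_sd = 5e-4,
                            cs_meanlog = log(0.95), cs_sdlog = 0.05,
                            pw_mean = 1.45, pw_sd = 0.06, pw_cs_cor = 0.2,
                            episodes = NULL) {
  pub <- example_gradients()
  if (is.null(episodes))
    episodes <- list(
      mating = list(n = 500L, model = "binary-logistic", rate = 245 / 500,
                    beta = pub$mating$beta, gamma = pub$mating$gamma),
      fertilization = list(n = 508L, model = "zero-inflated-count",
                           zero_prob = 0.2, count_mu = 12, count_disp = 0.9,
                           count_max = 80L, beta = pub$fertilization$beta,
                           gamma = pub$fertilization$gamma))
  ref <- default_outline(k)
  sl <- data.frame(slider = setdiff(seq_len(k), fixed))
  sl$before <- ((sl$slider - 2L) %% k) + 1L
  sl$after <- (sl$slider %% k) + 1L
  sliders <- slider_table(sl[c("before", "slider", "after")], k)
  axes <- shape_axis_basis(ref, length(axis_sd), sliders)
  if (length(axis_sd) > 2L * k - 4L) stop("more planted axes than shape dimensions")
  stopifnot(all(axis_sd >= 0), noise_sd >= 0, pw_cs_cor >= -1, pw_cs_cor <= 1)
  for (ep in episodes) {
    stopifnot(is.matrix(ep$gamma), max(abs(ep$gamma - t(ep$gamma))) < 1e-12,
              length(ep$beta) == nrow(ep$gamma))
    if (identical(ep$model, "binary-logistic"))
      stopifnot(ep$rate > 0, ep$rate < 1)
    if (identical(ep$model, "zero-inflated-count"))
      stopifnot(ep$zero_prob >= 0, ep$zero_prob < 1)
  }
  structure(list(k = k, fixed = fixed, sliders = sliders,
                 consensus = ref, axes = axes, axis_sd = axis_sd,
                 noise_sd = noise_sd, cs_meanlog = cs_meanlog,
                 cs_sdlog = cs_sdlog, pw_mean = pw_mean, pw_sd = pw_sd,
                 pw_cs_cor = pw_cs_cor, episodes = episodes),
            class = "synthetic_truth")
}

#' Generate synthetic specimens (landmarks + size traits, no fitness)
#'
#' Each specimen's outline is the reference plus planted-axis shape scores
#' plus isotropic digitizing noise, scaled by a log-normal centroid size and
#' placed at a random orientation and position (so alignment is actually
#' exercised). Pronotum width is drawn with the configured correlation to
#' log centroid size. With `digitizations = 2` the same underlying outline
#' is "digitized" twice with independent noise and placement, for
#' repeatability studies.
#'
#' @param truth a [synthetic_truth()] object.
#' @param n number of specimens.
#' @param seed RNG seed (generation is a pure function of truth, n, seed).
#' @param digitizations 1 or 2 digitizations per specimen.
#' @param id_prefix prefix for specimen ids.
#' @return A list: `landmarks` ([landmark_set]; with two digitizations the
#'   ids carry `_d1`/`_d2` suffixes and `subject_id` gives the specimen),
#'   `sliders`, `traits` (data.frame `specimen_id`, `pw`, `size_true`),
#'   `true_scores` (n x axes), `truth`.
#' @export
gen_specimens <- function(truth, n, seed = 1L, digitizations = 1L,
                          id_prefix = "s") {
  stopifnot(inherits(truth, "synthetic_truth"), digitizations %in% 1:2)
  set.seed(seed)
  k <- truth$k
  n_ax <- ncol(truth$axes)
  scores <- matrix(stats::rnorm(n * n_ax), n, n_ax) %*% diag(truth$axis_sd, n_ax)
  log_cs <- truth$cs_meanlog + truth$cs_sdlog * stats::rnorm(n)
  z_cs <- (log_cs - truth$cs_meanlog) / truth$cs_sdlog
  rho <- truth$pw_cs_cor
  pw <- truth$pw_mean + truth$pw_sd *
    (rho * z_cs + sqrt(1 - rho^2) * stats::rnorm(n))
  ids <- paste0(id_prefix, seq_len(n))
  nd <- n * digitizations
  coords <- array(0, c(k, 2, nd))
  all_ids <- character(nd)
  subject <- character(nd)
  cons_vec <- c(truth$consensus[, 1], truth$consensus[, 2])
  idx <- 0L
  for (i in seq_len(n)) {
    shape_vec <- cons_vec + truth$axes %*% scores[i, ]
    for (d in seq_len(digitizations)) {
      idx <- idx + 1L
      v <- shape_vec + truth$noise_sd * stats::rnorm(2 * k)
      cfg <- cbind(v[seq_len(k)], v[k + seq_len(k)]) * exp(log_cs[i])
      ang <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      cfg <- cfg %*% R
      cfg <- sweep(cfg, 2, stats::runif(2, -5, 5), "+")
      coords[, , idx] <- cfg
      all_ids[idx] <- if (digitizations == 1L) ids[i] else
        paste0(ids[i], "_d", d)
      subject[idx] <- ids[i]
    }
  }
  list(landmarks = landmark_set(coords, ids = all_ids),
       sliders = truth$sliders,
       traits = data.frame(specimen_id = ids, pw = pw,
                           size_true = exp(log_cs)),
       true_scores = scores, subject_id = subject, truth = truth)
}

# Individual selection surface on standardized traits,
# eta = beta'z + z'Gz/2 (the doubled-gamma convention, so recovered
# doubled quadratic gradients equal the planted gamma directly).
selection_surface_eta <- function(z, beta, gamma) {
  z <- as.matrix(z)
  as.vector(z %*% beta + 0.5 * rowSums((z %*% gamma) * z))
}

#' Generate fitness from a planted selection surface
#'
#' Given standardized traits and an episode's truth settings, draws
#' individual fitness on the raw scale (the pipeline relativizes later,
#' mirroring the analysis flow). Three models:
#' \describe{
#'   \item{binary-logistic}{`P(success) = plogis(a + eta)` with the
#'     intercept `a` solved numerically so the expected success rate equals
#'     the target `rate`.}
#'   \item{zero-inflated-count}{a structural zero with probability
#'     `zero_prob`, otherwise `1 +` a negative-binomial draw capped at
#'     `count_max`, with mean proportional to `exp(eta)` (normalized so the
#'     positive-part mean stays at `count_mu`).}
#'   \item{gaussian}{`w = 1 - tr(gamma)/2 + eta + N(0, sigma)`, i.e.
#'     expected relative fitness is exactly the planted quadratic surface
#'     with mean one; the estimation-recovery harness uses this model since
#'     nonlinear links make the regression-scale gradients attenuated
#'     versions of the planted link-scale parameters.}
#' }
#'
#' @param z standardized trait matrix (columns matching `episode$beta`).
#' @param episode one element of `truth$episodes` (or an equivalent list).
#' @param seed RNG seed.
#' @return Numeric fitness vector (0/1, counts, or gaussian relative
#'   fitness).
#' @export
gen_fitness <- function(z, episode, seed = 1L) {
  set.seed(seed)
  z <- as.matrix(z)
  eta <- selection_surface_eta(z, episode$beta, episode$gamma)
  model <- episode$model
  if (model == "binary-logistic") {
    f <- function(a) mean(stats::plogis(a + eta)) - episode$rate
    lo <- -30; hi <- 30
    if (f(lo) > 0 || f(hi) < 0)
      stop("target mating rate ", episode$rate, " unattainable")
    a <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    stats::rbinom(nrow(z), 1, stats::plogis(a + eta))
  } else if (model == "zero-inflated-count") {
    zero <- stats::rbinom(nrow(z), 1, episode$zero_prob)
    mu <- episode$count_mu * exp(eta) / mean(exp(eta))
    pos <- 1L + stats::rnbinom(nrow(z), size = episode$count_disp,
                               mu = pmax(mu - 1, 0.05))
    pos <- pmin(pos, episode$count_max)
    ifelse(zero == 1L, 0L, pos)
  } else if (model == "gaussian") {
    sigma <- if (is.null(episode$sigma)) 0.5 else episode$sigma
    1 - sum(diag(episode$gamma)) / 2 + eta + sigma * stats::rnorm(nrow(z))
  } else stop("unknown fitness model '", model, "'")
}

#' Generate a complete two-episode synthetic study
#'
#' Draws specimens for every configured episode and attaches fitness
#' generated from each episode's planted surface applied to the generator's
#' own true traits (pronotum width, log centroid size, planted shape-axis
#' scores), standardized within episode — the morphometric pipeline then has
#' to re-estimate those traits from the landmarks.
#'
#' @param truth a [synthetic_truth()].
#' @param seed RNG seed.
#' @return A list with `landmarks` (pooled [landmark_set]), `sliders`,
#'   `trait_table` (specimen_id, episode, pw, fitness), `true_traits`,
#'   `truth`.
#' @export
gen_study <- function(truth, seed = 1L) {
  sets <- list()
  tabs <- list()
  true_tr <- list()
  ep_names <- names(truth$episodes)
  for (j in seq_along(ep_names)) {
    ep <- truth$episodes[[j]]
    g <- gen_specimens(truth, ep$n, seed = seed + 1000L * j,
                       id_prefix = paste0(substr(ep_names[j], 1, 1), "_"))
    p <- length(ep$beta)
    zt <- cbind(pw = g$traits$pw, log_cs = log(g$traits$size_true),
                g$true_scores[, seq_len(p - 2L), drop = FALSE])
    zs <- standardize_traits(zt)
    colnames(zs) <- names(ep$beta)
    fit <- gen_fitness(zs, ep, seed = seed + 1000L * j + 500L)
    sets[[j]] <- g$landmarks
    tabs[[j]] <- data.frame(specimen_id = g$traits$specimen_id,
                            episode = ep_names[j], pw = g$traits$pw,
                            fitness = fit)
    true_tr[[j]] <- data.frame(specimen_id = g$traits$specimen_id,
                               episode = ep_names[j], zs)
  }
  pooled <- landmark_set(
    array(unlist(lapply(sets, function(s) s$coords)),
          c(truth$k, 2, sum(vapply(sets, function(s) s$n, 0L)))),
    ids = unlist(lapply(sets, function(s) s$ids)))
  list(landmarks = pooled, sliders = truth$sliders,
       trait_table = do.call(rbind, tabs),
       true_traits = do.call(rbind, true_tr), truth = truth)
}

#' End-to-end parameter-recovery report
#'
#' Runs the whole estimation pipeline on synthetic data with known truth:
#' generate specimens, align (with sliding), extract relative warps, build
#' the standardized trait set (PW, CS, RW1..), generate fitness from the
#' planted surface on those standardized traits (gaussian model, so the
#' planted gradients are exactly the regression estimands), estimate beta
#' and gamma, decompose gamma, and report every estimate with its standard
#' error and z-score against truth.
#'
#' @param truth a [synthetic_truth()]; its first episode's `beta`/`gamma`
#'   are the planted surface unless `beta`/`gamma` are given.
#' @param n specimens.
#' @param seed RNG seed.
#' @param beta,gamma optional planted surface overriding the truth episode.
#' @param sigma gaussian fitness noise sd.
#' @return A `recovery_report`: data.frames `beta` and `gamma` (true,
#'   estimate, se, z), `lambda` (planted-gamma eigenvalues vs estimated,
#'   with double-regression SEs), and `max_abs_z`.
#' @export
end_to_end_recovery <- function(truth, n = 5000, seed = 1L, beta = NULL,
                                gamma = NULL, sigma = 0.5) {
  ep <- truth$episodes[[1]]
  if (!is.null(beta)) ep$beta <- beta
  if (!is.null(gamma)) ep$gamma <- gamma
  ep$model <- "gaussian"; ep$sigma <- sigma
  p <- length(ep$beta)
  n_rw <- p - 2L
  g <- gen_specimens(truth, n, seed = seed)
  al <- gpa_align(g$landmarks, g$sliders)
  rw <- relative_warps(al)
  traits <- cbind(PW = g$traits$pw, CS = al$centroid_sizes,
                  rw$scores[, seq_len(n_rw), drop = FALSE])
  colnames(traits) <- names(ep$beta)
  z <- standardize_traits(traits)
  w <- gen_fitness(z, ep, seed = seed + 7L)
  quad <- quadratic_gradients(z, w)
  dec <- canonical_decompose(quad$gamma)
  dr <- double_regression(z, w, dec$M)
  # the planted linear coefficients are the estimand of the (correctly
  # specified) full second-order model; the first-order directional
  # gradient additionally absorbs a projection of the quadratic surface
  # whenever the realized traits are skewed
  beta_df <- data.frame(trait = names(ep$beta), true = as.vector(ep$beta),
                        estimate = as.vector(quad$beta2),
                        se = as.vector(quad$beta2_se))
  beta_df$z <- (beta_df$estimate - beta_df$true) / beta_df$se
  li <- which(lower.tri(ep$gamma, diag = TRUE), arr.ind = TRUE)
  gamma_df <- data.frame(row = rownames(ep$gamma)[li[, 1]],
                         col = colnames(ep$gamma)[li[, 2]],
                         true = ep$gamma[li],
                         estimate = quad$gamma[li], se = quad$gamma_se[li])
  gamma_df$z <- (gamma_df$estimate - gamma_df$true) / gamma_df$se
  lam_true <- sort(eigen(ep$gamma, symmetric = TRUE)$values, decreasing = TRUE)
  lambda_df <- data.frame(axis = rownames(dec$M), true = lam_true,
                          estimate = as.vector(dec$lambda),
                          se = as.vector(dr$lambda_se))
  lambda_df$z <- (lambda_df$estimate - lambda_df$true) / lambda_df$se
  structure(list(beta = beta_df, gamma = gamma_df, lambda = lambda_df,
                 n = n, seed = seed,
                 max_abs_z = max(abs(c(beta_df$z, gamma_df$z)))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("End-to-end recovery (n =", x$n, ", seed =", x$seed, ")\n")
  cat("  max |z| over beta and gamma entries:", round(x$max_abs_z, 2), "\n\n")
  print(cbind(x$beta[1], round(x$beta[-1], 4)))
  cat("\n")
  print(cbind(x$gamma[1:2], round(x$gamma[-(1:2)], 4)))
  cat("\n")
  print(cbind(x$lambda[1], round(x$lambda[-1], 4)))
  invisible(x)
}
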