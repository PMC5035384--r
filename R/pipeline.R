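#' Number of relative warps to retain by cumulative variance
#'
#' The smallest leading set of relative warps whose cumulative percent
#' variance exceeds the threshold (default 80%): later warps each explain
#' little shape variation and the nonlinear-selection models grow
#' quadratically in the trait count.
#'
#' @param pct_variance per-component percent-variance vector (non-increasing).
#' @param threshold cumulative percentage to exceed.
#' @return Integer count of retained components.
#' @export
select_rw_count <- function(pct_variance, threshold = 80) {
  if (length(pct_variance) == 0L) stop("empty percent-variance vector")
  cum <- cumsum(pct_variance)
  r <- which(cum > threshold)
  if (length(r) == 0L) length(pct_variance) else r[1]
}

#' Assemble a pipeline run configuration
#'
#' Either file inputs (`tps`, `sliders`, `trait_table` paths) or a
#' [synthetic_truth()] must be supplied.
#'
#' @param tps,sliders,trait_table input file paths (TPS landmarks, slider
#'   triples, CSV trait/fitness table).
#' @param truth a `synthetic_truth` for a simulated run.
#' @param out_dir output directory (created if missing).
#' @param n_perm permutations for all randomization tests.
#' @param seed seed controlling simulation and permutations.
#' @param rw_threshold cumulative-%-variance retention threshold.
#' @param make_figures write surface/deformation figures (PNG).
#' @return A `run_config` list.
#' @export
run_config <- function(tps = NULL, sliders = NULL, trait_table = NULL,
                       truth = NULL, out_dir = tempfile("shapeselect_run_"),
                       n_perm = 9999, seed = 1L, rw_threshold = 80,
                       make_figures = TRUE) {
  if (is.null(truth)) {
    for (f in c(tps, trait_table))
      if (!file.exists(f)) stop("input file not found: ", f)
  }
  if (n_perm < 99) stop("n_perm must be >= 99")
  structure(list(tps = tps, sliders = sliders, trait_table = trait_table,
                 truth = truth, out_dir = out_dir, n_perm = n_perm,
                 seed = seed, rw_threshold = rw_threshold,
                 make_figures = make_figures),
            class = "run_config")
}

#' Run the full two-episode selection analysis
#'
#' Orchestrates the stages on one dataset: morphometrics on the POOLED
#' specimen set (both episodes aligned together, so centroid size and the
#' relative warps live in one geometric space and selection can be compared
#' across episodes), then per-episode gradient and canonical analyses,
#' sequential model comparison of the episodes, and fitness-surface
#' visualizations over the two most strongly curved canonical axes. All
#' tables are written to `config$out_dir` along with a structured log
#' carrying the configuration hash and seeds.
#'
#' @param config a [run_config()].
#' @return A `pipeline_result` bundle: `aligned`, `rw`, `n_rw`, `traits`
#'   (per-episode standardized), `gradients` and `canonical` (per-episode),
#'   `comparison`, `out_dir`, `config_hash`, invisibly printed tables on
#'   disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cfg_txt <- deparse(config[setdiff(names(config), "truth")])
  cfg_file <- file.path(config$out_dir, "config.txt")
  writeLines(c(cfg_txt, if (!is.null(config$truth)) "synthetic"), cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  logf <- function(stage, ...) {
    line <- paste0(format(Sys.time(), "%H:%M:%OS2"), " [", stage, "] ",
                   paste0(..., collapse = " "))
    cat(line, "\n", file = log_path, append = TRUE)
  }
  logf("init", "config_hash=", hash, " seed=", config$seed)

  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logf(name, sprintf("done in %.2fs", proc.time()[3] - t0))
    out
  }

  inputs <- stage("input", {
    if (!is.null(config$truth)) gen_study(config$truth, seed = config$seed)
    else list(landmarks = read_tps(config$tps),
              sliders = if (!is.null(config$sliders))
                read_sliders(config$sliders, read_tps(config$tps)$k),
              trait_table = read_trait_table(config$trait_table))
  })
  tab <- inputs$trait_table
  lms <- inputs$landmarks
  if (!setequal(tab$specimen_id, lms$ids))
    stop("stage 'input' failed: trait table and TPS specimens disagree")
  tab <- tab[match(lms$ids, tab$specimen_id), ]

  aligned <- stage("morphometry", gpa_align(lms, inputs$sliders))
  rw <- stage("relative_warps", relative_warps(aligned))
  n_rw <- select_rw_count(rw$pct_variance, config$rw_threshold)
  logf("relative_warps", "retained RWs=", n_rw, " cum%=",
       sprintf("%.2f", sum(rw$pct_variance[seq_len(n_rw)])))

  episodes <- unique(tab$episode)
  gradients <- list(); canon <- list(); zs <- list(); ws <- list()
  for (j in seq_along(episodes)) {
    epn <- episodes[j]
    i <- tab$episode == epn
    traits <- cbind(PW = tab$pw[i], CS = aligned$centroid_sizes[i],
                    rw$scores[i, seq_len(n_rw), drop = FALSE])
    zs[[epn]] <- standardize_traits(traits)
    ws[[epn]] <- relative_fitness(tab$fitness[i])
    gradients[[epn]] <- stage(paste0("gradients_", epn),
      selection_gradients(zs[[epn]], ws[[epn]], n_perm = config$n_perm,
                          seed = config$seed + 11L * j,
                          standardize = FALSE, relativize = FALSE))
    canon[[epn]] <- stage(paste0("canonical_", epn),
      canonical_analysis(zs[[epn]], ws[[epn]], n_perm = config$n_perm,
                         seed = config$seed + 11L * j + 5L,
                         standardize = FALSE, relativize = FALSE))
    write_gradient_table(gradients[[epn]],
                         file.path(config$out_dir,
                                   paste0("gradients_", epn, ".csv")))
    write_canonical_table(canon[[epn]],
                          file.path(config$out_dir,
                                    paste0("canonical_", epn, ".csv")))
    if (config$make_figures) {
      ax <- order(canon[[epn]]$lambda)[1:2]   # most strongly curved axes
      y <- zs[[epn]] %*% t(canon[[epn]]$M[ax, , drop = FALSE])
      s <- fit_tps_surface(y, ws[[epn]], smoothing = "gcv")
      surface_plot(s, file.path(config$out_dir,
                                paste0("surface_", epn, ".png")),
                   xlab = rownames(canon[[epn]]$M)[ax[1]],
                   ylab = rownames(canon[[epn]]$M)[ax[2]])
    }
  }

  comparison <- NULL
  if (length(episodes) == 2L) {
    comparison <- stage("comparison",
      sequential_model_comparison(zs[[1]], ws[[1]], zs[[2]], ws[[2]]))
    utils::write.csv(comparison$blocks,
                     file.path(config$out_dir, "comparison_blocks.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison$per_trait_quadratic,
                     file.path(config$out_dir, "comparison_per_trait.csv"),
                     row.names = FALSE)
  }
  logf("done", "outputs in ", config$out_dir)
  structure(list(aligned = aligned, rw = rw, n_rw = n_rw, traits = zs,
                 fitness = ws, gradients = gradients, canonical = canon,
                 comparison = comparison, out_dir = config$out_dir,
                 config_hash = hash),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("shapeselect pipeline result (", dim(x$aligned$aligned)[3],
      " specimens, ", x$n_rw, " RWs retained)\n", sep = "")
  cat("outputs:", x$out_dir, "\n")
  for (ep in names(x$gradients)) {
    cat("\n==", ep, "==\n")
    print(x$gradients[[ep]])
  }
  if (!is.null(x$comparison)) { cat("\n"); print(x$comparison) }
  invisible(x)
}
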