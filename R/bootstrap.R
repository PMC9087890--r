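# Parametric-bootstrap confidence intervals: resimulate spectra from the
# fitted model, refit, and summarize the replicate estimates.

#' Parametric bootstrap for a fitted demographic model
#'
#' For each bootstrap replicate a joint SFS of `obs_size` SNPs is drawn
#' multinomially from the fitted model's expected spectrum and the same
#' model is refitted (at a reduced replicate count by default).  The mean
#' and percentile 95% interval of each parameter over successful refits are
#' reported.
#'
#' @param fit An `im_fit` from [fit_model()].
#' @param n_boot Number of bootstrap replicates.
#' @param settings Settings for the refits; defaults to the fit's settings
#'   with `n_reps` reduced to `refit_reps`.
#' @param refit_reps Replicate optimizations per refit (default 5; set to
#'   the original `n_reps` to restore full scale).
#' @param obs_size SNP count per replicate; defaults to the fitted data's.
#' @param exp_sims Simulations used to build the generating expected
#'   spectrum (default `settings$n_sims`).
#' @param failure_budget Maximum fraction of refits allowed to fail before
#'   the bootstrap itself errors.
#' @param seed Integer seed (defaults to the fit's seed + 1).
#' @param control Passed to [fit_model()].
#' @return A list of class `im_bootstrap`: `summary` (per-parameter mean,
#'   `lo`, `hi`), `replicates` (estimate table), `n_boot`, `n_failed`,
#'   `seed`.
#' @export
parametric_bootstrap <- function(fit, n_boot = 100, settings = NULL,
                                 refit_reps = 5L, obs_size = NULL,
                                 exp_sims = NULL, failure_budget = 0.2,
                                 seed = NULL, control = list()) {
  stopifnot(inherits(fit, "im_fit"))
  if (n_boot < 1) stop("n_boot must be at least 1", call. = FALSE)
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  settings <- settings %||% fit$settings
  settings$n_reps <- as.integer(refit_reps)
  obs_size <- obs_size %||% round(fit$obs_summary$S)
  seed <- as.integer(seed %||% ((fit$seed + 1) %% .Machine$integer.max))
  model <- build_model(fit$model_id, fit$params, settings)
  config <- sample_config(fit$obs_summary$n[1], fit$obs_summary$n[2])
  gen <- expected_jsfs(model, config, n_sims = exp_sims %||% settings$n_sims,
                       settings = settings, seed = seed)
  mask <- jsfs(gen$probs, folded = gen$folded)$mask
  probs <- gen$probs[!mask]
  cells <- which(!mask)
  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, n_boot)
  est <- list(); n_failed <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(boot_seeds[b])
    draw <- rmultinom(1, obs_size, probs)[, 1]
    counts <- matrix(0, nrow(gen$probs), ncol(gen$probs))
    counts[cells] <- draw
    obs_b <- jsfs(counts, folded = gen$folded,
                  n_sites = fit$obs_summary$n_sites)
    # common refit seed across replicates: replicate-to-replicate variation
    # then reflects only the multinomial resampling, not refit noise
    s_b <- settings
    s_b$seed <- seed
    f <- tryCatch(fit_model(obs_b, fit$model_id, s_b, fixed = fit$fixed,
                            control = control),
                  error = function(e) NULL)
    if (is.null(f)) { n_failed <- n_failed + 1L; next }
    est[[length(est) + 1L]] <- unclass(f$params)
  }
  if (n_failed > failure_budget * n_boot)
    stop(sprintf("%d of %d bootstrap refits failed (budget %.0f%%)",
                 n_failed, n_boot, 100 * failure_budget), call. = FALSE)
  if (!length(est)) stop("no successful bootstrap refit", call. = FALSE)
  tab <- do.call(rbind, est)
  used <- names(fit$free)
  full_used <- intersect(colnames(tab),
                         c("N_anc", "N_west", "N_east", "T_div", "T_contact",
                           "m_EW", "m_WE"))
  keep <- full_used[apply(tab[, full_used, drop = FALSE], 2,
                          function(v) any(v != 0)) |
                      full_used %in% c("N_anc", "N_west", "N_east", "T_div")]
  summ <- data.frame(
    param = keep,
    mean = colMeans(tab[, keep, drop = FALSE]),
    lo = apply(tab[, keep, drop = FALSE], 2, quantile, probs = 0.025),
    hi = apply(tab[, keep, drop = FALSE], 2, quantile, probs = 0.975),
    row.names = NULL)
  structure(list(summary = summ, replicates = as.data.frame(tab),
                 n_boot = n_boot, n_failed = n_failed, seed = seed,
                 model_id = fit$model_id, point = unclass(fit$params)),
            class = "im_bootstrap")
}

#' @export
print.im_bootstrap <- function(x, ...) {
  cat(sprintf("Parametric bootstrap for %s: %d replicates (%d failed)\n",
              x$model_id, x$n_boot, x$n_failed))
  print(x$summary, digits = 6)
  invisible(x)
}

#' Write bootstrap outputs
#' @param bs An `im_bootstrap`.
#' @param tsv_path,json_path Output files (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_bootstrap <- function(bs, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(bs$replicates, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path)) {
    out <- setNames(lapply(seq_len(nrow(bs$summary)), function(i)
      list(mean = bs$summary$mean[i], lo = bs$summary$lo[i],
           hi = bs$summary$hi[i])), bs$summary$param)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}
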