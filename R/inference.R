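# Composite-likelihood fitting of demographic models to an observed joint
# SFS, and AIC-based model selection across the ten-model ledger.
#
# The optimizer mirrors the cycle structure of SFS-simulation fitters:
# each replicate starts from a random point in the (log10) search box and
# performs n_cycles conditional-maximization cycles, each a bounded
# golden-section 1-D search per free parameter.  Within a replicate the
# coalescent simulation seed is fixed (common random numbers), so the Monte
# Carlo likelihood surface is deterministic and the 1-D searches are
# well-posed.

#' Composite log-likelihood of an observed joint SFS
#'
#' Multinomial composite log-likelihood `sum m_ij * log p_ij` over unmasked
#' cells, with `p` the floored, renormalized expected cell probabilities.
#' Monomorphic corners never contribute.
#'
#' @param obs A [jsfs()].
#' @param expected An [expected_jsfs()] of matching shape and folding.
#' @return Log-likelihood (natural log).
#' @export
composite_loglik <- function(obs, expected) {
  stopifnot(inherits(obs, "jsfs"), inherits(expected, "expected_jsfs"))
  if (!all(dim(obs$counts) == dim(expected$probs)))
    stop("observed and expected SFS shapes differ", call. = FALSE)
  if (isTRUE(obs$folded) != isTRUE(expected$folded))
    stop("folding of observed and expected SFS differs", call. = FALSE)
  m <- obs$counts; p <- expected$probs
  sel <- !obs$mask & m > 0
  if (any(p[sel] <= 0))
    stop("expected spectrum has zero probability where data are observed; ",
         "apply a cell-probability floor", call. = FALSE)
  sum(m[sel] * log(p[sel]))
}

#' Saturated (maximum observable) log-likelihood of a joint SFS
#'
#' The multinomial log-likelihood of the observed spectrum under cell
#' probabilities equal to the observed relative frequencies:
#' `sum m_ij * log(m_ij / M)`.  This is the best composite log-likelihood
#' any model could attain on these data.
#'
#' @param obs A [jsfs()].
#' @return Log-likelihood (natural log).
#' @export
max_obs_loglik <- function(obs) {
  stopifnot(inherits(obs, "jsfs"))
  m <- obs$counts[!obs$mask]
  M <- sum(m)
  if (M <= 0) stop("empty spectrum", call. = FALSE)
  m <- m[m > 0]
  sum(m * log(m / M))
}

# Draw a random starting point (named vector) uniform in log10 bounds,
# respecting T_contact < T_div.
.random_start <- function(free) {
  x <- setNames(10^runif(nrow(free), log10(free$lower), log10(free$upper)),
                free$name)
  if (all(c("T_contact", "T_div") %in% names(x)) &&
      x[["T_contact"]] >= x[["T_div"]])
    x[["T_contact"]] <- 10^runif(1, log10(free$lower[free$name == "T_contact"]),
                                 log10(x[["T_div"]] * 0.999))
  x
}

# Golden-section maximization of f over [lo, hi] using exactly n_evals
# evaluations; returns the best point seen (including optional known point).
.golden_max <- function(f, lo, hi, n_evals, x0 = NULL, f0 = -Inf) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  best_x <- if (f1 >= f2) x1 else x2
  best_f <- max(f1, f2)
  used <- 2L
  while (used < n_evals) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
      if (f1 > best_f) { best_f <- f1; best_x <- x1 }
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
      if (f2 > best_f) { best_f <- f2; best_x <- x2 }
    }
    used <- used + 1L
  }
  if (!is.null(x0) && f0 > best_f) list(x = x0, f = f0)
  else list(x = best_x, f = best_f)
}

# Rescale a parameter vector along the exact invariance ridge of the
# polymorphism-conditioned SFS (sizes and times * a, migration rates / a) so
# that the expected SNP yield mu * n_sites * E[total tree length] matches
# the observed SNP count.  Clipped so every free parameter stays in bounds.
.calibrate_scale <- function(x, free, a_target) {
  scale_up <- c("N_anc", "N_west", "N_east", "T_div", "T_contact")
  scale_dn <- c("m_EW", "m_WE", "m_sym")
  a_lo <- 0; a_hi <- Inf
  for (r in seq_len(nrow(free))) {
    nm <- free$name[r]
    if (nm %in% scale_up) {
      a_lo <- max(a_lo, free$lower[r] / x[[nm]])
      a_hi <- min(a_hi, free$upper[r] / x[[nm]])
    } else if (nm %in% scale_dn) {
      a_lo <- max(a_lo, x[[nm]] / free$upper[r])
      a_hi <- min(a_hi, x[[nm]] / free$lower[r])
    }
  }
  a <- min(max(a_target, a_lo), a_hi)
  for (nm in names(x)) {
    if (nm %in% scale_up) x[[nm]] <- x[[nm]] * a
    if (nm %in% scale_dn) x[[nm]] <- x[[nm]] / a
  }
  x
}

#' Fit one demographic model to an observed joint SFS
#'
#' Runs `settings$n_reps` independent replicate optimizations and returns the
#' replicate with the smallest gap `delta = lnL_obs - lnL_est` between the
#' saturated log-likelihood and the maximized composite log-likelihood
#' (ties resolve to the lower replicate index).
#'
#' When the observed spectrum carries `n_sites` (total surveyed sites) the
#' fit anchors the absolute parameter scale after every cycle by rescaling
#' along the size/time/migration invariance ridge so that the expected SNP
#' yield `mu * n_sites * E[tree length]` equals the observed SNP count.
#' Without `n_sites` (and with no fixed parameter) only relative parameters
#' are identified by a polymorphism-only spectrum, and a warning is issued.
#'
#' @param obs A [jsfs()].
#' @param model_id One of `model_ids()`.
#' @param settings An [inference_settings()] list.
#' @param fixed Optional named vector of parameters to hold fixed (removed
#'   from the search).
#' @param control List of optimizer knobs: `golden_evals` (evaluations per
#'   1-D search, default 8), `bracket0`/`bracket_decay`/`bracket_min`
#'   (log10 half-width schedule of the per-cycle search bracket, defaults
#'   4, 0.75, 0.2), `calibrate` (logical, default `TRUE`).
#' @return A list of class `im_fit`: fitted `params`, `lnL_est`, `lnL_obs`,
#'   `delta`, `AIC`, `k`, `n_evals`, `replicate`, `seed`, `converged`,
#'   per-replicate table `replicates`, plus echoes of settings and data
#'   summaries.
#' @export
fit_model <- function(obs, model_id, settings = inference_settings(),
                      fixed = NULL, control = list()) {
  stopifnot(inherits(obs, "jsfs"))
  .check_model_id(model_id)
  ctl <- utils::modifyList(list(golden_evals = 8L, bracket0 = 4,
                                bracket_decay = 0.75, bracket_min = 0.2,
                                calibrate = TRUE), control)
  free_all <- free_parameters(model_id)
  k <- nrow(free_all)
  free <- free_all[!free_all$name %in% names(fixed), , drop = FALSE]
  if (nrow(free) == 0) stop("no free parameters left", call. = FALSE)
  lnL_obs <- max_obs_loglik(obs)
  S <- jsfs_total(obs)
  calibrate <- isTRUE(ctl$calibrate) && !is.null(obs$n_sites) &&
    is.null(fixed)
  if (is.null(obs$n_sites) && is.null(fixed))
    warning("observed SFS has no n_sites and no parameter is fixed: ",
            "absolute sizes and times are only weakly identified",
            call. = FALSE)
  config <- sample_config(obs$n[1], obs$n[2])

  set.seed(settings$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, settings$n_reps)
  starts <- replicate(settings$n_reps, .random_start(free), simplify = FALSE)

  eval_counter <- 0L
  make_obj <- function(sim_seed, fixed_vals) {
    function(x_free) {
      params <- expand_free(model_id, c(x_free, fixed_vals))
      model <- build_model(model_id, params, settings)
      eval_counter <<- eval_counter + 1L
      exp_sfs <- expected_jsfs(model, config, n_sims = settings$n_sims,
                               settings = settings, seed = sim_seed)
      list(ll = composite_loglik(obs, exp_sfs),
           etot = exp_sfs$mean_total_length)
    }
  }

  reps <- vector("list", settings$n_reps)
  for (rep in seq_len(settings$n_reps)) {
    x <- starts[[rep]]
    obj <- make_obj(rep_seeds[rep], fixed)
    cur <- tryCatch(obj(x), error = function(e) NULL)
    if (is.null(cur)) { reps[[rep]] <- NULL; next }
    if (calibrate) {
      a <- S / (settings$mu * obs$n_sites * cur$etot)
      x <- .calibrate_scale(x, free, a)
      cur <- obj(x)
    }
    for (cycle in seq_len(settings$n_cycles)) {
      w <- max(ctl$bracket_min, ctl$bracket0 * ctl$bracket_decay^cycle)
      for (r in seq_len(nrow(free))) {
        nm <- free$name[r]
        lo <- log10(free$lower[r]); hi <- log10(free$upper[r])
        lo <- max(lo, log10(x[[nm]]) - w); hi <- min(hi, log10(x[[nm]]) + w)
        # ordering constraint between the two times
        if (nm == "T_contact" && "T_div" %in% names(x))
          hi <- min(hi, log10(x[["T_div"]]) - 1e-3)
        if (nm == "T_div" && "T_contact" %in% names(x))
          lo <- max(lo, log10(x[["T_contact"]]) + 1e-3)
        if (hi <= lo) next
        f1d <- function(lx) {
          xt <- x; xt[[nm]] <- 10^lx
          obj(xt)$ll
        }
        gr <- .golden_max(f1d, lo, hi, ctl$golden_evals,
                          x0 = log10(x[[nm]]), f0 = cur$ll)
        if (gr$f > cur$ll) {
          x[[nm]] <- 10^gr$x
          cur <- obj(x)   # refresh ll and expected tree length at new point
        }
      }
      if (calibrate) {
        a <- S / (settings$mu * obs$n_sites * cur$etot)
        x <- .calibrate_scale(x, free, a)
        cur <- obj(x)
      }
    }
    reps[[rep]] <- list(x = x, lnL_est = cur$ll,
                        delta = lnL_obs - cur$ll, seed = rep_seeds[rep])
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok))
    stop("optimization failed in every replicate for ", model_id,
         call. = FALSE)
  deltas <- vapply(reps, function(r) if (is.null(r)) Inf else r$delta,
                   numeric(1))
  best_i <- which.min(deltas)   # ties: lowest index
  best <- reps[[best_i]]
  params <- expand_free(model_id, c(best$x, fixed))
  rep_tab <- data.frame(
    replicate = which(ok),
    lnL_est = vapply(reps[ok], `[[`, numeric(1), "lnL_est"),
    delta = vapply(reps[ok], `[[`, numeric(1), "delta"),
    seed = vapply(reps[ok], `[[`, numeric(1), "seed"))
  structure(list(model_id = model_id, params = params,
                 free = setNames(as.numeric(best$x), names(best$x)),
                 fixed = fixed,
                 lnL_est = best$lnL_est, lnL_obs = lnL_obs,
                 delta = best$delta, AIC = 2 * k - 2 * best$lnL_est, k = k,
                 n_evals = eval_counter, replicate = best_i,
                 seed = settings$seed, converged = is.finite(best$lnL_est),
                 replicates = rep_tab, settings = settings,
                 obs_summary = list(S = S, n = obs$n, n_sites = obs$n_sites,
                                    folded = obs$folded)),
            class = "im_fit")
}

#' @export
print.im_fit <- function(x, ...) {
  cat(sprintf("Model %s fit: lnL_est = %.3f, lnL_obs = %.3f, delta = %.3f, AIC = %.3f\n",
              x$model_id, x$lnL_est, x$lnL_obs, x$delta, x$AIC))
  print(round(unclass(x$params), 8))
  invisible(x)
}

#' Akaike weights from a vector of AIC values
#'
#' `w_m = exp(-dAIC_m / 2) / sum_k exp(-dAIC_k / 2)` with
#' `dAIC_m = AIC_m - min(AIC)`.
#'
#' @param aic Numeric vector of AIC values.
#' @return Weights in `[0, 1]` summing to 1.
#' @export
akaike_weights <- function(aic) {
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit and rank a set of candidate models by AIC
#'
#' Fits every model in `ids`, computes `AIC = 2k - 2 lnL_est` (natural log),
#' AIC differences and Akaike weights
#' `w_m = exp(-dAIC_m/2) / sum exp(-dAIC/2)`.
#'
#' @param obs A [jsfs()].
#' @param ids Character vector of model identifiers (default all ten).
#' @param settings An [inference_settings()] list; each model's fit derives
#'   its seed deterministically from `settings$seed`.
#' @param control Passed to [fit_model()].
#' @return A list of class `model_selection`: `fits` (named list of
#'   `im_fit`), `table` (data frame with lnL, delta, AIC, dAIC, weight),
#'   `best` (identifier of the AIC-best model), `failed` (identifiers whose
#'   fit failed, excluded from the table).
#' @export
select_models <- function(obs, ids = model_ids(),
                          settings = inference_settings(), control = list()) {
  stopifnot(length(ids) >= 1)
  fits <- list(); failed <- character()
  for (i in seq_along(ids)) {
    id <- .check_model_id(ids[i])
    s_i <- settings
    s_i$seed <- as.integer((settings$seed + 7919 * i) %% .Machine$integer.max)
    f <- tryCatch(fit_model(obs, id, s_i, control = control),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warning("fit failed for ", id, ": ", conditionMessage(f), call. = FALSE)
      failed <- c(failed, id)
    } else fits[[id]] <- f
  }
  if (!length(fits)) stop("all model fits failed", call. = FALSE)
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  daic <- aic - min(aic)
  w <- akaike_weights(aic)
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    lnL_est = vapply(fits, `[[`, numeric(1), "lnL_est"),
                    lnL_obs = vapply(fits, `[[`, numeric(1), "lnL_obs"),
                    delta = vapply(fits, `[[`, numeric(1), "delta"),
                    AIC = aic, dAIC = daic, weight = w,
                    row.names = NULL)
  tab <- tab[order(tab$AIC), ]
  structure(list(fits = fits, table = tab, best = tab$model[1],
                 failed = failed, settings = settings),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection over", nrow(x$table), "candidate models (best:",
      x$best, ")\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' Write a model-selection table to TSV
#' @param sel A `model_selection`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_selection_tsv <- function(sel, path) {
  write.table(sel$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit (or selection) to JSON
#' @param x An `im_fit` or `model_selection`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  if (inherits(x, "im_fit")) {
    out <- list(model = x$model_id, params = as.list(unclass(x$params)),
                lnL_est = x$lnL_est, lnL_obs = x$lnL_obs, delta = x$delta,
                AIC = x$AIC, k = x$k, replicate = x$replicate,
                seed = x$seed,
                settings = unclass(x$settings))
  } else {
    out <- list(best = x$best, table = x$table,
                seed = x$settings$seed)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
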