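# Demographic model ledger: ten variants of the two-population
# isolation-migration model, their free parameters and search bounds, and
# construction of the executable epoch description used by the simulator.

# Migration-timing regimes and directions per model identifier.  "recent"
# means gene flow only on [0, T_contact) (secondary contact); "ancient"
# means gene flow only on [T_contact, T_div) (migration that later ceased);
# "continuous" means gene flow on the whole of [0, T_div).
.MODEL_LEDGER <- list(
  M1  = list(timing = "none",       direction = "none"),
  M2  = list(timing = "continuous", direction = "sym"),
  M3  = list(timing = "continuous", direction = "WE"),
  M4  = list(timing = "continuous", direction = "EW"),
  M5  = list(timing = "ancient",    direction = "sym"),
  M6  = list(timing = "recent",     direction = "both"),
  M7  = list(timing = "recent",     direction = "WE"),
  M8  = list(timing = "recent",     direction = "EW"),
  M9  = list(timing = "ancient",    direction = "WE"),
  M10 = list(timing = "ancient",    direction = "EW")
)

.PARAM_BOUNDS <- list(
  N_anc     = c(1e2, 1e8),
  N_west    = c(1e2, 1e8),
  N_east    = c(1e2, 1e8),
  T_div     = c(1e2, 1e7),   # years
  T_contact = c(1e2, 1e7),   # years; additionally constrained < T_div
  m_EW      = c(1e-9, 1e-3), # per-generation probabilities
  m_WE      = c(1e-9, 1e-3),
  m_sym     = c(1e-9, 1e-3)
)

#' Model identifiers of the ten isolation-migration variants
#' @return Character vector `c("M1", ..., "M10")`.
#' @export
model_ids <- function() names(.MODEL_LEDGER)

.check_model_id <- function(model_id) {
  if (!is.character(model_id) || length(model_id) != 1 ||
      !model_id %in% names(.MODEL_LEDGER))
    stop("unknown model id: ", paste(model_id, collapse = ","), call. = FALSE)
  model_id
}

#' Demographic parameters of a two-population history
#'
#' Bundles the seven quantities describing a two-deme isolation-migration
#' history: three diploid effective sizes, two times in years before present,
#' and two per-generation migration probabilities.  `m_EW` is the probability
#' of migration of the eastern lineage into the western lineage (forward in
#' time); equivalently, a lineage sampled in the west traces back into the
#' east with this probability per generation.  `m_WE` is the reverse.
#'
#' @param N_anc,N_west,N_east Diploid effective sizes (ancestral, western,
#'   eastern).
#' @param T_div Divergence time, years before present.
#' @param T_contact Time at which the migration regime changes, years before
#'   present; must satisfy `0 <= T_contact < T_div`.  Ignored by models
#'   without a regime change.
#' @param m_EW,m_WE Migration probabilities per generation (see above).
#' @return A named numeric vector of class `model_params`.
#' @export
model_params <- function(N_anc, N_west, N_east, T_div,
                         T_contact = 0, m_EW = 0, m_WE = 0) {
  p <- c(N_anc = unname(N_anc), N_west = unname(N_west),
         N_east = unname(N_east), T_div = unname(T_div),
         T_contact = unname(T_contact), m_EW = unname(m_EW),
         m_WE = unname(m_WE))
  if (any(!is.finite(p))) stop("non-finite parameter", call. = FALSE)
  if (any(p[c("N_anc", "N_west", "N_east")] <= 0))
    stop("effective sizes must be positive", call. = FALSE)
  if (p["T_div"] <= 0) stop("T_div must be positive", call. = FALSE)
  if (p["T_contact"] < 0 || p["m_EW"] < 0 || p["m_WE"] < 0)
    stop("negative time or migration probability", call. = FALSE)
  if (p["m_EW"] >= 1 || p["m_WE"] >= 1)
    stop("migration probabilities must be < 1", call. = FALSE)
  structure(p, class = "model_params")
}

#' Best-supported reference history for the Eurasian water strider system
#'
#' Point estimates of the secondary-contact history (model `M6`) used as the
#' package's reference parameterization: a deep west/east split followed by
#' recent bidirectional gene flow, with a large western deme, a much smaller
#' eastern deme and a small ancestral deme.
#'
#' @return A `model_params` vector.
#' @export
reference_history <- function() {
  model_params(N_anc = 5666, N_west = 7024866, N_east = 549728,
               T_div = 383708, T_contact = 2870,
               m_EW = 1.2e-6, m_WE = 3.6e-7)
}

#' Settings governing SFS simulation and composite-likelihood optimization
#'
#' @param mu Mutation rate per site per generation.
#' @param gen_time Generation time in years.
#' @param n_sims Coalescent simulations per expected-SFS evaluation.
#' @param n_cycles Conditional-maximization cycles per optimization replicate.
#' @param n_reps Independent replicate optimizations per model.
#' @param seed Integer seed; `NULL` draws one from the session RNG.
#' @param folded Logical; fit folded (minor-allele) spectra.
#' @param min_cell_prob Probability floor for empty expected cells; default
#'   `1 / (10 * n_sims * n_unmasked_cells)`, applied at evaluation time.
#' @return A list of class `inference_settings`.
#' @export
inference_settings <- function(mu = 3.5e-9, gen_time = 0.5,
                               n_sims = 50000L, n_cycles = 40L,
                               n_reps = 50L, seed = NULL,
                               folded = FALSE, min_cell_prob = NULL) {
  stopifnot(mu > 0, gen_time > 0, n_sims >= 1, n_cycles >= 1, n_reps >= 1)
  if (!is.null(min_cell_prob))
    stopifnot(min_cell_prob > 0, min_cell_prob < 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  structure(list(mu = mu, gen_time = gen_time, n_sims = as.integer(n_sims),
                 n_cycles = as.integer(n_cycles), n_reps = as.integer(n_reps),
                 seed = as.integer(seed), folded = folded,
                 min_cell_prob = min_cell_prob),
            class = "inference_settings")
}

#' Convert years before present to generations
#' @param t_years Nonnegative time in years.
#' @param settings An [inference_settings()] list (uses `gen_time`).
#' @return Time in generations, `t_years / gen_time`.
#' @export
years_to_generations <- function(t_years, settings) {
  if (any(t_years < 0)) stop("negative time", call. = FALSE)
  t_years / settings$gen_time
}

#' Free parameters and search bounds of a model
#'
#' Returns the search-space ledger for one model identifier: parameter names,
#' lower and upper bounds, and whether the 1-D searches operate on a log10
#' scale (they do, for every parameter).  Symmetric-migration models expose a
#' single shared rate `m_sym` that sets both directions.
#'
#' @param model_id One of `model_ids()`.
#' @return A data frame with columns `name`, `lower`, `upper`, `log10`.
#' @export
free_parameters <- function(model_id) {
  .check_model_id(model_id)
  led <- .MODEL_LEDGER[[model_id]]
  nm <- c("N_anc", "N_west", "N_east", "T_div")
  if (led$timing %in% c("recent", "ancient")) nm <- c(nm, "T_contact")
  nm <- c(nm, switch(led$direction,
                     none = character(),
                     sym  = "m_sym",
                     WE   = "m_WE",
                     EW   = "m_EW",
                     both = c("m_EW", "m_WE")))
  b <- do.call(rbind, .PARAM_BOUNDS[nm])
  data.frame(name = nm, lower = b[, 1], upper = b[, 2], log10 = TRUE,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Expand a named vector over a model's free parameters (possibly using
# m_sym) into a full model_params vector, zero-filling unused fields.
expand_free <- function(model_id, x) {
  led <- .MODEL_LEDGER[[.check_model_id(model_id)]]
  get0x <- function(nm) if (nm %in% names(x)) unname(x[[nm]]) else 0
  m_ew <- m_we <- 0
  if (led$direction == "sym") m_ew <- m_we <- get0x("m_sym")
  if (led$direction %in% c("WE", "both")) m_we <- get0x("m_WE")
  if (led$direction %in% c("EW", "both")) m_ew <- get0x("m_EW")
  model_params(N_anc = get0x("N_anc"), N_west = get0x("N_west"),
               N_east = get0x("N_east"), T_div = get0x("T_div"),
               T_contact = get0x("T_contact"), m_EW = m_ew, m_WE = m_we)
}

#' Build the executable epoch description of a model
#'
#' Translates a model identifier plus parameter values into the
#' piecewise-constant two-deme history consumed by the coalescent engine:
#' epoch boundaries in generations (ascending), per-epoch deme sizes and
#' backward migration rates, and a merge event at the divergence time moving
#' all lineages into the ancestral deme.
#'
#' Backward-rate convention: the forward migration probability `m_EW`
#' (eastern lineage into western) becomes the backward rate at which lineages
#' currently in the western deme jump to the eastern deme, and conversely for
#' `m_WE`.  This is the single place where the label-to-rate mapping lives.
#'
#' @param model_id One of `model_ids()`.
#' @param params A [model_params()] vector supplying the fields the model
#'   uses.
#' @param settings An [inference_settings()] list (uses `gen_time`).
#' @return A list of class `demographic_model`.
#' @export
build_model <- function(model_id, params, settings = inference_settings()) {
  led <- .MODEL_LEDGER[[.check_model_id(model_id)]]
  p <- params
  need_tc <- led$timing %in% c("recent", "ancient")
  if (need_tc && p[["T_contact"]] >= p[["T_div"]])
    stop("T_contact must be strictly less than T_div", call. = FALSE)
  td <- years_to_generations(p[["T_div"]], settings)
  tc <- if (need_tc) years_to_generations(p[["T_contact"]], settings) else 0
  mw_on <- p[["m_EW"]]   # backward rate for west-deme lineages
  me_on <- p[["m_WE"]]   # backward rate for east-deme lineages
  # assemble epochs [start, next start) up to the ancestral epoch [td, Inf)
  if (led$timing == "none" || led$timing == "continuous") {
    on <- led$timing == "continuous"
    starts <- c(0, td)
    mw <- c(if (on) mw_on else 0, 0)
    me <- c(if (on) me_on else 0, 0)
  } else if (led$timing == "recent") {
    starts <- c(0, tc, td); mw <- c(mw_on, 0, 0); me <- c(me_on, 0, 0)
  } else { # ancient
    starts <- c(0, tc, td); mw <- c(0, mw_on, 0); me <- c(0, me_on, 0)
  }
  Nw <- c(rep(p[["N_west"]], length(starts) - 1), p[["N_anc"]])
  Ne <- c(rep(p[["N_east"]], length(starts) - 1), p[["N_anc"]])
  # drop zero-length epochs (e.g. T_contact == 0)
  keep <- c(diff(starts) > 0, TRUE)
  starts <- starts[keep]; Nw <- Nw[keep]; Ne <- Ne[keep]
  mw <- mw[keep]; me <- me[keep]
  # canonicalize: merge an epoch into its predecessor when nothing changes
  # at the boundary (e.g. migration set to zero), so that e.g. a recent-
  # contact model with zero rates is indistinguishable from isolation only
  merge_at <- length(starts)
  keep <- rep(TRUE, length(starts))
  for (e in seq_along(starts)[-1]) {
    if (e == merge_at) next
    prev <- max(which(keep[1:(e - 1)]))
    if (Nw[e] == Nw[prev] && Ne[e] == Ne[prev] &&
        mw[e] == mw[prev] && me[e] == me[prev]) keep[e] <- FALSE
  }
  starts <- starts[keep]; Nw <- Nw[keep]; Ne <- Ne[keep]
  mw <- mw[keep]; me <- me[keep]
  structure(list(model_id = model_id, demes = c("west", "east", "ancestral"),
                 starts = starts, N_west = Nw, N_east = Ne,
                 m_west = mw, m_east = me,
                 merge_epoch = length(starts),  # 1-based epoch index
                 T_div_gen = td, gen_time = settings$gen_time,
                 params = p),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Two-deme demographic model", x$model_id, "\n")
  ends <- c(x$starts[-1], Inf)
  for (e in seq_along(x$starts)) {
    anc <- e >= x$merge_epoch
    cat(sprintf("  [%g, %g) gen: %s\n", x$starts[e], ends[e],
                if (anc) sprintf("ancestral deme N=%g", x$N_west[e])
                else sprintf("N_w=%g N_e=%g m_w->e=%g m_e->w=%g",
                             x$N_west[e], x$N_east[e], x$m_west[e],
                             x$m_east[e])))
  }
  invisible(x)
}

#' Export a model as fastsimcoal-style parameter text
#'
#' Human-readable `.par`-like export of a built model (not intended to be
#' bit-compatible with any external tool).
#'
#' @param model A `demographic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_par <- function(model, path) {
  p <- model$params
  lines <- c(
    "//Number of population samples (demes)", "2",
    "//Population effective sizes (diploid)",
    as.character(round(p[["N_west"]])), as.character(round(p[["N_east"]])),
    "//Migration matrix 0 (backward rates, recent epoch)",
    sprintf("0 %g", model$m_west[1]), sprintf("%g 0", model$m_east[1]),
    "//historical events: time source sink migrants newSize newGrowth migMatrix",
    sprintf("%g 0 0 0 1 0 1", model$starts[min(2, length(model$starts))]),
    sprintf("%g 1 0 1 %g 0 1", model$T_div_gen,
            p[["N_anc"]] / p[["N_west"]]))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize model choice and parameters to a YAML block
#' @param model_id Model identifier.
#' @param params A `model_params` vector.
#' @param path Optional output file; if `NULL` the YAML string is returned.
#' @return YAML string (invisibly if written to file).
#' @export
write_model_yaml <- function(model_id, params, path = NULL) {
  y <- yaml::as.yaml(list(model = model_id, params = as.list(unclass(params))))
  if (!is.null(path)) { writeLines(y, path); return(invisible(y)) }
  y
}

#' Read a model + parameter YAML block
#' @param path File path or YAML string.
#' @return List with `model_id` and `params`.
#' @export
read_model_yaml <- function(path) {
  y <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  list(model_id = .check_model_id(y$model),
       params = do.call(model_params, y$params))
}
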