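# R-side interface to the structured-coalescent engine: single-genealogy
# simulation, branch-class accumulation across many genealogies, and
# normalized expected joint-SFS probabilities.

#' Sample configuration for a two-deme simulation
#' @param n_west,n_east Haploid sample sizes in the western and eastern deme.
#' @return A list of class `sample_config`.
#' @export
sample_config <- function(n_west, n_east) {
  n_west <- as.integer(n_west); n_east <- as.integer(n_east)
  if (n_west < 0 || n_east < 0 || n_west + n_east < 2)
    stop("need at least 2 sampled lineages in total", call. = FALSE)
  structure(list(n_west = n_west, n_east = n_east), class = "sample_config")
}

.model_cpp_args <- function(model) {
  list(starts = as.numeric(model$starts),
       Nw = as.numeric(model$N_west), Ne = as.numeric(model$N_east),
       mw = as.numeric(model$m_west), me = as.numeric(model$m_east),
       merge_epoch = as.integer(model$merge_epoch - 1L))
}

#' Simulate one structured-coalescent genealogy
#'
#' Event times are drawn from competing exponential clocks for within-deme
#' coalescence and per-lineage migration; epoch boundaries and the merge into
#' the ancestral deme act as deterministic time barriers.
#'
#' @param model A `demographic_model` from [build_model()].
#' @param config A [sample_config()].
#' @param seed Optional integer seed.
#' @return A list of class `genealogy` with a per-branch table (`length` in
#'   generations, descendant counts `i` in the west and `j` in the east; the
#'   root branch is excluded), the `total_length`, and the tree as an
#'   [ape::phylo] object (tip labels `w1..`, `e1..`).
#' @export
simulate_genealogy <- function(model, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- .model_cpp_args(model)
  g <- cpp_simulate_genealogy(a$starts, a$Nw, a$Ne, a$mw, a$me, a$merge_epoch,
                              config$n_west, config$n_east)
  n <- g$n_tips
  branches <- data.frame(length = g$edge_length, i = g$edge_i, j = g$edge_j)
  # C++ ids: tips 0..n-1, internal nodes n..2n-2 in creation order (root
  # last).  ape wants tips 1..n and root n+1, so reverse the internal order.
  map <- function(id) ifelse(id < n, id + 1L, n + 1L + (2L * n - 2L - id))
  edge <- cbind(map(g$edge_parent), map(g$edge_child))
  phy <- structure(list(edge = edge, edge.length = g$edge_length,
                        tip.label = c(if (config$n_west > 0)
                                        paste0("w", seq_len(config$n_west)),
                                      if (config$n_east > 0)
                                        paste0("e", seq_len(config$n_east))),
                        Nnode = n - 1L),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy)
  structure(list(branches = branches, total_length = g$total_length,
                 tree = phy, config = config),
            class = "genealogy")
}

#' Write a simulated genealogy to newick
#' @param genealogy A `genealogy` from [simulate_genealogy()].
#' @param path Output file; branch lengths are in generations.
#' @return `path`, invisibly.
#' @export
write_genealogy_newick <- function(genealogy, path) {
  ape::write.tree(genealogy$tree, file = path)
  invisible(path)
}

#' Accumulate expected joint-SFS branch-class totals
#'
#' Simulates `n_sims` genealogies and accumulates, for every descendant-count
#' class `(i, j)`, the total branch length carried by branches of that class
#' (root branch excluded).  Relative class totals estimate the probability
#' that a polymorphic site falls in each joint-SFS cell under the
#' infinite-sites model.
#'
#' @param model A `demographic_model`.
#' @param config A [sample_config()].
#' @param n_sims Number of genealogies.
#' @param seed Optional integer seed; identical seeds give identical totals.
#' @return A list of class `branch_class_totals`: `totals` matrix
#'   (`(n_west+1) x (n_east+1)`), `n_sims`, `mean_total_length` (mean per
#'   genealogy, generations).
#' @export
accumulate_expected_jsfs <- function(model, config, n_sims, seed = NULL) {
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- .model_cpp_args(model)
  r <- cpp_accumulate_jsfs(a$starts, a$Nw, a$Ne, a$mw, a$me, a$merge_epoch,
                           config$n_west, config$n_east, as.integer(n_sims))
  structure(list(totals = r$totals, n = c(config$n_west, config$n_east),
                 n_sims = r$n_sims,
                 mean_total_length = r$sum_length / r$n_sims),
            class = "branch_class_totals")
}

#' Expected joint-SFS cell probabilities under a model
#'
#' Normalizes branch-class totals into per-cell probabilities conditioned on
#' polymorphism, flooring empty cells at `min_cell_prob` and renormalizing so
#' unmasked cells sum to 1.  The monomorphic corners `(0,0)` and
#' `(n_west, n_east)` are masked and carry zero probability.
#'
#' @param model A `demographic_model` (or a precomputed
#'   `branch_class_totals` in which case `config`/`n_sims` are ignored).
#' @param config A [sample_config()].
#' @param n_sims Simulations used for the approximation.
#' @param settings An [inference_settings()] list; supplies `min_cell_prob`
#'   and `folded`.
#' @param seed Optional integer seed.
#' @return A list of class `expected_jsfs` with `probs`, `n`, `folded`,
#'   `n_sims`, `floor`, `mean_total_length`, `model_id`, `params`.
#' @export
expected_jsfs <- function(model, config = NULL, n_sims = NULL,
                          settings = inference_settings(), seed = NULL) {
  if (inherits(model, "branch_class_totals")) {
    acc <- model
    model_id <- NA_character_; params <- NULL
  } else {
    acc <- accumulate_expected_jsfs(model, config,
                                    n_sims %||% settings$n_sims, seed)
    model_id <- model$model_id; params <- model$params
  }
  tot <- acc$totals
  nw1 <- nrow(tot); ne1 <- ncol(tot)
  mask <- matrix(FALSE, nw1, ne1)
  mask[1, 1] <- TRUE; mask[nw1, ne1] <- TRUE
  if (isTRUE(settings$folded)) {
    tot <- .fold_matrix(tot)
    foldable <- .folded_away(nw1 - 1L, ne1 - 1L)
    mask <- mask | foldable
  }
  s <- sum(tot[!mask])
  if (s <= 0) stop("no branch length accumulated in unmasked cells",
                   call. = FALSE)
  p <- tot / s
  floor_p <- settings$min_cell_prob %||% (1 / (10 * acc$n_sims * sum(!mask)))
  p[!mask] <- pmax(p[!mask], floor_p)
  p[mask] <- 0
  p <- p / sum(p)
  structure(list(probs = p, n = acc$n, folded = isTRUE(settings$folded),
                 n_sims = acc$n_sims, floor = floor_p,
                 mean_total_length = acc$mean_total_length,
                 model_id = model_id, params = params),
            class = "expected_jsfs")
}
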