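# Supporting population-genetic statistics: per-population diversity,
# hierarchical AMOVA with permutation tests, Mantel tests and great-circle
# distances.

#' Per-population diversity statistics
#'
#' For each population (and each lineage aggregate, when a lineage map is
#' present): `H_O`, the mean fraction of heterozygous genotypes among
#' non-missing calls; `H_E`, the unbiased expected heterozygosity
#' `(2n/(2n-1)) * 2*p*(1-p)` averaged over loci (`n` = diploid genotypes
#' observed at the locus); and `pi_S`, the mean proportion of pairwise
#' allele differences per SNP site.  All statistics are computed over the
#' retained (variable) loci only.
#'
#' @param geno A [genotype_matrix()].
#' @return A list of class `diversity_result` with data frames `populations`
#'   and (when lineages are mapped) `lineages`.
#' @export
diversity <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  one_set <- function(G) {
    nmiss <- colSums(!is.na(G))
    if (any(nmiss == 0))
      stop("a population has no genotyped individual at some locus",
           call. = FALSE)
    het <- colSums(G == 1, na.rm = TRUE) / nmiss
    p <- colSums(G, na.rm = TRUE) / (2 * nmiss)
    he <- ifelse(nmiss > 0 & 2 * nmiss > 1,
                 (2 * nmiss / (2 * nmiss - 1)) * 2 * p * (1 - p), 0)
    # pi per SNP: mean pairwise difference proportion over allele pairs
    c0 <- 2 * nmiss - colSums(G, na.rm = TRUE)
    c1 <- colSums(G, na.rm = TRUE)
    m <- 2 * nmiss
    pis <- ifelse(m > 1, c0 * c1 / (m * (m - 1) / 2), 0)
    c(H_O = mean(het), H_E = mean(he), pi_S = mean(pis))
  }
  pops <- sort(unique(geno$popmap))
  ptab <- t(vapply(pops, function(p)
    one_set(geno$G[geno$popmap == p, , drop = FALSE]), numeric(3)))
  out <- list(populations = data.frame(population = pops, ptab,
                                       row.names = NULL))
  if (!is.null(geno$lineages)) {
    lin_of_ind <- geno$lineages[geno$popmap]
    lins <- sort(unique(stats::na.omit(lin_of_ind)))
    ltab <- t(vapply(lins, function(l)
      one_set(geno$G[which(lin_of_ind == l), , drop = FALSE]), numeric(3)))
    out$lineages <- data.frame(lineage = lins, ltab, row.names = NULL)
  }
  structure(out, class = "diversity_result")
}

# Sums of squares from squared pairwise distances: for a set S,
# SS(S) = sum_{i<j in S} d2_ij / |S| (equal to the squared deviations from
# the centroid when d2 is squared Euclidean).
.ss_sets <- function(d2, f) {
  f <- as.character(f)
  lv <- unique(f)
  M <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
  pair2 <- colSums((d2 %*% M) * M)     # 2 * within-set pairwise sums
  sum(pair2 / (2 * colSums(M)))
}

.amova_components <- function(d2, pop, grp_of_pop) {
  pops <- unique(pop)
  grp <- grp_of_pop[pop]
  groups <- unique(grp_of_pop)
  N <- nrow(d2); P <- length(pops); G <- length(groups)
  ss_total <- sum(d2) / (2 * N)
  ss_wp <- .ss_sets(d2, factor(pop))
  ss_wg <- .ss_sets(d2, factor(grp))
  ss_ag <- ss_total - ss_wg          # among groups
  ss_ap <- ss_wg - ss_wp             # among populations within groups
  n_p <- table(pop)[pops]
  N_g <- vapply(groups, function(g) sum(grp == g), numeric(1))
  sum_np2_by_g <- vapply(groups, function(g) {
    pg <- pops[grp_of_pop[pops] == g]
    sum(n_p[pg]^2) / sum(n_p[pg])
  }, numeric(1))
  df_a <- G - 1; df_b <- P - G; df_c <- N - P
  n1 <- (N - sum(sum_np2_by_g)) / df_b
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_a
  n3 <- (N - sum(N_g^2) / N) / df_a
  ms_a <- if (df_a > 0) ss_ag / df_a else NA_real_
  ms_b <- if (df_b > 0) ss_ap / df_b else NA_real_
  ms_c <- if (df_c > 0) ss_wp / df_c else NA_real_
  s2_c <- ms_c
  s2_b <- if (df_b > 0) (ms_b - s2_c) / n1 else 0
  s2_a <- if (df_a > 0) (ms_a - s2_c - n2 * s2_b) / n3 else 0
  tot <- s2_a + s2_b + s2_c
  list(sigma2 = c(among_groups = s2_a, among_pops_within = s2_b,
                  within_pops = s2_c),
       phi = c(PHI_CT = if (tot != 0) s2_a / tot else NaN,
               PHI_SC = if ((s2_b + s2_c) != 0) s2_b / (s2_b + s2_c) else NaN,
               PHI_ST = if (tot != 0) (s2_a + s2_b) / tot else NaN),
       ss = c(among_groups = ss_ag, among_pops_within = ss_ap,
              within_pops = ss_wp, total = ss_total),
       df = c(df_a, df_b, df_c))
}

#' Hierarchical analysis of molecular variance
#'
#' Partitions genotypic variance (squared Euclidean distances on allele
#' dosage vectors, missing entries imputed at the locus mean; or any
#' user-supplied distance matrix) among groups, among populations within
#' groups, and within populations, with Phi-statistics and permutation
#' p-values: populations are permuted among groups for `PHI_CT`,
#' individuals among populations within groups for `PHI_SC`, and
#' individuals among all populations for `PHI_ST`.  P-values use the
#' add-one convention `p = (1 + #(perm >= obs)) / (n_perm + 1)`.
#'
#' @param geno A [genotype_matrix()], or a square individual-by-individual
#'   distance matrix (a `dist` or matrix, in which case `popmap` is
#'   required).
#' @param groups Named character vector population -> group.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional integer seed for the permutations.
#' @param popmap Population label per individual; only used for distance
#'   input.
#' @return A list of class `amova_result`: `sigma2`, `phi`, `p_values`,
#'   `ss`, `df`, `n_perm`, and a `degenerate` flag when all individuals are
#'   identical (Phi reported as `NaN`).
#' @export
amova <- function(geno, groups, n_perm = 5000, seed = NULL, popmap = NULL) {
  if (inherits(geno, "genotype_matrix")) {
    pop <- geno$popmap
    X <- geno$G
    # locus-mean imputation for missing entries
    if (anyNA(X)) {
      mu <- colMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 2]]
    }
    d2 <- as.matrix(stats::dist(X))^2
  } else {
    if (is.null(popmap))
      stop("popmap is required with distance input", call. = FALSE)
    d2 <- as.matrix(geno)^2
    pop <- as.character(popmap)
  }
  pops <- unique(pop)
  if (length(pops) < 2) stop("need at least two populations", call. = FALSE)
  if (!all(pops %in% names(groups)))
    stop("every population must be assigned to a group", call. = FALSE)
  grp_of_pop <- groups[pops]
  single_group <- length(unique(grp_of_pop)) < 2
  obs <- .amova_components(d2, pop, grp_of_pop)
  degenerate <- obs$ss["total"] == 0
  if (!is.null(seed)) set.seed(seed)
  p_values <- c(PHI_CT = NA_real_, PHI_SC = NA_real_, PHI_ST = NA_real_)
  if (!degenerate && n_perm > 0) {
    ge_ct <- ge_sc <- ge_st <- 0L
    for (b in seq_len(n_perm)) {
      # PHI_ST: individuals among all populations
      st <- .amova_components(d2, sample(pop), grp_of_pop)
      if (!is.nan(st$phi["PHI_ST"]) &&
          st$phi["PHI_ST"] >= obs$phi["PHI_ST"] - 1e-12) ge_st <- ge_st + 1L
      # PHI_SC: individuals among populations within their group
      pop_sc <- pop
      for (g in unique(grp_of_pop)) {
        sel <- grp_of_pop[pop] == g
        pop_sc[sel] <- sample(pop[sel])
      }
      sc <- .amova_components(d2, pop_sc, grp_of_pop)
      if (!is.nan(sc$phi["PHI_SC"]) &&
          sc$phi["PHI_SC"] >= obs$phi["PHI_SC"] - 1e-12) ge_sc <- ge_sc + 1L
      # PHI_CT: whole populations among groups
      if (!single_group) {
        g_perm <- setNames(sample(grp_of_pop), names(grp_of_pop))
        ct <- .amova_components(d2, pop, g_perm)
        if (!is.nan(ct$phi["PHI_CT"]) &&
            ct$phi["PHI_CT"] >= obs$phi["PHI_CT"] - 1e-12) ge_ct <- ge_ct + 1L
      }
    }
    p_values <- c(PHI_CT = if (single_group) NA_real_ else
                    (1 + ge_ct) / (n_perm + 1),
                  PHI_SC = (1 + ge_sc) / (n_perm + 1),
                  PHI_ST = (1 + ge_st) / (n_perm + 1))
  }
  structure(list(sigma2 = obs$sigma2, phi = obs$phi, p_values = p_values,
                 ss = obs$ss, df = obs$df, n_perm = n_perm,
                 degenerate = degenerate),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA\n")
  print(data.frame(component = names(x$sigma2), sigma2 = x$sigma2,
                   pct = 100 * x$sigma2 / sum(x$sigma2), row.names = NULL),
        digits = 5)
  print(data.frame(statistic = names(x$phi), value = x$phi,
                   p = x$p_values[names(x$phi)], row.names = NULL),
        digits = 5)
  invisible(x)
}

#' Labeled distance matrix
#' @param m Square symmetric numeric matrix with zero diagonal.
#' @param labels Optional row/column labels.
#' @return A validated matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric", call. = FALSE)
  if (any(diag(m) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(m < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (!is.null(labels)) rownames(m) <- colnames(m) <- labels
  structure(m, class = c("dist_matrix", "matrix"))
}

#' Mantel test of association between two distance matrices
#'
#' `r` is the Pearson correlation over the upper-triangle entries; the
#' permutation test simultaneously permutes rows and columns of `B` and the
#' one-tailed p-value (positive association) uses the add-one convention.
#' With `exact = TRUE` all `n!` label permutations are enumerated and the
#' p-value is the exact fraction of permutations whose statistic is at
#' least the observed one (the identity permutation included).
#'
#' @param A,B Square symmetric matrices with matching labels.
#' @param n_perm Number of random permutations (ignored when `exact`).
#' @param exact Logical; enumerate all permutations (feasible for n <= 8).
#' @param seed Optional integer seed.
#' @return A list of class `mantel_result` with `r`, `p`, `n_perm`.
#' @export
mantel <- function(A, B, n_perm = 999, exact = FALSE, seed = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("dimension mismatch", call. = FALSE)
  if (!is.null(rownames(A)) && !is.null(rownames(B))) {
    if (!all(rownames(A) == rownames(B)))
      stop("matrix labels differ", call. = FALSE)
  }
  ut <- upper.tri(A)
  a <- A[ut]
  if (sd(a) == 0 || sd(B[ut]) == 0) {
    return(structure(list(r = NaN, p = NA_real_, n_perm = 0,
                          flag = "constant matrix"),
                     class = "mantel_result"))
  }
  r_obs <- cor(a, B[ut])
  n <- nrow(A)
  r_perm_fun <- function(ord) cor(a, B[ord, ord][ut])
  if (exact) {
    perms <- .permutations(n)
    rs <- apply(perms, 1, r_perm_fun)
    p <- mean(rs >= r_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm))
      if (r_perm_fun(sample.int(n)) >= r_obs - 1e-12) ge <- ge + 1L
    p <- (1 + ge) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances in kilometres on a sphere of radius 6371 km.
#'
#' @param coords Data frame with columns `lat` and `lon` in decimal degrees
#'   (optionally a label column `site` used for matrix labels).
#' @return A `dist_matrix` in km.
#' @export
geo_distances <- function(coords) {
  if (!all(c("lat", "lon") %in% names(coords)))
    stop("coords needs 'lat' and 'lon' columns", call. = FALSE)
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
    stop("coordinates out of range", call. = FALSE)
  xy <- cbind(coords$lon, coords$lat)
  m <- geosphere::distm(xy, xy,
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371000))
  m <- m / 1000
  diag(m) <- 0
  dist_matrix((m + t(m)) / 2,
              labels = if ("site" %in% names(coords)) coords$site else NULL)
}
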