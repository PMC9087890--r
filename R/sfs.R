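# Observed joint site-frequency spectra: construction from genotypes,
# hypergeometric projection, folding, and text serialization in dadi-style
# and fastsimcoal-style dialects.

#' Construct a joint SFS object
#'
#' @param counts Numeric matrix of dimension `(n_west+1) x (n_east+1)`;
#'   entry `[i+1, j+1]` counts sites with `i` derived (or minor) copies in
#'   the west and `j` in the east.  Fractional counts (from projection) are
#'   allowed.
#' @param folded Logical; `TRUE` for a minor-allele spectrum.
#' @param n_sites Optional total number of surveyed sites (monomorphic
#'   included).  When present it lets the fitter anchor the absolute
#'   parameter scale through the mutation rate; the monomorphic corner cells
#'   themselves never enter the composite likelihood.
#' @return A list of class `jsfs` with `counts`, `n` (haploid sample sizes),
#'   `folded`, `mask` (logical matrix; masked cells are excluded from all
#'   totals) and optional `n_sites`.
#' @export
jsfs <- function(counts, folded = FALSE, n_sites = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and nonnegative", call. = FALSE)
  nw <- nrow(counts) - 1L; ne <- ncol(counts) - 1L
  mask <- matrix(FALSE, nw + 1L, ne + 1L)
  mask[1, 1] <- TRUE; mask[nw + 1L, ne + 1L] <- TRUE
  if (folded) mask <- mask | .folded_away(nw, ne)
  structure(list(counts = counts, n = c(west = nw, east = ne),
                 folded = folded, mask = mask, n_sites = n_sites),
            class = "jsfs")
}

#' @export
print.jsfs <- function(x, ...) {
  cat(sprintf("Joint SFS (%s), samples (%d, %d), %.6g sites in %d unmasked cells\n",
              if (x$folded) "folded" else "unfolded",
              x$n[1], x$n[2], jsfs_total(x), sum(!x$mask)))
  invisible(x)
}

#' Total mass over unmasked cells
#' @param x A `jsfs`.
#' @return Numeric scalar.
#' @export
jsfs_total <- function(x) sum(x$counts[!x$mask])

# Cells that a fold maps onto another cell (donors).  Pair of (i,j) is
# (nw-i, ne-j); the member with the smaller total count i+j receives the
# mass; equal-total non-self pairs resolve to the smaller i.
.fold_receiver <- function(nw, ne) {
  recv <- matrix(TRUE, nw + 1L, ne + 1L)
  for (i in 0:nw) for (j in 0:ne) {
    i2 <- nw - i; j2 <- ne - j
    if (i == i2 && j == j2) next
    tot1 <- i + j; tot2 <- i2 + j2
    if (tot1 > tot2 || (tot1 == tot2 && i > i2)) recv[i + 1L, j + 1L] <- FALSE
  }
  recv
}

.folded_away <- function(nw, ne) !.fold_receiver(nw, ne)

.fold_matrix <- function(m) {
  nw <- nrow(m) - 1L; ne <- ncol(m) - 1L
  recv <- .fold_receiver(nw, ne)
  out <- matrix(0, nw + 1L, ne + 1L)
  for (i in 0:nw) for (j in 0:ne) {
    ti <- if (recv[i + 1L, j + 1L]) c(i, j) else c(nw - i, ne - j)
    out[ti[1] + 1L, ti[2] + 1L] <- out[ti[1] + 1L, ti[2] + 1L] + m[i + 1L, j + 1L]
  }
  out
}

#' Fold a joint SFS onto minor-allele classes
#'
#' Cell `(i, j)` is merged with `(n_west - i, n_east - j)`; the member with
#' the smaller total count receives the mass and self-paired central cells
#' are unchanged.
#'
#' @param x An unfolded `jsfs`.
#' @return A folded `jsfs`.
#' @export
fold_jsfs <- function(x) {
  stopifnot(inherits(x, "jsfs"))
  if (x$folded) stop("spectrum is already folded", call. = FALSE)
  out <- jsfs(.fold_matrix(x$counts), folded = TRUE, n_sites = x$n_sites)
  out
}

#' Project a joint SFS down to smaller sample sizes
#'
#' Each unit of mass at `i` derived copies among `n` sampled alleles is
#' spread over target classes by the hypergeometric probability of drawing
#' `a` derived copies in a subsample of the target size, independently per
#' deme.  Mass landing on the monomorphic corners is dropped and reported.
#'
#' @param x An unfolded `jsfs`.
#' @param target Integer vector `c(n_west, n_east)` of target haploid sizes,
#'   each between 2 and the source size.
#' @return A `jsfs` at the target sizes with attribute `mass_lost` (mass
#'   dropped onto the monomorphic corners).
#' @export
project_jsfs <- function(x, target) {
  stopifnot(inherits(x, "jsfs"))
  if (x$folded) stop("project before folding", call. = FALSE)
  target <- as.integer(target)
  if (length(target) != 2 || any(target < 2) || any(target > x$n))
    stop("target sizes must satisfy 2 <= target <= source", call. = FALSE)
  nw <- x$n[1]; ne <- x$n[2]; mw <- target[1]; me <- target[2]
  # per-deme projection kernels: K[[d]][i+1, a+1] = P(a | i, n_d -> m_d)
  Kw <- outer(0:nw, 0:mw, function(i, a) dhyper(a, i, nw - i, mw))
  Ke <- outer(0:ne, 0:me, function(j, b) dhyper(b, j, ne - j, me))
  out <- t(Kw) %*% x$counts %*% Ke
  res <- jsfs(out, folded = FALSE, n_sites = x$n_sites)
  # mass lost = unmasked input mass minus unmasked output mass
  attr(res, "mass_lost") <- max(0, jsfs_total(x) - jsfs_total(res))
  res
}

#' Genotype matrix with population and lineage maps
#'
#' @param G Integer matrix, individuals x loci, entries 0/1/2 (count of
#'   non-reference alleles) or `NA` for missing.
#' @param popmap Character vector of population labels, one per individual
#'   (named by individual or in row order).
#' @param lineages Named character vector mapping population -> lineage
#'   (`"west"`/`"east"`, or any two labels; `"admixed"` populations are
#'   excluded from lineage-based spectra).
#' @return A list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, popmap, lineages = NULL) {
  G <- as.matrix(G)
  if (is.null(rownames(G))) rownames(G) <- paste0("ind", seq_len(nrow(G)))
  if (is.null(colnames(G))) colnames(G) <- paste0("locus", seq_len(ncol(G)))
  if (!all(G %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  if (length(popmap) != nrow(G))
    stop("popmap length must match individuals", call. = FALSE)
  structure(list(G = G, ids = rownames(G), loci = colnames(G),
                 popmap = setNames(as.character(popmap), rownames(G)),
                 lineages = lineages),
            class = "genotype_matrix")
}

#' Build an observed joint SFS from genotypes
#'
#' Each retained locus contributes one unit of mass: per-locus allele counts
#' are taken over non-missing genotypes in each lineage and, when `project`
#' is given, spread by hypergeometric projection to the fixed target sizes
#' (loci with fewer non-missing alleles than the target are dropped).  Loci
#' monomorphic in the pooled sample are excluded.
#'
#' @param geno A [genotype_matrix()].
#' @param grouping Named character vector population -> lineage with exactly
#'   two lineages (defaults to `geno$lineages`); populations mapped to other
#'   values (e.g. `"admixed"`) are ignored.
#' @param polarized Logical; if `FALSE` the spectrum is folded.
#' @param project Optional haploid target sizes `c(n_west, n_east)`.
#' @return A `jsfs`; attributes `n_dropped` (loci dropped for insufficient
#'   call rate), `n_monomorphic` (excluded monomorphic loci) and `mass_lost`.
#' @export
jsfs_from_genotypes <- function(geno, grouping = NULL, polarized = TRUE,
                                project = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  grouping <- grouping %||% geno$lineages
  if (is.null(grouping)) stop("no lineage grouping supplied", call. = FALSE)
  lin_of_ind <- grouping[geno$popmap]
  lins <- intersect(unique(lin_of_ind), setdiff(grouping, "admixed"))
  lins <- lins[!is.na(lins) & lins != "admixed"]
  if (length(lins) != 2)
    stop("grouping must yield exactly two non-admixed lineages", call. = FALSE)
  west <- which(lin_of_ind == lins[1]); east <- which(lin_of_ind == lins[2])
  if (length(west) == 0 || length(east) == 0)
    stop("empty lineage", call. = FALSE)
  Gw <- geno$G[west, , drop = FALSE]; Ge <- geno$G[east, , drop = FALSE]
  dw <- colSums(Gw, na.rm = TRUE); nw_obs <- 2L * colSums(!is.na(Gw))
  de <- colSums(Ge, na.rm = TRUE); ne_obs <- 2L * colSums(!is.na(Ge))
  poly <- (dw + de) > 0 & (dw + de) < (nw_obs + ne_obs)
  n_mono <- sum(!poly)
  tw <- if (is.null(project)) max(nw_obs) else as.integer(project[1])
  te <- if (is.null(project)) max(ne_obs) else as.integer(project[2])
  ok <- poly & nw_obs >= tw & ne_obs >= te
  n_drop <- sum(poly & !ok)
  counts <- matrix(0, tw + 1L, te + 1L)
  for (l in which(ok)) {
    pw <- dhyper(0:tw, dw[l], nw_obs[l] - dw[l], tw)
    pe <- dhyper(0:te, de[l], ne_obs[l] - de[l], te)
    counts <- counts + outer(pw, pe)
  }
  out <- jsfs(counts, folded = FALSE)
  lost <- sum(ok) - jsfs_total(out)
  if (!polarized) out <- fold_jsfs(out)
  attr(out, "n_dropped") <- n_drop
  attr(out, "n_monomorphic") <- n_mono
  attr(out, "mass_lost") <- max(0, lost)
  attr(out, "lineage_order") <- lins
  out
}

#' Read and write joint SFS text files
#'
#' Two dialects are supported.  `"dadi"`: a header line
#' `"<nrow> <ncol> <folded|unfolded>"`, one line of cell values in row-major
#' order, and a mask line of 0/1 flags in the same order.  `"obs"`: a
#' fastsimcoal-style table with `1 observations` on the first line, a header
#' of eastern-class labels and one labeled row per western class.
#'
#' @param x A `jsfs` (for writing).
#' @param path File path.
#' @param dialect `"dadi"` or `"obs"`.
#' @return `read_jsfs` returns a `jsfs`; `write_jsfs` returns `path`
#'   invisibly.
#' @export
write_jsfs <- function(x, path, dialect = c("dadi", "obs")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "jsfs"))
  if (dialect == "dadi") {
    hdr <- sprintf("%d %d %s", nrow(x$counts), ncol(x$counts),
                   if (x$folded) "folded" else "unfolded")
    if (!is.null(x$n_sites)) hdr <- paste(hdr, sprintf("sites=%.17g", x$n_sites))
    vals <- as.vector(t(x$counts))     # row-major
    msk <- as.integer(as.vector(t(x$mask)))
    writeLines(c(hdr, paste(format(vals, digits = 17), collapse = " "),
                 paste(msk, collapse = " ")), path)
  } else {
    hdr <- "1 observations"
    if (!is.null(x$n_sites)) hdr <- paste(hdr, sprintf("sites=%.17g", x$n_sites))
    col_lab <- paste0("d0_", 0:(ncol(x$counts) - 1L))
    rows <- vapply(seq_len(nrow(x$counts)), function(i)
      paste(c(paste0("d1_", i - 1L),
              format(x$counts[i, ], digits = 17)), collapse = "\t"),
      character(1))
    writeLines(c(hdr, paste(c("", col_lab), collapse = "\t"), rows), path)
  }
  invisible(path)
}

#' @rdname write_jsfs
#' @export
read_jsfs <- function(path, dialect = c("dadi", "obs")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  get_sites <- function(s) {
    m <- regmatches(s, regexpr("sites=[0-9.eE+-]+", s))
    if (length(m)) as.numeric(sub("sites=", "", m)) else NULL
  }
  if (dialect == "dadi") {
    if (length(lines) < 3) stop("malformed dadi SFS file", call. = FALSE)
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    nr <- as.integer(hdr[1]); nc <- as.integer(hdr[2])
    if (is.na(nr) || is.na(nc) || !hdr[3] %in% c("folded", "unfolded"))
      stop("malformed dadi SFS header", call. = FALSE)
    vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
    if (length(vals) != nr * nc)
      stop("SFS shape inconsistent with header", call. = FALSE)
    counts <- matrix(vals, nr, nc, byrow = TRUE)
    jsfs(counts, folded = hdr[3] == "folded", n_sites = get_sites(lines[1]))
  } else {
    if (length(lines) < 3 || !grepl("observation", lines[1]))
      stop("malformed .obs SFS file", call. = FALSE)
    nc <- length(strsplit(lines[2], "\t")[[1]]) - 1L
    body <- lines[-(1:2)]
    body <- body[nzchar(trimws(body))]
    rows <- lapply(body, function(s) strsplit(s, "\t")[[1]])
    counts <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(nc)))
    if (any(!is.finite(counts)))
      stop("SFS shape inconsistent with header", call. = FALSE)
    jsfs(counts, folded = FALSE, n_sites = get_sites(lines[1]))
  }
}

#' Read genotypes from a VCF plus population map
#'
#' Biallelic SNP records only (multiallelic records are rejected); `"."`
#' genotypes are treated as missing.  Positions are 1-based and the GT field
#' must be diploid.
#'
#' @param vcf_path Path to an (uncompressed or gzipped) VCF.
#' @param popmap_path Two-column TSV (individual, population), no header.
#' @param lineage_path Optional two-column TSV (population, lineage).
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(vcf_path, popmap_path, lineage_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop("multiallelic records are not supported", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(a, function(x) {
      if (length(x) != 2 || any(x == ".")) return(NA_integer_)
      sum(as.integer(x))
    }, integer(1))
  }
  G <- t(apply(gt, 1, dose))           # loci x individuals
  G <- t(G)                            # individuals x loci
  rownames(G) <- colnames(gt)
  colnames(G) <- rownames(gt)
  pm <- read.table(popmap_path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  pop <- setNames(pm[[2]], pm[[1]])
  if (!all(rownames(G) %in% names(pop)))
    stop("popmap is missing individuals present in the VCF", call. = FALSE)
  lin <- NULL
  if (!is.null(lineage_path)) {
    lt <- read.table(lineage_path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    lin <- setNames(lt[[2]], lt[[1]])
  }
  genotype_matrix(G, pop[rownames(G)], lin)
}
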