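# Synthetic ddRAD-like data generation: unlinked biallelic loci sampled one
# SNP per locus from structured-coalescent genealogies under a chosen
# demographic history, with optional admixed populations, uniform
# missingness, and coordinate/environment tables laid on a west-east
# gradient.

#' Specification of a synthetic ddRAD-like dataset
#'
#' Defaults emulate the shape of the empirical unlinked-SNP dataset the
#' package's reference system was built from: 1,179 unlinked biallelic loci
#' (one SNP each), about 3% missing genotypes, two diverged lineages plus
#' two admixed populations, under the [reference_history()] secondary-contact
#' model.
#'
#' @param model_id Model identifier for the generating history.
#' @param params A [model_params()] vector.
#' @param pops Data frame with columns `name`, `n` (diploid individuals),
#'   `lineage` (`"west"`, `"east"` or `"admixed"`), and optionally `alpha`
#'   (western ancestry proportion for admixed populations).
#' @param n_loci Number of unlinked loci.
#' @param locus_length Locus length in bp (used for positions and for the
#'   implied total-site count).
#' @param missing_rate Uniform genotype missingness rate (0 to 0.2).
#' @param settings An [inference_settings()] list (mutation rate and
#'   generation time).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model_id = "M6", params = reference_history(),
                           pops = NULL, n_loci = 1179L, locus_length = 300L,
                           missing_rate = 0.03,
                           settings = inference_settings()) {
  if (is.null(pops)) {
    pops <- data.frame(
      name = c(paste0("W", 1:5), paste0("E", 1:5), "ADM1", "ADM2"),
      n = 10L,
      lineage = c(rep("west", 5), rep("east", 5), "admixed", "admixed"),
      alpha = c(rep(NA_real_, 10), 0.5, 0.5))
  }
  if (!"alpha" %in% names(pops)) pops$alpha <- NA_real_
  stopifnot(n_loci >= 1, missing_rate >= 0, missing_rate <= 0.2,
            all(pops$lineage %in% c("west", "east", "admixed")),
            all(is.na(pops$alpha) | (pops$alpha >= 0 & pops$alpha <= 1)))
  if (any(pops$lineage == "admixed" & is.na(pops$alpha)))
    stop("admixed populations need an alpha", call. = FALSE)
  structure(list(model_id = model_id, params = params, pops = pops,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 missing_rate = missing_rate, settings = settings),
            class = "synthetic_spec")
}

#' Generate a synthetic ddRAD-like dataset
#'
#' For every locus one genealogy is simulated for the union of all sampled
#' haplotypes and a single mutation is placed on a branch chosen
#' proportionally to its length (equivalent to retaining one SNP sampled
#' uniformly among the locus's segregating sites).  Each haplotype of an
#' admixed individual descends from the western lineage with probability
#' `alpha` and the eastern lineage otherwise, independently per locus.
#' Missing genotypes are masked uniformly at `missing_rate`; loci
#' monomorphic after masking are redrawn (count reported).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_dataset`: `geno`
#'   ([genotype_matrix()]), `coords` and `env` data frames, `spec`,
#'   `n_redrawn`, and `n_sites` (implied total surveyed sites,
#'   `n_loci * locus_length`).
#' @export
generate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  pops <- spec$pops
  n_ind <- sum(pops$n)
  ind_pop <- rep(pops$name, pops$n)
  ind_lin <- rep(pops$lineage, pops$n)
  ind_alpha <- rep(pops$alpha, pops$n)
  ids <- unlist(lapply(seq_len(nrow(pops)), function(i)
    paste0(pops$name[i], "_", seq_len(pops$n[i]))))
  n_hap <- 2L * n_ind
  hap_lin <- rep(ind_lin, each = 2)
  hap_alpha <- rep(ind_alpha, each = 2)
  model <- build_model(spec$model_id, spec$params, spec$settings)
  a <- .model_cpp_args(model)

  sim_block <- function(n_loci_blk) {
    deme <- matrix(0L, n_hap, n_loci_blk)
    deme[hap_lin == "east", ] <- 1L
    adm <- which(hap_lin == "admixed")
    if (length(adm))
      deme[adm, ] <- matrix(
        rbinom(length(adm) * n_loci_blk, 1L,
               rep(1 - hap_alpha[adm], n_loci_blk)),
        length(adm), n_loci_blk)
    der <- cpp_sim_loci(a$starts, a$Nw, a$Ne, a$mw, a$me, a$merge_epoch, deme)
    G <- der[seq(1, n_hap, 2), , drop = FALSE] +
      der[seq(2, n_hap, 2), , drop = FALSE]
    if (spec$missing_rate > 0) {
      miss <- matrix(runif(n_ind * n_loci_blk) < spec$missing_rate,
                     n_ind, n_loci_blk)
      G[miss] <- NA_integer_
    }
    G
  }

  G <- sim_block(spec$n_loci)
  mono <- function(G) {
    cs <- colSums(G, na.rm = TRUE)
    nm <- 2 * colSums(!is.na(G))
    cs == 0 | cs == nm | nm == 0
  }
  n_redrawn <- 0L
  budget <- 50L
  while (any(bad <- mono(G)) && budget > 0L) {
    n_redrawn <- n_redrawn + sum(bad)
    G[, bad] <- sim_block(sum(bad))
    budget <- budget - 1L
  }
  if (any(mono(G)))
    stop("could not obtain the requested number of polymorphic loci",
         call. = FALSE)
  rownames(G) <- ids
  colnames(G) <- paste0("locus", seq_len(spec$n_loci))
  lineages <- setNames(pops$lineage, pops$name)
  geno <- genotype_matrix(G, ind_pop, lineages)
  # coordinates: longitudinal gradient (west 0-60 E, east 90-130 E), jittered
  base_lon <- ifelse(pops$lineage == "west",
                     seq(0, 60, length.out = nrow(pops)),
                     ifelse(pops$lineage == "east",
                            seq(90, 130, length.out = nrow(pops)), 75))
  coords <- data.frame(site = pops$name,
                       lon = base_lon + runif(nrow(pops), -3, 3),
                       lat = 45 + runif(nrow(pops), -5, 5))
  env <- data.frame(site = pops$name,
                    temp = 10 + 0.05 * coords$lon + rnorm(nrow(pops), 0, 0.5),
                    precip = 600 - 2 * coords$lon + rnorm(nrow(pops), 0, 20))
  structure(list(geno = geno, coords = coords, env = env, spec = spec,
                 n_redrawn = n_redrawn,
                 n_sites = spec$n_loci * spec$locus_length),
            class = "synthetic_dataset")
}

#' Draw a joint SFS directly from a model's expected spectrum
#'
#' Fast path for inference experiments: the expected joint SFS is
#' approximated once at high simulation count and `n_snps` unlinked SNPs are
#' drawn multinomially from it.  The returned spectrum also records the
#' implied number of surveyed sites
#' `n_sites = n_snps / (mu * E[total tree length])`, i.e. the sequence
#' length at which the generating history would be expected to yield
#' `n_snps` polymorphic sites; this is what anchors absolute parameter
#' scale when the spectrum is refitted.
#'
#' @param model_id Model identifier.
#' @param params A [model_params()] vector.
#' @param config A [sample_config()].
#' @param n_snps Number of SNPs to draw.
#' @param settings An [inference_settings()] list.
#' @param n_sims Simulations for the expected spectrum (default 200,000).
#' @param seed Integer seed.
#' @return A `jsfs` with `n_sites` set; attribute `probs` carries the
#'   generating cell probabilities.
#' @export
generate_jsfs <- function(model_id, params, config, n_snps,
                          settings = inference_settings(), n_sims = 200000L,
                          seed = NULL) {
  stopifnot(n_snps >= 1)
  model <- build_model(model_id, params, settings)
  ex <- expected_jsfs(model, config, n_sims = n_sims, settings = settings,
                      seed = seed)
  mask <- jsfs(ex$probs, folded = ex$folded)$mask
  if (!is.null(seed)) set.seed(seed + 1L)
  draw <- rmultinom(1, n_snps, ex$probs[!mask])[, 1]
  counts <- matrix(0, nrow(ex$probs), ncol(ex$probs))
  counts[which(!mask)] <- draw
  n_sites <- n_snps / (settings$mu * ex$mean_total_length)
  out <- jsfs(counts, folded = ex$folded, n_sites = n_sites)
  attr(out, "probs") <- ex$probs
  attr(out, "mean_total_length") <- ex$mean_total_length
  out
}

#' Write a synthetic dataset to disk
#'
#' Writes a plain-text VCF (biallelic SNPs, GT field), a popmap TSV
#' (individual, population), a lineage TSV (population, lineage), a
#' coordinates CSV, an environment CSV and a YAML echo of the generating
#' specification.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(ds, dir, prefix = "synth") {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(ext) file.path(dir, paste0(prefix, ext))
  G <- ds$geno$G
  n_loci <- ncol(G)
  pos <- (seq_len(n_loci) - 1L) * ds$spec$locus_length +
    ((seq_len(n_loci) * 2654435761) %% ds$spec$locus_length) + 1L
  gt <- matrix("./.", nrow = n_loci, ncol = nrow(G))
  for (i in seq_len(nrow(G))) {
    g <- G[i, ]
    gt[, i] <- c("0/0", "0/1", "1/1")[g + 1L]
    gt[is.na(g), i] <- "./."
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=imcoal synthetic ddRAD-like generator",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(n_loci), function(l)
    paste(c(colnames(G)[l], pos[l], colnames(G)[l], "A", "T", ".",
            "PASS", ".", "GT", gt[l, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), f(".vcf"))
  write.table(data.frame(ds$geno$ids, ds$geno$popmap), f(".popmap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(names(ds$geno$lineages), ds$geno$lineages),
              f(".lineages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  utils::write.csv(ds$coords, f(".coords.csv"), row.names = FALSE)
  utils::write.csv(ds$env, f(".env.csv"), row.names = FALSE)
  spec_echo <- list(model = ds$spec$model_id,
                    params = as.list(unclass(ds$spec$params)),
                    n_loci = ds$spec$n_loci,
                    locus_length = ds$spec$locus_length,
                    missing_rate = ds$spec$missing_rate,
                    n_redrawn = ds$n_redrawn, n_sites = ds$n_sites)
  writeLines(yaml::as.yaml(spec_echo), f(".spec.yaml"))
  invisible(c(vcf = f(".vcf"), popmap = f(".popmap.tsv"),
              lineages = f(".lineages.tsv"), coords = f(".coords.csv"),
              env = f(".env.csv"), spec = f(".spec.yaml")))
}
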