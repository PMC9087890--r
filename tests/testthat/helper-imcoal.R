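# Shared fixtures and utilities for the test suite.  Everything is built in
# code; heavy computations used by several acceptance checks are memoised in
# a session-level cache.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

quick_settings <- function(seed = 1, n_sims = 1000L, n_cycles = 6L,
                           n_reps = 2L) {
  inference_settings(n_sims = n_sims, n_cycles = n_cycles, n_reps = n_reps,
                     seed = seed)
}

# A small two-deme isolation history for cheap simulations.
toy_params <- function() {
  model_params(N_anc = 5e3, N_west = 2e5, N_east = 5e4, T_div = 2e5)
}

# Tiny deterministic genotype matrix: 3 populations x 4 individuals,
# dosages chosen by a seeded draw.
toy_genotypes <- function(n_pop = 3, n_per = 4, n_loci = 30, seed = 7,
                          missing = 0) {
  set.seed(seed)
  n <- n_pop * n_per
  p <- runif(n_loci, 0.1, 0.9)
  G <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (missing > 0) G[matrix(runif(n * n_loci) < missing, n, n_loci)] <- NA
  pops <- rep(paste0("P", seq_len(n_pop)), each = n_per)
  genotype_matrix(G, pops)
}

# The acceptance-scale simulation-and-selection run shared by several
# checks: 20,000 SNPs under the reference secondary-contact history,
# all ten models fitted at the reduced optimization scale.
acceptance_run <- function() {
  memo("acceptance_run", {
    seed <- 20260926L
    truth <- reference_history()
    cfg <- sample_config(10, 10)
    obs <- generate_jsfs("M6", truth, cfg, 20000,
                         inference_settings(seed = seed),
                         n_sims = 200000L, seed = seed + 1000L)
    sel <- select_models(obs, model_ids(),
                         inference_settings(n_sims = 5000L, n_cycles = 20L,
                                            n_reps = 5L, seed = seed))
    list(truth = truth, obs = obs, sel = sel,
         fit6 = sel$fits[["M6"]])
  })
}

# Run the msprime oracle (branch-mode joint AFS) through the system python;
# returns the averaged (n_w+1) x (n_e+1) spectrum.
msprime_jsfs <- function(params, n_w, n_e, n_reps, seed) {
  script <- file.path(tempdir(), "msprime_oracle.py")
  writeLines(c(
    "import json, sys",
    "import msprime",
    "import numpy as np",
    "spec = json.load(open(sys.argv[1]))",
    "p = spec['params']",
    "gen_time = 0.5",
    "dem = msprime.Demography()",
    "dem.add_population(name='W', initial_size=p['N_west'])",
    "dem.add_population(name='E', initial_size=p['N_east'])",
    "dem.add_population(name='A', initial_size=p['N_anc'])",
    "dem.set_migration_rate(source='W', dest='E', rate=p['m_EW'])",
    "dem.set_migration_rate(source='E', dest='W', rate=p['m_WE'])",
    "if p['T_contact'] > 0:",
    "    dem.add_migration_rate_change(time=p['T_contact']/gen_time, rate=0.0)",
    "dem.add_population_split(time=p['T_div']/gen_time, derived=['W','E'], ancestral='A')",
    "dem.sort_events()",
    "n_w, n_e = spec['n_w'], spec['n_e']",
    "afs = np.zeros((n_w+1, n_e+1))",
    "reps = msprime.sim_ancestry(",
    "    samples=[msprime.SampleSet(n_w, population='W', ploidy=1),",
    "             msprime.SampleSet(n_e, population='E', ploidy=1)],",
    "    demography=dem, ploidy=2, num_replicates=spec['n_reps'],",
    "    random_seed=spec['seed'])",
    "W = list(range(n_w)); E = list(range(n_w, n_w+n_e))",
    "for ts in reps:",
    "    afs += ts.allele_frequency_spectrum(sample_sets=[W, E],",
    "        mode='branch', polarised=True, span_normalise=True)",
    "json.dump((afs/spec['n_reps']).tolist(), open(sys.argv[2], 'w'))"),
    script)
  spec_f <- tempfile(fileext = ".json")
  out_f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(params = as.list(unclass(params)),
                            n_w = n_w, n_e = n_e, n_reps = n_reps,
                            seed = seed),
                       spec_f, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(script, spec_f, out_f))
  if (status != 0) stop("msprime oracle run failed")
  do.call(rbind, lapply(jsonlite::fromJSON(out_f, simplifyVector = FALSE),
                        unlist))
}
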