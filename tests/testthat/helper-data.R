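## Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# desk-scale dataset for unit tests
small_config <- function(seed = 42L) {
  sim_config(seed = seed, n_chrom = 2L, chrom_length = 3e6, n_peaks = 120L,
             n_background_ltrs = 60L, n_background_cgis = 40L,
             n_decoys_per_type = 3L)
}

small_ds <- function() cached("small_ds", simulate_dataset(small_config()))

small_ref <- function() small_ds()$reference

# the default study conditions (acceptance scale), plus its pipeline run
default_ds <- function() cached("default_ds", simulate_dataset(sim_config(seed = 7L)))

default_run <- function() cached("default_run", run_pipeline(default_ds()))

# tiny hand-rolled count table builder
make_counts <- function(region_id, mat, pat, replicate = 1L,
                        sample_id = paste0("s", replicate),
                        cross = "B6/CAST", unassigned = 0L) {
  data.frame(region_id = region_id, sample_id = sample_id,
             replicate = replicate, mat = mat, pat = pat,
             unassigned = unassigned, kind = "peak", cross = cross,
             stringsAsFactors = FALSE)
}

# minimal bias-result row for classifier tests
bias_row <- function(region_id, direction, significant = TRUE,
                     ratio = if (direction == "maternal") 0.9
                             else if (direction == "paternal") 0.1 else 0.5,
                     q = if (significant) 0.01 else 0.5,
                     cross = NA_character_) {
  data.frame(region_id = region_id, cross = cross, mat = 0, pat = 0,
             ratio = ratio, log2_ratio = 0, p = q, q = q,
             significant = significant,
             direction = if (significant) direction else "none",
             n_replicates = 2L, total_reads = 100L,
             stringsAsFactors = FALSE)
}
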