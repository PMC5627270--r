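# Shared simulated fixtures, memoised so the heavy end-to-end objects are
# built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fixture_world <- function(seed) {
  memo(paste0("world_", seed), simulate_world(sim_config(seed = seed)))
}

fixture_report <- function(seed) {
  memo(paste0("report_", seed), run_pipeline(fixture_world(seed)))
}

fixture_swapped_report <- function(seed) {
  memo(paste0("swapped_", seed), {
    w <- fixture_world(seed)
    run_pipeline(
      cfg = pipeline_config(),
      male_rna = emit_reads(w, "female", "rna", "whole"),
      female_rna = emit_reads(w, "male", "rna", "whole"),
      male_dna = emit_reads(w, "female", "genomic"),
      female_dna = emit_reads(w, "male", "genomic"),
      female_assembly = w$male_genome,
      frag_len_mean = w$cfg$frag_len_mean
    )
  })
}

fixture_scaffold_calls <- function(seed) {
  memo(paste0("calls_", seed), world_scaffold_calls(fixture_world(seed)))
}

# a light-weight world for unit tests: 3 detectable Y genes, small genome
small_cfg <- function(seed = 11,
                      y_gene_spec = ysubtract::y_gene_spec(
                        c("x_escapee", "autosomal_acquisition", "unique"),
                        divergence = c(0.2, 0.3, 0)
                      ),
                      n_background_autosomal = 4, scaffold_len = 5000, ...) {
  sim_config(
    seed = seed,
    n_autosomal_scaffolds = 3, n_x_scaffolds = 2, scaffold_len = scaffold_len,
    y_gene_spec = y_gene_spec,
    n_background_autosomal = n_background_autosomal, n_background_x = 2,
    ...
  )
}

fixture_small_world <- function() {
  memo("small_world", simulate_world(small_cfg()))
}

acceptance_seeds <- function() 101:105
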