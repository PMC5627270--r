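# End-to-end orchestration: simulate -> subtract -> sex-swap control ->
# paralog divergence -> tissue expression, with truth-based evaluation and a
# reproducibility manifest.

#' Compare called candidates against the planted truth
#'
#' Each candidate is assigned to its best-matching planted sequence (Y gene,
#' background gene, or paralog copy). A planted gene counts as recovered when
#' some candidate aligns to it over at least `min_coverage` of the gene at
#' `min_identity` identity. False positives are candidates whose best source
#' is an autosomal or X-linked gene without a Y copy.
#'
#' @param report A `filter_report`.
#' @param world The `sim_world` the report was computed from.
#' @param min_coverage,min_identity Recovery thresholds (defaults 0.9, 0.98).
#' @return List: `per_gene`, `per_candidate`, `sensitivity`,
#'   `n_false_positive`, `n_unassigned`.
#' @export
confusion_table <- function(report, world, min_coverage = 0.9,
                            min_identity = 0.98) {
  truth <- world$truth
  sources <- c(
    setNames(truth$sequence, truth$gene_id),
    setNames(world$background$sequence, world$background$gene_id),
    setNames(world$expressed$sequence[grepl("_par$", world$expressed$id)],
             world$expressed$id[grepl("_par$", world$expressed$id)])
  )
  cand <- report$candidates
  per_candidate <- tibble(candidate_id = character(0), source = character(0),
                          source_class = character(0), coverage_of_source = numeric(0),
                          identity = numeric(0))
  if (nrow(cand) > 0) {
    h <- best_local_hits(cand$sequence, sources)
    src_class <- function(id) {
      dplyr::case_when(
        is.na(id) ~ "unassigned",
        id %in% truth$gene_id ~ "y_gene",
        grepl("_par$", id) ~ "paralog",
        TRUE ~ "background"
      )
    }
    per_candidate <- tibble(
      candidate_id = cand$id,
      source = h$target_id,
      source_class = src_class(h$target_id),
      coverage_of_source = h$aln_len / nchar(sources[h$target_id]),
      identity = h$identity
    )
  }
  recovered <- vapply(truth$gene_id, function(g) {
    rows <- per_candidate[!is.na(per_candidate$source) &
                            per_candidate$source == g, , drop = FALSE]
    any(rows$coverage_of_source >= min_coverage &
          rows$identity >= min_identity)
  }, logical(1))
  per_gene <- tibble(
    gene_id = truth$gene_id, origin = truth$origin,
    detectable = truth$detectable, recovered = unname(recovered)
  )
  det <- per_gene$detectable
  list(
    per_gene = per_gene,
    per_candidate = per_candidate,
    sensitivity = if (any(det)) mean(per_gene$recovered[det]) else NA_real_,
    n_false_positive = sum(per_candidate$source_class %in%
                             c("background", "paralog")),
    n_unassigned = sum(per_candidate$source_class == "unassigned")
  )
}

#' Classify the female scaffolds of a world by coverage ratio
#'
#' Maps both sexes' genomic reads to the female assembly, computes normalized
#' coverage, and applies [classify_scaffold()].
#'
#' @param world A `sim_world`.
#' @param male_dna,female_dna Optional pre-emitted genomic read sets.
#' @param ... Passed to [classify_scaffold()].
#' @return A [classify_scaffold()] tibble.
#' @export
world_scaffold_calls <- function(world, male_dna = NULL, female_dna = NULL,
                                 ...) {
  male_dna <- male_dna %||% emit_reads(world, "male", "genomic")
  female_dna <- female_dna %||% emit_reads(world, "female", "genomic")
  mp_m <- map_reads(male_dna, world$female_genome)
  mp_f <- map_reads(female_dna, world$female_genome)
  lib_bases <- function(rd) sum(nchar(rd$mate1)) + sum(nchar(rd$mate2))
  cov <- compute_coverage(mp_m, mp_f, world$female_genome,
                          total_male_bases = lib_bases(male_dna),
                          total_female_bases = lib_bases(female_dna))
  classify_scaffold(cov, ...)
}

#' Run the complete analysis on a simulated world
#'
#' Simulates a world, runs the subtraction cascade in both sex orientations,
#' classifies scaffolds, finds paralogs with Ka/Ks for the candidates, and,
#' when the configuration includes a testis tissue, quantifies tissue TPM and
#' tests testis/accessory-gland enrichment of the recovered genes against all
#' planted genes. Writes a report bundle when `out_dir` is given.
#'
#' @param cfg A [sim_config()] (or a prebuilt `sim_world`).
#' @param pipeline A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param run_paralogs,run_expression Toggle the downstream analyses.
#' @return A `ysub_run` list: `world`, `report`, `sexswap`, `scaffold_calls`,
#'   `pairs`, `tpm`, `zscores`, `flags`, `enrichment`, `confusion`,
#'   `manifest`.
#' @export
run_full_analysis <- function(cfg = sim_config(), pipeline = pipeline_config(),
                              out_dir = NULL, run_paralogs = TRUE,
                              run_expression = TRUE) {
  world <- if (inherits(cfg, "sim_world")) cfg else simulate_world(cfg)
  cfg <- world$cfg
  swap <- sex_swap_control(world, pipeline)
  report <- swap$forward
  calls <- world_scaffold_calls(world)
  confusion <- confusion_table(report, world)

  pairs <- NULL
  if (run_paralogs && nrow(report$candidates) > 0) {
    pairs <- paralog_analysis(report$candidates, world$female_genome, calls)
  }

  tpm <- zsc <- flags <- NULL
  enrichment <- list()
  tissues <- names(cfg$rna_depth_by_tissue)
  if (run_expression && "testis" %in% tissues) {
    ex <- world$expressed
    all_records <- tibble(id = ex$id, sequence = ex$sequence,
                          length = nchar(ex$sequence))
    samples <- list()
    labels <- character(0)
    for (tis in tissues) {
      for (sex in c("male", "female")) {
        expressed_here <- any(vapply(ex$profile[ex[[sex]]], function(p) {
          isTRUE(p[[tis]] > 0)
        }, logical(1)))
        if (!expressed_here) next
        nm <- paste(sex, tis, sep = "_")
        samples[[nm]] <- emit_reads(world, sex, "rna", tis)
        labels[nm] <- tis
      }
    }
    tpm <- quantify_tpm(all_records, samples, cfg$frag_len_mean)
    zsc <- row_zscore(tpm)
    # bias flags are defined over dissected tissues, not whole body
    tissue_cols <- names(labels)[labels != "whole"]
    flags <- testis_bias_flags(tpm[, c("transcript_id", tissue_cols)],
                               labels[tissue_cols])
    y_set <- confusion$per_gene$gene_id[confusion$per_gene$recovered]
    if (length(y_set) > 0) {
      in_y <- flags$transcript_id %in% y_set
      enrichment$max_in_testis_or_gland <- binomial_enrichment(
        sum(flags$max_in_testis_or_gland[in_y]), sum(in_y),
        sum(flags$max_in_testis_or_gland), nrow(flags)
      )
      enrichment$exclusive_to_testis_and_gland <- binomial_enrichment(
        sum(flags$exclusive_to_testis_and_gland[in_y]), sum(in_y),
        sum(flags$exclusive_to_testis_and_gland), nrow(flags)
      )
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ysubtract")),
    seed = cfg$seed,
    sim_config = cfg[setdiff(names(cfg), "y_gene_spec")],
    n_y_genes = nrow(world$truth),
    pipeline_config = unclass(pipeline),
    stage_counts = report$stage_counts,
    n_candidates = nrow(report$candidates),
    sexswap = list(n_male_specific = swap$n_male_specific,
                   n_female_specific = swap$n_female_specific,
                   include_species = swap$include_species),
    sensitivity = confusion$sensitivity,
    n_false_positive = confusion$n_false_positive
  )

  run <- structure(
    list(world = world, report = report, sexswap = swap,
         scaffold_calls = calls, pairs = pairs, tpm = tpm, zscores = zsc,
         flags = flags, enrichment = enrichment, confusion = confusion,
         manifest = manifest),
    class = "ysub_run"
  )
  if (!is.null(out_dir)) write_run_bundle(run, out_dir)
  run
}

write_run_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (nrow(run$report$candidates) > 0) {
    write_fasta(setNames(run$report$candidates$sequence,
                         run$report$candidates$id), p("candidates.fasta"))
  }
  write_tsv_quiet(run$report$audit, p("audit.tsv"))
  write_tsv_quiet(run$report$stage_counts, p("stage_counts.tsv"))
  write_tsv_quiet(run$scaffold_calls, p("scaffold_classes.tsv"))
  write_tsv_quiet(run$confusion$per_gene, p("confusion.tsv"))
  if (!is.null(run$pairs)) {
    write_tsv_quiet(run$pairs, p("paralog_pairs.tsv"))
  }
  if (!is.null(run$tpm)) {
    write_tsv_quiet(run$tpm, p("tpm.tsv"))
    write_tsv_quiet(run$zscores, p("tpm_zscores.tsv"))
    write_tsv_quiet(run$flags, p("testis_flags.tsv"))
  }
  if (length(run$enrichment)) {
    jsonlite::write_json(lapply(run$enrichment, as.list), p("enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' @export
print.ysub_run <- function(x, ...) {
  cat("<ysub_run>\n")
  print(x$report)
  cat(sprintf("  sex swap: %d male-specific vs %d female-specific (include: %s)\n",
              x$sexswap$n_male_specific, x$sexswap$n_female_specific,
              x$sexswap$include_species))
  if (!is.na(x$confusion$sensitivity)) {
    cat(sprintf("  sensitivity on detectable genes: %.2f; false positives: %d\n",
                x$confusion$sensitivity, x$confusion$n_false_positive))
  }
  invisible(x)
}
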