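# The subtraction cascade: assemble male transcripts that the female genome
# cannot explain, then strip everything the female genome, female RNA,
# genomic coverage, relative expression, repeat content or effective length
# can still account for. What survives is the Y-candidate set.

#' Pipeline thresholds
#'
#' All thresholds are strict in the direction their wording implies:
#' "greater than", "less than", "50 percent or more".
#'
#' @param female_hit_len_frac Discard a transcript when more than this
#'   fraction of its length aligns to the female genome...
#' @param female_hit_identity ...at at least this identity.
#' @param min_aln_score Local alignments (matches minus mismatches) below
#'   this score are not considered hits, both against the female genome and
#'   against the repeat library.
#' @param female_rna_breadth Discard when female RNA reads cover at least
#'   this fraction of a transcript.
#' @param female_rna_max_mismatch Mismatch allowance for female RNA mapping.
#' @param merge_min_overlap Minimum suffix/prefix overlap (bp) when merging.
#' @param merge_min_identity Minimum identity within a merge overlap.
#' @param male_breadth_min Retain only transcripts with male genomic breadth
#'   above this...
#' @param female_breadth_max ...and female genomic breadth below this.
#' @param expr_ratio_min Required male/female RPKM ratio (exclusive).
#' @param eff_len_frac_min Required effective-length fraction (exclusive).
#' @param assembly_k K-mer size for transcript assembly.
#' @param genome_k K-mer size for the genomic repeat library.
#' @param sexswap_ratio_min A species is kept when it yields more than this
#'   ratio of male-specific to female-specific transcripts.
#' @param map_max_mismatch Mismatch allowance for read-to-reference and
#'   read-to-transcript mapping.
#' @param assembly_min_count Minimum k-mer multiplicity in assembly.
#' @param assembly_cleanup_ratio Relative-abundance floor for assembly k-mer
#'   cleanup (see [assemble_transcripts()]).
#' @param repeat_mult Median-multiple defining repetitive k-mers.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(female_hit_len_frac = 0.90,
                            female_hit_identity = 0.98,
                            min_aln_score = 50,
                            female_rna_breadth = 0.50,
                            female_rna_max_mismatch = 2,
                            merge_min_overlap = 30,
                            merge_min_identity = 0.95,
                            male_breadth_min = 0.60,
                            female_breadth_max = 0.10,
                            expr_ratio_min = 2.0,
                            eff_len_frac_min = 0.60,
                            assembly_k = 25,
                            genome_k = 31,
                            sexswap_ratio_min = 2.0,
                            map_max_mismatch = 2,
                            assembly_min_count = 2,
                            assembly_cleanup_ratio = 0.2,
                            repeat_mult = 10) {
  cfg <- as.list(environment())
  fracs <- c("female_hit_len_frac", "female_hit_identity", "female_rna_breadth",
             "merge_min_identity", "male_breadth_min", "female_breadth_max",
             "eff_len_frac_min")
  for (f in fracs) {
    if (!(cfg[[f]] > 0 && cfg[[f]] <= 1)) {
      abort(sprintf("pipeline_config: '%s' must lie in (0, 1]", f))
    }
  }
  for (f in c("expr_ratio_min", "sexswap_ratio_min", "min_aln_score", "repeat_mult")) {
    if (cfg[[f]] <= 0) abort(sprintf("pipeline_config: '%s' must be > 0", f))
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_stages <- function() {
  c("assembly", "female_genome", "female_rna", "merge",
    "genomic_coverage", "expression", "repeats", "effective_length")
}

# ---- per-stage pass rules (shared by the filters and refilter) -------------

pass_female_genome <- function(m, cfg) {
  hit <- !is.na(m$score) & m$score >= cfg$min_aln_score
  !(hit & m$coverage > cfg$female_hit_len_frac &
      m$identity >= cfg$female_hit_identity)
}

pass_female_rna <- function(m, cfg) !(m$breadth >= cfg$female_rna_breadth)

pass_genomic_coverage <- function(m, cfg) {
  m$breadth_male > cfg$male_breadth_min &
    m$breadth_female < cfg$female_breadth_max
}

pass_expression <- function(m, cfg) {
  m$eff_len > 0 &
    ((m$rpkm_female == 0 & m$rpkm_male > 0) |
       m$rpkm_male > cfg$expr_ratio_min * m$rpkm_female)
}

pass_repeats <- function(m, cfg) {
  !(!is.na(m$repeat_score) & m$repeat_score >= cfg$min_aln_score)
}

pass_effective_length <- function(m, cfg) {
  m$eff_len / m$length > cfg$eff_len_frac_min
}

stage_audit <- function(ids, stage, metric, value, pass) {
  tibble(id = ids, stage = stage, metric = metric, value = value, pass = pass)
}

keep_records <- function(records, pass, audit) {
  out <- records[pass, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}

# ---- exported stage filters ------------------------------------------------

#' Discard transcripts the female genome explains
#'
#' A transcript is discarded iff its best gapless local alignment to the
#' female genome covers more than `female_hit_len_frac` of its length at
#' `female_hit_identity` or better. Alignments scoring below `min_aln_score`
#' are treated as no hit, so transcripts without a qualifying hit are
#' retained.
#'
#' @param records Transcript-record tibble.
#' @param female_genome Named character vector of female scaffolds.
#' @param cfg A [pipeline_config()].
#' @return Retained records; the per-record audit is attached as
#'   `attr(, "audit")` and the measured metrics as `attr(, "metrics")`.
#' @export
filter_female_genome_hits <- function(records, female_genome,
                                      cfg = pipeline_config()) {
  h <- best_local_hits(records$sequence, female_genome)
  m <- tibble(id = records$id, score = h$score, coverage = h$coverage,
              identity = h$identity, target_id = h$target_id)
  m$coverage[is.na(m$coverage)] <- 0
  m$identity[is.na(m$identity)] <- 0
  pass <- pass_female_genome(m, cfg)
  out <- keep_records(records, pass,
                      stage_audit(records$id, "female_genome",
                                  "female_hit_coverage", m$coverage, pass))
  attr(out, "metrics") <- m
  out
}

breadth_of <- function(mappings, records) {
  vapply(seq_len(nrow(records)), function(i) {
    m <- mappings[mappings$target_id == records$id[i], , drop = FALSE]
    if (nrow(m) == 0) return(0)
    L <- records$length[i]
    ir <- IRanges::IRanges(start = m$start + 1, end = pmin(m$end, L))
    cov <- IRanges::coverage(ir, width = L)
    sum(IRanges::width(cov[cov > 0])) / L
  }, numeric(1))
}

#' Discard transcripts that female RNA-seq reads cover
#'
#' Female RNA reads are mapped to the transcripts with at most
#' `female_rna_max_mismatch` substitutions; a transcript is discarded iff the
#' covered fraction of its positions reaches `female_rna_breadth`.
#'
#' @inheritParams filter_female_genome_hits
#' @param female_rna Female RNA-seq reads (paired tibble or named character).
#' @export
filter_female_rna <- function(records, female_rna, cfg = pipeline_config()) {
  breadth <- if (nrow(records) == 0) {
    numeric(0)
  } else {
    mp <- map_reads(female_rna, setNames(records$sequence, records$id),
                    cfg$female_rna_max_mismatch)
    breadth_of(mp, records)
  }
  m <- tibble(id = records$id, breadth = breadth)
  pass <- pass_female_rna(m, cfg)
  out <- keep_records(records, pass,
                      stage_audit(records$id, "female_rna",
                                  "female_rna_breadth", breadth, pass))
  attr(out, "metrics") <- m
  out
}

#' Retain transcripts covered by male but not female genomic reads
#'
#' @inheritParams filter_female_genome_hits
#' @param coverage A [compute_coverage()] tibble holding a profile for every
#'   record (consistency error otherwise).
#' @export
filter_genomic_coverage <- function(records, coverage,
                                    cfg = pipeline_config()) {
  i <- match(records$id, coverage$target_id)
  if (anyNA(i) && nrow(records) > 0) {
    abort(sprintf("filter_genomic_coverage: no coverage profile for '%s'",
                  records$id[which(is.na(i))[1]]))
  }
  m <- tibble(id = records$id,
              breadth_male = coverage$breadth_male[i],
              breadth_female = coverage$breadth_female[i])
  pass <- pass_genomic_coverage(m, cfg)
  out <- keep_records(records, pass,
                      stage_audit(records$id, "genomic_coverage",
                                  "male_breadth", m$breadth_male, pass))
  attr(out, "metrics") <- m
  out
}

count_fragments <- function(reads, targets, max_mismatches = 2) {
  mp <- map_reads(reads, targets, max_mismatches)
  if (nrow(mp) == 0) {
    return(list(counts = setNames(rep(0, length(targets)), names(targets)),
                total = 0))
  }
  mp$fragment <- sub("/[12]$", "", mp$read_id)
  mp$mate <- ifelse(grepl("/2$", mp$read_id), 2L, 1L)
  mp <- mp[order(mp$fragment, mp$mate), , drop = FALSE]
  first <- !duplicated(mp$fragment) # mate 1 preferred
  tab <- table(mp$target_id[first])
  counts <- setNames(rep(0, length(targets)), names(targets))
  counts[names(tab)] <- as.numeric(tab)
  list(counts = counts, total = sum(first))
}

rpkm_of <- function(counts, eff_len, total) {
  ifelse(eff_len > 0 & total > 0, counts * 1e9 / (eff_len * total), 0)
}

#' Retain transcripts expressed in males beyond the female ratio
#'
#' RPKM is fragments x 1e9 / (effective length x library mapped fragments).
#' A record is retained iff male RPKM exceeds `expr_ratio_min` times female
#' RPKM; zero female RPKM with positive male RPKM retains. Records with zero
#' effective length are discarded with an audit note.
#'
#' @inheritParams filter_female_genome_hits
#' @param male_rna,female_rna RNA-seq reads per sex.
#' @param frag_len_mean Mean fragment length for the effective-length
#'   correction.
#' @export
filter_expression <- function(records, male_rna, female_rna, frag_len_mean,
                              cfg = pipeline_config()) {
  el <- effective_length(records$length, frag_len_mean)
  tg <- setNames(records$sequence, records$id)
  cm <- count_fragments(male_rna, tg, cfg$map_max_mismatch)
  cf <- count_fragments(female_rna, tg, cfg$map_max_mismatch)
  m <- tibble(
    id = records$id, length = records$length, eff_len = el,
    frags_male = unname(cm$counts), frags_female = unname(cf$counts),
    rpkm_male = unname(rpkm_of(cm$counts, el, cm$total)),
    rpkm_female = unname(rpkm_of(cf$counts, el, cf$total))
  )
  pass <- pass_expression(m, cfg)
  value <- ifelse(m$rpkm_female > 0, m$rpkm_male / m$rpkm_female,
                  ifelse(m$rpkm_male > 0, Inf, 0))
  out <- keep_records(records, pass,
                      stage_audit(records$id, "expression",
                                  "expression_ratio", value, pass))
  attr(out, "metrics") <- m
  out
}

#' Discard transcripts matching a genomic repeat library
#'
#' The repeat library is assembled from high-multiplicity genomic k-mers
#' ([repeat_library()]); a transcript is discarded iff any local alignment to
#' a library contig scores at least `min_aln_score`.
#'
#' @inheritParams filter_female_genome_hits
#' @param male_genomic_reads Male genomic reads, or a pre-built repeat
#'   library (named character vector) via `library`.
#' @param library Optional pre-built repeat library.
#' @export
filter_repeats <- function(records, male_genomic_reads = NULL,
                           cfg = pipeline_config(), library = NULL) {
  lib <- library %||% repeat_library(male_genomic_reads, cfg$genome_k,
                                     cfg$repeat_mult)
  score <- if (length(lib) == 0 || nrow(records) == 0) {
    rep(NA_integer_, nrow(records))
  } else {
    best_local_hits(records$sequence, lib)$score
  }
  m <- tibble(id = records$id, repeat_score = score)
  pass <- pass_repeats(m, cfg)
  out <- keep_records(records, pass,
                      stage_audit(records$id, "repeats", "repeat_score",
                                  as.numeric(score), pass))
  attr(out, "metrics") <- m
  out
}

#' Discard transcripts whose effective length is too short
#'
#' Retains a record iff effective length / length exceeds
#' `eff_len_frac_min`.
#'
#' @inheritParams filter_expression
#' @export
filter_effective_length <- function(records, frag_len_mean,
                                    cfg = pipeline_config()) {
  el <- effective_length(records$length, frag_len_mean)
  m <- tibble(id = records$id, length = records$length, eff_len = el)
  pass <- pass_effective_length(m, cfg)
  out <- keep_records(records, pass,
                      stage_audit(records$id, "effective_length",
                                  "eff_len_fraction", el / records$length, pass))
  attr(out, "metrics") <- m
  out
}

# ---- full cascade ----------------------------------------------------------

#' Run the full subtraction cascade
#'
#' Executes the nine stages in order: male RNA reads are mapped to the female
#' assembly (1); unmapped reads are assembled (2); transcripts explained by
#' the female genome (3) or female RNA (4) are discarded; survivors are
#' merged (5); merged transcripts must show male but not female genomic
#' coverage (6), male-biased expression (7), no repeat-library hit (8), and a
#' sufficient effective-length fraction (9).
#'
#' Metrics for stages 6-9 are measured for every merged record (filtering
#' happens at threshold application), so the report supports [refilter()].
#'
#' @param world Optional [simulate_world()] result supplying all inputs.
#' @param cfg A [pipeline_config()].
#' @param male_rna,female_rna,male_dna,female_dna Read sets (paired tibbles
#'   or named character vectors); required when `world` is absent.
#' @param female_assembly Named character vector of female scaffolds.
#' @param frag_len_mean Mean fragment length (bp).
#' @param proteome Optional proteome for merge scaffolding.
#' @param tissue Tissue whose RNA reads drive the pipeline when `world` is
#'   given (defaults to the first configured tissue).
#' @return A `filter_report`: `candidates`, `stage_counts`, `audit`,
#'   `premerge` and `merged_metrics` tables, `provenance`, and the
#'   configuration used.
#' @export
run_pipeline <- function(world = NULL, cfg = pipeline_config(),
                         male_rna = NULL, female_rna = NULL,
                         male_dna = NULL, female_dna = NULL,
                         female_assembly = NULL, frag_len_mean = NULL,
                         proteome = NULL, tissue = NULL) {
  if (!is.null(world)) {
    stopifnot(inherits(world, "sim_world"))
    tissue <- tissue %||% names(world$cfg$rna_depth_by_tissue)[1]
    male_rna <- male_rna %||% emit_reads(world, "male", "rna", tissue)
    female_rna <- female_rna %||% emit_reads(world, "female", "rna", tissue)
    male_dna <- male_dna %||% emit_reads(world, "male", "genomic")
    female_dna <- female_dna %||% emit_reads(world, "female", "genomic")
    female_assembly <- female_assembly %||% world$female_genome
    frag_len_mean <- frag_len_mean %||% world$cfg$frag_len_mean
  }
  needed <- c("male_rna", "female_rna", "male_dna", "female_dna",
              "female_assembly", "frag_len_mean")
  for (nm in needed) {
    if (is.null(get(nm))) abort(sprintf("run_pipeline: missing input '%s'", nm))
  }

  male_rna_flat <- flatten_reads(male_rna)
  counts <- list()

  # Step 1: subtract reads the female assembly explains
  mp1 <- map_reads(male_rna_flat, female_assembly, cfg$map_max_mismatch)
  un <- male_rna_flat[!names(male_rna_flat) %in% mp1$read_id]

  # Step 2: de novo assembly of the unexplained reads
  recs <- assemble_transcripts(un, k = cfg$assembly_k,
                               min_count = cfg$assembly_min_count,
                               cleanup_ratio = cfg$assembly_cleanup_ratio)
  counts$assembly <- c(n_in = length(un), n_out = nrow(recs))
  audits <- list()

  empty_report <- function() {
    new_filter_report(
      candidates = recs[0, ], stage_counts = counts, audit = audits,
      premerge = tibble(), merged_metrics = tibble(),
      merged = recs[0, ], cfg = cfg, frag_len_mean = frag_len_mean,
      n_reads = c(male_rna = length(male_rna_flat))
    )
  }
  if (nrow(recs) == 0) return(empty_report())

  # Step 3: female genome hits
  r3 <- filter_female_genome_hits(recs, female_assembly, cfg)
  audits$female_genome <- attr(r3, "audit")
  m3 <- attr(r3, "metrics")
  counts$female_genome <- c(n_in = nrow(recs), n_out = nrow(r3))

  # Step 4: female RNA coverage
  r4 <- filter_female_rna(r3, female_rna, cfg)
  audits$female_rna <- attr(r4, "audit")
  m4 <- attr(r4, "metrics")
  counts$female_rna <- c(n_in = nrow(r3), n_out = nrow(r4))

  premerge <- dplyr::left_join(
    dplyr::select(m3, "id", "score", "coverage", "identity"),
    m4, by = "id"
  )
  premerge$length <- recs$length[match(premerge$id, recs$id)]
  premerge$pass_female_genome <- pass_female_genome(premerge, cfg)
  premerge$pass_female_rna <- is.na(premerge$breadth) |
    pass_female_rna(premerge, cfg)

  # Step 5: merge survivors
  merged <- merge_transcripts(r4, cfg$merge_min_overlap,
                              cfg$merge_min_identity, proteome)
  counts$merge <- c(n_in = nrow(r4), n_out = nrow(merged))
  if (nrow(merged) == 0) return(empty_report())

  tg <- setNames(merged$sequence, merged$id)

  # Step 6 metrics: genomic coverage (measured for every merged record)
  mp_m <- map_reads(male_dna, tg, cfg$map_max_mismatch)
  mp_f <- map_reads(female_dna, tg, cfg$map_max_mismatch)
  covp <- compute_coverage(mp_m, mp_f, tg)
  i6 <- match(merged$id, covp$target_id)

  # Step 7 metrics: expression
  el <- effective_length(merged$length, frag_len_mean)
  cm <- count_fragments(male_rna, tg, cfg$map_max_mismatch)
  cf <- count_fragments(female_rna, tg, cfg$map_max_mismatch)

  # Step 8 metrics: repeat library
  lib <- repeat_library(male_dna, cfg$genome_k, cfg$repeat_mult)
  rep_score <- if (length(lib) == 0) rep(NA_integer_, nrow(merged)) else
    best_local_hits(merged$sequence, lib)$score

  merged_metrics <- tibble(
    id = merged$id, length = merged$length,
    breadth_male = covp$breadth_male[i6],
    breadth_female = covp$breadth_female[i6],
    eff_len = el,
    frags_male = unname(cm$counts), frags_female = unname(cf$counts),
    rpkm_male = unname(rpkm_of(cm$counts, el, cm$total)),
    rpkm_female = unname(rpkm_of(cf$counts, el, cf$total)),
    repeat_score = rep_score
  )

  p6 <- pass_genomic_coverage(merged_metrics, cfg)
  p7 <- pass_expression(merged_metrics, cfg)
  p8 <- pass_repeats(merged_metrics, cfg)
  p9 <- pass_effective_length(merged_metrics, cfg)

  audits$genomic_coverage <- stage_audit(merged$id, "genomic_coverage",
                                         "male_breadth",
                                         merged_metrics$breadth_male, p6)
  s6 <- p6
  audits$expression <- stage_audit(merged$id[s6], "expression",
                                   "expression_ratio",
                                   ifelse(merged_metrics$rpkm_female[s6] > 0,
                                          merged_metrics$rpkm_male[s6] /
                                            merged_metrics$rpkm_female[s6],
                                          ifelse(merged_metrics$rpkm_male[s6] > 0,
                                                 Inf, 0)),
                                   p7[s6])
  s7 <- s6 & p7
  audits$repeats <- stage_audit(merged$id[s7], "repeats", "repeat_score",
                                as.numeric(merged_metrics$repeat_score[s7]),
                                p8[s7])
  s8 <- s7 & p8
  audits$effective_length <- stage_audit(merged$id[s8], "effective_length",
                                         "eff_len_fraction",
                                         (merged_metrics$eff_len / merged_metrics$length)[s8],
                                         p9[s8])
  s9 <- s8 & p9

  counts$genomic_coverage <- c(n_in = nrow(merged), n_out = sum(s6))
  counts$expression <- c(n_in = sum(s6), n_out = sum(s7))
  counts$repeats <- c(n_in = sum(s7), n_out = sum(s8))
  counts$effective_length <- c(n_in = sum(s8), n_out = sum(s9))

  new_filter_report(
    candidates = merged[s9, , drop = FALSE],
    stage_counts = counts, audit = audits, premerge = premerge,
    merged_metrics = merged_metrics, merged = merged, cfg = cfg,
    frag_len_mean = frag_len_mean,
    n_reads = c(male_rna = length(male_rna_flat))
  )
}

new_filter_report <- function(candidates, stage_counts, audit, premerge,
                              merged_metrics, merged, cfg, frag_len_mean,
                              n_reads) {
  sc <- tibble(
    stage = names(stage_counts),
    n_in = unname(vapply(stage_counts, `[[`, numeric(1), "n_in")),
    n_out = unname(vapply(stage_counts, `[[`, numeric(1), "n_out"))
  )
  sc$n_discarded <- sc$n_in - sc$n_out
  structure(
    list(candidates = candidates, stage_counts = sc,
         audit = if (length(audit)) dplyr::bind_rows(audit) else
           stage_audit(character(0), character(0), character(0),
                       numeric(0), logical(0)),
         premerge = premerge, merged_metrics = merged_metrics,
         merged = merged, cfg = cfg, frag_len_mean = frag_len_mean,
         n_reads = n_reads),
    class = "filter_report"
  )
}

#' Re-apply (possibly tightened) thresholds to a completed report
#'
#' Uses the metrics recorded by [run_pipeline()] to recompute the final
#' candidate set under a different [pipeline_config()] without re-running
#' mapping or assembly. Merged records are failed when any contributing
#' pre-merge record fails a tightened pre-merge stage.
#'
#' @param report A `filter_report`.
#' @param cfg The configuration to apply.
#' @return List with `n_candidates` and `candidate_ids`.
#' @export
refilter <- function(report, cfg) {
  stopifnot(inherits(report, "filter_report"))
  if (nrow(report$merged) == 0) {
    return(list(n_candidates = 0L, candidate_ids = character(0)))
  }
  pm <- report$premerge
  p3 <- pass_female_genome(pm, cfg)
  p4 <- pass_female_rna(pm, cfg)
  p4[is.na(p4)] <- FALSE # no recorded breadth: the record never reached stage 4
  ok_pre_ids <- pm$id[p3 & p4]
  mm <- report$merged_metrics
  ok_prov <- vapply(report$merged$provenance, function(p) {
    all(p %in% ok_pre_ids)
  }, logical(1))
  keep <- ok_prov &
    pass_genomic_coverage(mm, cfg) & pass_expression(mm, cfg) &
    pass_repeats(mm, cfg) & pass_effective_length(mm, cfg)
  list(n_candidates = sum(keep), candidate_ids = report$merged$id[keep])
}

#' Sex-swapped false-positive control
#'
#' Runs the identical cascade twice, once as given and once with the sexes
#' exchanged (the male assembly standing in for the female one), and applies
#' the species-inclusion rule: keep a species only when it yields more than
#' `sexswap_ratio_min` times as many male-specific as female-specific
#' transcripts.
#'
#' @inheritParams run_pipeline
#' @param male_assembly Male genome assembly used as reference in the
#'   swapped orientation.
#' @return List with `n_male_specific`, `n_female_specific`,
#'   `include_species`, and the two `filter_report`s (`forward`, `swapped`).
#' @export
sex_swap_control <- function(world = NULL, cfg = pipeline_config(),
                             male_rna = NULL, female_rna = NULL,
                             male_dna = NULL, female_dna = NULL,
                             female_assembly = NULL, male_assembly = NULL,
                             frag_len_mean = NULL, tissue = NULL) {
  if (!is.null(world)) {
    stopifnot(inherits(world, "sim_world"))
    tissue <- tissue %||% names(world$cfg$rna_depth_by_tissue)[1]
    male_rna <- male_rna %||% emit_reads(world, "male", "rna", tissue)
    female_rna <- female_rna %||% emit_reads(world, "female", "rna", tissue)
    male_dna <- male_dna %||% emit_reads(world, "male", "genomic")
    female_dna <- female_dna %||% emit_reads(world, "female", "genomic")
    female_assembly <- female_assembly %||% world$female_genome
    male_assembly <- male_assembly %||% world$male_genome
    frag_len_mean <- frag_len_mean %||% world$cfg$frag_len_mean
  }
  if (is.null(male_assembly)) {
    abort("sex_swap_control: missing input 'male_assembly'")
  }
  forward <- run_pipeline(cfg = cfg, male_rna = male_rna,
                          female_rna = female_rna, male_dna = male_dna,
                          female_dna = female_dna,
                          female_assembly = female_assembly,
                          frag_len_mean = frag_len_mean)
  swapped <- run_pipeline(cfg = cfg, male_rna = female_rna,
                          female_rna = male_rna, male_dna = female_dna,
                          female_dna = male_dna,
                          female_assembly = male_assembly,
                          frag_len_mean = frag_len_mean)
  n_m <- nrow(forward$candidates)
  n_f <- nrow(swapped$candidates)
  structure(
    list(n_male_specific = n_m, n_female_specific = n_f,
         include_species = n_m > cfg$sexswap_ratio_min * n_f,
         forward = forward, swapped = swapped),
    class = "sexswap_control"
  )
}

#' @export
print.sexswap_control <- function(x, ...) {
  cat("<sexswap_control>\n")
  cat(sprintf("  male-specific  : %d\n", x$n_male_specific))
  cat(sprintf("  female-specific: %d\n", x$n_female_specific))
  cat(sprintf("  include species: %s\n", x$include_species))
  invisible(x)
}
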