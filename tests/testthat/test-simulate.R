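# The synthetic study generator: determinism, ploidy, read geometry, truth
# bookkeeping, and configuration validation.

test_that("read emission is deterministic and stream-isolated per seed", {
  w <- fixture_small_world()
  r1 <- emit_reads(w, "male", "rna", "whole")
  r2 <- emit_reads(w, "male", "rna", "whole")
  expect_identical(r1, r2)
  g1 <- emit_reads(w, "female", "genomic")
  g2 <- emit_reads(w, "female", "genomic")
  expect_identical(g1, g2)
  # a different stream yields different reads
  expect_false(identical(r1$mate1, emit_reads(w, "female", "rna", "whole")$mate1))
})

test_that("written FASTQ is byte-identical across runs of the same seed", {
  cfg <- small_cfg(seed = 23)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_to_dir(cfg, d1, force = TRUE)
  simulate_to_dir(cfg, d2, force = TRUE)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     info = f)
  }
  expect_error(simulate_to_dir(cfg, d1), "not empty")
})

test_that("hemizygosity halves male depth on X scaffolds", {
  w <- fixture_world(101)
  calls <- fixture_scaffold_calls(101)
  md <- emit_reads(w, "male", "genomic")
  fd <- emit_reads(w, "female", "genomic")
  cov <- compute_coverage(map_reads(md, w$female_genome),
                          map_reads(fd, w$female_genome), w$female_genome)
  xs <- grepl("^x", cov$target_id)
  ratio <- cov$depth_male / cov$depth_female
  expect_true(all(ratio[xs] > 0.4 & ratio[xs] < 0.6))
  expect_true(all(ratio[!xs] > 0.85 & ratio[!xs] < 1.15))
})

test_that("genomic read counts match depth x length / (2 x read length)", {
  w <- fixture_small_world()
  rd <- emit_reads(w, "female", "genomic")
  cfg <- w$cfg
  per_scaffold <- table(sub("^f_g_", "", rd$source))
  for (sid in names(w$female_genome)) {
    copies <- 2 # female: autosomes and X both diploid
    expected <- round(nchar(w$female_genome[[sid]]) * cfg$genomic_depth / 2 *
                        copies / (2 * cfg$read_len))
    expect_equal(unname(per_scaffold[[sid]]), expected, tolerance = 0.01)
  }
})

test_that("female data never contain Y-derived reads", {
  w <- fixture_small_world()
  gf <- emit_reads(w, "female", "genomic")
  rf <- emit_reads(w, "female", "rna", "whole")
  expect_false(any(grepl("_y0", gf$source)))
  expect_false(any(rf$source %in% paste0("f_r_whole_", w$truth$gene_id)))
  # and no female genomic read maps to a planted Y transcript cleanly
  mp <- map_reads(gf, setNames(w$truth$sequence, w$truth$gene_id))
  expect_lte(nrow(mp), 2) # at most stray paralog-derived reads
})

test_that("recent duplicates share at least 98 percent identity with their paralog", {
  w <- fixture_world(102)
  tr <- w$truth[w$truth$origin == "recent_duplicate", ]
  ex <- w$expressed
  for (i in seq_len(nrow(tr))) {
    par_seq <- ex$sequence[ex$id == tr$paralog_id[i]]
    a <- strsplit(tr$sequence[i], "")[[1]]
    b <- strsplit(par_seq, "")[[1]]
    expect_gte(mean(a == b), 0.98)
  }
})

test_that("error-free reads are exact substrings of their source", {
  w <- simulate_world(small_cfg(seed = 31, error_rate = 0))
  rd <- emit_reads(w, "male", "rna", "whole")
  idx <- sample(nrow(rd), 50)
  src_of <- function(s) sub("^m_r_whole_", "", s)
  pool <- c(setNames(w$expressed$sequence, w$expressed$id))
  ok <- vapply(idx, function(i) {
    src <- pool[[src_of(rd$source[i])]]
    grepl(rd$mate1[i], src, fixed = TRUE) ||
      grepl(rc(rd$mate1[i]), src, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("truth table covers every planted gene exactly once", {
  w <- fixture_world(101)
  expect_equal(nrow(w$truth), nrow(w$cfg$y_gene_spec))
  expect_false(any(duplicated(w$truth$gene_id)))
  has_par <- w$truth$divergence > 0
  expect_true(all(!is.na(w$truth$paralog_scaffold[has_par])))
  expect_true(all(is.na(w$truth$paralog_scaffold[!has_par])))
  expect_true(all(w$truth$paralog_class[w$truth$origin == "x_escapee"] == "X"))
})

test_that("coverage calibration: X and autosome log2 ratios sit in their bands", {
  calls <- fixture_scaffold_calls(101)
  xs <- grepl("^x", calls$scaffold_id)
  expect_true(all(calls$log2_ratio[xs] > -1.3 & calls$log2_ratio[xs] < -0.7))
  expect_true(all(abs(calls$log2_ratio[!xs]) < 0.3))
})

test_that("realized TPM preserves each gene's tissue rank order", {
  cfg <- small_cfg(
    seed = 47,
    rna_depth_by_tissue = c(whole = 50, head = 50, testis = 50,
                            accessory_gland = 50)
  )
  w <- simulate_world(cfg)
  recs <- tibble::tibble(id = w$expressed$id, sequence = w$expressed$sequence,
                         length = nchar(w$expressed$sequence))
  samples <- list(
    head = emit_reads(w, "male", "rna", "head"),
    testis = emit_reads(w, "male", "rna", "testis"),
    accessory_gland = emit_reads(w, "male", "rna", "accessory_gland")
  )
  tpm <- quantify_tpm(recs, samples, cfg$frag_len_mean)
  y <- tpm[tpm$transcript_id %in% w$truth$gene_id, ]
  # planted Y profile: testis (2) > accessory gland (1) > head (0.2 or 0)
  expect_true(all(y$testis > y$accessory_gland))
  expect_true(all(y$accessory_gland > y$head))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  expect_error(sim_config(read_len = 300, frag_len_mean = 200), "read_len")
  expect_error(sim_config(genomic_depth = 0), "genomic_depth")
  expect_error(sim_config(rna_depth_by_tissue = c(50)), "rna_depth_by_tissue")
  expect_error(y_gene_spec("recent_duplicate", divergence = 0.05),
               "recent_duplicate")
  expect_error(emit_reads(fixture_small_world(), "male", "rna", "antenna"),
               "antenna")
})
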