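# TPM quantification, z-scores, coding calls, bias flags, and the exact
# binomial enrichment test.

test_that("TPM normalizes to one million with best-target assignment", {
  set.seed(701)
  a <- random_dna_str(600)
  b <- random_dna_str(600)
  recs <- ysubtract:::new_records(c(a, b), ids = c("a", "b"))
  frag <- function(seq, i) substr(seq, 5 * i + 1, 5 * i + 100)
  reads <- setNames(
    c(vapply(1:8, function(i) frag(a, i), character(1)),
      vapply(1:8, function(i) frag(b, i), character(1))),
    sprintf("r%02d", 1:16)
  )
  tpm <- quantify_tpm(recs, list(s1 = reads), 200)
  expect_equal(sum(tpm$s1), 1e6, tolerance = 1e-9)
  expect_equal(tpm$s1, c(5e5, 5e5)) # equal counts, equal effective lengths
  # a single transcript absorbs the whole million
  tpm1 <- quantify_tpm(recs[1, ], list(s1 = reads[1:8]), 200)
  expect_equal(tpm1$s1, 1e6)
  expect_error(quantify_tpm(ysubtract:::new_records("ACGT", ids = "t"),
                            list(s1 = reads), 200), "effective length")
})

test_that("TPM columns sum to one million across a simulated tissue panel", {
  cfg <- small_cfg(seed = 72, rna_depth_by_tissue = c(whole = 40, testis = 40))
  w <- simulate_world(cfg)
  recs <- tibble::tibble(id = w$expressed$id, sequence = w$expressed$sequence,
                         length = nchar(w$expressed$sequence))
  tpm <- quantify_tpm(
    recs,
    list(male_whole = emit_reads(w, "male", "rna", "whole"),
         male_testis = emit_reads(w, "male", "rna", "testis")),
    cfg$frag_len_mean
  )
  expect_equal(sum(tpm$male_whole), 1e6, tolerance = 1e-6)
  expect_equal(sum(tpm$male_testis), 1e6, tolerance = 1e-6)
  expect_true(all(tpm$male_whole >= 0))
})

test_that("row z-scores have zero mean, unit sd, and flag constant rows", {
  mat <- tibble::tibble(transcript_id = c("t1", "t2"),
                        s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5))
  z <- row_zscore(mat)
  expect_equal(unlist(z[1, c("s1", "s2", "s3")], use.names = FALSE),
               c(-1, 0, 1))
  expect_equal(unlist(z[2, c("s1", "s2", "s3")], use.names = FALSE),
               c(0, 0, 0))
  expect_equal(z$constant, c(FALSE, TRUE))
  # property: any non-constant row standardizes exactly
  set.seed(702)
  m2 <- tibble::tibble(transcript_id = "x", a = runif(1), b = runif(1),
                       c = runif(1), d = runif(1))
  z2 <- row_zscore(m2)
  vals <- unlist(z2[1, c("a", "b", "c", "d")], use.names = FALSE)
  expect_lt(abs(mean(vals)), 1e-9)
  expect_lt(abs(sd(vals) - 1), 1e-9)
  expect_error(row_zscore(tibble::tibble(transcript_id = "x", a = 1)),
               "2 samples")
})

test_that("coding calls require an 80-codon open reading frame", {
  set.seed(703)
  gene <- paste0(random_dna_str(20), make_cds_test(200), random_dna_str(20))
  expect_equal(coding_call(c(g = gene))$coding, "coding")
  # boundary: 79 codons (excluding the stop) is noncoding, 80 is coding
  orf79 <- make_cds_test(80) # ATG + 78 sense + stop = 79 coding codons
  orf80 <- make_cds_test(81)
  expect_equal(coding_call(c(x = orf79))$coding, "noncoding")
  expect_equal(coding_call(c(x = orf80))$coding, "coding")
  # the call scans the reverse strand as well
  expect_equal(coding_call(c(g = rc(gene)))$coding, "coding")
  # random 300 bp sequence is almost never called coding
  calls <- vapply(1:100, function(i) {
    coding_call(c(x = random_dna_str(300)))$coding
  }, character(1))
  expect_gte(mean(calls == "noncoding"), 0.9)
})

test_that("binomial enrichment matches exhaustive pmf summation", {
  e <- binomial_enrichment(3, 5, 1, 2)
  expect_equal(e$p_value, 0.5)
  expect_equal(binomial_enrichment(0, 106, 5216, 17560)$p_value, 1)
  cases <- list(c(61, 106, 5216, 17560), c(36, 106, 1655, 17560),
                c(10, 50, 100, 1000), c(50, 1000, 100, 1000))
  for (cs in cases) {
    got <- do.call(binomial_enrichment, as.list(cs))$p_value
    want <- oracle_binom_upper(cs[1], cs[2], cs[3] / cs[4])
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(binomial_enrichment(5, 3, 1, 2), "counts")
  expect_error(binomial_enrichment(1, 2, 3, 0), "counts")
})

test_that("testis-bias flags follow max and exclusivity definitions", {
  mat <- tibble::tibble(
    transcript_id = c("both", "max_only", "none", "silent"),
    testis = c(100, 100, 5, 0),
    head = c(0.5, 50, 80, 0),
    ovary = c(0, 0, 10, 0)
  )
  labels <- c(testis = "testis", head = "head", ovary = "ovary")
  fl <- testis_bias_flags(mat, labels)
  expect_equal(fl$max_in_testis_or_gland, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fl$exclusive_to_testis_and_gland, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(testis_bias_flags(mat, labels[-1]), "no tissue label")
})

test_that("recovered Y candidates are testis-enriched on simulated tissue data", {
  for (seed in c(73, 74)) {
    cfg <- small_cfg(
      seed = seed,
      y_gene_spec = y_gene_spec(rep("unique", 8), 0),
      n_background_autosomal = 10, scaffold_len = 8000,
      rna_depth_by_tissue = c(whole = 50, head = 40, testis = 40, ovary = 40,
                              accessory_gland = 40)
    )
    run <- run_full_analysis(cfg, run_paralogs = FALSE)
    expect_true(length(run$enrichment) > 0)
    expect_lt(run$enrichment$max_in_testis_or_gland$p_value, 0.01)
  }
})
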