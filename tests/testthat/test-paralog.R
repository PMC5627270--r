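# Ka/Ks (NG86), translated paralog search, and coverage-based scaffold
# classification.

test_that("kaks handles the canonical small cases", {
  same <- kaks("ATGGCTAAAGGG", "ATGGCTAAAGGG")
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$ka_ks))
  # single synonymous third-position change
  syn <- kaks("TTT", "TTC")
  expect_equal(syn$ka, 0)
  expect_gt(syn$ks, 0)
  expect_equal(syn$sd, 1)
  expect_equal(syn$nd, 0)
  # malformed input
  expect_error(kaks("ATGG", "ATGC"), "multiple of 3")
  expect_error(kaks("ATG", "ATGAAA"), "equal length")
  expect_error(kaks("TAAATG", "TAAATG"), "stop")
})

test_that("NG86 counts match the pathway-enumeration oracle exhaustively", {
  sense <- sense_codons()
  for (c1 in sense) {
    for (c2 in sense) {
      got <- kaks(c1, c2)
      want <- oracle_ng86(c1, c2)
      expect_equal(got$s_sites, want$S, tolerance = 1e-12)
      expect_equal(got$sd, want$Sd, tolerance = 1e-12)
      expect_equal(got$nd, want$Nd, tolerance = 1e-12)
    }
  }
})

test_that("NG86 matches the oracle on random multi-codon pairs", {
  set.seed(601)
  for (n_codons in c(2, 3)) {
    for (rep in 1:50) {
      a <- random_cds(n_codons)
      b <- random_cds(n_codons)
      got <- kaks(a, b)
      want <- oracle_ng86(a, b)
      expect_equal(got$sd, want$Sd, tolerance = 1e-12)
      expect_equal(got$nd, want$Nd, tolerance = 1e-12)
      expect_equal(got$s_sites, want$S, tolerance = 1e-12)
    }
  }
  # 100 random 100-codon pairs at ~5% divergence
  for (rep in 1:100) {
    a <- random_cds(100)
    b <- a
    repeat {
      pos <- sample(300, 15)
      ch <- strsplit(a, "")[[1]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      b <- paste(ch, collapse = "")
      cods <- substring(b, 3 * (1:100) - 2, 3 * (1:100))
      if (!any(Biostrings::GENETIC_CODE[cods] == "*")) break
    }
    got <- kaks(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$ks, want$ks, tolerance = 1e-12)
    expect_equal(got$ka, want$ka, tolerance = 1e-12)
  }
})

test_that("synonymous-only divergence is recovered by Ks with tiny Ka", {
  set.seed(602)
  for (d in c(0.1, 0.2, 0.3)) {
    a <- random_cds(400)
    b <- mutate_synonymous(a, d)
    kk <- kaks(a, b)
    expect_lt(abs(kk$ks - d) / d, 0.15)
    expect_lt(kk$ka, 0.01)
  }
})

test_that("find_paralog locates a planted diverged copy on the right scaffold", {
  set.seed(603)
  cds <- random_cds(300)
  pep <- translate_nt(cds)
  paralog <- mutate_at_divergence <- local({
    ch <- strsplit(cds, "")[[1]]
    pos <- sample(length(ch), round(0.1 * length(ch)))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  })
  genome <- c(
    s1 = random_dna_str(3000),
    s2 = paste0(random_dna_str(1000), paralog, random_dna_str(1000)),
    s3 = random_dna_str(3000)
  )
  hit <- find_paralog(pep, genome)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$paralog_scaffold_id, "s2")
  expect_gte(hit$paralog_start, 900)
  expect_lte(hit$paralog_end, 2000)
  expect_gt(hit$pct_identity, 0.7)
  # reverse-strand placement is found too
  genome_rc <- c(s1 = genome[["s1"]],
                 s2 = rc(genome[["s2"]]))
  hit_rc <- find_paralog(pep, genome_rc)
  expect_equal(hit_rc$paralog_scaffold_id, "s2")
  expect_equal(hit_rc$strand, "-")
})

test_that("peptides without a homolog or below the floors return no paralog", {
  set.seed(604)
  pep <- translate_nt(random_cds(150))
  genome <- c(s1 = random_dna_str(4000), s2 = random_dna_str(4000))
  expect_equal(nrow(find_paralog(pep, genome)), 0)
  expect_error(find_paralog("MSTAPK", genome), "20 aa")
  # a hit below the identity floor is rejected even when it scores well
  cds <- random_cds(300)
  heavy <- local({
    ch <- strsplit(cds, "")[[1]]
    pos <- sample(length(ch), round(0.45 * length(ch)))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  })
  g2 <- c(s1 = paste0(random_dna_str(500), heavy, random_dna_str(500)))
  hit <- find_paralog(translate_nt(cds), g2, min_identity = 0.40)
  if (nrow(hit) == 1) expect_gte(hit$pct_identity, 0.40)
  hit_strict <- find_paralog(translate_nt(cds), g2, min_identity = 0.95)
  expect_equal(nrow(hit_strict), 0)
})

test_that("scaffold classification follows the coverage-ratio bands", {
  cov <- tibble::tibble(
    target_id = c("s1", "s2", "s3", "s4", "s5"),
    length = c(5000, 5000, 5000, 500, 5000),
    depth_male = c(10, 20, 40, 10, 10),
    depth_female = c(20, 20, 20, 20, 0),
    breadth_male = 1, breadth_female = c(1, 1, 1, 1, 0),
    normalized_ratio = c(-1.02, 0.05, 1.0, -1.0, NA),
    male_only = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  calls <- classify_scaffold(cov)
  expect_equal(calls$class[calls$scaffold_id == "s1"], "X")
  expect_equal(calls$class[calls$scaffold_id == "s2"], "autosome")
  expect_equal(calls$class[calls$scaffold_id == "s3"], "ambiguous")
  expect_equal(calls$class[calls$scaffold_id == "s5"], "male_only")
  expect_false("s4" %in% calls$scaffold_id) # below the 1 kb length floor
})

test_that("origin calls match the planted truth across the candidate set", {
  w <- fixture_world(101)
  rep <- fixture_report(101)
  calls <- fixture_scaffold_calls(101)
  pairs <- paralog_analysis(rep$candidates, w$female_genome, calls)
  cf <- confusion_table(rep, w)
  j <- dplyr::left_join(pairs, cf$per_candidate,
                        by = c(y_transcript_id = "candidate_id"))
  j <- dplyr::left_join(
    j, w$truth[, c("gene_id", "origin", "divergence", "paralog_scaffold")],
    by = c(source = "gene_id")
  )
  with_par <- !is.na(j$paralog_scaffold)
  expect_true(all(j$paralog_scaffold_id[with_par] ==
                    j$paralog_scaffold[with_par]))
  expected_call <- dplyr::case_when(
    j$origin == "x_escapee" ~ "ancestral_x_derived",
    j$origin == "autosomal_acquisition" ~ "autosomal_acquisition",
    TRUE ~ "unknown"
  )
  concord <- mean(j$origin_call == expected_call)
  expect_gte(concord, 0.95)
  # Ka and Ks grow with the planted divergence
  div <- j$divergence[with_par]
  expect_gt(suppressWarnings(cor(j$ks[with_par], div)), 0.8)
  # raw Ka/Ks values are preserved; display truncation is the plot's job
  expect_true(all(is.na(j$ka_ks[!with_par])))
})
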