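# Mapper, coverage, assembler and merger contracts.

test_that("mapper agrees with a brute-force Hamming scan on random instances", {
  set.seed(401)
  for (rep in 1:4) {
    targets <- setNames(
      vapply(1:5, function(i) random_dna_str(sample(150:300, 1)), character(1)),
      paste0("t", 1:5)
    )
    reads <- character(0)
    for (i in 1:30) {
      ti <- sample(5, 1)
      L <- sample(c(40, 50, 60), 1)
      s <- sample(nchar(targets[ti]) - L, 1)
      r <- substr(targets[[ti]], s, s + L - 1)
      n_mut <- sample(0:3, 1)
      if (n_mut > 0) {
        pos <- sample(L, n_mut)
        ch <- strsplit(r, "")[[1]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        r <- paste(ch, collapse = "")
      }
      if (runif(1) < 0.5) r <- rc(r)
      reads <- c(reads, r)
    }
    names(reads) <- sprintf("r%02d", seq_along(reads))
    got <- map_reads(reads, targets, 2)
    want <- oracle_map_reads(reads, targets, 2)
    got <- got[order(got$read_id), ]
    want <- want[order(want$read_id), ]
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("mapper tie-breaks to the lexicographically lowest target id", {
  seq <- random_dna_str(80)
  mp <- map_reads(setNames(seq, "r"), c(b = seq, a = seq), 2)
  expect_equal(mp$target_id, "a")
})

test_that("reads beyond the mismatch allowance stay unmapped", {
  tg <- c(t1 = random_dna_str(300))
  r <- substr(tg[[1]], 50, 149)
  ch <- strsplit(r, "")[[1]]
  for (p in c(10, 40, 70)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  r3 <- paste(ch, collapse = "")
  expect_equal(nrow(map_reads(setNames(r3, "x"), tg, 2)), 0)
  expect_equal(nrow(map_reads(setNames(r3, "x"), tg, 3)), 1)
})

test_that("coverage depth and breadth arithmetic is exact", {
  tg <- c(a = random_dna_str(1000), b = random_dna_str(500))
  # two male reads of 100 bp each at known places on 'a': 2000 aligned bases
  reads_m <- setNames(
    c(rep(substr(tg[["a"]], 1, 100), 10), rep(substr(tg[["a"]], 101, 200), 10)),
    sprintf("m%02d", 1:20)
  )
  mp_m <- map_reads(reads_m, tg, 0)
  cov <- compute_coverage(mp_m, mp_m[0, ], tg)
  a <- cov[cov$target_id == "a", ]
  expect_equal(a$depth_male, 2)
  expect_equal(a$breadth_male, 0.2)
  expect_equal(a$breadth_female, 0)
  expect_true(a$male_only)
  expect_true(is.na(a$normalized_ratio))
  expect_error(
    compute_coverage(dplyr::mutate(mp_m, target_id = "ghost"), mp_m[0, ], tg),
    "unknown target"
  )
})

test_that("effective length follows the fragment-length correction", {
  expect_equal(effective_length(1000, 200), 801)
  expect_equal(effective_length(150, 200), 0)
  expect_equal(effective_length(500, 200), 301)
  expect_gt(301 / 500, 0.6) # the value the final filter consumes
})

test_that("tiled error-free reads reconstruct a transcript exactly", {
  set.seed(402)
  tr <- random_dna_str(1000)
  reads <- tile_reads(c(t1 = tr), read_len = 100, step = 3) # ~33x per strand
  asm <- assemble_transcripts(reads)
  expect_equal(nrow(asm), 1)
  expect_equal(asm$length, 1000)
  expect_true(asm$sequence == tr || asm$sequence == rc(tr))
})

test_that("k-mer-disjoint transcripts assemble into separate contigs", {
  set.seed(403)
  t1 <- random_dna_str(600)
  t2 <- random_dna_str(600)
  reads <- tile_reads(c(a = t1, b = t2), 100, 4)
  asm <- assemble_transcripts(reads)
  expect_equal(nrow(asm), 2)
  expect_setequal(
    unname(vapply(asm$sequence, function(s) min(s, rc(s)), character(1))),
    unname(vapply(c(t1, t2), function(s) min(s, rc(s)), character(1)))
  )
})

test_that("singleton k-mers below min_count yield no contigs", {
  set.seed(404)
  tr <- random_dna_str(1000)
  starts <- seq(1, 901, by = 100)
  reads <- setNames(substring(tr, starts, starts + 99),
                    sprintf("r%02d", seq_along(starts))) # 1x, one strand
  expect_equal(nrow(assemble_transcripts(reads)), 0)
})

test_that("assembly reproduces the full planted transcriptome without errors", {
  cfg <- small_cfg(
    seed = 53, error_rate = 0,
    y_gene_spec = y_gene_spec(c("unique", "unique", "unique"), 0),
    rna_depth_by_tissue = c(whole = 30)
  )
  w <- simulate_world(cfg)
  rd <- emit_reads(w, "male", "rna", "whole")
  asm <- assemble_transcripts(rd)
  canon <- function(x) sort(vapply(x, function(s) min(s, rc(s)), character(1)),
                            method = "radix")
  expect_equal(unname(canon(asm$sequence)), unname(canon(w$expressed$sequence)))
})

test_that("merging joins qualifying overlaps and collapses redundancy", {
  set.seed(405)
  full <- random_dna_str(400)
  a <- substr(full, 1, 220)
  b <- substr(full, 181, 400) # 40 bp overlap
  m <- merge_transcripts(ysubtract:::new_records(c(a, b), ids = c("A", "B")))
  expect_equal(nrow(m), 1)
  expect_equal(m$sequence, full)
  expect_setequal(m$provenance[[1]], c("A", "B"))

  b20 <- substr(full, 201, 400) # 20 bp overlap: below the minimum
  m2 <- merge_transcripts(ysubtract:::new_records(c(a, b20), ids = c("A", "B")))
  expect_equal(nrow(m2), 2)

  m3 <- merge_transcripts(ysubtract:::new_records(c(a, a, rc(a)),
                                                  ids = c("A", "B", "C")))
  expect_equal(nrow(m3), 1)
})

test_that("merging handles reverse-complement overlaps and is idempotent", {
  set.seed(406)
  full <- random_dna_str(500)
  a <- substr(full, 1, 280)
  b <- rc(substr(full, 241, 500))
  m <- merge_transcripts(ysubtract:::new_records(c(a, b), ids = c("A", "B")))
  expect_equal(nrow(m), 1)
  expect_true(m$sequence == full || m$sequence == rc(full))
  m_again <- merge_transcripts(m)
  expect_equal(m_again$sequence, m$sequence)
})

test_that("merging is order-independent and never loses unique sequence", {
  set.seed(407)
  frags <- list()
  for (i in 1:3) {
    full <- random_dna_str(360)
    frags[[length(frags) + 1]] <- substr(full, 1, 200)
    frags[[length(frags) + 1]] <- substr(full, 161, 360)
  }
  frags <- c(frags, random_dna_str(250)) # one unrelated record
  seqs <- unlist(frags)
  perm <- sample(length(seqs))
  m1 <- merge_transcripts(ysubtract:::new_records(seqs, ids = paste0("r", seq_along(seqs))))
  m2 <- merge_transcripts(ysubtract:::new_records(seqs[perm], ids = paste0("s", seq_along(seqs))))
  canon <- function(x) sort(vapply(x, function(s) min(s, rc(s)), character(1)))
  expect_equal(unname(canon(m1$sequence)), unname(canon(m2$sequence)))
  expect_gte(sum(m1$length), 3 * 360 + 250)
})

test_that("repeat library recovers a planted satellite and nothing else", {
  w <- fixture_world(101)
  lib <- repeat_library(emit_reads(w, "male", "genomic"))
  expect_equal(length(lib), sum(w$truth$origin == "repeat_embedded"))
  for (motif in w$repeat_motif) {
    h <- best_local_hits(motif, lib)
    expect_gte(h$score, 50)
  }
})
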