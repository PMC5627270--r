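# Synthetic study generator: a diploid genome with autosomes, a hemizygous X
# and a male-limited Y, planted Y genes of known origin, tissue-resolved
# expression, and seeded paired-end read emission for both sexes.

#' Specify planted Y genes
#'
#' Each row describes one Y-linked gene to plant: its origin class, its
#' divergence from the paralog left in the female genome (substitutions per
#' site; 0 for genes without a paralog), its CDS length, and a relative
#' expression profile across tissues.
#'
#' @param origin One of `"x_escapee"`, `"autosomal_acquisition"`,
#'   `"recent_duplicate"`, `"repeat_embedded"`, `"unique"`.
#' @param divergence Substitutions/site separating the Y copy from its
#'   planted paralog. Recent duplicates must stay at or below 0.02
#'   (the 98 percent identity regime that defeats subtraction filters).
#' @param length CDS length in nucleotides (multiple of 3, including the
#'   start and stop codon).
#' @param expression_profile Named numeric vector of relative abundance per
#'   tissue; list of such vectors for multiple genes.
#' @return A tibble with one row per gene.
#' @export
y_gene_spec <- function(origin, divergence = 0, length = 1140,
                        expression_profile = NULL) {
  origins <- c("x_escapee", "autosomal_acquisition", "recent_duplicate",
               "repeat_embedded", "unique")
  if (!all(origin %in% origins)) {
    abort(sprintf("y_gene_spec: unknown origin '%s'",
                  setdiff(origin, origins)[1]))
  }
  n <- length(origin)
  divergence <- rep_len(divergence, n)
  len <- rep_len(length, n)
  if (is.null(expression_profile)) {
    expression_profile <- default_y_profile()
  }
  if (!is.list(expression_profile)) {
    expression_profile <- list(expression_profile)
  }
  profile <- rep_len(expression_profile, n)
  bad <- origin == "recent_duplicate" & divergence > 0.02
  if (any(bad)) {
    abort("y_gene_spec: recent_duplicate divergence must be <= 0.02")
  }
  bad <- origin %in% c("unique", "repeat_embedded") & divergence != 0
  if (any(bad)) {
    abort("y_gene_spec: unique/repeat_embedded genes carry no paralog; divergence must be 0")
  }
  if (any(len %% 3 != 0 | len < 240)) {
    abort("y_gene_spec: length must be a multiple of 3 and >= 240")
  }
  tibble(origin = origin, divergence = divergence, length = as.integer(len),
         expression_profile = profile)
}

default_y_profile <- function(exclusive = FALSE) {
  if (exclusive) {
    c(whole = 1, head = 0, testis = 2, accessory_gland = 1, ovary = 0)
  } else {
    c(whole = 1, head = 0.2, testis = 2, accessory_gland = 1, ovary = 0)
  }
}

default_bg_profile <- function() {
  c(whole = 1, head = 1, testis = 0.5, accessory_gland = 0.5, ovary = 1)
}

# background genes are mostly broadly expressed; a minority is testis-biased
# so enrichment tests have a realistic non-zero background rate
bg_profile_for <- function(i) {
  if (i %% 7 == 3) {
    c(whole = 1, head = 0, testis = 2, accessory_gland = 0.5, ovary = 0)
  } else if (i %% 5 == 0) {
    c(whole = 1, head = 0.3, testis = 3, accessory_gland = 1, ovary = 0.1)
  } else {
    default_bg_profile()
  }
}

#' Default planted Y gene set
#'
#' Twenty genes detectable by the subtraction pipeline (X escapees and
#' autosomal acquisitions at divergences 0.15-0.40 plus Y-unique genes), two
#' recent duplicates at 2 percent divergence (the regime the female-genome
#' filter deliberately removes), and two repeat-embedded genes the repeat
#' filter should remove.
#' @return A tibble as produced by [y_gene_spec()].
#' @export
default_y_genes <- function() {
  grades <- c(0.15, 0.18, 0.22, 0.26, 0.30, 0.35, 0.40)
  dplyr::bind_rows(
    y_gene_spec(rep("x_escapee", 7), grades),
    y_gene_spec(rep("autosomal_acquisition", 7), grades),
    y_gene_spec(rep("unique", 6), 0,
                expression_profile = default_y_profile(exclusive = TRUE)),
    y_gene_spec(rep("recent_duplicate", 2), 0.02),
    y_gene_spec(rep("repeat_embedded", 2), 0)
  )
}

#' Configuration for the synthetic world
#'
#' @param seed Integer seed; every random stream is derived from it.
#' @param n_autosomal_scaffolds,n_x_scaffolds Number of autosomal / X
#'   scaffolds in the female assembly.
#' @param scaffold_len Scaffold length in bp.
#' @param y_gene_spec Tibble from [y_gene_spec()] describing planted Y genes.
#' @param n_background_autosomal,n_background_x Autosomal / X-linked
#'   background genes expressed in both sexes.
#' @param genomic_depth Fold coverage of the diploid genome per sex (the
#'   hemizygous X and Y receive half of it in males).
#' @param rna_depth_by_tissue Named numeric vector, tissue -> fold coverage
#'   of a transcript at relative abundance 1.
#' @param read_len,frag_len_mean,frag_len_sd Read and fragment geometry (bp).
#' @param error_rate Per-base substitution error probability in `[0, 0.05]`.
#' @param repeat_spec List with `motif_len` (bp) and `copy_number` (tandem
#'   copies planted as a satellite array on an autosome); repeat-embedded Y
#'   genes carry one motif copy in their 3' UTR.
#' @param utr_len Length of the untranslated flanks added to each CDS.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_autosomal_scaffolds = 8L,
                       scaffold_len = 8000L,
                       n_x_scaffolds = 4L,
                       y_gene_spec = default_y_genes(),
                       n_background_autosomal = 12L,
                       n_background_x = 4L,
                       genomic_depth = 20,
                       rna_depth_by_tissue = c(whole = 50),
                       read_len = 100L,
                       frag_len_mean = 200,
                       frag_len_sd = 20,
                       error_rate = 0.001,
                       repeat_spec = list(motif_len = 100L, copy_number = 15L),
                       utr_len = 30L) {
  cfg <- list(
    seed = as.integer(seed),
    n_autosomal_scaffolds = as.integer(n_autosomal_scaffolds),
    scaffold_len = as.integer(scaffold_len),
    n_x_scaffolds = as.integer(n_x_scaffolds),
    y_gene_spec = y_gene_spec,
    n_background_autosomal = as.integer(n_background_autosomal),
    n_background_x = as.integer(n_background_x),
    genomic_depth = genomic_depth,
    rna_depth_by_tissue = rna_depth_by_tissue,
    read_len = as.integer(read_len),
    frag_len_mean = frag_len_mean,
    frag_len_sd = frag_len_sd,
    error_rate = error_rate,
    repeat_spec = repeat_spec,
    utr_len = as.integer(utr_len)
  )
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("sim_config: invalid '%s': %s", field, msg))
  }
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed", "must be a single integer")
  chk(cfg$genomic_depth > 0, "genomic_depth", "must be > 0")
  chk(length(cfg$rna_depth_by_tissue) >= 1 &&
        !is.null(names(cfg$rna_depth_by_tissue)) &&
        all(nzchar(names(cfg$rna_depth_by_tissue))),
      "rna_depth_by_tissue", "must be a named vector")
  chk(all(cfg$rna_depth_by_tissue > 0), "rna_depth_by_tissue", "depths must be > 0")
  chk(cfg$read_len <= cfg$frag_len_mean, "read_len",
      "must not exceed frag_len_mean")
  chk(cfg$error_rate >= 0 && cfg$error_rate <= 0.05, "error_rate",
      "must lie in [0, 0.05]")
  chk(cfg$n_autosomal_scaffolds >= 1, "n_autosomal_scaffolds", "must be >= 1")
  chk(cfg$n_x_scaffolds >= 1, "n_x_scaffolds", "must be >= 1")
  chk(cfg$scaffold_len >= 1000, "scaffold_len", "must be >= 1000")
  chk(is.data.frame(cfg$y_gene_spec), "y_gene_spec",
      "must be a tibble from y_gene_spec()")
  chk(cfg$repeat_spec$motif_len >= 40, "repeat_spec", "motif_len must be >= 40")
  structure(cfg, class = "sim_config")
}

stream_seed <- function(seed, ...) {
  key <- paste(..., sep = ":")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 131 + c) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1009 + h * 97 + 11) %% 2147483647)
}

# place items (tibble id, sequence) across n scaffolds; returns list(seqs =
# named character, placements = tibble(id, scaffold, start, end))
plant_scaffolds <- function(items, n_scaffolds, scaffold_len, prefix) {
  ids <- sprintf("%s%02d", prefix, seq_len(n_scaffolds))
  assign_to <- if (nrow(items)) {
    rep(seq_len(n_scaffolds), length.out = nrow(items))
  } else integer(0)
  seqs <- character(n_scaffolds)
  rows <- list()
  for (s in seq_len(n_scaffolds)) {
    its <- items[assign_to == s, , drop = FALSE]
    total <- sum(nchar(its$sequence))
    k <- nrow(its) + 1
    slack <- scaffold_len - total
    if (slack < k * 20) {
      abort(sprintf(
        "sim_config: invalid 'scaffold_len': %d bp cannot hold %d bp of planted sequence on %s%02d",
        scaffold_len, total, prefix, s))
    }
    sp <- slack %/% k
    parts <- character(0)
    pos <- 0L
    for (i in seq_len(nrow(its))) {
      spacer <- random_dna(sp)
      parts <- c(parts, spacer, its$sequence[i])
      start <- pos + nchar(spacer)
      end <- start + nchar(its$sequence[i])
      rows[[length(rows) + 1]] <- tibble(
        id = its$id[i], scaffold = ids[s], start = start, end = end
      )
      pos <- end
    }
    parts <- c(parts, random_dna(scaffold_len - pos))
    seqs[s] <- paste(parts, collapse = "")
  }
  list(
    seqs = setNames(seqs, ids),
    placements = if (length(rows)) dplyr::bind_rows(rows) else
      tibble(id = character(0), scaffold = character(0),
             start = integer(0), end = integer(0))
  )
}

#' Simulate a male/female sequencing study with known Y-gene truth
#'
#' Builds a female genome (autosomes twice, X twice), a male genome
#' (autosomes twice, X once, Y once), plants Y genes of the configured
#' origins together with their paralogs, a satellite repeat array, and
#' background genes expressed in both sexes. Reads are not generated here;
#' [emit_reads()] derives each read set deterministically from the seed.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_world` object: `female_genome`, `male_genome` (named
#'   character vectors), `truth` (one row per planted Y gene), `background`,
#'   `expressed` (the transcript registry used for RNA emission),
#'   `repeat_motif`, and the configuration.
#' @export
simulate_world <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(stream_seed(cfg$seed, "genome"))
  utr <- cfg$utr_len

  spec <- cfg$y_gene_spec
  ny <- nrow(spec)
  y_ids <- sprintf("y%03d", seq_len(ny))

  # one satellite motif per repeat-embedded gene (distinct motifs keep the
  # assembly graphs of different Y transcripts disjoint), each with its own
  # genomic tandem array; at least one array exists even without such genes
  n_motifs <- max(1L, sum(spec$origin == "repeat_embedded"))
  motifs <- vapply(seq_len(n_motifs), function(i) {
    random_dna(cfg$repeat_spec$motif_len)
  }, character(1))

  transcripts <- character(ny)
  mi <- 0
  for (i in seq_len(ny)) {
    cds <- make_cds(spec$length[i] %/% 3)
    tail_utr <- if (spec$origin[i] == "repeat_embedded") {
      mi <- mi + 1
      paste0(motifs[mi], random_dna(utr)) # one full motif copy in the 3' UTR
    } else {
      random_dna(utr)
    }
    transcripts[i] <- paste0(random_dna(utr), cds, tail_utr)
  }

  has_paralog <- spec$divergence > 0
  paralog_seq <- vapply(seq_len(ny), function(i) {
    if (has_paralog[i]) mutate_jc(transcripts[i], spec$divergence[i]) else ""
  }, character(1))
  paralog_ids <- as.character(ifelse(has_paralog, paste0(y_ids, "_par"),
                                     NA_character_))

  # background genes
  n_bga <- cfg$n_background_autosomal
  n_bgx <- cfg$n_background_x
  bg_ids <- c(sprintf("bga%03d", seq_len(n_bga)), sprintf("bgx%03d", seq_len(n_bgx)))
  bg_class <- c(rep("autosome", n_bga), rep("X", n_bgx))
  bg_len <- if (nrow(spec)) as.integer(median(spec$length)) else 1140L
  bg_seqs <- vapply(seq_along(bg_ids), function(i) {
    paste0(random_dna(utr), make_cds(bg_len %/% 3), random_dna(utr))
  }, character(1))

  # autosomal content: autosomal background + paralogs of acquisitions and
  # recent duplicates + the satellite array
  auto_par <- which(has_paralog &
                      spec$origin %in% c("autosomal_acquisition", "recent_duplicate"))
  x_par <- which(has_paralog & spec$origin == "x_escapee")
  arrays <- tibble(
    id = sprintf("satellite_array_%d", seq_along(motifs)),
    sequence = strrep(motifs, cfg$repeat_spec$copy_number)
  )
  auto_items <- dplyr::bind_rows(
    arrays,
    tibble(id = bg_ids[bg_class == "autosome"],
           sequence = bg_seqs[bg_class == "autosome"]),
    tibble(id = paralog_ids[auto_par], sequence = paralog_seq[auto_par])
  )
  x_items <- dplyr::bind_rows(
    tibble(id = bg_ids[bg_class == "X"], sequence = bg_seqs[bg_class == "X"]),
    tibble(id = paralog_ids[x_par], sequence = paralog_seq[x_par])
  )
  y_items <- tibble(id = y_ids, sequence = transcripts)

  auto <- plant_scaffolds(auto_items, cfg$n_autosomal_scaffolds,
                          cfg$scaffold_len, "a")
  xsc <- plant_scaffolds(x_items, cfg$n_x_scaffolds, cfg$scaffold_len, "x")
  n_y_scaffolds <- if (ny == 0) 0L else as.integer(ceiling(ny / 4))
  ysc <- plant_scaffolds(y_items, n_y_scaffolds, cfg$scaffold_len, "y")

  female_genome <- c(auto$seqs, xsc$seqs)
  male_genome <- c(auto$seqs, xsc$seqs, ysc$seqs)

  place <- dplyr::bind_rows(auto$placements, xsc$placements, ysc$placements)
  pl <- function(id, col) {
    i <- match(id, place$id)
    place[[col]][i]
  }

  truth <- tibble(
    gene_id = y_ids,
    origin = spec$origin,
    divergence = spec$divergence,
    sequence = transcripts,
    length = nchar(transcripts),
    y_scaffold = pl(y_ids, "scaffold"),
    y_start = pl(y_ids, "start"),
    y_end = pl(y_ids, "end"),
    paralog_id = paralog_ids,
    paralog_scaffold = pl(paralog_ids, "scaffold"),
    paralog_start = pl(paralog_ids, "start"),
    paralog_end = pl(paralog_ids, "end"),
    paralog_class = dplyr::case_when(
      !has_paralog ~ NA_character_,
      spec$origin == "x_escapee" ~ "X",
      TRUE ~ "autosome"
    ),
    detectable = spec$origin %in% c("x_escapee", "autosomal_acquisition", "unique"),
    expression_profile = spec$expression_profile
  )

  background <- tibble(
    gene_id = bg_ids,
    class = bg_class,
    sequence = bg_seqs,
    scaffold = pl(bg_ids, "scaffold"),
    start = pl(bg_ids, "start"),
    end = pl(bg_ids, "end")
  )

  expressed <- dplyr::bind_rows(
    tibble(id = y_ids, sequence = transcripts, male = TRUE, female = FALSE,
           profile = spec$expression_profile),
    tibble(id = bg_ids, sequence = bg_seqs, male = TRUE, female = TRUE,
           profile = lapply(seq_along(bg_ids), bg_profile_for)),
    tibble(id = paralog_ids[has_paralog], sequence = paralog_seq[has_paralog],
           male = TRUE, female = TRUE,
           profile = rep(list(default_bg_profile()), sum(has_paralog)))
  )

  structure(
    list(cfg = cfg, female_genome = female_genome, male_genome = male_genome,
         truth = truth, background = background, expressed = expressed,
         repeat_motif = motifs),
    class = "sim_world"
  )
}

#' @export
print.sim_world <- function(x, ...) {
  cat("<sim_world>\n")
  cat(sprintf("  female genome: %d scaffolds (%s bp)\n",
              length(x$female_genome),
              format(sum(nchar(x$female_genome)), big.mark = ",")))
  cat(sprintf("  male extra   : %d Y scaffolds\n",
              length(x$male_genome) - length(x$female_genome)))
  cat(sprintf("  planted Y genes: %d (%d detectable)\n",
              nrow(x$truth), sum(x$truth$detectable)))
  cat(sprintf("  background genes: %d, tissues: %s\n",
              nrow(x$background),
              paste(names(x$cfg$rna_depth_by_tissue), collapse = ", ")))
  invisible(x)
}

add_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

sample_fragment_reads <- function(seq, n, read_len, flm, fls, source_id) {
  L <- nchar(seq)
  if (n <= 0 || L < read_len) {
    return(tibble(read_id = character(0), mate1 = character(0),
                  mate2 = character(0), source = character(0)))
  }
  flen <- pmax(read_len, pmin(L, round(rnorm(n, flm, fls))))
  # fragments may overhang the ends and are clipped, so terminal positions
  # are sampled at full depth
  start <- floor(runif(n, min = read_len - flen, max = L - read_len + 1))
  fs <- pmax(0, start)
  fe <- pmin(L, start + flen)
  frag <- substring(seq, fs + 1, fe)
  minus <- sample(c(TRUE, FALSE), n, replace = TRUE)
  frag[minus] <- rc(frag[minus])
  w <- nchar(frag)
  mate1 <- substring(frag, 1, read_len)
  mate2 <- rc(substring(frag, w - read_len + 1, w))
  tibble(
    read_id = sprintf("%s_%06d", source_id, seq_len(n)),
    mate1 = mate1, mate2 = mate2, source = source_id
  )
}

#' Emit paired-end reads for one (sex, datatype, tissue) combination
#'
#' Each combination draws from its own RNG stream seeded from the world's
#' seed, so requesting one read set never perturbs another. Read names encode
#' the source sequence for debugging; the pipeline never reads them.
#'
#' @param world A [simulate_world()] result.
#' @param sex `"male"` or `"female"`.
#' @param datatype `"genomic"` or `"rna"`.
#' @param tissue Tissue name for RNA (defaults to the first configured
#'   tissue); must exist in `cfg$rna_depth_by_tissue`.
#' @return A tibble with `read_id`, `mate1`, `mate2`, `source`.
#' @export
emit_reads <- function(world, sex = c("male", "female"),
                       datatype = c("genomic", "rna"), tissue = NULL) {
  stopifnot(inherits(world, "sim_world"))
  sex <- match.arg(sex)
  datatype <- match.arg(datatype)
  cfg <- world$cfg

  if (datatype == "rna") {
    tissue <- tissue %||% names(cfg$rna_depth_by_tissue)[1]
    if (!tissue %in% names(cfg$rna_depth_by_tissue)) {
      abort(sprintf("emit_reads: unknown tissue '%s' (configured: %s)",
                    tissue, paste(names(cfg$rna_depth_by_tissue), collapse = ", ")))
    }
  } else {
    tissue <- NULL
  }

  set.seed(stream_seed(cfg$seed, sex, datatype, tissue %||% ""))
  rl <- cfg$read_len

  if (datatype == "genomic") {
    genome <- if (sex == "male") world$male_genome else world$female_genome
    copies <- vapply(names(genome), function(id) {
      kind <- substr(id, 1, 1)
      if (kind == "a") 2L
      else if (kind == "x") if (sex == "male") 1L else 2L
      else 1L # Y, male only
    }, integer(1))
    per_copy_depth <- cfg$genomic_depth / 2
    out <- lapply(seq_along(genome), function(i) {
      n <- round(nchar(genome[i]) * per_copy_depth * copies[i] / (2 * rl))
      sample_fragment_reads(genome[[i]], n, rl, cfg$frag_len_mean,
                            cfg$frag_len_sd,
                            sprintf("%s_g_%s", substr(sex, 1, 1), names(genome)[i]))
    })
  } else {
    depth <- cfg$rna_depth_by_tissue[[tissue]]
    ex <- world$expressed
    ex <- ex[ex[[sex]], , drop = FALSE]
    abund <- vapply(ex$profile, function(p) {
      if (tissue %in% names(p)) p[[tissue]] else 0
    }, numeric(1))
    keep <- abund > 0
    ex <- ex[keep, , drop = FALSE]
    abund <- abund[keep]
    out <- lapply(seq_len(nrow(ex)), function(i) {
      n <- round(nchar(ex$sequence[i]) * depth * abund[i] / (2 * rl))
      sample_fragment_reads(ex$sequence[i], n, rl, cfg$frag_len_mean,
                            cfg$frag_len_sd,
                            sprintf("%s_r_%s_%s", substr(sex, 1, 1), tissue, ex$id[i]))
    })
  }

  reads <- dplyr::bind_rows(out)
  reads$mate1 <- add_seq_errors(reads$mate1, cfg$error_rate)
  reads$mate2 <- add_seq_errors(reads$mate2, cfg$error_rate)
  reads
}

#' Tile error-free reads across sequences
#'
#' Deterministic helper that emits single-end reads starting every `step`
#' positions (always including the final window) from both strands.
#'
#' @param seqs Named character vector of source sequences.
#' @param read_len Read length (bp).
#' @param step Distance between consecutive read starts (bp).
#' @return Named character vector of reads.
#' @export
tile_reads <- function(seqs, read_len = 100, step = 5) {
  seqs <- as_named_seqs(seqs)
  out <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    if (L < read_len) return(character(0))
    starts <- unique(c(seq(1, L - read_len + 1, by = step), L - read_len + 1))
    fwd <- substring(seqs[i], starts, starts + read_len - 1)
    c(setNames(fwd, sprintf("%s_f%05d", names(seqs)[i], starts)),
      setNames(rc(fwd), sprintf("%s_r%05d", names(seqs)[i], starts)))
  })
  unlist(out)
}

#' Write a simulated world to disk
#'
#' Writes the female and male genome FASTA, the planted-gene truth table
#' (TSV), truth transcript FASTA, and gzipped FASTQ pairs for every
#' (sex, datatype, tissue) combination.
#'
#' @param cfg A [sim_config()] (or an existing `sim_world`).
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return The world, invisibly.
#' @export
simulate_to_dir <- function(cfg, dir, force = FALSE) {
  world <- if (inherits(cfg, "sim_world")) cfg else simulate_world(cfg)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(sprintf("simulate_to_dir: '%s' exists and is not empty (use force = TRUE)", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(world$female_genome, file.path(dir, "female_genome.fasta"))
  write_fasta(world$male_genome, file.path(dir, "male_genome.fasta"))
  write_fasta(setNames(world$truth$sequence, world$truth$gene_id),
              file.path(dir, "truth_transcripts.fasta"))
  tt <- world$truth
  tt$expression_profile <- vapply(tt$expression_profile, function(p) {
    paste(sprintf("%s=%g", names(p), p), collapse = ";")
  }, character(1))
  tt$sequence <- NULL
  write_tsv_quiet(tt, file.path(dir, "truth.tsv"))
  combos <- expand.grid(sex = c("male", "female"),
                        tissue = names(world$cfg$rna_depth_by_tissue),
                        stringsAsFactors = FALSE)
  for (sex in c("male", "female")) {
    rd <- emit_reads(world, sex, "genomic")
    write_fastq_pair(rd, file.path(dir, sprintf("%s_genomic_R1.fastq.gz", sex)),
                     file.path(dir, sprintf("%s_genomic_R2.fastq.gz", sex)))
  }
  for (i in seq_len(nrow(combos))) {
    rd <- emit_reads(world, combos$sex[i], "rna", combos$tissue[i])
    base <- sprintf("%s_rna_%s", combos$sex[i], combos$tissue[i])
    write_fastq_pair(rd, file.path(dir, paste0(base, "_R1.fastq.gz")),
                     file.path(dir, paste0(base, "_R2.fastq.gz")))
  }
  invisible(world)
}
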