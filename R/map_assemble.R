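# Read mapping, coverage, assembly and transcript merging. The mapping
# contract is deliberately simple: end-to-end alignment, substitutions only,
# best target by fewest mismatches with deterministic tie-breaks. That is all
# the downstream filters consume, and it keeps every stage oracle-checkable.

#' Map reads end-to-end against a set of targets
#'
#' A read maps iff it has an end-to-end alignment (no indels) to some target
#' with at most `max_mismatches` substitutions, on either strand. The best
#' hit is chosen by fewest mismatches, then lexicographically lowest target
#' id, then leftmost position, then forward strand. Unmapped reads are simply
#' absent from the result.
#'
#' @param reads Named character vector of reads, or a paired-read tibble
#'   (`read_id`, `mate1`, `mate2`; mates are mapped independently with
#'   `/1`, `/2` suffixes).
#' @param targets Named character vector (or `DNAStringSet`, or a tibble with
#'   `id`/`sequence`) of target sequences.
#' @param max_mismatches Maximum substitutions allowed (default 2).
#' @return Tibble: `read_id`, `target_id`, `start`, `end` (0-based,
#'   half-open on the target), `strand`, `mismatches`.
#' @export
map_reads <- function(reads, targets, max_mismatches = 2) {
  targets <- as_named_seqs(targets, "target")
  if (length(targets) == 0) abort("map_reads: targets must be non-empty")
  rd <- flatten_reads(reads)
  ord <- order(names(targets), method = "radix")
  tg <- targets[ord]
  if (length(rd) == 0) {
    return(tibble(read_id = character(0), target_id = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0)))
  }
  hits <- cpp_map_reads(unname(rd), unname(tg), as.integer(max_mismatches))
  tibble(
    read_id = names(rd)[hits$read],
    target_id = names(tg)[hits$target],
    start = hits$start,
    end = hits$start + nchar(rd[hits$read]),
    strand = hits$strand,
    mismatches = hits$mismatches
  )
}

#' Identify reads left unmapped by [map_reads()]
#' @param reads Reads as given to [map_reads()].
#' @param mappings The [map_reads()] result.
#' @return The unmapped subset, in the same representation as `reads`.
#' @export
unmapped_reads <- function(reads, mappings) {
  if (is.character(reads)) {
    rd <- flatten_reads(reads)
    return(rd[!names(rd) %in% mappings$read_id])
  }
  mapped <- unique(sub("/[12]$", "", mappings$read_id))
  reads[!reads$read_id %in% mapped, , drop = FALSE]
}

#' Per-target male/female depth and breadth
#'
#' Depth is total aligned bases divided by target length; breadth is the
#' fraction of positions covered at least once. The normalized log2 ratio
#' divides each depth by its library's total aligned bases before forming
#' log2(male/female); targets without female coverage are flagged male-only
#' and get no ratio.
#'
#' @param mappings_male,mappings_female [map_reads()] results per sex (the
#'   female table may have zero rows).
#' @param targets Named character vector of target sequences (or lengths).
#' @param total_male_bases,total_female_bases Per-library total bases used
#'   for normalization; default to the total aligned bases of each mapping.
#'   Passing sequenced library sizes keeps the autosomal mode at 0 when a
#'   large fraction of one library (for example Y reads in males) does not
#'   align to the reference.
#' @return Tibble: `target_id`, `length`, `depth_male`, `depth_female`,
#'   `breadth_male`, `breadth_female`, `normalized_ratio`, `male_only`.
#' @export
compute_coverage <- function(mappings_male, mappings_female, targets,
                             total_male_bases = NULL,
                             total_female_bases = NULL) {
  targets <- as_named_seqs(targets, "target")
  lens <- if (is.numeric(targets)) targets else nchar(targets)
  per_sex <- function(mp) {
    bad <- setdiff(unique(mp$target_id), names(lens))
    if (length(bad)) {
      abort(sprintf("compute_coverage: mapping references unknown target '%s'", bad[1]))
    }
    total <- sum(mp$end - mp$start)
    stats <- lapply(names(lens), function(id) {
      m <- mp[mp$target_id == id, , drop = FALSE]
      L <- lens[[id]]
      if (nrow(m) == 0) return(c(depth = 0, breadth = 0))
      ir <- IRanges::IRanges(start = m$start + 1, end = pmin(m$end, L))
      cov <- IRanges::coverage(ir, width = L)
      c(depth = sum(m$end - m$start) / L,
        breadth = sum(IRanges::width(cov[cov > 0])) / L)
    })
    list(total = total, m = do.call(rbind, stats))
  }
  male <- per_sex(mappings_male)
  female <- per_sex(mappings_female)
  tot_m <- total_male_bases %||% male$total
  tot_f <- total_female_bases %||% female$total
  ratio <- rep(NA_real_, length(lens))
  ok <- female$m[, "depth"] > 0 & tot_m > 0 & tot_f > 0
  if (any(ok)) {
    ratio[ok] <- log2((male$m[ok, "depth"] / tot_m) /
                        (female$m[ok, "depth"] / tot_f))
  }
  tibble(
    target_id = names(lens),
    length = unname(lens),
    depth_male = unname(male$m[, "depth"]),
    depth_female = unname(female$m[, "depth"]),
    breadth_male = unname(male$m[, "breadth"]),
    breadth_female = unname(female$m[, "breadth"]),
    normalized_ratio = ratio,
    male_only = unname(female$m[, "depth"] == 0 & male$m[, "depth"] > 0)
  )
}

#' Effective length of a transcript
#'
#' The fragment-length correction used by RPKM/TPM quantification:
#' `max(length - frag_len_mean + 1, 0)`.
#'
#' @param length Transcript length(s) in bp.
#' @param frag_len_mean Mean sequencing fragment length (bp), > 0.
#' @return Numeric vector of effective lengths.
#' @export
effective_length <- function(length, frag_len_mean) {
  stopifnot(frag_len_mean > 0)
  pmax(length - frag_len_mean + 1, 0)
}

#' Assemble transcripts from reads with a de Bruijn unitig assembler
#'
#' Contigs are maximal non-branching paths over canonical k-mers observed at
#' least `min_count` times. An iterative cleanup additionally removes k-mers
#' whose count falls below `cleanup_ratio` times the strongest adjacent
#' k-mer, which deletes the short branch paths left by coincident sequencing
#' errors (the role bubble/tip removal plays in production assemblers).
#' Contigs are reported on the strand holding their longest ORF.
#'
#' @param reads Named character vector or paired-read tibble.
#' @param k Odd k-mer size in `[15, 31]` (default 25).
#' @param min_count Minimum k-mer multiplicity (default 2, dropping
#'   singleton error k-mers).
#' @param cleanup_ratio Relative-abundance floor for the neighbour cleanup
#'   (0 disables it).
#' @param min_contig_len Minimum contig length to report (default `2 * k`).
#' @return Transcript-record tibble: `id`, `sequence`, `length`,
#'   `provenance` (list column of contributing ids).
#' @export
assemble_transcripts <- function(reads, k = 25, min_count = 2,
                                 cleanup_ratio = 0.2,
                                 min_contig_len = 2 * k) {
  if (k %% 2 != 1 || k < 15 || k > 31) {
    abort("assemble_transcripts: k must be odd and within [15, 31]")
  }
  rd <- flatten_reads(reads)
  if (length(rd) == 0) return(new_records(character(0)))
  contigs <- cpp_assemble(unname(rd), as.integer(k), as.integer(min_count),
                          cleanup_ratio, as.integer(min_contig_len))
  if (length(contigs) == 0) return(new_records(character(0)))
  oriented <- vapply(contigs, function(s) {
    orf <- longest_orf(s)
    if (orf$len_aa > 0 && orf$strand == "-") rc(s) else s
  }, character(1), USE.NAMES = FALSE)
  oriented <- oriented[order(-nchar(oriented), oriented, method = "radix")]
  new_records(oriented)
}

new_records <- function(seqs, ids = NULL, provenance = NULL) {
  ids <- ids %||% sprintf("contig_%04d", seq_along(seqs))
  tibble(
    id = ids,
    sequence = unname(seqs),
    length = nchar(seqs),
    provenance = provenance %||% as.list(ids)
  )
}

#' Merge overlapping or redundant transcript records
#'
#' Greedy agglomeration: exact duplicates and contained sequences (either
#' strand) are absorbed, then pairs whose suffix/prefix overlap spans at
#' least `min_overlap` bp at `min_identity` identity (either strand) are
#' joined, longest overlap first, until no qualifying overlap remains. When a
#' proteome is supplied, records hitting the same protein in compatible,
#' non-overlapping order are additionally scaffolded with an N gap
#' (simplified scaffolding-by-translational-mapping).
#'
#' @param records Transcript-record tibble (`id`, `sequence`, ...).
#' @param min_overlap Minimum suffix/prefix overlap in bp (default 30).
#' @param min_identity Minimum identity within the overlap (default 0.95).
#' @param proteome Optional named character vector of protein sequences.
#' @return A merged transcript-record tibble; `provenance` lists every input
#'   record that contributed to each output.
#' @export
merge_transcripts <- function(records, min_overlap = 30, min_identity = 0.95,
                              proteome = NULL) {
  stopifnot(min_overlap >= 1)
  if (nrow(records) <= 1) return(records)
  seqs <- records$sequence
  prov <- records$provenance %||% as.list(records$id)
  active <- rep(TRUE, length(seqs))

  # absorb duplicates / containments (either strand)
  ord <- order(-nchar(seqs))
  for (i in ord) {
    if (!active[i]) next
    for (j in seq_along(seqs)) {
      if (i == j || !active[j] || nchar(seqs[j]) > nchar(seqs[i])) next
      if (nchar(seqs[j]) == nchar(seqs[i]) && j < i) next
      if (grepl(seqs[j], seqs[i], fixed = TRUE) ||
          grepl(rc(seqs[j]), seqs[i], fixed = TRUE)) {
        prov[[i]] <- union(prov[[i]], prov[[j]])
        active[j] <- FALSE
      }
    }
  }

  repeat {
    idx <- which(active)
    if (length(idx) <= 1) break
    best <- NULL
    for (i in idx) for (j in idx) {
      if (i == j) next
      for (orient in c("ff", "fr", "rf")) {
        a <- if (orient == "rf") rc(seqs[i]) else seqs[i]
        b <- if (orient == "fr") rc(seqs[j]) else seqs[j]
        ov <- cpp_best_overlap(a, b, as.integer(min_overlap), min_identity)
        if (ov$overlap >= min_overlap &&
            ov$overlap < min(nchar(a), nchar(b)) &&
            (is.null(best) || ov$overlap > best$ov)) {
          best <- list(i = i, j = j, ov = ov$overlap, a = a, b = b)
        }
      }
    }
    if (is.null(best)) break
    merged <- paste0(best$a, substr(best$b, best$ov + 1, nchar(best$b)))
    seqs[best$i] <- merged
    prov[[best$i]] <- union(prov[[best$i]], prov[[best$j]])
    active[best$j] <- FALSE
  }

  seqs <- seqs[active]
  prov <- prov[active]

  # simplified STM: join fragments hitting the same protein in compatible order
  if (!is.null(proteome) && length(seqs) > 1) {
    proteome <- as_named_seqs(proteome, "prot")
    peps <- vapply(seqs, orf_peptide, character(1), USE.NAMES = FALSE)
    hit <- lapply(seq_along(seqs), function(i) {
      if (nchar(peps[i]) < 10) return(NULL)
      sc <- vapply(proteome, function(p) cpp_sw_score(peps[i], p, 11L, 1L),
                   integer(1))
      if (max(sc) < 50) return(NULL)
      b <- which.max(sc)
      aln <- cpp_sw_align(peps[i], proteome[[b]], 11L, 1L)
      list(prot = names(proteome)[b], tstart = aln$tstart, tend = aln$tend)
    })
    by_prot <- split(seq_along(seqs), vapply(hit, function(h) {
      if (is.null(h)) NA_character_ else h$prot
    }, character(1)))
    drop <- logical(length(seqs))
    for (grp in by_prot) {
      if (length(grp) < 2) next
      grp <- grp[order(vapply(hit[grp], `[[`, numeric(1), "tstart"))]
      spans <- vapply(hit[grp], function(h) c(h$tstart, h$tend), numeric(2))
      if (any(spans[1, -1] < spans[2, -ncol(spans)])) next # overlapping hits
      gaps <- pmax(3 * (spans[1, -1] - spans[2, -ncol(spans)]), 3)
      joined <- seqs[grp[1]]
      for (g in seq_along(gaps)) {
        joined <- paste0(joined, strrep("N", gaps[g]), seqs[grp[g + 1]])
      }
      seqs[grp[1]] <- joined
      prov[[grp[1]]] <- Reduce(union, prov[grp])
      drop[grp[-1]] <- TRUE
    }
    seqs <- seqs[!drop]
    prov <- prov[!drop]
  }

  ord <- order(-nchar(seqs), seqs, method = "radix")
  new_records(seqs[ord], ids = sprintf("transcript_%04d", seq_along(seqs)),
              provenance = prov[ord])
}

#' Build a repeat library from genomic reads
#'
#' Assembles contigs from genomic k-mers whose multiplicity reaches
#' `mult` times the median k-mer count — the high-abundance-k-mer view of
#' repeat content used to screen transcripts for repeat sequence.
#'
#' @param reads Genomic reads (named character vector or paired tibble).
#' @param k K-mer size (default 31).
#' @param mult Multiple of the median k-mer count that defines "repetitive"
#'   (default 10).
#' @return Named character vector of repeat contigs (possibly empty).
#' @export
repeat_library <- function(reads, k = 31, mult = 10) {
  rd <- flatten_reads(reads)
  if (length(rd) == 0) return(character(0))
  contigs <- cpp_repeat_contigs(unname(rd), as.integer(k), mult)
  if (length(contigs) == 0) return(character(0))
  contigs <- contigs[order(-nchar(contigs), contigs, method = "radix")]
  setNames(contigs, sprintf("repeat_%03d", seq_along(contigs)))
}

#' Best gapless local alignment of each query against a target set
#'
#' Seed-and-extend (16-mer seeds, both strands) with a maximal-scoring
#' segment per diagonal; score is matches minus mismatches, the BLAT-like
#' scale used by the female-genome and repeat filters.
#'
#' @param queries Character vector of query sequences.
#' @param targets Named character vector of targets.
#' @return Tibble with one row per query: `target_id` (NA if no hit),
#'   `score`, `qstart`, `qend`, `tstart`, `tend` (0-based half-open),
#'   `matches`, `aln_len`, `strand`, `coverage` (aligned fraction of the
#'   query), `identity` (matches / alignment length).
#' @export
best_local_hits <- function(queries, targets) {
  targets <- as_named_seqs(targets, "target")
  if (length(queries) == 0) {
    return(tibble(target_id = character(0), score = integer(0),
                  qstart = integer(0), qend = integer(0), tstart = integer(0),
                  tend = integer(0), matches = integer(0), aln_len = integer(0),
                  strand = character(0), coverage = numeric(0),
                  identity = numeric(0)))
  }
  if (length(targets) == 0) {
    return(tibble(target_id = NA_character_, score = NA_integer_,
                  qstart = NA_integer_, qend = NA_integer_,
                  tstart = NA_integer_, tend = NA_integer_,
                  matches = NA_integer_, aln_len = NA_integer_,
                  strand = NA_character_,
                  coverage = NA_real_, identity = NA_real_)[rep(1, length(queries)), ])
  }
  ord <- order(names(targets), method = "radix")
  tg <- targets[ord]
  h <- cpp_best_local_hit(unname(queries), unname(tg), 16L, 4L)
  tibble(
    target_id = ifelse(is.na(h$target), NA_character_, names(tg)[h$target]),
    score = h$score, qstart = h$qstart, qend = h$qend,
    tstart = h$tstart, tend = h$tend, matches = h$matches,
    aln_len = h$aln_len, strand = h$strand,
    coverage = h$aln_len / nchar(queries),
    identity = h$matches / h$aln_len
  )
}
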