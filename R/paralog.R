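# Paralog discovery in the female genome (6-frame translated Smith-Waterman),
# Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction, and
# X-versus-autosome classification of paralog scaffolds from normalized
# male/female coverage ratios.

# ---- NG86 ------------------------------------------------------------------

# fraction of synonymous single-base changes at each position of each sense
# codon; substitutions creating a stop codon count as nonsynonymous
ng86_site_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    code <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    cods <- sense_codons()
    t2 <- vapply(cods, function(cod) {
      ch <- strsplit(cod, "")[[1]]
      s <- 0
      for (p in 1:3) {
        for (b in setdiff(bases, ch[p])) {
          alt <- ch
          alt[p] <- b
          alt <- paste(alt, collapse = "")
          if (code[[alt]] != "*" && code[[alt]] == code[[cod]]) s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    tab <<- t2
    tab
  }
})

perms_of <- function(x) {
  n <- length(x)
  if (n <= 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perms_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# synonymous/nonsynonymous difference counts for one codon pair, averaging
# over all shortest substitution pathways; pathways crossing a stop codon are
# excluded (all pathways used as fallback if every one crosses a stop)
ng86_codon_diff <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  paths <- perms_of(pos)
  tally <- function(skip_stop) {
    res <- matrix(NA_real_, nrow = length(paths), ncol = 2)
    for (k in seq_along(paths)) {
      cur <- a
      sd <- nd <- 0
      ok <- TRUE
      for (p in paths[[k]]) {
        nxt <- cur
        nxt[p] <- b[p]
        cc <- paste(cur, collapse = "")
        nc <- paste(nxt, collapse = "")
        if (skip_stop && code[[nc]] == "*" && nc != c2) { ok <- FALSE; break }
        if (code[[cc]] == code[[nc]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) res[k, ] <- c(sd, nd)
    }
    res[!is.na(res[, 1]), , drop = FALSE]
  }
  res <- tally(TRUE)
  if (nrow(res) == 0) res <- tally(FALSE)
  c(sd = mean(res[, 1]), nd = mean(res[, 2]))
}

#' Nei-Gojobori (1986) Ka/Ks between two in-frame coding sequences
#'
#' Synonymous and nonsynonymous sites are counted from codon-position
#' degeneracy averaged over both sequences (changes creating stop codons
#' count as nonsynonymous); differences are averaged over all shortest
#' substitution pathways per codon, excluding pathways through stop codons;
#' both proportions receive the Jukes-Cantor correction. A saturated
#' proportion (>= 3/4) yields an infinite rate.
#'
#' @param y_cds,paralog_cds Equal-length, gap-free, in-frame codon sequences
#'   without internal stop codons.
#' @return One-row tibble: `ka`, `ks`, `ka_ks` (NA when Ks is 0), `s_sites`,
#'   `n_sites`, `sd`, `nd`, `ps`, `pn`.
#' @export
kaks <- function(y_cds, paralog_cds) {
  y_cds <- toupper(y_cds)
  paralog_cds <- toupper(paralog_cds)
  if (nchar(y_cds) != nchar(paralog_cds)) {
    abort("kaks: sequences must have equal length")
  }
  if (nchar(y_cds) %% 3 != 0 || nchar(y_cds) == 0) {
    abort("kaks: length must be a positive multiple of 3")
  }
  code <- Biostrings::GENETIC_CODE
  c1 <- codon_split(y_cds)
  c2 <- codon_split(paralog_cds)
  if (any(code[c1] == "*") || any(code[c2] == "*")) {
    abort("kaks: internal stop codon in input")
  }
  st <- ng86_site_table()
  s1 <- sum(st[c1])
  s2 <- sum(st[c2])
  S <- (s1 + s2) / 2
  N <- 3 * length(c1) - S
  d <- vapply(seq_along(c1), function(i) ng86_codon_diff(c1[i], c2[i]),
              numeric(2))
  Sd <- sum(d["sd", ])
  Nd <- sum(d["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 0.75) return(Inf) # saturated
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  ka_ks <- if (is.finite(ks) && ks > 0) ka / ks else
    if (is.infinite(ks)) ka / ks else NA_real_
  tibble(ka = ka, ks = ks, ka_ks = ka_ks, s_sites = S, n_sites = N,
         sd = Sd, nd = Nd, ps = ps, pn = pn)
}

#' Apply only synonymous substitutions at a target Ks
#'
#' Mutates distinct synonymous sites so that the realized synonymous
#' difference proportion matches the Jukes-Cantor expectation at divergence
#' `d`; useful for calibrating Ks recovery.
#'
#' @param cds In-frame coding sequence without internal stops.
#' @param d Target synonymous divergence (substitutions per synonymous site).
#' @return The mutated sequence.
#' @export
mutate_synonymous <- function(cds, d) {
  if (d <= 0) return(cds)
  code <- Biostrings::GENETIC_CODE
  cods <- codon_split(cds)
  st <- ng86_site_table()
  S <- sum(st[cods])
  opts <- list()
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(cods)) {
    ch <- strsplit(cods[i], "")[[1]]
    for (p in 1:3) {
      alts <- vapply(setdiff(bases, ch[p]), function(b) {
        alt <- ch; alt[p] <- b
        alt <- paste(alt, collapse = "")
        code[[alt]] != "*" && code[[alt]] == code[[cods[i]]]
      }, logical(1))
      if (any(alts)) {
        opts[[length(opts) + 1]] <- list(codon = i, pos = p,
                                         alts = setdiff(bases, ch[p])[alts])
      }
    }
  }
  n <- min(round(jc_p_obs(d) * S), length(opts))
  pick <- sample(seq_along(opts), n)
  for (k in pick) {
    o <- opts[[k]]
    b <- if (length(o$alts) == 1) o$alts else sample(o$alts, 1)
    idx <- 3 * (o$codon - 1) + o$pos
    substr(cds, idx, idx) <- b
  }
  cds
}

# ---- translated paralog search ---------------------------------------------

six_frames <- function(seq) {
  L <- nchar(seq)
  rev <- rc(seq)
  strands <- rep(c("+", "-"), each = 3)
  offsets <- rep(0:2, 2)
  subs <- vapply(seq_len(6), function(k) {
    src <- if (strands[k] == "+") seq else rev
    n <- ((L - offsets[k]) %/% 3) * 3
    substr(src, offsets[k] + 1, offsets[k] + n)
  }, character(1))
  nonempty <- nchar(subs) > 0
  peps <- character(6)
  if (any(nonempty)) {
    peps[nonempty] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(subs[nonempty]),
      if.fuzzy.codon = "solve", no.init.codon = TRUE
    ))
  }
  lapply(seq_len(6), function(k) {
    list(strand = strands[k], offset = offsets[k], peptide = peps[k])
  })
}

#' Find the closest paralog of a Y peptide in the female genome
#'
#' Local alignment (Smith-Waterman, BLOSUM62, affine gaps 11/1) of the
#' peptide against all six reading frames of every scaffold. The best hit is
#' chosen by score, ties broken by longer alignment then lexicographic
#' scaffold id. Hits scoring below `min_score` or aligning below
#' `min_identity` are reported as no paralog. The score floor is applied on
#' the bit-score scale (lambda = 0.267, K = 0.041, the gapped BLOSUM62
#' statistics), where 50 bits sits far above the random-alignment regime;
#' raw Smith-Waterman scores of unrelated sequences routinely pass 50.
#'
#' @param y_peptide Amino-acid sequence (>= 20 aa).
#' @param female_genome Named character vector of scaffolds.
#' @param min_score Bit-score floor (default 50).
#' @param min_identity Identity floor over the alignment (default 0.40).
#' @param frames Optional precomputed six-frame translations (a named list of
#'   `six_frames()` results per scaffold) to reuse across repeated searches.
#' @return A tibble with 0 rows (no paralog) or 1 row:
#'   `paralog_scaffold_id`, `paralog_start`, `paralog_end` (0-based half-open
#'   nucleotide span on the forward strand), `strand`, `aln_score`,
#'   `pct_identity`, plus the frame geometry and alignment strings needed for
#'   codon back-threading.
#' @export
find_paralog <- function(y_peptide, female_genome, min_score = 50,
                         min_identity = 0.40, frames = NULL) {
  if (nchar(y_peptide) < 20) {
    abort("find_paralog: peptide must be at least 20 aa")
  }
  female_genome <- as_named_seqs(female_genome, "scaffold")
  ids <- sort(names(female_genome), method = "radix")
  # raw-score equivalent of the bit-score floor
  raw_floor <- ceiling((min_score * log(2) + log(0.041)) / 0.267)
  frames <- frames %||% lapply(female_genome, six_frames)
  best <- NULL
  for (sid in ids) {
    for (fi in seq_along(frames[[sid]])) {
      fr <- frames[[sid]][[fi]]
      if (nchar(fr$peptide) < 5) next
      sc <- cpp_sw_score(y_peptide, fr$peptide, 11L, 1L)
      if (sc < raw_floor) next
      if (!is.null(best) && sc < best$score) next
      aln <- cpp_sw_align(y_peptide, fr$peptide, 11L, 1L)
      cand <- list(score = sc, scaffold = sid, frame = fi, strand = fr$strand,
                   offset = fr$offset, aln = aln, aln_len = aln$aln_len)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && aln$aln_len > best$aln_len)) {
        best <- cand
      }
    }
  }
  empty <- tibble(paralog_scaffold_id = character(0),
                  paralog_start = integer(0), paralog_end = integer(0),
                  strand = character(0), aln_score = numeric(0),
                  raw_score = integer(0),
                  pct_identity = numeric(0), frame_offset = integer(0),
                  alignment = list())
  if (is.null(best)) return(empty)
  identity <- best$aln$n_ident / best$aln$aln_len
  if (identity < min_identity) return(empty)
  L <- nchar(female_genome[[best$scaffold]])
  nt_s <- best$offset + 3 * best$aln$tstart
  nt_e <- best$offset + 3 * best$aln$tend
  if (best$strand == "-") {
    tmp <- nt_s
    nt_s <- L - nt_e
    nt_e <- L - tmp
  }
  bits <- (0.267 * best$score - log(0.041)) / log(2)
  tibble(paralog_scaffold_id = best$scaffold,
         paralog_start = as.integer(nt_s), paralog_end = as.integer(nt_e),
         strand = best$strand, aln_score = bits, raw_score = best$score,
         pct_identity = identity, frame_offset = as.integer(best$offset),
         alignment = list(best$aln))
}

# back-thread a protein alignment into paired codon sequences; codon pairs
# containing a stop or ambiguous base are dropped (the gap-stripping analog
# for diverged paralogs)
codon_pairs_from_alignment <- function(y_cds, scaffold_seq, hit) {
  aln <- hit$alignment[[1]]
  s <- if (hit$strand == "+") scaffold_seq else rc(scaffold_seq)
  off <- hit$frame_offset
  qa <- strsplit(aln$qaln, "")[[1]]
  ta <- strsplit(aln$taln, "")[[1]]
  qp <- aln$qstart
  tp <- aln$tstart
  code <- Biostrings::GENETIC_CODE
  yc <- pc <- character(0)
  for (i in seq_along(qa)) {
    if (qa[i] != "-" && ta[i] != "-") {
      y1 <- substr(y_cds, 3 * qp + 1, 3 * qp + 3)
      p1 <- substr(s, off + 3 * tp + 1, off + 3 * tp + 3)
      ok <- nchar(y1) == 3 && nchar(p1) == 3 &&
        !grepl("[^ACGT]", y1) && !grepl("[^ACGT]", p1) &&
        code[[y1]] != "*" && code[[p1]] != "*"
      if (ok) {
        yc <- c(yc, y1)
        pc <- c(pc, p1)
      }
      qp <- qp + 1
      tp <- tp + 1
    } else if (qa[i] == "-") {
      tp <- tp + 1
    } else {
      qp <- qp + 1
    }
  }
  list(y = paste(yc, collapse = ""), paralog = paste(pc, collapse = ""))
}

#' Classify scaffolds as X-linked or autosomal from coverage ratios
#'
#' X-linked scaffolds sit near log2(male/female) = -1 (hemizygous X),
#' autosomes near 0. A scaffold is called X when its normalized ratio falls
#' below `x_max_log2`, autosomal when within `auto_band` of zero, male-only
#' when it lacks female coverage, and ambiguous otherwise. Scaffolds shorter
#' than `min_len` are not classified.
#'
#' @param coverage A [compute_coverage()] tibble.
#' @param x_max_log2 Upper bound of the X class (default -0.5).
#' @param auto_band Half-width of the autosomal band around 0 (default 0.5).
#' @param min_len Minimum scaffold length (default 1000 bp).
#' @return Tibble: `scaffold_id`, `length`, `log2_ratio`, `class`.
#' @export
classify_scaffold <- function(coverage, x_max_log2 = -0.5, auto_band = 0.5,
                              min_len = 1000) {
  cov <- coverage[coverage$length >= min_len, , drop = FALSE]
  cls <- dplyr::case_when(
    cov$male_only ~ "male_only",
    is.na(cov$normalized_ratio) ~ "ambiguous",
    cov$normalized_ratio < x_max_log2 ~ "X",
    abs(cov$normalized_ratio) <= auto_band ~ "autosome",
    TRUE ~ "ambiguous"
  )
  tibble(scaffold_id = cov$target_id, length = cov$length,
         log2_ratio = cov$normalized_ratio, class = cls,
         x_max_log2 = x_max_log2, auto_band = auto_band)
}

#' Call the origin of Y candidates from their paralog's scaffold class
#'
#' Paralogs on X-class scaffolds mark ancestral/X-derived Y genes (escapees
#' of the proto-sex chromosome); autosomal paralogs mark secondary
#' acquisitions; anything else is unknown.
#'
#' @param pairs Paralog-pair tibble (needs `y_transcript_id`,
#'   `paralog_scaffold_id`).
#' @param scaffold_calls A [classify_scaffold()] tibble.
#' @return `pairs` with `scaffold_class` and `origin_call` columns.
#' @export
classify_origin <- function(pairs, scaffold_calls) {
  cls <- scaffold_calls$class[match(pairs$paralog_scaffold_id,
                                    scaffold_calls$scaffold_id)]
  pairs$scaffold_class <- cls
  pairs$origin_call <- dplyr::case_when(
    is.na(pairs$paralog_scaffold_id) ~ "unknown",
    !is.na(cls) & cls == "X" ~ "ancestral_x_derived",
    !is.na(cls) & cls == "autosome" ~ "autosomal_acquisition",
    TRUE ~ "unknown"
  )
  pairs
}

#' Paralog discovery and divergence for a candidate set
#'
#' For each candidate transcript: translate its longest ORF, search the
#' female genome for the closest paralog, back-thread the protein alignment
#' to paired codons, and estimate Ka/Ks (NG86). When scaffold classifications
#' are supplied, origins are called.
#'
#' @param records Candidate transcript records (`id`, `sequence`).
#' @param female_genome Named character vector of scaffolds.
#' @param scaffold_calls Optional [classify_scaffold()] tibble.
#' @param min_score,min_identity Floors passed to [find_paralog()]
#'   (bit score and identity).
#' @return One row per candidate: paralog location, alignment score and
#'   identity, `ka`, `ks`, `ka_ks`, `scaffold_class`, `origin_call`.
#' @export
paralog_analysis <- function(records, female_genome, scaffold_calls = NULL,
                             min_score = 50, min_identity = 0.40) {
  female_genome <- as_named_seqs(female_genome, "scaffold")
  frames <- lapply(female_genome, six_frames)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    base <- tibble(y_transcript_id = records$id[i],
                   paralog_scaffold_id = NA_character_,
                   paralog_start = NA_integer_, paralog_end = NA_integer_,
                   aln_score = NA_real_, pct_identity = NA_real_,
                   ka = NA_real_, ks = NA_real_, ka_ks = NA_real_)
    pep <- orf_peptide(records$sequence[i])
    if (nchar(pep) < 20) return(base)
    hit <- find_paralog(pep, female_genome, min_score, min_identity,
                        frames = frames)
    if (nrow(hit) == 0) return(base)
    base$paralog_scaffold_id <- hit$paralog_scaffold_id
    base$paralog_start <- hit$paralog_start
    base$paralog_end <- hit$paralog_end
    base$aln_score <- hit$aln_score
    base$pct_identity <- hit$pct_identity
    cp <- codon_pairs_from_alignment(orf_cds(records$sequence[i]),
                                     female_genome[[hit$paralog_scaffold_id]],
                                     hit)
    if (nchar(cp$y) >= 30) {
      kk <- kaks(cp$y, cp$paralog)
      base$ka <- kk$ka
      base$ks <- kk$ks
      base$ka_ks <- kk$ka_ks
    }
    base
  })
  pairs <- dplyr::bind_rows(rows)
  if (!is.null(scaffold_calls)) {
    pairs <- classify_origin(pairs, scaffold_calls)
  } else {
    pairs$scaffold_class <- NA_character_
    pairs$origin_call <- ifelse(is.na(pairs$paralog_scaffold_id),
                                "unknown", NA_character_)
  }
  pairs
}
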