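# Independent oracles: a brute-force all-positions mapper, and a
# pathway-enumeration NG86 calculator written separately from the package
# implementation.

oracle_map_reads <- function(reads, targets, max_mm) {
  tg <- targets[order(names(targets), method = "radix")]
  rows <- list()
  for (ri in seq_along(reads)) {
    best <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") reads[[ri]] else rc(reads[[ri]])
      L <- nchar(q)
      qc <- strsplit(q, "")[[1]]
      for (ti in seq_along(tg)) {
        Lt <- nchar(tg[[ti]])
        if (Lt < L) next
        tc <- strsplit(tg[[ti]], "")[[1]]
        for (s in 0:(Lt - L)) {
          mm <- sum(qc != tc[(s + 1):(s + L)])
          if (mm > max_mm) next
          cand <- list(mm = mm, ti = ti, s = s, strand = strand)
          if (is.null(best) ||
              mm < best$mm ||
              (mm == best$mm && ti < best$ti) ||
              (mm == best$mm && ti == best$ti && s < best$s) ||
              (mm == best$mm && ti == best$ti && s == best$s &&
                 strand == "+" && best$strand == "-")) {
            best <- cand
          }
        }
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = names(reads)[ri], target_id = names(tg)[best$ti],
        start = best$s, end = best$s + nchar(reads[[ri]]),
        strand = best$strand, mismatches = best$mm
      )
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(read_id = character(0), target_id = character(0),
                   start = integer(0), end = integer(0),
                   strand = character(0), mismatches = integer(0))
}

# --- NG86 oracle ------------------------------------------------------------

.oracle_code <- Biostrings::GENETIC_CODE
.oracle_bases <- c("A", "C", "G", "T")

oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    for (b in .oracle_bases[.oracle_bases != ch[pos]]) {
      mut <- ch
      mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (.oracle_code[[mutc]] != "*" &&
          .oracle_code[[mutc]] == .oracle_code[[codon]]) {
        syn <- syn + 1
      }
    }
    total <- total + syn / 3
  }
  total
}

# enumerate every ordering of the differing positions via recursion distinct
# from the package's permutation generator
oracle_paths <- function(remaining, current, acc) {
  if (length(remaining) == 0) return(append(acc, list(current)))
  for (i in seq_along(remaining)) {
    acc <- oracle_paths(remaining[-i], c(current, remaining[i]), acc)
  }
  acc
}

oracle_codon_diff <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  if (length(diff_pos) == 0) return(c(0, 0))
  orderings <- oracle_paths(diff_pos, integer(0), list())
  score_path <- function(ord, forbid_stop) {
    cur <- a
    sd <- 0
    nd <- 0
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- .oracle_code[[paste(cur, collapse = "")]]
      aa2 <- .oracle_code[[paste(nxt, collapse = "")]]
      if (forbid_stop && aa2 == "*" &&
          paste(nxt, collapse = "") != c2) {
        return(NULL)
      }
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  kept <- Filter(Negate(is.null), lapply(orderings, score_path, forbid_stop = TRUE))
  if (length(kept) == 0) {
    kept <- lapply(orderings, score_path, forbid_stop = FALSE)
  }
  m <- do.call(rbind, kept)
  colMeans(m)
}

oracle_ng86 <- function(seq1, seq2) {
  n <- nchar(seq1) %/% 3
  c1 <- substring(seq1, 3 * seq_len(n) - 2, 3 * seq_len(n))
  c2 <- substring(seq2, 3 * seq_len(n) - 2, 3 * seq_len(n))
  S <- (sum(vapply(c1, oracle_syn_sites, numeric(1))) +
          sum(vapply(c2, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * n - S
  d <- rowSums(vapply(seq_len(n), function(i) oracle_codon_diff(c1[i], c2[i]),
                      numeric(2)))
  ps <- if (S > 0) d[1] / S else 0
  pn <- if (N > 0) d[2] / N else 0
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 0.75) return(Inf)
    -0.75 * log(1 - 4 * p / 3)
  }
  list(S = S, N = N, Sd = d[1], Nd = d[2], ks = jc(ps), ka = jc(pn))
}

oracle_binom_upper <- function(k, n, p) {
  sum(vapply(k:n, function(x) {
    choose(n, x) * p^x * (1 - p)^(n - x)
  }, numeric(1)))
}

random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_cds_test <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- setdiff(names(gc)[gc != "*"], "ATG")
  paste0("ATG",
         paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
         "TAA")
}
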