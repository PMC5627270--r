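# Small sequence utilities shared across modules.

#' Reverse-complement DNA sequences
#'
#' @param x Character vector of DNA sequences (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @export
rc <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# the 61 sense codons of the standard genetic code
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

# random single-ORF coding sequence: ATG + (n_codons - 2) sense codons + TAA
make_cds <- function(n_codons) {
  stopifnot(n_codons >= 3)
  body <- sample(setdiff(sense_codons(), "ATG"), n_codons - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

codon_split <- function(seq) {
  n <- nchar(seq) %/% 3
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

translate_nt <- function(seq) {
  # tolerant translation used for ORF handling; trims partial codons
  n <- (nchar(seq) %/% 3) * 3
  if (n == 0) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(substr(seq, 1, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
}

#' Locate the longest open reading frame
#'
#' Scans all three frames of both strands for ATG-to-stop open reading
#' frames. The returned coordinates refer to the strand on which the ORF was
#' found ("+" is the input orientation).
#'
#' @param seq A single DNA sequence.
#' @return A list with `len_aa` (codons excluding the stop), `strand`,
#'   `start` and `end` (0-based half-open nucleotide span of the ORF
#'   including its stop codon, on `strand`). `len_aa` is 0 when no complete
#'   ORF exists.
#' @export
longest_orf <- function(seq) {
  best <- list(len_aa = 0L, strand = "+", start = NA_integer_, end = NA_integer_)
  stops <- stop_codons()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    L <- nchar(s)
    for (frame in 0:2) {
      n <- (L - frame) %/% 3
      if (n < 2) next
      cods <- substring(s, frame + 3 * (seq_len(n) - 1) + 1,
                        frame + 3 * seq_len(n))
      is_start <- cods == "ATG"
      is_stop <- cods %in% stops
      open_at <- NA_integer_
      for (i in seq_len(n)) {
        if (is.na(open_at) && is_start[i]) open_at <- i
        if (!is.na(open_at) && is_stop[i]) {
          len <- i - open_at # codons excluding stop
          if (len > best$len_aa) {
            best <- list(
              len_aa = len, strand = strand,
              start = frame + 3L * (open_at - 1L),
              end = frame + 3L * i
            )
          }
          open_at <- NA_integer_
        }
      }
    }
  }
  best
}

orf_peptide <- function(seq) {
  orf <- longest_orf(seq)
  if (orf$len_aa == 0) return("")
  s <- if (orf$strand == "+") seq else rc(seq)
  cds <- substr(s, orf$start + 1, orf$end - 3) # drop the stop codon
  translate_nt(cds)
}

orf_cds <- function(seq) {
  orf <- longest_orf(seq)
  if (orf$len_aa == 0) return("")
  s <- if (orf$strand == "+") seq else rc(seq)
  substr(s, orf$start + 1, orf$end - 3)
}

# expected proportion of differing sites at Jukes-Cantor divergence d
jc_p_obs <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# JC distance from an observed difference proportion
jc_correct <- function(p) {
  ifelse(p >= 0.75, NaN, -0.75 * log(1 - 4 * p / 3))
}

#' Apply point substitutions at a given divergence
#'
#' Substitutes `round(p * nchar(seq))` sites, where `p` is the Jukes-Cantor
#' expected difference proportion at divergence `d` (substitutions/site), at
#' uniformly sampled distinct positions. Uses the current RNG state.
#'
#' @param seq A single DNA sequence.
#' @param d Divergence in substitutions per site.
#' @return The mutated sequence.
#' @export
mutate_jc <- function(seq, d) {
  if (d <= 0) return(seq)
  L <- nchar(seq)
  n_sub <- round(jc_p_obs(d) * L)
  if (n_sub == 0) return(seq)
  pos <- sample.int(L, n_sub)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# read tibbles: flatten a paired-read tibble into a named vector of mates
flatten_reads <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
    return(setNames(unname(reads), ids))
  }
  stopifnot(is.data.frame(reads))
  if (!all(c("read_id", "mate1", "mate2") %in% names(reads))) {
    abort("paired reads need columns read_id, mate1, mate2")
  }
  setNames(
    c(reads$mate1, reads$mate2),
    c(paste0(reads$read_id, "/1"), paste0(reads$read_id, "/2"))
  )
}

as_named_seqs <- function(x, prefix = "seq") {
  if (inherits(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (is.data.frame(x)) {
    idcol <- intersect(c("id", "target_id", "scaffold_id"), names(x))[1]
    x <- setNames(x$sequence, x[[idcol]])
  }
  if (is.null(names(x))) names(x) <- sprintf("%s_%04d", prefix, seq_along(x))
  x
}
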