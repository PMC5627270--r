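# Readers and writers for the standard interchange formats. Sequence parsing
# is delegated to Biostrings; tables go through readr.

#' Read a FASTA file into a named character vector
#' @param path Path to a FASTA file (optionally gzipped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#' @param seqs Named character vector (or tibble with id/sequence columns).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_named_seqs(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a pair of FASTQ files into a paired-read tibble
#'
#' @param path1,path2 Paths to the R1/R2 FASTQ files (optionally gzipped).
#' @return A tibble with columns `read_id`, `mate1`, `mate2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  rd <- function(p) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(p, format = "fastq"),
      error = function(e) {
        abort(sprintf("malformed FASTQ in '%s': %s", p, conditionMessage(e)))
      }
    )
    setNames(as.character(x), sub("/[12]$", "", sub("\\s.*$", "", names(x))))
  }
  m1 <- rd(path1)
  m2 <- rd(path2)
  if (length(m1) != length(m2)) {
    abort(sprintf("FASTQ pair mismatch: %d vs %d records", length(m1), length(m2)))
  }
  tibble(read_id = names(m1), mate1 = unname(m1), mate2 = unname(m2))
}

#' Write a paired-read tibble to gzipped FASTQ (Phred+33)
#'
#' @param reads Tibble with `read_id`, `mate1`, `mate2`.
#' @param path1,path2 Output paths (".gz" suffix triggers gzip).
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  wr <- function(seqs, ids, suffix, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    txt <- paste0("@", ids, suffix, "\n", seqs, "\n+\n", qual)
    writeLines(txt, con)
  }
  wr(reads$mate1, reads$read_id, "/1", path1)
  wr(reads$mate2, reads$read_id, "/2", path2)
  invisible(c(path1, path2))
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
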