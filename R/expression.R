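# Tissue expression of Y candidates: TPM quantification, row z-scores for
# heatmap-style comparison, an ORF-based coding call, testis-bias flags, and
# the exact binomial enrichment test.

#' Quantify expression as TPM across samples
#'
#' Fragments are assigned to their best target ([map_reads()] tie-breaks);
#' per-transcript fragment counts are divided by effective length and
#' renormalized so each sample sums to one million.
#'
#' @param records Transcript records (`id`, `sequence`).
#' @param samples Named list of read sets (paired tibbles or named character
#'   vectors), one per sample.
#' @param frag_len_mean Mean fragment length (bp) for the effective-length
#'   correction.
#' @param max_mismatches Mapping mismatch allowance (default 2).
#' @return A `tpm_matrix`: tibble with `transcript_id` plus one TPM column
#'   per sample.
#' @export
quantify_tpm <- function(records, samples, frag_len_mean,
                         max_mismatches = 2) {
  stopifnot(nrow(records) > 0, length(samples) > 0,
            !is.null(names(samples)))
  el <- effective_length(records$length, frag_len_mean)
  if (all(el == 0)) {
    abort("quantify_tpm: all effective lengths are 0")
  }
  tg <- setNames(records$sequence, records$id)
  cols <- lapply(samples, function(rd) {
    cnt <- count_fragments(rd, tg, max_mismatches)$counts
    rate <- ifelse(el > 0, cnt / el, 0)
    if (sum(rate) > 0) rate * 1e6 / sum(rate) else rate
  })
  out <- tibble(transcript_id = records$id)
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  class(out) <- c("tpm_matrix", class(out))
  out
}

tpm_values <- function(mat) {
  as.matrix(mat[, setdiff(names(mat), "transcript_id"), drop = FALSE])
}

#' Row-normalize an expression matrix to z-scores
#'
#' Per transcript: subtract the row mean and divide by the sample standard
#' deviation (n-1 denominator). Constant rows become all-zero and are
#' flagged in the `constant` column.
#'
#' @param mat A `tpm_matrix` (or tibble with `transcript_id` + value
#'   columns); each row needs at least 2 samples.
#' @return The matrix with values replaced by z-scores, plus a `constant`
#'   logical column.
#' @export
row_zscore <- function(mat) {
  v <- tpm_values(mat)
  if (ncol(v) < 2) abort("row_zscore: need at least 2 samples per row")
  mu <- rowMeans(v)
  sdev <- apply(v, 1, sd)
  constant <- sdev == 0
  z <- (v - mu) / ifelse(constant, 1, sdev)
  z[constant, ] <- 0
  out <- tibble(transcript_id = mat$transcript_id)
  for (j in seq_len(ncol(v))) out[[colnames(v)[j]]] <- z[, j]
  out$constant <- constant
  out
}

#' Call coding potential from the longest open reading frame
#'
#' A transcript is called coding iff its longest ATG-to-stop ORF (either
#' strand) reaches `min_orf_aa` codons.
#'
#' @param x Transcript records tibble or character vector of sequences.
#' @param min_orf_aa Minimum ORF length in amino acids (default 80).
#' @return Tibble: `id`, `orf_aa`, `coding` ("coding"/"noncoding").
#' @export
coding_call <- function(x, min_orf_aa = 80) {
  seqs <- if (is.data.frame(x)) setNames(x$sequence, x$id) else
    as_named_seqs(x, "seq")
  orf <- vapply(seqs, function(s) longest_orf(s)$len_aa, integer(1))
  tibble(id = names(seqs), orf_aa = unname(orf),
         coding = unname(ifelse(orf >= min_orf_aa, "coding", "noncoding")))
}

#' Exact one-sided binomial enrichment test
#'
#' Tests whether `k_y` of `n_y` genes having a property is more than expected
#' under the background rate `k_bg / n_bg`: the upper-tail probability
#' P(X >= k_y) for X ~ Binomial(n_y, k_bg / n_bg).
#'
#' @param k_y,n_y Count and size of the gene set of interest.
#' @param k_bg,n_bg Count and size of the background.
#' @return One-row `enrichment_result` tibble: `k_y`, `n_y`, `k_bg`, `n_bg`,
#'   `p0`, `p_value`.
#' @export
binomial_enrichment <- function(k_y, n_y, k_bg, n_bg) {
  ok <- function(k, n) length(k) == 1 && length(n) == 1 && !is.na(k) &&
    !is.na(n) && n > 0 && k >= 0 && k <= n
  if (!ok(k_y, n_y) || !ok(k_bg, n_bg)) {
    abort("binomial_enrichment: counts must satisfy 0 <= k <= n, n > 0")
  }
  p0 <- k_bg / n_bg
  p <- pbinom(k_y - 1, n_y, p0, lower.tail = FALSE)
  out <- tibble(k_y = k_y, n_y = n_y, k_bg = k_bg, n_bg = n_bg,
                p0 = p0, p_value = p)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Flag testis/accessory-gland expression bias per transcript
#'
#' `max_in_testis_or_gland`: the sample with the highest TPM is a testis or
#' accessory-gland sample (and is expressed at all).
#' `exclusive_to_testis_and_gland`: expression above `expr_present_min`
#' occurs only in testis/accessory-gland samples (and in at least one).
#'
#' @param mat A `tpm_matrix`.
#' @param tissue_labels Named character vector mapping sample column names to
#'   tissues (values such as "testis", "accessory_gland", "head", "ovary").
#' @param expr_present_min TPM above which a transcript counts as expressed
#'   (default 1).
#' @return Tibble: `transcript_id`, `max_in_testis_or_gland`,
#'   `exclusive_to_testis_and_gland`.
#' @export
testis_bias_flags <- function(mat, tissue_labels, expr_present_min = 1) {
  v <- tpm_values(mat)
  missing_lab <- setdiff(colnames(v), names(tissue_labels))
  if (length(missing_lab)) {
    abort(sprintf("testis_bias_flags: no tissue label for sample '%s'",
                  missing_lab[1]))
  }
  male_limited <- tissue_labels[colnames(v)] %in% c("testis", "accessory_gland")
  max_flag <- vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    max(r) > 0 && male_limited[which.max(r)]
  }, logical(1))
  excl_flag <- vapply(seq_len(nrow(v)), function(i) {
    expressed <- v[i, ] > expr_present_min
    any(expressed) && all(male_limited[expressed])
  }, logical(1))
  tibble(transcript_id = mat$transcript_id,
         max_in_testis_or_gland = max_flag,
         exclusive_to_testis_and_gland = excl_flag)
}
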