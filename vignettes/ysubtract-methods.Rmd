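---
title: "Methods: subtractive inference of Y-linked transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtractive inference of Y-linked transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

A Y chromosome is male-limited and typically impossible to assemble from
short reads, yet its genes leave two usable footprints: they are *expressed
in males* and they are *absent from female sequence data*. `ysubtract`
exploits both. Transcripts are assembled from the male RNA-seq reads that do
not map to a female genome assembly, and each candidate must then survive a
series of subtractive filters — against the female assembly, female RNA,
female genomic read coverage, relative expression, a repeat library, and a
length-reliability criterion — before being reported as Y-linked. The
design is deliberately conservative: every filter removes candidates that
*could* be explained without invoking the Y, so the survivors are
male-limited with high specificity, at the cost of known blind spots
discussed below.

## The cascade and its thresholds

`pipeline_config()` pins the decision thresholds. All comparisons are strict
in the direction of their wording.

* **Stage 1 — read subtraction.** Male RNA reads are mapped end-to-end
  (substitutions only, ≤ `map_max_mismatch` = 2) to the female assembly;
  only unmapped reads continue. The mapper is intentionally minimal: the
  simulator plants intron-free transcripts, so spliced alignment adds
  nothing, and an end-to-end Hamming contract can be verified against a
  brute-force oracle. Ties are broken by fewest mismatches, then
  lexicographically lowest target id, then leftmost position, then forward
  strand, making every downstream count reproducible.
* **Stage 2 — assembly.** A canonical-k-mer de Bruijn unitig assembler
  (`assembly_k` = 25, `assembly_min_count` = 2). Contigs are reported on the
  strand carrying the longest open reading frame. Beyond the count floor, an
  iterative cleanup removes k-mers whose count falls below
  `assembly_cleanup_ratio` = 0.2 times their strongest graph neighbour; this
  is the role tip and bubble removal plays in production assemblers.
  Without it, two reads that happen to share a sequencing error at the same
  site (expected a handful of times per transcriptome at an error rate of
  10^-3 and 50× depth) create a count-2 branch that fragments the
  transcript. Contigs shorter than 2k are dropped, which also discards the
  short orphan paths such coincident errors leave behind.
* **Stage 3 — female genome.** A transcript is discarded iff its best
  gapless local alignment to the female assembly covers more than
  `female_hit_len_frac` = 0.90 of its length at identity ≥
  `female_hit_identity` = 0.98. Alignment score is matches − mismatches;
  hits scoring below `min_aln_score` = 50 are treated as *no hit*. Read
  literally, the underlying rule ("discard if a strong hit, or if the score
  is below 50") would also discard transcripts with *no* female-genome hit
  at all — the very transcripts the subtraction is meant to keep — so the
  score clause is interpreted as a hit-quality floor, not a discard rule.
  Gapless alignment is exact here because divergence is modelled (and, for
  diverged paralogs, dominated) by substitutions.
* **Stage 4 — female RNA.** Discard iff female RNA reads, mapped at ≤
  `female_rna_max_mismatch` = 2 mismatches, cover ≥ `female_rna_breadth` =
  0.50 of the transcript's positions. Breadth is computed per transcript
  (fraction of covered positions), the less forgiving of the two readings of
  "mapped 50% or more of their sequence".
* **Stage 5 — merging.** Suffix/prefix overlaps of ≥ `merge_min_overlap` =
  30 bp at ≥ `merge_min_identity` = 0.95, either strand, longest overlap
  first; exact duplicates and contained sequences are absorbed. With a
  proteome supplied, fragments hitting the same protein in compatible,
  non-overlapping order are additionally joined with an N gap (a simplified
  scaffolding-by-translational-mapping step).
* **Stage 6 — genomic coverage.** Retain iff male genomic breadth >
  `male_breadth_min` = 0.60 and female genomic breadth <
  `female_breadth_max` = 0.10.
* **Stage 7 — expression.** RPKM = fragments × 10⁹ / (effective length ×
  library mapped fragments). Retain iff male RPKM > `expr_ratio_min` = 2 ×
  female RPKM; zero female RPKM with positive male RPKM retains. The ratio
  form is used rather than the stricter verbal "expression in males but not
  females", because the ratio is the precise statement of the same rule. A
  record with zero effective length cannot be quantified and is discarded
  with an audit note.
* **Stage 8 — repeats.** The repeat library is assembled from genomic
  k-mers (`genome_k` = 31) whose multiplicity reaches `repeat_mult` = 10 ×
  the median k-mer count — a high-abundance-k-mer proxy for a dedicated
  repeat-discovery tool. A transcript is discarded on any library hit with
  score ≥ `min_aln_score`.
* **Stage 9 — effective length.** Retain iff effective length / length >
  `eff_len_frac_min` = 0.60, with effective length = max(L − mean fragment
  length + 1, 0). This simple fragment-length correction may differ from
  what a likelihood-based quantifier reports as "effective length", but the
  pass/fail contract (> 0.6 × length) is preserved under either definition
  for the fragment geometries simulated here.

Stage order is fixed; a discarded transcript never re-enters. The
`filter_report` records, for every record, the measured metric and the
pass/fail decision at each stage it reached, so input = retained + discarded
holds at every stage.

## The sex-swap control

`sex_swap_control()` reruns the identical cascade with the sexes exchanged
(the male assembly serving as reference). Female-specific calls estimate the
false-positive rate empirically, and the species-inclusion rule — keep a
species only when male-specific transcripts outnumber female-specific ones
more than `sexswap_ratio_min` = 2-fold — guards against datasets whose
coverage or assembly quality makes the subtraction unreliable.

## Paralog search and divergence

`find_paralog()` runs Smith–Waterman (BLOSUM62, affine gaps 11/1) of the
candidate's ORF peptide against all six reading frames of every female
scaffold. Two floors apply: alignment identity ≥ 0.40, and a score floor of
50 interpreted on the **bit-score scale** (λ = 0.267, K = 0.041, the
standard gapped BLOSUM62 statistics). The bit-score interpretation matters:
raw local-alignment scores of unrelated sequences routinely exceed 50 in a
genome-sized search space, whereas 50 bits sits far above the random regime.
With a raw floor, Y-unique genes acquire spurious "paralogs" and their
origin is misclassified; with the bit floor, planted unique genes return no
paralog, as they should.

Ka/Ks uses the Nei–Gojobori (1986) counting method with equal pathway
weighting, chosen because it is closed-form and verifiable against an
exhaustive substitution-pathway oracle (the test suite enumerates every
pathway for all sense-codon pairs and for random 100-codon pairs and demands
exact agreement of site and difference counts). Conventions: substitutions
that create a stop codon count as nonsynonymous when counting sites;
pathways passing through a stop codon are excluded from the averaging (all
pathways are used as a fallback when every pathway crosses a stop); both
difference proportions receive the Jukes–Cantor correction, and a saturated
proportion (≥ 3/4, which single-codon inputs can produce) is reported as an
infinite rate rather than silently truncated. Ka/Ks is undefined (NA) when
Ks = 0. The codon alignment is derived by back-threading the protein
alignment; codon pairs containing a stop or an ambiguous base are dropped
pairwise, the codon-level analogue of gap stripping. For display, Ka/Ks
values above 3 are truncated at 3 in `plot_divergence()` while raw values
remain in the tables.

## Scaffold classification by coverage ratio

A hemizygous X receives half the male genomic coverage of an autosome, so
log2(normalized male/female) clusters near −1 for X scaffolds and near 0 for
autosomes. `classify_scaffold()` calls X below `x_max_log2` = −0.5 and
autosome within ±`auto_band` = 0.5 of zero — thresholds chosen to bisect the
two expected modes — with scaffolds under 1000 bp left unclassified and
zero-female-coverage scaffolds flagged male-only. Normalization divides each
depth by its library's total bases. Normalizing by *aligned* bases instead
would shift the autosomal mode upward whenever a substantial fraction of the
male library (the Y reads) cannot align to the female reference; in the
synthetic worlds the Y is ~20% of the male genome and the shift would be
+0.26, so library-size normalization is the default in
`world_scaffold_calls()`.

## Expression and enrichment

`quantify_tpm()` assigns each fragment to its best target and renormalizes
count/effective-length rates to 10⁶ per sample. Row z-scores use the n−1
standard deviation; constant rows become zero and are flagged. The coding
call is a longest-ORF rule (≥ 80 codons, both strands) — a deliberately
simple stand-in for classifier-based coding-potential tools; it is
conservative on fragments, and a random 300 bp sequence essentially never
reaches 80 codons. Tissue-bias flags are computed over dissected-tissue
samples only (a whole-body sample would defeat the exclusivity definition),
with "expressed" meaning TPM > 1 — a threshold the exclusivity rule needs
but that is otherwise unstated, so it is exposed as `expr_present_min`.
Enrichment is the exact one-sided upper-tail binomial probability at the
background rate; the two planned tests (highest-in-testis/gland, and
exclusive-to-testis/gland) are reported raw, without multiplicity
correction.

## What the synthetic worlds emulate

`simulate_world()` builds a female assembly (autosomes ×2, X ×2) and a male
genome (autosomes ×2, X ×1, Y ×1), so the expected male/female depth ratio
is 1 on autosomes and 1/2 on X. Sequence is i.i.d. uniform; genes are planted
as single-ORF coding sequences with short UTRs; paralogs are copies with a
*fixed number* of substitutions, round(p(d)·L) with p(d) the Jukes–Cantor
expected difference proportion at divergence d, at uniform random positions.
The fixed count makes the recent-duplicate identity deterministically ≥ 98%
— the regime the stage-3 filter removes by design — while keeping expected
divergence consistent with the Jukes–Cantor model for Ka/Ks recovery.
Repeat-embedded Y genes carry one full copy of a satellite motif in their 3'
UTR, and each motif also exists as a genomic tandem array on an autosome;
distinct motifs per gene keep the assembly graphs of different Y transcripts
disjoint. Default planted set: 7 X escapees and 7 autosomal acquisitions at
divergences 0.15–0.40, 6 Y-unique genes, 2 recent duplicates at 0.02, and 2
repeat-embedded genes — 20 genes detectable by design, 4 designed misses.
Divergences of 0.15 and above reflect the regime in which subtraction is
expected to work at these read lengths: below roughly 0.1, stray
cross-mapping of female reads onto the Y copy begins to erode the genomic
and RNA breadth criteria, which is precisely the known blind spot of the
method.

Fragments are sampled with overhang beyond the source ends and clipped, so
terminal positions are covered at full depth; error-free reads at ≥ 20×
therefore reconstruct planted transcripts full length, which makes the
assembler's fidelity contract directly testable. Reads carry a per-base
substitution error (default 10^-3); each (sex, datatype, tissue) combination
draws from its own RNG stream derived from the world seed, so adding a
tissue never perturbs other read sets.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: realistic repeat landscapes and
transposable-element families, GC and coverage biases, indels and structural
variation, heterozygosity beyond X hemizygosity, spliced transcripts and
isoforms, quality-score-correlated errors, and genuinely fragmented female
assemblies. Real applications should expect lower sensitivity than the
synthetic benchmark, particularly for young, X-homologous Y genes.

## Problem sizes and numerical checks

The shipped tests and the acceptance script use worlds of 8 autosomal + 4 X
scaffolds of 8 kb, ~56 expressed genes of ~1.3 kb, 20× genomic and 50× RNA
coverage (≈ 40,000 genomic and 25,000 RNA read mates per sex) — sizes chosen
so a full cascade runs in seconds while keeping per-gene read depth at
realistic study levels. Five independent seeds back the recovery,
sex-swap, and classification claims. The threshold-monotonicity property is
checked by re-applying 50 randomly tightened configurations to the recorded
per-record metrics (`refilter()`), which is exact because metrics do not
depend on thresholds, and three tightened settings are additionally
cross-checked against full pipeline reruns. Mapping-resolution parameters
(k-mer sizes, mismatch allowances) are excluded from the sweep since
changing them changes the measured metrics themselves, not the decision
rules. Degenerate inputs are defined rather than accidental: empty read sets
assemble to empty record sets, a world without Y scaffolds yields an empty
candidate list, zero female coverage flags a target male-only instead of
producing an infinite ratio, and constant expression rows z-score to zero
with a flag.

## Known limitations

Sensitivity to Y genes with close homologs is bounded by design (the ≥ 98%
identity duplicate is always removed at stage 3); transcripts shorter than
~2.5× the fragment length are discarded by the effective-length rule no
matter how convincing their male specificity; the assembler targets
desk-scale read sets (up to roughly a million reads), not production
volumes; and the mapper's no-indel contract means indel-diverged paralogs
are effectively invisible to stages 1, 4 and 6, though the gapped protein
search still finds them downstream.
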