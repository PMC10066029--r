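---
title: "Measuring what supplementary data adds to variant literature retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring what supplementary data adds to variant literature retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suppvar)
```

## The retrieval model

`suppvar` treats variant-literature search as boolean retrieval over three
separately indexed document collections: abstracts, full texts and
supplementary data (SD). A variant query is not a string but an
equivalence class of strings, and the retrieval unit for evaluation is the
*parent article*, not the individual file — an article that contributes an
abstract, a body and four spreadsheet attachments is still one article.

Three assumptions shape the design:

* **Variant identity is well-defined across levels.** A protein-level
  substitution, the coding changes that can produce it under the standard
  genetic code, and their genomic projections all denote the same
  biological object, so retrieval should union mentions at every level.
* **Curation is recall-oriented.** For rarely studied variants every
  document matters; the metrics therefore focus on *silence* (queries with
  an empty baseline result) and *novelty* (SD hits whose article the
  baseline missed) rather than on ranking quality.
* **Mentions are surface forms, not annotations.** No entity recognizer is
  assumed; a document mentions a variant iff one of the query's generated
  surface forms occurs verbatim (post-normalization) in its text.

## Nomenclature expansion

`parse_variant()` accepts `GENE:change` with the change at protein level
(1-letter, 3-letter, `p.`-prefixed, arrow, spaced and `600V>E`
substitution spellings; stop as `*`, `X` or `Ter`), coding level
(`c.1799T>A` or bare `1799T>A`) and genomic level (`g.123A>G`). Two
deliberate resolutions of ambiguous spellings:

* `A123G` (both letters are amino acids *and* nucleotides) parses as a
  **protein** change with an `ambiguous` flag, because the benchmarks this
  tool targets are protein-change SNPs;
* bare `123A>G` (both letters nucleotides, `>` present) parses as
  **coding**, also flagged.

Cross-level mapping needs a transcript model: exon intervals in
transcription order, the CDS and its offset in the spliced transcript.
`protein_to_coding()` enumerates the nine single-nucleotide mutants of the
codon and keeps those translating to the target residue — the result can
legitimately be empty (e.g. Lys→Trp needs two edits) and can contain
several coding changes, all of which are rendered. On the minus strand
genomic changes are reported on the forward strand, so the coding↔genomic
maps complement bases in both directions; both maps are inverse to each
other by construction and by property test.

Every expansion template must re-parse to the change that generated it
(parser–generator closure); this is what keeps the query language and the
rendering inventory from drifting apart as templates are added. The
template set is the function argument `templates`; the default inventory
is the package's minimum contract, and gene-synonym alternation is **off**
unless a lexicon is supplied, because unconstrained gene aliasing is a
recall experiment of its own.

## Indexing and matching

`normalize_text()` case-folds maximal alphanumeric runs but keeps `>`,
`→`, `.` and `*` *inside* tokens, so `c.1799T>A` survives as one token
while a sentence-final period is stripped. Matching is exact on normalized
tokens; multi-token templates (`V 600 E`) match as contiguous token
sequences. There is deliberately no fuzzy matching: OCR-corrupted mentions
(`£858R`) are simply missed, and the synthetic generator measures exactly
how much that costs.

Gene co-occurrence (`require_gene = TRUE`) is the default because a bare
`V600E` in a table row is not attributable to a gene. The proximity filter
— keep a match only if the nearest gene mention is within `max_distance`
words or characters — is **off** by default: it is a precision heuristic
whose cost to recall should be an explicit user decision. Ranking (for
top-k screening) is by number of distinct matched forms, ties broken by
document id: deterministic and reproducible, nothing more is claimed for
it.

## Evaluation metrics

For each benchmark variant, with `B` the baseline article set (abstract ∪
full text) and `S` the SD article set:

* silent iff `B = ∅`; rescued iff silent and `S ≠ ∅`;
  rescue rate `= 100 · n_rescued / n_silent` (0 when nothing is silent,
  flagged);
* novel SD articles `= S \ B`; relative gain
  `= 100 · mean|S \ B| / mean|B|`, undefined (`NA`, with a warning) when
  the baseline mean is 0;
* significance analysis: raw labels are merged case-insensitively —
  substring `benign` first, then `pathogenic`, else `unknown` — and the
  SD-only stratum (silent but rescued) is cross-tabulated against all
  other variants. The chi-squared statistic is computed from the textbook
  formula `Σ(|O−E|−c)²/E` with `c = 0.5` only on 2×2 tables (default on,
  matching common statistical software), p-values from the upper tail of
  the χ² distribution. The label-merging rule has a known sharp edge: a
  raw label like "conflicting interpretations of pathogenicity" would
  merge to `pathogenic` by substring; the generator emits the truncated
  "Conflicting interpretations" spelling, and real inputs with such labels
  should be pre-mapped.

Percentages in written reports are rounded to 2 decimals; all in-memory
values are unrounded. Overall columns pooled from per-stratum averages use
size-weighted means (`pooled_mean()`).

## What the synthetic generator emulates — and what it does not

`simulation_config()` defaults encode the study conditions the package is
built to measure:

| parameter | default | rationale |
|---|---|---|
| `n_variants` | 1000 | a ClinVar-scale benchmark draw |
| `placement` | abstract .100, fulltext .129, sd_only .441, absent .330 | 77.1% of variants invisible to the baseline, 57.2% of those recoverable from SD |
| `significance` | pathogenic .0841, benign .1068, unknown .8091 | the SD-only stratum is dominated by variants of unknown significance |
| `variants_per_sd_file` | 25 | SD files are many-variant tables mixing genes, which creates gene–variant mismatch hazards |
| `ocr_noise_rate` | 0 | noise is opt-in; the confusion table ships with `L→£`, `O→0`, `I→1`, `S→5` |

Each variant gets exactly one planted mention (or none, for `absent`),
rendered with a template drawn uniformly from its expansion. OCR noise is
applied as a *separate seeded stage* over the finished supplementary text,
so the pre-noise corpus is byte-identical across noise rates and the RNG
stream of document generation is independent of the noise setting. The
ground truth records every planted mention, its document and whether it
survived the noise intact.

The generator does **not** emulate: realistic article prose (filler is
drawn from a fixed word list), per-article SD file-count distributions (a
single `variants_per_sd_file` knob instead), variants mentioned in several
articles, or image content (noise is applied at text level). Consequently,
a 100% recall result on a noise-free synthetic corpus shows that the
expansion/index/matching chain is lossless for its own templates — it says
nothing about templates real authors use that the inventory lacks, which
is the main open question for any template-based expander.

## Numerical and degenerate-input choices

* Coordinates are 1-based throughout (HGVS convention); codon index
  `= ceil(cDNA position / 3)`; exon intervals inclusive.
* Reference mismatches (query says Val, transcript codon says Met) are
  errors, never silent corrections; synonymous coding changes are flagged,
  not rejected.
* Empty collections index to empty (warned) indexes; empty result sets are
  valid; `precision_at_k` on an empty ranking is 0 with a warning; a
  contingency analysis is skipped (reported `NULL`) when either stratum is
  empty.
* Chi-squared requires positive marginals and at least a 2×2 table;
  the continuity correction is clamped so a corrected deviation can never
  go negative.
* Determinism: all generators are seeded (`seed`, with fixed offsets per
  stage), index construction is order-stable, and rankings have total
  order — reports regenerate bit-identically from persisted outcomes.

## Problem sizes

The bundled tests run the full pipeline at 40–1000 variants, 4–20 genes
and corpora of a few hundred documents; the acceptance script's synthetic
experiment uses the default n = 1000. These sizes were chosen so that
binomial checks on the placement machinery have reasonable power (3σ on
n = 1000 is ±4 percentage points of silence) while the whole suite stays
interactive. The retrieval metrics are scale-free — they consume
per-variant article *sets* — so nothing about the formulas changes at
literature scale; what does change at scale (index engineering, ranking
under millions of hits) is explicitly out of scope.

## Known limitations

* No indels, duplications, intronic or UTR coordinates: the benchmark
  scope is single-nucleotide protein-changing (and nonsense) variants.
* No full HGVS grammar, no accession resolution, no external database
  lookups; transcripts come from the package's own TSV/JSON/FASTA formats.
* Exact token matching means OCR noise and creative typography reduce
  recall by design; the proximity filter is the only precision heuristic
  shipped.
* Legacy binary `.xls` is not ingested (convert upstream); `.xlsx` is read
  through its XML cell model via `readxl`, and image supplements are
  expected as pre-extracted `.txt` sidecars produced by an external OCR
  stage.
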