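# suppvar

Supplementary-data aware retrieval of genomic variant literature.

## The problem

Curating a genomic variant — deciding whether, say, `BRAF:V600E` is
pathogenic — means collecting every publication that mentions it. Two
things make this hard:

1. **Nomenclature.** The same single-nucleotide variant is written dozens
   of ways: `V600E`, `Val600Glu`, `p.V600E`, `c.1799T>A`,
   `g.140453136A>T`, spaced and arrow spellings, and so on. A literal
   search misses most mentions.
2. **Silence.** A large fraction of variants — especially variants of
   unknown significance (VUS) — return *no* document at all when only
   abstracts and full texts are searched, because high-throughput results
   live in the supplementary data (SD) files attached to papers:
   spreadsheets, CSV tables, OCRized images.

`suppvar` implements the full pipeline needed to quantify how much the SD
collection helps:

* a **nomenclature engine** that parses `GENE:change` queries at protein,
  coding (cDNA) or genomic level and expands them into every equivalent
  description. Protein → coding uses the standard genetic code: the coding
  changes for an amino-acid substitution `ref`→`alt` at codon *p* are
  exactly the single-nucleotide codon mutants whose translation is `alt`.
  Coding → genomic walks the transcript's exons, complementing bases on
  the minus strand;
* **corpus ingestion** for the three collections (abstract, full text,
  supplementary) from JSONL, with table flattening (CSV/TSV/XLSX → text)
  and the SD selection filter `[(gene AND variant) OR polymorphism OR
  mutat*]`;
* an **inverted index** whose tokenizer preserves variant-internal
  punctuation (`c.1799T>A` stays one token), with gene co-occurrence
  matching and an optional gene–variant proximity filter;
* **evaluation metrics**: for each benchmark variant the abstract ∪
  full-text article set is the *baseline*; the variant is *silent* when
  that set is empty and *rescued* when the SD index returns a document.
  The rescue rate (relative silence reduction) is
  `100 · n_rescued / n_silent`; the novelty gain is
  `100 · avg(novel SD docs) / avg(baseline docs)` where an SD hit is novel
  iff its parent article is absent from the baseline. Significance
  distributions (pathogenic / benign / unknown, merged from raw labels)
  are compared between SD-only variants and the rest with Pearson's
  chi-squared test of independence (Yates continuity correction on 2×2
  tables);
* a seeded **synthetic-data generator** producing transcripts, a
  benchmark of single-nucleotide protein changes and a three-collection
  corpus with known ground truth, including many-variant SD tables and
  OCR-style character noise (e.g. `L` → `£`).

## Worked example

Expanding a query across all three levels, using a toy BRAF transcript
whose codon 600 is `GTG`:

```r
library(suppvar)
tx <- toy_braf_transcript()
ex <- expand_all(parse_variant("BRAF:V600E"), tx)
ex$forms
#>              form   level template
#> 1           V600E protein       p1
#> 2       Val600Glu protein       p3
#> 3         p.V600E protein  hgvs_p1
#> 4     p.Val600Glu protein  hgvs_p3
#> 5          V600→E protein    arrow
#> 6         V 600 E protein   spaced
#> 7          600V>E protein      sub
#> 8       c.1799T>A  coding   hgvs_c
#> 9         1799T>A  coding   c_bare
#> 10 g.140001799T>A genomic   hgvs_g
```

The coding form follows from codon arithmetic: codon 600 occupies cDNA
positions 1798–1800, and `GTG` (Val) → `GAG` (Glu) is the T→A change at
position 1799.

A complete synthetic experiment — 400 variants, defaults placing 77.1% of
them outside the baseline collections:

```r
cfg <- simulation_config(seed = 2024, n_variants = 400)
sim <- simulate_experiment(cfg)
idx <- lapply(stats::setNames(nm = c("abstract", "fulltext", "supplementary")),
              function(coll) build_index(sim$corpus, coll))
report <- evaluate_benchmark(sim$benchmark, idx, sim$transcripts)
report
#> Benchmark evaluation: 400 variants (0 skipped)
#>   silent in baseline: 317 (79.25%); rescued by SD: 180 (56.78%)
#>   avg docs: baseline 0.21, SD 0.45, novel 0.45 (gain +218.07%)
#>   significance chi2(2, N = 400) = 0.36, p = 0.835
```

Reading the output: 317/400 variants return nothing from the
abstract/full-text baseline (79.25%, near the configured 77.1% placement
mass), and searching the supplementary tables rescues 180 of them
(56.78%, near the configured 44.1/77.1 = 57.2% recoverable fraction). The
SD collection roughly triples the average number of retrieved articles,
all of them novel here because the simulated SD files hang off articles
the baseline never returns. `write_report(report, dir)` emits the
table-shaped TSVs and a JSON report.

A thin command-line front end over the same functions lives at
`inst/cli/suppvar.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "suppvar.R", package = "suppvar"))')
Rscript $CLI expand BRAF:V600E
Rscript $CLI simulate --config sim.yaml --out sim/
Rscript $CLI index --corpus sim/supplementary.jsonl --collection supplementary --out idx/supplementary.json
Rscript $CLI search GENE03:T160I --indexes idx/ --transcripts sim/transcripts.tsv
Rscript $CLI evaluate --benchmark sim/benchmark.tsv --indexes idx/ --out report/
```

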