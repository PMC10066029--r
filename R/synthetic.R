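# Seeded synthetic data: transcripts, a benchmark of single-nucleotide
# protein changes, and a three-collection corpus with known ground truth.
# The generator emulates the statistical structure of real variant-curation
# corpora: a large baseline-silent fraction, supplementary tables that mix
# many variants from different genes, and OCR-style character noise in the
# supplementary collection.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"])

FILLER_WORDS <- c(
  "analysis", "cohort", "patients", "samples", "sequencing", "results",
  "observed", "reported", "clinical", "study", "data", "figure", "table",
  "method", "assay", "expression", "protein", "tumor", "cells", "allele",
  "frequency", "population", "screening", "panel", "exome", "candidate",
  "signal", "control", "case", "evidence")

#' Configuration of a synthetic retrieval experiment
#'
#' The defaults describe the study conditions the package evaluates: a
#' ClinVar-like benchmark in which 77.1% of variants are invisible to the
#' abstract/full-text baseline (placement mass on `sd_only` + `absent`),
#' of which 441/771 = 57.2% are recoverable from supplementary data; a
#' significance distribution matching the supplementary-only stratum
#' (8.41% pathogenic, 10.68% benign, 80.91% unknown); and supplementary
#' files that are many-variant tables.
#'
#' @param seed integer seed; every downstream generator derives its RNG
#'   state from it.
#' @param n_genes number of synthetic genes/transcripts.
#' @param n_variants benchmark size.
#' @param placement named probabilities over `abstract`, `fulltext`,
#'   `sd_only`, `absent` (where the single planted mention of each variant
#'   lives; `absent` variants are mentioned nowhere).
#' @param significance named probabilities over `pathogenic`, `benign`,
#'   `unknown`; raw labels are sampled among unmerged spellings ("Likely
#'   benign", "not provided", ...).
#' @param variants_per_sd_file rows per supplementary table; tables mix
#'   genes, creating gene-variant mismatch hazards.
#' @param ocr_noise_rate per-character substitution probability applied to
#'   supplementary text only.
#' @param ocr_substitutions named character vector, OCR confusion table.
#' @param templates protein surface-form templates used when rendering
#'   mentions.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 20L,
                              n_variants = 1000L,
                              placement = c(abstract = 0.100,
                                            fulltext = 0.129,
                                            sd_only = 0.441,
                                            absent = 0.330),
                              significance = c(pathogenic = 0.0841,
                                               benign = 0.1068,
                                               unknown = 0.8091),
                              variants_per_sd_file = 25L,
                              ocr_noise_rate = 0,
                              ocr_substitutions = c(L = "£", O = "0",
                                                    I = "1", S = "5"),
                              templates = protein_templates()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n_genes <- as.integer(n_genes); n_variants <- as.integer(n_variants)
  if (n_genes < 1L || n_variants < 1L) stop("counts must be >= 1")
  if (ocr_noise_rate < 0 || ocr_noise_rate > 1)
    stop("ocr_noise_rate must be in [0, 1]")
  chk <- function(p, nm) {
    if (!setequal(names(p), nm)) stop("need probabilities named ",
                                      paste(nm, collapse = ", "))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("probabilities must be non-negative and sum to 1")
    p[nm]
  }
  placement <- chk(placement, c("abstract", "fulltext", "sd_only", "absent"))
  significance <- chk(significance, c("pathogenic", "benign", "unknown"))
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_variants = n_variants, placement = placement,
                 significance = significance,
                 variants_per_sd_file = as.integer(variants_per_sd_file),
                 ocr_noise_rate = ocr_noise_rate,
                 ocr_substitutions = ocr_substitutions,
                 templates = templates),
            class = "sim_config")
}

#' Generate synthetic genes and transcript models
#'
#' Random coding sequences (ATG start, sense codons only, terminal stop)
#' placed on single- or multi-exon transcripts on both strands, with
#' optional 5' and 3' UTR within the exons.
#'
#' @param config a [simulation_config()].
#' @return named list of [transcript_model()] objects.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  out <- list()
  for (i in seq_len(config$n_genes)) {
    gene <- sprintf("GENE%02d", i)
    n_codons <- sample(120:320, 1L)
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, n_codons - 1L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    cds_offset <- sample(c(0L, 30L, 60L), 1L)
    utr3 <- 3L * sample(0:20, 1L)
    total <- cds_offset + nchar(cds) + utr3
    n_exons <- sample(1:4, 1L)
    cuts <- sort(sample(seq_len(total - 1L), n_exons - 1L))
    widths <- diff(c(0L, cuts, total))
    strand <- sample(c("+", "-"), 1L)
    gaps <- sample(50:500, n_exons, replace = TRUE)
    anchor <- sample(1e6:2e6, 1L)
    if (strand == "+") {
      starts <- anchor + cumsum(c(0L, (widths + gaps)[-n_exons]))
      exons <- data.frame(start = starts, end = starts + widths - 1L)
    } else {
      ends <- anchor - cumsum(c(0L, (widths + gaps)[-n_exons]))
      exons <- data.frame(start = ends - widths + 1L, end = ends)
    }
    out[[gene]] <- transcript_model(gene, sprintf("chr%d", sample(1:22, 1L)),
                                    strand, exons, cds, cds_offset)
  }
  out
}

sample_unmerged_label <- function(class) {
  pool <- switch(class,
    pathogenic = c("Pathogenic", "Likely pathogenic"),
    benign = c("Benign", "Likely benign"),
    unknown = c("Uncertain significance", "not provided",
                "Conflicting interpretations"))
  sample(pool, 1L)
}

#' Generate a synthetic benchmark of protein-level SNPs
#'
#' Every sampled variant is a single amino-acid substitution reachable by
#' exactly one nucleotide change of its codon (nonsense changes included),
#' so the cross-level expansion is always non-empty. Raw significance
#' labels are drawn with their unmerged spellings.
#'
#' @param config a [simulation_config()].
#' @param transcripts result of [generate_reference()].
#' @return list with `benchmark` (data.frame `gene`, `protein_change`,
#'   `raw_significance`, `source`) and `details` (adds `variant_id`, codon
#'   index and residues).
#' @export
generate_benchmark <- function(config, transcripts) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- names(transcripts)
  seen <- character()
  rows <- vector("list", config$n_variants)
  i <- 1L
  attempts <- 0L
  while (i <= config$n_variants) {
    attempts <- attempts + 1L
    if (attempts > 50L * config$n_variants)
      stop("could not sample enough distinct variants; increase n_genes")
    gene <- sample(genes, 1L)
    tx <- transcripts[[gene]]
    n_codons <- nchar(tx$cds_sequence) %/% 3L
    ci <- sample(2:(n_codons - 1L), 1L)
    codon <- substr(tx$cds_sequence, 3L * ci - 2L, 3L * ci)
    ref_aa <- translate_codon(codon)
    alts <- character()
    for (off in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(codon, off, off) == b) next
      mut <- codon; substr(mut, off, off) <- b
      aa <- translate_codon(mut)
      if (aa != ref_aa) alts <- c(alts, aa)
    }
    if (!length(alts)) next
    alt_aa <- sample(unique(alts), 1L)
    change <- aa_change(ref_aa, ci, alt_aa)
    pc <- render_protein_form(change, "p1")
    key <- paste0(gene, ":", pc)
    if (key %in% seen) next
    seen <- c(seen, key)
    class <- sample(names(config$significance), 1L,
                    prob = config$significance)
    rows[[i]] <- data.frame(variant_id = key, gene = gene,
                            protein_change = pc,
                            raw_significance = sample_unmerged_label(class),
                            source = "synthetic", codon = ci,
                            ref_aa = ref_aa, alt_aa = alt_aa,
                            stringsAsFactors = FALSE)
    i <- i + 1L
  }
  details <- do.call(rbind, rows)
  list(benchmark = details[, c("gene", "protein_change", "raw_significance",
                               "source")],
       details = details)
}

apply_ocr_noise <- function(text, rate, subs) {
  if (rate <= 0) return(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  idx <- which(chars %in% names(subs))
  if (length(idx)) {
    hit <- idx[stats::runif(length(idx)) < rate]
    chars[hit] <- unname(subs[chars[hit]])
  }
  paste(chars, collapse = "")
}

filler <- function(n) paste(sample(FILLER_WORDS, n, replace = TRUE),
                            collapse = " ")

#' Generate the three-collection corpus with ground truth
#'
#' For each benchmark variant a placement is drawn from the configured
#' distribution. `abstract`/`fulltext` variants get their own short article
#' containing the gene symbol next to one randomly chosen surface form of
#' the variant. `sd_only` variants are written into multi-variant
#' supplementary tables (one row per variant, genes mixed within a file,
#' parent articles disjoint from the baseline articles). `absent` variants
#' appear nowhere. OCR-style character noise is applied to supplementary
#' text at the configured rate; the ground truth records the rendered form
#' of every planted mention and whether it survived the noise intact.
#'
#' @param config a [simulation_config()].
#' @param bench result of [generate_benchmark()].
#' @param transcripts result of [generate_reference()].
#' @return list with `corpus` (see [corpus()]) and `truth` (data.frame with
#'   one row per variant: `variant_id`, `placement`, `form`, `level`,
#'   `doc_id`, `article_id`, `intact`); the corpus fingerprint is attached
#'   to both as attribute `fingerprint`.
#' @export
generate_corpus <- function(config, bench, transcripts) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  details <- bench$details
  n <- nrow(details)
  placement <- sample(names(config$placement), n, replace = TRUE,
                      prob = config$placement)

  # pre-draw one surface form per variant
  forms <- character(n); levels <- character(n)
  for (i in seq_len(n)) {
    q <- parse_variant(paste0(details$gene[i], ":", details$protein_change[i]))
    ex <- expand_all(q, transcripts[[details$gene[i]]],
                     templates = config$templates)
    k <- sample(nrow(ex$forms), 1L)
    forms[i] <- ex$forms$form[k]
    levels[i] <- ex$forms$level[k]
  }

  docs <- list()
  truth <- data.frame(variant_id = details$variant_id, placement = placement,
                      form = forms, level = levels,
                      doc_id = NA_character_, article_id = NA_character_,
                      intact = FALSE, stringsAsFactors = FALSE)

  for (i in which(placement %in% c("abstract", "fulltext"))) {
    coll <- placement[i]
    doc_id <- sprintf("%s%05d", if (coll == "abstract") "A" else "F", i)
    art <- sprintf("PMID%05d", i)
    text <- paste(filler(8), details$gene[i], forms[i], filler(8))
    docs[[length(docs) + 1L]] <-
      data.frame(doc_id = doc_id, parent_article_id = art, collection = coll,
                 text = text, file_type = "", stringsAsFactors = FALSE)
    truth$doc_id[i] <- doc_id; truth$article_id[i] <- art
    truth$intact[i] <- TRUE
  }

  sd_idx <- which(placement == "sd_only")
  if (length(sd_idx)) {
    sd_idx <- sample(sd_idx)  # shuffle so files mix genes
    files <- split(sd_idx, ceiling(seq_along(sd_idx) / config$variants_per_sd_file))
    ftypes <- c("xlsx", "csv", "docx", "txt", "tif", "jpg", "pdf")
    for (f in seq_along(files)) {
      ix <- files[[f]]
      doc_id <- sprintf("S%04d", f)
      art <- sprintf("PMCSD%04d", f)
      header <- "Supplementary table listing gene variant mutations and frequencies"
      rows <- vapply(ix, function(i)
        paste(details$gene[i], forms[i],
              sprintf("%.3f", stats::runif(1L)), sample(FILLER_WORDS, 1L)),
        "")
      text <- paste(c(header, rows), collapse = "\n")
      docs[[length(docs) + 1L]] <-
        data.frame(doc_id = doc_id, parent_article_id = art,
                   collection = "supplementary", text = text,
                   file_type = sample(ftypes, 1L), stringsAsFactors = FALSE)
      truth$doc_id[ix] <- doc_id; truth$article_id[ix] <- art
      truth$intact[ix] <- TRUE
    }
  }

  # filler-only distractor abstracts
  for (d in seq_len(max(1L, n %/% 50L))) {
    docs[[length(docs) + 1L]] <-
      data.frame(doc_id = sprintf("D%04d", d),
                 parent_article_id = sprintf("PMIDX%04d", d),
                 collection = "abstract", text = filler(20), file_type = "",
                 stringsAsFactors = FALSE)
  }

  cp <- corpus(docs)

  # OCR noise is a separate seeded stage over the finished supplementary
  # text, so the pre-noise corpus content is identical across noise rates
  if (config$ocr_noise_rate > 0) {
    set.seed(config$seed + 3L)
    sup <- which(cp$collection == "supplementary")
    for (j in sup)
      cp$text[j] <- apply_ocr_noise(cp$text[j], config$ocr_noise_rate,
                                    config$ocr_substitutions)
    for (i in seq_len(n)) {
      if (is.na(truth$doc_id[i]) || truth$placement[i] != "sd_only") next
      txt <- cp$text[cp$doc_id == truth$doc_id[i]]
      truth$intact[i] <- grepl(truth$form[i], txt, fixed = TRUE) &&
        grepl(details$gene[i], txt, fixed = TRUE)
    }
  }

  fp <- sprintf("sim|seed=%d|docs=%d|chars=%d", config$seed, nrow(cp),
                sum(nchar(cp$text)))
  attr(cp, "fingerprint") <- fp
  attr(truth, "fingerprint") <- fp
  list(corpus = cp, truth = truth)
}

#' Run the full synthetic pipeline for one configuration
#'
#' Convenience wrapper: reference, benchmark, corpus.
#'
#' @param config a [simulation_config()].
#' @return list with `transcripts`, `benchmark`, `details`, `corpus`,
#'   `truth` and the `config`.
#' @export
simulate_experiment <- function(config) {
  transcripts <- generate_reference(config)
  bench <- generate_benchmark(config, transcripts)
  cg <- generate_corpus(config, bench, transcripts)
  list(transcripts = transcripts, benchmark = bench$benchmark,
       details = bench$details, corpus = cg$corpus, truth = cg$truth,
       config = config)
}

#' Score retrieval results against the planted ground truth
#'
#' Recall: fraction of planted, retrievable mentions (variants with a
#' planted document) whose document was retrieved. Precision: fraction of
#' retrieved documents that are the variant's planted document.
#'
#' @param retrieved named list mapping `variant_id` to the character vector
#'   of retrieved doc ids (any collection). May carry a `fingerprint`
#'   attribute; if both sides carry one, they must agree.
#' @param truth ground-truth data.frame from [generate_corpus()].
#' @return list with `recall`, `precision` and a per-placement breakdown
#'   data.frame.
#' @export
score_against_truth <- function(retrieved, truth) {
  fa <- attr(retrieved, "fingerprint"); fb <- attr(truth, "fingerprint")
  if (!is.null(fa) && !is.null(fb) && !identical(fa, fb))
    stop("results and ground truth come from different corpora")
  planted <- truth[!is.na(truth$doc_id), , drop = FALSE]
  hit <- vapply(seq_len(nrow(planted)), function(i)
    planted$doc_id[i] %in% retrieved[[planted$variant_id[i]]], logical(1L))
  n_retr <- sum(lengths(retrieved))
  n_true_retr <- sum(vapply(names(retrieved), function(v) {
    pd <- truth$doc_id[truth$variant_id == v]
    sum(retrieved[[v]] %in% pd)
  }, 0))
  by_pl <- do.call(rbind, lapply(split(hit, planted$placement), function(h)
    data.frame(n = length(h), retrieved = sum(h), recall = mean(h))))
  list(recall = if (nrow(planted)) mean(hit) else NA_real_,
       precision = if (n_retr) n_true_retr / n_retr else NA_real_,
       by_placement = by_pl)
}

#' Write a simulated experiment to disk
#'
#' Produces `transcripts.tsv`, `benchmark.tsv`, one JSONL per collection
#' (`abstract.jsonl`, `fulltext.jsonl`, `supplementary.jsonl`) and
#' `truth.json` under `dir`.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcripts(sim$transcripts, file.path(dir, "transcripts.tsv"))
  write_benchmark(sim$benchmark, file.path(dir, "benchmark.tsv"))
  for (coll in COLLECTIONS) {
    write_documents(sim$corpus[sim$corpus$collection == coll, , drop = FALSE],
                    file.path(dir, paste0(coll, ".jsonl")))
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulation configuration from YAML
#'
#' Every field of [simulation_config()] may appear; missing fields take the
#' defaults.
#'
#' @param path YAML file.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the yaml package")
  y <- yaml::read_yaml(path)
  args <- list(seed = y$seed)
  for (f in c("n_genes", "n_variants", "variants_per_sd_file",
              "ocr_noise_rate", "templates"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  for (f in c("placement", "significance", "ocr_substitutions"))
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  do.call(simulation_config, args)
}
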