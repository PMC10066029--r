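# Evaluation metrics: silence reduction and novelty gain of the
# supplementary-data collection, clinical-significance contingency analysis
# with a chi-squared test of independence, and precision@k.

SIGNIFICANCE_LEVELS <- c("pathogenic", "benign", "unknown")

#' Merge raw clinical-significance labels into three classes
#'
#' Case-insensitive substring mapping: labels containing "benign" (e.g.
#' "Benign", "Likely benign") map to `benign`; labels containing
#' "pathogenic" (checked after benign, so "likely benign" can never be
#' shadowed) map to `pathogenic`; everything else (e.g. "Uncertain
#' significance", "Conflicting interpretations", "not provided") maps to
#' `unknown`.
#'
#' @param raw character vector of free-text significance labels.
#' @return factor with levels `pathogenic`, `benign`, `unknown`.
#' @examples
#' merge_significance(c("Likely benign", "Likely pathogenic", "not provided"))
#' @export
merge_significance <- function(raw) {
  out <- rep("unknown", length(raw))
  low <- tolower(raw)
  out[grepl("pathogenic", low, fixed = TRUE)] <- "pathogenic"
  out[grepl("benign", low, fixed = TRUE)] <- "benign"
  factor(out, levels = SIGNIFICANCE_LEVELS)
}

#' Read and write a benchmark of variants
#'
#' Tab-delimited with columns `gene`, `protein_change`, `raw_significance`
#' and `source` (e.g. `BRCA`, `ClinVar`, `synthetic`).
#'
#' @param path TSV file.
#' @return data.frame with the four columns.
#' @export
read_benchmark <- function(path) {
  d <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("gene", "protein_change", "raw_significance", "source")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("benchmark missing column(s): ", paste(miss, collapse = ", "))
  d[, need]
}

#' @rdname read_benchmark
#' @param benchmark data.frame as returned by [read_benchmark()].
#' @export
write_benchmark <- function(benchmark, path) {
  utils::write.table(benchmark, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-variant retrieval outcome
#'
#' Records, for one benchmark variant, the article ids retrieved from the
#' baseline collections (abstracts plus full texts) and from the
#' supplementary-data collection. Novel SD articles are the set difference:
#' an SD hit counts as novel only when its parent article was absent from
#' the baseline result.
#'
#' @param variant_id identifier of the benchmark variant.
#' @param baseline_docs,sd_docs character vectors of parent article ids.
#' @return object of class `retrieval_outcome` with `novel_sd_docs`
#'   precomputed.
#' @export
retrieval_outcome <- function(variant_id, baseline_docs, sd_docs) {
  baseline_docs <- unique(as.character(baseline_docs))
  sd_docs <- unique(as.character(sd_docs))
  structure(list(variant_id = variant_id,
                 baseline_docs = baseline_docs,
                 sd_docs = sd_docs,
                 novel_sd_docs = setdiff(sd_docs, baseline_docs)),
            class = "retrieval_outcome")
}

#' Silence-reduction metrics
#'
#' A variant is silent when its baseline (abstract + full-text) result is
#' empty; it is rescued when at least one supplementary-data document is
#' retrieved for it. The rescue rate is the relative reduction of the
#' silence: `100 * n_rescued / n_silent` (0 when nothing is silent).
#'
#' @param outcomes list of [retrieval_outcome()] objects.
#' @return list with `n_total`, `n_silent`, `silent_pct`, `n_rescued`,
#'   `rescue_rate` and `sd_docs_rescued` (mean/min/max SD documents among
#'   rescued variants, `NA` when none).
#' @export
silence_metrics <- function(outcomes) {
  n_base <- vapply(outcomes, function(o) length(o$baseline_docs), 0L)
  n_sd <- vapply(outcomes, function(o) length(o$sd_docs), 0L)
  silent <- n_base == 0L
  rescued <- silent & n_sd > 0L
  n_silent <- sum(silent)
  sd_resc <- n_sd[rescued]
  list(n_total = length(outcomes),
       n_silent = n_silent,
       silent_pct = if (length(outcomes)) 100 * n_silent / length(outcomes) else 0,
       n_rescued = sum(rescued),
       rescue_rate = if (n_silent > 0L) 100 * sum(rescued) / n_silent else 0,
       sd_docs_rescued = if (length(sd_resc))
         c(mean = mean(sd_resc), min = min(sd_resc), max = max(sd_resc))
       else c(mean = NA_real_, min = NA_real_, max = NA_real_))
}

#' Novelty metrics of the supplementary-data collection
#'
#' Averages, over all outcomes, of the number of baseline documents, SD
#' documents, novel SD documents (parent article absent from the baseline)
#' and documents across all collections, plus the relative gain
#' `100 * avg_novel / avg_baseline` (undefined — `NA` — when the baseline
#' average is 0).
#'
#' @param outcomes list of [retrieval_outcome()] objects.
#' @return list of per-metric `mean`/`min`/`max` vectors and
#'   `relative_gain`.
#' @export
novelty_metrics <- function(outcomes) {
  mmm <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  n_base <- vapply(outcomes, function(o) length(o$baseline_docs), 0L)
  n_sd <- vapply(outcomes, function(o) length(o$sd_docs), 0L)
  n_novel <- vapply(outcomes, function(o) length(o$novel_sd_docs), 0L)
  n_all <- vapply(outcomes, function(o)
    length(union(o$baseline_docs, o$sd_docs)), 0L)
  list(baseline = mmm(n_base), sd = mmm(n_sd), novel = mmm(n_novel),
       all = mmm(n_all),
       relative_gain = relative_gain(mean(n_novel), mean(n_base)))
}

#' Relative novelty gain
#'
#' @param avg_novel,avg_baseline average per-variant document counts.
#' @return `100 * avg_novel / avg_baseline`; `NA` (undefined) when the
#'   baseline average is 0.
#' @export
relative_gain <- function(avg_novel, avg_baseline) {
  if (avg_baseline == 0) {
    warning("baseline average is 0; relative gain undefined")
    return(NA_real_)
  }
  100 * avg_novel / avg_baseline
}

#' Pooled (weighted) mean across benchmarks
#'
#' Combines per-benchmark averages into the overall column of a report:
#' `sum(w * x) / sum(w)` with the benchmark sizes as weights.
#'
#' @param x per-benchmark means.
#' @param w benchmark sizes.
#' @export
pooled_mean <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  sum(w * x) / sum(w)
}

#' Contingency table of clinical significance between two variant groups
#'
#' Cross-tabulates merged significance labels (pathogenic / benign /
#' unknown) for two disjoint groups of variants, typically the variants
#' found only in the supplementary data versus the rest of the benchmark.
#'
#' @param group_a,group_b character vectors of raw significance labels, or
#'   benchmark data.frames (then disjointness of `gene:protein_change` is
#'   verified).
#' @param names row labels for the two groups.
#' @return object of class `contingency_table`: integer `counts` (2 x 3)
#'   and row-wise `pct` matrices.
#' @export
significance_contingency <- function(group_a, group_b,
                                     names = c("group_a", "group_b")) {
  get_labels <- function(g) {
    if (is.data.frame(g)) g$raw_significance else as.character(g)
  }
  if (is.data.frame(group_a) && is.data.frame(group_b)) {
    ka <- paste(group_a$gene, group_a$protein_change, sep = ":")
    kb <- paste(group_b$gene, group_b$protein_change, sep = ":")
    if (length(intersect(ka, kb)))
      stop("groups are not disjoint: ",
           paste(utils::head(intersect(ka, kb), 3L), collapse = ", "))
  }
  la <- get_labels(group_a); lb <- get_labels(group_b)
  if (!length(la) || !length(lb)) stop("empty group")
  counts <- rbind(table(merge_significance(la)),
                  table(merge_significance(lb)))
  rownames(counts) <- names
  contingency_table(counts)
}

#' Build a contingency table from a counts matrix
#'
#' @param counts matrix of non-negative integer counts with row and column
#'   labels.
#' @return object of class `contingency_table` with `counts`, row-wise
#'   `pct` and the grand total `n`.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  pct <- 100 * counts / rowSums(counts)
  structure(list(counts = counts, pct = pct, n = sum(counts)),
            class = "contingency_table")
}

#' Reconstruct contingency counts from printed percentages
#'
#' Inverts a published percentage table: `counts = round(pct * n / 100)`
#' per row, with the published group sizes.
#'
#' @param pct matrix of row-wise percentages.
#' @param n vector of group sizes, one per row.
#' @return a [contingency_table()].
#' @export
contingency_from_percentages <- function(pct, n) {
  pct <- as.matrix(pct)
  stopifnot(length(n) == nrow(pct))
  counts <- round(sweep(pct, 1L, n, `*`) / 100)
  dimnames(counts) <- dimnames(pct)
  contingency_table(counts)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table (N = ", x$n, ")\n", sep = "")
  print(x$counts)
  cat("Row percentages:\n")
  print(round(x$pct, 2))
  invisible(x)
}

#' Pearson's chi-squared test of independence
#'
#' Computes the statistic `sum((|O - E| - c)^2 / E)` over the table, with
#' the continuity correction `c = 0.5` applied iff `correction` is on and
#' the table is 2 x 2 (the default: on for 2 x 2 tables, off otherwise);
#' degrees of freedom `(r - 1)(s - 1)`; the p-value from the upper tail of
#' the chi-squared distribution (the regularized incomplete gamma function,
#' via [stats::pchisq()]).
#'
#' @param table a [contingency_table()] or a plain counts matrix.
#' @param correction logical or `NULL` (the default rule above).
#' @return list with `statistic`, `df`, `p_value`, `expected` and
#'   `correction`.
#' @export
chi2_independence <- function(table, correction = NULL) {
  counts <- if (inherits(table, "contingency_table")) table$counts
            else as.matrix(table)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal total; expected counts undefined")
  expected <- outer(rs, cs) / n
  is2x2 <- nrow(counts) == 2L && ncol(counts) == 2L
  if (is.null(correction)) correction <- is2x2
  cc <- if (correction && is2x2) 0.5 else 0
  dev <- pmax(abs(counts - expected) - cc, 0)
  statistic <- sum(dev^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       expected = expected, correction = cc > 0)
}

#' Precision at rank k
#'
#' @param ranked character vector of retrieved doc ids, best first.
#' @param relevant set of relevant doc ids.
#' @param k cut-off rank (>= 1).
#' @return `|top-k intersect relevant| / min(k, |ranked|)`; 0 (with a
#'   warning) for an empty ranking.
#' @export
precision_at_k <- function(ranked, relevant, k) {
  stopifnot(k >= 1L)
  if (!length(ranked)) {
    warning("empty ranking; precision@", k, " reported as 0")
    return(0)
  }
  top <- utils::head(ranked, k)
  length(intersect(top, relevant)) / min(k, length(ranked))
}

#' Persist and reload per-variant retrieval outcomes
#'
#' JSON array of objects with `variant_id`, `baseline_docs` and `sd_docs`;
#' novel sets are recomputed on load, so a reloaded report is identical to
#' the original.
#'
#' @param outcomes list of [retrieval_outcome()] objects.
#' @param path JSON file.
#' @export
write_outcomes <- function(outcomes, path) {
  recs <- lapply(outcomes, function(o)
    list(variant_id = o$variant_id,
         baseline_docs = as.list(o$baseline_docs),
         sd_docs = as.list(o$sd_docs)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    retrieval_outcome(r$variant_id,
                      unlist(r$baseline_docs, use.names = FALSE) %||% character(),
                      unlist(r$sd_docs, use.names = FALSE) %||% character()))
}

#' Run the full benchmark evaluation
#'
#' For each benchmark variant: expand the query across all reachable levels
#' (using the gene's transcript model when available), search the three
#' collection indexes, and derive the per-variant retrieval outcome on
#' parent-article identity. Produces the silence, novelty and
#' clinical-significance analyses, per source and overall.
#'
#' @param benchmark data.frame as in [read_benchmark()].
#' @param indexes named list of [build_index()] results with entries
#'   `abstract`, `fulltext`, `supplementary`.
#' @param transcripts optional named list of [transcript_model()]s keyed by
#'   gene.
#' @param require_gene passed to [search_variant()].
#' @param gene_synonyms optional lexicon, see [read_gene_synonyms()].
#' @param proximity optional list `list(max_distance =, unit =)` to apply
#'   [proximity_filter()] to every collection result (off by default).
#' @return object of class `sd_eval_report`: `outcomes`, `silence` and
#'   `novelty` (per source plus `Total`), `significance` (contingency table
#'   of SD-only variants vs the rest, with 2 x 3 and pathogenic-vs-benign
#'   2 x 2 chi-squared tests), and `n_skipped` unparseable rows.
#' @export
evaluate_benchmark <- function(benchmark, indexes, transcripts = NULL,
                               require_gene = TRUE, gene_synonyms = NULL,
                               proximity = NULL) {
  stopifnot(is.data.frame(benchmark))
  if (!nrow(benchmark)) stop("empty benchmark")
  need <- c("abstract", "fulltext", "supplementary")
  miss <- setdiff(need, names(indexes))
  if (length(miss)) stop("missing index(es): ", paste(miss, collapse = ", "))

  outcomes <- list()
  kept <- logical(nrow(benchmark))
  for (i in seq_len(nrow(benchmark))) {
    q <- tryCatch(
      parse_variant(paste0(benchmark$gene[i], ":", benchmark$protein_change[i])),
      error = function(e) NULL)
    if (is.null(q)) {
      message("skipping unparseable benchmark row ", i, ": ",
              benchmark$gene[i], ":", benchmark$protein_change[i])
      next
    }
    tx <- if (!is.null(transcripts)) transcripts[[q$gene]] else NULL
    ex <- tryCatch(expand_all(q, tx, gene_synonyms = gene_synonyms),
                   error = function(e) NULL)
    if (is.null(ex)) {
      message("skipping benchmark row ", i, ": expansion failed")
      next
    }
    res <- search_collections(ex, indexes[need], require_gene = require_gene)
    if (!is.null(proximity))
      res <- Map(function(r, idx) proximity_filter(r, proximity$max_distance,
                                                   proximity$unit, idx),
                 res, indexes[need])
    kept[i] <- TRUE
    outcomes[[length(outcomes) + 1L]] <- retrieval_outcome(
      variant_id = paste0(benchmark$gene[i], ":", benchmark$protein_change[i]),
      baseline_docs = union(res$abstract$articles, res$fulltext$articles),
      sd_docs = res$supplementary$articles)
  }
  if (!length(outcomes)) stop("no benchmark row could be evaluated")

  bm <- benchmark[kept, , drop = FALSE]
  by_source <- split(seq_along(outcomes), bm$source)
  silence <- c(lapply(by_source, function(ix) silence_metrics(outcomes[ix])),
               list(Total = silence_metrics(outcomes)))
  novelty <- c(lapply(by_source, function(ix) novelty_metrics(outcomes[ix])),
               list(Total = novelty_metrics(outcomes)))

  n_base <- vapply(outcomes, function(o) length(o$baseline_docs), 0L)
  n_sd <- vapply(outcomes, function(o) length(o$sd_docs), 0L)
  sd_only <- n_base == 0L & n_sd > 0L
  significance <- NULL
  if (any(sd_only) && any(!sd_only)) {
    tab <- significance_contingency(bm$raw_significance[!sd_only],
                                    bm$raw_significance[sd_only],
                                    names = c("rest", "sd_only"))
    significance <- list(
      table = tab,
      chi2_all = chi2_independence(tab),
      chi2_path_benign = chi2_independence(
        tab$counts[, c("pathogenic", "benign")]))
  }
  structure(list(outcomes = outcomes, silence = silence, novelty = novelty,
                 significance = significance, n_skipped = sum(!kept)),
            class = "sd_eval_report")
}

#' @export
print.sd_eval_report <- function(x, ...) {
  tot <- x$silence$Total
  cat("Benchmark evaluation: ", tot$n_total, " variants (",
      x$n_skipped, " skipped)\n", sep = "")
  cat(sprintf("  silent in baseline: %d (%.2f%%); rescued by SD: %d (%.2f%%)\n",
              tot$n_silent, tot$silent_pct, tot$n_rescued, tot$rescue_rate))
  nov <- x$novelty$Total
  cat(sprintf("  avg docs: baseline %.2f, SD %.2f, novel %.2f (gain %s)\n",
              nov$baseline[["mean"]], nov$sd[["mean"]], nov$novel[["mean"]],
              if (is.na(nov$relative_gain)) "undefined"
              else sprintf("+%.2f%%", nov$relative_gain)))
  if (!is.null(x$significance))
    cat(sprintf("  significance chi2(%d, N = %d) = %.2f, p = %.3g\n",
                x$significance$chi2_all$df, x$significance$table$n,
                x$significance$chi2_all$statistic,
                x$significance$chi2_all$p_value))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (full report, percentages rounded to 2 decimals) and
#' the three table-shaped TSVs `silence.tsv`, `novelty.tsv` and
#' `significance.tsv` under `dir`.
#'
#' @param report an [evaluate_benchmark()] result.
#' @param dir output directory, created if needed.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r2 <- function(x) round(x, 2)

  sil <- do.call(rbind, lapply(names(report$silence), function(src) {
    s <- report$silence[[src]]
    data.frame(source = src, n_total = s$n_total, n_silent = s$n_silent,
               silent_pct = r2(s$silent_pct), n_rescued = s$n_rescued,
               rescue_rate = r2(s$rescue_rate),
               sd_docs_mean = r2(s$sd_docs_rescued[["mean"]]),
               sd_docs_min = s$sd_docs_rescued[["min"]],
               sd_docs_max = s$sd_docs_rescued[["max"]])
  }))
  utils::write.table(sil, file.path(dir, "silence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  nov <- do.call(rbind, lapply(names(report$novelty), function(src) {
    nv <- report$novelty[[src]]
    data.frame(source = src,
               avg_baseline = r2(nv$baseline[["mean"]]),
               avg_sd = r2(nv$sd[["mean"]]),
               avg_novel = r2(nv$novel[["mean"]]),
               avg_all = r2(nv$all[["mean"]]),
               relative_gain = r2(nv$relative_gain))
  }))
  utils::write.table(nov, file.path(dir, "novelty.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (!is.null(report$significance)) {
    tab <- report$significance$table
    sig <- data.frame(group = rownames(tab$counts), tab$counts,
                      round(tab$pct, 2), check.names = FALSE)
    names(sig) <- c("group", paste0("n_", colnames(tab$counts)),
                    paste0("pct_", colnames(tab$counts)))
    utils::write.table(sig, file.path(dir, "significance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  json <- list(
    silence = lapply(report$silence, function(s)
      list(n_total = s$n_total, n_silent = s$n_silent,
           silent_pct = r2(s$silent_pct), n_rescued = s$n_rescued,
           rescue_rate = r2(s$rescue_rate),
           sd_docs_rescued = as.list(r2(s$sd_docs_rescued)))),
    novelty = lapply(report$novelty, function(nv)
      list(baseline = as.list(r2(nv$baseline)), sd = as.list(r2(nv$sd)),
           novel = as.list(r2(nv$novel)), all = as.list(r2(nv$all)),
           relative_gain = r2(nv$relative_gain))),
    significance = if (is.null(report$significance)) NULL else list(
      counts = report$significance$table$counts,
      pct = round(report$significance$table$pct, 2),
      chi2_all = report$significance$chi2_all[c("statistic", "df", "p_value")],
      chi2_path_benign =
        report$significance$chi2_path_benign[c("statistic", "df", "p_value")]),
    n_skipped = report$n_skipped)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}
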