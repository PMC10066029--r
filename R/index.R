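# Inverted-index retrieval: tokenization that keeps variant-internal
# punctuation, per-collection index construction, surface-form matching with
# gene co-occurrence, and the gene-variant proximity filter.

#' Tokenize text, preserving variant-internal punctuation
#'
#' Tokens are case-folded maximal runs of letters/digits that may contain
#' the characters `>`, the arrow `→`, `.` and `*` in their interior — so
#' `c.1799T>A`, `V600→E` and `V600*` each survive as one token. Trailing
#' periods (sentence punctuation) are stripped. Each token carries its
#' 0-based character offset in the original string.
#'
#' @param text a single string.
#' @return data.frame with columns `token`, `pos` (1-based token index) and
#'   `offset` (0-based character offset).
#' @examples
#' normalize_text("BRAF V600E.")
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- enc2utf8(text)
  m <- gregexpr("\\*?[A-Za-z0-9][A-Za-z0-9>.*→£]*", text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(), pos = integer(), offset = integer()))
  toks <- regmatches(text, list(m))[[1]]
  starts <- as.integer(m)
  # strip trailing sentence periods
  stripped <- sub("\\.+$", "", toks)
  keep <- nzchar(stripped)
  data.frame(token = tolower(stripped[keep]),
             pos = seq_len(sum(keep)),
             offset = starts[keep] - 1L,
             stringsAsFactors = FALSE)
}

#' Build an inverted index over one collection of a corpus
#'
#' Deterministic for a fixed corpus: the same documents always produce an
#' index with the same fingerprint.
#'
#' @param x a corpus data.frame (see [corpus()]).
#' @param collection which collection to index; `NULL` indexes all rows.
#' @return object of class `inverted_index`: token postings, per-document
#'   token streams (needed for n-gram and proximity matching), the
#'   document-to-article map and a content fingerprint.
#' @export
build_index <- function(x, collection = NULL) {
  d <- if (is.null(collection)) x else x[x$collection == collection, , drop = FALSE]
  if (!nrow(d)) warning("empty collection", if (!is.null(collection))
    paste0(" '", collection, "'") else "")
  docs <- vector("list", nrow(d))
  names(docs) <- d$doc_id
  postings <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(d))) {
    ts <- normalize_text(d$text[i])
    docs[[i]] <- ts
    for (tok in unique(ts$token)) {
      postings[[tok]] <- c(postings[[tok]], d$doc_id[i])
    }
  }
  n_post <- sum(vapply(docs, nrow, 0L))
  structure(list(collection = collection %||% "all",
                 docs = docs,
                 postings = postings,
                 parent = stats::setNames(d$parent_article_id, d$doc_id),
                 fingerprint = sprintf("%s|docs=%d|tokens=%d|postings=%d",
                                       collection %||% "all", nrow(d),
                                       length(ls(postings)), n_post)),
            class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("Inverted index [", x$fingerprint, "]\n", sep = ""); invisible(x)
}

index_tokens <- function(idx) ls(idx$postings)

# token sequences of the surface forms, normalized the same way as documents
form_token_seqs <- function(forms) {
  lapply(forms, function(f) normalize_text(f)$token)
}

#' Retrieve documents matching any surface form of an expanded variant
#'
#' A document matches when at least one surface form occurs as a normalized
#' token (multi-token forms such as `V 600 E` are matched as contiguous
#' token sequences). With `require_gene = TRUE` (the default) the gene
#' symbol — or any alias carried by the expansion set — must also occur in
#' the same document; each match span then records its distance to the
#' nearest gene mention in both token and character units.
#'
#' @param expansion an [expand_all()] result.
#' @param index an [build_index()] result.
#' @param require_gene logical, default `TRUE`.
#' @return object of class `query_result`: `spans` (one row per match
#'   occurrence: `doc_id`, `form`, `pos`, `offset`, `gene_word_dist`,
#'   `gene_char_dist`), `docs` (sorted unique matching doc ids), `articles`
#'   (their parent article ids), plus the query and collection labels.
#' @export
search_variant <- function(expansion, index, require_gene = TRUE) {
  stopifnot(inherits(expansion, "expansion_set"),
            inherits(index, "inverted_index"))
  forms <- expansion$forms$form
  if (!length(forms)) stop("empty expansion set")
  seqs <- form_token_seqs(forms)
  ok <- lengths(seqs) > 0L
  forms <- forms[ok]; seqs <- seqs[ok]
  gene_toks <- tolower(expansion$genes)

  # candidate docs: union of postings of each form's first token
  cand <- unique(unlist(lapply(seqs, function(s)
    index$postings[[s[[1]]]]), use.names = FALSE))
  cand <- sort(cand)

  span_rows <- list()
  for (doc_id in cand) {
    ts <- index$docs[[doc_id]]
    gene_pos <- which(ts$token %in% gene_toks)
    if (require_gene && !length(gene_pos)) next
    for (k in seq_along(forms)) {
      s <- seqs[[k]]; n <- length(s)
      hits <- which(ts$token == s[[1]])
      if (n > 1L)
        hits <- hits[vapply(hits, function(h)
          h + n - 1L <= nrow(ts) &&
            identical(ts$token[h:(h + n - 1L)], s), logical(1L))]
      for (h in hits) {
        wd <- cd <- NA_integer_
        if (length(gene_pos)) {
          wd <- min(abs(gene_pos - h))
          cd <- min(abs(ts$offset[gene_pos] - ts$offset[h]))
        }
        span_rows[[length(span_rows) + 1L]] <-
          data.frame(doc_id = doc_id, form = forms[[k]], pos = h,
                     offset = ts$offset[h], gene_word_dist = wd,
                     gene_char_dist = cd, stringsAsFactors = FALSE)
      }
    }
  }
  spans <- if (length(span_rows)) do.call(rbind, span_rows)
           else data.frame(doc_id = character(), form = character(),
                           pos = integer(), offset = integer(),
                           gene_word_dist = integer(),
                           gene_char_dist = integer())
  docs <- sort(unique(spans$doc_id))
  structure(list(query = expansion$query, collection = index$collection,
                 spans = spans, docs = docs,
                 articles = sort(unique(unname(index$parent[docs])))),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat("Query ", x$query$raw_text, " on '", x$collection, "': ",
      length(x$docs), " document(s), ", nrow(x$spans), " span(s)\n", sep = "")
  invisible(x)
}

#' Keep only matches close to a gene mention
#'
#' Precision heuristic for supplementary tables that mix hundreds of
#' variants from different genes: a match span is kept only when its nearest
#' mention of the query gene lies within `max_distance`, measured in words
#' (tokens) or character offsets. Document and article sets are re-projected
#' from the surviving spans; the filter can only shrink a result.
#'
#' @param result a [search_variant()] result obtained with
#'   `require_gene = TRUE`.
#' @param max_distance distance threshold.
#' @param unit `"word"` (token positions) or `"offset"` (characters).
#' @param index the index the result came from (for article re-projection).
#' @return a filtered `query_result`.
#' @export
proximity_filter <- function(result, max_distance, unit = c("word", "offset"),
                             index) {
  unit <- match.arg(unit)
  stopifnot(inherits(result, "query_result"))
  sp <- result$spans
  col <- if (unit == "word") "gene_word_dist" else "gene_char_dist"
  if (nrow(sp) && anyNA(sp[[col]]))
    stop("gene distances unavailable; search with require_gene = TRUE ",
         "before applying the proximity filter")
  sp <- sp[!is.na(sp[[col]]) & sp[[col]] <= max_distance, , drop = FALSE]
  rownames(sp) <- NULL
  docs <- sort(unique(sp$doc_id))
  structure(list(query = result$query, collection = result$collection,
                 spans = sp, docs = docs,
                 articles = sort(unique(unname(index$parent[docs])))),
            class = "query_result")
}

#' Rank the documents of a query result
#'
#' Deterministic ordering for top-k screening: by number of distinct
#' surface forms matched in the document (descending), ties broken by
#' doc id (ascending).
#'
#' @param result a [search_variant()] result.
#' @return character vector of doc ids, best first.
#' @export
ranked_docs <- function(result) {
  if (!nrow(result$spans)) return(character())
  nforms <- tapply(result$spans$form, result$spans$doc_id,
                   function(f) length(unique(f)))
  ids <- names(nforms)
  ids[order(-as.integer(nforms), ids)]
}

#' Persist and reload an inverted index
#'
#' The on-disk form is a single JSON object with the collection label, the
#' fingerprint, the document-to-article map and the per-document normalized
#' token streams (token, position, offset). Postings are rebuilt on load,
#' so the file stays compact and the loaded index is identical in behavior.
#'
#' @param index a [build_index()] result.
#' @param path JSON file.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "inverted_index"))
  obj <- list(collection = index$collection,
              fingerprint = index$fingerprint,
              parent = as.list(index$parent),
              docs = lapply(index$docs, function(d)
                list(token = d$token, pos = d$pos, offset = d$offset)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  docs <- lapply(obj$docs, function(d)
    data.frame(token = unlist(d$token) %||% character(),
               pos = as.integer(unlist(d$pos) %||% integer()),
               offset = as.integer(unlist(d$offset) %||% integer()),
               stringsAsFactors = FALSE))
  postings <- new.env(parent = emptyenv())
  for (doc_id in names(docs)) {
    for (tok in unique(docs[[doc_id]]$token))
      postings[[tok]] <- c(postings[[tok]], doc_id)
  }
  structure(list(collection = obj$collection, docs = docs,
                 postings = postings,
                 parent = unlist(obj$parent) %||%
                   stats::setNames(character(), character()),
                 fingerprint = obj$fingerprint),
            class = "inverted_index")
}

#' Search every collection index for one expanded variant
#'
#' @param expansion an [expand_all()] result.
#' @param indexes named list of [build_index()] results (typically
#'   `abstract`, `fulltext`, `supplementary`).
#' @param ... passed to [search_variant()].
#' @return named list of `query_result` objects.
#' @export
search_collections <- function(expansion, indexes, ...) {
  lapply(indexes, function(idx) search_variant(expansion, idx, ...))
}
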