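# Document collections: JSONL ingestion, tabular-to-text conversion of
# supplementary files, and the supplementary-data selection filter.

COLLECTIONS <- c("abstract", "fulltext", "supplementary")

#' Assemble a corpus of documents
#'
#' A corpus is a data.frame with one row per document and columns `doc_id`,
#' `parent_article_id`, `collection` (one of `abstract`, `fulltext`,
#' `supplementary`), `text` and `file_type` (non-empty for supplementary
#' documents). A parent article may own documents in several collections.
#'
#' @param documents a data.frame with the columns above (`file_type`
#'   optional), or a list of such data.frames to be concatenated.
#' @return validated corpus data.frame of class `sd_corpus`.
#' @export
corpus <- function(documents) {
  if (is.list(documents) && !is.data.frame(documents))
    documents <- do.call(rbind, documents)
  d <- as.data.frame(documents)
  need <- c("doc_id", "parent_article_id", "collection", "text")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("corpus missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$file_type)) d$file_type <- ""
  d <- d[, c(need, "file_type")]
  bad <- setdiff(unique(d$collection), COLLECTIONS)
  if (length(bad)) stop("unknown collection label(s): ", paste(bad, collapse = ", "))
  dup <- d$doc_id[duplicated(d$doc_id)]
  if (length(dup)) stop("duplicate doc_id: ", paste(unique(dup), collapse = ", "))
  rownames(d) <- NULL
  class(d) <- c("sd_corpus", "data.frame")
  d
}

#' Read documents from a JSONL file
#'
#' One JSON object per line with mandatory fields `doc_id`,
#' `parent_article_id` and `text`; `file_type` is optional. The collection
#' tag is applied to every document read.
#'
#' @param path JSONL file.
#' @param collection one of `"abstract"`, `"fulltext"`, `"supplementary"`.
#' @return corpus data.frame (possibly empty, with a warning).
#' @export
read_documents <- function(path, collection) {
  collection <- match.arg(collection, COLLECTIONS)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("no documents in ", path)
    return(corpus(data.frame(doc_id = character(), parent_article_id = character(),
                             collection = character(), text = character(),
                             file_type = character())))
  }
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("line ", i, " of ", path,
                                             ": invalid JSON (", conditionMessage(e), ")"))
    for (f in c("doc_id", "parent_article_id", "text"))
      if (is.null(rec[[f]]))
        stop("line ", i, " of ", path, ": missing field '", f, "'")
    rows[[i]] <- data.frame(doc_id = as.character(rec$doc_id),
                            parent_article_id = as.character(rec$parent_article_id),
                            collection = collection,
                            text = as.character(rec$text),
                            file_type = as.character(rec$file_type %||% ""),
                            stringsAsFactors = FALSE)
  }
  corpus(rows)
}

#' Write a corpus to JSONL
#'
#' One object per line, fields as in [read_documents()]; `collection` is
#' included so a mixed corpus round-trips. Reading each collection back with
#' [read_documents()] recovers the original corpus.
#'
#' @param x a corpus data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_documents <- function(x, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    rec <- list(doc_id = x$doc_id[i], parent_article_id = x$parent_article_id[i],
                collection = x$collection[i], text = x$text[i])
    if (nzchar(x$file_type[i])) rec$file_type <- x$file_type[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Flatten a tabular supplementary file to plain text
#'
#' Converts a table to searchable text the way supplementary files are
#' flattened before indexing: one output line per row, cells joined by a
#' single space, every sheet of a workbook concatenated with a sheet-name
#' header line. Cells are read as character so numeric content is kept
#' verbatim (no scientific-notation mangling). Plain `.txt` sidecar files
#' (e.g. OCR output produced upstream for image supplements) pass through
#' unchanged.
#'
#' @param path a `.csv`, `.tsv`/`.tab`, `.xlsx` or `.txt` file.
#' @return a single string; empty (with a warning) for an empty table.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines("BRAF,V600E,0.12", f)
#' tabular_to_text(f)
#' @export
tabular_to_text <- function(path) {
  ext <- tolower(tools::file_ext(path))
  join_rows <- function(m) {
    if (is.null(dim(m)) || nrow(m) == 0L) return(character())
    apply(m, 1L, function(r) {
      r <- as.character(r)
      r[is.na(r)] <- ""
      trimws(paste(r, collapse = " "))
    })
  }
  lines <- switch(ext,
    csv = , tsv = , tab = {
      sep <- if (ext == "csv") "," else "\t"
      d <- tryCatch(
        utils::read.table(path, sep = sep, header = FALSE,
                          colClasses = "character", quote = "\"",
                          fill = TRUE, blank.lines.skip = TRUE,
                          fileEncoding = "UTF-8"),
        error = function(e) data.frame())
      join_rows(as.matrix(d))
    },
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading .xlsx requires the readxl package")
      sheets <- readxl::excel_sheets(path)
      out <- character()
      for (s in sheets) {
        d <- readxl::read_excel(path, sheet = s, col_names = FALSE,
                                col_types = "text", .name_repair = "minimal")
        out <- c(out, paste0("## ", s), join_rows(as.matrix(d)))
      }
      out
    },
    txt = readLines(path, warn = FALSE, encoding = "UTF-8"),
    stop("unsupported tabular file type: .", ext))
  if (!length(lines) || !any(nzchar(lines)))
    warning("empty table: ", path)
  paste(lines, collapse = "\n")
}

filter_tokens <- function(text) {
  toks <- regmatches(text, gregexpr("[A-Za-z0-9]+", text))[[1]]
  tolower(toks)
}

#' Supplementary-data collection selection filter
#'
#' Decides whether an article qualifies for the supplementary-data
#' collection: true iff the tokens `gene` AND `variant` are both present, OR
#' the token `polymorphism` is present, OR any token starts with `mutat`.
#' Tokens are maximal runs of letters/digits, matched case-insensitively.
#'
#' @param article_text character vector of article texts.
#' @return logical vector.
#' @examples
#' collection_filter("the gene carries a variant")
#' collection_filter("somatic mutations were called")
#' collection_filter("protein expression study")
#' @export
collection_filter <- function(article_text) {
  vapply(article_text, function(txt) {
    toks <- filter_tokens(txt)
    ("gene" %in% toks && "variant" %in% toks) ||
      "polymorphism" %in% toks ||
      any(startsWith(toks, "mutat"))
  }, logical(1L), USE.NAMES = FALSE)
}

#' File-type distribution of supplementary documents
#'
#' @param x a corpus data.frame (non-supplementary rows are ignored).
#' @return data.frame `file_type`/`n`, sorted by descending count, ties
#'   broken alphabetically.
#' @export
file_type_stats <- function(x) {
  ft <- x$file_type[x$collection == "supplementary"]
  if (!length(ft))
    return(data.frame(file_type = character(), n = integer()))
  tab <- table(ft)
  out <- data.frame(file_type = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$file_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
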