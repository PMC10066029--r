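# Minimal transcript model: enough structure to map a CDS-relative change
# onto the genome (exon walk, strand complement) and back.

#' Construct a transcript model
#'
#' A deliberately small model of a protein-coding transcript: the exon
#' intervals (1-based, inclusive, listed in transcription order — descending
#' genomic coordinates on the minus strand), the coding sequence itself and
#' the offset of the CDS start within the spliced transcript (length of the
#' 5' UTR).
#'
#' @param gene gene symbol.
#' @param contig contig/chromosome identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end` in
#'   transcription order; intervals must not overlap.
#' @param cds_sequence coding nucleotide string; length divisible by 3, no
#'   internal stop codons required by construction elsewhere.
#' @param cds_offset 0-based offset of the first CDS base in the spliced
#'   transcript (default 0: CDS starts at the transcript start).
#' @return object of class `transcript_model`.
#' @examples
#' transcript_model("G1", "chr1", "+", data.frame(start = 101, end = 109),
#'                  "ATGGTGTAA")
#' @export
transcript_model <- function(gene, contig, strand, exons, cds_sequence,
                             cds_offset = 0L) {
  stopifnot(is.character(gene), nzchar(gene), strand %in% c("+", "-"))
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons)))
    stop("exons need columns 'start' and 'end'")
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (any(exons$end < exons$start)) stop("exon end before start")
  # transcription order: ascending on +, descending on -
  g_ord <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(g_ord, seq_len(nrow(exons))))
    stop("exons must be listed in transcription order")
  by_start <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(by_start$start[-1L] <= by_start$end[-nrow(by_start)]))
    stop("exon intervals overlap")
  cds_sequence <- toupper(cds_sequence)
  if (!grepl("^[ACGT]*$", cds_sequence)) stop("CDS contains non-ACGT characters")
  if (nchar(cds_sequence) %% 3L != 0L)
    stop("CDS length must be divisible by 3")
  cds_offset <- as.integer(cds_offset)
  if (cds_offset < 0L) stop("cds_offset must be >= 0")
  if (sum(exons$end - exons$start + 1L) < cds_offset + nchar(cds_sequence))
    stop("exons too short for cds_offset + CDS length")
  structure(list(gene = gene, contig = contig, strand = strand, exons = exons,
                 cds_sequence = cds_sequence, cds_offset = cds_offset),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript ", x$gene, " (", x$contig, x$strand, "), ",
      nrow(x$exons), " exon(s), CDS ", nchar(x$cds_sequence), " nt (",
      nchar(x$cds_sequence) %/% 3L, " codons), 5'UTR ", x$cds_offset,
      " nt\n", sep = "")
  invisible(x)
}

#' Read and write transcript models
#'
#' The tab-delimited format has one transcript per row with columns `gene`,
#' `contig`, `strand`, `exons` (e.g. `"100-199;300-350"`, transcription
#' order), `cds_offset` and `cds_sequence`. A `cds_sequence` of `"."` means
#' the sequence is looked up by gene name in the FASTA file given as
#' `cds_fasta`. The JSON equivalent is an array of objects with the same
#' fields, `exons` as an array of `{start, end}` pairs.
#'
#' @param path file path (`.tsv`/`.txt` for the delimited format, `.json`
#'   for the JSON equivalent — dispatch on extension).
#' @param cds_fasta optional FASTA of CDS sequences named by gene.
#' @return `read_transcripts`: named list of [transcript_model()] objects
#'   keyed by gene. `write_transcripts`: the path, invisibly.
#' @export
read_transcripts <- function(path, cds_fasta = NULL) {
  seqs <- NULL
  if (!is.null(cds_fasta)) {
    ss <- Biostrings::readDNAStringSet(cds_fasta)
    seqs <- stats::setNames(as.character(ss), names(ss))
  }
  rows <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    d <- utils::read.delim(path, header = TRUE, colClasses = "character")
    lapply(seq_len(nrow(d)), function(i) as.list(d[i, ]))
  }
  out <- list()
  for (r in rows) {
    ex <- r$exons
    if (is.character(ex)) {
      pieces <- strsplit(strsplit(ex, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
      ex <- data.frame(start = as.integer(vapply(pieces, `[`, "", 1L)),
                       end = as.integer(vapply(pieces, `[`, "", 2L)))
    } else {
      ex <- data.frame(start = vapply(ex, function(e) as.integer(e$start), 0L),
                       end = vapply(ex, function(e) as.integer(e$end), 0L))
    }
    cds <- r$cds_sequence
    if (identical(cds, ".")) {
      if (is.null(seqs) || is.null(seqs[[r$gene]]))
        stop("transcript ", r$gene, " defers to FASTA but no CDS found there")
      cds <- seqs[[r$gene]]
    }
    out[[r$gene]] <- transcript_model(r$gene, r$contig, r$strand, ex, cds,
                                      as.integer(r$cds_offset %||% 0L))
  }
  out
}

#' @rdname read_transcripts
#' @param transcripts named list of [transcript_model()] objects.
#' @export
write_transcripts <- function(transcripts, path) {
  rows <- lapply(transcripts, function(tx) {
    data.frame(gene = tx$gene, contig = tx$contig, strand = tx$strand,
               exons = paste(tx$exons$start, tx$exons$end, sep = "-",
                             collapse = ";"),
               cds_offset = tx$cds_offset, cds_sequence = tx$cds_sequence,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A toy BRAF transcript for examples and demonstrations
#'
#' Single-exon plus-strand model whose codon 600 is `GTG` (Val), so that
#' `V600E` maps to `c.1799T>A` (`GTG` -> `GAG`). The surrounding codons are
#' filler (`GCT`, Ala) and the CDS ends with a stop codon.
#'
#' @param strand `"+"` (default) or `"-"`; the minus-strand variant places
#'   the same CDS on the reverse strand for round-trip demonstrations.
#' @return a [transcript_model()].
#' @export
toy_braf_transcript <- function(strand = "+") {
  cds <- paste0(strrep("GCT", 599), "GTG", strrep("GCT", 100), "TAA")
  n <- nchar(cds)
  exons <- if (strand == "+") data.frame(start = 140000001L,
                                         end = 140000000L + n)
           else data.frame(start = 140000001L, end = 140000000L + n)
  transcript_model("BRAF", "chr7", strand, exons, cds)
}
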