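# Shared fixtures, all built in code.

# Plus/minus-strand toy transcript: codon 600 is GTG so V600E <-> c.1799T>A.
braf_toy <- function(strand = "+") toy_braf_transcript(strand)

# Small transcript with a known CDS on a chosen strand / exon structure.
make_tx <- function(cds, strand = "+", exons = NULL, cds_offset = 0L,
                    gene = "G1", contig = "chrT") {
  n <- cds_offset + nchar(cds)
  if (is.null(exons)) exons <- data.frame(start = 1001L, end = 1000L + n)
  transcript_model(gene, contig, strand, exons, cds, cds_offset)
}

# Random CDS of n_codons sense codons (seeded by caller).
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Build an expansion set by hand (for retrieval oracles on arbitrary forms).
make_expansion <- function(forms, gene = "GENEX",
                           level = "protein", template = "manual") {
  structure(list(
    query = structure(list(gene = gene, change = NULL, level = level,
                           raw_text = paste0(gene, ":", forms[[1]]),
                           ambiguous = FALSE), class = "variant_query"),
    forms = data.frame(form = forms, level = level, template = template,
                       stringsAsFactors = FALSE),
    genes = gene), class = "expansion_set")
}

# Tiny corpus data.frame from parallel vectors.
make_corpus <- function(texts, collection = "abstract",
                        doc_ids = sprintf("d%03d", seq_along(texts)),
                        parents = sprintf("p%03d", seq_along(texts)),
                        file_type = "") {
  corpus(data.frame(doc_id = doc_ids, parent_article_id = parents,
                    collection = collection, text = texts,
                    file_type = file_type, stringsAsFactors = FALSE))
}

# Independent translation oracle: Biostrings, never the package's own codon
# helpers.
oracle_translate <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}
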