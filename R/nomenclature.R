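# Variant nomenclature: parsing GENE:change queries and generating the
# equivalent descriptions at protein / coding / genomic level together with
# their syntactic surface forms.

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
AA3 <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His","Ile",
         "Leu","Lys","Met","Phe","Pro","Ser","Thr","Trp","Tyr","Val")
names(AA3) <- AA1

#' Convert between one- and three-letter amino-acid codes
#'
#' The stop codon is canonically `"*"` at one-letter level and `"Ter"` at
#' three-letter level; `"X"` is accepted as a one-letter stop alternate.
#'
#' @param aa character vector of residue codes (1- or 3-letter, any case for
#'   3-letter codes).
#' @return `aa_to_1`: canonical 1-letter codes; `aa_to_3`: 3-letter codes.
#' @examples
#' aa_to_1("Val")
#' aa_to_3("*")
#' @export
aa_to_1 <- function(aa) {
  out <- character(length(aa))
  for (i in seq_along(aa)) {
    a <- aa[[i]]
    if (nchar(a) == 1L) {
      a <- toupper(a)
      if (a == "X") a <- "*"
      if (!a %in% c(AA1, "*")) stop("unknown amino-acid code: '", aa[[i]], "'")
      out[[i]] <- a
    } else {
      a3 <- paste0(toupper(substr(a, 1, 1)), tolower(substr(a, 2, nchar(a))))
      if (a3 == "Ter") { out[[i]] <- "*"; next }
      hit <- names(AA3)[AA3 == a3]
      if (length(hit) != 1L) stop("unknown amino-acid code: '", aa[[i]], "'")
      out[[i]] <- hit
    }
  }
  out
}

#' @rdname aa_to_1
#' @export
aa_to_3 <- function(aa) {
  one <- aa_to_1(aa)
  ifelse(one == "*", "Ter", unname(AA3[one]))
}

#' Construct a protein-level single amino-acid change
#'
#' @param ref,alt reference and alternate residues (1- or 3-letter; stop as
#'   `"*"`, `"X"` or `"Ter"`).
#' @param pos 1-based codon index.
#' @param synonymous logical; a synonymous change (`ref == alt`) must be
#'   flagged explicitly, otherwise it is rejected.
#' @return an object of class `aa_change` with fields `ref`, `pos`, `alt`
#'   (1-letter canonical) and `synonymous`.
#' @examples
#' aa_change("V", 600, "E")
#' aa_change("Val", 600, "Glu")
#' @export
aa_change <- function(ref, pos, alt, synonymous = FALSE) {
  ref <- aa_to_1(ref); alt <- aa_to_1(alt)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("codon position must be >= 1")
  if (ref == alt && !synonymous)
    stop("ref and alt residues are identical; flag synonymous changes explicitly")
  structure(list(ref = ref, pos = pos, alt = alt, synonymous = synonymous),
            class = "aa_change")
}

#' Construct a coding (cDNA, CDS-relative) single-nucleotide change
#'
#' @param pos 1-based position in the coding sequence.
#' @param ref,alt reference and alternate bases, in `A`, `C`, `G`, `T`.
#' @return an object of class `coding_change`.
#' @examples
#' coding_change(1799, "T", "A")
#' @export
coding_change <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("cDNA position must be >= 1")
  if (!ref %in% c("A","C","G","T") || !alt %in% c("A","C","G","T"))
    stop("bases must be one of A, C, G, T")
  if (ref == alt) stop("ref and alt bases are identical")
  structure(list(pos = pos, ref = ref, alt = alt), class = "coding_change")
}

#' Construct a genomic single-nucleotide change (forward strand)
#'
#' @param contig contig/chromosome identifier (may be `NA` when parsed from a
#'   bare `g.` string; it is filled in from a transcript model at expansion
#'   time).
#' @param pos 1-based genomic coordinate.
#' @param ref,alt forward-strand reference and alternate bases.
#' @return an object of class `genomic_change`.
#' @export
genomic_change <- function(contig, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("genomic position must be >= 1")
  if (!ref %in% c("A","C","G","T") || !alt %in% c("A","C","G","T"))
    stop("bases must be one of A, C, G, T")
  if (ref == alt) stop("ref and alt bases are identical")
  structure(list(contig = contig, pos = pos, ref = ref, alt = alt),
            class = "genomic_change")
}

#' @export
print.aa_change <- function(x, ...) {
  cat("p.", x$ref, x$pos, x$alt,
      if (x$synonymous) " (synonymous)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.coding_change <- function(x, ...) {
  cat("c.", x$pos, x$ref, ">", x$alt, "\n", sep = ""); invisible(x)
}

#' @export
print.genomic_change <- function(x, ...) {
  cat(if (!is.na(x$contig)) paste0(x$contig, ":") else "",
      "g.", x$pos, x$ref, ">", x$alt, "\n", sep = "")
  invisible(x)
}

variant_level <- function(change) {
  if (inherits(change, "aa_change")) "protein"
  else if (inherits(change, "coding_change")) "coding"
  else if (inherits(change, "genomic_change")) "genomic"
  else stop("not a variant change object")
}

#' Parse a variant query string
#'
#' Accepts `GENE:change` with the change at protein level (`V600E`,
#' `Val600Glu`, `p.V600E`, `p.Val600Glu`, arrow `V600→E`, spaced
#' `V 600 E`, substitution `600V>E`, stop as `*`/`X`/`Ter`), coding level
#' (`c.1799T>A` or bare `1799T>A`), or genomic level (`g.123A>G`, contig left
#' `NA`).
#'
#' A form like `A123G` where both letters are also valid nucleotides is
#' resolved as a protein-level change (the benchmarks are protein-change
#' SNPs); the parse is marked with `ambiguous = TRUE`. A bare `123A>G` with
#' two nucleotide letters is resolved as coding.
#'
#' @param text the query string, e.g. `"BRAF:V600E"`.
#' @return an object of class `variant_query` with fields `gene`, `change`,
#'   `level`, `raw_text` and `ambiguous`.
#' @examples
#' parse_variant("BRAF:V600E")
#' parse_variant("BRAF:Val600Glu")
#' parse_variant("BRAF:c.1799T>A")
#' @export
parse_variant <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty variant query")
  sep <- regexpr(":", text, fixed = TRUE)
  if (sep < 0) stop("variant query must be GENE:change, got '", text, "'")
  gene <- substr(text, 1L, sep - 1L)
  body <- substr(text, sep + 1L, nchar(text))
  if (!nzchar(gene)) stop("empty gene symbol in '", text, "'")
  if (!nzchar(body)) stop("empty change descriptor in '", text, "'")
  parsed <- parse_change(body)
  structure(list(gene = gene, change = parsed$change, level = parsed$level,
                 raw_text = text, ambiguous = parsed$ambiguous),
            class = "variant_query")
}

# Grammar for the change part; each emitted surface template must re-parse
# to the same normalized change (parser-generator closure).
parse_change <- function(body) {
  b <- trimws(body)
  nt <- "[ACGTacgt]"
  mk <- function(change, level, ambiguous = FALSE)
    list(change = change, level = level, ambiguous = ambiguous)

  # coding: c.1799T>A
  m <- regmatches(b, regexec(paste0("^c\\.(\\d+)(", nt, ")>(", nt, ")$"), b))[[1]]
  if (length(m))
    return(mk(coding_change(m[2], m[3], m[4]), "coding"))
  # genomic: g.123A>G
  m <- regmatches(b, regexec(paste0("^g\\.(\\d+)(", nt, ")>(", nt, ")$"), b))[[1]]
  if (length(m))
    return(mk(genomic_change(NA_character_, m[2], m[3], m[4]), "genomic"))
  # bare NNNX>Y: coding when both letters are nucleotides, else protein
  # substitution form 600V>E
  m <- regmatches(b, regexec("^(\\d+)([A-Za-z*])>([A-Za-z*])$", b))[[1]]
  if (length(m)) {
    both_nt <- grepl(paste0("^", nt, "$"), m[3]) && grepl(paste0("^", nt, "$"), m[4])
    if (both_nt)
      return(mk(coding_change(m[2], m[3], m[4]), "coding", ambiguous = TRUE))
    return(mk(aa_change(m[3], m[2], m[4]), "protein"))
  }
  # protein 3-letter, optional p. prefix: Val600Glu / p.Val600Glu
  m <- regmatches(b, regexec("^(?:p\\.)?([A-Za-z]{3})(\\d+)([A-Za-z]{3}|\\*)$", b))[[1]]
  if (length(m) && is_aa3(m[2]) && (m[4] == "*" || is_aa3(m[4])))
    return(mk(aa_change(m[2], m[3], m[4]), "protein"))
  # protein 1-letter, optional p. prefix: V600E / p.V600E; stop as * or X
  m <- regmatches(b, regexec("^(?:p\\.)?([A-Za-z*])(\\d+)([A-Za-z*])$", b))[[1]]
  if (length(m) && is_aa1(m[2]) && is_aa1(m[4])) {
    ambiguous <- grepl(paste0("^", nt, "$"), m[2]) &&
      grepl(paste0("^", nt, "$"), m[4])
    return(mk(aa_change(m[2], m[3], m[4]), "protein", ambiguous = ambiguous))
  }
  # arrow form V600->E / V600→E
  m <- regmatches(b, regexec("^([A-Za-z*])(\\d+)(?:→|->)([A-Za-z*])$", b))[[1]]
  if (length(m) && is_aa1(m[2]) && is_aa1(m[4]))
    return(mk(aa_change(m[2], m[3], m[4]), "protein"))
  # spaced form V 600 E
  m <- regmatches(b, regexec("^([A-Za-z*]) (\\d+) ([A-Za-z*])$", b))[[1]]
  if (length(m) && is_aa1(m[2]) && is_aa1(m[4]))
    return(mk(aa_change(m[2], m[3], m[4]), "protein"))
  stop("unparseable change descriptor: '", body, "'")
}

is_aa1 <- function(x) toupper(x) %in% c(AA1, "*", "X")
is_aa3 <- function(x) {
  x3 <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  x3 %in% c(AA3, "Ter")
}

#' Protein-level surface-form templates
#'
#' The default inventory used by [expand_protein_surface_forms()]. Each id
#' names one way a single amino-acid substitution is written in the
#' literature; stop-gain changes additionally trigger the `*`/`X`/`Ter`
#' alternates.
#'
#' @return character vector of template ids.
#' @export
protein_templates <- function() {
  c("p1", "p3", "hgvs_p1", "hgvs_p3", "arrow", "spaced", "sub")
}

render_protein_form <- function(change, template, stop1 = "*") {
  r1 <- change$ref; a1 <- change$alt
  if (r1 == "*") r1 <- stop1
  if (a1 == "*") a1 <- stop1
  r3 <- aa_to_3(change$ref); a3 <- aa_to_3(change$alt)
  p <- change$pos
  switch(template,
    p1      = paste0(r1, p, a1),
    p3      = paste0(r3, p, a3),
    hgvs_p1 = paste0("p.", r1, p, a1),
    hgvs_p3 = paste0("p.", r3, p, a3),
    arrow   = paste0(r1, p, "→", a1),
    spaced  = paste(r1, p, a1),
    sub     = paste0(p, r1, ">", a1),
    stop("unknown protein template: ", template))
}

#' Generate the protein-level surface forms of an amino-acid change
#'
#' Emits, per enabled template, the compact 1-letter form (`V600E`), the
#' 3-letter form (`Val600Glu`), both with `p.` prefix, the arrow form
#' (`V600→E`), the spaced form (`V 600 E`) and the substitution form
#' (`600V>E`). Stop-gain changes are additionally rendered with `X` in place
#' of `*` for the 1-letter templates (`Ter` is the 3-letter spelling).
#'
#' @param change an [aa_change()].
#' @param templates template ids to enable; see [protein_templates()].
#' @return data.frame with columns `form`, `level` (`"protein"`), `template`;
#'   no duplicate forms.
#' @examples
#' expand_protein_surface_forms(aa_change("V", 600, "E"))
#' @export
expand_protein_surface_forms <- function(change, templates = protein_templates()) {
  stopifnot(inherits(change, "aa_change"))
  forms <- vapply(templates, function(t) render_protein_form(change, t), "")
  ids <- templates
  if (change$ref == "*" || change$alt == "*") {
    xt <- intersect(templates, c("p1", "hgvs_p1", "arrow", "spaced", "sub"))
    forms <- c(forms, vapply(xt, function(t)
      render_protein_form(change, t, stop1 = "X"), ""))
    ids <- c(ids, paste0(xt, "_stopx"))
  }
  out <- data.frame(form = unname(forms), level = "protein",
                    template = ids, stringsAsFactors = FALSE)
  out[!duplicated(out$form), , drop = FALSE]
}

render_coding_forms <- function(change) {
  data.frame(
    form = c(paste0("c.", change$pos, change$ref, ">", change$alt),
             paste0(change$pos, change$ref, ">", change$alt)),
    level = "coding",
    template = c("hgvs_c", "c_bare"),
    stringsAsFactors = FALSE)
}

render_genomic_forms <- function(change) {
  data.frame(form = paste0("g.", change$pos, change$ref, ">", change$alt),
             level = "genomic", template = "hgvs_g",
             stringsAsFactors = FALSE)
}

#' Translate a codon with the standard genetic code
#'
#' @param codon a 3-letter nucleotide string.
#' @return 1-letter amino acid, `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("not a codon: '", codon, "'")
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Map a protein change to the coding changes that can produce it
#'
#' Enumerates the nine single-nucleotide mutants of the codon at the change's
#' position and keeps those whose mutated codon translates to the alternate
#' residue under the standard genetic code. The result may be empty (some
#' substitutions need more than one nucleotide change).
#'
#' @param change an [aa_change()].
#' @param tx a [transcript_model()] supplying the coding sequence.
#' @return list of [coding_change()] objects, ordered by cDNA position then
#'   alternate base.
#' @examples
#' tx <- transcript_model("G", "chr1", "+",
#'                        data.frame(start = 101, end = 106),
#'                        "GTGGAA")
#' protein_to_coding(aa_change("V", 1, "E"), tx)
#' @export
protein_to_coding <- function(change, tx) {
  stopifnot(inherits(change, "aa_change"), inherits(tx, "transcript_model"))
  cds <- tx$cds_sequence
  if (3L * change$pos > nchar(cds))
    stop("codon ", change$pos, " beyond coding sequence (",
         nchar(cds) %/% 3L, " codons)")
  codon <- substr(cds, 3L * change$pos - 2L, 3L * change$pos)
  obs <- translate_codon(codon)
  if (obs != change$ref)
    stop("reference mismatch at codon ", change$pos, ": transcript has ",
         codon, " (", obs, "), query expects ", change$ref)
  out <- list()
  for (off in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, off, off) == b) next
      mut <- codon
      substr(mut, off, off) <- b
      if (translate_codon(mut) == change$alt) {
        out[[length(out) + 1L]] <-
          coding_change(3L * (change$pos - 1L) + off, substr(codon, off, off), b)
      }
    }
  }
  out
}

#' Map a coding change to the protein change it induces
#'
#' @param change a [coding_change()].
#' @param tx a [transcript_model()].
#' @return an [aa_change()]; synonymous changes are returned with
#'   `synonymous = TRUE`, not treated as errors.
#' @export
coding_to_protein <- function(change, tx) {
  stopifnot(inherits(change, "coding_change"), inherits(tx, "transcript_model"))
  cds <- tx$cds_sequence
  if (change$pos > nchar(cds))
    stop("cDNA position ", change$pos, " beyond coding sequence (",
         nchar(cds), " nt)")
  have <- substr(cds, change$pos, change$pos)
  if (have != change$ref)
    stop("reference mismatch at c.", change$pos, ": transcript has ", have,
         ", query expects ", change$ref)
  ci <- (change$pos - 1L) %/% 3L + 1L
  codon <- substr(cds, 3L * ci - 2L, 3L * ci)
  mut <- codon
  off <- change$pos - 3L * (ci - 1L)
  substr(mut, off, off) <- change$alt
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(mut)
  aa_change(ref_aa, ci, alt_aa, synonymous = ref_aa == alt_aa)
}

#' Map between coding and genomic coordinates of a transcript
#'
#' `coding_to_genomic` walks the exons in transcription order to place a
#' CDS-relative position on the genome; on the minus strand the reported
#' bases are complemented so the result is always forward-strand.
#' `genomic_to_coding` is the inverse.
#'
#' @param change a [coding_change()] (or [genomic_change()] for the inverse).
#' @param tx a [transcript_model()].
#' @return a [genomic_change()] (or [coding_change()]).
#' @export
coding_to_genomic <- function(change, tx) {
  stopifnot(inherits(change, "coding_change"), inherits(tx, "transcript_model"))
  if (change$pos > nchar(tx$cds_sequence))
    stop("cDNA position ", change$pos, " beyond coding sequence")
  tpos <- tx$cds_offset + change$pos
  w <- tx$exons$end - tx$exons$start + 1L
  cum <- cumsum(w)
  if (tpos > cum[length(cum)])
    stop("position beyond transcript (", cum[length(cum)], " nt of exon)")
  i <- which(tpos <= cum)[1L]
  within <- tpos - c(0L, cum)[i]
  if (tx$strand == "+") {
    g <- tx$exons$start[i] + within - 1L
    genomic_change(tx$contig, g, change$ref, change$alt)
  } else {
    g <- tx$exons$end[i] - within + 1L
    genomic_change(tx$contig, g, complement_base(change$ref),
                   complement_base(change$alt))
  }
}

#' @rdname coding_to_genomic
#' @export
genomic_to_coding <- function(change, tx) {
  stopifnot(inherits(change, "genomic_change"), inherits(tx, "transcript_model"))
  if (!is.na(change$contig) && change$contig != tx$contig)
    stop("contig mismatch: change on ", change$contig, ", transcript on ",
         tx$contig)
  w <- tx$exons$end - tx$exons$start + 1L
  cum <- cumsum(w)
  i <- which(change$pos >= tx$exons$start & change$pos <= tx$exons$end)
  if (length(i) != 1L)
    stop("genomic position ", change$pos, " not inside an exon")
  within <- if (tx$strand == "+") change$pos - tx$exons$start[i] + 1L
            else tx$exons$end[i] - change$pos + 1L
  tpos <- c(0L, cum)[i] + within
  cpos <- tpos - tx$cds_offset
  if (cpos < 1L || cpos > nchar(tx$cds_sequence))
    stop("genomic position maps outside the coding sequence")
  if (tx$strand == "+") coding_change(cpos, change$ref, change$alt)
  else coding_change(cpos, complement_base(change$ref),
                     complement_base(change$alt))
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Expand a variant query into all reachable surface forms
#'
#' Produces the union of surface forms across every level reachable from the
#' query: protein templates always (once an amino-acid change is known),
#' coding and genomic renderings when a transcript model enables the
#' cross-level mapping. Without a transcript, only the query's own level is
#' expanded. Gene-synonym alternation is applied only when a lexicon is
#' supplied and is off by default.
#'
#' @param query a [variant_query][parse_variant()] (or a string, parsed on
#'   the fly).
#' @param tx optional [transcript_model()] for the query's gene.
#' @param gene_synonyms optional synonym lexicon (see [read_gene_synonyms()]);
#'   aliases of the query gene widen the gene co-occurrence match in
#'   [search_variant()].
#' @param templates protein template ids, see [protein_templates()].
#' @return an object of class `expansion_set`: list with `query`, `forms`
#'   (data.frame `form`/`level`/`template`, unique forms) and `genes`
#'   (gene symbol plus any aliases).
#' @examples
#' tx <- toy_braf_transcript()
#' ex <- expand_all(parse_variant("BRAF:V600E"), tx)
#' subset(ex$forms, level == "coding")
#' @export
expand_all <- function(query, tx = NULL, gene_synonyms = NULL,
                       templates = protein_templates()) {
  if (is.character(query)) query <- parse_variant(query)
  stopifnot(inherits(query, "variant_query"))
  if (!is.null(tx) && tx$gene != query$gene)
    stop("transcript model is for gene ", tx$gene, ", query is for ",
         query$gene)

  aa <- NULL; codings <- list(); genomics <- list()
  ch <- query$change
  if (query$level == "protein") {
    aa <- ch
    if (!is.null(tx)) codings <- protein_to_coding(aa, tx)
  } else if (query$level == "coding") {
    codings <- list(ch)
    if (!is.null(tx)) {
      aa <- coding_to_protein(ch, tx)
      # sibling coding changes yielding the same protein change
      if (!aa$synonymous) codings <- protein_to_coding(aa, tx)
    }
  } else { # genomic
    genomics <- list(ch)
    if (!is.null(tx)) {
      c0 <- genomic_to_coding(ch, tx)
      codings <- list(c0)
      aa <- coding_to_protein(c0, tx)
      if (!aa$synonymous) codings <- protein_to_coding(aa, tx)
    }
  }
  if (!is.null(tx) && length(codings))
    genomics <- lapply(codings, coding_to_genomic, tx = tx)

  parts <- list()
  if (!is.null(aa))
    parts[[length(parts) + 1L]] <- expand_protein_surface_forms(aa, templates)
  for (cc in codings) parts[[length(parts) + 1L]] <- render_coding_forms(cc)
  for (gc in genomics) parts[[length(parts) + 1L]] <- render_genomic_forms(gc)
  forms <- do.call(rbind, parts)
  forms <- forms[!duplicated(forms$form), , drop = FALSE]
  rownames(forms) <- NULL

  genes <- query$gene
  if (!is.null(gene_synonyms)) {
    al <- gene_synonyms$alias[gene_synonyms$symbol == query$gene]
    genes <- unique(c(genes, al))
  }
  structure(list(query = query, forms = forms, genes = genes),
            class = "expansion_set")
}

#' @export
print.expansion_set <- function(x, ...) {
  cat("Expansion of ", x$query$raw_text, ": ", nrow(x$forms),
      " surface forms (",
      paste(names(table(x$forms$level)), table(x$forms$level),
            sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Read a gene-synonym lexicon
#'
#' Two-column tab-delimited file mapping `symbol` to `alias`, one alias per
#' line. Used to widen gene co-occurrence matching; off unless supplied.
#'
#' @param path TSV file path.
#' @return data.frame with columns `symbol`, `alias`.
#' @export
read_gene_synonyms <- function(path) {
  d <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("symbol", "alias") %in% names(d)))
    stop("gene-synonym lexicon needs columns 'symbol' and 'alias'")
  d[, c("symbol", "alias")]
}
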