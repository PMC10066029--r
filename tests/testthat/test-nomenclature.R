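test_that("parse_variant recognizes protein, coding and genomic notations", {
  q <- parse_variant("BRAF:V600E")
  expect_identical(q$gene, "BRAF")
  expect_identical(q$level, "protein")
  expect_identical(q$change$ref, "V")
  expect_identical(q$change$pos, 600L)
  expect_identical(q$change$alt, "E")

  q3 <- parse_variant("BRAF:Val600Glu")
  expect_identical(q3$change[c("ref", "pos", "alt")],
                   q$change[c("ref", "pos", "alt")])

  qc <- parse_variant("BRAF:c.1799T>A")
  expect_identical(qc$level, "coding")
  expect_identical(qc$change$pos, 1799L)
  expect_identical(qc$change$ref, "T")
  expect_identical(qc$change$alt, "A")

  qg <- parse_variant("BRAF:g.140001799T>A")
  expect_identical(qg$level, "genomic")
  expect_true(is.na(qg$change$contig))

  # prefixed and stop notations
  expect_identical(parse_variant("TP53:p.R306X")$change$alt, "*")
  expect_identical(parse_variant("TP53:Arg306Ter")$change$alt, "*")
  expect_identical(parse_variant("TP53:R306*")$change$alt, "*")
})

test_that("parse_variant resolves ambiguity and rejects bad input", {
  # both letters valid amino acids -> protein, flagged ambiguous
  qa <- parse_variant("EGFR:A123G")
  expect_identical(qa$level, "protein")
  expect_true(qa$ambiguous)
  # unambiguous protein letters are not flagged
  expect_false(parse_variant("BRAF:V600E")$ambiguous)
  # bare NNNX>Y with two nucleotides -> coding
  qb <- parse_variant("BRAF:1799T>A")
  expect_identical(qb$level, "coding")
  # substitution form with a non-nucleotide letter -> protein
  qs <- parse_variant("BRAF:600V>E")
  expect_identical(qs$level, "protein")
  expect_identical(qs$change$pos, 600L)

  expect_error(parse_variant("BRAF:"), "empty change")
  expect_error(parse_variant(":V600E"), "empty gene")
  expect_error(parse_variant("BRAF:Zzz600Glu"), "Zzz600Glu")
  expect_error(parse_variant("not a variant"), "GENE:change")
})

test_that("protein surface forms cover the template contract", {
  f <- expand_protein_surface_forms(aa_change("V", 600, "E"))
  expect_setequal(
    f$form,
    c("V600E", "Val600Glu", "p.V600E", "p.Val600Glu", "V600→E",
      "V 600 E", "600V>E"))
  # one form per enabled template for a distinct-letter substitution
  expect_identical(nrow(f), length(protein_templates()))
  expect_identical(anyDuplicated(f$form), 0L)
  # identity template always a member
  expect_true("V600E" %in% f$form)

  # stop-gain changes add the X spelling; 3-letter uses Ter
  fs <- expand_protein_surface_forms(aa_change("R", 306, "*"))
  expect_true(all(c("R306*", "R306X", "Arg306Ter", "p.R306X") %in% fs$form))
})

test_that("protein_to_coding matches the nine-mutant enumeration oracle", {
  tx <- braf_toy()
  got <- protein_to_coding(aa_change("V", 600, "E"), tx)
  expect_length(got, 1L)
  expect_identical(got[[1]]$pos, 1799L)
  expect_identical(got[[1]]$ref, "T")
  expect_identical(got[[1]]$alt, "A")

  # no single-nucleotide path K(AAA) -> W(TGG)
  txk <- make_tx("AAAGGG")
  expect_length(protein_to_coding(aa_change("K", 1, "W"), txk), 0L)

  # reference mismatch and range errors
  expect_error(protein_to_coding(aa_change("M", 600, "E"), tx), "mismatch")
  expect_error(protein_to_coding(aa_change("V", 10000, "E"), tx), "beyond")

  # brute-force oracle over random (codon, target-aa) pairs
  gc <- Biostrings::GENETIC_CODE
  set.seed(41)
  aas <- unique(unname(gc))
  for (rep in 1:1000) {
    codon <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                   collapse = "")
    ref <- unname(gc[codon])
    if (ref == "*") next
    alt <- sample(setdiff(aas, ref), 1)
    expected <- character()
    for (off in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(codon, off, off) == b) next
      mut <- codon; substr(mut, off, off) <- b
      if (unname(gc[mut]) == alt)
        expected <- c(expected, paste0(off, substr(codon, off, off), b))
    }
    txr <- make_tx(paste0(codon, "GGG"))
    got <- protein_to_coding(aa_change(ref, 1, alt), txr)
    expect_setequal(vapply(got, function(g) paste0(g$pos, g$ref, g$alt), ""),
                    expected)
  }
})

test_that("coding_to_protein agrees with the full-CDS translation oracle", {
  tx <- braf_toy()
  aa <- coding_to_protein(coding_change(1799, "T", "A"), tx)
  expect_identical(aa$ref, "V"); expect_identical(aa$pos, 600L)
  expect_identical(aa$alt, "E"); expect_false(aa$synonymous)

  # synonymous flag, not an error: GCT -> GCC is still Ala
  txa <- make_tx("GCTGGG")
  s <- coding_to_protein(coding_change(3, "T", "C"), txa)
  expect_true(s$synonymous)
  expect_identical(s$ref, s$alt)

  expect_error(coding_to_protein(coding_change(1799, "G", "A"), tx), "mismatch")
  expect_error(coding_to_protein(coding_change(1e6, "T", "A"), tx), "beyond")

  # random positions on random CDS: translate-before/after oracle
  set.seed(42)
  for (rep in 1:50) {
    cds <- random_cds(30)
    txr <- make_tx(cds)
    pos <- sample(nchar(cds), 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mut <- cds; substr(mut, pos, pos) <- alt
    before <- oracle_translate(cds); after <- oracle_translate(mut)
    ci <- (pos - 1) %/% 3 + 1
    got <- coding_to_protein(coding_change(pos, ref, alt), txr)
    expect_identical(got$ref, substr(before, ci, ci))
    expect_identical(got$alt, substr(after, ci, ci))
    expect_identical(got$pos, as.integer(ci))
    expect_identical(got$synonymous, substr(before, ci, ci) == substr(after, ci, ci))
  }
})

test_that("coding_to_genomic walks exons correctly on both strands", {
  # single exon, + strand, identity offset: c.1 at exon start
  txp <- make_tx("ATGAAA", exons = data.frame(start = 1001L, end = 1006L))
  g <- coding_to_genomic(coding_change(1, "A", "G"), txp)
  expect_identical(g$pos, 1001L)
  expect_identical(g$ref, "A"); expect_identical(g$alt, "G")

  # minus strand: reported bases are complements, mapping is an involution
  txm <- make_tx("ATGAAA", strand = "-",
                 exons = data.frame(start = 1001L, end = 1006L))
  cc <- coding_change(2, "T", "C")
  gm <- coding_to_genomic(cc, txm)
  expect_identical(gm$ref, "A"); expect_identical(gm$alt, "G")
  back <- genomic_to_coding(gm, txm)
  expect_identical(back[c("pos", "ref", "alt")], cc[c("pos", "ref", "alt")])

  # multi-exon models vs an exhaustive per-exon coordinate table
  set.seed(43)
  for (strand in c("+", "-")) {
    cds <- random_cds(20)  # 60 nt
    w <- c(17L, 25L, 18L)
    if (strand == "+") {
      starts <- c(2001L, 2101L, 2301L)
      exons <- data.frame(start = starts, end = starts + w - 1L)
      gpos_by_tpos <- unlist(Map(function(s, e) s:e, exons$start, exons$end))
    } else {
      ends <- c(2901L, 2801L, 2601L)
      exons <- data.frame(start = ends - w + 1L, end = ends)
      gpos_by_tpos <- unlist(Map(function(s, e) e:s, exons$start, exons$end))
    }
    txe <- make_tx(cds, strand = strand, exons = exons)
    for (pos in seq_len(nchar(cds))) {
      ref <- substr(cds, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      g <- coding_to_genomic(coding_change(pos, ref, alt), txe)
      expect_identical(g$pos, gpos_by_tpos[[pos]])
      if (strand == "+") expect_identical(g$ref, ref)
      else expect_identical(g$ref, chartr("ACGT", "TGCA", ref))
      rt <- genomic_to_coding(g, txe)
      expect_identical(rt$pos, pos)
      expect_identical(rt$ref, ref)
      expect_identical(rt$alt, alt)
    }
  }

  expect_error(coding_to_genomic(coding_change(5000, "A", "G"), txp), "beyond")
})

test_that("protein->coding->protein round trip holds", {
  set.seed(44)
  for (rep in 1:40) {
    cds <- random_cds(25)
    txr <- make_tx(cds)
    prot <- oracle_translate(cds)
    ci <- sample(25, 1)
    ref <- substr(prot, ci, ci)
    alt <- sample(setdiff(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*"),
                          ref), 1)
    a <- aa_change(ref, ci, alt)
    for (cc in protein_to_coding(a, txr)) {
      b <- coding_to_protein(cc, txr)
      expect_identical(b[c("ref", "pos", "alt")], a[c("ref", "pos", "alt")])
    }
  }
})

test_that("every emitted surface form re-parses to the same change", {
  changes <- list(aa_change("V", 600, "E"), aa_change("R", 12, "*"),
                  aa_change("L", 858, "R"))
  for (a in changes) {
    ex <- expand_all(structure(list(gene = "G1", change = a,
                                    level = "protein", raw_text = "G1:x",
                                    ambiguous = FALSE),
                               class = "variant_query"),
                     tx = NULL)
    for (f in ex$forms$form) {
      q <- parse_variant(paste0("G1:", f))
      expect_identical(q$level, "protein")
      expect_identical(q$change[c("ref", "pos", "alt")],
                       a[c("ref", "pos", "alt")])
    }
  }
  # coding and genomic renderings re-parse at their level
  tx <- braf_toy()
  ex <- expand_all(parse_variant("BRAF:V600E"), tx)
  cf <- ex$forms[ex$forms$level == "coding", ]
  for (f in cf$form)
    expect_identical(parse_variant(paste0("BRAF:", f))$change$pos, 1799L)
  gf <- ex$forms[ex$forms$level == "genomic", ]
  for (f in gf$form)
    expect_identical(parse_variant(paste0("BRAF:", f))$level, "genomic")
})

test_that("expand_all unions levels and honors the transcript requirement", {
  tx <- braf_toy()
  ex <- expand_all(parse_variant("BRAF:V600E"), tx)
  expect_true(all(c("V600E", "Val600Glu", "1799T>A", "c.1799T>A") %in%
                    ex$forms$form))
  # superset of each constituent expander
  expect_true(all(expand_protein_surface_forms(aa_change("V", 600, "E"))$form
                  %in% ex$forms$form))
  expect_identical(anyDuplicated(ex$forms$form), 0L)

  # without a transcript: protein templates only
  ex0 <- expand_all(parse_variant("BRAF:V600E"))
  expect_setequal(ex0$forms$form,
                  expand_protein_surface_forms(aa_change("V", 600, "E"))$form)

  # a coding query without transcript stays at coding level
  exc <- expand_all(parse_variant("BRAF:c.1799T>A"))
  expect_setequal(exc$forms$level, "coding")

  # from the coding query with a transcript the protein forms are reached
  exc2 <- expand_all(parse_variant("BRAF:c.1799T>A"), tx)
  expect_true(all(c("V600E", "Val600Glu") %in% exc2$forms$form))

  # gene synonyms widen the gene list only when supplied
  lex <- data.frame(symbol = "BRAF", alias = "BRAF1")
  expect_identical(expand_all(parse_variant("BRAF:V600E"), tx)$genes, "BRAF")
  expect_setequal(expand_all(parse_variant("BRAF:V600E"), tx,
                             gene_synonyms = lex)$genes,
                  c("BRAF", "BRAF1"))
  # transcript for the wrong gene is rejected
  expect_error(expand_all(parse_variant("KRAS:G12D"), tx), "KRAS")
})

test_that("transcript models validate and round-trip through TSV and JSON", {
  expect_error(transcript_model("G", "c", "+", data.frame(start = 10, end = 5),
                                "ATG"), "end before start")
  expect_error(transcript_model("G", "c", "+", data.frame(start = 1, end = 9),
                                "ATGA"), "divisible")
  expect_error(transcript_model("G", "c", "+",
                                data.frame(start = c(1, 5), end = c(6, 9)),
                                "ATG"), "overlap")
  expect_error(transcript_model("G", "c", "+", data.frame(start = 1, end = 3),
                                "ATGAAA"), "too short")

  txs <- list(B = make_tx("ATGAAATAA", gene = "B"),
              M = make_tx("ATGCCCTAA", strand = "-", gene = "M",
                          exons = data.frame(start = c(3005L, 2001L),
                                             end = c(3009L, 2004L))))
  tsv <- tempfile(fileext = ".tsv")
  write_transcripts(txs, tsv)
  back <- read_transcripts(tsv)
  expect_identical(back, txs)

  # FASTA-deferred CDS
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">B", "ATGAAATAA", ">M", "ATGCCCTAA"), fa)
  d <- utils::read.delim(tsv, colClasses = "character")
  d$cds_sequence <- "."
  tsv2 <- tempfile(fileext = ".tsv")
  utils::write.table(d, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_transcripts(tsv2, cds_fasta = fa), txs)

  # JSON equivalent
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(txs, function(tx) list(
    gene = tx$gene, contig = tx$contig, strand = tx$strand,
    exons = lapply(seq_len(nrow(tx$exons)), function(i)
      list(start = tx$exons$start[i], end = tx$exons$end[i])),
    cds_offset = tx$cds_offset, cds_sequence = tx$cds_sequence)),
    js, auto_unbox = TRUE)
  expect_identical(read_transcripts(js), txs)
})
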