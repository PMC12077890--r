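test_that("dinucleotide classification follows the canonical splice rules", {
  expect_identical(classify_intron("GT", "AG"), "U2")
  expect_identical(classify_intron("GC", "AG"), "U2")
  expect_identical(classify_intron("AT", "AC"), "U12")
  expect_warning(cls <- classify_intron("CT", "AC"),
                 "minus-strand")
  expect_identical(cls, "ambiguous")
  expect_error(classify_intron("GR", "AG"), "non-ACGTN")
  # curated override wins over the sequence rule
  expect_identical(classify_intron("GT", "AG", override = "U12"), "U12")
  expect_identical(classify_intron(c("GT", "AT"), c("AG", "AC"),
                                   override = c(NA, "U2")),
                   c("U2", "U2"))
  expect_error(classify_intron("GT", "AG", override = "minor"),
               "unknown class token")
})

make_planted_genome <- function(donor, acceptor) {
  # one transcript, exons [0,100) and [200,300), intron [100,200)
  set.seed(42)
  g <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  substr(g, 101, 102) <- donor
  substr(g, 199, 200) <- acceptor
  Biostrings::DNAStringSet(setNames(g, "chr1"))
}

plus_models <- function() {
  ex <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 201), c(100, 300)), strand = "+")
  ex$gene_id <- "g1"
  GenomicRanges::GRangesList(t1 = ex)
}

test_that("extract_introns recovers coordinates and dinucleotides", {
  cat1 <- extract_introns(plus_models(), make_planted_genome("GT", "AG"))
  rec <- cat1$records
  expect_equal(nrow(rec), 1L)
  expect_equal(c(rec$start, rec$end), c(100L, 200L))
  expect_identical(rec$donor_dinuc, "GT")
  expect_identical(rec$acceptor_dinuc, "AG")
  expect_identical(rec$intron_class, "U2")
  expect_equal(cat1$counts_by_class$U2, 1L)
})

test_that("minus-strand dinucleotides are read in transcript orientation", {
  # genome carries CT..AC: reverse complement of a GT..AG intron
  ex <- plus_models()[[1]]
  GenomicRanges::strand(ex) <- "-"
  models <- GenomicRanges::GRangesList(t1 = ex)
  cat1 <- extract_introns(models, make_planted_genome("CT", "AC"))
  expect_identical(cat1$records$donor_dinuc, "GT")
  expect_identical(cat1$records$acceptor_dinuc, "AG")
  expect_identical(cat1$records$intron_class, "U2")
})

test_that("single-exon transcripts yield no introns", {
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 300),
                               strand = "+")
  ex$gene_id <- "g1"
  cat1 <- extract_introns(GenomicRanges::GRangesList(t1 = ex),
                          make_planted_genome("GT", "AG"))
  expect_equal(nrow(cat1$records), 0L)
})

test_that("short exon gaps are skipped with a warning", {
  ex <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 103), c(100, 200)), strand = "+")
  ex$gene_id <- "g1"
  expect_warning(
    cat1 <- extract_introns(GenomicRanges::GRangesList(t1 = ex),
                            make_planted_genome("GT", "AG")),
    "shorter than")
  expect_equal(nrow(cat1$records), 0L)
})

test_that("a chromosome absent from the genome is a named hard error", {
  ex <- GenomicRanges::GRanges("chrZ",
    IRanges::IRanges(c(1, 201), c(100, 300)), strand = "+")
  ex$gene_id <- "g1"
  expect_error(
    extract_introns(GenomicRanges::GRangesList(t1 = ex),
                    make_planted_genome("GT", "AG")),
    "chrZ")
})

test_that("planted classes round-trip for all 256 dinucleotide pairs", {
  # one long genome, 256 two-exon transcripts, each intron planted with one
  # donor x acceptor combination; extracted classes must equal the rule
  # applied directly
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(d1 = bases, d2 = bases, a1 = bases, a2 = bases,
                       stringsAsFactors = FALSE)
  donors <- paste0(pairs$d1, pairs$d2)
  acceptors <- paste0(pairs$a1, pairs$a2)
  n <- nrow(pairs)
  pitch <- 400L
  set.seed(9)
  g <- paste(sample(bases, n * pitch, TRUE), collapse = "")
  starts0 <- (seq_len(n) - 1L) * pitch            # exon1 [s, s+100)
  for (i in seq_len(n)) {
    substr(g, starts0[i] + 101L, starts0[i] + 102L) <- donors[i]
    substr(g, starts0[i] + 199L, starts0[i] + 200L) <- acceptors[i]
  }
  genome <- Biostrings::DNAStringSet(setNames(g, "chr1"))
  models <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i) {
    ex <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(starts0[i] + c(1L, 201L),
                       starts0[i] + c(100L, 300L)), strand = "+")
    ex$gene_id <- paste0("g", i)
    ex
  }))
  names(models) <- paste0("t", seq_len(n))
  cat1 <- suppressWarnings(extract_introns(models, genome))
  rec <- cat1$records[order(cat1$records$start), ]
  expect_equal(nrow(rec), n)
  expected <- suppressWarnings(classify_intron(donors, acceptors))
  expect_identical(rec$intron_class, expected)
  expect_identical(rec$donor_dinuc, donors)
  expect_identical(rec$acceptor_dinuc, acceptors)
})

test_that("classes are invariant under genome reverse-complement", {
  # mirror the construct: reverse-complement the genome, mirror exon
  # coordinates, flip strands; every intron class must be unchanged
  combos <- list(c("GT", "AG"), c("GC", "AG"), c("AT", "AC"), c("CA", "TG"))
  for (co in combos) {
    genome <- make_planted_genome(co[1], co[2])
    fwd <- suppressWarnings(extract_introns(plus_models(), genome))
    L <- Biostrings::width(genome)[1]
    rc <- Biostrings::reverseComplement(genome)
    names(rc) <- "chr1"
    ex <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(L - c(300, 100) + 1L, L - c(201, 1) + 1L),
      strand = "-")
    ex$gene_id <- "g1"
    rev <- suppressWarnings(
      extract_introns(GenomicRanges::GRangesList(t1 = ex), rc))
    expect_identical(rev$records$intron_class, fwd$records$intron_class)
    expect_identical(rev$records$donor_dinuc, fwd$records$donor_dinuc)
  }
})

test_that("duplicate introns across transcripts collapse to one record", {
  ex1 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 201), c(100, 300)), strand = "+")
  ex1$gene_id <- "g1"
  ex2 <- ex1
  models <- GenomicRanges::GRangesList(t1 = ex1, t2 = ex2)
  cat1 <- extract_introns(models, make_planted_genome("GT", "AG"))
  expect_equal(nrow(cat1$records), 1L)
  expect_identical(cat1$records$transcript_id, "t1,t2")
})

write_table_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("intron tables load with census, dedup and pragma handling", {
  hdr <- paste(c("chrom", "start", "end", "strand", "gene_id",
                 "intron_class"), collapse = "\t")
  p <- write_table_fixture(c("# coordinates=0-based-half-open", hdr,
                             "chr1\t100\t200\t+\tg1\tU12",
                             "chr1\t400\t500\t+\tg2\tU2",
                             "chr2\t10\t90\t-\tg3\tU2"))
  cat1 <- load_intron_table(p)
  expect_equal(cat1$counts_by_class$U12, 1L)
  expect_equal(cat1$counts_by_class$U2, 2L)

  # duplicate rows differing only in gene: one record, both genes counted
  p2 <- write_table_fixture(c("# coordinates=0-based-half-open", hdr,
                              "chr1\t100\t200\t+\tg1\tU12",
                              "chr1\t100\t200\t+\tg9\tU12"))
  expect_warning(cat2 <- load_intron_table(p2), "duplicate")
  expect_equal(nrow(cat2$records), 1L)
  expect_equal(cat2$genes_by_class$U12, 2L)

  # 1-based pragma shifts start by -1
  p3 <- write_table_fixture(c("# coordinates=1-based", hdr,
                              "chr1\t101\t200\t+\tg1\tU2"))
  cat3 <- load_intron_table(p3)
  expect_equal(cat3$records$start, 100L)
  expect_equal(cat3$records$end, 200L)

  p4 <- write_table_fixture(c(hdr, "chr1\t100\t200\t+\tg1\tminor"))
  expect_error(load_intron_table(p4), "unknown class")
})

test_that("catalog TSV writing round-trips through load_intron_table", {
  cat1 <- extract_introns(plus_models(), make_planted_genome("AT", "AC"))
  path <- tempfile(fileext = ".tsv")
  write_intron_catalog(cat1, path)
  cat2 <- load_intron_table(path)
  expect_equal(cat2$records$start, cat1$records$start)
  expect_equal(cat2$records$end, cat1$records$end)
  expect_identical(cat2$records$intron_class, cat1$records$intron_class)
})
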