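#' @keywords internal
"_PACKAGE"

# Coordinates are 0-based half-open everywhere inside the package; GTF
# (1-based closed) is converted on read and all written tables carry a
# header pragma stating the convention.

COORD_PRAGMA <- "# coordinates=0-based-half-open"

#' Classify introns by terminal dinucleotides
#'
#' Minor (U12-type) introns are identified by their canonical AT-AC termini,
#' major (U2-type) introns by GT-AG or GC-AG; every other combination is
#' `"ambiguous"`. Dinucleotides must be given in transcript orientation
#' (i.e. reverse-complemented for minus-strand introns). An explicit class
#' from a curated table (IAOD-style) overrides the sequence rule, because
#' dinucleotide termini are only a proxy: genuine U12 introns include GT-AG
#' subtypes that sequence rules alone cannot recover.
#'
#' @param donor character vector of 2-letter donor (5') dinucleotides.
#' @param acceptor character vector of 2-letter acceptor (3') dinucleotides.
#' @param override optional character vector of curated class labels
#'   (`"U12"`, `"U2"`, `"ambiguous"` or `NA`); non-`NA` entries win.
#' @return character vector with levels `"U12"`, `"U2"`, `"ambiguous"`.
#' @examples
#' classify_intron("GT", "AG")  # "U2"
#' classify_intron("AT", "AC")  # "U12"
#' @export
classify_intron <- function(donor, acceptor, override = NULL) {
  donor <- toupper(donor)
  acceptor <- toupper(acceptor)
  bad <- grepl("[^ACGTN]", donor) | grepl("[^ACGTN]", acceptor) |
    nchar(donor) != 2L | nchar(acceptor) != 2L
  if (any(bad)) {
    stop("non-ACGTN dinucleotide(s): ",
         paste(unique(paste0(donor[bad], "-", acceptor[bad])), collapse = ", "))
  }
  pair <- paste0(donor, "-", acceptor)
  cls <- rep("ambiguous", length(pair))
  cls[pair == "AT-AC"] <- "U12"
  cls[pair %in% c("GT-AG", "GC-AG")] <- "U2"
  if (sum(pair == "CT-AC") > 0L) {
    # CT-AC is the reverse complement of GT-AG: the usual signature of a
    # minus-strand intron read in genome orientation by mistake.
    warning(sum(pair == "CT-AC"),
            " CT-AC intron(s): possible un-reverse-complemented minus-strand")
  }
  if (!is.null(override)) {
    stopifnot(length(override) == length(cls))
    ok <- !is.na(override)
    if (any(ok & !override %in% c("U12", "U2", "ambiguous"))) {
      stop("unknown class token in override: ",
           paste(unique(override[ok & !override %in%
                                   c("U12", "U2", "ambiguous")]),
                 collapse = ", "))
    }
    cls[ok] <- override[ok]
  }
  cls
}

new_intron_catalog <- function(records) {
  stopifnot(is.data.frame(records))
  records$intron_id <- if (nrow(records) == 0L) character(0) else
    intron_id(records)
  counts <- table(factor(records$intron_class,
                         levels = c("U12", "U2", "ambiguous")))
  genes <- vapply(c("U12", "U2", "ambiguous"), function(cl) {
    g <- records$gene_id[records$intron_class == cl]
    length(unique(unlist(strsplit(g, ",", fixed = TRUE))))
  }, integer(1))
  structure(
    list(records = records,
         counts_by_class = as.list(counts),
         genes_by_class = as.list(genes)),
    class = "intron_catalog")
}

intron_id <- function(records) {
  paste0(records$chrom, ":", records$start, "-", records$end,
         ":", records$strand)
}

#' @export
print.intron_catalog <- function(x, ...) {
  cat("intron_catalog:", nrow(x$records), "introns\n")
  cat("  by class:",
      paste(names(x$counts_by_class), unlist(x$counts_by_class),
            sep = "=", collapse = ", "), "\n")
  cat("  genes with >=1 intron of class:",
      paste(names(x$genes_by_class), unlist(x$genes_by_class),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract and classify introns from gene models and a genome
#'
#' Builds one intron per gap between consecutive exons of each transcript,
#' reads the terminal dinucleotides from the genome (reverse-complemented on
#' the minus strand so both are reported in transcript orientation) and
#' classifies each intron. Introns sharing coordinates and strand across
#' transcripts are collapsed into a single quantification unit; all parent
#' gene and transcript ids are retained as comma-separated lists.
#'
#' @param gene_models path to a GTF (ensembl dialect, `gene_id` and
#'   `transcript_id` attributes) or BED12 file, or a `GRangesList` of exons
#'   grouped by transcript (with `gene_id` in the metadata of each element).
#' @param genome path to a FASTA file (an `.fai` index is created if absent)
#'   or a named [Biostrings::DNAStringSet].
#' @param min_intron_length gaps shorter than this (default 4 nt, room for
#'   both dinucleotides) are skipped with a warning.
#' @return An `intron_catalog`: a list with `records` (one row per unique
#'   intron; 0-based half-open coordinates), `counts_by_class` and
#'   `genes_by_class`.
#' @export
extract_introns <- function(gene_models, genome, min_intron_length = 4L) {
  exons <- load_gene_models(gene_models)
  seqs <- open_genome(genome)

  rec <- do.call(rbind, lapply(names(exons), function(tx) {
    ex <- exons[[tx]]
    if (length(ex) < 2L) return(NULL)
    ex <- sort(ex)                       # genomic order
    strand <- as.character(GenomicRanges::strand(ex))[1]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    gid <- ex$gene_id[1]
    # gaps between consecutive exons, 0-based half-open
    s0 <- GenomicRanges::end(ex)[-length(ex)]        # 1-based end = 0-based start
    e0 <- GenomicRanges::start(ex)[-1] - 1L          # 0-based exclusive end
    idx <- if (strand == "-") rev(seq_along(s0)) else seq_along(s0)
    data.frame(chrom = chrom, start = s0, end = e0, strand = strand,
               gene_id = gid, transcript_id = tx, intron_index = idx,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rec) || nrow(rec) == 0L) {
    return(new_intron_catalog(empty_intron_records()))
  }
  short <- rec$end - rec$start < min_intron_length
  if (any(short)) {
    warning(sum(short), " exon gap(s) shorter than ", min_intron_length,
            " nt skipped")
    rec <- rec[!short, , drop = FALSE]
  }
  if (nrow(rec) == 0L) return(new_intron_catalog(empty_intron_records()))

  # collapse duplicate coordinates, keeping all parents
  key <- paste(rec$chrom, rec$start, rec$end, rec$strand)
  agg_tx <- tapply(rec$transcript_id, key, function(x)
    paste(unique(x), collapse = ","))
  agg_gn <- tapply(rec$gene_id, key, function(x)
    paste(unique(x), collapse = ","))
  first <- !duplicated(key)
  rec <- rec[first, , drop = FALSE]
  rec$transcript_id <- as.character(agg_tx[key[first]])
  rec$gene_id <- as.character(agg_gn[key[first]])

  din <- intron_dinucleotides(rec, seqs)
  rec$donor_dinuc <- din$donor
  rec$acceptor_dinuc <- din$acceptor
  rec$intron_class <- classify_intron(din$donor, din$acceptor)
  rownames(rec) <- NULL
  new_intron_catalog(rec)
}

empty_intron_records <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             transcript_id = character(), intron_index = integer(),
             donor_dinuc = character(), acceptor_dinuc = character(),
             intron_class = character(), stringsAsFactors = FALSE)
}

load_gene_models <- function(gene_models) {
  if (methods::is(gene_models, "GRangesList")) return(gene_models)
  if (!is.character(gene_models) || !file.exists(gene_models)) {
    stop("gene model file not found: ", gene_models)
  }
  if (grepl("\\.bed$", gene_models, ignore.case = TRUE)) {
    gr <- rtracklayer::import(gene_models, format = "BED")
    ex <- rtracklayer::blocks(gr)           # exon blocks per BED12 record
    ex <- GenomicRanges::GRangesList(lapply(seq_along(ex), function(i) {
      g <- ex[[i]]
      g$gene_id <- gr$name[i]
      GenomicRanges::strand(g) <- GenomicRanges::strand(gr)[i]
      g
    }))
    names(ex) <- gr$name
    return(ex)
  }
  gr <- rtracklayer::import(gene_models, format = "GTF")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", gene_models)
  ex <- GenomicRanges::split(gr, gr$transcript_id)
  ex
}

open_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (!is.character(genome) || !file.exists(genome)) {
    stop("genome FASTA not found: ", genome)
  }
  if (!file.exists(paste0(genome, ".fai"))) Rsamtools::indexFa(genome)
  Rsamtools::FaFile(genome)
}

intron_dinucleotides <- function(rec, seqs) {
  chroms <- if (methods::is(seqs, "DNAStringSet")) names(seqs) else
    GenomicRanges::seqnames(Rsamtools::seqinfo(seqs))
  miss <- setdiff(unique(rec$chrom), chroms)
  if (length(miss) > 0L) {
    stop("chromosome(s) absent from genome: ", paste(miss, collapse = ", "))
  }
  don_gr <- GenomicRanges::GRanges(rec$chrom,
    IRanges::IRanges(rec$start + 1L, rec$start + 2L))
  acc_gr <- GenomicRanges::GRanges(rec$chrom,
    IRanges::IRanges(rec$end - 1L, rec$end))
  get <- function(gr) {
    if (methods::is(seqs, "DNAStringSet")) {
      ss <- seqs[as.character(GenomicRanges::seqnames(gr))]
      as.character(Biostrings::subseq(ss, GenomicRanges::start(gr),
                                      GenomicRanges::end(gr)))
    } else {
      as.character(Biostrings::getSeq(seqs, gr))
    }
  }
  left <- get(don_gr)
  right <- get(acc_gr)
  minus <- rec$strand == "-"
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  donor <- ifelse(minus, rc(right), left)
  acceptor <- ifelse(minus, rc(left), right)
  list(donor = toupper(donor), acceptor = toupper(acceptor))
}

#' Import an intron class table
#'
#' Reads a curated tab-separated intron table (IAOD-style) with columns
#' `chrom`, `start`, `end`, `strand`, `gene_id`, `intron_class`. A header
#' pragma line `# coordinates=...` declares the coordinate convention;
#' `1-based` coordinates are shifted to the internal 0-based half-open
#' convention on read (start - 1). Rows duplicated in coordinates are
#' collapsed with a warning; their gene ids are all retained and counted.
#'
#' @param path TSV file path.
#' @return An `intron_catalog` with the curated classes taken verbatim.
#' @export
load_intron_table <- function(path) {
  if (!file.exists(path)) stop("intron table not found: ", path)
  header <- readLines(path, n = 5L)
  pragma <- grep("^#\\s*coordinates\\s*=", header, value = TRUE)
  one_based <- length(pragma) > 0L && grepl("1-based", pragma[1])
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "intron_class")
  if (!all(need %in% names(tab))) {
    stop("intron table missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  bad <- !tab$intron_class %in% c("U12", "U2", "ambiguous")
  if (any(bad)) {
    stop("unknown class token(s): ",
         paste(unique(tab$intron_class[bad]), collapse = ", "))
  }
  if (one_based) tab$start <- tab$start - 1L

  key <- paste(tab$chrom, tab$start, tab$end, tab$strand)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate intron row(s) collapsed")
    agg_gn <- tapply(tab$gene_id, key, function(x)
      paste(unique(x), collapse = ","))
    cls <- tapply(tab$intron_class, key, function(x) {
      if (length(unique(x)) > 1L)
        stop("conflicting classes for one intron")
      x[1]
    })
    first <- !duplicated(key)
    tab <- tab[first, , drop = FALSE]
    tab$gene_id <- as.character(agg_gn[key[first]])
    tab$intron_class <- as.character(cls[key[first]])
  }
  rec <- data.frame(
    chrom = tab$chrom, start = as.integer(tab$start),
    end = as.integer(tab$end), strand = tab$strand,
    gene_id = tab$gene_id,
    transcript_id = if ("transcript_id" %in% names(tab))
      tab$transcript_id else NA_character_,
    intron_index = if ("intron_index" %in% names(tab))
      as.integer(tab$intron_index) else NA_integer_,
    donor_dinuc = if ("donor_dinuc" %in% names(tab))
      tab$donor_dinuc else NA_character_,
    acceptor_dinuc = if ("acceptor_dinuc" %in% names(tab))
      tab$acceptor_dinuc else NA_character_,
    intron_class = tab$intron_class,
    stringsAsFactors = FALSE)
  new_intron_catalog(rec)
}

#' Write an intron catalog to TSV
#'
#' Output carries the `# coordinates=0-based-half-open` pragma so that
#' [load_intron_table()] round-trips without coordinate shifts.
#'
#' @param catalog an `intron_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intron_catalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(COORD_PRAGMA, con)
  utils::write.table(catalog$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# GRanges view of the catalog (1-based closed, for overlap machinery)
catalog_granges <- function(catalog) {
  rec <- catalog$records
  gr <- GenomicRanges::GRanges(
    rec$chrom, IRanges::IRanges(rec$start + 1L, rec$end),
    strand = rec$strand)
  gr$intron_id <- rec$intron_id
  gr$intron_class <- rec$intron_class
  gr$gene_id <- rec$gene_id
  gr
}
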