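# Read counting over introns and flanking exons, retention index,
# retained-intron calling, class summaries and the differential screen.

#' Counting configuration
#'
#' @param min_overlap minimum aligned bases of a fragment inside an interval
#'   for the fragment to count toward it (default 10 nt).
#' @param flank_width width of each flanking exonic window on either side of
#'   the intron (default 100 nt).
#' @param mapq_min minimum mapping quality (default 10); primary alignments
#'   only, always.
#' @param drop_duplicates drop PCR/optical duplicate-flagged reads (default
#'   `FALSE`: intron signal is low and duplicate removal can erase it).
#' @return a list of class `counting_params`.
#' @export
counting_params <- function(min_overlap = 10L, flank_width = 100L,
                            mapq_min = 10L, drop_duplicates = FALSE) {
  structure(list(min_overlap = as.integer(min_overlap),
                 flank_width = as.integer(flank_width),
                 mapq_min = as.integer(mapq_min),
                 drop_duplicates = isTRUE(drop_duplicates)),
            class = "counting_params")
}

new_sample_counts <- function(sample_id, condition, library_size, per_intron) {
  structure(list(sample_id = sample_id, condition = condition,
                 library_size = library_size, per_intron = per_intron),
            class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat("sample_counts:", x$sample_id, "(", x$condition, ") —",
      x$library_size, "fragments,", nrow(x$per_intron), "introns\n")
  invisible(x)
}

#' Count fragments over introns and flanking exons
#'
#' For every intron in the catalog, counts (i) `intron_reads`: fragments
#' with at least `min_overlap` aligned bases inside the intron body;
#' (ii) `junction_spliced_reads`: fragments whose alignment contains a
#' splice gap exactly spanning the intron — these never count toward
#' `intron_reads`; (iii) `flank_exon_reads`: fragments with at least
#' `min_overlap` aligned bases in the two adjacent exonic windows of width
#' `flank_width`. Paired-end mates sharing a read name are merged into one
#' fragment so a fragment counts once. Only primary alignments with
#' MAPQ >= `mapq_min` are used.
#'
#' @param alignments path to a coordinate-sorted, indexed BAM (a `.sam` file
#'   is converted and indexed into a temporary directory).
#' @param catalog an `intron_catalog`.
#' @param params a [counting_params()] list.
#' @param sample_id,condition labels stored in the result.
#' @return A `sample_counts` object: per-intron counts plus `library_size`
#'   (total fragments passing filters).
#' @export
count_intron_reads <- function(alignments, catalog,
                               params = counting_params(),
                               sample_id = basename(alignments),
                               condition = NA_character_) {
  stopifnot(inherits(catalog, "intron_catalog"))
  if (nrow(catalog$records) == 0L) stop("empty intron catalog")
  bam <- alignments
  if (grepl("\\.sam$", bam, ignore.case = TRUE)) {
    if (!file.exists(bam)) stop("alignment file not found: ", bam)
    bam <- Rsamtools::asBam(bam,
      destination = tempfile(fileext = ""), overwrite = TRUE)
  }
  if (!file.exists(bam)) stop("alignment file not found: ", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index (.bai) missing for ", bam, "; index the file first")
  }

  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isUnmappedQuery = FALSE,
    isDuplicate = if (params$drop_duplicates) FALSE else NA)
  gal <- GenomicAlignments::readGAlignments(
    bam, use.names = FALSE,
    param = Rsamtools::ScanBamParam(flag = flag, what = "qname",
                                    mapqFilter = params$mapq_min))

  rec <- catalog$records
  bam_chroms <- GenomeInfoDb::seqlevels(gal)
  absent <- setdiff(unique(rec$chrom), bam_chroms)
  if (length(absent) > 0L) {
    warning("chromosome(s) absent from BAM header, zero counts: ",
            paste(absent, collapse = ", "))
  }

  # fragment = union of aligned blocks of all alignments sharing a qname
  qname <- S4Vectors::mcols(gal)$qname
  frag_id <- match(qname, unique(qname))
  n_frag <- length(unique(qname))

  blocks <- unlist(GenomicAlignments::grglist(gal))  # ref-space blocks, split at N
  block_frag <- rep(frag_id, S4Vectors::elementNROWS(
    GenomicAlignments::grglist(gal)))
  gaps <- unlist(GenomicAlignments::junctions(gal))  # splice gaps
  gap_frag <- rep(frag_id, S4Vectors::elementNROWS(
    GenomicAlignments::junctions(gal)))

  introns <- catalog_granges(catalog)
  GenomicRanges::strand(introns) <- "*"

  olap_count <- function(targets, target_of) {
    # fragments with >= min_overlap total aligned bases in their target
    hits <- GenomicRanges::findOverlaps(blocks, targets, ignore.strand = TRUE)
    if (length(hits) == 0L) {
      return(data.frame(frag = integer(), target = integer()))
    }
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(blocks)[S4Vectors::queryHits(hits)],
      IRanges::ranges(targets)[S4Vectors::subjectHits(hits)]))
    key <- paste(block_frag[S4Vectors::queryHits(hits)],
                 target_of[S4Vectors::subjectHits(hits)])
    tot <- tapply(ov, key, sum)
    keep <- tot >= params$min_overlap
    ks <- strsplit(names(tot)[keep], " ", fixed = TRUE)
    data.frame(frag = as.integer(vapply(ks, `[`, "", 1L)),
               target = as.integer(vapply(ks, `[`, "", 2L)))
  }

  n_int <- length(introns)
  body_pairs <- olap_count(introns, seq_len(n_int))

  # junction-spliced: gap exactly equal to the intron interval
  js <- integer(n_int)
  spliced_pairs <- NULL
  if (length(gaps) > 0L) {
    jh <- GenomicRanges::findOverlaps(gaps, introns, type = "equal",
                                      ignore.strand = TRUE)
    if (length(jh) > 0L) {
      spliced_pairs <- unique(data.frame(
        frag = gap_frag[S4Vectors::queryHits(jh)],
        target = S4Vectors::subjectHits(jh)))
      js <- tabulate(spliced_pairs$target, nbins = n_int)
    }
  }
  # a junction-spliced fragment never counts toward the intron body
  if (!is.null(spliced_pairs) && nrow(body_pairs) > 0L) {
    drop <- paste(body_pairs$frag, body_pairs$target) %in%
      paste(spliced_pairs$frag, spliced_pairs$target)
    body_pairs <- body_pairs[!drop, , drop = FALSE]
  }
  ir <- tabulate(body_pairs$target, nbins = n_int)

  # flanking exonic windows (clipped at position 0)
  fl_left <- GenomicRanges::GRanges(rec$chrom,
    IRanges::IRanges(pmax(rec$start - params$flank_width, 0L) + 1L,
                     rec$start))
  fl_right <- GenomicRanges::GRanges(rec$chrom,
    IRanges::IRanges(rec$end + 1L, rec$end + params$flank_width))
  flanks <- c(fl_left, fl_right)
  flank_of <- rep(seq_len(n_int), 2L)
  flank_pairs <- olap_count(flanks, flank_of)
  fr <- tabulate(flank_pairs$target, nbins = n_int)
  flank_len <- IRanges::width(IRanges::ranges(fl_left)) +
    IRanges::width(IRanges::ranges(fl_right))

  per_intron <- data.frame(
    intron_id = rec$intron_id,
    intron_class = rec$intron_class,
    gene_id = rec$gene_id,
    intron_reads = ir,
    intron_length = rec$end - rec$start,
    flank_exon_reads = fr,
    flank_exon_length = as.integer(flank_len),
    junction_spliced_reads = js,
    stringsAsFactors = FALSE)
  new_sample_counts(sample_id, condition, n_frag, per_intron)
}

#' Load precomputed per-intron counts from TSV
#'
#' Expects columns `sample`, `condition`, `intron_id`, `intron_reads`,
#' `flank_exon_reads`, `junction_spliced_reads`. Interval lengths and intron
#' classes are taken from the catalog; `library_size` per sample is either a
#' `library_size` column or the sum of all counted fragments.
#'
#' @param path TSV path.
#' @param catalog an `intron_catalog`.
#' @param flank_width used to reconstruct flank lengths when the catalog
#'   lacks them (default 100).
#' @return list of `sample_counts`, one per sample.
#' @export
read_counts_tsv <- function(path, catalog, flank_width = 100L) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("sample", "intron_id", "intron_reads", "flank_exon_reads",
            "junction_spliced_reads")
  if (!all(need %in% names(tab))) {
    stop("counts table missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  rec <- catalog$records
  lapply(split(tab, tab$sample), function(s) {
    m <- match(s$intron_id, rec$intron_id)
    if (anyNA(m)) stop("intron_id(s) absent from catalog: ",
                       paste(utils::head(s$intron_id[is.na(m)]), collapse = ", "))
    per <- data.frame(
      intron_id = s$intron_id,
      intron_class = rec$intron_class[m],
      gene_id = rec$gene_id[m],
      intron_reads = s$intron_reads,
      intron_length = rec$end[m] - rec$start[m],
      flank_exon_reads = s$flank_exon_reads,
      flank_exon_length = 2L * as.integer(flank_width),
      junction_spliced_reads = s$junction_spliced_reads,
      stringsAsFactors = FALSE)
    lib <- if ("library_size" %in% names(s)) s$library_size[1] else
      sum(s$intron_reads + s$flank_exon_reads + s$junction_spliced_reads)
    cond <- if ("condition" %in% names(s)) s$condition[1] else NA_character_
    new_sample_counts(s$sample[1], cond, lib, per)
  })
}

#' Retention index
#'
#' The retention index RI of an intron in a sample is the ratio of read
#' densities: `(intron_reads / intron_length) / (flank_exon_reads /
#' flank_exon_length)`. RI near 0 means the intron is spliced out; RI near 1
#' means intron coverage matches exonic coverage (full retention). When the
#' flank density is zero the index is undefined (`NA`) and the intron is
#' excluded from retention calling rather than throwing.
#'
#' @param counts a `sample_counts` object or its `per_intron` data frame.
#' @return numeric vector of RI values (`NA` where undefined).
#' @export
retention_index <- function(counts) {
  per <- if (inherits(counts, "sample_counts")) counts$per_intron else counts
  flank_density <- per$flank_exon_reads / per$flank_exon_length
  ri <- (per$intron_reads / per$intron_length) / flank_density
  ri[flank_density == 0] <- NA_real_
  ri
}

#' Call retained introns
#'
#' An intron is called retained in a sample when its retention index and raw
#' intron read count both clear their thresholds. The reads gate guards
#' against high RI driven by a handful of fragments in a lowly covered gene.
#'
#' @param ri retention index vector (`NA` = undefined, never called).
#' @param intron_reads raw intron fragment counts.
#' @param ri_min RI threshold (default 0.1).
#' @param reads_min minimum intron fragments (default 10).
#' @return logical vector (`NA` where RI is undefined).
#' @export
call_retained <- function(ri, intron_reads, ri_min = 0.1, reads_min = 10L) {
  out <- ri >= ri_min & intron_reads >= reads_min
  out[is.na(ri)] <- NA
  out
}

#' Per-intron, per-sample retention table
#'
#' @param samples list of `sample_counts`.
#' @param ri_min,reads_min thresholds passed to [call_retained()].
#' @return long data frame: one row per intron x sample with counts, RI and
#'   the retained call.
#' @export
retention_table <- function(samples, ri_min = 0.1, reads_min = 10L) {
  do.call(rbind, lapply(samples, function(s) {
    ri <- retention_index(s)
    data.frame(sample_id = s$sample_id, condition = s$condition,
               s$per_intron, ri = ri,
               retained = call_retained(ri, s$per_intron$intron_reads,
                                        ri_min, reads_min),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Percent retained introns per class and condition
#'
#' An intron counts as retained in a condition when it is called retained in
#' more than half of the replicates in which its RI is defined; introns with
#' no defined RI in any replicate are excluded from numerator and
#' denominator (their count is reported). The percentage is
#' `100 * retained / evaluable` per intron class.
#'
#' @param samples list of `sample_counts` (conditions taken from each).
#' @param ri_min,reads_min thresholds passed to [call_retained()].
#' @return data frame: condition, intron_class, n_evaluable, n_retained,
#'   n_undefined, percent_retained.
#' @export
class_retention_summary <- function(samples, ri_min = 0.1, reads_min = 10L) {
  conds <- unique(vapply(samples, `[[`, "", "condition"))
  ids <- samples[[1]]$per_intron$intron_id
  cls <- samples[[1]]$per_intron$intron_class
  out <- do.call(rbind, lapply(conds, function(cond) {
    reps <- Filter(function(s) identical(s$condition, cond), samples)
    # introns x replicates matrix of retained calls (NA = RI undefined)
    R <- vapply(reps, function(s) {
      m <- match(ids, s$per_intron$intron_id)
      ri <- retention_index(s)[m]
      call_retained(ri, s$per_intron$intron_reads[m], ri_min, reads_min)
    }, logical(length(ids)))
    R <- matrix(R, nrow = length(ids))
    n_def <- rowSums(!is.na(R))
    status <- ifelse(n_def == 0L, NA,
                     rowSums(R, na.rm = TRUE) / pmax(n_def, 1L) > 0.5)
    do.call(rbind, lapply(sort(unique(cls)), function(cl) {
      st <- status[cls == cl]
      n_eval <- sum(!is.na(st))
      if (n_eval == 0L) {
        warning("class ", cl, " has no evaluable introns in condition ",
                cond)
        pct <- NA_real_
      } else pct <- 100 * sum(st, na.rm = TRUE) / n_eval
      data.frame(condition = cond, intron_class = cl,
                 n_evaluable = n_eval, n_retained = sum(st, na.rm = TRUE),
                 n_undefined = sum(is.na(st)), percent_retained = pct,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

cpm_matrix <- function(samples, pseudocount = 0) {
  ids <- samples[[1]]$per_intron$intron_id
  m <- vapply(samples, function(s) {
    stopifnot(identical(s$per_intron$intron_id, ids))
    if (s$library_size <= 0) stop("library size must be > 0 for ",
                                  s$sample_id)
    s$per_intron$intron_reads / s$library_size * 1e6
  }, numeric(length(ids)))
  m <- matrix(m, nrow = length(ids),
              dimnames = list(ids, vapply(samples, `[[`, "", "sample_id")))
  m + pseudocount
}

#' Per-intron fold change of normalized intron reads between conditions
#'
#' Intron reads are normalized to counts per million counted fragments
#' (CPM); the per-intron fold change is `(mean CPM in b + pc) / (mean CPM in
#' a + pc)` with pseudocount `pc`. The per-class distribution of `log2FC`
#' supports class-level contrasts of intron-read signal.
#'
#' @param cond_a,cond_b lists of `sample_counts` for the two conditions.
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return data frame: intron_id, intron_class, gene_id, mean_cpm_a,
#'   mean_cpm_b, log2fc; attribute `class_summary` holds per-class medians.
#' @export
intron_read_foldchange <- function(cond_a, cond_b, pseudocount = 0.5) {
  stopifnot(length(cond_a) >= 1L, length(cond_b) >= 1L)
  ma <- cpm_matrix(cond_a)
  mb <- cpm_matrix(cond_b)
  per <- cond_a[[1]]$per_intron
  lfc <- log2((rowMeans(mb) + pseudocount) / (rowMeans(ma) + pseudocount))
  out <- data.frame(intron_id = per$intron_id,
                    intron_class = per$intron_class,
                    gene_id = per$gene_id,
                    mean_cpm_a = rowMeans(ma), mean_cpm_b = rowMeans(mb),
                    log2fc = lfc, stringsAsFactors = FALSE)
  cls <- vapply(split(out$log2fc, out$intron_class), stats::median,
                numeric(1))
  attr(out, "class_summary") <- data.frame(
    intron_class = names(cls), median_log2fc = unname(cls),
    stringsAsFactors = FALSE)
  out
}

#' Differential intron retention screen
#'
#' Tests each intron for a change in normalized intron reads between two
#' conditions on the `log2(CPM + pc)` scale, controls the false discovery
#' rate across all tested introns of both classes jointly with
#' Benjamini-Hochberg, and rolls results up to genes (the minimum-q intron
#' represents its gene). With the default `method = "moderated"` the
#' per-intron variance is moderated across introns (limma's empirical-Bayes
#' linear model), which keeps the screen calibrated and powered at the small
#' replicate numbers typical of in-vivo designs; `method = "student"` is the
#' plain two-sided unpaired Student t test. Significance defaults to
#' q < 0.05 and |log2FC| >= log2(1.4).
#'
#' @param cond_a,cond_b lists of `sample_counts` (>= 2 replicates each for
#'   testing; with fewer, fold changes are returned with a warning and no
#'   p-values).
#' @param method `"moderated"` (default) or `"student"`.
#' @param pseudocount CPM pseudocount before log2 (default 0.5).
#' @param alpha q-value cutoff for the `significant` flag (default 0.05).
#' @param lfc_min absolute log2 fold-change cutoff (default `log2(1.4)`).
#' @return list of class `differential_retention`: `per_intron` (intron_id,
#'   class, gene_id, log2fc, p_value, q_value, direction, significant) and
#'   `per_gene` (minimum-q roll-up).
#' @export
differential_retention <- function(cond_a, cond_b,
                                   method = c("moderated", "student"),
                                   pseudocount = 0.5, alpha = 0.05,
                                   lfc_min = log2(1.4)) {
  method <- match.arg(method)
  la <- log2(cpm_matrix(cond_a) + pseudocount)
  lb <- log2(cpm_matrix(cond_b) + pseudocount)
  per <- cond_a[[1]]$per_intron
  lfc <- rowMeans(lb) - rowMeans(la)

  if (ncol(la) < 2L || ncol(lb) < 2L) {
    warning("fewer than 2 replicates in a condition: fold-change-only mode")
    p <- rep(NA_real_, length(lfc))
  } else if (method == "moderated") {
    x <- cbind(la, lb)
    design <- cbind(Intercept = 1,
                    group = rep(c(0, 1), c(ncol(la), ncol(lb))))
    fit <- limma::eBayes(limma::lmFit(x, design), trend = FALSE)
    p <- fit$p.value[, "group"]
    # zero variance everywhere and equal means: no evidence, p = 1
    p[is.na(p) & abs(lfc) < 1e-12] <- 1
  } else {
    n1 <- ncol(la); n2 <- ncol(lb)
    v1 <- matrixStats_rowVars(la)
    v2 <- matrixStats_rowVars(lb)
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    tstat <- lfc / se
    p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
    # degenerate: zero within-group variance in both groups
    p[se == 0 & abs(lfc) < 1e-12] <- 1    # equal means: p = 1 by convention
    p[se == 0 & abs(lfc) >= 1e-12] <- 0
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    intron_id = per$intron_id, intron_class = per$intron_class,
    gene_id = per$gene_id, log2fc = lfc, p_value = p, q_value = q,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
    significant = !is.na(q) & q < alpha & abs(lfc) >= lfc_min,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL

  gene <- do.call(rbind, lapply(split(out, out$gene_id), function(g) {
    g[which.min(replace(g$q_value, is.na(g$q_value), Inf)), , drop = FALSE]
  }))
  rownames(gene) <- NULL
  structure(list(per_intron = out, per_gene = gene,
                 method = method, alpha = alpha, lfc_min = lfc_min),
            class = "differential_retention")
}

# rowVars without adding a dependency
matrixStats_rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' @export
print.differential_retention <- function(x, ...) {
  cat("differential_retention (", x$method, "): ",
      nrow(x$per_intron), " introns tested, ",
      sum(x$per_intron$significant, na.rm = TRUE),
      " significant at q<", x$alpha, ", |log2FC|>=",
      round(x$lfc_min, 3), "\n", sep = "")
  invisible(x)
}
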