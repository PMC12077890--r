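# Independent brute-force oracles used to validate the package's
# implementations, plus small fixture builders. Oracles deliberately share
# no code with the functions they check.

# ---- interval counting oracle -------------------------------------------

# Random fragment set over a set of introns. Fragments are block lists
# (0-based half-open); ~15% carry a random internal gap and ~10% a gap
# exactly spanning a randomly chosen intron (a junction-spliced fragment).
random_fragments <- function(n_frag, introns, chrom_len, read_len = 50L) {
  blocks <- vector("list", n_frag)
  for (f in seq_len(n_frag)) {
    u <- runif(1)
    if (u < 0.10) {                      # exact junction over an intron
      i <- sample.int(nrow(introns), 1L)
      a <- sample(10:40, 1L)
      s <- introns$start[i] - a
      blocks[[f]] <- cbind(start = c(s, introns$end[i]),
                           end = c(introns$start[i],
                                   introns$end[i] + (read_len - a)))
    } else if (u < 0.25) {               # random internal gap
      s <- sample.int(chrom_len - 3L * read_len, 1L) - 1L
      gap <- sample(20:500, 1L)
      a <- sample(10:(read_len - 10L), 1L)
      blocks[[f]] <- cbind(start = c(s, s + a + gap),
                           end = c(s + a, s + gap + read_len))
    } else {                             # contiguous
      s <- sample.int(chrom_len - read_len, 1L) - 1L
      blocks[[f]] <- cbind(start = s, end = s + read_len)
    }
  }
  blocks
}

# Quadratic all-pairs overlap oracle mirroring the counting contract:
# a fragment counts toward an interval when its blocks overlap it by
# >= min_overlap bases in total; a fragment with a gap exactly spanning an
# intron is junction-spliced for that intron and never counts to its body.
# Every intron is checked against every block of every fragment with plain
# interval arithmetic (no interval-tree machinery).
oracle_count <- function(blocks, introns, min_overlap = 10L,
                         flank_width = 100L) {
  n_int <- nrow(introns)
  n_frag <- length(blocks)
  bfrag <- rep(seq_len(n_frag), vapply(blocks, nrow, 0L))
  bs <- unlist(lapply(blocks, function(b) b[, "start"]))
  be <- unlist(lapply(blocks, function(b) b[, "end"]))
  gfrag <- rep(seq_len(n_frag),
               pmax(vapply(blocks, nrow, 0L) - 1L, 0L))
  gs <- unlist(lapply(blocks, function(b)
    if (nrow(b) > 1L) b[-nrow(b), "end"] else numeric(0)))
  ge <- unlist(lapply(blocks, function(b)
    if (nrow(b) > 1L) b[-1L, "start"] else numeric(0)))

  # rowsum keyed by fragment id over all fragments (zero-filled)
  frag_sum <- function(ov) {
    out <- numeric(n_frag)
    t <- rowsum(ov, bfrag)
    out[as.integer(rownames(t))] <- t[, 1]
    out
  }
  ir <- fr <- js <- integer(n_int)
  for (i in seq_len(n_int)) {
    s <- introns$start[i]; e <- introns$end[i]
    ov_body <- frag_sum(pmax(0, pmin(be, e) - pmax(bs, s)))
    fls <- max(s - flank_width, 0L)
    ov_fl <- frag_sum(pmax(0, pmin(be, s) - pmax(bs, fls)) +
                        pmax(0, pmin(be, e + flank_width) - pmax(bs, e)))
    spliced <- unique(gfrag[gs == s & ge == e])
    js[i] <- length(spliced)
    body <- which(ov_body >= min_overlap)
    ir[i] <- length(setdiff(body, spliced))
    fr[i] <- sum(ov_fl >= min_overlap)
  }
  list(intron_reads = ir, flank_exon_reads = fr,
       junction_spliced_reads = js)
}

# SAM emission for arbitrary block fragments
write_blocks_sam <- function(blocks, chrom, chrom_len, path) {
  lines <- vapply(seq_along(blocks), function(f) {
    b <- blocks[[f]]
    widths <- b[, "end"] - b[, "start"]
    cig <- paste0(widths[1], "M")
    if (nrow(b) > 1L) {
      for (k in 2:nrow(b)) {
        cig <- paste0(cig, b[k, "start"] - b[k - 1L, "end"], "N",
                      widths[k], "M")
      }
    }
    sprintf("orafrag%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
            f, chrom, b[1, "start"] + 1L, cig,
            strrep("A", sum(widths)))
  }, "")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
               lines), path)
  path
}

# non-overlapping random introns on one chromosome
random_introns <- function(n_int, chrom_len, min_len = 200L,
                           max_len = 1500L, flank_width = 100L) {
  pitch <- max_len + 2L * flank_width + 300L
  stopifnot(n_int * pitch < chrom_len)
  start <- (seq_len(n_int) - 1L) * pitch + flank_width + 200L +
    sample.int(100L, n_int, replace = TRUE)
  len <- sample(min_len:max_len, n_int, replace = TRUE)
  data.frame(chrom = "chrO", start = start, end = start + len,
             strand = "+", gene_id = sprintf("g%04d", seq_len(n_int)),
             intron_class = sample(c("U12", "U2"), n_int, replace = TRUE))
}

catalog_from_introns <- function(introns) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# coordinates=0-based-half-open",
               paste(c("chrom", "start", "end", "strand", "gene_id",
                       "intron_class"), collapse = "\t"),
               sprintf("%s\t%d\t%d\t%s\t%s\t%s", introns$chrom,
                       introns$start, introns$end, introns$strand,
                       introns$gene_id, introns$intron_class)), path)
  load_intron_table(path)
}

# ---- translation oracle --------------------------------------------------

# Full-translation oracle for PTC scanning, via Biostrings (independent of
# the package's codon walk).
oracle_scan_ptc <- function(seq, intron_span) {
  n_codon <- nchar(seq) %/% 3
  if (n_codon == 0L) {
    return(list(has_ptc = FALSE, ptc_codon_index = NA_integer_))
  }
  trimmed <- substr(seq, 1L, n_codon * 3L)
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(trimmed), if.fuzzy.codon = "X")))
  stop_pos <- regexpr("*", aa, fixed = TRUE)
  if (stop_pos < 0) {
    return(list(has_ptc = FALSE, ptc_codon_index = NA_integer_,
                ptc_in_intron = NA, truncated = NA_integer_,
                frameshift = (intron_span[2] - intron_span[1]) %% 3 != 0))
  }
  idx <- as.integer(stop_pos)
  base0 <- (idx - 1L) * 3L
  list(has_ptc = TRUE, ptc_codon_index = idx,
       ptc_in_intron = base0 >= intron_span[1] && base0 < intron_span[2],
       truncated = idx - 1L,
       frameshift = (intron_span[2] - intron_span[1]) %% 3 != 0)
}

# random CDS without internal stop, random intron sequence
random_cds_intron <- function() {
  repeat {
    n_codon <- sample(5:40, 1L)
    body <- paste(sample(c("A", "C", "G", "T"), 3L * n_codon, TRUE),
                  collapse = "")
    cds <- paste0("ATG", body)
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    if (!any(head(codons, -1) %in% c("TAA", "TAG", "TGA"))) break
  }
  intron_len <- sample(4:60, 1L)   # any frame, frameshifts included
  intron <- paste(sample(c("A", "C", "G", "T"), intron_len, TRUE),
                  collapse = "")
  junctions <- seq(3, nchar(cds) - 3, by = 3)
  ip <- sample(junctions, 1L)
  list(cds = cds, intron = intron, insertion_point = ip)
}

# ---- isotope oracles -----------------------------------------------------

# per-carbon Bernoulli convolution: distribution of natural labels among m
# unlabeled carbons
oracle_bernoulli_convolution <- function(m, p) {
  d <- 1
  for (i in seq_len(m)) d <- convolve_step(d, p)
  d
}
convolve_step <- function(d, p) {
  out <- numeric(length(d) + 1L)
  out[seq_along(d)] <- d * (1 - p)
  out[seq_along(d) + 1L] <- out[seq_along(d) + 1L] + d * p
  out
}

# exhaustive grid-search oracle for the ISA fit
oracle_isa_grid <- function(obs, n_units, n_grid = 200L) {
  Dg <- seq(0, 1, length.out = n_grid)
  gg <- seq(0, 1, length.out = n_grid)
  k <- 0:n_units
  # model mass at even isotopologues for each D
  B <- vapply(Dg, function(D) dbinom(k, n_units, D),
              numeric(n_units + 1L))      # (n+1) x n_grid
  even_idx <- 2L * k + 1L
  obs_even <- obs[even_idx]
  obs_odd_ss <- sum(obs[-even_idx]^2)
  best <- c(Inf, NA, NA)
  for (gi in seq_along(gg)) {
    g <- gg[gi]
    mod <- g * B
    mod[1, ] <- mod[1, ] + (1 - g)
    ss <- colSums((mod - obs_even)^2) + obs_odd_ss
    j <- which.min(ss)
    if (ss[j] < best[1]) best <- c(ss[j], Dg[j], g)
  }
  list(ss = best[1], D = best[2], g = best[3])
}
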