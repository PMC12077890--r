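# Premature-termination-codon scanning of intron-retained transcripts.
# A retained intron inserted into a coding sequence can carry an in-frame
# stop codon (or shift the frame and create one downstream), truncating the
# protein — the mechanism by which minor intron retention inactivates
# Insig1/Insig2 and derepresses SREBP1c.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Transcript model for retention analysis
#'
#' @param transcript_id label.
#' @param spliced_cds coding sequence from the annotated start codon
#'   (must begin `ATG` and translate without an internal stop when spliced;
#'   a terminal stop codon is allowed).
#' @param exon_boundaries integer vector of CDS offsets at exon-exon
#'   junctions (0-based: an intron after CDS position `k` has boundary `k`).
#' @param insertion_point CDS offset where the retained intron sits; must be
#'   one of `exon_boundaries`.
#' @param intron_seq nucleotide sequence of the retained intron.
#' @return list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, spliced_cds, exon_boundaries,
                             insertion_point, intron_seq) {
  spliced_cds <- toupper(spliced_cds)
  intron_seq <- toupper(intron_seq)
  if (substr(spliced_cds, 1, 3) != "ATG") {
    stop("spliced CDS must start with ATG")
  }
  codons <- substring(spliced_cds, seq(1, nchar(spliced_cds) - 2, 3),
                      seq(3, nchar(spliced_cds), 3))
  internal <- utils::head(codons, -1)
  if (any(internal %in% STOP_CODONS)) {
    stop("spliced CDS contains an internal stop codon")
  }
  structure(list(transcript_id = transcript_id, spliced_cds = spliced_cds,
                 exon_boundaries = as.integer(exon_boundaries),
                 insertion_point = as.integer(insertion_point),
                 intron_seq = intron_seq),
            class = "transcript_model")
}

#' Build the intron-retained transcript sequence
#'
#' Inserts the retained intron into the spliced CDS at its exon-exon
#' junction. Insertion anywhere other than an annotated junction is a hard
#' error: retained introns sit between exons by construction.
#'
#' @param model a [transcript_model()].
#' @return the retained nucleotide sequence (character scalar), with
#'   attribute `intron_span` = 0-based half-open interval of the intron
#'   within it.
#' @export
build_retained_transcript <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  ip <- model$insertion_point
  if (!ip %in% model$exon_boundaries) {
    stop("insertion_point ", ip, " is not an exon-exon junction")
  }
  seq <- paste0(substr(model$spliced_cds, 1, ip), model$intron_seq,
                substr(model$spliced_cds, ip + 1, nchar(model$spliced_cds)))
  attr(seq, "intron_span") <- c(ip, ip + nchar(model$intron_seq))
  seq
}

#' Scan a retained transcript for a premature termination codon
#'
#' Translates codon-by-codon from the annotated start codon (position 0 of
#' `retained_seq`) with the standard genetic code; the first `TAA`/`TAG`/
#' `TGA` encountered is the termination codon. Scanning starts at the start
#' codon, not at the intron, because a frame-shifting intron (length not a
#' multiple of 3) can create its stop downstream of the intron itself; the
#' biological readout is the truncated protein. Ambiguity codes translate as
#' `X` and are never a stop.
#'
#' @param retained_seq nucleotide sequence beginning at the start codon.
#' @param intron_span 0-based half-open `c(start, end)` of the retained
#'   intron within `retained_seq` (taken from the attribute left by
#'   [build_retained_transcript()] when omitted).
#' @return list of class `ptc_result`: `has_ptc`, `ptc_codon_index` (1-based
#'   codon ordinal from the start codon), `ptc_in_intron` (first base of the
#'   stop lies inside the intron), `truncated_protein_length` (amino acids),
#'   `frameshifted_downstream` (intron length not a multiple of 3).
#' @export
scan_ptc <- function(retained_seq, intron_span = attr(retained_seq,
                                                      "intron_span")) {
  seq <- toupper(as.character(retained_seq))
  if (nchar(seq) == 0L) stop("empty sequence")
  if (is.null(intron_span) || length(intron_span) != 2L) {
    stop("intron_span must be c(start, end), 0-based half-open")
  }
  n_codon <- nchar(seq) %/% 3
  has_ptc <- FALSE
  idx <- NA_integer_
  if (n_codon > 0L) {
    starts <- seq.int(1L, by = 3L, length.out = n_codon)
    codons <- substring(seq, starts, starts + 2L)
    codons[grepl("[^ACGT]", codons)] <- "XXX"   # ambiguity: never a stop
    hit <- which(codons %in% STOP_CODONS)
    if (length(hit) > 0L) {
      has_ptc <- TRUE
      idx <- hit[1]
    }
  }
  intron_len <- intron_span[2] - intron_span[1]
  structure(list(
    has_ptc = has_ptc,
    ptc_codon_index = idx,
    ptc_in_intron = if (has_ptc)
      (idx - 1L) * 3L >= intron_span[1] && (idx - 1L) * 3L < intron_span[2]
      else NA,
    truncated_protein_length = if (has_ptc) idx - 1L else NA_integer_,
    frameshifted_downstream = intron_len %% 3L != 0L),
    class = "ptc_result")
}

#' @export
print.ptc_result <- function(x, ...) {
  if (x$has_ptc) {
    cat("PTC at codon", x$ptc_codon_index,
        if (isTRUE(x$ptc_in_intron)) "(inside retained intron)" else
          "(downstream of intron)",
        "- truncated protein:", x$truncated_protein_length, "aa\n")
  } else cat("no premature termination codon\n")
  if (x$frameshifted_downstream) cat("downstream frame shifted\n")
  invisible(x)
}

#' PTC scan over a set of transcript models
#'
#' @param models list of [transcript_model()] objects.
#' @return data frame: transcript, has_ptc, ptc_codon_index, ptc_in_intron,
#'   truncated_len, frameshift.
#' @export
scan_ptc_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    seq <- build_retained_transcript(m)
    r <- scan_ptc(seq)
    data.frame(transcript = m$transcript_id, has_ptc = r$has_ptc,
               ptc_codon_index = r$ptc_codon_index,
               ptc_in_intron = r$ptc_in_intron,
               truncated_len = r$truncated_protein_length,
               frameshift = r$frameshifted_downstream,
               stringsAsFactors = FALSE)
  }))
}
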