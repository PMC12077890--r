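# Synthetic-data generators with known ground truth: intron catalogs and
# per-sample counts with planted class-specific retention, optional SAM
# emission for end-to-end alignment-counting tests, and tracing MIDs from
# the one-turn glutamine labeling model.

#' Retention simulation configuration
#'
#' Default scenarios plant the observed class-level retention frequencies of
#' the motivating study as ground-truth parameters (explicit parameter
#' reuse, not result reproduction): `"zlko"` — minor-spliceosome knockout
#' liver, U12 retention probability 0.56 vs U2 0.003; `"mash"` — diet-induced
#' steatohepatitis, U12 0.46 vs U2 0.035. Control-arm baselines (not printed
#' in the study) default to U12 0.05 and the same U2 background. The intron
#' census matches the annotated genome: 657 minor vs 211,005 major introns.
#'
#' @param scenario `"zlko"`, `"mash"`, or `"custom"` (then supply
#'   `retention_prob`).
#' @param n_u12,n_u2 introns per class.
#' @param retention_prob named list `list(U12 = c(<cond1> = p, <cond2> = p),
#'   U2 = ...)`; condition names define the design.
#' @param theta_retained,theta_background RI level planted for retained /
#'   non-retained introns (defaults 0.3 / 0.005).
#' @param exon_depth mean flanking-exon fragment count per intron per
#'   sample (default 50).
#' @param n_replicates per condition (default 4, the study's RNA-seq arm
#'   size).
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2; default 0.1, typical bulk RNA-seq).
#' @param intron_length,flank_width interval geometry in nt.
#' @param shared_truth draw each intron's retained status once and share it
#'   across conditions (a global-null design for calibration studies).
#' @param fold_change,n_affected multiply intron-read means of the first
#'   `n_affected` U12 introns by `fold_change` in the second condition
#'   (power studies); `NULL`/0 disables.
#' @param seed RNG seed.
#' @return list of class `retention_sim_config`.
#' @export
retention_sim_config <- function(scenario = c("zlko", "mash", "custom"),
                                 n_u12 = 657L, n_u2 = 211005L,
                                 retention_prob = NULL,
                                 theta_retained = 0.3,
                                 theta_background = 0.005,
                                 exon_depth = 50, n_replicates = 4L,
                                 dispersion = 0.1,
                                 intron_length = 1000L, flank_width = 100L,
                                 shared_truth = FALSE,
                                 fold_change = NULL, n_affected = 0L,
                                 seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(retention_prob)) {
    retention_prob <- switch(scenario,
      zlko = list(U12 = c(CTR = 0.05, KO = 0.56),
                  U2 = c(CTR = 0.003, KO = 0.003)),
      mash = list(U12 = c(chow = 0.05, MASH = 0.46),
                  U2 = c(chow = 0.035, MASH = 0.035)),
      custom = stop("scenario 'custom' requires retention_prob"))
  }
  stopifnot(all(unlist(retention_prob) >= 0),
            all(unlist(retention_prob) <= 1),
            exon_depth > 0, theta_retained > 0, theta_background >= 0,
            identical(names(retention_prob[["U12"]]),
                      names(retention_prob[["U2"]])))
  structure(list(scenario = scenario, n_u12 = as.integer(n_u12),
                 n_u2 = as.integer(n_u2), retention_prob = retention_prob,
                 theta_retained = theta_retained,
                 theta_background = theta_background,
                 exon_depth = exon_depth,
                 n_replicates = as.integer(n_replicates),
                 dispersion = dispersion,
                 intron_length = as.integer(intron_length),
                 flank_width = as.integer(flank_width),
                 shared_truth = isTRUE(shared_truth),
                 fold_change = fold_change,
                 n_affected = as.integer(n_affected),
                 seed = as.integer(seed)),
            class = "retention_sim_config")
}

sim_catalog <- function(config) {
  n <- config$n_u12 + config$n_u2
  cls <- c(rep("U12", config$n_u12), rep("U2", config$n_u2))
  pitch <- config$intron_length + 2L * config$flank_width + 200L
  start <- (seq_len(n) - 1L) * pitch + config$flank_width + 100L
  rec <- data.frame(
    chrom = "chrS", start = start, end = start + config$intron_length,
    strand = "+",
    gene_id = sprintf("gene%06d", seq_len(n)),
    transcript_id = sprintf("tx%06d", seq_len(n)),
    intron_index = 1L,
    donor_dinuc = ifelse(cls == "U12", "AT", "GT"),
    acceptor_dinuc = ifelse(cls == "U12", "AC", "AG"),
    intron_class = cls, stringsAsFactors = FALSE)
  new_intron_catalog(rec)
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(as.integer(stats::rpois(n, mu)))
  as.integer(stats::rnbinom(n, size = 1 / dispersion, mu = mu))
}

#' Simulate a retention dataset with planted truth
#'
#' Each intron is independently assigned retained/not per condition with the
#' configured class probability; intron fragment counts are drawn
#' negative-binomially around `theta * exon_depth * intron_length /
#' flank_length` (so the expected retention index is `theta`), flanking-exon
#' counts around `exon_depth`. The truth table records every assignment, so
#' downstream estimators can be scored without re-simulation.
#'
#' @param config a [retention_sim_config()].
#' @return list: `catalog` (an `intron_catalog`), `samples` (list of
#'   `sample_counts`, `n_replicates` per condition), `truth` (data frame:
#'   intron_id, intron_class, condition, retained, theta, affected).
#' @export
simulate_retention_dataset <- function(config) {
  stopifnot(inherits(config, "retention_sim_config"))
  set.seed(config$seed)
  catalog <- sim_catalog(config)
  rec <- catalog$records
  n <- nrow(rec)
  conds <- names(config$retention_prob[["U12"]])
  flank_len <- 2 * config$flank_width
  len_ratio <- config$intron_length / flank_len

  shared <- NULL
  truth <- list(); samples <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    p <- ifelse(rec$intron_class == "U12",
                config$retention_prob[["U12"]][[cond]],
                config$retention_prob[["U2"]][[cond]])
    if (config$shared_truth) {
      if (is.null(shared)) shared <- stats::runif(n) < p
      retained <- shared
    } else {
      retained <- stats::runif(n) < p
    }
    theta <- ifelse(retained, config$theta_retained,
                    config$theta_background)
    mu_intron <- theta * config$exon_depth * len_ratio
    affected <- rep(FALSE, n)
    if (!is.null(config$fold_change) && config$n_affected > 0L &&
        ci == 2L) {
      u12_idx <- which(rec$intron_class == "U12")
      affected[u12_idx[seq_len(min(config$n_affected, length(u12_idx)))]] <-
        TRUE
      mu_intron[affected] <- mu_intron[affected] * config$fold_change
    }
    truth[[cond]] <- data.frame(
      intron_id = rec$intron_id, intron_class = rec$intron_class,
      condition = cond, retained = retained, theta = theta,
      affected = affected, stringsAsFactors = FALSE)
    for (r in seq_len(config$n_replicates)) {
      ir <- rnbinom_mu(n, mu_intron, config$dispersion)
      fr <- rnbinom_mu(n, config$exon_depth, config$dispersion)
      js <- rnbinom_mu(n, config$exon_depth * 0.3, config$dispersion)
      per <- data.frame(
        intron_id = rec$intron_id, intron_class = rec$intron_class,
        gene_id = rec$gene_id, intron_reads = ir,
        intron_length = config$intron_length,
        flank_exon_reads = fr, flank_exon_length = flank_len,
        junction_spliced_reads = js, stringsAsFactors = FALSE)
      samples[[paste0(cond, "_rep", r)]] <- new_sample_counts(
        paste0(cond, "_rep", r), cond, sum(ir) + sum(fr) + sum(js), per)
    }
  }
  list(catalog = catalog, samples = samples,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Emit a sample's counts as SAM fragments
#'
#' Writes one single-end SAM record per counted fragment: intron-body reads
#' fully inside the intron, flanking-exon reads fully inside one flank
#' window, and junction-spliced reads with an `N` CIGAR gap exactly spanning
#' the intron (25 nt anchors each side). Counting the resulting alignments
#' with [count_intron_reads()] reproduces the input counts (junction
#' fragments additionally register in the flanking windows their anchors
#' occupy).
#'
#' @param sample a `sample_counts` object.
#' @param catalog the matching `intron_catalog`.
#' @param path output `.sam` path.
#' @param read_len read length (default 50; must fit inside intron and
#'   flank windows).
#' @param flank_width geometry used for flank placement (default 100).
#' @param seed placement RNG seed.
#' @return `path`, invisibly.
#' @export
write_sample_sam <- function(sample, catalog, path, read_len = 50L,
                             flank_width = 100L, seed = 1L) {
  set.seed(seed)
  rec <- catalog$records
  stopifnot(identical(rec$intron_id, sample$per_intron$intron_id))
  per <- sample$per_intron
  chrom_len <- vapply(split(rec$end + flank_width + read_len + 10L,
                            rec$chrom), function(x) as.integer(max(x)),
                      integer(1))

  recs <- character(0)
  qn <- 0L
  emit <- function(chrom, pos0, cigar) {
    qn <<- qn + 1L
    sprintf("frag%07d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
            qn, chrom, pos0 + 1L, cigar,
            strrep("A", read_len))
  }
  out <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    chrom <- rec$chrom[i]; s <- rec$start[i]; e <- rec$end[i]
    body <- per$intron_reads[i]; fl <- per$flank_exon_reads[i]
    jn <- per$junction_spliced_reads[i]
    lines <- character(body + fl + jn)
    k <- 0L
    if (body > 0L) {
      pos <- s + sample.int(e - s - read_len + 1L, body, replace = TRUE) - 1L
      for (p in pos) { k <- k + 1L; lines[k] <- emit(chrom, p,
                                                    paste0(read_len, "M")) }
    }
    if (fl > 0L) {
      side <- stats::runif(fl) < 0.5
      off <- sample.int(flank_width - read_len + 1L, fl, replace = TRUE) - 1L
      pos <- ifelse(side, s - flank_width + off, e + off)
      for (p in pos) { k <- k + 1L; lines[k] <- emit(chrom, p,
                                                    paste0(read_len, "M")) }
    }
    if (jn > 0L) {
      anchor <- read_len %/% 2L
      cigar <- sprintf("%dM%dN%dM", anchor, e - s, read_len - anchor)
      for (j in seq_len(jn)) { k <- k + 1L
        lines[k] <- emit(chrom, s - anchor, cigar) }
    }
    out[[i]] <- lines
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ch in names(chrom_len)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, chrom_len[[ch]]), con)
  }
  writeLines(unlist(out), con)
  invisible(path)
}

#' Tracing simulation configuration
#'
#' One-turn [U-13C]glutamine labeling model. `f_red` is the reductive
#' fraction of glutamine-derived citrate synthesis; `e_akg` the
#' alpha-ketoglutarate M+5 enrichment; `c_g` the share of the citrate pool
#' carrying glutamine carbon; `D`/`g` the ISA parameters of the lipogenic
#' acetyl-CoA pool and fatty-acid turnover.
#'
#' @param f_red reductive fraction in \[0, 1\] (default 0.3).
#' @param e_akg alpha-KG M+5 enrichment (default 0.8).
#' @param c_g glutamine carbon share of citrate (default 0.8).
#' @param D lipogenic acetyl-CoA labeled fraction (default 0.2).
#' @param g fraction of fatty-acid pool newly synthesized (default 0.3).
#' @param p_13C natural 13C abundance (default 0.0107).
#' @param noise_cv multiplicative measurement noise CV (default 0.005).
#' @param n_replicates replicates (default 3, the study's tracing arm).
#' @param seed RNG seed.
#' @return list of class `tracing_sim_config`.
#' @export
tracing_sim_config <- function(f_red = 0.3, e_akg = 0.8, c_g = 0.8,
                               D = 0.2, g = 0.3, p_13C = 0.0107,
                               noise_cv = 0.005, n_replicates = 3L,
                               seed = 1L) {
  vals <- c(f_red = f_red, e_akg = e_akg, c_g = c_g, D = D, g = g)
  stopifnot(all(vals >= 0), all(vals <= 1), noise_cv >= 0,
            p_13C >= 0, p_13C < 0.5)
  structure(list(f_red = f_red, e_akg = e_akg, c_g = c_g, D = D, g = g,
                 p_13C = p_13C, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "tracing_sim_config")
}

#' True (pre-noise) MIDs of the one-turn glutamine model
#'
#' Citrate: M+5 from reductive carboxylation (`c_g * f_red * e`), M+4 from
#' the oxidative route with unlabeled acetyl-CoA
#' (`c_g * (1 - f_red) * e * (1 - D)`), M+6 oxidative with labeled
#' acetyl-CoA (`c_g * (1 - f_red) * e * D`), remainder M+0. Fumarate and
#' malate: M+4 = `e * (1 - f_red) * c_g`, remainder M+0. Fatty acids from
#' the ISA model at `(D, g)`.
#'
#' @param config a [tracing_sim_config()].
#' @return named list of numeric fraction vectors.
#' @export
tracing_true_mids <- function(config) {
  with(config, {
    cit <- numeric(7)
    cit[6] <- c_g * f_red * e_akg                  # M+5
    cit[5] <- c_g * (1 - f_red) * e_akg * (1 - D)  # M+4
    cit[7] <- c_g * (1 - f_red) * e_akg * D        # M+6
    cit[1] <- 1 - sum(cit)
    fum <- numeric(5)
    fum[5] <- e_akg * (1 - f_red) * c_g
    fum[1] <- 1 - sum(fum)
    if (cit[1] < -1e-12 || fum[1] < -1e-12) {
      stop("inconsistent fractions: negative M+0 remainder")
    }
    cit[1] <- max(cit[1], 0); fum[1] <- max(fum[1], 0)
    list(citrate = cit, fumarate = fum, malate = fum,
         palmitate = isa_model_mid(D, g, 8L),
         oleate = isa_model_mid(D, g, 9L))
  })
}

#' Simulate raw tracing MIDs with natural abundance and noise
#'
#' Applies the natural-abundance forward map to the true one-turn MIDs,
#' adds multiplicative Gaussian noise (`CV = noise_cv`), clamps at zero and
#' renormalizes — yielding raw MIDs as a mass spectrometer would report
#' them (before correction).
#'
#' @param config a [tracing_sim_config()].
#' @return list: `mids` (list of raw `mid_vector`s, one per metabolite per
#'   replicate, with `sample` attributes), `truth` (one-row data frame of
#'   the generating parameters, with `d_identifiable`).
#' @export
simulate_tracing_mids <- function(config) {
  stopifnot(inherits(config, "tracing_sim_config"))
  set.seed(config$seed)
  true <- tracing_true_mids(config)
  mids <- list()
  for (r in seq_len(config$n_replicates)) {
    for (met in names(true)) {
      x <- true[[met]]
      n <- length(x) - 1L
      contaminated <- as.numeric(
        natural_abundance_matrix(n, config$p_13C) %*% x)
      noisy <- contaminated * (1 + stats::rnorm(n + 1L, 0,
                                                config$noise_cv))
      noisy <- pmax(noisy, 0)
      m <- mid_vector(met, noisy)
      attr(m, "sample") <- paste0("rep", r)
      attr(m, "condition") <- "sim"
      mids[[paste0("rep", r, ".", met)]] <- m
    }
  }
  truth <- data.frame(f_red = config$f_red, e_akg = config$e_akg,
                      c_g = config$c_g, D = config$D, g = config$g,
                      d_identifiable = config$g >= 0.01 && config$D > 0,
                      stringsAsFactors = FALSE)
  list(mids = mids, truth = truth)
}
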