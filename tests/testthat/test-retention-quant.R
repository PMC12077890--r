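# helpers to build in-memory samples without touching alignments
mk_sample <- function(id, cond, intron_reads, flank_reads,
                      intron_len = 1000L, flank_len = 200L,
                      lib = NULL, classes = NULL, genes = NULL) {
  n <- length(intron_reads)
  per <- data.frame(
    intron_id = sprintf("chrT:%d-%d:+", seq_len(n) * 10000L,
                        seq_len(n) * 10000L + intron_len),
    intron_class = classes %||% rep("U12", n),
    gene_id = genes %||% sprintf("g%03d", seq_len(n)),
    intron_reads = intron_reads, intron_length = intron_len,
    flank_exon_reads = flank_reads, flank_exon_length = flank_len,
    junction_spliced_reads = 0L, stringsAsFactors = FALSE)
  minorflux:::new_sample_counts(id, cond,
    lib %||% sum(intron_reads + flank_reads), per)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("retention index is the intron-to-flank density ratio", {
  # intron 5 reads/kb vs flank 50 reads/kb -> RI = 0.1
  s <- mk_sample("a", "x", intron_reads = 5L, flank_reads = 10L,
                 intron_len = 1000L, flank_len = 200L)
  expect_equal(retention_index(s), 0.1)
  # zero flank coverage: undefined, excluded from calling
  s0 <- mk_sample("a", "x", intron_reads = 5L, flank_reads = 0L)
  expect_true(is.na(retention_index(s0)))
  expect_true(is.na(call_retained(retention_index(s0), 5L)))
})

test_that("retained calls require both the RI and the reads gate", {
  expect_true(call_retained(0.5, 100L))
  expect_false(call_retained(0.5, 3L))
  expect_false(call_retained(0.05, 100L))
  expect_identical(call_retained(c(0.5, NA), c(100L, 100L)),
                   c(TRUE, NA))
})

test_that("class summary computes percent retained per class/condition", {
  # 100 U12 introns, 56 retained at high RI -> 56%
  ir <- c(rep(75L, 56), rep(1L, 44))
  reps <- lapply(1:2, function(r)
    mk_sample(paste0("s", r), "KO", ir, rep(50L, 100)))
  s <- class_retention_summary(reps)
  expect_equal(s$percent_retained[s$intron_class == "U12"], 56)
  # none retained -> 0%
  reps0 <- lapply(1:2, function(r)
    mk_sample(paste0("s", r), "KO", rep(0L, 10), rep(50L, 10)))
  s0 <- class_retention_summary(reps0)
  expect_equal(s0$percent_retained, 0)
})

test_that("percent retained is invariant to uniform depth scaling", {
  set.seed(11)
  ir <- c(rpois(30, 75), rpois(70, 1))
  fl <- rpois(100, 50)
  base <- lapply(1:3, function(r) mk_sample(paste0("s", r), "KO", ir, fl))
  scaled <- lapply(1:3, function(r)
    mk_sample(paste0("s", r), "KO", ir * 7L, fl * 7L))
  expect_equal(class_retention_summary(base)$percent_retained,
               class_retention_summary(scaled)$percent_retained)
})

test_that("fold change of normalized intron reads behaves arithmetically", {
  a <- list(mk_sample("a1", "A", c(10L, 50L), c(50L, 50L), lib = 1e6))
  b <- list(mk_sample("b1", "B", c(40L, 50L), c(50L, 50L), lib = 1e6))
  fc <- intron_read_foldchange(a, b, pseudocount = 0)
  expect_equal(fc$log2fc, c(2, 0))   # 10 vs 40 CPM -> log2FC 2
  fc2 <- intron_read_foldchange(a, a, pseudocount = 0.5)
  expect_equal(fc2$log2fc, c(0, 0))  # identical tables -> identity
})

test_that("doubling only U12 intron reads shifts only the U12 log2FC", {
  set.seed(21)
  n <- 400
  classes <- rep(c("U12", "U2"), each = n / 2)
  ir <- rpois(n, 60)
  a <- lapply(1:3, function(r) mk_sample(paste0("a", r), "A",
    rpois(n, ir), rpois(n, 50), classes = classes, lib = 1e6))
  b <- lapply(1:3, function(r) mk_sample(paste0("b", r), "B",
    rpois(n, ifelse(classes == "U12", 2 * ir, ir)), rpois(n, 50),
    classes = classes, lib = 1e6))
  fc <- intron_read_foldchange(a, b)
  med <- attr(fc, "class_summary")
  expect_equal(med$median_log2fc[med$intron_class == "U12"], 1,
               tolerance = 0.1)
  expect_equal(med$median_log2fc[med$intron_class == "U2"], 0,
               tolerance = 0.1)
})

test_that("identical conditions give log2FC 0 and p = 1 throughout", {
  set.seed(31)
  mk <- function(id) mk_sample(id, "X", rpois(50, 40), rpois(50, 50))
  a <- list(mk("r1"), mk("r2"), mk("r3"))
  b <- lapply(a, function(s) { s$sample_id <- paste0(s$sample_id, "b"); s })
  for (m in c("moderated", "student")) {
    dr <- differential_retention(a, b, method = m)
    expect_equal(dr$per_intron$log2fc, rep(0, 50))
    expect_equal(dr$per_intron$p_value, rep(1, 50))
  }
})

test_that("degenerate zero-variance equal-mean introns get p = 1", {
  a <- lapply(1:2, function(r) mk_sample(paste0("a", r), "A",
    rep(20L, 5), rep(50L, 5)))
  b <- lapply(1:2, function(r) mk_sample(paste0("b", r), "B",
    rep(20L, 5), rep(50L, 5)))
  dr <- differential_retention(a, b, method = "student")
  expect_equal(dr$per_intron$p_value, rep(1, 5))
})

test_that("fewer than two replicates falls back to fold-change-only", {
  a <- list(mk_sample("a1", "A", rpois(10, 40), rpois(10, 50)))
  b <- list(mk_sample("b1", "B", rpois(10, 40), rpois(10, 50)))
  expect_warning(dr <- differential_retention(a, b), "fold-change-only")
  expect_true(all(is.na(dr$per_intron$p_value)))
  expect_true(all(is.finite(dr$per_intron$log2fc)))
})

test_that("q-values dominate p-values and are monotone in p rank", {
  set.seed(41)
  sim <- simulate_retention_dataset(retention_sim_config(
    scenario = "custom", n_u12 = 300, n_u2 = 0,
    retention_prob = list(U12 = c(A = 1, B = 1), U2 = c(A = 0, B = 0)),
    shared_truth = TRUE, seed = 41))
  a <- Filter(function(s) s$condition == "A", sim$samples)
  b <- Filter(function(s) s$condition == "B", sim$samples)
  dr <- differential_retention(a, b)
  tab <- dr$per_intron[order(dr$per_intron$p_value), ]
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
  expect_true(all(diff(tab$q_value) >= -1e-12))
})

test_that("gene roll-up keeps the minimum-q intron per gene", {
  set.seed(51)
  genes <- rep(c("gA", "gB"), each = 5)
  a <- lapply(1:3, function(r) mk_sample(paste0("a", r), "A",
    rpois(10, 40), rpois(10, 50), genes = genes))
  b <- lapply(1:3, function(r) mk_sample(paste0("b", r), "B",
    rpois(10, 40), rpois(10, 50), genes = genes))
  dr <- differential_retention(a, b)
  expect_equal(nrow(dr$per_gene), 2L)
  for (g in c("gA", "gB")) {
    expect_equal(dr$per_gene$q_value[dr$per_gene$gene_id == g],
                 min(dr$per_intron$q_value[dr$per_intron$gene_id == g]))
  }
})

test_that("counting matches the definition on hand-placed alignments", {
  introns <- data.frame(chrom = "chrO", start = 1000L, end = 2000L,
                        strand = "+", gene_id = "g1", intron_class = "U12")
  cat1 <- catalog_from_introns(introns)
  blocks <- list(
    cbind(start = 1200L, end = 1250L),            # inside intron body
    cbind(start = c(975L, 2000L), end = c(1000L, 2025L)),  # exact junction
    cbind(start = 920L, end = 970L),              # left flank window
    cbind(start = 1990L, end = 2040L))            # 10 in intron, 40 in flank
  sam <- tempfile(fileext = ".sam")
  write_blocks_sam(blocks, "chrO", 5000L, sam)
  sc <- count_intron_reads(sam, cat1, sample_id = "t")
  expect_equal(sc$per_intron$intron_reads, 2L)            # body + boundary
  expect_equal(sc$per_intron$junction_spliced_reads, 1L)
  expect_equal(sc$per_intron$flank_exon_reads, 3L)  # flank, junction, boundary
  expect_equal(sc$library_size, 4L)
})

test_that("counting equals the brute-force overlap oracle", {
  set.seed(61)
  for (rep in 1:4) {
    n_int <- sample(20:40, 1)
    introns <- random_introns(n_int, chrom_len = 200000L)
    blocks <- random_fragments(500L, introns, chrom_len = 150000L)
    sam <- tempfile(fileext = ".sam")
    write_blocks_sam(blocks, "chrO", 250000L, sam)
    cat1 <- catalog_from_introns(introns)
    sc <- count_intron_reads(sam, cat1)
    ora <- oracle_count(blocks, introns)
    expect_identical(sc$per_intron$intron_reads, ora$intron_reads)
    expect_identical(sc$per_intron$flank_exon_reads, ora$flank_exon_reads)
    expect_identical(sc$per_intron$junction_spliced_reads,
                     ora$junction_spliced_reads)
  }
})

test_that("an unindexed BAM is a hard error", {
  introns <- data.frame(chrom = "chrO", start = 1000L, end = 2000L,
                        strand = "+", gene_id = "g1", intron_class = "U2")
  cat1 <- catalog_from_introns(introns)
  sam <- tempfile(fileext = ".sam")
  write_blocks_sam(list(cbind(start = 1200L, end = 1250L)), "chrO",
                   5000L, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE)
  expect_error(count_intron_reads(bam, cat1), "index")
})

test_that("introns on chromosomes missing from the BAM get zero counts", {
  introns <- data.frame(chrom = c("chrO", "chrMiss"),
                        start = c(1000L, 1000L), end = c(2000L, 2000L),
                        strand = "+", gene_id = c("g1", "g2"),
                        intron_class = "U2")
  cat1 <- catalog_from_introns(introns)
  sam <- tempfile(fileext = ".sam")
  write_blocks_sam(list(cbind(start = 1200L, end = 1250L)), "chrO",
                   5000L, sam)
  expect_warning(sc <- count_intron_reads(sam, cat1), "chrMiss")
  expect_equal(sc$per_intron$intron_reads[2], 0L)
})

test_that("precomputed counts TSV loads into per-sample objects", {
  introns <- data.frame(chrom = "chrO", start = c(1000L, 5000L),
                        end = c(2000L, 5600L), strand = "+",
                        gene_id = c("g1", "g2"),
                        intron_class = c("U12", "U2"))
  cat1 <- catalog_from_introns(introns)
  path <- tempfile(fileext = ".tsv")
  ids <- cat1$records$intron_id
  writeLines(c("sample\tcondition\tintron_id\tintron_reads\tflank_exon_reads\tjunction_spliced_reads",
               sprintf("s1\tA\t%s\t30\t50\t10", ids[1]),
               sprintf("s1\tA\t%s\t2\t60\t40", ids[2]),
               sprintf("s2\tB\t%s\t35\t45\t12", ids[1]),
               sprintf("s2\tB\t%s\t1\t55\t42", ids[2])), path)
  samples <- read_counts_tsv(path, cat1)
  expect_equal(length(samples), 2L)
  expect_equal(samples[["s1"]]$per_intron$intron_reads, c(30L, 2L))
  expect_equal(samples[["s1"]]$per_intron$intron_length, c(1000L, 600L))
  expect_equal(samples[["s2"]]$condition, "B")
})
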