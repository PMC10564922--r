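test_that("caller intersection keeps shared junctions with max read support", {
  a <- make_calls(c("chr1", "chr1", "chr2"), c(100L, 500L, 900L),
                  c(200L, 700L, 1200L), reads = c(5L, 3L, 8L),
                  caller = "find_circ")
  b <- a; b$caller <- "circexplorer2"; b$junction_reads <- c(2L, 9L, 1L)
  cons <- intersect_callers(a, b)
  expect_equal(nrow(cons$features), 3)
  expect_equal(unname(cons$counts[, "S1"]), c(5L, 9L, 8L))

  # disjoint call sets yield an empty consensus
  b2 <- b; b2$start <- b2$start + 10L; b2$end <- b2$end + 10L
  expect_equal(nrow(intersect_callers(a, b2)$features), 0)
  # ... unless the tolerance covers the wobble
  cons_tol <- intersect_callers(a, b2, tolerance = 10L)
  expect_equal(nrow(cons_tol$features), 3)
  # canonical coordinates are the elementwise minimum, keeping the operation
  # symmetric
  expect_equal(cons_tol$features$start, a$start)
  swapped <- intersect_callers(b2, a, tolerance = 10L)
  expect_identical(cons_tol$features, swapped$features)
})

test_that("consensus matches a brute-force set intersection on simulated callers", {
  b <- simulate_study(small_config(seed = 21))
  cons <- intersect_callers(b$calls$find_circ, b$calls$circexplorer2)
  # oracle: plain set intersection of the junction keys each caller reports
  key <- function(calls) unique(paste(calls$chrom, calls$start, calls$end,
                                      sep = "_"))
  oracle <- intersect(key(b$calls$find_circ), key(b$calls$circexplorer2))
  expect_setequal(cons$features$circ_id, oracle)
  expect_setequal(cons$features$circ_id, b$ground_truth$caller_overlap)
  # consensus counts equal the true counts (both callers reported them)
  expect_equal(cons$counts[cons$features$circ_id, b$samples],
               b$counts$circrna$values[cons$features$circ_id, b$samples])
})

test_that("consensus intersection is symmetric at every tolerance", {
  set.seed(14)
  for (tol in c(0L, 1L, 2L)) {
    n <- 30
    starts <- sort(sample(seq(1000, 1e6, by = 50), n))
    a <- make_calls(rep("chr3", n), starts, starts + 500L,
                    reads = sample(2:20, n, TRUE))
    # caller B reports a subset, wobbled by up to 2 bp
    sel <- sort(sample(n, 18))
    b <- a[sel, ]
    b$start <- b$start + sample(-2:2, 18, TRUE)
    b$end <- b$end + sample(-2:2, 18, TRUE)
    ab <- intersect_callers(a, b, tolerance = tol)
    ba <- intersect_callers(b, a, tolerance = tol)
    expect_identical(ab$features, ba$features, label = paste("tolerance", tol))
  }
})

test_that("support filtering applies a strict majority rule and is monotone", {
  counts <- rbind(
    ten = c(rep(2L, 10), rep(0L, 8)),   # >= 2 reads in 10 of 18 samples
    nine = c(rep(2L, 9), rep(0L, 9)),   # exactly half: removed
    zero = rep(0L, 18)
  )
  colnames(counts) <- sprintf("s%02d", 1:18)
  feats <- data.frame(circ_id = rownames(counts), chrom = "chr1",
                      start = 1:3, end = 11:13, strand = "+",
                      stringsAsFactors = FALSE)
  cs <- circ_set(feats, counts)
  kept <- filter_by_support(cs, consensus_config(min_reads = 2))
  expect_equal(kept$features$circ_id, "ten")

  # monotonicity: raising min_reads never grows the retained set
  set.seed(2)
  m <- matrix(rnbinom(40 * 18, mu = 3, size = 2), 40, 18,
              dimnames = list(sprintf("c%02d", 1:40), sprintf("s%02d", 1:18)))
  cs2 <- circ_set(data.frame(circ_id = rownames(m), chrom = "chr1",
                             start = seq_len(40) * 10L,
                             end = seq_len(40) * 10L + 5L, strand = "+",
                             stringsAsFactors = FALSE), m)
  prev <- filter_by_support(cs2, consensus_config(min_reads = 1))$features$circ_id
  for (mr in 2:6) {
    cur <- filter_by_support(cs2, consensus_config(min_reads = mr))$features$circ_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("annotation classes follow the documented precedence", {
  genes <- data.frame(
    gene_id = c(rep("gA", 4), rep("gL", 2)),
    gene_type = c(rep("protein_coding", 4), rep("lncRNA", 2)),
    transcript_id = c(rep("gA.t1", 4), rep("gL.t1", 2)),
    chrom = "chr1", strand = "+",
    exon_start = c(1000L, 2000L, 3000L, 4000L, 9000L, 10000L),
    exon_end = c(1120L, 2090L, 3150L, 4100L, 9200L, 10200L),
    stringsAsFactors = FALSE
  )
  feats <- data.frame(
    circ_id = c("pc", "intronic", "lnc", "none"),
    chrom = "chr1",
    start = c(2000L, 1200L, 9050L, 50000L),
    end = c(3150L, 1900L, 10100L, 51000L),
    strand = "+", stringsAsFactors = FALSE
  )
  cs <- circ_set(feats, matrix(1L, 4, 2, dimnames = list(NULL, c("s1", "s2"))))
  ann <- annotate_circ(cs, genes)$features
  expect_equal(ann$annotation_class,
               c("protein_coding", "sense_intronic", "lncRNA", "intergenic"))
  # exon 2 + exon 3 (spanning exons 2000-2090 and 3000-3150): 90 + 150
  expect_equal(ann$exon_count[1], 2L)
  expect_equal(ann$spliced_length[1], 240L)
  expect_equal(ann$host_gene_id[1], "gA")
  # every circRNA receives exactly one class
  expect_true(all(ann$annotation_class %in%
                    c("protein_coding", "sense_intronic", "lncRNA", "intergenic")))
})

test_that("annotation on the simulated loci recovers the intended classes", {
  b <- simulate_study(small_config(seed = 33))
  feats <- b$circ_features
  cs <- circ_set(feats[, c("circ_id", "chrom", "start", "end", "strand")],
                 b$counts$circrna$values)
  ann <- annotate_circ(cs, b$gene_models)$features
  agree <- mean(ann$annotation_class == feats$true_class)
  expect_gt(agree, 0.95)
})

test_that("characterisation histograms count planted isoform structure", {
  feats <- data.frame(
    circ_id = sprintf("c%02d", 1:14), chrom = "chr1",
    start = seq_len(14) * 100L, end = seq_len(14) * 100L + 50L, strand = "+",
    annotation_class = "protein_coding",
    host_gene_id = c(rep("gBig", 11), rep("gSmall", 2), "gOne"),
    exon_count = c(rep(3L, 12), 2L, 12L),
    spliced_length = c(rep(350L, 12), 900L, 2500L),
    stringsAsFactors = FALSE
  )
  cs <- circ_set(feats, matrix(1L, 14, 2, dimnames = list(NULL, c("a", "b"))))
  ch <- characterize(cs)
  iso <- setNames(ch$isoforms_per_gene$n_isoforms,
                  ch$isoforms_per_gene$host_gene_id)
  expect_equal(iso[["gBig"]], 11L)
  expect_equal(ch$isoform_hist$count[ch$isoform_hist$bin == ">10"], 1L)
  expect_equal(ch$exon_hist$count[ch$exon_hist$bin == ">10"], 1L)
  expect_equal(sum(ch$length_hist$count), 14L)

  empty <- circ_set(feats[0, ], matrix(1L, 0, 2, dimnames = list(NULL, c("a", "b"))))
  ch0 <- characterize(empty)
  expect_equal(nrow(ch0$isoforms_per_gene), 0)
  expect_equal(sum(ch0$length_hist$count), 0)
})
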