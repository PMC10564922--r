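# Shared fixture builders and independent oracles used across test files.

pair_table_path <- function() {
  system.file("extdata", "veos_mirna_circ_pairs.tsv", package = "cernaforge")
}

# a small bundle keeps simulation-heavy tests fast
small_config <- function(seed = 42L, ...) {
  simulation_config(n_circ = 80L, n_mirna = 25L, n_mrna = 120L,
                    n_exclusive_case = 4L, n_exclusive_control = 10L,
                    seed = seed, ...)
}

write_calls_file <- function(rows, dialect = "find_circ") {
  f <- tempfile(fileext = ".bed")
  if (dialect == "find_circ") {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", rows$chrom, rows$start,
                       rows$end, "x", rows$junction_reads, rows$strand), f)
  } else {
    writeLines(sprintf("%s\t%d\t%d\tx\t0\t%s\t%d\t%d\t0\t1\t10\t0\t%d",
                       rows$chrom, rows$start, rows$end, rows$strand,
                       rows$start, rows$end, rows$junction_reads), f)
  }
  f
}

make_calls <- function(chrom, start, end, strand = "+", reads = 5L,
                       caller = "find_circ", sample_id = "S1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             junction_reads = reads, caller = caller, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

make_em <- function(values, n_case, n_control, totals = NULL,
                    unit = "raw_count") {
  samples <- c(sprintf("P%02d", seq_len(n_case)),
               sprintf("C%02d", seq_len(n_control)))
  colnames(values) <- samples
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  }
  groups <- setNames(rep(c("case", "control"), c(n_case, n_control)), samples)
  if (!is.null(totals)) totals <- setNames(rep_len(totals, length(samples)), samples)
  expression_matrix(values, groups, totals, unit = unit)
}

# independent nearest-neighbour oracle: direct stack-sum over a contiguous,
# perfectly paired duplex written down by hand from the parameter table
stack_sum_oracle <- function(mirna, target, j5) {
  nn <- nn_parameters()
  m <- strsplit(chartr("Tt", "Uu", toupper(mirna)), "")[[1]]
  t <- strsplit(chartr("Tt", "Uu", toupper(target)), "")[[1]]
  L <- length(m)
  # miRNA base i pairs target base j5 + (L - i)
  pairs <- vapply(seq_len(L), function(i) paste0(m[i], t[j5 + L - i]),
                  character(1))
  nn$init + sum(vapply(seq_len(L - 1), function(i) {
    nn$stack[[paste0(pairs[i], pairs[i + 1])]]
  }, numeric(1)))
}

# exhaustive hypergeometric upper tail by enumeration of the sampling space
hyper_enum_oracle <- function(k, K, N, n) {
  # P(X >= k) where X counts annotated genes among n drawn from N
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x)
  }, numeric(1))) / total
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
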