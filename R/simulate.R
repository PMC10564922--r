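# Seeded generator of complete in-silico case/control plasma RNA-seq studies
# with planted ground truth, used to validate every downstream stage.

#' Simulation configuration
#'
#' Defaults describe the study design the package targets: 10 case and 8
#' control plasma samples; negative-binomial counts for three RNA classes
#' (variance mu + alpha * mu^2); a global multiplicative down-shift of
#' circRNA abundance in cases; planted differential features with a fixed
#' fold change; planted group-exclusive circRNAs; two caller views of the
#' circRNA set with independent dropout; and miRNA response elements planted
#' as reverse-complement sites in target sequences.
#'
#' Class mean/dispersion defaults are chosen so that the standard low-count
#' prefilters (mean count 5 / 2 / 50 for mRNA / circRNA / miRNA) retain most
#' features, and mapped-read totals are log-normal around 1e6 so per-million
#' values are O(1)-O(100).
#'
#' @param n_case,n_control Sample sizes (defaults 10 and 8).
#' @param n_circ,n_mirna,n_mrna Feature counts per RNA class.
#' @param nb_mean,nb_dispersion Named vectors (circrna, mirna, mrna) of NB
#'   mean and dispersion parameters.
#' @param case_circ_downshift Multiplicative factor in (0, 1] applied to all
#'   circRNA means in case samples.
#' @param frac_de Named vector of fractions of features per class receiving a
#'   planted differential effect.
#' @param de_fold_change Linear fold change of planted differential features.
#' @param frac_de_up Named vector: probability that a planted differential
#'   feature is up- (rather than down-) regulated in cases.
#' @param n_exclusive_case,n_exclusive_control Numbers of planted
#'   group-exclusive circRNAs.
#' @param caller_dropout Length-2 vector: fraction of true circRNAs each
#'   caller independently fails to report.
#' @param mre_plant_rate Fraction of (differential miRNA, differential
#'   target) pairs receiving a planted complementary site.
#' @param mirna_length,circ_seq_length,mrna_seq_length Sequence lengths (nt).
#' @param annotation_fracs Intended annotation-class composition of the
#'   simulated circRNA loci.
#' @param mapped_total_meanlog,mapped_total_sdlog Log-normal parameters of
#'   per-sample total mapped reads.
#' @param seed RNG seed; the same seed reproduces the bundle exactly.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 10L, n_control = 8L,
                              n_circ = 300L, n_mirna = 60L, n_mrna = 400L,
                              nb_mean = c(circrna = 8, mirna = 250, mrna = 100),
                              nb_dispersion = c(circrna = 0.2, mirna = 0.2, mrna = 0.2),
                              case_circ_downshift = 0.5,
                              frac_de = c(circrna = 0.1, mirna = 0.15, mrna = 0.1),
                              de_fold_change = 4,
                              frac_de_up = c(circrna = 0.05, mirna = 0.6, mrna = 0.8),
                              n_exclusive_case = 6L, n_exclusive_control = 30L,
                              caller_dropout = c(find_circ = 0.12, circexplorer2 = 0.12),
                              mre_plant_rate = 0.3,
                              mirna_length = 22L, circ_seq_length = 500L,
                              mrna_seq_length = 800L,
                              annotation_fracs = c(protein_coding = 0.94,
                                                   sense_intronic = 0.03,
                                                   lncRNA = 0.02,
                                                   intergenic = 0.01),
                              mapped_total_meanlog = log(1e6),
                              mapped_total_sdlog = 0.2,
                              seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
              n_mrna = as.integer(n_mrna), nb_mean = nb_mean,
              nb_dispersion = nb_dispersion,
              case_circ_downshift = case_circ_downshift, frac_de = frac_de,
              de_fold_change = de_fold_change, frac_de_up = frac_de_up,
              n_exclusive_case = as.integer(n_exclusive_case),
              n_exclusive_control = as.integer(n_exclusive_control),
              caller_dropout = caller_dropout,
              mre_plant_rate = mre_plant_rate,
              mirna_length = as.integer(mirna_length),
              circ_seq_length = as.integer(circ_seq_length),
              mrna_seq_length = as.integer(mrna_seq_length),
              annotation_fracs = annotation_fracs,
              mapped_total_meanlog = mapped_total_meanlog,
              mapped_total_sdlog = mapped_total_sdlog,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_case > 0, n_control > 0, n_circ > 0, n_mirna > 0, n_mrna > 0,
              all(nb_mean > 0), all(nb_dispersion > 0),
              case_circ_downshift > 0, case_circ_downshift <= 1,
              all(frac_de >= 0), de_fold_change > 1,
              all(frac_de_up >= 0 & frac_de_up <= 1),
              n_exclusive_case >= 0, n_exclusive_control >= 0,
              all(caller_dropout >= 0 & caller_dropout < 1),
              mre_plant_rate >= 0, mre_plant_rate <= 1,
              mirna_length >= 16)
  })
  n_planted <- cfg$n_exclusive_case + cfg$n_exclusive_control +
    round(cfg$frac_de[["circrna"]] * cfg$n_circ)
  if (n_planted >= cfg$n_circ) {
    stop("infeasible config: exclusive plus differential circRNAs (",
         n_planted, ") must be fewer than n_circ (", cfg$n_circ, ")")
  }
  structure(cfg, class = "simulation_config")
}

# sample() treats a length-1 vector as 1:x; this keeps draws literal
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Plant a miRNA response element in a target sequence
#'
#' Replaces the target substring starting at `position` with the reverse
#' complement of the miRNA 5' region (`site_len` nucleotides: the seed plus
#' a configurable 3'-pairing extent, by default the full miRNA). After
#' planting, the 5'-most paired target base of a perfect duplex sits exactly
#' at `position`.
#'
#' @param mirna_seq miRNA sequence (RNA).
#' @param target_seq Target sequence (RNA).
#' @param position 1-based offset at which the site is written.
#' @param site_len Length of the miRNA 5' prefix to complement (>= 8).
#' @return The modified target sequence.
#' @export
plant_mre <- function(mirna_seq, target_seq, position,
                      site_len = nchar(mirna_seq)) {
  stopifnot(site_len >= 8)
  target_seq <- .norm_rna(target_seq)
  tlen <- nchar(target_seq)
  if (position < 1 || position + site_len - 1 > tlen) {
    stop("planting position out of range (position ", position,
         ", site length ", site_len, ", target length ", tlen, ")")
  }
  site <- rc_rna(substr(.norm_rna(mirna_seq), 1, site_len))
  paste0(substr(target_seq, 1, position - 1), site,
         substr(target_seq, position + site_len, tlen))
}

# Gene models: one transcript per gene, 4-10 exons, on chr1..chr22.
.sim_gene_models <- function(n_genes, lnc_frac = 0.08) {
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%04d", g)
    chrom <- paste0("chr", sample(1:22, 1))
    strand <- sample(c("+", "-"), 1)
    type <- if (runif(1) < lnc_frac) "lncRNA" else "protein_coding"
    n_ex <- sample(4:10, 1)
    ex_len <- sample(80:300, n_ex, replace = TRUE)
    introns <- sample(200:1500, n_ex - 1, replace = TRUE)
    start <- sample(1e4:1e8, 1)
    es <- integer(n_ex); ee <- integer(n_ex)
    pos <- start
    for (e in seq_len(n_ex)) {
      es[e] <- pos; ee[e] <- pos + ex_len[e]
      pos <- ee[e] + if (e < n_ex) introns[e] else 0L
    }
    rows[[g]] <- data.frame(
      gene_id = gid, gene_type = type, transcript_id = paste0(gid, ".t1"),
      chrom = chrom, strand = strand, exon_start = es, exon_end = ee,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# circRNA loci tied to the gene models, with the intended annotation class.
.sim_circ_loci <- function(genes, config) {
  tx <- split(genes, genes$transcript_id)
  coding <- names(tx)[vapply(tx, function(t) t$gene_type[1] == "protein_coding", logical(1))]
  lnc <- names(tx)[vapply(tx, function(t) t$gene_type[1] == "lncRNA", logical(1))]
  n <- config$n_circ
  fr <- config$annotation_fracs
  n_pc <- round(n * fr[["protein_coding"]])
  n_si <- round(n * fr[["sense_intronic"]])
  n_ln <- if (length(lnc)) round(n * fr[["lncRNA"]]) else 0L
  n_ig <- n - n_pc - n_si - n_ln
  # isoform multiplicity: weight host-gene sampling so some genes host many
  # circRNAs, as observed in plasma studies
  w <- stats::rexp(length(coding)) + 0.05
  seen <- character(0)
  out <- list()
  add <- function(chrom, s, e, strand, class, host) {
    id <- paste(chrom, s, e, sep = "_")
    if (id %in% seen) return(FALSE)
    seen <<- c(seen, id)
    out[[length(out) + 1]] <<- data.frame(
      circ_id = id, chrom = chrom, start = s, end = e, strand = strand,
      true_class = class, true_host = host, stringsAsFactors = FALSE
    )
    TRUE
  }
  draw_pc <- function() {
    t <- tx[[sample(coding, 1, prob = w)]]
    n_ex <- nrow(t)
    a <- .sample1(seq_len(n_ex))
    b <- .sample1(a:n_ex)
    add(t$chrom[1], t$exon_start[a], t$exon_end[b], t$strand[1],
        "protein_coding", t$gene_id[1])
  }
  draw_si <- function() {
    t <- tx[[sample(coding, 1)]]
    if (nrow(t) < 2) return(FALSE)
    k <- .sample1(seq_len(nrow(t) - 1))
    lo <- t$exon_end[k] + 5L
    hi <- t$exon_start[k + 1] - 5L
    if (hi - lo < 60) return(FALSE)
    s <- .sample1(lo:(hi - 50))
    e <- min(hi, s + .sample1(50:(hi - s)))
    add(t$chrom[1], s, e, t$strand[1], "sense_intronic", t$gene_id[1])
  }
  draw_ln <- function() {
    t <- tx[[sample(lnc, 1)]]
    a <- .sample1(seq_len(nrow(t)))
    b <- .sample1(a:nrow(t))
    add(t$chrom[1], t$exon_start[a], t$exon_end[b], t$strand[1],
        "lncRNA", t$gene_id[1])
  }
  draw_ig <- function() {
    chrom <- paste0("chr", sample(1:22, 1))
    s <- sample(150000000:200000000, 1)  # beyond all simulated genes
    add(chrom, s, s + sample(200:2000, 1), sample(c("+", "-"), 1),
        "intergenic", NA_character_)
  }
  fill <- function(k, fun) {
    made <- 0L; tries <- 0L
    while (made < k && tries < 50L * max(k, 1L)) {
      tries <- tries + 1L
      if (fun()) made <- made + 1L
    }
    made
  }
  fill(n_pc, draw_pc)
  fill(n_si, draw_si)
  if (n_ln > 0) fill(n_ln, draw_ln)
  fill(n - length(out), draw_ig)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# NB count matrix for one class with planted differential features.
.sim_counts <- function(ids, samples, groups, mean0, disp, frac_de, fc,
                        frac_up, global_case_factor = 1) {
  n <- length(ids)
  base_mean <- stats::rlnorm(n, log(mean0), 0.5)
  n_de <- round(frac_de * n)
  de_idx <- if (n_de > 0) sample(seq_len(n), n_de) else integer(0)
  de_up <- runif(length(de_idx)) < frac_up
  m <- matrix(0L, n, length(samples), dimnames = list(ids, samples))
  is_case <- groups == "case"
  for (i in seq_len(n)) {
    mu <- rep(base_mean[i], length(samples))
    mu[is_case] <- mu[is_case] * global_case_factor
    if (i %in% de_idx) {
      f <- if (de_up[match(i, de_idx)]) fc else 1 / fc
      mu[is_case] <- mu[is_case] * f
    }
    m[i, ] <- stats::rnbinom(length(samples), mu = mu, size = 1 / disp)
  }
  truth <- data.frame(
    feature_id = ids[de_idx],
    direction = ifelse(de_up, "Up", "Down"),
    fold_change = ifelse(de_up, fc, 1 / fc),
    stringsAsFactors = FALSE
  )
  list(counts = m, de_truth = truth[order(truth$feature_id), , drop = FALSE])
}

#' Simulate a complete in-silico case/control study
#'
#' Generates gene models, circRNA loci, NB count matrices for the three RNA
#' classes (with the configured global circRNA down-shift in cases and
#' planted differential features), planted group-exclusive circRNAs, two
#' caller views of the circRNA set with independent dropout, miRNA and
#' target sequences with planted response elements, a gene-set annotation,
#' and a ground-truth record consistent with all of the above.
#'
#' @param config A [simulation_config()].
#' @return A list of class `study_bundle` with elements `samples`, `groups`,
#'   `mapped_totals`, `calls` (per-caller call tables), `counts`
#'   (per-class [expression_matrix()] objects), `gene_models`,
#'   `circ_features`, `sequences`, `gene_sets`, `ground_truth`, `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  samples <- c(sprintf("P%02d", seq_len(config$n_case)),
               sprintf("C%02d", seq_len(config$n_control)))
  groups <- setNames(rep(c("case", "control"),
                         c(config$n_case, config$n_control)), samples)

  genes <- .sim_gene_models(max(20L, ceiling(config$n_circ * 0.7)))
  loci <- .sim_circ_loci(genes, config)
  circ_ids <- loci$circ_id

  sim_circ <- .sim_counts(circ_ids, samples, groups,
                          config$nb_mean[["circrna"]],
                          config$nb_dispersion[["circrna"]],
                          config$frac_de[["circrna"]], config$de_fold_change,
                          config$frac_de_up[["circrna"]],
                          global_case_factor = config$case_circ_downshift)
  circ_counts <- sim_circ$counts

  # planted exclusive circRNAs come from the non-differential pool
  pool <- setdiff(circ_ids, sim_circ$de_truth$feature_id)
  n_excl <- config$n_exclusive_case + config$n_exclusive_control
  excl <- if (n_excl > 0) sample(pool, n_excl) else character(0)
  excl_case <- utils::head(excl, config$n_exclusive_case)
  excl_control <- utils::tail(excl, config$n_exclusive_control)
  is_case <- groups == "case"
  force_support <- function(row, cols, min_reads = 2L) {
    need <- floor(length(cols) / 2) + 1L
    vals <- stats::rnbinom(length(cols), mu = 10, size = 5)
    top <- order(vals, decreasing = TRUE)[seq_len(need)]
    vals[top] <- pmax(vals[top], min_reads)
    row[cols] <- vals
    row
  }
  for (id in excl_case) {
    r <- rep(0L, length(samples))
    r <- force_support(r, which(is_case))
    circ_counts[id, ] <- r
  }
  for (id in excl_control) {
    r <- rep(0L, length(samples))
    r <- force_support(r, which(!is_case))
    circ_counts[id, ] <- r
  }

  sim_mi <- .sim_counts(sprintf("hsa-miR-sim-%03d", seq_len(config$n_mirna)),
                        samples, groups, config$nb_mean[["mirna"]],
                        config$nb_dispersion[["mirna"]],
                        config$frac_de[["mirna"]], config$de_fold_change,
                        config$frac_de_up[["mirna"]])
  sim_mr <- .sim_counts(sprintf("mrna%04d", seq_len(config$n_mrna)),
                        samples, groups, config$nb_mean[["mrna"]],
                        config$nb_dispersion[["mrna"]],
                        config$frac_de[["mrna"]], config$de_fold_change,
                        config$frac_de_up[["mrna"]])

  mapped_totals <- setNames(
    round(stats::rlnorm(length(samples), config$mapped_total_meanlog,
                        config$mapped_total_sdlog)),
    samples
  )

  # two caller views: independent feature-level dropout
  drop_a <- sample(circ_ids, round(config$caller_dropout[[1]] * length(circ_ids)))
  drop_b <- sample(circ_ids, round(config$caller_dropout[[2]] * length(circ_ids)))
  seen_a <- setdiff(circ_ids, drop_a)
  seen_b <- setdiff(circ_ids, drop_b)
  make_calls <- function(seen, caller) {
    rows <- list()
    for (s in samples) {
      idx <- which(circ_ids %in% seen & circ_counts[, s] > 0)
      if (!length(idx)) next
      rows[[s]] <- data.frame(
        chrom = loci$chrom[idx], start = loci$start[idx], end = loci$end[idx],
        strand = loci$strand[idx], junction_reads = circ_counts[idx, s],
        caller = caller, sample_id = s, stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  calls <- list(find_circ = make_calls(seen_a, "find_circ"),
                circexplorer2 = make_calls(seen_b, "circexplorer2"))
  expressed <- circ_ids[rowSums(circ_counts > 0) > 0]
  overlap_truth <- sort(intersect(intersect(seen_a, seen_b), expressed))

  # sequences and planted miRNA response elements
  mirna_seqs <- setNames(.random_rna(config$n_mirna, config$mirna_length),
                         rownames(sim_mi$counts))
  circ_seqs <- setNames(.random_rna(length(circ_ids), config$circ_seq_length),
                        circ_ids)
  mrna_seqs <- setNames(.random_rna(config$n_mrna, config$mrna_seq_length),
                        rownames(sim_mr$counts))
  de_mi <- sim_mi$de_truth$feature_id
  mre <- data.frame(mirna_id = character(), target_id = character(),
                    target_class = character(), position = integer(),
                    stringsAsFactors = FALSE)
  plant_into <- function(seqs, targets, class) {
    L <- config$mirna_length
    occupied <- setNames(vector("list", length(targets)), targets)
    for (mid in de_mi) {
      for (tid in targets) {
        if (runif(1) >= config$mre_plant_rate) next
        # sites must not overlap an earlier plant in the same target, so that
        # every recorded ground-truth site survives intact
        pos <- NA_integer_
        for (try in 1:20) {
          p <- sample(seq_len(nchar(seqs[[tid]]) - L + 1), 1)
          if (!any((p:(p + L - 1)) %in% occupied[[tid]])) { pos <- p; break }
        }
        if (is.na(pos)) next
        occupied[[tid]] <- c(occupied[[tid]], pos:(pos + L - 1))
        seqs[[tid]] <- plant_mre(mirna_seqs[[mid]], seqs[[tid]], pos)
        mre[nrow(mre) + 1, ] <<- list(mid, tid, class, as.integer(pos))
      }
    }
    seqs
  }
  circ_seqs <- plant_into(circ_seqs, sim_circ$de_truth$feature_id, "circRNA")
  mrna_seqs <- plant_into(mrna_seqs, sim_mr$de_truth$feature_id, "mRNA")

  # gene-set annotation over the mRNA universe
  n_terms <- 15L
  gs <- do.call(rbind, lapply(seq_len(n_terms), function(k) {
    size <- sample(15:40, 1)
    data.frame(term_id = sprintf("T%03d", k),
               term_name = sprintf("simulated process %d", k),
               gene_id = sample(rownames(sim_mr$counts), size),
               stringsAsFactors = FALSE)
  }))

  iso_truth <- as.data.frame(
    table(host_gene_id = loci$true_host[loci$true_class == "protein_coding"]),
    responseName = "n_isoforms", stringsAsFactors = FALSE
  )

  structure(list(
    samples = samples, groups = groups, mapped_totals = mapped_totals,
    calls = calls,
    counts = list(
      circrna = expression_matrix(circ_counts, groups, mapped_totals),
      mirna = expression_matrix(sim_mi$counts, groups, mapped_totals),
      mrna = expression_matrix(sim_mr$counts, groups, mapped_totals)
    ),
    gene_models = genes, circ_features = loci,
    sequences = list(mirna = mirna_seqs, circrna = circ_seqs, mrna = mrna_seqs),
    gene_sets = gs,
    ground_truth = list(
      de = list(circrna = sim_circ$de_truth, mirna = sim_mi$de_truth,
                mrna = sim_mr$de_truth),
      exclusive_case = sort(excl_case),
      exclusive_control = sort(excl_control),
      caller_overlap = overlap_truth,
      mre = mre,
      isoforms_per_gene = iso_truth
    ),
    config = config
  ), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(paste0("study_bundle: %d case / %d control samples; ",
                     "%d circRNAs, %d miRNAs, %d mRNAs (seed %d)\n"),
              sum(x$groups == "case"), sum(x$groups == "control"),
              nrow(x$counts$circrna$values), nrow(x$counts$mirna$values),
              nrow(x$counts$mrna$values), x$config$seed))
  invisible(x)
}

#' Write a study bundle to a directory of plain-text files
#'
#' Emits every bundle component in the formats the pipeline reads: per-sample
#' caller tables (`calls_find_circ/`, `calls_circexplorer2/`), count matrices,
#' sample tables, FASTA sequence sets, the gene-model and gene-set tables,
#' and the ground-truth record (under `ground_truth/`).
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # caller tables: find_circ as BED6 (reads in the score slot),
  # circexplorer2 as BED12+ with reads in column 13
  dir.create(file.path(dir, "calls_find_circ"), showWarnings = FALSE)
  dir.create(file.path(dir, "calls_circexplorer2"), showWarnings = FALSE)
  for (s in bundle$samples) {
    a <- bundle$calls$find_circ
    a <- a[a$sample_id == s, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", a$chrom, a$start, a$end,
                       paste(a$chrom, a$start, a$end, sep = "_"),
                       a$junction_reads, a$strand),
               file.path(dir, "calls_find_circ", paste0(s, ".bed")))
    b <- bundle$calls$circexplorer2
    b <- b[b$sample_id == s, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d\t0\t%d",
                       b$chrom, b$start, b$end,
                       paste(b$chrom, b$start, b$end, sep = "_"),
                       b$strand, b$start, b$end, b$end - b$start,
                       b$junction_reads),
               file.path(dir, "calls_circexplorer2", paste0(s, ".txt")))
  }
  for (cls in names(bundle$counts)) {
    write_count_matrix(bundle$counts[[cls]]$values,
                       file.path(dir, paste0("counts_", cls, ".tsv")))
  }
  utils::write.table(
    data.frame(sample = bundle$samples, group = bundle$groups[bundle$samples]),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(sample = bundle$samples,
               mapped_reads = bundle$mapped_totals[bundle$samples]),
    file.path(dir, "mapped_totals.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  write_fasta(bundle$sequences$mirna, file.path(dir, "mirnas.fa"))
  write_fasta(bundle$sequences$circrna, file.path(dir, "circ_seqs.fa"))
  write_fasta(bundle$sequences$mrna, file.path(dir, "mrna_seqs.fa"))
  utils::write.table(bundle$gene_models, file.path(dir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$gene_sets, file.path(dir, "gene_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt_dir <- file.path(dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  for (cls in names(bundle$ground_truth$de)) {
    utils::write.table(bundle$ground_truth$de[[cls]],
                       file.path(gt_dir, paste0("de_", cls, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(bundle$ground_truth$exclusive_case,
             file.path(gt_dir, "exclusive_case.txt"))
  writeLines(bundle$ground_truth$exclusive_control,
             file.path(gt_dir, "exclusive_control.txt"))
  writeLines(bundle$ground_truth$caller_overlap,
             file.path(gt_dir, "caller_overlap.txt"))
  utils::write.table(bundle$ground_truth$mre, file.path(gt_dir, "mre.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
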