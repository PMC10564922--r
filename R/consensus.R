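# Consensus circRNA identification from two back-spliced-junction callers,
# support filtering, annotation against gene models, and characterisation
# summaries.

#' Consensus-calling configuration
#'
#' The support rule follows the convention of plasma circRNA studies: a
#' circRNA is retained when it has at least `min_reads` back-spliced reads in
#' strictly more than half of the samples considered.
#'
#' @param min_reads Minimum back-spliced read count per supporting sample
#'   (default 2).
#' @param tolerance Maximum per-endpoint coordinate difference (bp) for two
#'   callers' junctions to be considered the same (default 0, exact match).
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(min_reads = 2L, tolerance = 0L) {
  stopifnot(min_reads >= 1, tolerance >= 0)
  structure(list(min_reads = as.integer(min_reads),
                 tolerance = as.integer(tolerance)),
            class = "consensus_config")
}

#' Construct a circRNA set
#'
#' Container pairing a feature table (`circ_id`, `chrom`, `start`, `end`,
#' `strand`, plus optional annotation columns) with a per-sample
#' back-spliced-read count matrix whose rows align with the feature table.
#'
#' @param features `data.frame` of circRNA features.
#' @param counts Integer matrix, one row per feature, one column per sample.
#' @return A list of class `circ_set`.
#' @export
circ_set <- function(features, counts) {
  stopifnot(nrow(features) == nrow(counts))
  if (nrow(counts) && any(counts < 0)) stop("junction read counts must be non-negative")
  rownames(counts) <- features$circ_id
  rownames(features) <- NULL
  structure(list(features = features, counts = counts), class = "circ_set")
}

#' @export
print.circ_set <- function(x, ...) {
  cat(sprintf("circ_set: %d circRNAs x %d samples\n",
              nrow(x$features), ncol(x$counts)))
  invisible(x)
}

.empty_circ_set <- function(samples = character()) {
  circ_set(
    data.frame(circ_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), stringsAsFactors = FALSE),
    matrix(0L, 0, length(samples), dimnames = list(NULL, samples))
  )
}

# Unique junction table for one caller's calls, with a per-junction key.
.feature_table <- function(calls) {
  key <- paste(calls$chrom, calls$start, calls$end, sep = "_")
  feats <- calls[!duplicated(key), c("chrom", "start", "end", "strand")]
  feats$key <- key[!duplicated(key)]
  strands <- split(calls$strand, key)
  feats$strand <- vapply(feats$key, function(k) {
    u <- setdiff(unique(strands[[k]]), ".")
    if (length(u) == 1) u else "."
  }, character(1))
  rownames(feats) <- NULL
  feats[order(feats$chrom, feats$start, feats$end), , drop = FALSE]
}

# Junction x sample read-count matrix; duplicate (junction, sample) rows keep
# the maximum reported count.
.call_count_matrix <- function(calls, feats, samples) {
  m <- matrix(0L, nrow(feats), length(samples),
              dimnames = list(feats$key, samples))
  if (!nrow(calls)) return(m)
  key <- paste(calls$chrom, calls$start, calls$end, sep = "_")
  ord <- order(key, calls$sample_id, -calls$junction_reads)
  first <- !duplicated(paste(key[ord], calls$sample_id[ord]))
  sel <- ord[first]
  m[cbind(match(key[sel], feats$key), match(calls$sample_id[sel], samples))] <-
    calls$junction_reads[sel]
  m
}

.strand_compatible <- function(a, b) a == "." | b == "." | a == b

# Match junctions of caller A to caller B within +/- tolerance per endpoint.
# Returns index pairs (ia, ib); at tolerance 0 this is exact key matching.
.match_features <- function(fa, fb, tolerance) {
  if (!nrow(fa) || !nrow(fb)) return(data.frame(ia = integer(), ib = integer()))
  if (tolerance == 0) {
    ib <- match(fa$key, fb$key)
    ok <- !is.na(ib) & .strand_compatible(fa$strand, fb$strand[ib])
    return(data.frame(ia = which(ok), ib = ib[ok]))
  }
  used <- rep(FALSE, nrow(fb))
  ia <- ib <- integer()
  for (i in order(fa$chrom, fa$start, fa$end)) {
    cand <- which(!used &
                    fb$chrom == fa$chrom[i] &
                    abs(fb$start - fa$start[i]) <= tolerance &
                    abs(fb$end - fa$end[i]) <= tolerance &
                    .strand_compatible(fa$strand[i], fb$strand))
    if (!length(cand)) next
    d <- abs(fb$start[cand] - fa$start[i]) + abs(fb$end[cand] - fa$end[i])
    j <- cand[order(d, fb$start[cand], fb$end[cand])][1]
    used[j] <- TRUE
    ia <- c(ia, i); ib <- c(ib, j)
  }
  data.frame(ia = ia, ib = ib)
}

#' Intersect the call sets of two circRNA callers
#'
#' A circRNA enters the consensus when both callers report a junction whose
#' start and end each differ by at most `tolerance` bp. The retained
#' per-sample read count is the maximum of the two callers' counts (a
#' monotone, caller-symmetric combination). With `mode = "per_sample"` (the
#' default) a junction must be reported by both callers in at least one
#' common sample; `mode = "pooled"` only requires both callers to report it
#' somewhere in the study.
#'
#' @param calls_a,calls_b Call tables as returned by [read_bsj_calls()]
#'   (rows from several samples may be concatenated).
#' @param tolerance Maximum per-endpoint coordinate difference in bp.
#' @param mode `"per_sample"` or `"pooled"`.
#' @return A [circ_set()] sorted by (chrom, start, end). Matched junctions
#'   with unequal coordinates take the elementwise minimum, keeping the
#'   operation symmetric in its two arguments.
#' @export
intersect_callers <- function(calls_a, calls_b, tolerance = 0L,
                              mode = c("per_sample", "pooled")) {
  mode <- match.arg(mode)
  samples <- sort(union(unique(calls_a$sample_id), unique(calls_b$sample_id)))
  if (!nrow(calls_a) || !nrow(calls_b)) return(.empty_circ_set(samples))
  fa <- .feature_table(calls_a)
  fb <- .feature_table(calls_b)
  ma <- .call_count_matrix(calls_a, fa, samples)
  mb <- .call_count_matrix(calls_b, fb, samples)
  pairs <- .match_features(fa, fb, tolerance)
  if (!nrow(pairs)) return(.empty_circ_set(samples))
  ca <- ma[pairs$ia, , drop = FALSE]
  cb <- mb[pairs$ib, , drop = FALSE]
  keep <- if (mode == "per_sample") rowSums(ca > 0 & cb > 0) > 0 else rep(TRUE, nrow(pairs))
  if (!any(keep)) return(.empty_circ_set(samples))
  pairs <- pairs[keep, , drop = FALSE]
  counts <- pmax(ca[keep, , drop = FALSE], cb[keep, , drop = FALSE])
  sa <- fa$strand[pairs$ia]; sb <- fb$strand[pairs$ib]
  feats <- data.frame(
    chrom = fa$chrom[pairs$ia],
    start = pmin(fa$start[pairs$ia], fb$start[pairs$ib]),
    end = pmin(fa$end[pairs$ia], fb$end[pairs$ib]),
    strand = ifelse(sa == ".", sb, sa),
    stringsAsFactors = FALSE
  )
  feats$circ_id <- paste(feats$chrom, feats$start, feats$end, sep = "_")
  ord <- order(feats$chrom, feats$start, feats$end)
  feats <- feats[ord, c("circ_id", "chrom", "start", "end", "strand")]
  circ_set(feats, counts[ord, , drop = FALSE])
}

#' Filter circRNAs by back-spliced read support
#'
#' Retains circRNAs with at least `config$min_reads` reads in strictly more
#' than half of the `n_samples` samples.
#'
#' @param circs A [circ_set()].
#' @param config A [consensus_config()].
#' @param n_samples Number of samples the majority rule refers to; defaults
#'   to the number of count columns.
#' @return The filtered `circ_set`.
#' @export
filter_by_support <- function(circs, config = consensus_config(),
                              n_samples = ncol(circs$counts)) {
  stopifnot(inherits(circs, "circ_set"))
  if (!nrow(circs$features)) return(circs)
  keep <- rowSums(circs$counts >= config$min_reads) > n_samples / 2
  circ_set(circs$features[keep, , drop = FALSE],
           circs$counts[keep, , drop = FALSE])
}

#' Annotate consensus circRNAs against gene models
#'
#' Each circRNA receives exactly one annotation class by precedence:
#' `protein_coding` (both junction endpoints fall on exons of one coding
#' transcript) > `sense_intronic` (contained in an intron of a coding
#' transcript on the same strand) > `lncRNA` (overlaps a lncRNA transcript)
#' > `intergenic`. For `protein_coding` circRNAs, `exon_count` is the number
#' of host-transcript exons between the junction endpoints and
#' `spliced_length` the summed length of those exons clipped to the junction
#' span. Unstranded (`.`) calls match either strand.
#'
#' @param circs A [circ_set()].
#' @param genes Gene model table (see [read_gene_models()]).
#' @return The `circ_set` with feature columns `annotation_class`,
#'   `host_gene_id`, `exon_count`, `spliced_length` added.
#' @export
annotate_circ <- function(circs, genes) {
  stopifnot(inherits(circs, "circ_set"))
  f <- circs$features
  n <- nrow(f)
  cls <- rep("intergenic", n)
  host <- rep(NA_character_, n)
  ec <- rep(NA_integer_, n)
  sl <- rep(NA_integer_, n)
  if (n) {
    tx <- split(genes, genes$transcript_id)
    tx <- tx[order(names(tx))]
    meta <- data.frame(
      chrom = vapply(tx, function(t) t$chrom[1], character(1)),
      strand = vapply(tx, function(t) t$strand[1], character(1)),
      type = vapply(tx, function(t) t$gene_type[1], character(1)),
      gene = vapply(tx, function(t) t$gene_id[1], character(1)),
      span_s = vapply(tx, function(t) min(t$exon_start), numeric(1)),
      span_e = vapply(tx, function(t) max(t$exon_end), numeric(1)),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(n)) {
      cand <- which(meta$chrom == f$chrom[i] &
                      meta$span_s < f$end[i] & meta$span_e > f$start[i])
      found_intronic <- found_lnc <- NA_character_
      for (k in cand) {
        t <- tx[[k]]
        same_strand <- f$strand[i] == "." || meta$strand[k] == "." ||
          f$strand[i] == meta$strand[k]
        es <- t$exon_start; ee <- t$exon_end
        if (meta$type[k] == "protein_coding" && same_strand) {
          s_on <- any(es <= f$start[i] & f$start[i] < ee)
          e_on <- any(es < f$end[i] & f$end[i] <= ee)
          if (s_on && e_on) {
            ov <- which(ee > f$start[i] & es < f$end[i])
            cls[i] <- "protein_coding"
            host[i] <- meta$gene[k]
            ec[i] <- length(ov)
            sl[i] <- sum(pmin(ee[ov], f$end[i]) - pmax(es[ov], f$start[i]))
            break
          }
          contained <- f$start[i] >= meta$span_s[k] && f$end[i] <= meta$span_e[k]
          touches_exon <- any(ee > f$start[i] & es < f$end[i])
          if (contained && !touches_exon && is.na(found_intronic)) {
            found_intronic <- meta$gene[k]
          }
        }
        if (meta$type[k] == "lncRNA" && is.na(found_lnc)) found_lnc <- meta$gene[k]
      }
      if (cls[i] != "protein_coding") {
        if (!is.na(found_intronic)) {
          cls[i] <- "sense_intronic"; host[i] <- found_intronic
        } else if (!is.na(found_lnc)) {
          cls[i] <- "lncRNA"; host[i] <- found_lnc
        }
      }
    }
  }
  f$annotation_class <- cls
  f$host_gene_id <- host
  f$exon_count <- ec
  f$spliced_length <- sl
  circ_set(f, circs$counts)
}

.binned_counts <- function(x, max_single = 10L) {
  x <- x[!is.na(x)]
  levels <- c(as.character(seq_len(max_single)), paste0(">", max_single))
  b <- ifelse(x > max_single, paste0(">", max_single), as.character(x))
  as.data.frame(table(bin = factor(b, levels = levels)),
                responseName = "count", stringsAsFactors = FALSE)
}

#' Characterise an annotated circRNA set
#'
#' Produces the three standard descriptive summaries: circRNA isoforms per
#' host gene (bins 1..10 and ">10"), spliced-length histogram (200-bp bins up
#' to 2 kb, then a single overflow bin), and exon-count histogram (bins 1..10
#' and ">10").
#'
#' @param circs An annotated [circ_set()] (see [annotate_circ()]).
#' @return A list with elements `isoforms_per_gene` (per-gene counts),
#'   `isoform_hist`, `length_hist`, `exon_hist`.
#' @export
characterize <- function(circs) {
  stopifnot(inherits(circs, "circ_set"))
  f <- circs$features
  hosts <- f$host_gene_id[!is.na(f$host_gene_id)]
  iso <- table(hosts)
  isoforms_per_gene <- data.frame(host_gene_id = names(iso),
                                  n_isoforms = as.integer(iso),
                                  stringsAsFactors = FALSE)
  len_breaks <- c(seq(0, 2000, by = 200), Inf)
  lens <- f$spliced_length[!is.na(f$spliced_length)]
  length_hist <- as.data.frame(
    table(bin = cut(lens, breaks = len_breaks, include.lowest = TRUE)),
    responseName = "count", stringsAsFactors = FALSE
  )
  structure(list(
    isoforms_per_gene = isoforms_per_gene,
    isoform_hist = .binned_counts(as.integer(iso)),
    length_hist = length_hist,
    exon_hist = .binned_counts(f$exon_count)
  ), class = "circ_characterization")
}

#' Per-sample caller comparison report
#'
#' For each sample, the number of junctions reported by each caller and the
#' size of their per-sample overlap (at the given tolerance).
#'
#' @param calls_a,calls_b Call tables as for [intersect_callers()].
#' @param tolerance Matching tolerance in bp.
#' @return `data.frame` with columns `sample_id`, `n_caller_a`, `n_caller_b`,
#'   `overlap`.
#' @export
caller_report <- function(calls_a, calls_b, tolerance = 0L) {
  samples <- sort(union(unique(calls_a$sample_id), unique(calls_b$sample_id)))
  out <- lapply(samples, function(s) {
    a <- calls_a[calls_a$sample_id == s, , drop = FALSE]
    b <- calls_b[calls_b$sample_id == s, , drop = FALSE]
    ov <- if (nrow(a) && nrow(b)) {
      nrow(.match_features(.feature_table(a), .feature_table(b), tolerance))
    } else 0L
    data.frame(sample_id = s, n_caller_a = nrow(a), n_caller_b = nrow(b),
               overlap = ov, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
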