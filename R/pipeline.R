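# Orchestration of the full analysis from a directory of study inputs to a
# directory of deterministic artifacts with a checksum manifest.

#' Pipeline configuration
#'
#' Bundles input locations and stage parameters. The stage defaults echo the
#' standard protocol: consensus support of at least 2 back-spliced reads in
#' a strict majority of samples, DE significance at linear fold change > 1.5
#' and p < 0.05, a duplex energy gate of -20 kcal/mol, and enrichment
#' significance at FDR < 0.05 and p < 0.01.
#'
#' @param input_dir Directory laid out as written by [write_study_bundle()].
#' @param out_dir Output directory for artifacts.
#' @param consensus A [consensus_config()].
#' @param de_circ,de_mirna,de_mrna Per-class [de_config()]s.
#' @param target A [target_config()].
#' @param enrich_p,enrich_fdr Enrichment thresholds.
#' @param corr_method Correlation method for the pattern comparison.
#' @param seed Seed fixed at the start of the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            consensus = consensus_config(),
                            de_circ = de_config("circrna"),
                            de_mirna = de_config("mirna"),
                            de_mrna = de_config("mrna"),
                            target = target_config(),
                            enrich_p = 0.01, enrich_fdr = 0.05,
                            corr_method = "pearson",
                            seed = 1L) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 consensus = consensus, de_circ = de_circ,
                 de_mirna = de_mirna, de_mrna = de_mrna, target = target,
                 enrich_p = enrich_p, enrich_fdr = enrich_fdr,
                 corr_method = corr_method, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; nested
#' sections `consensus`, `de`, `target` override individual stage
#' parameters.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  cc <- do.call(consensus_config, as.list(y$consensus %||% list()))
  tc <- do.call(target_config, as.list(y$target %||% list()))
  mk_de <- function(class) {
    args <- as.list((y$de %||% list())[[class]] %||% list())
    do.call(de_config, c(list(class = class), args))
  }
  pipeline_config(
    input_dir = y$input_dir, out_dir = y$out_dir,
    consensus = cc, de_circ = mk_de("circrna"), de_mirna = mk_de("mirna"),
    de_mrna = mk_de("mrna"), target = tc,
    enrich_p = y$enrich_p %||% 0.01, enrich_fdr = y$enrich_fdr %||% 0.05,
    corr_method = y$corr_method %||% "pearson", seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pipeline_inputs <- function(input_dir) {
  c(groups = "groups.tsv", mapped_totals = "mapped_totals.tsv",
    counts_mirna = "counts_mirna.tsv", counts_mrna = "counts_mrna.tsv",
    mirnas = "mirnas.fa", circ_seqs = "circ_seqs.fa",
    mrna_seqs = "mrna_seqs.fa", gene_models = "gene_models.tsv",
    gene_sets = "gene_sets.tsv", calls_a = "calls_find_circ",
    calls_b = "calls_circexplorer2")
}

#' Run the full ceRNA analysis pipeline
#'
#' Executes the stages in order — consensus circRNA detection, BSJ-per-million
#' quantification, differential expression for the three RNA classes, target
#' prediction restricted to differentially expressed molecules, network
#' assembly under the inverse-expression constraint, gene-set enrichment of
#' the network mRNAs, and the group-wise correlation-pattern comparison —
#' writing every intermediate artifact to `config$out_dir` and returning a
#' manifest of files with MD5 checksums. Rerunning with identical inputs and
#' configuration reproduces identical checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest` (`data.frame` of stage, file,
#'   md5) and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  ind <- config$input_dir
  req <- .pipeline_inputs(ind)
  missing <- req[!file.exists(file.path(ind, req))]
  if (length(missing)) {
    stop("missing pipeline input(s): ",
         paste(file.path(ind, missing), collapse = ", "))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  emit <- function(stage, file) {
    manifest[nrow(manifest) + 1, ] <<- list(
      stage, basename(file), unname(tools::md5sum(file))
    )
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  groups <- read_sample_table(file.path(ind, "groups.tsv"))
  totals <- read_sample_table(file.path(ind, "mapped_totals.tsv"))

  ## stage 1: consensus circRNA detection and annotation
  res <- list()
  run_stage("circ_consensus", function() {
    read_dir <- function(sub, dialect) {
      files <- sort(list.files(file.path(ind, sub), full.names = TRUE))
      do.call(rbind, lapply(files, read_bsj_calls, dialect = dialect))
    }
    calls_a <- read_dir("calls_find_circ", "find_circ")
    calls_b <- read_dir("calls_circexplorer2", "circexplorer2")
    consensus <- intersect_callers(calls_a, calls_b,
                                   tolerance = config$consensus$tolerance)
    consensus <- filter_by_support(consensus, config$consensus)
    genes <- read_gene_models(file.path(ind, "gene_models.tsv"))
    consensus <- annotate_circ(consensus, genes)
    f <- file.path(out, "circ_consensus.tsv")
    utils::write.table(consensus$features, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("circ_consensus", f)
    f2 <- file.path(out, "caller_report.tsv")
    utils::write.table(caller_report(calls_a, calls_b,
                                     config$consensus$tolerance),
                       f2, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("circ_consensus", f2)
    res$consensus <<- consensus
  })

  ## stage 2: quantification
  run_stage("quantify", function() {
    em <- expression_matrix(res$consensus$counts, groups, totals)
    tpm <- bsj_tpm(em)
    f <- file.path(out, "circ_tpm.tsv")
    write_count_matrix(round(tpm$values, 4), f)
    emit("quantify", f)
    shift <- group_shift_test(tpm)
    excl <- exclusive_features(em, config$consensus)
    f2 <- file.path(out, "group_shift.tsv")
    utils::write.table(
      data.frame(t_statistic = shift$t_statistic, p_value = shift$p_value,
                 direction = shift$direction),
      f2, sep = "\t", quote = FALSE, row.names = FALSE
    )
    emit("quantify", f2)
    f3 <- file.path(out, "exclusive_case.txt")
    writeLines(excl$case_only, f3); emit("quantify", f3)
    f4 <- file.path(out, "exclusive_control.txt")
    writeLines(excl$control_only, f4); emit("quantify", f4)
    res$tpm <<- tpm; res$shift <<- shift; res$exclusive <<- excl
  })

  ## stage 3: differential expression (three classes)
  run_stage("diffexpr", function() {
    circ_em <- expression_matrix(res$consensus$counts, groups, totals)
    mi_em <- expression_matrix(read_count_matrix(file.path(ind, "counts_mirna.tsv")),
                               groups, totals)
    mr_em <- expression_matrix(read_count_matrix(file.path(ind, "counts_mrna.tsv")),
                               groups, totals)
    de <- list(circrna = nb_wald_test(circ_em, config$de_circ),
               mirna = nb_wald_test(mi_em, config$de_mirna),
               mrna = nb_wald_test(mr_em, config$de_mrna))
    for (cls in names(de)) {
      f <- file.path(out, paste0("de_", cls, ".tsv"))
      utils::write.table(de[[cls]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit("diffexpr", f)
    }
    res$de <<- de
  })

  ## stage 4: target prediction on differentially expressed molecules
  run_stage("target_predict", function() {
    de_ids <- function(cls) {
      d <- res$de[[cls]]
      d$feature_id[d$status != "NS"]
    }
    mirnas <- read_fasta(file.path(ind, "mirnas.fa"))
    circ_seqs <- read_fasta(file.path(ind, "circ_seqs.fa"))
    mrna_seqs <- read_fasta(file.path(ind, "mrna_seqs.fa"))
    mi <- mirnas[intersect(names(mirnas), de_ids("mirna"))]
    ci <- circ_seqs[intersect(names(circ_seqs), de_ids("circrna"))]
    mr <- mrna_seqs[intersect(names(mrna_seqs), de_ids("mrna"))]
    hits_circ <- predict_targets(mi, ci, config$target)
    hits_mrna <- predict_targets(mi, mr, config$target)
    f <- file.path(out, "hits_circ.tsv")
    utils::write.table(hits_circ, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("target_predict", f)
    f2 <- file.path(out, "hits_mrna.tsv")
    utils::write.table(hits_mrna, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("target_predict", f2)
    res$hits <<- list(circ = hits_circ, mrna = hits_mrna)
  })

  ## stage 5: network assembly under the inverse-expression constraint
  run_stage("network", function() {
    circ_mi <- inverse_filter(attach_status(res$hits$circ,
                                            res$de[c("mirna", "circrna")],
                                            target_class = "circRNA"))
    mi_mrna <- inverse_filter(attach_status(res$hits$mrna,
                                            res$de[c("mirna", "mrna")],
                                            target_class = "mRNA"))
    net <- assemble_triples(circ_mi, mi_mrna)
    f <- file.path(out, "network_edges.tsv")
    write_network(net, f, "edge_list_tsv")
    emit("network", f)
    f2 <- file.path(out, "network.graphml")
    write_network(net, f2, "graphml")
    emit("network", f2)
    s <- network_summary(net)
    f3 <- file.path(out, "network_summary.tsv")
    utils::write.table(data.frame(metric = names(s),
                                  value = unlist(s, use.names = FALSE)),
                       f3, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("network", f3)
    res$network <<- net
  })

  ## stage 6: gene-set enrichment of the network mRNAs
  run_stage("enrichment", function() {
    ann <- read_gene_sets(file.path(ind, "gene_sets.tsv"))
    expressed <- res$de$mrna$feature_id
    universe <- intersect(unique(ann$gene_id), expressed)
    query <- intersect(unique(res$network$triples$mrna_id), universe)
    enr <- if (length(query)) {
      hypergeom_enrich(query, ann, universe,
                       p_threshold = config$enrich_p,
                       fdr_threshold = config$enrich_fdr)
    } else {
      data.frame(term_id = character(), term_name = character(),
                 k = integer(), K = integer(), n = integer(), N = integer(),
                 p_value = numeric(), fdr = numeric(),
                 significant = logical(), stringsAsFactors = FALSE)
    }
    f <- file.path(out, "enrichment.tsv")
    utils::write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("enrichment", f)
    res$enrichment <<- enr
  })

  ## stage 7: group-wise correlation-pattern comparison
  run_stage("correlation", function() {
    mr_em <- expression_matrix(read_count_matrix(file.path(ind, "counts_mrna.tsv")),
                               groups, totals)
    mr_tpm <- bsj_tpm(mr_em)
    pairs <- unique(res$network$triples[, c("circ_id", "mrna_id")])
    if (nrow(pairs)) {
      pc <- correlation_pattern(res$tpm, mr_tpm, "case", pairs,
                                method = config$corr_method)
      pk <- correlation_pattern(res$tpm, mr_tpm, "control", pairs,
                                method = config$corr_method)
      div <- pattern_divergence(pc, pk)
      f <- file.path(out, "correlation_case.tsv")
      write_count_matrix(round(pc$matrix, 4), f, id_col = "circ_id")
      emit("correlation", f)
      f2 <- file.path(out, "correlation_control.tsv")
      write_count_matrix(round(pk$matrix, 4), f2, id_col = "circ_id")
      emit("correlation", f2)
      f3 <- file.path(out, "correlation_divergence.tsv")
      utils::write.table(
        data.frame(metric = names(div), value = unlist(div, use.names = FALSE)),
        f3, sep = "\t", quote = FALSE, row.names = FALSE
      )
      emit("correlation", f3)
      res$correlation <<- list(case = pc, control = pk, divergence = div)
    } else {
      f <- file.path(out, "correlation_divergence.tsv")
      utils::write.table(data.frame(metric = "n_pairs_compared", value = 0),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("correlation", f)
      res$correlation <<- NULL
    }
  })

  mf <- file.path(out, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, results = res))
}
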