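# Assembly of the differentially expressed circRNA-miRNA-mRNA network under
# the inverse-expression constraint, plus the summary counts used to report
# such networks.

#' Attach differential-expression statuses to predicted target edges
#'
#' Joins each predicted miRNA-target interaction to the Up/Down/NS status of
#' both endpoints and drops edges with any NS endpoint (only differentially
#' expressed molecules enter the network).
#'
#' @param hits `data.frame` of predicted interactions with columns
#'   `mirna_id`, `target_id` (and optionally `total_energy`, `position`,
#'   `target_class`).
#' @param de One or more differential-expression tables (a `data.frame` with
#'   `feature_id` and `status`, or a list of them covering the relevant RNA
#'   classes).
#' @param target_class Class label recorded for the target side when `hits`
#'   has no `target_class` column.
#' @return `data.frame` of status-annotated edges with columns `mirna_id`,
#'   `target_id`, `target_class`, `mirna_status`, `target_status`,
#'   `total_energy`, `position`.
#' @export
attach_status <- function(hits, de, target_class = "circRNA") {
  if (is.data.frame(de)) de <- list(de)
  status <- do.call(c, unname(lapply(de, function(d) {
    setNames(d$status, d$feature_id)
  })))
  need <- unique(c(hits$mirna_id, hits$target_id))
  missing <- setdiff(need, names(status))
  if (length(missing)) {
    stop("no differential-expression record for feature(s): ",
         paste(missing, collapse = ", "))
  }
  edges <- data.frame(
    mirna_id = hits$mirna_id,
    target_id = hits$target_id,
    target_class = if ("target_class" %in% names(hits)) hits$target_class else target_class,
    mirna_status = unname(status[hits$mirna_id]),
    target_status = unname(status[hits$target_id]),
    total_energy = if ("total_energy" %in% names(hits)) hits$total_energy else NA_real_,
    position = if ("position" %in% names(hits)) as.integer(hits$position) else NA_integer_,
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$mirna_status != "NS" & edges$target_status != "NS", ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Convert a miRNA-circRNA pair table to status-annotated edges
#'
#' The pair-table format (see [read_pair_table()]) already carries both
#' endpoints' statuses, so this is a column mapping.
#'
#' @param pairs `data.frame` from [read_pair_table()].
#' @return Status-annotated edge table as produced by [attach_status()].
#' @export
pair_table_edges <- function(pairs) {
  data.frame(
    mirna_id = pairs$mirna_id, target_id = pairs$circ_id,
    target_class = "circRNA", mirna_status = pairs$mirna_status,
    target_status = pairs$circ_status, total_energy = pairs$total_energy,
    position = pairs$position, stringsAsFactors = FALSE
  )
}

#' Retain only inversely expressed edges
#'
#' Keeps edges joining one up- and one down-regulated endpoint, the sponge
#' hypothesis's expectation for circRNA-miRNA (and miRNA-mRNA) pairs.
#' Idempotent.
#'
#' @param edges Status-annotated edge table (statuses `"Up"`/`"Down"`).
#' @return The discordant subset of `edges`.
#' @export
inverse_filter <- function(edges) {
  out <- edges[edges$mirna_status != edges$target_status, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble circRNA-miRNA-mRNA triples from the two bipartite layers
#'
#' For every miRNA present in both the circRNA-miRNA and miRNA-mRNA edge
#' sets, all (circRNA, miRNA, mRNA) combinations become triples. Edges and
#' nodes not participating in any triple are excluded from the network.
#'
#' @param circ_mi Status-annotated circRNA-miRNA edges.
#' @param mi_mrna Status-annotated miRNA-mRNA edges.
#' @return A list of class `cerna_network` with elements `circ_mi`,
#'   `mi_mrna`, `triples` (`circ_id`, `mirna_id`, `mrna_id`), and `nodes`
#'   (`id`, `class`, `status`).
#' @export
assemble_triples <- function(circ_mi, mi_mrna) {
  shared <- intersect(unique(circ_mi$mirna_id), unique(mi_mrna$mirna_id))
  cm <- circ_mi[circ_mi$mirna_id %in% shared, , drop = FALSE]
  mm <- mi_mrna[mi_mrna$mirna_id %in% shared, , drop = FALSE]
  rownames(cm) <- rownames(mm) <- NULL
  if (length(shared)) {
    triples <- merge(
      data.frame(mirna_id = cm$mirna_id, circ_id = cm$target_id,
                 stringsAsFactors = FALSE),
      data.frame(mirna_id = mm$mirna_id, mrna_id = mm$target_id,
                 stringsAsFactors = FALSE),
      by = "mirna_id"
    )[, c("circ_id", "mirna_id", "mrna_id")]
    triples <- unique(triples)
    triples <- triples[order(triples$circ_id, triples$mirna_id, triples$mrna_id), ,
                       drop = FALSE]
  } else {
    triples <- data.frame(circ_id = character(), mirna_id = character(),
                          mrna_id = character(), stringsAsFactors = FALSE)
  }
  rownames(triples) <- NULL
  nodes <- unique(rbind(
    data.frame(id = cm$target_id, class = rep("circRNA", nrow(cm)),
               status = cm$target_status, stringsAsFactors = FALSE),
    data.frame(id = cm$mirna_id, class = rep("miRNA", nrow(cm)),
               status = cm$mirna_status, stringsAsFactors = FALSE),
    data.frame(id = mm$mirna_id, class = rep("miRNA", nrow(mm)),
               status = mm$mirna_status, stringsAsFactors = FALSE),
    data.frame(id = mm$target_id, class = rep("mRNA", nrow(mm)),
               status = mm$target_status, stringsAsFactors = FALSE)
  ))
  nodes <- nodes[order(nodes$class, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(circ_mi = cm, mi_mrna = mm, triples = triples, nodes = nodes),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf(paste0("cerna_network: %d circRNAs, %d miRNAs, %d mRNAs; ",
                     "%d + %d edges, %d triples\n"),
              sum(x$nodes$class == "circRNA"), sum(x$nodes$class == "miRNA"),
              sum(x$nodes$class == "mRNA"), nrow(x$circ_mi), nrow(x$mi_mrna),
              nrow(x$triples)))
  invisible(x)
}

# round half away from zero, one decimal
.round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Summarise a set of network edges or an assembled network
#'
#' For an edge table: number of pairs, distinct miRNAs and distinct targets,
#' the percentage of status-discordant (opposite-direction) pairs to one
#' decimal, and the per-miRNA degree. For a `cerna_network`: distinct node
#' counts per class and the number of triples.
#'
#' @param x Status-annotated edge table or a `cerna_network`.
#' @return A list of summary counts.
#' @export
network_summary <- function(x) {
  if (inherits(x, "cerna_network")) {
    return(list(
      n_circ = sum(x$nodes$class == "circRNA"),
      n_mirna = sum(x$nodes$class == "miRNA"),
      n_mrna = sum(x$nodes$class == "mRNA"),
      n_circ_mi_edges = nrow(x$circ_mi),
      n_mi_mrna_edges = nrow(x$mi_mrna),
      n_triples = nrow(x$triples)
    ))
  }
  edges <- x
  deg <- sort(table(edges$mirna_id), decreasing = TRUE)
  opp <- edges$mirna_status != edges$target_status
  circ_targets <- if ("target_class" %in% names(edges)) {
    unique(edges$target_id[edges$target_class == "circRNA"])
  } else {
    unique(edges$target_id)
  }
  list(
    n_pairs = nrow(edges),
    n_distinct_mirna = length(unique(edges$mirna_id)),
    n_distinct_circ = length(circ_targets),
    pct_opposite = if (nrow(edges)) .round1(100 * mean(opp)) else NA_real_,
    n_up_mirna = length(unique(edges$mirna_id[edges$mirna_status == "Up"])),
    n_down_mirna = length(unique(edges$mirna_id[edges$mirna_status == "Down"])),
    n_up_target = length(unique(edges$target_id[edges$target_status == "Up"])),
    n_down_target = length(unique(edges$target_id[edges$target_status == "Down"])),
    mirna_degree = setNames(as.integer(deg), names(deg))
  )
}
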