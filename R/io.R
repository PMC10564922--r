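# File readers and writers for every external representation the pipeline
# touches. Genomic coordinates are 0-based half-open (BED convention)
# throughout; display identifiers keep the chr_start_end form verbatim from
# the input files.

#' Read back-spliced junction calls from a circRNA caller output table
#'
#' Parses the tabular output of one of the two supported circRNA callers into
#' a normalised table of back-spliced junction (BSJ) observations. Both
#' dialects are BED-derived and already 0-based half-open, so coordinates are
#' taken as printed; the dialect only determines which column carries the
#' junction-spanning read count:
#'
#' * `find_circ`: BED6-style, read support in column 5 (the score slot).
#' * `circexplorer2`: BED12-style annotation output, read support in
#'   column 13 (`readNumber`).
#'
#' These column maps are documented assumptions about the callers' default
#' output layout; callers were run elsewhere and their tables are inputs here.
#'
#' @param path Path to a whitespace- or tab-separated caller table.
#' @param dialect `"find_circ"` or `"circexplorer2"`.
#' @param sample_id Sample label attached to every call; defaults to the file
#'   name without its extension.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `junction_reads`, `caller`, `sample_id`. An empty file yields a
#'   zero-row table.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr17\t67945408\t67975958\tcirc1\t12\t+", f)
#' read_bsj_calls(f, "find_circ", sample_id = "P01")
#' @export
read_bsj_calls <- function(path, dialect = c("find_circ", "circexplorer2"),
                           sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), junction_reads = integer(),
    caller = character(), sample_id = character(),
    stringsAsFactors = FALSE
  )
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  read_col <- switch(dialect, find_circ = 5L, circexplorer2 = 13L)
  min_cols <- max(6L, read_col)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < min_cols) {
      stop(sprintf("line %d: expected at least %d columns for dialect '%s', got %d",
                   lineno[i], min_cols, dialect, length(f)))
    }
    if (!nzchar(f[1])) stop(sprintf("line %d: empty chromosome name", lineno[i]))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("line %d: non-integer coordinates '%s', '%s'", lineno[i], f[2], f[3]))
    }
    if (start >= end) {
      stop(sprintf("line %d: start (%d) must be less than end (%d)", lineno[i], start, end))
    }
    jr <- suppressWarnings(as.numeric(f[read_col]))
    if (is.na(jr) || jr < 0) {
      stop(sprintf("line %d: invalid junction read count '%s'", lineno[i], f[read_col]))
    }
    strand <- if (f[6] %in% c("+", "-")) f[6] else "."
    rows[[i]] <- data.frame(
      chrom = f[1], start = start, end = end, strand = strand,
      junction_reads = as.integer(round(jr)), caller = dialect,
      sample_id = sample_id, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a miRNA-circRNA pair table
#'
#' Reads a six-column TSV of predicted miRNA-circRNA interactions of the kind
#' published alongside plasma circRNA studies: miRNA identifier and
#' differential-expression status, circRNA identifier (`chr_start_end`) and
#' status, predicted duplex total energy (kcal/mol), and the 1-based site
#' position within the target. Status labels are normalised for case and
#' surrounding whitespace; both ASCII hyphen-minus and the typographic minus
#' sign are accepted in energy values.
#'
#' The package ships such a table under
#' `system.file("extdata", "veos_mirna_circ_pairs.tsv", package = "cernaforge")`:
#' the 24 miRNA-circRNA pairs reported in a plasma study of very early-onset
#' schizophrenia (10 cases, 8 controls), used as a worked example.
#'
#' @param path Path to a tab-separated file with header columns `mirna_id`,
#'   `mirna_status`, `circ_id`, `circ_status`, `total_energy`, `position`.
#' @return A `data.frame` with those six columns; statuses are `"Up"`/`"Down"`,
#'   `total_energy` numeric, `position` integer.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("mirna_id", "mirna_status", "circ_id", "circ_status",
            "total_energy", "position")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pair table is missing column(s): ", paste(miss, collapse = ", "))
  norm_status <- function(x, col) {
    x <- tolower(trimws(x))
    bad <- setdiff(unique(x), c("up", "down"))
    if (length(bad)) {
      stop("unknown status label(s) in ", col, ": ", paste(bad, collapse = ", "))
    }
    ifelse(x == "up", "Up", "Down")
  }
  en <- gsub("\u2212", "-", trimws(as.character(df$total_energy)))
  en_num <- suppressWarnings(as.numeric(en))
  if (any(is.na(en_num))) {
    stop("non-numeric total_energy value(s): ",
         paste(unique(en[is.na(en_num)]), collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$position))
  if (any(is.na(pos) | pos < 1)) stop("position must be a positive integer")
  out <- data.frame(
    mirna_id = trimws(df$mirna_id),
    mirna_status = norm_status(df$mirna_status, "mirna_status"),
    circ_id = trimws(df$circ_id),
    circ_status = norm_status(df$circ_status, "circ_status"),
    total_energy = en_num,
    position = pos,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a feature-by-sample count or expression matrix from TSV
#'
#' First column holds feature identifiers, remaining columns one sample each.
#'
#' @param path Path to a TSV file with a header row.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("count matrix needs a feature column and at least one sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param m Matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @param id_col Name for the feature-identifier column.
#' @export
write_count_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample annotation table into a named vector
#'
#' Used for group labels (`sample`, `group`) and per-sample mapped-read
#' totals (`sample`, `mapped_reads`).
#'
#' @param path Path to a two-column TSV with header.
#' @return Named vector (names = sample IDs).
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("sample table needs two columns")
  setNames(df[[2]], as.character(df[[1]]))
}

#' Read sequences from a FASTA file
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of upper-case sequences; names are truncated
#'   at the first whitespace.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a GTF-lite gene model table
#'
#' One row per exon, tab-separated with header columns `gene_id`, `gene_type`,
#' `transcript_id`, `chrom`, `strand`, `exon_start`, `exon_end` (0-based
#' half-open). This deliberately compact format replaces the full GTF
#' attribute grammar.
#'
#' @param path Path to the table.
#' @return `data.frame` with the seven columns above.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "gene_type", "transcript_id", "chrom", "strand",
            "exon_start", "exon_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene model table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$exon_start >= df$exon_end)) stop("gene models contain invalid exon intervals")
  df[need]
}

#' Read a gene-set annotation table
#'
#' Long-format table mapping terms to genes: columns `term_id`, `term_name`,
#' `gene_id`.
#'
#' @param path Path to the table.
#' @return `data.frame` with the three columns above.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("term_id", "term_name", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene set table missing column(s): ", paste(miss, collapse = ", "))
  df[need]
}

# Flatten a ceRNA network into a single edge table (miRNA always the `from`
# endpoint so the two bipartite layers share one schema).
network_edges <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  layer <- function(edges, class) {
    if (is.null(edges) || !nrow(edges)) return(NULL)
    data.frame(
      from = edges$mirna_id, to = edges$target_id,
      from_class = "miRNA", to_class = class,
      from_status = edges$mirna_status, to_status = edges$target_status,
      total_energy = edges$total_energy, position = edges$position,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(layer(network$circ_mi, "circRNA"), layer(network$mi_mrna, "mRNA"))
  if (is.null(out)) {
    out <- data.frame(
      from = character(), to = character(), from_class = character(),
      to_class = character(), from_status = character(), to_status = character(),
      total_energy = numeric(), position = integer(), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

.network_from_edge_table <- function(edges) {
  mk <- function(sub, class) {
    data.frame(
      mirna_id = sub$from, target_id = sub$to, target_class = class,
      mirna_status = sub$from_status, target_status = sub$to_status,
      total_energy = sub$total_energy, position = as.integer(sub$position),
      stringsAsFactors = FALSE
    )
  }
  circ_mi <- mk(edges[edges$to_class == "circRNA", , drop = FALSE], "circRNA")
  mi_mrna <- mk(edges[edges$to_class == "mRNA", , drop = FALSE], "mRNA")
  assemble_triples(circ_mi, mi_mrna)
}

#' Convert a ceRNA network to an igraph object
#'
#' Vertices carry `class` (circRNA/miRNA/mRNA) and `status` (Up/Down)
#' attributes; edges carry duplex energy and site position.
#'
#' @param network A `cerna_network` (see [assemble_triples()]).
#' @return An [igraph::igraph] graph.
#' @export
as_igraph <- function(network) {
  edges <- network_edges(network)
  nodes <- network$nodes
  if (is.null(nodes) || !nrow(nodes)) {
    ids <- unique(c(edges$from, edges$to))
    cls <- ifelse(ids %in% edges$from, "miRNA",
                  edges$to_class[match(ids, edges$to)])
    st <- ifelse(ids %in% edges$from,
                 edges$from_status[match(ids, edges$from)],
                 edges$to_status[match(ids, edges$to)])
    nodes <- data.frame(id = ids, class = cls, status = st,
                        stringsAsFactors = FALSE)
  }
  # directed miRNA -> target so endpoint roles survive serialisation
  igraph::graph_from_data_frame(
    edges[, c("from", "to", "to_class", "from_status", "to_status",
              "total_energy", "position")],
    directed = TRUE, vertices = nodes
  )
}

#' Write a ceRNA network to file
#'
#' Supported formats round-trip: [read_network()] on the written file yields
#' an identical edge set with identical node classes and statuses.
#'
#' @param network A `cerna_network`.
#' @param path Output path.
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edge_list_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_list_tsv") {
    utils::write.table(network_edges(network), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Read a ceRNA network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @return A `cerna_network`.
#' @export
read_network <- function(path, format = c("edge_list_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_list_tsv") {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(
      from = el$from, to = el$to, from_class = "miRNA",
      to_class = el$to_class, from_status = el$from_status,
      to_status = el$to_status, total_energy = el$total_energy,
      position = as.integer(el$position), stringsAsFactors = FALSE
    )
  }
  .network_from_edge_table(edges)
}
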