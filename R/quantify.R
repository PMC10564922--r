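# BSJ-TPM normalisation, global group-shift comparison, fold changes, and
# group-exclusive expression detection.

#' Construct an expression matrix with sample metadata
#'
#' Couples a feature-by-sample value matrix with group labels, optional
#' per-sample total mapped-read counts, and the unit of its values so that
#' the unit is tracked through every transform.
#'
#' @param values Numeric matrix, features x samples (colnames required).
#' @param groups Named vector mapping each sample to `"case"` or `"control"`.
#' @param mapped_totals Optional named vector of per-sample total mapped
#'   reads; must be positive.
#' @param unit `"raw_count"` or `"tpm"`.
#' @return A list of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups, mapped_totals = NULL,
                              unit = c("raw_count", "tpm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have sample colnames")
  g <- groups[colnames(values)]
  if (any(is.na(g))) {
    stop("groups missing for sample(s): ",
         paste(colnames(values)[is.na(g)], collapse = ", "))
  }
  if (!all(g %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  if (!is.null(mapped_totals)) {
    mapped_totals <- mapped_totals[colnames(values)]
    if (any(is.na(mapped_totals) | mapped_totals <= 0)) {
      stop("mapped_totals must be positive for every sample")
    }
  }
  structure(list(values = values, groups = g, mapped_totals = mapped_totals,
                 unit = unit), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d features x %d samples (%d case / %d control)\n",
              x$unit, nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

.group_cols <- function(em, group) which(em$groups == group)

#' Normalise back-spliced junction reads to reads per million mapped reads
#'
#' `tpm[i, s] = counts[i, s] / mapped_totals[s] * 1e6`. This is the standard
#' per-million normalisation of junction-spanning read counts (here called
#' TPM after the field's convention for circRNA abundance; no transcript
#' length enters because the junction is a point feature).
#'
#' @param counts An `expression_matrix` with unit `"raw_count"` and
#'   `mapped_totals` set.
#' @return An `expression_matrix` with unit `"tpm"`.
#' @export
bsj_tpm <- function(counts) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "raw_count") stop("input must be in raw counts")
  if (is.null(counts$mapped_totals)) stop("mapped_totals are required for TPM normalisation")
  tpm <- sweep(counts$values, 2, counts$mapped_totals, "/") * 1e6
  expression_matrix(tpm, counts$groups, counts$mapped_totals, unit = "tpm")
}

#' Test for a global shift in circRNA abundance between groups
#'
#' Computes each feature's average expression per group, log10-transforms
#' with a pseudocount of 1 (mirroring the usual density-curve comparison of
#' per-feature group means), and compares the two per-feature mean
#' distributions with Welch's two-sample t-test. The direction is reported
#' only when the test is significant at `alpha`.
#'
#' @param tpm An `expression_matrix` in TPM units.
#' @param alpha Significance level gating the reported direction.
#' @return A list of class `group_shift_result` with `t_statistic`,
#'   `p_value`, `direction` (`"case_lower"`, `"case_higher"`, `"none"`), and
#'   the per-group mean vectors.
#' @export
group_shift_test <- function(tpm, alpha = 0.05) {
  stopifnot(inherits(tpm, "expression_matrix"))
  if (nrow(tpm$values) < 2) stop("need at least two features for the group-shift test")
  ic <- .group_cols(tpm, "case"); ik <- .group_cols(tpm, "control")
  if (!length(ic) || !length(ik)) stop("both groups must be non-empty")
  mc <- rowMeans(tpm$values[, ic, drop = FALSE])
  mk <- rowMeans(tpm$values[, ik, drop = FALSE])
  x <- log10(mc + 1); y <- log10(mk + 1)
  tt <- stats::t.test(x, y)
  direction <- "none"
  if (is.finite(tt$p.value) && tt$p.value < alpha && mean(x) != mean(y)) {
    direction <- if (mean(x) < mean(y)) "case_lower" else "case_higher"
  }
  structure(list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 direction = direction, case_means = mc, control_means = mk),
            class = "group_shift_result")
}

#' Detect group-exclusively expressed features
#'
#' A feature is exclusive to a group when it passes the support rule within
#' that group (at least `config$min_reads` reads in strictly more than half
#' of that group's samples) and has zero counts in every sample of the other
#' group. The two sets are disjoint by construction.
#'
#' @param counts An `expression_matrix` of raw counts.
#' @param config A [consensus_config()] supplying `min_reads`.
#' @return List with character vectors `case_only` and `control_only`.
#' @export
exclusive_features <- function(counts, config = consensus_config()) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "raw_count") stop("exclusive expression is defined on raw counts")
  v <- counts$values
  ic <- .group_cols(counts, "case"); ik <- .group_cols(counts, "control")
  support <- function(cols) {
    rowSums(v[, cols, drop = FALSE] >= config$min_reads) > length(cols) / 2
  }
  zero_in <- function(cols) rowSums(v[, cols, drop = FALSE] > 0) == 0
  case_only <- support(ic) & zero_in(ik)
  control_only <- support(ik) & zero_in(ic)
  list(case_only = rownames(v)[case_only],
       control_only = rownames(v)[control_only])
}

#' Per-feature log2 fold change (case vs control)
#'
#' `log2((mean_case + eps) / (mean_control + eps))`. The pseudocount keeps
#' exclusively expressed features finite while ranking them extreme.
#'
#' @param tpm An `expression_matrix` (typically TPM).
#' @param pseudocount Positive pseudocount `eps` (default 0.01).
#' @return Named numeric vector of log2 fold changes.
#' @export
log2fc <- function(tpm, pseudocount = 0.01) {
  stopifnot(inherits(tpm, "expression_matrix"), pseudocount > 0)
  mc <- rowMeans(tpm$values[, .group_cols(tpm, "case"), drop = FALSE])
  mk <- rowMeans(tpm$values[, .group_cols(tpm, "control"), drop = FALSE])
  setNames(log2((mc + pseudocount) / (mk + pseudocount)), rownames(tpm$values))
}
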