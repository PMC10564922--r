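# Self-contained negative-binomial Wald differential expression:
# median-of-ratios size factors, per-feature NB GLM with a group covariate
# and log size-factor offset, Cox-Reid-adjusted profile-likelihood dispersion,
# Wald z-test with BH adjustment, and the fold-change/p-value status rule.

#' Differential-expression configuration
#'
#' Class-specific low-count prefilters follow the usual plasma RNA-seq
#' convention (mean raw count of at least 5 for mRNA, 2 for circRNA, 50 for
#' miRNA). Significance combines a linear fold-change gate with a raw
#' p-value gate; the Benjamini-Hochberg adjusted p-value is always reported
#' alongside but does not gate the call.
#'
#' @param class RNA class, one of `"mrna"`, `"circrna"`, `"mirna"`; sets the
#'   default prefilter.
#' @param prefilter_min_count Minimum mean raw count across all samples for a
#'   feature to be tested; overrides the class default when given.
#' @param fc_threshold Fold-change threshold (default 1.5). Interpreted on
#'   the linear scale unless `fc_scale = "log2"`.
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param pseudocount Pseudocount used where fold changes are computed from
#'   normalised means.
#' @param fc_scale `"linear"` (Up iff FC > `fc_threshold`) or `"log2"`
#'   (Up iff log2 FC > `fc_threshold`).
#' @return A list of class `de_config`.
#' @export
de_config <- function(class = c("mrna", "circrna", "mirna"),
                      prefilter_min_count = NULL,
                      fc_threshold = 1.5, p_threshold = 0.05,
                      pseudocount = 0.01,
                      fc_scale = c("linear", "log2")) {
  class <- match.arg(class)
  fc_scale <- match.arg(fc_scale)
  if (is.null(prefilter_min_count)) {
    prefilter_min_count <- c(mrna = 5, circrna = 2, mirna = 50)[[class]]
  }
  stopifnot(prefilter_min_count > 0, fc_threshold > 0, p_threshold > 0,
            pseudocount > 0)
  structure(list(class = class, prefilter_min_count = prefilter_min_count,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 pseudocount = pseudocount, fc_scale = fc_scale),
            class = "de_config")
}

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median ratio of its counts to the per-feature
#' geometric-mean reference, computed over features observed in every sample;
#' factors are then normalised to geometric mean 1. When no feature is
#' nonzero in all samples (common for sparse circRNA matrices) the function
#' falls back to library-size ratios with a warning.
#'
#' @param counts Feature-by-sample matrix of raw counts.
#' @return Named vector of positive size factors with geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (!nrow(counts) || all(counts == 0)) stop("cannot compute size factors of an all-zero matrix")
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  ok <- is.finite(loggeo)
  if (any(ok)) {
    sf <- apply(logc[ok, , drop = FALSE], 2, function(lc) {
      exp(stats::median(lc - loggeo[ok]))
    })
  } else {
    warning("no feature observed in every sample; falling back to library-size ratios")
    sf <- colSums(counts)
  }
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors; check the count matrix")
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

# One IRLS pass for an NB GLM with log link, fixed dispersion alpha,
# design X = [1, group], and offset `off`. Returns NULL on failure.
.nb_irls <- function(y, X, off, alpha, beta) {
  mu <- NULL; A <- NULL
  for (it in 1:50) {
    eta <- pmin(pmax(off + drop(X %*% beta), -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    Xw <- X * w
    A <- crossprod(Xw, X)
    z <- (eta - off) + (y - mu) / mu
    newb <- tryCatch(solve(A, crossprod(Xw, z)), error = function(e) NULL)
    if (is.null(newb)) return(NULL)
    delta <- max(abs(newb - beta))
    beta <- drop(newb)
    if (delta < 1e-8) break
  }
  eta <- pmin(pmax(off + drop(X %*% beta), -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  A <- crossprod(X * w, X)
  list(beta = beta, mu = mu, info = A)
}

# Fit one feature: profile the Cox-Reid-adjusted NB likelihood over log
# dispersion (beta refit by IRLS at each dispersion), then report the Wald
# statistic for the group coefficient.
.nb_fit_feature <- function(y, x, off) {
  X <- cbind(intercept = 1, group = x)
  s <- exp(off)
  m0 <- mean(y[x == 0] / s[x == 0]); m1 <- mean(y[x == 1] / s[x == 1])
  beta_init <- c(log(max(m0, 1e-8)), log(max(m1, 1e-8)) - log(max(m0, 1e-8)))
  nll <- function(la) {
    a <- exp(la)
    fit <- .nb_irls(y, X, off, a, beta_init)
    if (is.null(fit)) return(1e10)
    ll <- sum(stats::dnbinom(y, size = 1 / a, mu = pmax(fit$mu, 1e-12), log = TRUE))
    cr <- 0.5 * as.numeric(determinant(fit$info, logarithm = TRUE)$modulus)
    -(ll - cr)
  }
  opt <- tryCatch(stats::optimize(nll, c(log(1e-8), log(1e3)), tol = 1e-3),
                  error = function(e) NULL)
  alpha <- if (!is.null(opt)) exp(opt$minimum) else NA_real_
  if (is.na(alpha)) {
    # moment fallback: alpha from pooled mean/variance of normalised counts
    yn <- y / s
    v <- stats::var(yn); m <- mean(yn)
    alpha <- max((v - m) / max(m^2, 1e-8), 1e-8)
  }
  fit <- .nb_irls(y, X, off, alpha, beta_init)
  if (is.null(fit)) {
    return(list(converged = FALSE, beta1 = NA_real_, se = NA_real_,
                alpha = alpha))
  }
  se <- tryCatch(sqrt(solve(fit$info)[2, 2]), error = function(e) NA_real_)
  list(converged = is.finite(se), beta1 = fit$beta[2], se = se, alpha = alpha)
}

#' Negative-binomial Wald differential expression test
#'
#' For every feature passing the low-count prefilter, fits a
#' negative-binomial GLM with a case/control covariate and log size-factor
#' offset. The dispersion is estimated per feature by maximising the
#' Cox-Reid-adjusted profile likelihood (with a moment-based fallback); the
#' group coefficient is tested with a two-sided Wald z-test, and
#' Benjamini-Hochberg adjusted p-values are reported alongside the raw ones.
#' Features whose fit does not converge are flagged (`NA` p-value, status
#' `"NS"`). There is no information sharing across features, so results
#' approximate rather than replicate shrinkage-based DE tools.
#'
#' @param counts An [expression_matrix()] of raw counts; both groups need at
#'   least two samples.
#' @param config A [de_config()].
#' @return `data.frame` with columns `feature_id`, `base_mean`, `log2fc`,
#'   `lfc_se`, `wald_statistic`, `p_value`, `adjusted_p`, `status`
#'   (see [call_status()]). The log2 fold change is case vs control.
#' @export
nb_wald_test <- function(counts, config = de_config()) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "raw_count") stop("differential expression requires raw counts")
  x <- as.integer(counts$groups == "case")
  if (sum(x) < 2 || sum(1 - x) < 2) stop("each group needs at least two samples")
  v <- round(counts$values)
  keep <- rowMeans(v) >= config$prefilter_min_count
  if (!any(keep)) stop("no features pass the prefilter")
  v <- v[keep, , drop = FALSE]
  sf <- size_factors(v)
  off <- log(sf)
  norm <- sweep(v, 2, sf, "/")
  fits <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    fits[[i]] <- tryCatch(.nb_fit_feature(v[i, ], x, off),
                          error = function(e) list(converged = FALSE,
                                                   beta1 = NA_real_,
                                                   se = NA_real_,
                                                   alpha = NA_real_))
  }
  beta1 <- vapply(fits, `[[`, numeric(1), "beta1")
  se <- vapply(fits, `[[`, numeric(1), "se")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  wald <- ifelse(conv, beta1 / se, NA_real_)
  # Wald statistic referred to a t distribution with residual degrees of
  # freedom: without cross-feature dispersion shrinkage the normal reference
  # is anti-conservative at these sample sizes
  p <- ifelse(conv, 2 * stats::pt(-abs(wald), df = ncol(v) - 2), NA_real_)
  res <- data.frame(
    feature_id = rownames(v),
    base_mean = rowMeans(norm),
    log2fc = beta1 / log(2),
    lfc_se = se / log(2),
    wald_statistic = wald,
    p_value = p,
    adjusted_p = stats::p.adjust(p, method = "BH"),
    dispersion = vapply(fits, `[[`, numeric(1), "alpha"),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  call_status(res, config)
}

#' Assign Up/Down/NS status to differential-expression records
#'
#' Up requires a linear fold change above `fc_threshold` and raw p-value
#' below `p_threshold`; Down requires the reciprocal fold change; everything
#' else (including non-converged fits) is NS. With `fc_scale = "log2"` the
#' threshold is applied on the log2 scale instead.
#'
#' @param records `data.frame` with columns `log2fc` and `p_value`.
#' @param config A [de_config()].
#' @return `records` with a `status` column of `"Up"`, `"Down"`, `"NS"`.
#' @export
call_status <- function(records, config = de_config()) {
  lfc <- records$log2fc
  p <- records$p_value
  if (config$fc_scale == "linear") {
    up <- 2^lfc > config$fc_threshold
    dn <- 2^lfc < 1 / config$fc_threshold
  } else {
    up <- lfc > config$fc_threshold
    dn <- lfc < -config$fc_threshold
  }
  sig <- !is.na(p) & !is.na(lfc) & p < config$p_threshold
  records$status <- ifelse(sig & up, "Up", ifelse(sig & dn, "Down", "NS"))
  records
}
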