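# Seed-anchored miRNA target-site discovery with a nearest-neighbour duplex
# free-energy gate. This is a seed-scan / energy-extension re-implementation
# in the miRanda family, not a port: site positions and the -20 kcal/mol
# gate are the contract, not numerical equality with any particular tool.

#' Target-prediction configuration
#'
#' @param energy_threshold Maximum (i.e. least negative) duplex total energy
#'   in kcal/mol for a site to be reported (default -20).
#' @param seed_start,seed_end miRNA seed region, 1-based positions 2-8 by
#'   default.
#' @param max_wobble Maximum number of G:U wobble pairs tolerated inside the
#'   seed match (default 1); mismatches and gaps are not allowed in the seed.
#' @return A list of class `target_config`.
#' @export
target_config <- function(energy_threshold = -20, seed_start = 2L,
                          seed_end = 8L, max_wobble = 1L) {
  stopifnot(energy_threshold < 0, seed_start >= 1, seed_end > seed_start,
            max_wobble >= 0)
  structure(list(energy_threshold = energy_threshold,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 max_wobble = as.integer(max_wobble)),
            class = "target_config")
}

.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

.norm_rna <- function(s) chartr("Tt", "Uu", toupper(s))

#' Reverse complement of an RNA sequence
#'
#' @param s RNA (or DNA; T is converted to U) sequence string.
#' @return Reverse-complemented RNA string.
#' @export
rc_rna <- function(s) {
  ch <- strsplit(.norm_rna(s), "")[[1]]
  paste(rev(unname(.RNA_COMP[ch])), collapse = "")
}

# Base-pair type for miRNA base m against target base t; NA when unpaired.
.pair_type <- function(m, t) {
  p <- paste0(m, t)
  ifelse(p %in% c("AU", "UA", "CG", "GC", "GU", "UG"), p, NA_character_)
}

#' Nearest-neighbour RNA duplex parameters
#'
#' Stacking free energies (kcal/mol, 37 degrees C) for adjacent base pairs in
#' an RNA:RNA duplex, keyed `"<pair1><pair2>"` where each pair is written
#' miRNA-base then target-base and pair 2 is the 3'-adjacent pair on the
#' miRNA strand. Watson-Crick/Watson-Crick stacks follow the published
#' individual-nearest-neighbour parameter set of Xia et al. (Biochemistry
#' 1998); stacks containing G:U wobbles use a condensed two-value
#' approximation (-1.1 for a single wobble, -0.3 for tandem wobbles) rather
#' than the full sequence-dependent wobble tables. Loop terms: `init` is the
#' duplex initiation penalty, `bulge1` the single-nucleotide bulge penalty
#' (stacking across the bulge is retained), `loop11` the 1x1 internal-loop
#' penalty (no stacking across).
#'
#' @return List with `stack` (named numeric vector over all 36 pair
#'   combinations), `init`, `bulge1`, `loop11`.
#' @export
nn_parameters <- function() .NN

.make_nn <- function() {
  wc <- c("AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33,
          "CU/GA" = -2.08, "CA/GU" = -2.11, "GU/CA" = -2.24,
          "GA/CU" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26,
          "GC/CG" = -3.42)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  wobble <- c("GU", "UG")
  stack <- numeric(0)
  for (p1 in pairs) for (p2 in pairs) {
    x <- substr(p1, 1, 1); z <- substr(p1, 2, 2)
    y <- substr(p2, 1, 1); w <- substr(p2, 2, 2)
    key <- paste0(x, y, "/", z, w)
    sym <- paste0(w, z, "/", y, x)
    n_wob <- (p1 %in% wobble) + (p2 %in% wobble)
    val <- if (n_wob == 0) {
      if (key %in% names(wc)) wc[[key]] else wc[[sym]]
    } else if (n_wob == 1) -1.1 else -0.3
    stack[paste0(p1, p2)] <- val
  }
  list(stack = stack, init = 4.09, bulge1 = 3.8, loop11 = 1.5)
}

.NN <- .make_nn()

.stack_dg <- function(p1, p2) .NN$stack[[paste0(p1, p2)]]

#' Scan a target sequence for miRNA seed-complementary sites
#'
#' Reports every 1-based target offset where the window pairs, antiparallel,
#' with the miRNA seed (positions `seed_start`..`seed_end`, 5'->3') using
#' Watson-Crick pairs plus at most `max_wobble` G:U wobbles; no mismatches
#' or gaps are allowed at this stage. All overlapping candidates are
#' returned; energy filtering happens later.
#'
#' @param mirna_seq,target_seq RNA strings (T is converted to U).
#' @param config A [target_config()].
#' @return Integer vector of candidate seed-window start offsets (position of
#'   the target base paired with the seed's 3'-most miRNA base).
#' @export
scan_sites <- function(mirna_seq, target_seq, config = target_config()) {
  m <- strsplit(.norm_rna(mirna_seq), "")[[1]]
  t <- strsplit(.norm_rna(target_seq), "")[[1]]
  k <- config$seed_end - config$seed_start + 1
  if (length(m) < config$seed_end || length(t) < k) return(integer(0))
  n_win <- length(t) - k + 1
  all_ok <- rep(TRUE, n_win)
  n_wob <- rep(0L, n_win)
  for (d in 0:(k - 1)) {
    # target base at offset j + d pairs miRNA seed base seed_end - d
    mb <- m[config$seed_end - d]
    tb <- t[(1 + d):(n_win + d)]
    wc_ok <- tb == .RNA_COMP[[mb]]
    wob_ok <- (mb == "G" & tb == "U") | (mb == "U" & tb == "G")
    all_ok <- all_ok & (wc_ok | wob_ok)
    n_wob <- n_wob + as.integer(wob_ok & !wc_ok)
  }
  which(all_ok & n_wob <= config$max_wobble)
}

# Dynamic-programming extension of the duplex beyond the seed towards the
# miRNA 3' end (target 5' direction). Allows stacked pairs, single-nucleotide
# bulges on either strand (stacking retained across the bulge), and 1x1
# internal loops. Returns the best (most negative) extension energy, the
# 5'-most target index it reaches, and the number of pairs added.
.extend3 <- function(m, t, j, seed_end_pair, config) {
  L <- length(m)
  if (L <= config$seed_end || j <= 1) {
    return(list(energy = 0, jmin = j, npairs = 0L))
  }
  i0 <- config$seed_end
  imax <- L
  jmin_lim <- max(1L, j - (L - i0) - 3L)
  width <- j - jmin_lim           # target indices jmin_lim .. j-1
  if (width < 1) return(list(energy = 0, jmin = j, npairs = 0L))
  ii <- function(i) i - i0        # 1..L-i0
  jj <- function(jt) j - jt       # 1..width
  E <- matrix(Inf, nrow = L - i0, ncol = width)
  NP <- matrix(0L, nrow = L - i0, ncol = width)
  pairm <- matrix(NA_character_, nrow = L - i0, ncol = width)
  best <- list(energy = 0, jmin = j, npairs = 0L)
  for (i in (i0 + 1):L) {
    for (jt in (j - 1):jmin_lim) {
      cur <- .pair_type(m[i], t[jt])
      if (is.na(cur)) next
      e <- Inf; np <- 0L
      # stacked from (i-1, jt+1)
      if (i == i0 + 1 && jt == j - 1) {
        cand <- .stack_dg(seed_end_pair, cur)
        if (cand < e) { e <- cand; np <- 1L }
      } else if (i > i0 + 1 && jt + 1 <= j - 1) {
        pe <- E[ii(i - 1), jj(jt + 1)]
        if (is.finite(pe)) {
          cand <- pe + .stack_dg(pairm[ii(i - 1), jj(jt + 1)], cur)
          if (cand < e) { e <- cand; np <- NP[ii(i - 1), jj(jt + 1)] + 1L }
        }
      }
      # miRNA bulge from (i-2, jt+1): miRNA base i-1 unpaired
      if (i == i0 + 2 && jt == j - 1) {
        cand <- .NN$bulge1 + .stack_dg(seed_end_pair, cur)
        if (cand < e) { e <- cand; np <- 1L }
      } else if (i > i0 + 2 && jt + 1 <= j - 1) {
        pe <- E[ii(i - 2), jj(jt + 1)]
        if (is.finite(pe)) {
          cand <- pe + .NN$bulge1 + .stack_dg(pairm[ii(i - 2), jj(jt + 1)], cur)
          if (cand < e) { e <- cand; np <- NP[ii(i - 2), jj(jt + 1)] + 1L }
        }
      }
      # target bulge from (i-1, jt+2): target base jt+1 unpaired
      if (i == i0 + 1 && jt == j - 2) {
        cand <- .NN$bulge1 + .stack_dg(seed_end_pair, cur)
        if (cand < e) { e <- cand; np <- 1L }
      } else if (i > i0 + 1 && jt + 2 <= j - 1) {
        pe <- E[ii(i - 1), jj(jt + 2)]
        if (is.finite(pe)) {
          cand <- pe + .NN$bulge1 + .stack_dg(pairm[ii(i - 1), jj(jt + 2)], cur)
          if (cand < e) { e <- cand; np <- NP[ii(i - 1), jj(jt + 2)] + 1L }
        }
      }
      # 1x1 internal loop from (i-2, jt+2)
      if (i == i0 + 2 && jt == j - 2) {
        cand <- .NN$loop11
        if (cand < e) { e <- cand; np <- 1L }
      } else if (i > i0 + 2 && jt + 2 <= j - 1) {
        pe <- E[ii(i - 2), jj(jt + 2)]
        if (is.finite(pe)) {
          cand <- pe + .NN$loop11
          if (cand < e) { e <- cand; np <- NP[ii(i - 2), jj(jt + 2)] + 1L }
        }
      }
      if (!is.finite(e)) next
      E[ii(i), jj(jt)] <- e
      NP[ii(i), jj(jt)] <- np
      pairm[ii(i), jj(jt)] <- cur
      if (e < best$energy ||
          (e == best$energy && jt < best$jmin)) {
        best <- list(energy = e, jmin = jt, npairs = np)
      }
    }
  }
  best
}

#' Total duplex free energy at a candidate seed site
#'
#' Builds a local miRNA:target hybrid anchored at the seed match and extends
#' it by banded dynamic programming towards the miRNA 3' end (allowing
#' single-nucleotide bulges with retained cross-bulge stacking and 1x1
#' internal loops) and by one pair at miRNA position 1. The energy is the
#' duplex initiation penalty plus the sum of nearest-neighbour stack terms
#' and loop penalties from [nn_parameters()]; more negative is more stable.
#' Extensions are only included when they lower the energy.
#'
#' @param mirna_seq,target_seq RNA strings.
#' @param position A candidate offset from [scan_sites()].
#' @param config A [target_config()].
#' @return List with `total_energy` (kcal/mol), `position` (1-based offset of
#'   the 5'-most paired target base), and `n_paired` bases.
#' @export
duplex_energy <- function(mirna_seq, target_seq, position,
                          config = target_config()) {
  m <- strsplit(.norm_rna(mirna_seq), "")[[1]]
  t <- strsplit(.norm_rna(target_seq), "")[[1]]
  j <- as.integer(position)
  k <- config$seed_end - config$seed_start + 1
  if (j < 1 || j + k - 1 > length(t)) stop("position out of range for the target")
  # seed pairs: miRNA base seed_start + d pairs target base j + (k - 1 - d)
  seed_pairs <- character(k)
  for (d in 0:(k - 1)) {
    sp <- .pair_type(m[config$seed_start + d], t[j + k - 1 - d])
    if (is.na(sp)) stop("position is not a seed-complementary site")
    seed_pairs[d + 1] <- sp
  }
  e <- .NN$init
  for (d in seq_len(k - 1)) e <- e + .stack_dg(seed_pairs[d], seed_pairs[d + 1])
  npairs <- k
  # pairs are listed 5'->3' on the miRNA; the seed's 3'-most pair closes at
  # target index j, from where the 3' extension proceeds
  ext <- .extend3(m, t, j, seed_pairs[k], config)
  pos5 <- j
  if (ext$energy < 0) {
    e <- e + ext$energy
    npairs <- npairs + ext$npairs
    pos5 <- ext$jmin
  }
  # one optional pair at miRNA position seed_start - 1 (typically position 1)
  if (config$seed_start > 1) {
    j1 <- j + k
    if (j1 <= length(t)) {
      p1 <- .pair_type(m[config$seed_start - 1], t[j1])
      if (!is.na(p1)) {
        dg <- .stack_dg(p1, seed_pairs[1])
        if (dg < 0) { e <- e + dg; npairs <- npairs + 1L }
      }
    }
  }
  list(total_energy = e, position = pos5, n_paired = npairs)
}

#' Predict miRNA target sites across sequence sets
#'
#' For every (miRNA, target) pair: scan for seed-complementary candidate
#' sites, compute the duplex total energy at each, keep the best-energy site
#' (ties broken by the smallest position), and report the pair only when
#' that energy is at or below `config$energy_threshold`. Output ordering is
#' deterministic (miRNA id, then target id).
#'
#' @param mirnas,targets Named character vectors of RNA sequences, or paths
#'   to FASTA files.
#' @param config A [target_config()].
#' @return `data.frame` of class `duplex_hits` with columns `mirna_id`,
#'   `target_id`, `position` (1-based offset of the site's 5'-most paired
#'   target base), `alignment_score` (number of paired bases), and
#'   `total_energy` (kcal/mol). Every row satisfies
#'   `total_energy <= energy_threshold`.
#' @export
predict_targets <- function(mirnas, targets, config = target_config()) {
  if (is.character(mirnas) && length(mirnas) == 1 && is.null(names(mirnas)) &&
      file.exists(mirnas)) mirnas <- read_fasta(mirnas)
  if (is.character(targets) && length(targets) == 1 && is.null(names(targets)) &&
      file.exists(targets)) targets <- read_fasta(targets)
  if (anyDuplicated(names(mirnas))) stop("duplicate miRNA sequence IDs")
  if (anyDuplicated(names(targets))) stop("duplicate target sequence IDs")
  rows <- list()
  for (mid in sort(names(mirnas))) {
    for (tid in sort(names(targets))) {
      cand <- scan_sites(mirnas[[mid]], targets[[tid]], config)
      if (!length(cand)) next
      res <- lapply(cand, function(j) {
        duplex_energy(mirnas[[mid]], targets[[tid]], j, config)
      })
      en <- vapply(res, `[[`, numeric(1), "total_energy")
      pos <- vapply(res, `[[`, numeric(1), "position")
      best <- order(en, pos)[1]
      if (en[best] <= config$energy_threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = mid, target_id = tid,
          position = as.integer(pos[best]),
          alignment_score = res[[best]]$n_paired,
          total_energy = en[best],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    mirna_id = character(), target_id = character(), position = integer(),
    alignment_score = integer(), total_energy = numeric(),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("duplex_hits", "data.frame")
  out
}
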