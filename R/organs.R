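#' Normalize conservation scores across organs
#'
#' Restricts to metabolites with a finite (non-censored) score in every
#' organ, log2-transforms the scores and centers each organ's column on
#' zero. Centering removes the organ-wide differences in total metabolome
#' divergence so that organs can be compared metabolite by metabolite.
#'
#' @param mcs A data.frame as returned by [mcs_table()] covering >= 2 organs.
#' @return A numeric matrix (metabolite x organ, organs in alphabetical
#'   order) of class \code{normalized_scores}; per-organ column means are 0.
#'   \code{attr(, "n_dropped")} counts metabolites missing or censored in at
#'   least one organ.
#' @export
normalize_scores <- function(mcs) {
  organs <- sort(unique(mcs$organ))
  if (length(organs) < 2L) stop("need >= 2 organs", call. = FALSE)
  ok <- mcs[!mcs$censored & is.finite(mcs$mcs), , drop = FALSE]
  tab <- table(ok$metabolite)
  complete <- names(tab)[tab == length(organs)]
  n_dropped <- length(unique(mcs$metabolite)) - length(complete)
  if (!length(complete)) stop("no metabolite has a finite score in every organ", call. = FALSE)
  ok <- ok[ok$metabolite %in% complete, , drop = FALSE]
  m <- matrix(NA_real_, length(complete), length(organs),
              dimnames = list(sort(complete), organs))
  m[cbind(match(ok$metabolite, rownames(m)), match(ok$organ, organs))] <- log2(ok$mcs)
  m <- sweep(m, 2L, colMeans(m))
  attr(m, "n_dropped") <- n_dropped
  class(m) <- c("normalized_scores", class(m))
  m
}

#' Organ-specific deviation in conservation
#'
#' For each metabolite and organ, the deviation is the organ's normalized
#' score minus the mean of the other organs' normalized scores; large
#' positive deviations mark metabolites more strongly conserved in that
#' organ than elsewhere. Per organ, the top 10% most strongly deviating
#' metabolites (ceiling(n/10), ties broken by metabolite id) are flagged.
#'
#' @param scores A \code{normalized_scores} matrix.
#' @return A data.frame \code{metabolite, organ, deviation, top_decile}.
#' @export
organ_deviation <- function(scores) {
  stopifnot(inherits(scores, "normalized_scores"))
  n_org <- ncol(scores)
  if (n_org < 2L) stop("need >= 2 organs", call. = FALSE)
  out <- list()
  for (j in seq_len(n_org)) {
    others <- scores[, -j, drop = FALSE]
    dev <- scores[, j] - rowMeans(others)
    ord <- order(-dev, rownames(scores))
    k <- ceiling(nrow(scores) / 10)
    top <- rownames(scores)[ord[seq_len(k)]]
    out[[j]] <- data.frame(metabolite = rownames(scores),
                           organ = colnames(scores)[j],
                           deviation = unname(dev),
                           top_decile = rownames(scores) %in% top,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Association between organ differences in levels and in conservation
#'
#' For every metabolite and unordered organ pair (fixed alphabetical organ
#' order so signs are reproducible), computes (i) the species-averaged log2
#' fold change of metabolite levels between the two organs and (ii) the
#' difference of the normalized conservation scores, then the Spearman
#' correlation across all metabolite-by-pair points. Significance comes from
#' a one-sided permutation test that reshuffles each metabolite's organ
#' labels of the scores independently, preserving each metabolite's score
#' multiset (the fold-change points of one metabolite are not independent,
#' so an analytic p-value would be anticonservative).
#'
#' @param traits A \code{trait_matrix} or aggregated traits covering the
#'   same organs as \code{scores}.
#' @param scores A \code{normalized_scores} matrix.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param absolute If TRUE correlate absolute values of both differences
#'   instead of signed ones.
#' @return List \code{rho}, \code{p_perm} (one-sided, +1 smoothed),
#'   \code{n_points}, \code{n_perm}, \code{seed}, \code{pairs} (the point
#'   table).
#' @export
crossorgan_association <- function(traits, scores, n_perm = 10000, seed = 1,
                                   absolute = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  stopifnot(inherits(scores, "normalized_scores"))
  agg <- if (inherits(traits, "trait_matrix")) aggregate_replicates(traits) else traits
  organs <- colnames(scores)
  mets <- rownames(scores)
  agg <- agg[agg$organ %in% organs & agg$metabolite %in% mets, , drop = FALSE]

  pair_idx <- utils::combn(seq_along(organs), 2L)
  # species-averaged log2 level fold change per (metabolite, pair)
  lvl_fc <- matrix(NA_real_, length(mets), ncol(pair_idx),
                   dimnames = list(mets, apply(pair_idx, 2L, function(p)
                     paste(organs[p], collapse = "|"))))
  for (k in seq_len(ncol(pair_idx))) {
    o1 <- organs[pair_idx[1L, k]]; o2 <- organs[pair_idx[2L, k]]
    a1 <- agg[agg$organ == o1, c("species", "metabolite", "log10_level")]
    a2 <- agg[agg$organ == o2, c("species", "metabolite", "log10_level")]
    mm <- merge(a1, a2, by = c("species", "metabolite"), suffixes = c("_1", "_2"))
    # log2 FC from log10 levels: log2(10^(a-b)) = (a-b) * log2(10)
    mm$fc <- (mm$log10_level_1 - mm$log10_level_2) * log2(10)
    fc <- tapply(mm$fc, mm$metabolite, mean)
    lvl_fc[names(fc), k] <- fc
  }

  score_diff_fun <- function(sc) {
    sd_m <- sc[, pair_idx[1L, ], drop = FALSE] - sc[, pair_idx[2L, ], drop = FALSE]
    sd_m
  }
  sc_diff <- score_diff_fun(unclass(scores))
  keep <- is.finite(lvl_fc) & is.finite(sc_diff)
  xs <- lvl_fc[keep]; ys <- sc_diff[keep]
  if (absolute) { xs <- abs(xs); ys <- abs(ys) }
  rho_obs <- stats::cor(xs, ys, method = "spearman")

  set.seed(seed)
  n_ge <- 0L
  sc <- unclass(scores)
  for (p in seq_len(n_perm)) {
    perm <- t(apply(sc, 1L, sample))
    colnames(perm) <- organs
    yd <- score_diff_fun(perm)[keep]
    if (absolute) yd <- abs(yd)
    if (stats::cor(xs, yd, method = "spearman") >= rho_obs) n_ge <- n_ge + 1L
  }
  p_perm <- (1 + n_ge) / (n_perm + 1)
  list(rho = rho_obs, p_perm = p_perm, n_points = sum(keep),
       n_perm = n_perm, seed = seed,
       pairs = data.frame(level_log2fc = lvl_fc[keep], score_diff = sc_diff[keep]))
}
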