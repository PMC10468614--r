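#' Metabolite conservation scores for one organ
#'
#' For every metabolite measured in at least two species, prunes the tree to
#' the measured species, fits the Brownian-motion rate \eqn{\sigma^2} to the
#' aggregated log10 levels and reports the conservation score
#' \eqn{MCS = 1/\sigma^2}. Metabolites whose fitted rate is exactly zero
#' (identical values across species) get a censored record with
#' \code{mcs = NA}.
#'
#' @param tree A \code{phylo} object covering (at least) the measured species.
#' @param traits A \code{trait_matrix} (raw replicates) or the output of
#'   [aggregate_replicates()].
#' @param tip_se_table Optional data.frame \code{(organ, species, metabolite,
#'   se)} of per-tip sampling SDs for the measurement-error-aware fit.
#' @return A data.frame with columns \code{metabolite}, \code{organ},
#'   \code{sigma2}, \code{mcs}, \code{n_tips}, \code{censored}. Metabolites
#'   with fewer than two measured species are skipped (reported via
#'   \code{attr(, "skipped")}).
#' @export
mcs_table <- function(tree, traits, tip_se_table = NULL) {
  validate_phylogeny(tree)
  agg <- if (inherits(traits, "trait_matrix")) aggregate_replicates(traits) else traits
  stopifnot(all(c("organ", "species", "metabolite", "log10_level") %in% names(agg)))

  out <- list()
  skipped <- character()
  for (org in unique(agg$organ)) {
    a <- agg[agg$organ == org, , drop = FALSE]
    for (met in unique(a$metabolite)) {
      am <- a[a$metabolite == met, , drop = FALSE]
      am <- am[am$species %in% tree$tip.label, , drop = FALSE]
      if (nrow(am) < 2L) {
        skipped <- c(skipped, paste0(org, "/", met))
        next
      }
      y <- stats::setNames(am$log10_level, am$species)
      se <- NULL
      if (!is.null(tip_se_table)) {
        st <- tip_se_table[tip_se_table$organ == org & tip_se_table$metabolite == met, ]
        if (nrow(st)) se <- stats::setNames(st$se, st$species)[names(y)]
      }
      fit <- fit_bm(tree, y, tip_se = se)
      cens <- fit$sigma2 <= 0
      out[[length(out) + 1L]] <- data.frame(
        metabolite = met, organ = org, sigma2 = fit$sigma2,
        mcs = if (cens) NA_real_ else 1 / fit$sigma2,
        n_tips = fit$n_tips, censored = cens, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no metabolite had >= 2 measured species", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Clade-split reproducibility of conservation scores
#'
#' Computes conservation scores independently on two disjoint clades
#' (subtrees induced by the given tip sets, original branch lengths) and
#' reports their agreement as the Pearson correlation of the log10 scores
#' across metabolites scored in both clades.
#'
#' @param tree A \code{phylo} object.
#' @param traits Trait matrix or aggregated traits for one organ.
#' @param clade_a,clade_b Disjoint character vectors of tip labels.
#' @return List with \code{scores} (data.frame metabolite, mcs_cladeA,
#'   mcs_cladeB), \code{r} (Pearson r of log10 scores), \code{n} (metabolites
#'   in both), \code{n_censored} (dropped for a zero rate in either clade),
#'   \code{degenerate} (TRUE when either clade's log-scores are constant, so
#'   r is undefined).
#' @export
clade_split_mcs <- function(tree, traits, clade_a, clade_b) {
  if (length(intersect(clade_a, clade_b))) {
    stop("clades must be disjoint tip sets", call. = FALSE)
  }
  agg <- if (inherits(traits, "trait_matrix")) aggregate_replicates(traits) else traits
  sub_a <- prune_to_tips(tree, clade_a)
  sub_b <- prune_to_tips(tree, clade_b)
  ta <- mcs_table(sub_a, agg[agg$species %in% sub_a$tip.label, , drop = FALSE])
  tb <- mcs_table(sub_b, agg[agg$species %in% sub_b$tip.label, , drop = FALSE])
  mm <- merge(ta[, c("metabolite", "organ", "mcs")],
              tb[, c("metabolite", "organ", "mcs")],
              by = c("metabolite", "organ"), suffixes = c("_cladeA", "_cladeB"))
  if (!nrow(mm)) stop("no metabolite scored in both clades", call. = FALSE)
  ok <- is.finite(mm$mcs_cladeA) & is.finite(mm$mcs_cladeB)
  n_censored <- sum(!ok)
  mm <- mm[ok, , drop = FALSE]
  la <- log10(mm$mcs_cladeA); lb <- log10(mm$mcs_cladeB)
  degenerate <- nrow(mm) < 3L || stats::sd(la) == 0 || stats::sd(lb) == 0
  r <- if (degenerate) NA_real_ else stats::cor(la, lb)
  list(scores = mm, r = r, n = nrow(mm), n_censored = n_censored,
       degenerate = degenerate)
}

#' Bootstrap/ANOVA partition of conservation-score variance
#'
#' Resamples replicate measurements with replacement within each
#' (species, metabolite) pair, recomputes conservation scores \code{n_boot}
#' times, and partitions the total variance of the bootstrap log10 scores
#' into a between-metabolite component and an error (replicate noise)
#' component with a one-way ANOVA on metabolite identity. Pairs with a single
#' replicate are removed before resampling.
#'
#' @param raw A \code{trait_matrix} for one organ, with replicates.
#' @param tree A \code{phylo} object.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Master RNG seed; per-replicate child seeds are derived
#'   deterministically from it.
#' @return List of class \code{variance_partition}: \code{organ},
#'   \code{between_metabolite_fraction}, \code{error_fraction} (sum to 1),
#'   \code{n_boot}, and \code{boot_scores} (long data.frame of the bootstrap
#'   log10 scores).
#' @export
bootstrap_variance_partition <- function(raw, tree, n_boot = 100, seed = 1) {
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  raw <- trait_matrix(raw)
  if (length(unique(raw$organ)) != 1L) stop("one organ at a time", call. = FALSE)

  key <- interaction(raw$species, raw$metabolite, drop = TRUE)
  n_rep <- table(key)
  keep <- key %in% names(n_rep)[n_rep >= 2L]
  raw <- raw[keep, , drop = FALSE]
  if (!nrow(raw)) stop("no (species, metabolite) pair has >= 2 replicates", call. = FALSE)
  groups <- split(seq_len(nrow(raw)), droplevels(interaction(raw$species, raw$metabolite)))

  boot <- list()
  for (b in seq_len(n_boot)) {
    set.seed(child_seed(seed, b))
    idx <- unlist(lapply(groups, function(ix) ix[sample.int(length(ix), replace = TRUE)]),
                  use.names = FALSE)
    res <- raw[idx, , drop = FALSE]
    tab <- mcs_table(tree, trait_matrix(res))
    tab <- tab[!tab$censored, , drop = FALSE]
    if (nrow(tab)) {
      boot[[b]] <- data.frame(boot = b, metabolite = tab$metabolite,
                              log10_mcs = log10(tab$mcs), stringsAsFactors = FALSE)
    }
  }
  bs <- do.call(rbind, boot)
  # a perfect fit (zero replicate noise) triggers a harmless F-test warning
  aov_tab <- suppressWarnings(stats::anova(stats::lm(log10_mcs ~ metabolite, data = bs)))
  ss <- aov_tab[["Sum Sq"]]
  between <- ss[1L] / sum(ss)
  structure(list(organ = raw$organ[1L],
                 between_metabolite_fraction = between,
                 error_fraction = 1 - between,
                 n_boot = n_boot, boot_scores = bs),
            class = "variance_partition")
}

# Deterministic 32-bit child seed from a master seed and an index.
child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483647)
}
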