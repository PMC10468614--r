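#' Flag metabolites that participate in essential reactions
#'
#' A reaction is essential when strictly more than half of its associated
#' genes are essential (knockout lethal or causing infertility); a metabolite
#' is flagged when it is a substrate or product of at least one essential
#' reaction. Reactions with an empty gene set are excluded and reported.
#'
#' @param reaction_genes Named list: reaction id -> character vector of gene
#'   ids.
#' @param reaction_metabolites Named list: reaction id -> character vector of
#'   substrate/product metabolite ids.
#' @param essential_genes Character vector of essential gene ids.
#' @return Named logical vector over all metabolites appearing in
#'   \code{reaction_metabolites}; \code{attr(, "essential_reactions")} and
#'   \code{attr(, "excluded_reactions")} carry the intermediate calls.
#' @export
essential_metabolite_flags <- function(reaction_genes, reaction_metabolites,
                                       essential_genes) {
  rxns <- names(reaction_genes)
  stopifnot(setequal(rxns, names(reaction_metabolites)))
  empty <- rxns[vapply(reaction_genes, length, 1L) == 0L]
  if (length(empty)) {
    message("excluding reactions with no associated genes: ",
            paste(empty, collapse = ", "))
  }
  rxns <- setdiff(rxns, empty)
  ess_rxn <- vapply(rxns, function(r) {
    g <- reaction_genes[[r]]
    mean(g %in% essential_genes) > 0.5
  }, logical(1L))
  mets <- sort(unique(unlist(reaction_metabolites, use.names = FALSE)))
  flag <- stats::setNames(rep(FALSE, length(mets)), mets)
  for (r in rxns[ess_rxn]) flag[reaction_metabolites[[r]]] <- TRUE
  attr(flag, "essential_reactions") <- rxns[ess_rxn]
  attr(flag, "excluded_reactions") <- empty
  flag
}

#' Univariate variance-explained scan of metabolite features
#'
#' For each feature, fits a linear model of log2 conservation score on organ
#' membership plus the feature, pooling all organs, and reports the variance
#' explained beyond organ alone: \eqn{\Delta R^2 = R^2(organ + feature) -
#' R^2(organ)}. P-values come from the nested-model F test and are
#' Benjamini-Hochberg adjusted across all tested features. Factor features
#' with more than two levels (e.g. chemical class) are expanded into one
#' binary indicator per level, each tested separately; skewed continuous
#' features may be named in \code{log_features} to be log10-transformed
#' first.
#'
#' @param mcs A data.frame from [mcs_table()] pooled over organs.
#' @param features A data.frame with a \code{metabolite} column and one
#'   column per feature (numeric, logical, or factor/character).
#' @param log_features Character vector of feature columns to
#'   log10-transform (values must be positive; zeros get a half-minimum
#'   pseudocount).
#' @param fdr_threshold Adjusted-p threshold used for the \code{significant}
#'   column (default 0.01).
#' @return A data.frame of class \code{feature_scan}: \code{feature},
#'   \code{delta_r2} (proportion, >= 0 by construction of nested OLS),
#'   \code{p_value}, \code{p_adj}, \code{significant}, \code{n}. Constant
#'   features are skipped with a warning.
#' @export
univariate_scan <- function(mcs, features, log_features = character(),
                            fdr_threshold = 0.01) {
  dat <- merge(mcs[!mcs$censored, c("metabolite", "organ", "mcs")],
               features, by = "metabolite")
  dat$.y <- log2(dat$mcs)
  dat$organ <- factor(dat$organ)
  feat_cols <- setdiff(names(features), "metabolite")

  cols <- list()
  for (f in feat_cols) {
    v <- dat[[f]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v) && nlevels(droplevels(v)) > 2L) {
      for (lv in levels(droplevels(v))) {
        cols[[paste0(f, ":", lv)]] <- as.numeric(v == lv)
      }
    } else if (is.factor(v)) {
      cols[[f]] <- as.numeric(v == levels(droplevels(v))[2L])
    } else if (is.logical(v)) {
      cols[[f]] <- as.numeric(v)
    } else {
      x <- as.numeric(v)
      if (f %in% log_features) {
        pos <- x[x > 0 & !is.na(x)]
        if (!length(pos)) { warning("feature ", f, " has no positive values; skipped"); next }
        x[!is.na(x) & x <= 0] <- min(pos) / 2
        x <- log10(x)
      }
      cols[[f]] <- x
    }
  }

  rows <- list()
  for (f in names(cols)) {
    x <- cols[[f]]
    ok <- !is.na(x) & !is.na(dat$.y)
    if (sum(ok) < 4L || stats::sd(x[ok]) == 0) {
      warning("feature ", f, " constant or too sparse; skipped")
      next
    }
    d <- data.frame(y = dat$.y[ok], organ = droplevels(dat$organ[ok]), x = x[ok])
    if (nlevels(d$organ) > 1L) {
      m0 <- stats::lm(y ~ organ, data = d)
      m1 <- stats::lm(y ~ organ + x, data = d)
    } else {  # single organ: the covariate degenerates to the intercept
      m0 <- stats::lm(y ~ 1, data = d)
      m1 <- stats::lm(y ~ x, data = d)
    }
    dr2 <- summary(m1)$r.squared - summary(m0)$r.squared
    p <- stats::anova(m0, m1)[2L, "Pr(>F)"]
    rows[[f]] <- data.frame(feature = f, delta_r2 = dr2, p_value = p,
                            n = nrow(d), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable feature", call. = FALSE)
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adj < fdr_threshold
  res <- res[order(-res$delta_r2), c("feature", "delta_r2", "p_value", "p_adj",
                                     "significant", "n")]
  rownames(res) <- NULL
  class(res) <- c("feature_scan", "data.frame")
  res
}

#' AIC-stepwise multivariate model of conservation scores
#'
#' Starting from a linear model of log2 conservation score on organ
#' membership plus all candidate features (chemical class entered as a
#' single multilevel factor), performs bidirectional stepwise selection
#' minimizing AIC with organ membership never eligible for removal. For
#' every retained feature the independent contribution is the drop in
#' adjusted R-squared when that feature alone is removed and the model
#' refitted (negative drops are clipped to 0 and flagged). The features-total
#' variance explained is the final model's adjusted R-squared minus the
#' independent contribution of organ membership.
#'
#' @param mcs A data.frame from [mcs_table()] pooled over organs.
#' @param features Data.frame with \code{metabolite} plus candidate columns
#'   (typically the individually significant features).
#' @param log_features As in [univariate_scan()].
#' @return List of class \code{multivariate_report}: \code{model} (the final
#'   lm), \code{selected} (feature terms retained), \code{contributions}
#'   (data.frame term, adj_r2_drop, clipped), \code{adj_r2_full},
#'   \code{organ_independent}, \code{features_total}, \code{n}.
#' @export
multivariate_selection <- function(mcs, features, log_features = character()) {
  dat <- merge(mcs[!mcs$censored, c("metabolite", "organ", "mcs")],
               features, by = "metabolite")
  dat$.y <- log2(dat$mcs)
  dat$organ <- factor(dat$organ)
  feat_cols <- setdiff(names(features), "metabolite")
  for (f in feat_cols) {
    v <- dat[[f]]
    if (is.character(v)) dat[[f]] <- factor(v)
    if (is.logical(v)) dat[[f]] <- as.numeric(v)
    if (is.numeric(dat[[f]]) && f %in% log_features) {
      x <- dat[[f]]
      pos <- x[x > 0 & !is.na(x)]
      x[!is.na(x) & x <= 0] <- min(pos) / 2
      dat[[f]] <- log10(x)
    }
  }
  dat <- dat[stats::complete.cases(dat[, c(".y", "organ", feat_cols)]), , drop = FALSE]
  # drop constants and exact duplicates (later-ordered duplicate removed)
  keep <- character()
  seen <- list()
  for (f in feat_cols) {
    v <- dat[[f]]
    key <- paste(as.character(v), collapse = "\r")
    if (length(unique(v)) < 2L) { warning("dropping constant feature ", f); next }
    if (key %in% unlist(seen)) { warning("dropping duplicated feature ", f); next }
    seen[[f]] <- key
    keep <- c(keep, f)
  }
  base_term <- if (nlevels(droplevels(dat$organ)) > 1L) "organ" else "1"
  fml_full <- stats::as.formula(paste(".y ~", base_term, "+",
                                      paste(keep, collapse = " + ")))
  full <- stats::lm(fml_full, data = dat)
  sel <- stats::step(full,
                     scope = list(lower = stats::as.formula(paste(".y ~", base_term)),
                                  upper = fml_full),
                     direction = "both", trace = 0, k = 2)
  terms_sel <- attr(stats::terms(sel), "term.labels")
  feat_sel <- setdiff(terms_sel, "organ")
  adj_full <- summary(sel)$adj.r.squared

  drop_one <- function(term) {
    red <- stats::update(sel, stats::as.formula(paste(". ~ . -", term)))
    adj_full - summary(red)$adj.r.squared
  }
  contrib <- data.frame(term = feat_sel,
                        adj_r2_drop = vapply(feat_sel, drop_one, 1.0),
                        stringsAsFactors = FALSE)
  contrib$clipped <- contrib$adj_r2_drop < 0
  contrib$adj_r2_drop <- pmax(contrib$adj_r2_drop, 0)
  organ_ind <- if (base_term == "organ") max(drop_one("organ"), 0) else 0
  structure(list(model = sel, selected = feat_sel, contributions = contrib,
                 adj_r2_full = adj_full, organ_independent = organ_ind,
                 features_total = adj_full - organ_ind, n = nrow(dat)),
            class = "multivariate_report")
}

#' @export
print.multivariate_report <- function(x, ...) {
  cat("Stepwise multivariate model of log2(MCS) ~ organ + features\n")
  cat(sprintf("  n = %d, adjusted R^2 = %.3f, features total = %.3f\n",
              x$n, x$adj_r2_full, x$features_total))
  cat("  retained:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
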