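#' Conservation difference between annotated and non-annotated metabolites
#'
#' Per organ, a two-sided Wilcoxon rank-sum test of log2 conservation scores
#' between flagged (e.g. IEM-associated) and non-flagged metabolites, plus a
#' pooled linear model \code{log2(mcs) ~ organ + flag}. Optional exclusion
#' variants (dropping a chemical class or a pathway's metabolites) are
#' re-run and reported alongside, to check that an association is not driven
#' by one group of metabolites.
#'
#' @param mcs Data.frame from [mcs_table()] over one or more organs.
#' @param flags Named logical vector over metabolites.
#' @param exclusions Optional named list: variant name -> character vector of
#'   metabolite ids to drop for that variant.
#' @return List: \code{per_organ} (data.frame organ, n_flagged, n_other, W,
#'   p_value), \code{pooled} (lm summary coefficients for the flag),
#'   \code{variants} (same structure per exclusion variant; skipped variants
#'   noted).
#' @export
group_conservation_test <- function(mcs, flags, exclusions = NULL) {
  run_one <- function(tab) {
    tab <- tab[!tab$censored & is.finite(tab$mcs), , drop = FALSE]
    tab$flag <- flags[tab$metabolite]
    tab <- tab[!is.na(tab$flag), , drop = FALSE]
    per <- lapply(sort(unique(tab$organ)), function(org) {
      d <- tab[tab$organ == org, ]
      y1 <- log2(d$mcs[d$flag]); y0 <- log2(d$mcs[!d$flag])
      if (length(y1) < 2L || length(y0) < 2L) {
        return(data.frame(organ = org, n_flagged = length(y1), n_other = length(y0),
                          W = NA_real_, p_value = NA_real_))
      }
      wt <- suppressWarnings(stats::wilcox.test(y1, y0, alternative = "two.sided"))
      # fully tied samples: no evidence either way, two-sided p is 1
      p <- if (length(unique(c(y1, y0))) == 1L) 1 else wt$p.value
      data.frame(organ = org, n_flagged = length(y1), n_other = length(y0),
                 W = unname(wt$statistic), p_value = p)
    })
    per <- do.call(rbind, per)
    pooled <- if (length(unique(tab$flag)) == 2L) {
      fml <- if (length(unique(tab$organ)) > 1L) log2(mcs) ~ factor(organ) + flag
             else log2(mcs) ~ flag
      fit <- stats::lm(fml, data = tab)
      suppressWarnings(summary(fit))$coefficients["flagTRUE", , drop = FALSE]
    } else NULL
    list(per_organ = per, pooled = pooled)
  }
  base <- run_one(mcs)
  variants <- list()
  for (vn in names(exclusions)) {
    sub <- mcs[!(mcs$metabolite %in% exclusions[[vn]]), , drop = FALSE]
    v <- tryCatch(run_one(sub), error = function(e) NULL)
    if (is.null(v) || all(is.na(v$per_organ$p_value))) {
      variants[[vn]] <- list(skipped = TRUE)
    } else variants[[vn]] <- v
  }
  c(base, list(variants = variants))
}

#' Independently associated disease conditions
#'
#' Applies the two-stage procedure for broad disease conditions: first keep
#' conditions whose member metabolites are significantly more conserved in a
#' univariate two-sided rank-sum test in at least \code{min_organs} of the
#' organs (p < 0.05 and higher median in the members); then fit one
#' multivariate linear model of log2 conservation score on organ plus all
#' retained condition flags and report the conditions whose coefficient
#' stays significant (p < 0.05). Perfectly collinear duplicate memberships
#' are reduced to the first-named condition.
#'
#' @param mcs Data.frame from [mcs_table()] over >= 1 organs.
#' @param memberships Named list: condition -> character vector of member
#'   metabolite ids.
#' @param min_organs Organs in which the univariate test must pass (default
#'   3).
#' @param min_members Minimum annotated metabolites for a condition to enter
#'   (default 10).
#' @return List: \code{univariate} (data.frame condition, n_members,
#'   n_organs_significant, passed), \code{independent} (character vector,
#'   possibly empty), \code{model} (the multivariate lm or NULL),
#'   \code{coefficients}.
#' @export
multivariate_disease_model <- function(mcs, memberships, min_organs = 3,
                                       min_members = 10) {
  tab <- mcs[!mcs$censored & is.finite(mcs$mcs), , drop = FALSE]
  mets <- unique(tab$metabolite)
  organs <- sort(unique(tab$organ))
  memberships <- memberships[vapply(memberships, function(m)
    sum(mets %in% m) >= min_members, TRUE)]
  uni <- lapply(names(memberships), function(cond) {
    inset <- tab$metabolite %in% memberships[[cond]]
    nsig <- 0L
    for (org in organs) {
      d <- tab[tab$organ == org, ]; f <- d$metabolite %in% memberships[[cond]]
      if (sum(f) < 2L || sum(!f) < 2L) next
      y1 <- log2(d$mcs[f]); y0 <- log2(d$mcs[!f])
      p <- suppressWarnings(stats::wilcox.test(y1, y0)$p.value)
      if (!is.na(p) && p < 0.05 && stats::median(y1) > stats::median(y0)) nsig <- nsig + 1L
    }
    data.frame(condition = cond, n_members = sum(mets %in% memberships[[cond]]),
               n_organs_significant = nsig, passed = nsig >= min_organs,
               stringsAsFactors = FALSE)
  })
  uni <- if (length(uni)) do.call(rbind, uni) else
    data.frame(condition = character(), n_members = integer(),
               n_organs_significant = integer(), passed = logical())
  retained <- uni$condition[uni$passed]
  if (!length(retained)) {
    return(list(univariate = uni, independent = character(), model = NULL,
                coefficients = NULL))
  }
  # design matrix; drop exact-duplicate membership columns (keep first)
  X <- vapply(retained, function(cond) as.numeric(tab$metabolite %in% memberships[[cond]]),
              numeric(nrow(tab)))
  X <- matrix(X, nrow = nrow(tab), dimnames = list(NULL, retained))
  dup <- duplicated(t(X))
  retained <- retained[!dup]
  X <- X[, !dup, drop = FALSE]
  safe <- make.names(retained, unique = TRUE)
  colnames(X) <- safe
  d <- data.frame(y = log2(tab$mcs), X)
  if (length(organs) > 1L) d$organ <- factor(tab$organ)
  fit <- stats::lm(y ~ ., data = d)
  cf <- summary(fit)$coefficients
  indep <- retained[vapply(safe, function(s)
    s %in% rownames(cf) && !is.na(cf[s, 4L]) && cf[s, 4L] < 0.05, TRUE)]
  cf_cond <- cf[rownames(cf) %in% safe, , drop = FALSE]
  rownames(cf_cond) <- retained[match(rownames(cf_cond), safe)]
  list(univariate = uni, independent = indep, model = fit, coefficients = cf_cond)
}

#' Aggregate conservation score across organs
#'
#' The per-metabolite median of the normalized (log2, per-organ centered)
#' conservation scores across the organs.
#'
#' @param scores A \code{normalized_scores} matrix from [normalize_scores()].
#' @return Named numeric vector of aggregate scores; \code{attr(,
#'   "n_dropped")} counts metabolites with a missing organ.
#' @export
aggregate_mcs <- function(scores) {
  stopifnot(inherits(scores, "normalized_scores"))
  ok <- stats::complete.cases(unclass(scores))
  out <- apply(unclass(scores)[ok, , drop = FALSE], 1L, stats::median)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Logistic biomarker classifier with ROC/AUC
#'
#' Fits a logistic regression of a binary label on a single conservation
#' score, sweeps the score thresholds for the ROC curve, and computes AUC
#' both by the trapezoid rule and by the rank (Mann-Whitney) formula; for a
#' single monotone covariate the two are identical and are asserted to agree
#' to 1e-9.
#'
#' @param score Named numeric vector (e.g. the aggregate conservation
#'   score).
#' @param labels Named logical vector over the same metabolites.
#' @return List of class \code{classifier_report}: \code{roc} (data.frame
#'   fpr, tpr, threshold), \code{auc}, \code{auc_rank}, \code{model}
#'   (the glm), \code{n_pos}, \code{n_neg}.
#' @export
biomarker_roc <- function(score, labels) {
  common <- intersect(names(score), names(labels))
  s <- score[common]; y <- labels[common]
  ok <- is.finite(s) & !is.na(y)
  s <- s[ok]; y <- y[ok]
  if (length(unique(y)) < 2L) stop("labels contain a single class", call. = FALSE)
  # perfect separation is a legitimate input here (AUC = 1); the fitted
  # coefficients are then boundary values and the warning is expected
  fit <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial()))

  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(th) mean(s[y] >= th), 1.0)
  fpr <- vapply(thr, function(th) mean(s[!y] >= th), 1.0)
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  r <- rank(s)
  n1 <- sum(y); n0 <- sum(!y)
  auc_rank <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (abs(auc_trap - auc_rank) > 1e-9) {
    stop(sprintf("AUC identity violated: trapezoid %.12f vs rank %.12f",
                 auc_trap, auc_rank), call. = FALSE)
  }
  structure(list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
                 auc = auc_trap, auc_rank = auc_rank, model = fit,
                 n_pos = n1, n_neg = n0),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("logistic biomarker classifier: AUC = %.4f (%d pos / %d neg)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Association between conservation and the number of linked diseases
#'
#' Spearman correlation between a metabolite's conservation score and its
#' count of specific disease associations, plus a multivariate linear model
#' controlling for abundance and essentiality so the count effect can be
#' judged independently of those covariates.
#'
#' @param score Named numeric conservation score (aggregate or one organ's
#'   log score).
#' @param n_diseases Named integer vector of disease counts.
#' @param abundance Optional named numeric abundances (log10-transformed in
#'   the model).
#' @param essential Optional named logical essentiality flags.
#' @return List: \code{rho}, \code{p_value}, \code{n}, \code{model}
#'   (lm or NULL), \code{count_coefficient} (row of the lm summary or NULL).
#' @export
disease_count_association <- function(score, n_diseases, abundance = NULL,
                                      essential = NULL) {
  common <- intersect(names(score), names(n_diseases))
  s <- score[common]; k <- n_diseases[common]
  ok <- is.finite(s) & !is.na(k)
  s <- s[ok]; k <- k[ok]
  if (all(k == 0)) {
    warning("all disease counts are zero; correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(s),
                model = NULL, count_coefficient = NULL))
  }
  ct <- suppressWarnings(stats::cor.test(s, k, method = "spearman"))
  model <- NULL; cc <- NULL
  if (!is.null(abundance) && !is.null(essential)) {
    d <- data.frame(y = s, count = k,
                    log_abund = log10(pmax(abundance[names(s)], .Machine$double.xmin)),
                    essential = as.numeric(essential[names(s)]))
    d <- d[stats::complete.cases(d), , drop = FALSE]
    # constant covariates (e.g. no essential metabolite in the set) are inert
    keep <- c("count", names(which(vapply(d[c("log_abund", "essential")],
                                          function(v) length(unique(v)) > 1L, TRUE))))
    model <- stats::lm(stats::reformulate(keep, response = "y"), data = d)
    cc <- summary(model)$coefficients["count", , drop = FALSE]
  }
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(s),
       model = model, count_coefficient = cc)
}
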