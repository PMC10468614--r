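#' Construct a trait matrix of relative metabolite levels
#'
#' A trait matrix is the long table of per-replicate relative metabolite
#' levels for one or more organs, on the linear scale. Downstream fitting
#' works on the per-(species, metabolite) mean of the log10-transformed
#' replicate values; see [aggregate_replicates()].
#'
#' @param df A data.frame with columns \code{organ}, \code{species},
#'   \code{metabolite}, \code{replicate}, \code{level} (relative level,
#'   linear scale, strictly positive).
#' @return The validated data.frame with class \code{"trait_matrix"}.
#' @export
trait_matrix <- function(df) {
  req <- c("organ", "species", "metabolite", "replicate", "level")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("trait table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$level)) stop("trait table contains NA levels", call. = FALSE)
  bad <- which(df$level <= 0)
  if (length(bad)) {
    b <- df[bad[1L], ]
    stop(sprintf("nonpositive level for organ=%s species=%s metabolite=%s replicate=%s",
                 b$organ, b$species, b$metabolite, b$replicate), call. = FALSE)
  }
  df <- as.data.frame(df)
  class(df) <- c("trait_matrix", "data.frame")
  df
}

#' Read a trait matrix from long-format TSV
#'
#' @param path Path to a TSV with columns organ, species, metabolite,
#'   replicate, level.
#' @return A \code{trait_matrix}.
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  trait_matrix(df)
}

#' Aggregate replicates to per-species log10 trait values
#'
#' Each (organ, species, metabolite) is collapsed to the arithmetic mean of
#' the log10-transformed replicate levels, the single continuous trait value
#' the Brownian-motion fit consumes.
#'
#' @param raw A \code{trait_matrix}.
#' @return A data.frame with columns \code{organ}, \code{species},
#'   \code{metabolite}, \code{log10_level}, one row per combination.
#' @examples
#' tm <- trait_matrix(data.frame(organ = "liver", species = "A",
#'   metabolite = "m1", replicate = 1:2, level = c(10, 1000)))
#' aggregate_replicates(tm)$log10_level  # 2
#' @export
aggregate_replicates <- function(raw) {
  raw <- trait_matrix(raw)
  agg <- stats::aggregate(
    list(log10_level = log10(raw$level)),
    by = list(organ = raw$organ, species = raw$species, metabolite = raw$metabolite),
    FUN = mean
  )
  agg[order(agg$organ, agg$metabolite, agg$species), , drop = FALSE]
}

#' Spread aggregated traits of one organ to a species-by-metabolite matrix
#'
#' @param agg Output of [aggregate_replicates()], restricted to one organ if
#'   several are present.
#' @param organ Organ to select (default: the single organ present).
#' @return A numeric matrix, rows = species, columns = metabolites, NA where
#'   a species lacks a measurement.
#' @export
trait_wide <- function(agg, organ = NULL) {
  if (!is.null(organ)) agg <- agg[agg$organ == organ, , drop = FALSE]
  if (length(unique(agg$organ)) > 1L) {
    stop("multiple organs present; pass `organ`", call. = FALSE)
  }
  sp <- sort(unique(agg$species))
  mt <- sort(unique(agg$metabolite))
  m <- matrix(NA_real_, length(sp), length(mt), dimnames = list(sp, mt))
  m[cbind(match(agg$species, sp), match(agg$metabolite, mt))] <- agg$log10_level
  m
}
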