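## Rank-comparison outputs: E-rank vs P-rank scatter data and the
## E-rank minus P-rank bar series, plus display capping and TSV/CSV export.
## The plot-ready tables are the contract (pure functions of the ranked
## set, byte-stable when written); rendered figures are presentation.

utils::globalVariables(c("e_rank_ordinal", "p_rank", "position",
                         "rank_diff"))

.rankedOrEmpty <- function(ranked) {
  if (methods::is(ranked, "RankedSNPSet")) ranked <- rankedTable(ranked)
  if (!is.data.frame(ranked) || nrow(ranked) == 0L)
    stop("empty ranked set", call. = FALSE)
  ranked
}

#' E-rank vs P-rank scatter data
#'
#' One point per SNP with the evolutionarily adjusted rank on the x-axis
#' and the raw statistical-significance rank on the y-axis; points below
#' the identity line are SNPs promoted by the evolutionary adjustment. The
#' extra columns replicate the hover payload of an interactive view.
#'
#' @param ranked a [RankedSNPSet-class] (or its ranked table).
#' @return data.frame with columns rsid, e_rank_ordinal (x), p_rank (y),
#'   rank_diff, e_score, p_value; attribute \code{identity_line} marks the
#'   y = x reference line metadata.
#' @export
erankVsPrank <- function(ranked) {
  r <- .rankedOrEmpty(ranked)
  out <- r[order(r$e_rank_ordinal),
           c("rsid", "e_rank_ordinal", "p_rank", "rank_diff", "e_score",
             "p_value")]
  rownames(out) <- NULL
  attr(out, "identity_line") <- list(intercept = 0, slope = 1)
  attr(out, "axes") <- c(x = "e_rank_ordinal", y = "p_rank")
  out
}

#' E-rank minus P-rank bar series
#'
#' One bar per SNP showing the rank shift caused by the evolutionary
#' adjustment. Negative bars mark SNPs whose relative significance is most
#' enhanced by the adjustment. Over a complete ranked set (two permutations
#' of 1..N) the series sums to zero.
#'
#' @param ranked a [RankedSNPSet-class] (or its ranked table).
#' @param order \code{"p_rank"} (default) or \code{"rank_diff"}: series
#'   position of the bars.
#' @return data.frame with columns rsid, position, p_rank, e_rank_ordinal,
#'   rank_diff, e_score.
#' @export
erankMinusPrank <- function(ranked, order = c("p_rank", "rank_diff")) {
  order <- match.arg(order)
  r <- .rankedOrEmpty(ranked)
  o <- if (order == "p_rank") base::order(r$p_rank)
       else base::order(r$rank_diff, r$rsid)
  out <- r[o, c("rsid", "p_rank", "e_rank_ordinal", "rank_diff", "e_score")]
  out <- cbind(position = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Cap a result set for display
#'
#' Tabulated and plotted views retain at most \code{limit} records (default
#' 1000) so rank plots stay interpretable; the caller's current sort order
#' is preserved, so pre-sorting chooses which records survive the cap. The
#' full set remains available for bulk export ([writeBulkCsv()]).
#'
#' @param x a data.frame (e.g. a ranked or summary table) or a
#'   [RankedSNPSet-class].
#' @param limit maximum number of records to retain (>= 1).
#' @return list with \code{data} (the first \code{limit} rows, order
#'   preserved) and \code{truncated} (TRUE if rows were dropped).
#' @examples
#' capForDisplay(data.frame(i = 1:5), limit = 3)$truncated  # TRUE
#' @export
capForDisplay <- function(x, limit = 1000L) {
  if (methods::is(x, "RankedSNPSet")) x <- rankedTable(x)
  stopifnot(is.data.frame(x), limit >= 1L)
  truncated <- nrow(x) > limit
  list(data = utils::head(x, limit), truncated = truncated)
}

#' Write plot-ready data as TSV
#'
#' Deterministic, byte-stable TSV serialization of a plot-data table: the
#' same ranked set always yields an identical file.
#'
#' @param plotData data.frame from [erankVsPrank()] or [erankMinusPrank()].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writePlotData <- function(plotData, file) {
  stopifnot(is.data.frame(plotData))
  utils::write.table(plotData, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(file)
}

#' Bulk CSV export without display limit
#'
#' @param x a [RankedSNPSet-class], [AssociationSet-class] or data.frame.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeBulkCsv <- function(x, file) {
  if (methods::is(x, "RankedSNPSet")) x <- rankedTable(x)
  if (methods::is(x, "AssociationSet")) x <- associationRecords(x)
  stopifnot(is.data.frame(x))
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Render the rank-comparison figures
#'
#' \code{plotRankScatter} draws the E-rank vs P-rank scatter with the
#' identity reference line; \code{plotRankDiff} the E-rank minus P-rank
#' bars. Both accept the capped or full ranked set.
#'
#' @param ranked a [RankedSNPSet-class] (or its ranked table).
#' @param order bar order for \code{plotRankDiff}.
#' @return a ggplot object.
#' @export
plotRankScatter <- function(ranked) {
  d <- erankVsPrank(ranked)
  ggplot2::ggplot(d, ggplot2::aes(x = e_rank_ordinal, y = p_rank)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "E-rank (evolutionary-adjusted)",
                  y = "P-rank (statistical significance)") +
    ggplot2::theme_minimal()
}

#' @rdname plotRankScatter
#' @export
plotRankDiff <- function(ranked, order = c("p_rank", "rank_diff")) {
  d <- erankMinusPrank(ranked, order = order)
  ggplot2::ggplot(d, ggplot2::aes(x = position, y = rank_diff)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::labs(x = "SNP", y = "E-rank - P-rank") +
    ggplot2::theme_minimal()
}
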