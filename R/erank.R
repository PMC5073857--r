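## E-rank: evolutionary adjustment of GWAS association P-values.
## e_score = (P / MAF) * 1 / (Kr * Kt), where Kr and Kt are the within-set
## midranks of the site's evolutionary rate (descending) and evolutionary
## span (ascending). Conserved positions (low rate, long span) get large
## Kr * Kt, hence small scores, hence promotion in the E-rank ordering.

#' Midranks of a numeric vector
#'
#' Ranks 1..N with ties receiving the mean of the tied positions (midrank),
#' so the ranks always sum to N(N+1)/2. \code{direction = "descending"}
#' ranks the largest value 1.
#'
#' @param values finite numeric vector.
#' @param direction \code{"ascending"} (default) or \code{"descending"}.
#' @return numeric midranks.
#' @examples
#' rankValues(c(3, 1, 1, 2))                  # 4 1.5 1.5 3
#' rankValues(c(3, 1, 1, 2), "descending")    # 1 3.5 3.5 2
#' @export
rankValues <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (length(values) == 0L)
    stop("cannot rank an empty vector", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all values must be finite", call. = FALSE)
  x <- if (direction == "descending") -values else values
  rank(x, ties.method = "average")
}

#' E-rank score of one record
#'
#' \code{(p / maf) * 1 / (kR * kT)}. A zero P-value is clamped to the
#' smallest representable positive double with a warning; a missing or zero
#' MAF yields \code{NA} (the "unrankable" signal) with a warning, never a
#' division-by-zero crash.
#'
#' @param p association P-value(s) in (0, 1].
#' @param maf minor allele frequency(ies), > 0.
#' @param kR,kT within-set ranks, >= 1.
#' @return positive numeric score(s); NA where unrankable.
#' @examples
#' eScore(0.05, 0.5, 1, 1)     # 0.1
#' eScore(1e-6, 0.1, 10, 5)    # 2e-7
#' @export
eScore <- function(p, maf, kR, kT) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p must lie in (0, 1]", call. = FALSE)
  if (any(kR < 1, na.rm = TRUE) || any(kT < 1, na.rm = TRUE))
    stop("ranks must be >= 1", call. = FALSE)
  if (any(p == 0, na.rm = TRUE)) {
    warning("P-value of 0 clamped to smallest representable positive value",
            call. = FALSE)
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  unrankable <- is.na(maf) | maf <= 0
  if (any(unrankable)) {
    warning(sum(unrankable), " record(s) unrankable: MAF missing or zero",
            call. = FALSE)
    maf[unrankable] <- NA_real_
  }
  (p / maf) / (kR * kT)
}

#' Compute E-rank rankings for a set of SNPs
#'
#' Ranks a set of association records (typically one study's SNPs: the
#' ranking scope is exactly the supplied set). Kr is the midrank of
#' \code{evol_rate} descending -- the fastest-evolving site ranks 1, the
#' most conserved ranks N -- and Kt the midrank of \code{evol_span}
#' ascending -- the longest-lived position ranks N. Each record's E-rank
#' score is \code{(p/maf)/(Kr*Kt)}; ordinal P-rank and E-rank are assigned
#' ascending with deterministic tie-break by rsid. Records lacking MAF
#' (missing or zero), rate or span are excluded with per-record reasons
#' rather than distorting every other record's ranks.
#'
#' @param records data.frame with columns \code{rsid}, \code{p_value},
#'   \code{maf}, \code{evol_rate}, \code{evol_span} (an [AssociationSet-class]
#'   joined to site metrics also works: extra columns are carried through to
#'   \code{excluded}, ignored for ranking).
#' @return a [RankedSNPSet-class].
#' @examples
#' recs <- data.frame(rsid = c("rs1", "rs2"),
#'                    p_value = c(1e-6, 1e-6), maf = c(0.2, 0.2),
#'                    evol_rate = c(0, 3), evol_span = c(1, 0.2))
#' rankedTable(computeRankings(recs))  # rs1 (conserved) ranks first
#' @export
computeRankings <- function(records) {
  if (methods::is(records, "AssociationSet"))
    records <- associationRecords(records)
  need <- c("rsid", "p_value", "maf", "evol_rate", "evol_span")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$p_value)] <- "missing P-value"
  reason[is.na(records$maf) | records$maf <= 0] <- "MAF missing or zero"
  reason[is.na(records$evol_rate)] <- "undefined evolutionary rate"
  reason[is.na(records$evol_span)] <- "undefined evolutionary span"
  rankable <- is.na(reason)
  if (!any(rankable)) {
    stop("no rankable records; reasons: ",
         paste(unique(reason[!rankable]), collapse = "; "), call. = FALSE)
  }
  excluded <- records[!rankable, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!rankable]
  r <- records[rankable, need, drop = FALSE]
  n <- nrow(r)
  r$k_r <- rankValues(r$evol_rate, "descending")
  r$k_t <- rankValues(r$evol_span, "ascending")
  r$e_score <- eScore(r$p_value, r$maf, r$k_r, r$k_t)
  r$p_rank <- integer(n)
  r$p_rank[order(r$p_value, r$rsid)] <- seq_len(n)
  r$e_rank_ordinal <- integer(n)
  r$e_rank_ordinal[order(r$e_score, r$rsid)] <- seq_len(n)
  r$rank_diff <- r$e_rank_ordinal - r$p_rank
  rownames(r) <- NULL
  methods::new("RankedSNPSet", ranked = r,
               excluded = if (nrow(excluded)) excluded
                          else data.frame(reason = character()))
}

#' @describeIn rankedTable accessor for the ranked table.
#' @export
setMethod("rankedTable", "RankedSNPSet", function(x) x@ranked)

#' Accessors for RankedSNPSet
#'
#' \code{rankedTable} returns the per-SNP ranking table;
#' \code{excludedTable} the unrankable records with their exclusion reasons.
#'
#' @param x a [RankedSNPSet-class].
#' @return a data.frame.
#' @rdname rankedTable
#' @export
setMethod("excludedTable", "RankedSNPSet", function(x) x@excluded)

setMethod("show", "RankedSNPSet", function(object) {
  cat("RankedSNPSet:", nrow(object@ranked), "ranked SNP(s),",
      nrow(object@excluded), "excluded\n")
  if (nrow(object@ranked)) {
    top <- object@ranked[order(object@ranked$e_rank_ordinal), ]
    print(utils::head(top[, c("rsid", "p_value", "maf", "k_r", "k_t",
                              "e_score", "p_rank", "e_rank_ordinal",
                              "rank_diff")], 5L), row.names = FALSE)
    if (nrow(top) > 5L) cat("  ...", nrow(top) - 5L, "more\n")
  }
})

#' Write / read a ranking table as TSV
#'
#' @param x a [RankedSNPSet-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeRankings <- function(x, file) {
  stopifnot(methods::is(x, "RankedSNPSet"))
  utils::write.table(rankedTable(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
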