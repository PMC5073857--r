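## In-memory GWAS association store: flat TSV/CSV in, indexed records with
## an explicit rejection report, filter/summarize/sort/search semantics.

.REQUIRED_COLS <- c("rsid", "pmid", "phenotype", "p_value")
.OPTIONAL_COLS <- c("study_title", "phenotype_category", "allele", "maf",
                    "chrom", "pos", "region_type", "gene", "aa_change",
                    "polyphen2", "sift", "evod")

#' Controlled region-type vocabulary
#'
#' Minimal closed set of genomic region categories used by the store's
#' region filter: intron, missense, synonymous, 3'UTR, 5'UTR, intergenic,
#' other. Extensible by passing \code{extra} tokens.
#'
#' @param extra additional tokens to allow.
#' @return character vector of valid tokens.
#' @export
regionTypeVocabulary <- function(extra = character()) {
  c("intron", "missense", "synonymous", "3'UTR", "5'UTR", "intergenic",
    "other", extra)
}

.P_MAX <- 0.05  # ingest inclusion rule: only associations with P <= 0.05

#' Load GWAS association records
#'
#' Reads a TSV or CSV association table (header matched case-insensitively;
#' required columns \code{rsid, pmid, phenotype, p_value}) into an
#' [AssociationSet-class]. Ingest rules: the P-value must parse, be positive
#' and be at most 0.05 (the inclusion threshold of the source catalogue);
#' \code{(rsid, pmid, phenotype)} must be unique -- later duplicates are
#' dropped. Every dropped row appears in the rejection report with its
#' reason; \code{log10_p} is derived at 6 significant digits. Positional
#' indexes by rsid and PMID are built for lookup.
#'
#' @param source path to a TSV/CSV file, or a data.frame.
#' @return an [AssociationSet-class].
#' @export
loadAssociations <- function(source) {
  df <- if (is.data.frame(source)) {
    source
  } else {
    sep <- if (grepl("\\.csv$", source, ignore.case = TRUE)) "," else "\t"
    utils::read.table(source, header = TRUE, sep = sep, quote = "\"",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", comment.char = "",
                      fill = TRUE)
  }
  names(df) <- tolower(names(df))
  miss <- setdiff(.REQUIRED_COLS, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cc in setdiff(.OPTIONAL_COLS, names(df)))
    df[[cc]] <- NA_character_
  df <- df[, c(.REQUIRED_COLS, .OPTIONAL_COLS)]
  pv <- suppressWarnings(as.numeric(df$p_value))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(pv)] <- "unparsable P-value"
  reason[is.na(reason) & pv <= 0] <- "non-positive P-value"
  reason[is.na(reason) & pv > .P_MAX] <-
    sprintf("exceeds %.2f inclusion threshold", .P_MAX)
  key <- paste(df$rsid, df$pmid, df$phenotype, sep = "\r")
  reason[is.na(reason) & duplicated(key)] <-
    "duplicate (rsid, pmid, phenotype) key"
  keep <- is.na(reason)
  rejected <- df[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[!keep]
    rejected$row <- which(!keep)
  } else {
    rejected <- data.frame(reason = character(), row = integer())
  }
  rec <- df[keep, , drop = FALSE]
  rec$p_value <- pv[keep]
  rec$log10_p <- signif(log10(rec$p_value), 6L)
  rec$maf <- suppressWarnings(as.numeric(rec$maf))
  rec$pos <- suppressWarnings(as.integer(rec$pos))
  rownames(rec) <- NULL
  .newAssociationSet(rec, rejected)
}

.newAssociationSet <- function(records, rejected = data.frame(
                                 reason = character(), row = integer())) {
  idx <- if (nrow(records)) {
    list(rsid = split(seq_len(nrow(records)), records$rsid),
         pmid = split(seq_len(nrow(records)), records$pmid))
  } else list(rsid = list(), pmid = list())
  methods::new("AssociationSet", records = records, rejected = rejected,
               index = idx)
}

#' Accessors for AssociationSet
#'
#' \code{associationRecords} returns the accepted records;
#' \code{rejectedRecords} the rejection report (one row per dropped input
#' row, with \code{reason}).
#'
#' @param x an [AssociationSet-class].
#' @return a data.frame.
#' @rdname associationRecords
#' @export
setMethod("associationRecords", "AssociationSet", function(x) x@records)

#' @rdname associationRecords
#' @export
setMethod("rejectedRecords", "AssociationSet", function(x) x@rejected)

setMethod("show", "AssociationSet", function(object) {
  r <- object@records
  cat("AssociationSet:", nrow(r), "record(s);",
      length(unique(r$rsid)), "SNP(s);",
      length(unique(r$pmid)), "study(ies);",
      nrow(object@rejected), "rejected at ingest\n")
})

#' Look up records by rsid or study
#'
#' @param x an [AssociationSet-class].
#' @param rsid,pmid identifier to look up.
#' @return data.frame of matching records (possibly empty).
#' @export
getSnp <- function(x, rsid) {
  stopifnot(methods::is(x, "AssociationSet"))
  x@records[x@index$rsid[[rsid]], , drop = FALSE]
}

#' @rdname getSnp
#' @export
getStudy <- function(x, pmid) {
  stopifnot(methods::is(x, "AssociationSet"))
  x@records[x@index$pmid[[as.character(pmid)]], , drop = FALSE]
}

#' Filter association records
#'
#' Conjunctive (AND) filtering on the study-view criteria: a P-value cutoff,
#' an E-score cutoff (requires rankings computed over the set -- see
#' Details), a region type from the controlled vocabulary, a phenotype and a
#' gene (both matched case-insensitively, exact string).
#'
#' With \code{maxEScore}, \code{rankings} must be the [RankedSNPSet-class]
#' computed from this set (error otherwise); records whose rsid is absent
#' from the rankings (e.g. unrankable ones) are dropped by that criterion.
#'
#' @param x an [AssociationSet-class].
#' @param maxP keep records with \code{p_value <= maxP}.
#' @param maxEScore keep records whose SNP's E-rank score is
#'   \code{<= maxEScore}.
#' @param regionType token from [regionTypeVocabulary()].
#' @param phenotype,gene exact, case-insensitive match.
#' @param rankings a [RankedSNPSet-class]; required with \code{maxEScore}.
#' @param vocabulary valid region-type tokens.
#' @param ... unused.
#' @return a filtered [AssociationSet-class] (rejection report empty).
#' @rdname filterRecords
#' @export
setMethod("filterRecords", "AssociationSet", function(
    x, maxP = NULL, maxEScore = NULL, regionType = NULL, phenotype = NULL,
    gene = NULL, rankings = NULL, vocabulary = regionTypeVocabulary(), ...) {
  rec <- x@records
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(maxP))
    keep <- keep & !is.na(rec$p_value) & rec$p_value <= maxP
  if (!is.null(regionType)) {
    if (!regionType %in% vocabulary)
      stop("unknown region type ", sQuote(regionType), "; valid tokens: ",
           paste(vocabulary, collapse = ", "), call. = FALSE)
    keep <- keep & !is.na(rec$region_type) & rec$region_type == regionType
  }
  if (!is.null(phenotype))
    keep <- keep & !is.na(rec$phenotype) &
      tolower(rec$phenotype) == tolower(phenotype)
  if (!is.null(gene))
    keep <- keep & !is.na(rec$gene) & tolower(rec$gene) == tolower(gene)
  if (!is.null(maxEScore)) {
    if (is.null(rankings) || !methods::is(rankings, "RankedSNPSet"))
      stop("maxEScore requires rankings computed for this set ",
           "(pass rankings = computeRankings(...))", call. = FALSE)
    es <- rankedTable(rankings)
    sc <- es$e_score[match(rec$rsid, es$rsid)]
    keep <- keep & !is.na(sc) & sc <= maxEScore
  }
  .newAssociationSet(rec[keep, , drop = FALSE])
})

#' Per-SNP summary across studies and phenotypes
#'
#' One row per distinct rsid: distinct study and phenotype counts, the
#' minimum and maximum P-value across all the SNP's records, and the
#' carried annotation fields (first non-missing value per SNP). Optionally
#' joins evolutionary rate and span from a site-metrics table by
#' (chrom, pos).
#'
#' @param x an [AssociationSet-class].
#' @param siteMetrics optional data.frame from [siteEvolutionTable()] /
#'   [readSiteMetrics()].
#' @param ... unused.
#' @return data.frame, one row per rsid, ordered by rsid.
#' @rdname summarizeBySnp
#' @export
setMethod("summarizeBySnp", "AssociationSet", function(x, siteMetrics = NULL,
                                                       ...) {
  rec <- x@records
  if (nrow(rec) == 0L) return(data.frame())
  first <- function(v) {
    v <- v[!is.na(v) & nzchar(as.character(v))]
    if (length(v)) v[[1L]] else NA
  }
  by <- split(seq_len(nrow(rec)), rec$rsid)
  rows <- lapply(names(by), function(id) {
    rr <- rec[by[[id]], , drop = FALSE]
    data.frame(rsid = id,
               chrom = first(rr$chrom), pos = first(rr$pos),
               gene = first(rr$gene), region_type = first(rr$region_type),
               n_studies = length(unique(rr$pmid)),
               n_phenotypes = length(unique(rr$phenotype)),
               min_p = min(rr$p_value), max_p = max(rr$p_value),
               allele = first(rr$allele), maf = first(rr$maf),
               aa_change = first(rr$aa_change),
               polyphen2 = first(rr$polyphen2), sift = first(rr$sift),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rsid), ]
  rownames(out) <- NULL
  if (!is.null(siteMetrics)) {
    m <- match(paste(out$chrom, out$pos), paste(siteMetrics$chrom,
                                                siteMetrics$pos))
    out$evol_rate <- siteMetrics$evol_rate[m]
    out$evol_span <- siteMetrics$evol_span_fraction[m]
  } else {
    out$evol_rate <- NA_real_
    out$evol_span <- NA_real_
  }
  out
})

#' Per-study summary
#'
#' One row per PMID: the number of distinct SNPs, distinct phenotypes and
#' distinct genes (non-empty) among the study's records. Ordered by PMID.
#'
#' @param x an [AssociationSet-class].
#' @return data.frame with columns pmid, n_snps, n_phenotypes, n_genes.
#' @rdname summarizeByStudy
#' @export
setMethod("summarizeByStudy", "AssociationSet", function(x) {
  rec <- x@records
  if (nrow(rec) == 0L)
    return(data.frame(pmid = character(), n_snps = integer(),
                      n_phenotypes = integer(), n_genes = integer()))
  by <- split(seq_len(nrow(rec)), rec$pmid)
  rows <- lapply(names(by), function(id) {
    rr <- rec[by[[id]], , drop = FALSE]
    genes <- rr$gene[!is.na(rr$gene) & nzchar(rr$gene)]
    data.frame(pmid = id,
               n_snps = length(unique(rr$rsid)),
               n_phenotypes = length(unique(rr$phenotype)),
               n_genes = length(unique(genes)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pmid), ]
  rownames(out) <- NULL
  out
})

.SORT_KEYS <- c("rsid", "chrom", "pos", "gene", "region_type", "p_value",
                "log10_p", "allele", "maf", "pmid", "study_title",
                "phenotype", "aa_change", "polyphen2", "sift", "evod",
                "evol_rate", "evol_span", "n_studies", "n_phenotypes",
                "min_p", "max_p", "n_snps", "n_genes")

.sortTable <- function(df, key, decreasing) {
  if (!key %in% .SORT_KEYS)
    stop("unknown sort key ", sQuote(key), "; valid keys: ",
         paste(.SORT_KEYS, collapse = ", "), call. = FALSE)
  if (!key %in% names(df))
    stop("column ", sQuote(key), " not present in this table", call. = FALSE)
  v <- df[[key]]
  missing <- is.na(v) | (is.character(v) & !nzchar(ifelse(is.na(v), "x", v)))
  o <- order(missing,                      # missing values last, always
             xtfrm(v) * if (decreasing) -1 else 1,
             df$rsid %||% seq_len(nrow(df)),
             method = "radix")
  df[o, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sort records or summary tables
#'
#' Stable sort by one of the controlled sortable columns (the resource's
#' sortable fields: identifier, chromosome, position, evolutionary rate and
#' span, study/phenotype counts, min/max P, region, allele, MAF, scores and
#' study fields). Missing values always sort last, regardless of direction;
#' ties are broken by rsid.
#'
#' @param x an [AssociationSet-class] or a summary data.frame.
#' @param key sort column.
#' @param decreasing sort direction.
#' @return object of the same kind as \code{x}, reordered.
#' @rdname sortRecords
#' @export
setMethod("sortRecords", "AssociationSet",
          function(x, key, decreasing = FALSE) {
  .newAssociationSet(.sortTable(x@records, key, decreasing), x@rejected)
})

#' @rdname sortRecords
#' @export
setMethod("sortRecords", "data.frame", function(x, key, decreasing = FALSE) {
  out <- .sortTable(x, key, decreasing)
  rownames(out) <- NULL
  out
})

#' Keyword search over records
#'
#' Case-insensitive substring match of a free-text query against phenotype,
#' phenotype category, gene and study title.
#'
#' @param x an [AssociationSet-class].
#' @param query non-empty search string.
#' @return a filtered [AssociationSet-class].
#' @rdname keywordSearch
#' @export
setMethod("keywordSearch", "AssociationSet", function(x, query) {
  query <- trimws(query)
  if (!nzchar(query))
    stop("empty search query", call. = FALSE)
  rec <- x@records
  fields <- c("phenotype", "phenotype_category", "gene", "study_title")
  hit <- rep(FALSE, nrow(rec))
  for (f in intersect(fields, names(rec))) {
    v <- as.character(rec[[f]])
    v[is.na(v)] <- ""
    hit <- hit | grepl(tolower(query), tolower(v), fixed = TRUE)
  }
  .newAssociationSet(rec[hit, , drop = FALSE])
})
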