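## Tree and alignment-column I/O. Coordinates are 1-based throughout;
## branch lengths are millions of years (My). Rate conversion to per-Gy
## happens once, in the rate computation, never here.

#' Construct a TimeTree from an ape phylo object
#'
#' @param phylo an \code{ape::phylo} with branch lengths in My.
#' @return a [TimeTree-class].
#' @export
TimeTree <- function(phylo) {
  methods::new("TimeTree", phylo = phylo)
}

.checkNewickSyntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at character ", i,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at character ",
         length(chars), call. = FALSE)
  stripped <- gsub("[[:space:]]+$", "", text)
  if (!nzchar(stripped) || substring(stripped, nchar(stripped)) != ";")
    stop("Newick parse error: missing terminal ';' at character ",
         nchar(stripped) + 1L, call. = FALSE)
  invisible(TRUE)
}

#' Read a time-calibrated tree from Newick
#'
#' Parses a Newick string (or a file containing one) into a
#' [TimeTree-class]. Branch lengths are interpreted as durations in millions
#' of years. Every edge must carry a branch length: a missing length is an
#' error ("unlengthed edge"), never silently defaulted. Malformed Newick is
#' reported with the character offset of the offending parenthesis or the
#' missing semicolon; duplicate leaf labels are an error.
#'
#' @param source a Newick string (containing ";") or a path to a file.
#' @return a [TimeTree-class].
#' @examples
#' tr <- readTimeTree("((H:100,B:100):400,(C:100,D:100):400);")
#' totalTreeTime(tr)
#' @export
readTimeTree <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  isText <- grepl("[();]", source) || !file.exists(source)
  text <- if (isText) source
          else paste(readLines(source, warn = FALSE), collapse = "")
  .checkNewickSyntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e)
                    stop("Newick parse error: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(phy))
    stop("Newick parse error: no tree could be read", call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  TimeTree(phy)
}

#' Serialize a TimeTree to Newick
#'
#' @param tree a [TimeTree-class].
#' @param file optional path; if missing the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeTimeTree <- function(tree, file = NULL) {
  stopifnot(methods::is(tree, "TimeTree"))
  txt <- ape::write.tree(tree@phylo)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @describeIn totalTreeTime sum of branch durations of the wrapped phylo.
setMethod("totalTreeTime", "TimeTree", function(tree) {
  sum(tree@phylo$edge.length)
})

#' Leaf labels of a TimeTree
#'
#' @param tree a [TimeTree-class].
#' @return character vector of leaf (taxon) labels.
#' @rdname leafLabels
#' @export
setMethod("leafLabels", "TimeTree", function(tree) tree@phylo$tip.label)

setMethod("show", "TimeTree", function(object) {
  phy <- object@phylo
  cat("TimeTree with", length(phy$tip.label), "leaves;",
      "total time", format(sum(phy$edge.length)), "My\n")
  cat("  leaves:", paste(utils::head(phy$tip.label, 8L), collapse = ", "),
      if (length(phy$tip.label) > 8L) "..." else "", "\n")
})

#' Construct a SiteColumn
#'
#' @param residues named character vector, taxon -> residue; bases are
#'   upper-cased, \code{"-"} is GAP, \code{"N"} is MISSING.
#' @param referenceTaxon label of the reference (human) sequence.
#' @param chrom,pos reference coordinate (1-based).
#' @param assembly assembly label, opaque metadata.
#' @return a [SiteColumn-class].
#' @export
SiteColumn <- function(residues, referenceTaxon, chrom = "chr1", pos = 1L,
                       assembly = "B37/hg19") {
  res <- toupper(as.character(residues))
  names(res) <- names(residues)
  bad <- setdiff(unique(res), .RESIDUE_TOKENS)
  if (length(bad))
    stop("unknown residue character(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  methods::new("SiteColumn", chrom = chrom, pos = as.integer(pos),
               assembly = assembly, referenceTaxon = referenceTaxon,
               residues = res)
}

#' Taxa in which a position exists
#'
#' Taxa of a [SiteColumn-class] whose residue is a proper base (A/C/G/T).
#' GAP and MISSING taxa are excluded: both carry no usable base, and both
#' are treated as "position absent" for the evolutionary timespan.
#'
#' @param column a [SiteColumn-class].
#' @return character vector of taxon labels.
#' @rdname presentTaxa
#' @export
setMethod("presentTaxa", "SiteColumn", function(column) {
  names(column@residues)[column@residues %in% .BASES]
})

setMethod("show", "SiteColumn", function(object) {
  cat("SiteColumn ", object@chrom, ":", object@pos,
      " (", object@assembly, "), reference ", object@referenceTaxon,
      "=", object@residues[[object@referenceTaxon]], "\n", sep = "")
  cat("  ", paste(names(object@residues), object@residues,
                  sep = "=", collapse = " "), "\n", sep = "")
})

## ---- column readers -------------------------------------------------------

.columnsFromMatrix <- function(mat, referenceTaxon, chrom, startPos,
                               assembly) {
  ## mat: taxa x alignment-columns character matrix
  if (!referenceTaxon %in% rownames(mat))
    stop("reference taxon ", sQuote(referenceTaxon),
         " absent from alignment", call. = FALSE)
  bad <- setdiff(unique(as.vector(mat)), .RESIDUE_TOKENS)
  if (length(bad))
    stop("unknown residue character(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  refRow <- mat[referenceTaxon, ]
  out <- vector("list", sum(refRow != .GAP))
  k <- 0L
  pos <- startPos - 1L
  nSkipped <- 0L
  for (j in seq_len(ncol(mat))) {
    if (refRow[j] == .GAP) next      # no human coordinate at a reference gap
    pos <- pos + 1L
    if (refRow[j] == .MISSING) {     # position exists but human base unknown
      nSkipped <- nSkipped + 1L
      next
    }
    k <- k + 1L
    out[[k]] <- SiteColumn(mat[, j], referenceTaxon, chrom = chrom,
                           pos = pos, assembly = assembly)
  }
  if (nSkipped > 0L)
    warning(nSkipped, " position(s) skipped: reference base is 'N'",
            call. = FALSE)
  out[seq_len(k)]
}

.readColumnsFasta <- function(source, referenceTaxon, chrom, startPos,
                              assembly) {
  seqs <- if (length(source) > 1L || !file.exists(source[1L])) {
    stopifnot(!is.null(names(source)))
    source
  } else {
    s <- Biostrings::readBStringSet(source)
    stats::setNames(as.character(s), names(s))
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("aligned FASTA rows have unequal lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  .columnsFromMatrix(mat, referenceTaxon, chrom, startPos, assembly)
}

.readColumnsTsv <- function(source, referenceTaxon, chrom, startPos,
                            assembly) {
  df <- utils::read.delim(source, check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  nm <- names(df)
  chromCol <- which(tolower(nm) == "chrom")
  posCol <- which(tolower(nm) == "pos")
  taxa <- nm[setdiff(seq_along(nm), c(chromCol, posCol))]
  if (!referenceTaxon %in% taxa)
    stop("reference taxon ", sQuote(referenceTaxon),
         " absent from TSV header", call. = FALSE)
  out <- vector("list", nrow(df))
  k <- 0L
  nSkipped <- 0L
  for (i in seq_len(nrow(df))) {
    res <- toupper(unlist(df[i, taxa, drop = TRUE]))
    names(res) <- taxa
    bad <- setdiff(unique(res), .RESIDUE_TOKENS)
    if (length(bad))
      stop("unknown residue character(s): ",
           paste(sQuote(bad), collapse = ", "), " at row ", i, call. = FALSE)
    if (!res[[referenceTaxon]] %in% .BASES) {
      nSkipped <- nSkipped + 1L
      next
    }
    k <- k + 1L
    out[[k]] <- SiteColumn(
      res, referenceTaxon,
      chrom = if (length(chromCol)) df[i, chromCol] else chrom,
      pos = if (length(posCol)) as.integer(df[i, posCol])
            else startPos + i - 1L,
      assembly = assembly)
  }
  if (nSkipped > 0L)
    warning(nSkipped, " row(s) skipped: no reference base", call. = FALSE)
  out[seq_len(k)]
}

.readColumnsMaf <- function(source, referenceTaxon, assembly) {
  lines <- readLines(source, warn = FALSE)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "a")) { i <- i + 1L; next }
    ## collect the s-lines of this block
    j <- i + 1L
    srcs <- character(); starts <- integer(); strands <- character()
    texts <- character()
    while (j <= n && (startsWith(lines[j], "s") ||
                      startsWith(lines[j], "i") ||
                      startsWith(lines[j], "e") ||
                      startsWith(lines[j], "q"))) {
      if (startsWith(lines[j], "s ") || startsWith(lines[j], "s\t")) {
        f <- strsplit(trimws(lines[j]), "[[:space:]]+")[[1]]
        if (length(f) < 7L)
          stop("malformed MAF 's' line: ", lines[j], call. = FALSE)
        srcs <- c(srcs, f[2]); starts <- c(starts, as.integer(f[3]))
        strands <- c(strands, f[5]); texts <- c(texts, f[7])
      }
      j <- j + 1L
    }
    if (length(srcs)) {
      taxa <- sub("\\..*$", "", srcs)
      refIdx <- match(referenceTaxon, taxa)
      if (is.na(refIdx))
        stop("reference taxon ", sQuote(referenceTaxon),
             " absent from MAF block", call. = FALSE)
      if (strands[refIdx] != "+")
        stop("reference sequence on '-' strand is not supported",
             call. = FALSE)
      mat <- do.call(rbind, strsplit(toupper(texts), "", fixed = TRUE))
      rownames(mat) <- taxa
      refChrom <- sub("^[^.]*\\.?", "", srcs[refIdx])
      if (!nzchar(refChrom)) refChrom <- "chr?"
      cols <- .columnsFromMatrix(mat, referenceTaxon, chrom = refChrom,
                                 startPos = starts[refIdx] + 1L,
                                 assembly = assembly)
      out <- c(out, cols)
    }
    i <- j
  }
  out
}

#' Read alignment columns for the reference sequence
#'
#' Extracts one [SiteColumn-class] per reference-sequence position (where
#' the reference carries a base A/C/G/T) from a UCSC-style MAF file, an
#' aligned FASTA, or a per-position TSV (header of taxon names, optional
#' \code{chrom}/\code{pos} columns, one row per position). \code{"-"} is
#' recorded as GAP (position absent in that species), \code{"N"} as MISSING
#' (no data); species absent from a MAF block are recorded as MISSING.
#' Reference coordinates are 1-based (MAF starts, which are 0-based, are
#' converted).
#'
#' @param source file path, or for \code{format = "fasta"} optionally a
#'   named character vector of equal-length aligned sequences.
#' @param format one of \code{"fasta"}, \code{"maf"}, \code{"tsv"}.
#' @param referenceTaxon label of the reference (human) sequence.
#' @param chrom,startPos coordinate of the first reference base (used where
#'   the source itself carries no coordinates).
#' @param assembly assembly label carried into each column.
#' @return list of [SiteColumn-class], in reference-coordinate order.
#' @examples
#' cols <- readColumns(c(H = "AC-", B = "AC-", C = "GCA", D = "GCA"),
#'                     format = "fasta", referenceTaxon = "H")
#' length(cols)  # 2: the reference-gap column has no human coordinate
#' @export
readColumns <- function(source, format = c("fasta", "maf", "tsv"),
                        referenceTaxon, chrom = "chr1", startPos = 1L,
                        assembly = "B37/hg19") {
  format <- match.arg(format)
  switch(format,
    fasta = .readColumnsFasta(source, referenceTaxon, chrom,
                              as.integer(startPos), assembly),
    tsv = .readColumnsTsv(source, referenceTaxon, chrom,
                          as.integer(startPos), assembly),
    maf = {
      cols <- .readColumnsMaf(source, referenceTaxon, assembly)
      ## species missing from a block: mark MISSING against the block union
      allTaxa <- unique(unlist(lapply(cols, function(cc) names(cc@residues))))
      lapply(cols, function(cc) {
        absent <- setdiff(allTaxa, names(cc@residues))
        if (!length(absent)) return(cc)
        res <- c(cc@residues,
                 stats::setNames(rep(.MISSING, length(absent)), absent))
        SiteColumn(res, cc@referenceTaxon, chrom = cc@chrom, pos = cc@pos,
                   assembly = cc@assembly)
      })
    })
}

## ---- site-metrics TSV -----------------------------------------------------

.METRIC_COLS <- c("chrom", "pos", "evol_rate", "evol_span_fraction",
                  "evol_span_my", "n_present_taxa", "conservation_class")

#' Write per-site evolutionary metrics to TSV
#'
#' One row per position with columns \code{chrom, pos, evol_rate,
#' evol_span_fraction, evol_span_my, n_present_taxa, conservation_class}.
#' Numeric values are written at 6 significant digits and round-trip
#' losslessly through [readSiteMetrics()] at that precision. Undefined rates
#' are written as \code{NA}.
#'
#' @param metrics data.frame as produced by [siteEvolutionTable()].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeSiteMetrics <- function(metrics, file) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L)
    stop("no site metrics to write", call. = FALSE)
  miss <- setdiff(.METRIC_COLS, names(metrics))
  if (length(miss))
    stop("metrics table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- metrics[, .METRIC_COLS]
  for (cc in c("evol_rate", "evol_span_fraction", "evol_span_my"))
    out[[cc]] <- signif(out[[cc]], 6L)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read per-site evolutionary metrics from TSV
#'
#' @param file path written by [writeSiteMetrics()].
#' @return data.frame with the standard metric columns.
#' @export
readSiteMetrics <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  miss <- setdiff(.METRIC_COLS, names(df))
  if (length(miss))
    stop("site-metrics file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}
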