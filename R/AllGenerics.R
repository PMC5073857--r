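#' Total time elapsed on a tree
#'
#' The sum of all branch durations of a [TimeTree-class], in millions of
#' years. This is the denominator of the evolutionary span fraction, and
#' (after pruning to the taxa in which a position exists, and conversion to
#' billions of years) of the evolutionary rate.
#'
#' @param tree a [TimeTree-class].
#' @return a single non-negative number, in My.
#' @examples
#' tr <- readTimeTree("((H:100,B:100):400,(C:100,D:100):400);")
#' totalTreeTime(tr)  # 1200
#' @export
setGeneric("totalTreeTime", function(tree) standardGeneric("totalTreeTime"))

#' @rdname leafLabels
#' @export
setGeneric("leafLabels", function(tree) standardGeneric("leafLabels"))

#' @rdname presentTaxa
#' @export
setGeneric("presentTaxa", function(column) standardGeneric("presentTaxa"))

#' @rdname associationRecords
#' @export
setGeneric("associationRecords",
           function(x) standardGeneric("associationRecords"))

#' @rdname associationRecords
#' @export
setGeneric("rejectedRecords", function(x) standardGeneric("rejectedRecords"))

#' @rdname rankedTable
#' @export
setGeneric("rankedTable", function(x) standardGeneric("rankedTable"))

#' @rdname rankedTable
#' @export
setGeneric("excludedTable", function(x) standardGeneric("excludedTable"))

#' @rdname filterRecords
#' @export
setGeneric("filterRecords", function(x, ...) standardGeneric("filterRecords"))

#' @rdname summarizeBySnp
#' @export
setGeneric("summarizeBySnp", function(x, ...) standardGeneric("summarizeBySnp"))

#' @rdname summarizeByStudy
#' @export
setGeneric("summarizeByStudy", function(x) standardGeneric("summarizeByStudy"))

#' @rdname sortRecords
#' @export
setGeneric("sortRecords",
           function(x, key, decreasing = FALSE) standardGeneric("sortRecords"))

#' @rdname keywordSearch
#' @export
setGeneric("keywordSearch", function(x, query) standardGeneric("keywordSearch"))
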