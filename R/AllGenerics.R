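#' @rdname ErgCohort-accessors
#' @export
setGeneric("clinical", function(x) standardGeneric("clinical"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("fusionCalls", function(x) standardGeneric("fusionCalls"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("mutationCalls", function(x) standardGeneric("mutationCalls"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("segTable", function(x) standardGeneric("segTable"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("exprCounts", function(x) standardGeneric("exprCounts"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("methBeta", function(x) standardGeneric("methBeta"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("probeAnno", function(x) standardGeneric("probeAnno"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("geneAnno", function(x) standardGeneric("geneAnno"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("regionAnno", function(x) standardGeneric("regionAnno"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("cohortGenome", function(x) standardGeneric("cohortGenome"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname ErgCohort-accessors
#' @export
setGeneric("sampleGroups<-", function(x, value) standardGeneric("sampleGroups<-"))

#' Accessors for ErgCohort slots
#'
#' `clinical()`, `fusionCalls()`, `mutationCalls()`, `segTable()`,
#' `exprCounts()`, `methBeta()`, `probeAnno()`, `geneAnno()`,
#' `regionAnno()`, `cohortGenome()` and `thresholds()` return the
#' corresponding layer. `sampleGroups()` returns the named factor of group
#' labels (ERG_POS / ERG_NEG / UNASSIGNED) keyed by sample; the replacement
#' form updates the clinical table from a named vector.
#'
#' @param x an `ErgCohort`.
#' @param value named character/factor of group labels for
#'   `sampleGroups<-`.
#' @return The requested slot, or the named group factor.
#' @name ErgCohort-accessors
NULL

#' @rdname ErgCohort-accessors
setMethod("clinical", "ErgCohort", function(x) x@clinical)
#' @rdname ErgCohort-accessors
setMethod("fusionCalls", "ErgCohort", function(x) x@fusions)
#' @rdname ErgCohort-accessors
setMethod("mutationCalls", "ErgCohort", function(x) x@mutations)
#' @rdname ErgCohort-accessors
setMethod("segTable", "ErgCohort", function(x) x@segments)
#' @rdname ErgCohort-accessors
setMethod("exprCounts", "ErgCohort", function(x) x@expression)
#' @rdname ErgCohort-accessors
setMethod("methBeta", "ErgCohort", function(x) x@methylation)
#' @rdname ErgCohort-accessors
setMethod("probeAnno", "ErgCohort", function(x) x@probeAnno)
#' @rdname ErgCohort-accessors
setMethod("geneAnno", "ErgCohort", function(x) x@genes)
#' @rdname ErgCohort-accessors
setMethod("regionAnno", "ErgCohort", function(x) x@regions)
#' @rdname ErgCohort-accessors
setMethod("cohortGenome", "ErgCohort", function(x) x@genome)
#' @rdname ErgCohort-accessors
setMethod("thresholds", "ErgCohort", function(x) x@thresholds)
#' @rdname ErgCohort-accessors
setMethod("sampleGroups", "ErgCohort", function(x) {
  g <- factor(x@clinical$group, levels = .GROUP_LEVELS)
  names(g) <- x@clinical$sample_id
  g
})
#' @rdname ErgCohort-accessors
setMethod("sampleGroups<-", "ErgCohort", function(x, value) {
  stopifnot(!is.null(names(value)))
  idx <- match(x@clinical$sample_id, names(value))
  g <- as.character(value)[idx]
  g[is.na(g)] <- "UNASSIGNED"
  if (!all(g %in% .GROUP_LEVELS)) stop("invalid group label")
  x@clinical$group <- g
  validObject(x)
  x
})

#' @rdname AlterationMatrix-accessors
#' @export
setGeneric("alteredMatrix", function(x, classes = .EVENT_CLASSES)
  standardGeneric("alteredMatrix"))
#' @rdname AlterationMatrix-accessors
#' @export
setGeneric("altFrequency", function(x, samples = NULL,
                                    classes = .EVENT_CLASSES)
  standardGeneric("altFrequency"))

#' Accessors for AlterationMatrix
#'
#' `alteredMatrix()` collapses the class dimension to a logical
#' gene x sample matrix (any of the requested event classes).
#' `altFrequency()` returns the per-gene alteration fraction over a sample
#' subset. `dimnames`/`dim` behave as for the underlying array.
#'
#' @param x an `AlterationMatrix`.
#' @param classes subset of `c("mut","amp","del","fusion")`.
#' @param samples sample identifiers (default: all).
#' @return logical matrix, or named numeric vector of frequencies.
#' @name AlterationMatrix-accessors
NULL

#' @rdname AlterationMatrix-accessors
setMethod("alteredMatrix", "AlterationMatrix", function(x, classes = .EVENT_CLASSES) {
  classes <- match.arg(classes, .EVENT_CLASSES, several.ok = TRUE)
  sub <- x@calls[, , classes, drop = FALSE]
  out <- apply(sub, c(1L, 2L), any)
  dimnames(out) <- dimnames(x@calls)[1:2]
  out
})

#' @rdname AlterationMatrix-accessors
setMethod("altFrequency", "AlterationMatrix",
          function(x, samples = NULL, classes = .EVENT_CLASSES) {
  m <- alteredMatrix(x, classes)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing))
      stop("unknown sample(s): ", paste(missing, collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  rowMeans(m)
})

#' @rdname AlterationMatrix-accessors
#' @export
setMethod("dim", "AlterationMatrix", function(x) dim(x@calls))
#' @rdname AlterationMatrix-accessors
#' @export
setMethod("dimnames", "AlterationMatrix", function(x) dimnames(x@calls))

#' @rdname BinTrack-accessors
#' @export
setGeneric("binStatus", function(x) standardGeneric("binStatus"))
#' @rdname BinTrack-accessors
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' Accessors for BinTrack
#'
#' `binStatus()` returns the bins x samples ternary status matrix
#' (-1/0/+1); `binRanges()` the parallel `GRanges` of bin intervals.
#'
#' @param x a `BinTrack`.
#' @name BinTrack-accessors
NULL

#' @rdname BinTrack-accessors
setMethod("binStatus", "BinTrack", function(x) x@status)
#' @rdname BinTrack-accessors
setMethod("binRanges", "BinTrack", function(x) x@bins)
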