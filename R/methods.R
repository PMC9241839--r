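#' @rdname CountTable-class
#' @param ... unused.
#' @export
setMethod("counts", "CountTable", function(object, ...) object@counts)

#' @rdname CountTable-class
#' @export
setMethod("taxonIds", "CountTable", function(object) rownames(object@counts))

#' @rdname CountTable-class
#' @export
setMethod("sampleIds", "CountTable", function(object) colnames(object@counts))

#' @rdname CountTable-class
#' @export
setMethod("dim", "CountTable", function(x) dim(x@counts))

#' @rdname CountTable-class
#' @param i,j taxon and sample indices (integer, logical or character).
#' @param drop ignored; subsetting always returns a CountTable.
#' @export
setMethod("[", "CountTable", function(x, i, j, ..., drop = FALSE) {
  m <- x@counts
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  new("CountTable", counts = m, metadata = x@metadata)
})

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d taxa x %d samples (total reads %s)\n",
              nrow(object@counts), ncol(object@counts),
              format(sum(object@counts), big.mark = ",")))
  if (length(object@metadata))
    cat("  metadata fields:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' @rdname DistanceMatrix-class
#' @param object,x a DistanceMatrix.
#' @export
setMethod("sampleIds", "DistanceMatrix", function(object) rownames(object@values))

#' @rdname DistanceMatrix-class
#' @param ... unused.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' @rdname DistanceMatrix-class
#' @export
setMethod("dim", "DistanceMatrix", function(x) dim(x@values))

#' Subset a DistanceMatrix to a set of samples
#' @rdname DistanceMatrix-class
#' @param i,j sample indices; a single index set `i` selects the square
#'   submatrix.
#' @param drop ignored.
#' @export
setMethod("[", "DistanceMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(j)) j <- i
  new("DistanceMatrix", values = x@values[i, j, drop = FALSE],
      method = x@method)
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s): %d samples\n",
              ifelse(is.na(object@method), "unknown metric", object@method),
              nrow(object@values)))
})

#' @rdname SourceSet-class
#' @param object a SourceSet.
#' @export
setMethod("phaseLabels", "SourceSet", function(object) rownames(object@sourceCounts))

#' @rdname SourceSet-class
#' @export
setMethod("sourceCounts", "SourceSet", function(object) object@sourceCounts)

#' @rdname SourceSet-class
#' @export
setMethod("taxonIds", "SourceSet", function(object) colnames(object@sourceCounts))

setMethod("show", "SourceSet", function(object) {
  cat(sprintf("SourceSet: %d source communities (%s) over %d taxa, depth %s\n",
              nrow(object@sourceCounts),
              paste(rownames(object@sourceCounts), collapse = ", "),
              ncol(object@sourceCounts), object@depth))
})

#' @rdname Attribution-class
#' @param object a Attribution.
#' @export
setMethod("proportions", "Attribution", function(object) object@proportions)

#' @rdname Attribution-class
#' @export
setMethod("restartSD", "Attribution", function(object) object@restartSD)

#' @rdname Attribution-class
#' @export
setMethod("sampleIds", "Attribution", function(object) rownames(object@proportions))

setMethod("show", "Attribution", function(object) {
  cat(sprintf("Attribution: %d sinks over sources {%s}\n",
              nrow(object@proportions),
              paste(colnames(object@proportions), collapse = ", ")))
})

#' @rdname GeneratedCohort-class
#' @param object a GeneratedCohort.
#' @export
setMethod("cohortTable", "GeneratedCohort", function(object) object@table)

#' @rdname GeneratedCohort-class
#' @export
setMethod("cohortMetadata", "GeneratedCohort", function(object) object@metadata)

#' @rdname GeneratedCohort-class
#' @export
setMethod("cohortTree", "GeneratedCohort", function(object) object@tree)

#' @rdname GeneratedCohort-class
#' @export
setMethod("cohortTruth", "GeneratedCohort", function(object) object@truth)

setMethod("show", "GeneratedCohort", function(object) {
  md <- object@metadata
  cat(sprintf("GeneratedCohort: %d mice, %d time points, %d taxa, %d samples\n",
              length(unique(md$mouse_id)), length(unique(md$age_weeks)),
              nrow(counts(object@table)), ncol(counts(object@table))))
})
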