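#' @import methods
NULL

#' Canonical life-phase labels
#'
#' The five murine life phases used throughout the package, in canonical
#' chronological order: maturing (MR), mature (MA), middle age (MD), old (OD)
#' and very old (VO).
#'
#' @return Character vector of the five phase labels in canonical order.
#' @export
#' @examples
#' lifePhases()
lifePhases <- function() c("MR", "MA", "MD", "OD", "VO")

#' CountTable: taxa-by-sample integer counts
#'
#' The universal currency of the pipeline: a nonnegative integer matrix with
#' taxa as rows and samples as columns, both uniquely named. Validity
#' enforces integrality, nonnegativity, unique identifiers and matching
#' dimnames.
#'
#' @slot counts integer matrix (taxa x samples) with dimnames.
#' @slot metadata list of arbitrary per-object annotations (e.g. rarefaction
#'   reports).
#'
#' @seealso [CountTable()] for the constructor, [readCountTable()] for I/O.
#' @export
setClass("CountTable",
  representation(counts = "matrix", metadata = "list"),
  prototype(counts = matrix(integer(0), 0, 0), metadata = list())
)

setValidity("CountTable", function(object) {
  m <- object@counts
  msgs <- character(0)
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    msgs <- c(msgs, "counts must have taxon row names and sample column names")
  if (anyDuplicated(rownames(m)))
    msgs <- c(msgs, sprintf("duplicate taxon id: %s",
                            rownames(m)[duplicated(rownames(m))][1]))
  if (anyDuplicated(colnames(m)))
    msgs <- c(msgs, sprintf("duplicate sample id: %s",
                            colnames(m)[duplicated(colnames(m))][1]))
  if (length(m) > 0) {
    if (any(is.na(m))) msgs <- c(msgs, "counts contain NA")
    else {
      if (any(m < 0)) msgs <- c(msgs, "counts must be nonnegative")
      if (any(m != round(m))) msgs <- c(msgs, "counts must be integral")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CountTable
#'
#' @param counts numeric/integer matrix of nonnegative counts, taxa as rows,
#'   samples as columns. Dimnames are required unless `taxon_ids` /
#'   `sample_ids` are given.
#' @param taxon_ids optional character vector of row (taxon) identifiers.
#' @param sample_ids optional character vector of column (sample) identifiers.
#' @param metadata optional list of annotations.
#' @return A validated [CountTable-class] object.
#' @export
#' @examples
#' ct <- CountTable(matrix(c(5, 1, 0, 2), 2, 2,
#'   dimnames = list(c("ASV1", "ASV2"), c("s1", "s2"))))
#' ct
CountTable <- function(counts, taxon_ids = NULL, sample_ids = NULL,
                       metadata = list()) {
  counts <- as.matrix(counts)
  if (!is.null(taxon_ids)) rownames(counts) <- taxon_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  mode(counts) <- "numeric"
  if (length(counts) && all(!is.na(counts)) && all(counts == round(counts)) &&
      max(counts, 0) < .Machine$integer.max)
    storage.mode(counts) <- "integer"
  new("CountTable", counts = counts, metadata = metadata)
}

#' DistanceMatrix: pairwise sample dissimilarities
#'
#' Symmetric, nonnegative, zero-diagonal matrix of pairwise dissimilarities
#' with sample identifiers on both dimensions.
#'
#' @slot values square numeric matrix with matching row/column sample names.
#' @slot method character scalar naming the dissimilarity.
#' @export
setClass("DistanceMatrix",
  representation(values = "matrix", method = "character"),
  prototype(values = matrix(numeric(0), 0, 0), method = NA_character_)
)

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "matrix must be square")
  if (nrow(v) > 0) {
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
      msgs <- c(msgs, "row and column sample ids must match")
    if (any(is.na(v))) msgs <- c(msgs, "distances contain NA")
    else {
      if (max(abs(v - t(v))) > 1e-12) msgs <- c(msgs, "matrix must be symmetric")
      if (any(diag(v) != 0)) msgs <- c(msgs, "diagonal must be exactly zero")
      if (any(v < 0)) msgs <- c(msgs, "distances must be nonnegative")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DistanceMatrix
#'
#' @param values square numeric matrix (sample x sample) with matching
#'   dimnames, or a [stats::dist] object with labels.
#' @param method optional name of the dissimilarity measure.
#' @return A validated [DistanceMatrix-class].
#' @export
DistanceMatrix <- function(values, method = NA_character_) {
  if (inherits(values, "dist")) values <- as.matrix(values)
  values <- as.matrix(values)
  diag(values) <- 0
  values <- (values + t(values)) / 2
  new("DistanceMatrix", values = values, method = as.character(method))
}

#' SourceSet: per-phase source communities for source tracking
#'
#' Each row is one pooled, rarefied source community; rows are labelled by
#' life phase (labels may repeat after batch calibration appends control
#' communities).
#'
#' @slot sourceCounts integer matrix (sources x taxa); row names are phase
#'   labels, column names taxon ids.
#' @slot depth integer rarefaction depth each row was drawn to.
#' @export
setClass("SourceSet",
  representation(sourceCounts = "matrix", depth = "integer"),
  prototype(sourceCounts = matrix(integer(0), 0, 0), depth = NA_integer_)
)

setValidity("SourceSet", function(object) {
  m <- object@sourceCounts
  msgs <- character(0)
  if (nrow(m) > 0) {
    if (is.null(rownames(m)) || is.null(colnames(m)))
      msgs <- c(msgs, "sourceCounts must carry phase row labels and taxon column names")
    if (any(m < 0) || any(m != round(m)))
      msgs <- c(msgs, "source counts must be nonnegative integers")
    if (!is.na(object@depth) && any(rowSums(m) != object@depth))
      msgs <- c(msgs, "each source row total must equal the rarefaction depth")
  }
  if (length(msgs)) msgs else TRUE
})

#' Attribution: per-sink source proportions
#'
#' Posterior mean proportions of each sink over the known sources plus the
#' "unknown" component, together with the standard deviation of the
#' proportions across Gibbs restarts.
#'
#' @slot proportions numeric matrix (sinks x sources+unknown), rows summing
#'   to one; last column is named "unknown".
#' @slot restartSD numeric matrix of the same shape: SD over restarts.
#' @export
setClass("Attribution",
  representation(proportions = "matrix", restartSD = "matrix"),
  prototype(proportions = matrix(numeric(0), 0, 0),
            restartSD = matrix(numeric(0), 0, 0))
)

setValidity("Attribution", function(object) {
  p <- object@proportions
  msgs <- character(0)
  if (nrow(p) > 0) {
    if (is.null(colnames(p)) || !"unknown" %in% colnames(p))
      msgs <- c(msgs, "proportions must include an 'unknown' column")
    if (any(p < -1e-12) || any(p > 1 + 1e-12))
      msgs <- c(msgs, "proportions must lie in [0, 1]")
    if (max(abs(rowSums(p) - 1)) > 1e-9)
      msgs <- c(msgs, "each sink's proportions must sum to 1 (within 1e-9)")
    if (!identical(dim(p), dim(object@restartSD)))
      msgs <- c(msgs, "restartSD must match proportions in shape")
    if (any(object@restartSD < 0)) msgs <- c(msgs, "restartSD must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' GeneratedCohort: a simulated longitudinal mouse cohort
#'
#' Output of [simulateCohort()]: the count table, per-sample metadata, a
#' rooted phylogeny, the ground truth used for evaluation, and enough
#' internal state (expected per-sample compositions, per-sample seeds and
#' depths) for [applyDietShift()] to redraw counts reproducibly.
#'
#' @slot table a [CountTable-class].
#' @slot metadata data.frame with sample_id, mouse_id, age_weeks, life_phase,
#'   diet, cage.
#' @slot tree character scalar: rooted newick with taxon tips.
#' @slot truth data.frame with sample_id, age_weeks, phase, diet.
#' @slot design list echoing the [cohortDesign()] used.
#' @slot expectedProfiles numeric matrix (taxa x samples) of post-perturbation
#'   expected relative abundances.
#' @slot sampleSeeds integer vector of per-sample RNG seeds.
#' @slot depths integer vector of per-sample sequencing depths.
#' @export
setClass("GeneratedCohort",
  representation(table = "CountTable", metadata = "data.frame",
                 tree = "character", truth = "data.frame", design = "list",
                 expectedProfiles = "matrix", sampleSeeds = "integer",
                 depths = "integer")
)

setValidity("GeneratedCohort", function(object) {
  msgs <- character(0)
  ct <- object@table
  if (ncol(counts(ct)) > 0) {
    if (any(colSums(counts(ct)) <= 0))
      msgs <- c(msgs, "every sample must have total count > 0")
    if (!identical(colnames(counts(ct)), object@metadata$sample_id))
      msgs <- c(msgs, "metadata rows must align with table samples")
    tr <- object@truth
    if (!isTRUE(all.equal(tr$age_weeks,
                          object@metadata$age_weeks[match(tr$sample_id,
                                                   object@metadata$sample_id)])))
      msgs <- c(msgs, "truth ages must equal metadata ages exactly")
  }
  if (length(msgs)) msgs else TRUE
})
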