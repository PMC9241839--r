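#' End-to-end microbiota age prediction
#'
#' Runs the full pipeline on a cohort: low-prevalence filtering, rarefaction,
#' Bray-Curtis dissimilarity, pairwise PERMANOVA between time points with
#' Benjamini-Hochberg correction, selection of one source time point per life
#' phase, pooling/rarefaction of the source communities, Gibbs attribution of
#' every sink, and conversion to predicted ages via the midpoint formula with
#' the uncertainty filter.
#'
#' @param cohort a [GeneratedCohort-class], or a list with elements `table`
#'   ([CountTable-class]) and `metadata` (data.frame with sample_id,
#'   age_weeks).
#' @param config a [runConfig()].
#' @param sink_samples optional character vector restricting which samples
#'   are attributed as sinks (default: all samples surviving rarefaction).
#' @param calibration optional list with `table` (a [CountTable-class] of
#'   control samples) and `ages` (named numeric): appended as calibration
#'   sources via [calibrateSources()].
#' @return List with elements `table` (rarefied), `distance`, `pairwise`,
#'   `selection`, `sources`, `attribution`, `predictions`, `evaluation`.
#' @export
#' @examples
#' \donttest{
#' co <- simulateCohort(cohortDesign(n_mice = 4, n_taxa = 40,
#'   depth_mean = 1500, seed = 1))
#' res <- predictCohortAges(co, runConfig(rarefaction_depth = 800,
#'   n_permutations = 99, burnins = 25, restarts = 3))
#' head(res$predictions)
#' }
predictCohortAges <- function(cohort, config = runConfig(),
                              sink_samples = NULL, calibration = NULL) {
  if (is(cohort, "GeneratedCohort")) {
    table <- cohortTable(cohort)
    metadata <- cohortMetadata(cohort)
  } else {
    table <- cohort$table
    metadata <- cohort$metadata
  }
  table <- filterLowPrevalence(table, config$min_prevalence)
  rarefied <- rarefyTable(table, config$rarefaction_depth,
                          seed = config$random_seed)
  md <- joinMetadata(rarefied, metadata)
  dm <- brayCurtis(rarefied)

  ages <- md$age_weeks
  pw <- pairwisePermanova(dm, as.character(ages),
                          n_permutations = config$n_permutations,
                          seed = config$random_seed, exhaustive = "never")
  sel <- selectSources(pw, alpha = config$fdr_alpha)

  params <- sourceTrackingParams(burnins = config$burnins,
                                 restarts = config$restarts,
                                 rarefaction_depth = config$rarefaction_depth,
                                 seed = config$random_seed)
  slices <- stats::setNames(lapply(seq_len(nrow(sel)), function(k)
    rarefied[, ages == sel$chosen_timepoint[k]]), sel$phase)
  sources <- prepareSources(slices, params)
  if (!is.null(calibration))
    sources <- calibrateSources(sources, calibration$table,
                                calibration$ages, params)

  sinks <- rarefied
  if (!is.null(sink_samples))
    sinks <- rarefied[, sampleIds(rarefied) %in% sink_samples]
  att <- attributeAll(sinks, sources, params)

  truth <- stats::setNames(md$age_weeks, md$sample_id)
  preds <- predictAge(att, midpoints = config$phase_midpoints,
                      threshold = config$uncertainty_threshold,
                      actual_ages = truth)
  eval <- tryCatch(evaluatePredictions(preds), error = function(e) NULL)
  list(table = rarefied, distance = dm, pairwise = pw, selection = sel,
       sources = sources, attribution = att, predictions = preds,
       evaluation = eval)
}

#' Write age predictions to TSV
#'
#' Emits sample id, per-phase proportions, unknown proportion, predicted age
#' and the retained flag.
#'
#' @param result list from [predictCohortAges()], or an
#'   [Attribution-class]/prediction pair.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(result, path) {
  p <- proportions(result$attribution)
  byPhase <- t(rowsum(t(p[, colnames(p) != "unknown", drop = FALSE]),
                      group = colnames(p)[colnames(p) != "unknown"]))
  df <- data.frame(sample_id = rownames(p), byPhase,
                   unknown = p[, "unknown"],
                   predicted_age_weeks = result$predictions$predicted_age_weeks,
                   retained = result$predictions$retained,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
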