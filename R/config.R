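#' Default life-phase midpoints (weeks)
#'
#' Midpoint ages, in weeks, of the five murine life phases used by the age
#' formula: maturing (MR) 10.5, mature (MA) 19.5, middle age (MD) 51.5,
#' old (OD) 93 and very old (VO) 110.
#'
#' @return Named numeric vector in canonical phase order.
#' @export
#' @examples
#' phaseMidpoints()
phaseMidpoints <- function() {
  c(MR = 10.5, MA = 19.5, MD = 51.5, OD = 93, VO = 110)
}

#' Default life-phase age ranges (weeks)
#'
#' Age windows assigning samples to the five life phases: MR 9-12, MA 17-22,
#' MD 47-56, OD 86-100, VO 108-112. Ages falling between windows are labelled
#' "intermediate" and excluded from source selection. The windows are
#' symmetric around [phaseMidpoints()].
#'
#' @return Data frame with columns phase, min_weeks, max_weeks.
#' @export
phaseRanges <- function() {
  data.frame(
    phase = lifePhases(),
    min_weeks = c(9, 17, 47, 86, 108),
    max_weeks = c(12, 22, 56, 100, 112)
  )
}

#' Assign life phases from age
#'
#' @param age_weeks numeric vector of host ages in weeks.
#' @param ranges data frame as returned by [phaseRanges()].
#' @return Character vector of phase labels; ages outside every window get
#'   "intermediate".
#' @export
#' @examples
#' assignLifePhase(c(10, 30, 110))
assignLifePhase <- function(age_weeks, ranges = phaseRanges()) {
  out <- rep("intermediate", length(age_weeks))
  for (k in seq_len(nrow(ranges))) {
    hit <- age_weeks >= ranges$min_weeks[k] & age_weeks <= ranges$max_weeks[k]
    out[hit] <- ranges$phase[k]
  }
  out
}

#' Pipeline run configuration
#'
#' Bundles the tunable constants of the full pipeline. Defaults are the reference
#' settings: rarefaction to 2,733 reads, taxa present in fewer than 5 samples
#' removed, 9,999 label permutations with Benjamini-Hochberg correction at
#' FDR 0.01, Gibbs sampling with 100 burn-in sweeps and 10 restarts, and an
#' uncertainty (unknown-source) threshold of 30%.
#'
#' @param rarefaction_depth positive integer; reads per sample after
#'   rarefaction.
#' @param min_prevalence positive integer; minimum number of samples a taxon
#'   must occur in.
#' @param n_permutations positive integer; PERMANOVA label permutations.
#' @param fdr_alpha significance level applied to BH-adjusted p-values.
#' @param burnins positive integer; Gibbs burn-in sweeps per restart.
#' @param restarts positive integer; independent Gibbs restarts.
#' @param uncertainty_threshold proportion in (0,1); sinks whose unknown
#'   proportion exceeds it are flagged not retained.
#' @param phase_midpoints named numeric vector, see [phaseMidpoints()].
#' @param random_seed integer master seed.
#' @return A list of class `RunConfig`.
#' @export
#' @examples
#' cfg <- runConfig(n_permutations = 199)
#' cfg$rarefaction_depth
runConfig <- function(rarefaction_depth = 2733L,
                      min_prevalence = 5L,
                      n_permutations = 9999L,
                      fdr_alpha = 0.01,
                      burnins = 100L,
                      restarts = 10L,
                      uncertainty_threshold = 0.30,
                      phase_midpoints = phaseMidpoints(),
                      random_seed = 1L) {
  stopifnot(rarefaction_depth >= 1, min_prevalence >= 1, n_permutations >= 1,
            fdr_alpha > 0, fdr_alpha < 1, burnins >= 1, restarts >= 1,
            uncertainty_threshold > 0, uncertainty_threshold < 1,
            all(diff(phase_midpoints) > 0))
  structure(list(
    rarefaction_depth = as.integer(rarefaction_depth),
    min_prevalence = as.integer(min_prevalence),
    n_permutations = as.integer(n_permutations),
    fdr_alpha = fdr_alpha,
    burnins = as.integer(burnins),
    restarts = as.integer(restarts),
    uncertainty_threshold = uncertainty_threshold,
    phase_midpoints = phase_midpoints,
    random_seed = as.integer(random_seed)
  ), class = "RunConfig")
}

#' Read / write a RunConfig as a flat key=value file
#'
#' Scalar fields are written one per line as `key=value`; the midpoint map is
#' flattened as `midpoint.MR=10.5` etc.
#'
#' @param path file path.
#' @return [readRunConfig()] returns a `RunConfig`; [writeRunConfig()] its
#'   path, invisibly.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  mid <- startsWith(keys, "midpoint.")
  midpoints <- phaseMidpoints()
  if (any(mid)) {
    mp <- as.numeric(vals[mid])
    names(mp) <- sub("^midpoint\\.", "", keys[mid])
    midpoints[names(mp)] <- mp
  }
  args <- as.list(as.numeric(vals[!mid]))
  names(args) <- keys[!mid]
  args$phase_midpoints <- midpoints
  do.call(runConfig, args)
}

#' @rdname readRunConfig
#' @param config a `RunConfig` from [runConfig()].
#' @export
writeRunConfig <- function(config, path) {
  scalars <- config[setdiff(names(config), "phase_midpoints")]
  lines <- c(sprintf("%s=%s", names(scalars), unlist(scalars)),
             sprintf("midpoint.%s=%s", names(config$phase_midpoints),
                     config$phase_midpoints))
  writeLines(lines, path)
  invisible(path)
}
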