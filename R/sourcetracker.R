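#' Source-tracking sampler parameters
#'
#' Hyperparameters and run settings of the collapsed Gibbs source-attribution
#' sampler. Defaults follow the standard run settings (100 burn-ins, 10
#' restarts, rarefaction to 2,733 reads) and the reference source-tracking
#' tool's published priors (alpha_known = 0.001, alpha_unknown = 0.1,
#' beta = 10).
#'
#' @param alpha_known Dirichlet pseudocount on the known sources' taxon
#'   compositions (their posterior combines observed source counts with
#'   currently assigned sink reads).
#' @param alpha_unknown Dirichlet prior pseudocount of the learned unknown
#'   source.
#' @param beta symmetric Dirichlet prior on the mixing proportions.
#' @param burnins full Gibbs sweeps discarded per restart.
#' @param restarts independent random restarts; one proportion draw is
#'   retained per restart.
#' @param rarefaction_depth sink reads are subsampled to this depth before
#'   attribution (NA disables sink rarefaction).
#' @param seed integer master seed; per-sink streams are derived from it.
#' @return A list of class `SourceTrackingParams`.
#' @export
sourceTrackingParams <- function(alpha_known = 0.001, alpha_unknown = 0.1,
                                 beta = 10, burnins = 100L, restarts = 10L,
                                 rarefaction_depth = 2733L, seed = 1L) {
  stopifnot(alpha_known > 0, alpha_unknown > 0, beta > 0, burnins >= 1,
            restarts >= 1)
  structure(list(alpha_known = alpha_known, alpha_unknown = alpha_unknown,
                 beta = beta, burnins = as.integer(burnins),
                 restarts = as.integer(restarts),
                 rarefaction_depth = as.integer(rarefaction_depth),
                 seed = as.integer(seed)),
            class = "SourceTrackingParams")
}

# Subsample a count vector to `depth` reads without replacement.
rarefyVector <- function(x, depth) {
  reads <- rep.int(seq_along(x), x)
  keep <- sample(reads, depth)
  tabulate(keep, nbins = length(x))
}

harmonizeTaxa <- function(mats) {
  taxa <- Reduce(union, lapply(mats, colnames))
  lapply(mats, function(m) {
    out <- matrix(0, nrow(m), length(taxa),
                  dimnames = list(rownames(m), taxa))
    out[, colnames(m)] <- m
    out
  })
}

#' Pool and rarefy per-phase source communities
#'
#' For each life phase, sums all samples of the phase's chosen time point
#' into one pooled count vector and rarefies it to the configured depth.
#' Taxa are harmonized to the union across phases, absentees zero-filled.
#'
#' @param tables named list of [CountTable-class] slices, one per phase
#'   (names are the phase labels, canonical order recommended).
#' @param params a [sourceTrackingParams()].
#' @return A [SourceSet-class] with one row per phase.
#' @export
prepareSources <- function(tables, params = sourceTrackingParams()) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list (names are phase labels)")
  pooled <- lapply(names(tables), function(ph) {
    ct <- tables[[ph]]
    if (ncol(counts(ct)) == 0) stop("empty phase slice: ", ph)
    v <- rowSums(counts(ct))
    matrix(v, 1, dimnames = list(ph, names(v)))
  })
  pooled <- harmonizeTaxa(pooled)
  depth <- params$rarefaction_depth
  set.seed(params$seed)
  rows <- lapply(pooled, function(m) {
    if (!is.na(depth)) {
      if (sum(m) < depth)
        stop("pooled source for phase '", rownames(m),
             "' has fewer than ", depth, " reads")
      m[1, ] <- rarefyVector(m[1, ], depth)
    }
    m
  })
  sc <- do.call(rbind, rows)
  storage.mode(sc) <- "integer"
  new("SourceSet", sourceCounts = sc,
      depth = if (is.na(depth)) NA_integer_ else as.integer(depth))
}

#' Attribute one sink to the sources by collapsed Gibbs sampling
#'
#' Runs the collapsed Dirichlet-multinomial Gibbs sampler over the sink's
#' read assignments to the known sources plus a learned unknown source.
#' Source compositions are integrated out: a known source's posterior
#' composition combines its observed counts (smoothed by `alpha_known`) with
#' the sink reads currently assigned to it, and the unknown source is the
#' same form starting from zero counts with prior `alpha_unknown`.
#' Reported proportions are the mean over restarts; `restart_sd` the standard
#' deviation over restarts. The sink is subsampled to the configured
#' rarefaction depth first when deeper (shallower sinks are used as-is here;
#' [attributeAll()] drops them with a report).
#'
#' @param sink named nonnegative integer vector of taxon counts, or a
#'   one-sample [CountTable-class].
#' @param sources a [SourceSet-class]; taxa must align by name with the sink.
#' @param params a [sourceTrackingParams()].
#' @param sink_id identifier used in the output.
#' @return An [Attribution-class] with a single row.
#' @export
gibbsAttribute <- function(sink, sources, params = sourceTrackingParams(),
                           sink_id = "sink") {
  if (is(sink, "CountTable")) {
    stopifnot(ncol(counts(sink)) == 1)
    sink_id <- sampleIds(sink)
    sink <- counts(sink)[, 1]
  }
  taxa <- taxonIds(sources)
  extra <- setdiff(names(sink)[sink > 0], taxa)
  if (length(extra))
    stop("sink taxa missing from the source set: ",
         paste(extra, collapse = ", "))
  x <- stats::setNames(numeric(length(taxa)), taxa)
  sink <- sink[names(sink) %in% taxa]
  x[names(sink)] <- sink
  if (sum(x) < 1) stop("empty sink")
  set.seed(params$seed)
  if (!is.na(params$rarefaction_depth) && sum(x) > params$rarefaction_depth)
    x <- rarefyVector(x, params$rarefaction_depth)
  reads <- rep.int(seq_along(x) - 1L, x)
  m <- sourceCounts(sources)
  storage.mode(m) <- "double"
  draws <- gibbs_restarts_cpp(as.integer(reads), m,
                              params$alpha_known, params$alpha_unknown,
                              params$beta, params$burnins, params$restarts)
  colnames(draws) <- c(phaseLabels(sources), "unknown")
  p <- matrix(colMeans(draws), 1, dimnames = list(sink_id, colnames(draws)))
  s <- matrix(apply(draws, 2, stats::sd), 1,
              dimnames = list(sink_id, colnames(draws)))
  if (params$restarts == 1) s[] <- 0
  new("Attribution", proportions = p / sum(p), restartSD = s)
}

#' Exact posterior source attribution by enumeration
#'
#' Independent validation oracle: enumerates every assignment of the sink's
#' reads to the known sources plus the unknown source, computes each
#' assignment's unnormalized posterior weight under the same collapsed
#' Dirichlet-multinomial model as the Gibbs sampler, and returns the exact
#' posterior mean of the mixing proportions. Only feasible for tiny sinks.
#'
#' @param sink named nonnegative integer count vector (total <= 10).
#' @param sources a [SourceSet-class].
#' @param params a [sourceTrackingParams()] (burnins/restarts ignored).
#' @return Named numeric vector of exact posterior mean proportions
#'   (known sources plus "unknown").
#' @export
oracleAttribute <- function(sink, sources, params = sourceTrackingParams()) {
  taxa <- taxonIds(sources)
  x <- stats::setNames(numeric(length(taxa)), taxa)
  sink <- sink[names(sink) %in% taxa]
  x[names(sink)] <- sink
  N <- sum(x)
  V <- nrow(sourceCounts(sources))
  K <- V + 1
  if (N < 1) stop("empty sink")
  if (N > 10 || K^N > 1e6)
    stop("instance too large for exact enumeration")
  Tn <- length(taxa)
  reads <- rep.int(seq_along(x), x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  # known sources and the unknown share one collapsed form: the unknown is a
  # source with zero observed counts and its own pseudocount
  m <- rbind(sourceCounts(sources), unknown = rep(0, Tn))
  alpha <- c(rep(params$alpha_known, V), params$alpha_unknown)
  Mv <- rowSums(m)
  beta <- params$beta
  logw <- apply(grid, 1, function(z) {
    lw <- 0
    for (v in seq_len(K)) {
      sel <- z == v
      n_vt <- tabulate(reads[sel], nbins = Tn)
      n_v <- sum(n_vt)
      lw <- lw + lgamma(n_v + beta) +
        sum(lgamma(m[v, ] + n_vt + alpha[v]) - lgamma(m[v, ] + alpha[v])) -
        (lgamma(Mv[v] + n_v + Tn * alpha[v]) - lgamma(Mv[v] + Tn * alpha[v]))
    }
    lw
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  props <- vapply(seq_len(K), function(v)
    sum(w * (rowSums(grid == v) / N)), 0)
  stats::setNames(props, c(phaseLabels(sources), "unknown"))
}

#' Attribute every sink sample in a table
#'
#' Runs [gibbsAttribute()] on each sample of `sinks` with an independent,
#' counter-derived seed per sink (so serial and parallel runs agree). Sinks
#' with fewer reads than the rarefaction depth are dropped and reported via a
#' message and the `dropped` attribute.
#'
#' @param sinks a [CountTable-class] of sink samples.
#' @param sources a [SourceSet-class].
#' @param params a [sourceTrackingParams()].
#' @return An [Attribution-class], one row per retained sink (attribute
#'   `dropped` lists sinks below depth).
#' @export
attributeAll <- function(sinks, sources, params = sourceTrackingParams()) {
  m <- counts(sinks)
  if (ncol(m) == 0)
    return(new("Attribution",
               proportions = matrix(numeric(0), 0, nrow(sourceCounts(sources)) + 1,
                 dimnames = list(NULL, c(phaseLabels(sources), "unknown"))),
               restartSD = matrix(numeric(0), 0, nrow(sourceCounts(sources)) + 1)))
  depth <- params$rarefaction_depth
  totals <- colSums(m)
  dropped <- character(0)
  if (!is.na(depth)) {
    dropped <- colnames(m)[totals < depth]
    if (length(dropped))
      message("attributeAll: dropped ", length(dropped),
              " sink(s) below depth ", depth)
    m <- m[, totals >= depth, drop = FALSE]
  }
  rows <- lapply(seq_len(ncol(m)), function(j) {
    pj <- params
    pj$seed <- as.integer((as.double(params$seed) + j) %% .Machine$integer.max)
    gibbsAttribute(m[, j], sources, pj, sink_id = colnames(m)[j])
  })
  att <- new("Attribution",
             proportions = do.call(rbind, lapply(rows, proportions)),
             restartSD = do.call(rbind, lapply(rows, restartSD)))
  attr(att, "dropped") <- dropped
  att
}
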