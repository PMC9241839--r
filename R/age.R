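#' Predict host age from source attributions
#'
#' Applies the life-phase midpoint formula: the predicted age is the sum over
#' phases of the phase's attributed proportion times its midpoint age,
#' y = a_MR x_MR + a_MA x_MA + a_MD x_MD + a_OD x_OD + a_VO x_VO.
#' Proportions carried by several source rows with the same phase label (as
#' after batch calibration) are summed per phase first. With
#' `renormalize = TRUE` (default) the known-phase proportions are divided by
#' (1 - unknown) before the weighted sum, so predictions stay within the
#' midpoint range; with it off the raw proportions enter the sum. A sink with
#' all mass on the unknown source gets an undefined (NA) prediction and
#' `retained = FALSE`.
#'
#' @param attr an [Attribution-class].
#' @param midpoints named midpoint map, see [phaseMidpoints()].
#' @param renormalize divide known proportions by (1 - unknown) first.
#' @param threshold uncertainty threshold passed to [filterUncertain()].
#' @param actual_ages optional named numeric vector (names = sink ids) of
#'   chronological ages for evaluation.
#' @return data.frame with columns sink_id, predicted_age_weeks,
#'   unknown_proportion, retained, and actual_age_weeks when supplied.
#' @export
#' @examples
#' a <- new("Attribution",
#'   proportions = matrix(c(1, 0, 0, 0, 0, 0), 1,
#'     dimnames = list("s", c(lifePhases(), "unknown"))),
#'   restartSD = matrix(0, 1, 6))
#' predictAge(a)$predicted_age_weeks  # 10.5
predictAge <- function(attr, midpoints = phaseMidpoints(),
                       renormalize = TRUE, threshold = 0.30,
                       actual_ages = NULL) {
  p <- proportions(attr)
  unknown <- p[, "unknown"]
  known <- p[, colnames(p) != "unknown", drop = FALSE]
  bad <- setdiff(colnames(known), names(midpoints))
  if (length(bad))
    stop("source labels without a midpoint: ", paste(bad, collapse = ", "))
  byPhase <- t(rowsum(t(known), group = colnames(known)))
  x <- matrix(0, nrow(p), length(midpoints),
              dimnames = list(rownames(p), names(midpoints)))
  x[, colnames(byPhase)] <- byPhase
  if (renormalize) {
    denom <- 1 - unknown
    x <- x / ifelse(denom > 0, denom, NA_real_)
  }
  pred <- as.numeric(x %*% midpoints[colnames(x)])
  out <- data.frame(sink_id = rownames(p),
                    predicted_age_weeks = pred,
                    unknown_proportion = unknown,
                    retained = unknown <= threshold & !is.na(pred),
                    row.names = NULL)
  if (!is.null(actual_ages))
    out$actual_age_weeks <- as.numeric(actual_ages[out$sink_id])
  out
}

#' Flag predictions exceeding the uncertainty threshold
#'
#' Marks `retained = FALSE` exactly when the unknown-source proportion is
#' strictly greater than `threshold` ("more than 30%" in the default
#' configuration: 0.30 exactly is retained). Nothing is deleted; only the
#' flag is set.
#'
#' @param preds data.frame from [predictAge()].
#' @param threshold proportion in (0, 1).
#' @return The data.frame with an updated `retained` column.
#' @export
filterUncertain <- function(preds, threshold = 0.30) {
  stopifnot(threshold > 0, threshold < 1)
  preds$retained <- preds$unknown_proportion <= threshold &
    !is.na(preds$predicted_age_weeks)
  preds
}

#' Append batch-calibration sources from control samples
#'
#' Pools control samples per life phase (each control's age is mapped through
#' the phase windows individually), rarefies each pool to the configured
#' depth, and appends the pooled communities as additional source rows
#' carrying their phase label. Attribution then distributes mass over
#' base + calibration rows; [predictAge()] sums proportions of the same phase
#' label before the weighted sum. An empty control set returns the base set
#' unchanged.
#'
#' @param base a [SourceSet-class].
#' @param control_sinks a [CountTable-class] of control samples.
#' @param control_ages numeric ages (weeks) named by control sample id, or
#'   aligned with the table's samples.
#' @param params a [sourceTrackingParams()].
#' @param ranges phase windows, see [phaseRanges()].
#' @return A [SourceSet-class] with the calibration rows appended.
#' @export
calibrateSources <- function(base, control_sinks, control_ages,
                             params = sourceTrackingParams(),
                             ranges = phaseRanges()) {
  m <- counts(control_sinks)
  if (ncol(m) == 0) return(base)
  if (!is.null(names(control_ages)))
    control_ages <- control_ages[colnames(m)]
  if (length(control_ages) != ncol(m) || any(is.na(control_ages)))
    stop("every control sample needs an age")
  phases <- assignLifePhase(control_ages, ranges)
  if (any(phases == "intermediate"))
    stop("control ages outside every phase window: ",
         paste(colnames(m)[phases == "intermediate"], collapse = ", "))
  slices <- lapply(split(seq_len(ncol(m)), phases), function(j)
    control_sinks[, j])
  extra <- prepareSources(slices, params)
  mats <- harmonizeTaxa(list(sourceCounts(base), sourceCounts(extra)))
  sc <- rbind(mats[[1]], mats[[2]])
  storage.mode(sc) <- "integer"
  new("SourceSet", sourceCounts = sc, depth = base@depth)
}

#' Evaluate predictions against chronological age
#'
#' Spearman correlation (overall and per age stratum, split at `split_age`)
#' and a least-squares polynomial regression of predicted on actual age with
#' adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1). Only retained predictions
#' enter. Degenerate (constant) predictions yield NA correlations.
#'
#' @param preds data.frame from [predictAge()] including `actual_age_weeks`.
#' @param split_age stratum boundary in weeks (default 62: younger vs older).
#' @param degree polynomial degree (default 2).
#' @return List of class `EvaluationReport`: overall and per-stratum
#'   `spearman_rho` / `spearman_p` / `n`, `polynomial_degree`, `adjusted_r2`.
#' @export
evaluatePredictions <- function(preds, split_age = 62, degree = 2L) {
  keep <- preds[preds$retained & !is.na(preds$actual_age_weeks), ]
  spear <- function(d) {
    if (nrow(d) < 3 || stats::sd(d$predicted_age_weeks) == 0 ||
        stats::sd(d$actual_age_weeks) == 0)
      return(list(rho = NA_real_, p = NA_real_, n = nrow(d)))
    ct <- suppressWarnings(stats::cor.test(d$actual_age_weeks,
                                           d$predicted_age_weeks,
                                           method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
  }
  overall <- spear(keep)
  young <- spear(keep[keep$actual_age_weeks < split_age, ])
  old <- spear(keep[keep$actual_age_weeks >= split_age, ])
  adj_r2 <- NA_real_
  if (nrow(keep) > degree + 1 && stats::sd(keep$actual_age_weeks) > 0) {
    fit <- stats::lm(predicted_age_weeks ~ poly(actual_age_weeks, degree),
                     data = keep)
    # summary.lm warns on an exactly collinear (perfect) fit; that case is a
    # legitimate input here
    adj_r2 <- suppressWarnings(summary(fit)$adj.r.squared)
  }
  structure(list(
    spearman_rho = overall$rho, spearman_p = overall$p, n = overall$n,
    young = young, old = old, split_age = split_age,
    polynomial_degree = as.integer(degree), adjusted_r2 = adj_r2
  ), class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: n=%d retained\n", x$n))
  cat(sprintf("  overall  rho=%.3f (p=%.3g)\n", x$spearman_rho, x$spearman_p))
  cat(sprintf("  <%g wk   rho=%.3f (n=%d)\n", x$split_age, x$young$rho,
              x$young$n))
  cat(sprintf("  >=%g wk  rho=%.3f (n=%d)\n", x$split_age, x$old$rho, x$old$n))
  cat(sprintf("  degree-%d polynomial adjusted R^2 = %.3f\n",
              x$polynomial_degree, x$adjusted_r2))
  invisible(x)
}
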