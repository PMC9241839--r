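# Pseudo-F for a label assignment, from the squared distance matrix.
# SS_total = (1/N) sum_{i<j} d_ij^2 ; SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2
permanovaF <- function(D2, group_idx, n_per_group) {
  N <- nrow(D2)
  a <- length(group_idx)
  ss_total <- sum(D2) / (2 * N)
  ss_within <- 0
  for (g in seq_len(a)) {
    idx <- group_idx[[g]]
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * n_per_group[g])
  }
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (N - a))
}

#' PERMANOVA of a distance matrix against group labels
#'
#' One-way permutational multivariate analysis of variance (Anderson's
#' pseudo-F). Significance is assessed by uniform random permutation of the
#' sample labels; with Monte-Carlo permutations
#' p = (1 + #\{permuted F >= observed F\}) / (n_permutations + 1). For two
#' groups with at most 10,000 distinct arrangements, the exact p over all
#' arrangements is computed instead (controlled by `exhaustive`). Labels are
#' permuted freely across samples (not stratified by mouse or cage).
#'
#' @param dm a [DistanceMatrix-class].
#' @param labels group label per sample (>= 2 groups, each of size >= 2).
#' @param n_permutations Monte-Carlo permutations (default 9,999).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive "auto" (exact enumeration for two groups when feasible),
#'   "never", or "always" (two groups only).
#' @return List with `pseudo_F`, `p_value`, `n_permutations` (NA when exact)
#'   and `exact` flag.
#' @export
#' @examples
#' m <- matrix(1, 6, 6) ; m[1:3, 1:3] <- 0 ; m[4:6, 4:6] <- 0 ; diag(m) <- 0
#' dimnames(m) <- list(letters[1:6], letters[1:6])
#' permanova(DistanceMatrix(m), rep(c("A", "B"), each = 3), 199, seed = 1)
permanova <- function(dm, labels, n_permutations = 9999L, seed = 1L,
                      exhaustive = c("auto", "never", "always")) {
  exhaustive <- match.arg(exhaustive)
  D2 <- as.matrix(dm)^2
  N <- nrow(D2)
  if (length(labels) != N) stop("labels must match the number of samples")
  f <- factor(labels)
  n_g <- table(f)
  if (nlevels(f) < 2) stop("need at least 2 groups")
  if (any(n_g < 2))
    stop("group of size < 2: ", names(n_g)[n_g < 2][1])
  idx_of <- function(fac) split(seq_len(N), fac)
  obs <- permanovaF(D2, idx_of(f), as.numeric(n_g))

  two_groups <- nlevels(f) == 2
  n1 <- as.numeric(n_g[1])
  feasible <- two_groups && choose(N, n1) <= 10000
  use_exact <- (exhaustive == "always") ||
    (exhaustive == "auto" && feasible)
  if (exhaustive == "always" && !two_groups)
    stop("exhaustive enumeration is implemented for two groups only")

  tol <- 1e-12
  if (use_exact) {
    combos <- utils::combn(N, n1)
    n2 <- N - n1
    fs <- apply(combos, 2, function(i1)
      permanovaF(D2, list(i1, setdiff(seq_len(N), i1)), c(n1, n2)))
    p <- mean(fs >= obs - tol)
    list(pseudo_F = obs, p_value = p, n_permutations = NA_integer_,
         exact = TRUE)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      fp <- f[sample.int(N)]
      if (permanovaF(D2, idx_of(fp), as.numeric(n_g)) >= obs - tol)
        hits <- hits + 1L
    }
    list(pseudo_F = obs,
         p_value = (1 + hits) / (n_permutations + 1),
         n_permutations = as.integer(n_permutations),
         exact = FALSE)
  }
}

#' Pairwise PERMANOVA with Benjamini-Hochberg correction
#'
#' Runs [permanova()] on the two-group submatrix of every unordered pair of
#' labels and adjusts the p-values across all pairs with the
#' Benjamini-Hochberg step-up procedure.
#'
#' @inheritParams permanova
#' @return data.frame with columns group_a, group_b, pseudo_F, p_value,
#'   p_adjusted, n_permutations, exact.
#' @export
pairwisePermanova <- function(dm, labels, n_permutations = 9999L, seed = 1L,
                              exhaustive = c("auto", "never", "always")) {
  exhaustive <- match.arg(exhaustive)
  f <- factor(labels)
  lev <- levels(f)
  if (length(lev) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    sel <- f %in% c(ga, gb)
    r <- permanova(dm[which(sel)], droplevels(f[sel]),
                   n_permutations = n_permutations,
                   seed = (seed + k) %% .Machine$integer.max,
                   exhaustive = exhaustive)
    data.frame(group_a = ga, group_b = gb, pseudo_F = r$pseudo_F,
               p_value = r$p_value, n_permutations = r$n_permutations,
               exact = r$exact)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bhAdjust(out$p_value)
  out[, c("group_a", "group_b", "pseudo_F", "p_value", "p_adjusted",
          "n_permutations", "exact")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that all p-values lie in (0, 1] and applies the standard BH
#' step-up procedure (via [stats::p.adjust()]), returning adjusted values in
#' input order.
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order and length.
#' @export
#' @examples
#' bhAdjust(c(0.005, 0.04))
bhAdjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select one source time point per life phase
#'
#' For each life phase, picks the member time point with the fewest
#' significantly different pairs (BH-adjusted p < `alpha`) against all other
#' time points, i.e. the community most similar to the rest of the cohort.
#' Ties break toward the earlier age (reported via `tie_broken`).
#'
#' @param pairwise data.frame from [pairwisePermanova()] whose group labels
#'   are time-point ages (coercible to numeric).
#' @param phase_map named character vector mapping time-point label to life
#'   phase, or NULL to assign phases from age via [assignLifePhase()].
#'   Time points mapped to "intermediate" are not eligible as sources.
#' @param alpha significance threshold on adjusted p-values (default 0.01).
#' @return data.frame with columns phase, chosen_timepoint,
#'   n_significant_pairs, tie_broken; one row per phase in canonical order.
#' @export
selectSources <- function(pairwise, phase_map = NULL, alpha = 0.01) {
  tps <- unique(c(pairwise$group_a, pairwise$group_b))
  if (is.null(phase_map)) {
    phase_map <- assignLifePhase(as.numeric(tps))
    names(phase_map) <- tps
  }
  sig <- pairwise$p_adjusted < alpha
  n_sig <- vapply(tps, function(tp)
    sum(sig & (pairwise$group_a == tp | pairwise$group_b == tp)), 0L)
  out <- lapply(lifePhases(), function(ph) {
    members <- tps[phase_map[tps] == ph]
    if (!length(members))
      stop("life phase without time points: ", ph)
    cnt <- n_sig[members]
    best <- min(cnt)
    cand <- members[cnt == best]
    chosen <- cand[order(as.numeric(cand))][1]
    data.frame(phase = ph,
               chosen_timepoint = as.numeric(chosen),
               n_significant_pairs = as.integer(best),
               tie_broken = length(cand) > 1)
  })
  do.call(rbind, out)
}
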