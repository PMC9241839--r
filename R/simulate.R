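#' Default longitudinal sampling grid
#'
#' 26 sampling ages in weeks: 9, 10 and 12 weeks, then 4- to 5-week intervals
#' from 17 to 112 weeks. The grid is consistent with the life-phase windows of
#' [phaseRanges()] (three MR, two MA, three MD, four OD and two VO time
#' points; the rest are intermediate).
#'
#' @return Strictly increasing numeric vector of length 26.
#' @export
defaultTimepoints <- function() {
  c(9, 10, 12, 17, 21, 26, 30, 34, 39, 43, 47, 52, 56, 60, 64,
    69, 73, 77, 82, 86, 90, 95, 99, 103, 108, 112)
}

archetypeNames <- c("early_decliner", "long_term_commensal", "mid_successor",
                    "late_successor", "transient")

#' Succession archetype
#'
#' A taxon's expected relative-abundance trajectory over the five life
#' phases, plus a phylum tag used for compositional-balance summaries.
#'
#' @param name one of `early_decliner`, `long_term_commensal`,
#'   `mid_successor`, `late_successor`, `transient`.
#' @param phase_means named nonnegative numeric vector over
#'   `c("MR","MA","MD","OD","VO")`; at least one value must be positive. An
#'   `early_decliner` must peak at MR and a `late_successor` at OD or VO.
#' @param phylum_label free-form tag, e.g. "Firmicutes-like".
#' @return A list of class `SuccessionArchetype`.
#' @export
#' @examples
#' successionArchetype("early_decliner",
#'   c(MR = 0.8, MA = 0.3, MD = 0.05, OD = 0, VO = 0), "Firmicutes-like")
successionArchetype <- function(name, phase_means, phylum_label) {
  name <- match.arg(name, archetypeNames)
  phase_means <- phase_means[lifePhases()]
  names(phase_means) <- lifePhases()
  if (any(is.na(phase_means)) || any(phase_means < 0))
    stop("phase_means must be nonnegative over all five phases")
  if (all(phase_means == 0)) stop("at least one phase mean must be positive")
  peak <- lifePhases()[which.max(phase_means)]
  if (name == "early_decliner" && peak != "MR")
    stop("early_decliner must peak at MR")
  if (name == "late_successor" && !peak %in% c("OD", "VO"))
    stop("late_successor must peak at OD or VO")
  structure(list(name = name, phase_means = phase_means,
                 phylum_label = phylum_label),
            class = "SuccessionArchetype")
}

#' Default archetype set
#'
#' Five archetypes emulating the succession patterns of the aging murine gut:
#' Firmicutes-like early decliners and transients, Bacteroidota-like
#' long-term commensals and mid-life successors, and Firmicutes-like late
#' successors. With the default mix the summed Bacteroidota-like fraction
#' exceeds the Firmicutes-like fraction at middle age, and the two phyla
#' converge in old/very old animals.
#'
#' @return Named list of five `SuccessionArchetype` objects.
#' @export
defaultArchetypes <- function() {
  list(
    early_decliner = successionArchetype("early_decliner",
      c(MR = 2.0, MA = 0.3, MD = 0, OD = 0, VO = 0), "Firmicutes-like"),
    long_term_commensal = successionArchetype("long_term_commensal",
      c(MR = 0.2, MA = 0.9, MD = 1.0, OD = 0.9, VO = 0.9), "Bacteroidota-like"),
    mid_successor = successionArchetype("mid_successor",
      c(MR = 0.02, MA = 0.3, MD = 1.0, OD = 0.6, VO = 0.5), "Bacteroidota-like"),
    late_successor = successionArchetype("late_successor",
      c(MR = 0, MA = 0.01, MD = 0.03, OD = 1.2, VO = 1.3), "Firmicutes-like"),
    transient = successionArchetype("transient",
      c(MR = 0.5, MA = 0.7, MD = 0.4, OD = 0.5, VO = 0.45), "Firmicutes-like")
  )
}

defaultArchetypeMix <- function(n_taxa, archetypes = defaultArchetypes()) {
  w <- c(early_decliner = 0.12, long_term_commensal = 0.28,
         mid_successor = 0.20, late_successor = 0.20, transient = 0.20)
  n <- floor(w * n_taxa)
  n[length(n)] <- n_taxa - sum(n[-length(n)])
  lapply(seq_along(archetypes),
         function(i) list(archetype = archetypes[[i]], count = n[[i]]))
}

#' Cohort simulation design
#'
#' Parameters of the synthetic longitudinal cohort. Defaults emulate the
#' reference cohort design: 20 mice in 4 cages sampled at the 26 default ages from
#' 9 to 112 weeks, 651 taxa, mean depth 10,000 reads (uniform in
#' 0.8-1.2 x mean) and per-mouse multiplicative log-normal overdispersion.
#'
#' @param n_mice positive integer.
#' @param timepoints_weeks strictly increasing ages in weeks within [9, 112].
#' @param n_taxa positive integer.
#' @param depth_mean positive integer mean sequencing depth.
#' @param overdispersion sigma of the per-mouse log-normal perturbation.
#' @param archetype_mix list of `list(archetype =, count =)` entries whose
#'   counts sum to `n_taxa`; defaults to [defaultArchetypes()] in proportions
#'   12/28/20/20/20 percent.
#' @param taxon_scale_sigma sigma of a per-taxon log-normal abundance scale
#'   (0 makes all taxa of an archetype identical in expectation).
#' @param seed integer master seed.
#' @return A list of class `CohortDesign`, including a `taxa` data.frame
#'   mapping taxon ids to archetypes and phylum tags.
#' @export
#' @examples
#' d <- cohortDesign(n_mice = 4, n_taxa = 40)
#' nrow(d$taxa)
cohortDesign <- function(n_mice = 20L,
                         timepoints_weeks = defaultTimepoints(),
                         n_taxa = 651L,
                         depth_mean = 10000L,
                         overdispersion = 0.3,
                         archetype_mix = NULL,
                         taxon_scale_sigma = 0.5,
                         seed = 1L) {
  stopifnot(n_mice >= 1, n_taxa >= 1, depth_mean >= 1, overdispersion >= 0,
            all(diff(timepoints_weeks) > 0),
            timepoints_weeks[1] >= 9,
            timepoints_weeks[length(timepoints_weeks)] <= 112)
  if (is.null(archetype_mix)) archetype_mix <- defaultArchetypeMix(n_taxa)
  counts <- vapply(archetype_mix, function(e) e$count, 0)
  if (sum(counts) != n_taxa)
    stop("archetype counts must sum to n_taxa (got ", sum(counts), ")")
  taxa <- data.frame(
    taxon_id = sprintf("ASV%04d", seq_len(n_taxa)),
    archetype = rep(vapply(archetype_mix, function(e) e$archetype$name, ""),
                    counts),
    phylum = rep(vapply(archetype_mix, function(e) e$archetype$phylum_label, ""),
                 counts)
  )
  structure(list(n_mice = as.integer(n_mice),
                 timepoints_weeks = timepoints_weeks,
                 n_taxa = as.integer(n_taxa),
                 depth_mean = as.integer(depth_mean),
                 overdispersion = overdispersion,
                 archetype_mix = archetype_mix,
                 taxon_scale_sigma = taxon_scale_sigma,
                 seed = as.integer(seed),
                 taxa = taxa),
            class = "CohortDesign")
}

# Per-taxon expected (unnormalized) phase means: archetype means times a
# deterministic per-taxon log-normal scale drawn from the design seed.
taxonPhaseMeans <- function(design) {
  mix <- design$archetype_mix
  means <- do.call(rbind, lapply(mix, function(e)
    matrix(e$archetype$phase_means, nrow = e$count, ncol = 5, byrow = TRUE)))
  colnames(means) <- lifePhases()
  rownames(means) <- design$taxa$taxon_id
  # deterministic in the design seed; restores the caller's RNG state
  scales <- local({
    rs <- get0(".Random.seed", envir = globalenv())
    set.seed((design$seed %% 1000000L) * 131L + 17L)
    s <- exp(stats::rnorm(design$n_taxa, 0, design$taxon_scale_sigma))
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
    s
  })
  means * scales
}

#' Expected community profiles per time point
#'
#' Interpolates each taxon's phase means piecewise-linearly across the
#' sampling grid (anchored at the phase midpoint ages, clamped outside) and
#' normalizes each time-point column to sum to one.
#'
#' @param design a [cohortDesign()].
#' @return Numeric matrix (taxa x timepoints) of expected relative
#'   abundances; every column sums to 1.
#' @export
buildPhaseProfiles <- function(design) {
  anchors <- phaseMidpoints()
  means <- taxonPhaseMeans(design)
  tp <- design$timepoints_weeks
  prof <- t(apply(means, 1, function(y)
    stats::approx(anchors, y, xout = tp, rule = 2)$y))
  colnames(prof) <- sprintf("w%03d", round(tp))
  tot <- colSums(prof)
  if (any(tot <= 0)) stop("degenerate profile: all-zero column after mixing")
  sweep(prof, 2, tot, "/")
}

# Normalized expected profile at one phase's midpoint (exact phase means).
phasePointProfile <- function(design, phase) {
  means <- taxonPhaseMeans(design)[, phase]
  if (sum(means) <= 0) stop("degenerate profile for phase ", phase)
  means / sum(means)
}

sampleSeedStream <- function(master, n) {
  as.integer((as.double(master) * 48271 + 7919 * seq_len(n)) %% 2147483647)
}

#' Simulate a longitudinal cohort
#'
#' For every mouse x time point, the expected community is the time point's
#' profile from [buildPhaseProfiles()] perturbed by a per-mouse multiplicative
#' log-normal factor (drawn once per mouse x taxon, so a mouse keeps its
#' individual deviation for life), renormalized, and sampled multinomially at
#' a depth drawn uniformly in 0.8-1.2 x `depth_mean`. Fully reproducible
#' given the design seed.
#'
#' @param design a [cohortDesign()].
#' @return A [GeneratedCohort-class].
#' @export
#' @examples
#' co <- simulateCohort(cohortDesign(n_mice = 2, n_taxa = 20,
#'   depth_mean = 500, seed = 7))
#' co
simulateCohort <- function(design) {
  profiles <- buildPhaseProfiles(design)
  tp <- design$timepoints_weeks
  n_s <- design$n_mice * length(tp)
  set.seed(design$seed)
  mouse_fx <- matrix(exp(stats::rnorm(design$n_taxa * design$n_mice, 0,
                                      design$overdispersion)),
                     design$n_taxa, design$n_mice)
  depths <- as.integer(round(stats::runif(n_s, 0.8, 1.2) * design$depth_mean))
  seeds <- sampleSeedStream(design$seed, n_s)

  ids <- character(n_s); ages <- numeric(n_s); mice <- character(n_s)
  expected <- matrix(0, design$n_taxa, n_s)
  cmat <- matrix(0L, design$n_taxa, n_s)
  k <- 0L
  for (m in seq_len(design$n_mice)) {
    for (t in seq_along(tp)) {
      k <- k + 1L
      p <- profiles[, t] * mouse_fx[, m]
      p <- p / sum(p)
      expected[, k] <- p
      set.seed(seeds[k])
      cmat[, k] <- as.integer(stats::rmultinom(1, depths[k], p))
      ids[k] <- sprintf("M%02d_t%02d", m, t)
      ages[k] <- tp[t]
      mice[k] <- sprintf("M%02d", m)
    }
  }
  rownames(cmat) <- design$taxa$taxon_id
  colnames(cmat) <- ids
  rownames(expected) <- design$taxa$taxon_id
  colnames(expected) <- ids
  metadata <- data.frame(
    sample_id = ids, mouse_id = mice, age_weeks = ages,
    life_phase = assignLifePhase(ages), diet = "standard",
    cage = sprintf("C%d", (match(mice, unique(mice)) - 1L) %/% 5L + 1L)
  )
  truth <- data.frame(sample_id = ids, age_weeks = ages,
                      phase = metadata$life_phase, diet = metadata$diet)
  new("GeneratedCohort",
      table = CountTable(cmat),
      metadata = metadata,
      tree = simulateTree(design$n_taxa, design$seed,
                          tip_labels = design$taxa$taxon_id),
      truth = truth,
      design = unclass(design),
      expectedProfiles = expected,
      sampleSeeds = seeds,
      depths = depths)
}

#' Simulate a rooted phylogeny for the synthetic taxa
#'
#' Random rooted bifurcating tree with positive branch lengths, via
#' [ape::rtree()].
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param tip_labels optional tip names; defaults to `ASV0001`, ...
#' @return Newick string (rooted, bifurcating).
#' @export
#' @examples
#' simulateTree(3, seed = 1)
simulateTree <- function(n_taxa, seed, tip_labels = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (is.null(tip_labels)) tip_labels <- sprintf("ASV%04d", seq_len(n_taxa))
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = TRUE, tip.label = tip_labels)
  ape::write.tree(tr)
}

#' Shift samples toward the late-life community (western-diet scenario)
#'
#' Blends the expected composition of the target samples toward the pure
#' very-old (VO) phase profile with weight `shift_strength`, then redraws
#' their counts with the same per-sample seed and depth. A strength of 0
#' leaves counts bit-identical; a strength of 1 replaces the expectation by
#' the VO profile (and is idempotent). Shifted samples (strength > 0) are
#' relabelled `diet = "western"`.
#'
#' @param cohort a [GeneratedCohort-class].
#' @param target_samples character vector of sample ids to shift.
#' @param shift_strength blending weight in [0, 1].
#' @return A new [GeneratedCohort-class].
#' @export
applyDietShift <- function(cohort, target_samples, shift_strength) {
  stopifnot(shift_strength >= 0, shift_strength <= 1)
  ids <- sampleIds(cohortTable(cohort))
  missing <- setdiff(target_samples, ids)
  if (length(missing))
    stop("unknown sample id: ", paste(missing, collapse = ", "))
  design <- do.call(cohortDesign, cohort@design[setdiff(names(cohort@design),
                                                        "taxa")])
  vo <- phasePointProfile(design, "VO")
  cmat <- counts(cohortTable(cohort))
  expected <- cohort@expectedProfiles
  for (sid in target_samples) {
    j <- match(sid, ids)
    p <- (1 - shift_strength) * expected[, j] + shift_strength * vo
    p <- p / sum(p)
    expected[, j] <- p
    set.seed(cohort@sampleSeeds[j])
    cmat[, j] <- as.integer(stats::rmultinom(1, cohort@depths[j], p))
  }
  metadata <- cohort@metadata
  truth <- cohort@truth
  if (shift_strength > 0) {
    metadata$diet[metadata$sample_id %in% target_samples] <- "western"
    truth$diet[truth$sample_id %in% target_samples] <- "western"
  }
  initialize(cohort, table = CountTable(cmat), metadata = metadata,
             truth = truth, expectedProfiles = expected)
}
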