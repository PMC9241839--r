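test_that("midpoint formula reproduces degenerate and uniform attributions", {
  mk <- function(v) makeAttribution(setNames(c(v, 0), c(lifePhases(),
                                                        "unknown")))
  expect_equal(predictAge(mk(c(1, 0, 0, 0, 0)))$predicted_age_weeks, 10.5)
  expect_equal(predictAge(mk(c(0, 0, 0, 0, 1)))$predicted_age_weeks, 110)
  expect_equal(predictAge(mk(rep(0.2, 5)))$predicted_age_weeks,
               (10.5 + 19.5 + 51.5 + 93 + 110) / 5)
  expect_equal(predictAge(mk(rep(0.2, 5)))$predicted_age_weeks, 56.9)
})

test_that("renormalization divides by one minus the unknown proportion", {
  a <- makeAttribution(c(MR = 0.3, MA = 0.3, MD = 0, OD = 0, VO = 0,
                         unknown = 0.4))
  on <- predictAge(a, renormalize = TRUE)
  off <- predictAge(a, renormalize = FALSE)
  expect_equal(on$predicted_age_weeks, (0.3 * 10.5 + 0.3 * 19.5) / 0.6)
  expect_equal(off$predicted_age_weeks, 0.3 * 10.5 + 0.3 * 19.5)
  # all mass unknown: undefined prediction, not retained
  u <- makeAttribution(c(MR = 0, MA = 0, MD = 0, OD = 0, VO = 0, unknown = 1))
  pu <- predictAge(u, renormalize = TRUE)
  expect_true(is.na(pu$predicted_age_weeks))
  expect_false(pu$retained)
})

test_that("predictions stay within the midpoint range when renormalized", {
  set.seed(8)
  for (i in 1:50) {
    v <- runif(6); v <- v / sum(v)
    names(v) <- c(lifePhases(), "unknown")
    pr <- predictAge(makeAttribution(v))$predicted_age_weeks
    expect_gte(pr, 10.5); expect_lte(pr, 110)
  }
})

test_that("prediction is affine: averaging attributions commutes with predicting", {
  set.seed(2)
  vs <- lapply(1:10, function(i) {
    v <- runif(6); v / sum(v)
  })
  props <- do.call(rbind, vs)
  colnames(props) <- c(lifePhases(), "unknown")
  rownames(props) <- paste0("s", 1:10)
  att <- new("Attribution", proportions = props, restartSD = props * 0)
  preds <- predictAge(att, renormalize = FALSE)$predicted_age_weeks
  avg_att <- makeAttribution(colMeans(props))
  expect_equal(predictAge(avg_att, renormalize = FALSE)$predicted_age_weeks,
               mean(preds), tolerance = 1e-12)
})

test_that("duplicate phase labels (calibration rows) are summed per phase", {
  p <- matrix(c(0.2, 0.3, 0.1, 0.1, 0.1, 0.1, 0.1), 1,
              dimnames = list("s", c("MA", "MA", "MR", "MD", "OD", "VO",
                                     "unknown")))
  att <- new("Attribution", proportions = p, restartSD = p * 0)
  pr <- predictAge(att, renormalize = FALSE)
  expect_equal(pr$predicted_age_weeks,
               0.5 * 19.5 + 0.1 * 10.5 + 0.1 * 51.5 + 0.1 * 93 + 0.1 * 110)
})

test_that("uncertainty filter is strict at the 30% boundary", {
  mk <- function(u) makeAttribution(c(MR = 1 - u, MA = 0, MD = 0, OD = 0,
                                      VO = 0, unknown = u))
  over <- filterUncertain(predictAge(mk(0.31)), 0.30)
  at <- filterUncertain(predictAge(mk(0.30)), 0.30)
  under <- filterUncertain(predictAge(mk(0.05)), 0.30)
  expect_false(over$retained)
  expect_true(at$retained)    # exactly 30% is retained ("more than" is strict)
  expect_true(under$retained)
  # near-1 threshold retains everything with any known mass
  expect_true(filterUncertain(predictAge(mk(0.97)), 0.999)$retained)
  expect_error(filterUncertain(predictAge(mk(0.5)), 1.5), "threshold")
})

test_that("calibration appends phase-labelled control sources", {
  sc <- rbind(A = c(t1 = 300L, t2 = 200L, t3 = 0L, t4 = 0L),
              B = c(t1 = 0L, t2 = 0L, t3 = 150L, t4 = 350L))
  ss <- new("SourceSet", sourceCounts = sc, depth = 500L)
  # empty control set: unchanged
  empty <- CountTable(matrix(integer(0), 2, 0,
                             dimnames = list(c("t1", "t2"), NULL)))
  expect_identical(sourceCounts(calibrateSources(ss, empty, numeric(0))),
                   sourceCounts(ss))
  # controls aged 17.9-21.9 weeks map to the MA phase
  set.seed(3)
  m <- matrix(rmultinom(3, 400, prob = rep(0.25, 4)), 4,
              dimnames = list(paste0("t", 1:4), paste0("c", 1:3)))
  ctl <- CountTable(m)
  ages <- setNames(c(17.9, 19.5, 21.9), paste0("c", 1:3))
  cal <- calibrateSources(ss, ctl, ages,
                          sourceTrackingParams(rarefaction_depth = 500))
  expect_identical(phaseLabels(cal), c("A", "B", "MA"))
  expect_equal(sum(sourceCounts(cal)["MA", ]), 500)
  # taxa harmonized: original rows unchanged
  expect_equal(sourceCounts(cal)[c("A", "B"), colnames(sourceCounts(ss))],
               sourceCounts(ss))
  # an out-of-window control age errors
  expect_error(calibrateSources(ss, ctl, setNames(c(30, 19, 20),
                                                  paste0("c", 1:3)),
                                sourceTrackingParams(rarefaction_depth = 500)),
               "c1")
})

test_that("calibration reduces error on a batch-shifted cohort", {
  # batch B: same archetypes, different per-taxon abundance scales (a
  # systematic compositional batch offset); sources trained on batch A
  dA <- cohortDesign(n_mice = 6, n_taxa = 40, depth_mean = 2000, seed = 1)
  dB <- cohortDesign(n_mice = 8, n_taxa = 40, depth_mean = 2000, seed = 202)
  coA <- simulateCohort(dA)
  coB <- simulateCohort(dB)
  depth <- 800L
  params <- sourceTrackingParams(rarefaction_depth = depth, seed = 5,
                                 restarts = 5, burnins = 50)
  rarA <- suppressMessages(rarefyTable(cohortTable(coA), depth, seed = 1))
  mdA <- joinMetadata(rarA, cohortMetadata(coA))
  # train sources on one batch-A time point per phase (the midpoint-nearest)
  slices <- setNames(lapply(c(10, 21, 52, 95, 108), function(a)
    rarA[, mdA$age_weeks == a]), lifePhases())
  ss <- prepareSources(slices, params)

  mdB <- cohortMetadata(coB)
  ma_ids <- mdB$sample_id[mdB$life_phase == "MA"]
  ctl_ids <- ma_ids[1:4]
  sink_ids <- setdiff(ma_ids, ctl_ids)
  ctl <- cohortTable(coB)[, ctl_ids]
  ctl_ages <- setNames(mdB$age_weeks[match(ctl_ids, mdB$sample_id)], ctl_ids)
  cal <- calibrateSources(ss, ctl, ctl_ages, params)
  sinks <- cohortTable(coB)[, sink_ids]
  truth <- setNames(mdB$age_weeks[match(sink_ids, mdB$sample_id)], sink_ids)

  err <- function(sources) {
    att <- suppressMessages(attributeAll(sinks, sources, params))
    pr <- predictAge(att, actual_ages = truth)
    mean(abs(pr$predicted_age_weeks - pr$actual_age_weeks), na.rm = TRUE)
  }
  expect_lt(err(cal), err(ss))
})

test_that("evaluation report handles perfect, antitone and degenerate cases", {
  mkpred <- function(pred, act) data.frame(
    sink_id = paste0("s", seq_along(pred)), predicted_age_weeks = pred,
    unknown_proportion = 0, retained = TRUE, actual_age_weeks = act)
  act <- c(9, 17, 30, 52, 77, 95, 112, 40, 64, 86)
  perf <- evaluatePredictions(mkpred(act, act))
  expect_equal(perf$spearman_rho, 1)
  expect_equal(perf$adjusted_r2, 1, tolerance = 1e-9)
  rev <- evaluatePredictions(mkpred(rev(sort(act)), sort(act)))
  expect_equal(rev$spearman_rho, -1)
  const <- evaluatePredictions(mkpred(rep(50, 10), act))
  expect_true(is.na(const$spearman_rho))
  # strata split at 62 weeks
  expect_equal(perf$young$n, sum(act < 62))
  expect_equal(perf$old$n, sum(act >= 62))
})
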