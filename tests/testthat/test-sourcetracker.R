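test_that("source preparation pools, rarefies and harmonizes taxa", {
  set.seed(1)
  mk <- function(ids, n, depth) {
    m <- rmultinom(n, depth, prob = rep(1 / length(ids), length(ids)))
    dimnames(m) <- list(ids, paste0(ids[1], "_s", seq_len(n)))
    CountTable(m)
  }
  tables <- list(MR = mk(c("a", "b"), 2, 400),
                 MA = mk(c("b", "c"), 2, 400),
                 MD = mk(c("a", "c"), 2, 400),
                 OD = mk(c("a", "d"), 2, 400),
                 VO = mk(c("c", "d"), 2, 400))
  ss <- prepareSources(tables, sourceTrackingParams(rarefaction_depth = 500))
  expect_equal(nrow(sourceCounts(ss)), 5)
  expect_identical(phaseLabels(ss), lifePhases())
  expect_true(all(rowSums(sourceCounts(ss)) == 500))
  expect_setequal(taxonIds(ss), c("a", "b", "c", "d"))
  # taxa absent from a phase stay zero after harmonization
  expect_equal(sourceCounts(ss)["MR", "d"], 0L, ignore_attr = TRUE)
  # a pool below depth errors, naming the phase
  shallow <- list(MR = mk(c("a", "b"), 1, 100))
  expect_error(prepareSources(shallow,
                              sourceTrackingParams(rarefaction_depth = 500)),
               "MR")
})

test_that("pooling a sample already at depth is the identity", {
  m <- matrix(c(300L, 200L), 2, 1, dimnames = list(c("a", "b"), "s"))
  ss <- prepareSources(list(MA = CountTable(m)),
                       sourceTrackingParams(rarefaction_depth = 500))
  expect_equal(sourceCounts(ss)["MA", c("a", "b")], c(a = 300L, b = 200L))
})

test_that("pooling identical samples preserves expected composition", {
  m <- matrix(rep(c(600L, 400L), 2), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  fracs <- vapply(1:60, function(s) {
    ss <- prepareSources(list(MR = CountTable(m)),
                         sourceTrackingParams(rarefaction_depth = 1000,
                                              seed = s))
    sourceCounts(ss)["MR", "a"] / 1000
  }, 0)
  expect_lt(abs(mean(fracs) - 0.6), 0.02 * 0.6)
})

test_that("single-read sink has the closed-form posterior", {
  # one read of a taxon present in source A; for N = 1 the mixing terms
  # cancel and P(A) = phi_A(t) / (phi_A(t) + 1/T)
  sc <- matrix(c(9L, 1L), 1, 2, dimnames = list("A", c("t1", "t2")))
  ss <- new("SourceSet", sourceCounts = sc, depth = 10L)
  p <- sourceTrackingParams(alpha_known = 0.001, alpha_unknown = 0.1,
                            beta = 10, rarefaction_depth = NA)
  o <- oracleAttribute(c(t1 = 1L), ss, p)
  phiA <- (9 + 0.001) / (10 + 2 * 0.001)
  expect_equal(unname(o["A"]), phiA / (phiA + 1 / 2), tolerance = 1e-12)
  expect_equal(sum(o), 1, tolerance = 1e-12)
})

test_that("exact posterior is symmetric for exchangeable sources", {
  sc <- matrix(c(5L, 5L, 5L, 5L), 2, 2,
               dimnames = list(c("A", "B"), c("t1", "t2")))
  ss <- new("SourceSet", sourceCounts = sc, depth = 10L)
  p <- sourceTrackingParams(rarefaction_depth = NA)
  o <- oracleAttribute(c(t1 = 2L, t2 = 2L), ss, p)
  expect_equal(unname(o["A"]), unname(o["B"]), tolerance = 1e-12)
  expect_error(oracleAttribute(c(t1 = 200L), ss, p), "too large")
})

test_that("Gibbs sampling converges to the exact posterior", {
  sc <- matrix(c(8L, 1L, 1L, 1L, 1L, 8L), 2, 3, byrow = TRUE,
               dimnames = list(c("A", "B"), c("t1", "t2", "t3")))
  ss <- new("SourceSet", sourceCounts = sc, depth = 10L)
  p <- sourceTrackingParams(rarefaction_depth = NA, restarts = 800,
                            burnins = 50, seed = 4)
  for (sink in list(c(t1 = 4L, t3 = 2L), c(t2 = 3L), c(t1 = 1L, t2 = 1L,
                                                       t3 = 1L))) {
    o <- oracleAttribute(sink, ss, p)
    g <- proportions(gibbsAttribute(sink, ss, p))[1, ]
    expect_lt(mean(abs(o - g)), 0.02)
  }
})

test_that("sinks from one source's profile are attributed to it", {
  src <- disjointSources()
  p <- sourceTrackingParams(rarefaction_depth = 500L, seed = 1)
  props <- vapply(1:5, function(s) {
    set.seed(100 + s)
    sink <- rmultinom(1, 500, prob = src$pA)[, 1]
    names(sink) <- src$taxa
    pp <- p; pp$seed <- s
    proportions(gibbsAttribute(sink, src$ss, pp))[1, "A"]
  }, 0)
  expect_true(all(props >= 0.90))
})

test_that("byte-identical sources share attribution symmetrically", {
  sc <- rbind(A = c(t1 = 300L, t2 = 200L), B = c(t1 = 300L, t2 = 200L))
  ss <- new("SourceSet", sourceCounts = sc, depth = 500L)
  set.seed(9)
  sink <- rmultinom(1, 500, prob = c(0.6, 0.4))[, 1]
  names(sink) <- c("t1", "t2")
  g <- proportions(gibbsAttribute(sink, ss,
    sourceTrackingParams(rarefaction_depth = 500, restarts = 20, seed = 2)))
  expect_lt(abs(g[1, "A"] - g[1, "B"]), 0.10)
})

test_that("sinks foreign to every source go to the unknown component", {
  sc <- rbind(A = c(t1 = 250L, t2 = 250L, t3 = 0L, t4 = 0L),
              B = c(t1 = 0L, t2 = 250L, t3 = 250L, t4 = 0L))
  ss <- new("SourceSet", sourceCounts = sc, depth = 500L)
  p <- sourceTrackingParams(rarefaction_depth = NA, seed = 3)
  sink <- c(t4 = 6L)  # taxon absent from every known source
  o <- oracleAttribute(sink, ss, p)
  expect_gte(o["unknown"], 0.5)
  g <- proportions(gibbsAttribute(sink, ss, p))[1, ]
  expect_gte(g["unknown"], 0.5)
})

test_that("attribution of a table is deterministic and drops shallow sinks", {
  src <- disjointSources(500L, n_per = 30)
  ss <- src$ss
  mix <- 0.5 * src$pA + 0.5 * src$pB
  set.seed(5)
  m <- cbind(
    deep1 = rmultinom(1, 800, prob = mix)[, 1],
    deep2 = rmultinom(1, 600, prob = src$pA)[, 1],
    shallow = rmultinom(1, 100, prob = mix)[, 1]
  )
  rownames(m) <- src$taxa
  sinks <- CountTable(m)
  p <- sourceTrackingParams(rarefaction_depth = 500L, restarts = 5,
                            burnins = 50, seed = 7)
  expect_message(a1 <- attributeAll(sinks, ss, p), "dropped 1 sink")
  a2 <- suppressMessages(attributeAll(sinks, ss, p))
  expect_identical(proportions(a1), proportions(a2))
  expect_identical(rownames(proportions(a1)), c("deep1", "deep2"))
  expect_identical(attr(a1, "dropped"), "shallow")
  expect_equal(rowSums(proportions(a1)), c(deep1 = 1, deep2 = 1),
               tolerance = 1e-9)
  # empty sink table gives an empty attribution
  a0 <- attributeAll(sinks[, 0], ss, p)
  expect_equal(nrow(proportions(a0)), 0)
})

test_that("explicit two-source mixtures are recovered", {
  src <- disjointSources(2733L)
  mix <- 0.7 * src$pA + 0.3 * src$pB
  set.seed(21)
  est <- vapply(1:8, function(i) {
    sink <- rmultinom(1, 2733, prob = mix)[, 1]
    names(sink) <- src$taxa
    pp <- sourceTrackingParams(seed = i)
    proportions(gibbsAttribute(sink, src$ss, pp))[1, "A"]
  }, 0)
  expect_lt(abs(mean(est) - 0.7), 0.05)
})

test_that("restart dispersion shrinks with sink depth", {
  src <- disjointSources(1000L, n_per = 30)
  mix <- 0.5 * src$pA + 0.5 * src$pB
  medSD <- function(depth) {
    sds <- vapply(1:5, function(s) {
      set.seed(s)
      sink <- rmultinom(1, depth, prob = mix)[, 1]
      names(sink) <- src$taxa
      p <- sourceTrackingParams(rarefaction_depth = NA, restarts = 10,
                                seed = s)
      mean(restartSD(gibbsAttribute(sink, src$ss, p))[1, ])
    }, 0)
    stats::median(sds)
  }
  expect_lt(medSD(2000L), medSD(40L))
})
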