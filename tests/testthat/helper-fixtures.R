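# Shared fixtures, built in code.

# Small count table with explicit values.
toyTable <- function() {
  CountTable(matrix(c(5L, 1L, 0L, 2L), 2, 2,
                    dimnames = list(c("ASV1", "ASV2"), c("s1", "s2"))))
}

# Reduced cohort design for unit tests (fast but structurally faithful).
smallDesign <- function(seed = 1, n_mice = 4, n_taxa = 40,
                        depth_mean = 2000, ...) {
  cohortDesign(n_mice = n_mice, n_taxa = n_taxa, depth_mean = depth_mean,
               seed = seed, ...)
}

# Two well-separated source communities over disjoint taxon supports, each
# occupying `n_per` taxa with log-normal abundances (community-like richness;
# with very few occupied taxa the unknown component of the model can mimic
# any sink, so recovery is only meaningful at realistic richness). Returns
# the SourceSet plus the true generating profiles.
disjointSources <- function(depth = 2733L, n_per = 100L, sigma = 1,
                            seed = 1) {
  set.seed(seed)
  n_taxa <- 2L * n_per
  pA <- c(exp(rnorm(n_per, 0, sigma)), rep(0, n_per)); pA <- pA / sum(pA)
  pB <- c(rep(0, n_per), exp(rnorm(n_per, 0, sigma))); pB <- pB / sum(pB)
  sc <- rbind(A = rmultinom(1, depth, pA)[, 1],
              B = rmultinom(1, depth, pB)[, 1])
  colnames(sc) <- paste0("t", seq_len(n_taxa))
  names(pA) <- names(pB) <- colnames(sc)
  list(ss = new("SourceSet", sourceCounts = sc, depth = as.integer(depth)),
       pA = pA, pB = pB, taxa = colnames(sc))
}

# Attribution with a single sink and explicit proportions.
makeAttribution <- function(props, sd = NULL, id = "sink1") {
  p <- matrix(props, 1, dimnames = list(id, names(props)))
  if (is.null(sd)) sd <- p * 0
  new("Attribution", proportions = p, restartSD = sd)
}

# Exact two-group PERMANOVA pseudo-F computed independently, straight from
# the sums-of-squares definition (test oracle; no shared code with the
# implementation).
referenceF <- function(D, labels) {
  D2 <- D^2
  N <- nrow(D2)
  f <- factor(labels)
  a <- nlevels(f)
  ss_t <- sum(D2[upper.tri(D2)]) / N
  ss_w <- 0
  for (lv in levels(f)) {
    i <- which(f == lv)
    ss_w <- ss_w + sum(D2[i, i][upper.tri(D2[i, i])]) / length(i)
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (N - a))
}
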