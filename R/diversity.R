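#' Rarefy a count table to even depth
#'
#' Uniform subsampling without replacement (a single draw per sample) to
#' exactly `depth` reads. Samples with fewer than `depth` reads are dropped;
#' their ids are reported in the returned table's metadata under
#' `rarefaction_dropped` (and via a message).
#'
#' @param table a [CountTable-class].
#' @param depth positive integer target depth (default 2,733).
#' @param seed integer seed; the draw is reproducible.
#' @return A rarefied [CountTable-class]; every retained sample totals exactly
#'   `depth`.
#' @export
#' @examples
#' ct <- CountTable(matrix(c(1000L, 1000L), 2, 1,
#'   dimnames = list(c("t1", "t2"), "s1")))
#' colSums(counts(rarefyTable(ct, 1000, seed = 1)))
rarefyTable <- function(table, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be a positive integer")
  m <- counts(table)
  totals <- colSums(m)
  dropped <- colnames(m)[totals < depth]
  if (length(dropped))
    message("rarefyTable: dropped ", length(dropped),
            " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  keep <- totals >= depth
  m <- m[, keep, drop = FALSE]
  set.seed(seed)
  # vegan warns when a table has no 1-counts (its "looks like non-count
  # data" heuristic); integrality is already enforced by CountTable validity
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(m), depth)),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  meta <- table@metadata
  meta$rarefaction_dropped <- dropped
  meta$rarefaction_depth <- as.integer(depth)
  CountTable(rar, metadata = meta)
}

#' Alpha diversity per sample
#'
#' Shannon entropy (natural log), Simpson diversity reported as 1 - D (the
#' probability two reads differ), bias-corrected Chao1 richness
#' S_obs + F1(F1-1) / (2(F2+1)) with F1/F2 the singleton/doubleton counts
#' (set `bias_corrected = FALSE` for the classic S_obs + F1^2/(2 F2) form),
#' and Pielou's evenness H / ln(S_obs), undefined (NA) for single-taxon
#' samples.
#'
#' @param table a [CountTable-class]; every sample must have total > 0.
#' @param bias_corrected use the bias-corrected Chao1 (default).
#' @return data.frame with columns sample_id, observed, shannon, simpson,
#'   chao1, pielou.
#' @export
#' @examples
#' ct <- CountTable(matrix(c(5L, 5L), 2, 1,
#'   dimnames = list(c("t1", "t2"), "s1")))
#' alphaDiversity(ct)
alphaDiversity <- function(table, bias_corrected = TRUE) {
  m <- counts(table)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("zero-total sample: ", colnames(m)[totals == 0][1])
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    p <- x / sum(x)
    H <- -sum(p * log(p))
    s_obs <- length(x)
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    chao1 <- if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
             else if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs
    data.frame(sample_id = colnames(m)[j],
               observed = s_obs,
               shannon = H,
               simpson = 1 - sum(p^2),
               chao1 = chao1,
               pielou = if (s_obs >= 2) H / log(s_obs) else NA_real_)
  })
  do.call(rbind, res)
}

#' Bray-Curtis dissimilarity
#'
#' d(A, B) = sum |a_t - b_t| / sum (a_t + b_t); typically applied to a
#' rarefied (equal-depth) table but any nonnegative table is accepted.
#'
#' @param table a [CountTable-class]; every sample must have total > 0.
#' @return A [DistanceMatrix-class] with entries in [0, 1].
#' @export
brayCurtis <- function(table) {
  m <- counts(table)
  if (any(colSums(m) == 0))
    stop("zero-total sample: ", colnames(m)[colSums(m) == 0][1])
  DistanceMatrix(as.matrix(vegan::vegdist(t(m), method = "bray")),
                 method = "bray-curtis")
}

#' Weighted UniFrac distance
#'
#' Unnormalized weighted UniFrac: for each branch, its length times the
#' absolute difference between the fractions of each sample's reads
#' descending from it, summed over branches. `normalized = TRUE` divides by
#' the maximum attainable value (branch lengths weighted by total descendant
#' fractions), as in the normalized variant.
#'
#' @param table a [CountTable-class]; every taxon must be a tip of `tree`.
#' @param tree a rooted phylogeny: newick string, file path, or an
#'   [ape::phylo] object with branch lengths.
#' @param normalized logical; default FALSE (the unnormalized variant).
#' @return A [DistanceMatrix-class].
#' @export
weightedUniFrac <- function(table, tree, normalized = FALSE) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or newick")
  missing <- setdiff(taxonIds(table), tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  m <- counts(table)
  if (any(colSums(m) == 0))
    stop("zero-total sample: ", colnames(m)[colSums(m) == 0][1])
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(m, taxa_are_rows = TRUE),
    phyloseq::phy_tree(ape::keep.tip(tree, taxonIds(table)))
  )
  d <- phyloseq::UniFrac(ps, weighted = TRUE, normalized = normalized)
  v <- as.matrix(d)[sampleIds(table), sampleIds(table)]
  DistanceMatrix(v, method = if (normalized) "weighted-unifrac-normalized"
                             else "weighted-unifrac")
}

#' Principal-coordinate analysis (classical MDS)
#'
#' Double-centers -D^2/2, eigendecomposes, keeps positive eigenvalues, and
#' scales eigenvectors by the square roots of the eigenvalues. Explained
#' fractions are eigenvalues over the sum of positive eigenvalues (negative
#' eigenvalues are dropped), hence non-increasing and summing to at most 1.
#'
#' @param dm a [DistanceMatrix-class].
#' @param n_axes number of axes requested; truncated with a warning when it
#'   exceeds the number of positive eigenvalues.
#' @return List of class `PcoaResult` with `sample_ids`, `coordinates`
#'   (samples x axes) and `explained_fraction`.
#' @export
pcoaOrdination <- function(dm, n_axes = 2L) {
  stopifnot(n_axes >= 1)
  D <- as.matrix(dm)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12 & e$values > 0
  k_avail <- sum(pos)
  if (n_axes > k_avail)
    warning("only ", k_avail, " positive eigenvalues; extra axes are zero")
  k_use <- min(n_axes, k_avail)
  lam <- e$values[pos]
  coords <- matrix(0, n, n_axes)
  if (k_use > 0)
    coords[, seq_len(k_use)] <- e$vectors[, which(pos)[seq_len(k_use)],
                                          drop = FALSE] %*%
      diag(sqrt(lam[seq_len(k_use)]), k_use)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  structure(list(sample_ids = rownames(D),
                 coordinates = coords,
                 explained_fraction = if (k_avail > 0)
                   (lam / sum(lam))[seq_len(k_use)] else numeric(0)),
            class = "PcoaResult")
}
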