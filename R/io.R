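#' Read a taxa-by-sample count table from TSV
#'
#' Expects a tab-separated file whose first column holds taxon identifiers and
#' whose header row holds sample identifiers (the dominant amplicon-table
#' orientation). `transposed = TRUE` accepts a samples-by-taxa file instead.
#'
#' @param path path to a TSV file.
#' @param transposed logical; set TRUE when the file stores samples as rows.
#' @return A validated [CountTable-class].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' ct <- CountTable(matrix(c(5, 1, 0, 2), 2, 2,
#'   dimnames = list(c("ASV1", "ASV2"), c("s1", "s2"))))
#' writeCountTable(ct, tf)
#' readCountTable(tf)
readCountTable <- function(path, transposed = FALSE) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("no samples: header lists no sample columns")
  if (anyDuplicated(header[-1]))
    stop(if (transposed) "duplicate taxon id: " else "duplicate sample id: ",
         header[-1][duplicated(header[-1])][1])
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (nrow(df) == 0) stop("no samples: file has no data rows")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop(if (transposed) "duplicate sample id: " else "duplicate taxon id: ",
         ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer cell at row '%s', column '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(num != round(num))) {
    bad <- which(num != round(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer cell at row '%s', column '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  rownames(num) <- ids
  if (transposed) num <- t(num)
  if (anyDuplicated(rownames(num)))
    stop("duplicate taxon id: ", rownames(num)[duplicated(rownames(num))][1])
  if (anyDuplicated(colnames(num)))
    stop("duplicate sample id: ", colnames(num)[duplicated(colnames(num))][1])
  CountTable(num)
}

#' Write a CountTable to TSV
#'
#' Inverse of [readCountTable()]: integer tables round-trip byte-identically.
#'
#' @param table a [CountTable-class].
#' @param path output path.
#' @param id_column header name of the taxon-id column.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(table, path, id_column = "taxon_id") {
  m <- counts(table)
  lines <- c(paste(c(id_column, colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], format(m[i, ], scientific = FALSE,
                                              trim = TRUE)),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

requiredMetadataCols <- c("sample_id", "mouse_id", "age_weeks", "life_phase",
                          "diet", "cage")

#' Read / write sample metadata TSV
#'
#' QIIME-style mapping file keyed by `sample_id`, with columns mouse_id,
#' age_weeks, life_phase, diet and cage.
#'
#' @param path file path.
#' @return [readSampleMetadata()] returns a data.frame.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(requiredMetadataCols, names(df))
  if (length(missing))
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1])
  if (any(df$age_weeks < 0 | df$age_weeks > 150))
    stop("age_weeks outside [0, 150]")
  df
}

#' @rdname readSampleMetadata
#' @param metadata data.frame of sample metadata.
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a square distance matrix TSV
#'
#' @param path file path.
#' @return [readDistanceMatrix()] returns a [DistanceMatrix-class].
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  DistanceMatrix(as.matrix(df))
}

#' @rdname readDistanceMatrix
#' @param dm a [DistanceMatrix-class].
#' @export
writeDistanceMatrix <- function(dm, path) {
  m <- as.matrix(dm)
  utils::write.table(data.frame(sample_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove low-prevalence taxa
#'
#' Drops every taxon observed (nonzero) in fewer than `min_samples` samples.
#' The reference protocol uses `min_samples = 5`. Samples are never removed and
#' retained counts are never altered; the operation is idempotent.
#'
#' @param table a [CountTable-class].
#' @param min_samples positive integer; minimum number of samples a taxon must
#'   be present in to be kept.
#' @return Filtered [CountTable-class] (possibly with zero taxa).
#' @export
#' @examples
#' ct <- CountTable(matrix(c(1, 3, 0, 4, 0, 5), 3, 2,
#'   dimnames = list(paste0("t", 1:3), c("a", "b"))))
#' filterLowPrevalence(ct, 2)
filterLowPrevalence <- function(table, min_samples) {
  stopifnot(min_samples >= 1)
  prevalence <- rowSums(counts(table) > 0)
  table[prevalence >= min_samples, ]
}

#' Join a count table with sample metadata
#'
#' Validates that every sample in the table has exactly one metadata row and
#' returns the metadata reordered to the table's sample order, so grouping by
#' phase, age, diet or mouse aligns positionally with the count columns.
#'
#' @param table a [CountTable-class].
#' @param metadata data.frame with a `sample_id` column.
#' @return The metadata data.frame, one row per table sample, in table order.
#' @export
joinMetadata <- function(table, metadata) {
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample id in metadata: ",
         metadata$sample_id[duplicated(metadata$sample_id)][1])
  orphans <- setdiff(sampleIds(table), metadata$sample_id)
  if (length(orphans))
    stop("samples without metadata: ", paste(orphans, collapse = ", "))
  metadata[match(sampleIds(table), metadata$sample_id), , drop = FALSE]
}
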