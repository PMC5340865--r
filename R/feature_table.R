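#' Construct a validated feature table
#'
#' A feature table is the universal currency of the package: a
#' samples-by-features matrix of non-negative integer read counts whose
#' feature identifiers are, in the usual sequence-keyed mode, the exact
#' denoised amplicon sequences (sOTUs) themselves.
#'
#' @param counts Numeric matrix, samples in rows and features in columns,
#'   with unique non-empty row and column names. All entries must be
#'   non-negative integers (stored as integer-valued doubles or integers).
#' @param sequence_keyed Logical; if `TRUE` (default `NA` = auto-detect),
#'   feature identifiers are required to be uppercase DNA strings over
#'   `{A,C,G,T,N}`.
#'
#' @return A matrix of class `feature_table`.
#' @export
feature_table <- function(counts, sequence_keyed = NA) {
  if (!is.matrix(counts)) {
    counts <- as.matrix(counts)
  }
  storage.mode(counts) <- "double"
  validate_feature_table(counts, sequence_keyed = sequence_keyed)
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' @rdname feature_table
#' @param x Object to coerce or test.
#' @export
as_feature_table <- function(x) {
  if (inherits(x, "feature_table")) return(x)
  feature_table(x)
}

#' @rdname feature_table
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

#' Validate feature-table invariants
#'
#' Checks non-negativity, integrality (with the offending coordinates named
#' in the error), and uniqueness of sample and feature identifiers.
#'
#' @param counts Matrix to validate.
#' @param sequence_keyed See [feature_table()].
#' @return Invisibly, `TRUE`.
#' @export
validate_feature_table <- function(counts, sequence_keyed = NA) {
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    stop("feature table has no sample identifiers (row names)")
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    stop("feature table has no feature identifiers (column names)")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "invalid count %s at sample '%s' (row %d), feature '%s' (column %d): counts must be non-negative integers",
      format(counts[i, j]), rownames(counts)[i], i, colnames(counts)[j], j))
  }
  if (isTRUE(sequence_keyed)) {
    dna <- grepl("^[ACGTN]+$", colnames(counts))
    if (!all(dna)) {
      stop("sequence-keyed table has a non-DNA feature identifier: ",
           colnames(counts)[!dna][1])
    }
  }
  invisible(TRUE)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features, %s reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  if (ncol(x) > 0 && all(grepl("^[ACGTN]+$", colnames(x)))) {
    cat("feature identifiers are DNA sequences (sequence-keyed)\n")
  }
  invisible(x)
}

#' Per-sample relative frequencies
#'
#' Converts counts to within-sample relative frequencies. Samples with a
#' zero total cannot be normalized; they are dropped and recorded in the
#' `"dropped_samples"` attribute, with a warning.
#'
#' @param table A [feature_table()] (or coercible matrix).
#' @return A samples-by-features matrix of frequencies, each retained row
#'   summing to 1; attribute `dropped_samples` lists zero-total samples.
#' @export
relative_frequencies <- function(table) {
  x <- as_feature_table(table)
  totals <- rowSums(x)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " zero-total sample(s) dropped: ",
            paste(utils::head(rownames(x)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
  }
  freq <- unclass(x)[!zero, , drop = FALSE] / totals[!zero]
  attr(freq, "dropped_samples") <- rownames(x)[zero]
  freq
}

# Run code under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
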