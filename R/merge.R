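#' Merge sequence-keyed feature tables into one feature space
#'
#' Tables from different studies (or different sequencing runs) rarely
#' share a read length, but Deblur sOTUs amplified from a shared primer
#' share their 5' start. Features are therefore matched across tables by
#' exact sequence identity after trimming every sequence to a common
#' length, keeping the 5' prefix. Within a table, features that collide
#' after trimming have their counts summed per sample; across tables the
#' trimmed feature spaces are unioned, with absent features filled with 0.
#'
#' @param tables A non-empty list of sequence-keyed [feature_table()]s.
#'   If the list is named, names are used as study prefixes to
#'   disambiguate colliding sample identifiers.
#' @param trim_length Trim length in bases; default `NULL` uses the global
#'   minimum feature length across all tables.
#' @return A merged [feature_table()]. Total reads are conserved.
#' @export
merge_tables <- function(tables, trim_length = NULL) {
  if (!is.list(tables) || length(tables) < 1) {
    stop("merge_tables() needs a non-empty list of feature tables")
  }
  tables <- lapply(tables, as_feature_table)
  for (t in tables) {
    if (ncol(t) > 0 && !all(grepl("^[ACGTN]+$", colnames(t)))) {
      stop("merge_tables() requires sequence-keyed tables ",
           "(feature identifiers must be DNA sequences)")
    }
  }
  if (is.null(trim_length)) {
    lens <- unlist(lapply(tables, function(t) nchar(colnames(t))))
    if (length(lens) == 0) stop("cannot merge tables with no features")
    trim_length <- min(lens)
  }
  trimmed <- lapply(tables, trim_features, trim_length = trim_length)

  all_samples <- unlist(lapply(trimmed, rownames))
  if (anyDuplicated(all_samples)) {
    if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
      stop("sample identifier collision across tables (",
           paste(utils::head(unique(all_samples[duplicated(all_samples)]), 3),
                 collapse = ", "),
           "); name the table list by study to disambiguate")
    }
    trimmed <- lapply(seq_along(trimmed), function(i) {
      t <- trimmed[[i]]
      rownames(t) <- paste(names(tables)[i], rownames(t), sep = ".")
      t
    })
  }

  features <- unique(unlist(lapply(trimmed, colnames)))
  samples <- unlist(lapply(trimmed, rownames))
  out <- matrix(0, nrow = length(samples), ncol = length(features),
                dimnames = list(samples, features))
  for (t in trimmed) {
    out[rownames(t), colnames(t)] <- unclass(t)
  }
  feature_table(out)
}

#' @rdname merge_tables
#' @param table A sequence-keyed [feature_table()].
#' @return `trim_features()`: the table with feature identifiers trimmed to
#'   their 5' prefix of `trim_length` bases, counts of colliding features
#'   summed within each sample.
#' @export
trim_features <- function(table, trim_length) {
  x <- as_feature_table(table)
  if (ncol(x) == 0) return(x)
  if (any(nchar(colnames(x)) < trim_length)) {
    stop("trim_length ", trim_length, " exceeds the shortest feature length")
  }
  trimmed_ids <- substr(colnames(x), 1L, trim_length)
  if (!anyDuplicated(trimmed_ids)) {
    colnames(x) <- trimmed_ids
    return(x)
  }
  grp <- factor(trimmed_ids, levels = unique(trimmed_ids))
  # rowsum() operates on rows; transpose so features (columns) are summed
  collapsed <- t(rowsum(t(unclass(x)), grp))
  colnames(collapsed) <- levels(grp)
  feature_table(collapsed)
}
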