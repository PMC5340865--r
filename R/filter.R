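#' Match bloom sequences against table features by exact prefix identity
#'
#' A table feature matches a bloom if, after trimming both sequences to
#' the shorter of the two lengths (keeping the 5' prefix), the strings are
#' identical. Matching is exact: no mismatches, no indels. One bloom may
#' match several features that share its trimmed prefix; all are returned.
#'
#' @param feature_ids Character vector of table feature sequences (or a
#'   [feature_table()], whose column names are used).
#' @param bloom_catalog Named character vector of bloom sequences
#'   (see [read_fasta()]); must be non-empty.
#' @return Data.frame of matches with columns `bloom_id`, `feature_id`;
#'   the unique matched feature identifiers are in attribute
#'   `"matched_features"`.
#' @export
match_blooms <- function(feature_ids, bloom_catalog) {
  if (is_feature_table(feature_ids) || is.matrix(feature_ids)) {
    feature_ids <- colnames(feature_ids)
  }
  if (length(bloom_catalog) == 0) {
    stop("empty bloom catalog: filtering with nothing to filter is ",
         "almost certainly a mistake")
  }
  if (is.null(names(bloom_catalog))) {
    names(bloom_catalog) <- paste0("bloom_", seq_along(bloom_catalog))
  }
  blooms <- toupper(bloom_catalog)
  feats <- toupper(feature_ids)
  hits <- list()
  flen <- nchar(feats)
  for (b in seq_along(blooms)) {
    L <- pmin(nchar(blooms[b]), flen)
    hit <- substr(feats, 1L, L) == substr(rep(blooms[b], length(feats)), 1L, L)
    if (any(hit)) {
      hits[[length(hits) + 1L]] <- data.frame(
        bloom_id = names(blooms)[b],
        feature_id = feature_ids[hit],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(bloom_id = character(0), feature_id = character(0),
               stringsAsFactors = FALSE)
  attr(out, "matched_features") <- unique(out$feature_id)
  out
}

#' Remove matched features from a feature table, with full accounting
#'
#' The filtered table contains exactly the unmatched features, with the
#' surviving counts untouched. The report records the total reads removed,
#' the per-sample fraction of reads dropped, and the quartiles of those
#' fractions. Samples reduced to a zero total are retained and flagged
#' (silently dropping samples would break meta-analysis bookkeeping);
#' downstream rarefaction drops them explicitly.
#'
#' @param table A [feature_table()].
#' @param matched_ids Feature identifiers to remove (a character vector,
#'   or the output of [match_blooms()]).
#' @return A list with `table` (the filtered [feature_table()]) and
#'   `report` (a `filter_report`).
#' @export
filter_table <- function(table, matched_ids) {
  x <- as_feature_table(table)
  pairs <- NULL
  if (is.data.frame(matched_ids)) {
    pairs <- matched_ids
    matched_ids <- unique(matched_ids$feature_id)
  }
  unknown <- setdiff(matched_ids, colnames(x))
  if (length(unknown) > 0) {
    stop("matched_ids not present in the table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  keep <- !(colnames(x) %in% matched_ids)
  filtered <- unclass(x)[, keep, drop = FALSE]
  orig_tot <- rowSums(unclass(x))
  new_tot <- rowSums(filtered)
  dropped_frac <- ifelse(orig_tot > 0, (orig_tot - new_tot) / orig_tot, 0)
  names(dropped_frac) <- rownames(x)
  report <- structure(list(
    n_blooms_supplied = if (!is.null(pairs)) length(unique(pairs$bloom_id))
                        else NA_integer_,
    n_matched_features = sum(!keep),
    reads_removed_total = sum(orig_tot) - sum(new_tot),
    per_sample_dropped_fraction = dropped_frac,
    quartiles = stats::quantile(dropped_frac, probs = c(0.25, 0.5, 0.75),
                                names = FALSE, type = 7),
    matched_pairs = pairs,
    emptied_samples = rownames(x)[orig_tot > 0 & new_tot == 0]
  ), class = "filter_report")
  list(table = feature_table(filtered), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d feature(s) removed, %s reads removed\n",
              x$n_matched_features,
              format(x$reads_removed_total, big.mark = ",")))
  cat(sprintf(
    "per-sample dropped read fraction: %.1f%% / %.1f%% / %.1f%% (25th/50th/75th percentile)\n",
    100 * x$quartiles[1], 100 * x$quartiles[2], 100 * x$quartiles[3]))
  if (length(x$emptied_samples) > 0) {
    cat(sprintf("%d sample(s) emptied by filtering (retained, flagged)\n",
                length(x$emptied_samples)))
  }
  invisible(x)
}

#' Filter a table by the top-k blooms of a ranked list
#'
#' Nested filtering: depth `k` removes blooms 1 through `k` of the ranked
#' list, so each depth includes all shallower depths; `k = 0` returns the
#' table unchanged. Reads removed are non-decreasing in `k`.
#'
#' @param table A [feature_table()].
#' @param ranked_blooms Ranked bloom sequences: a character vector in rank
#'   order (e.g. [read_bloom_list()]) or a ranked candidate data.frame
#'   from [rank_candidates()].
#' @param k Filter depth, `0 <= k <= length(ranked_blooms)`.
#' @return The filtered [feature_table()]; the `filter_report` is in
#'   attribute `"report"` (for `k > 0`).
#' @export
nested_filter <- function(table, ranked_blooms, k) {
  seqs <- ranked_bloom_sequences(ranked_blooms)
  if (length(k) != 1 || is.na(k) || k < 0 || k > length(seqs) ||
      k != round(k)) {
    stop("filter depth k must be an integer in [0, ", length(seqs), "]")
  }
  if (k == 0) return(as_feature_table(table))
  matches <- match_blooms(table, seqs[seq_len(k)])
  res <- filter_table(table, matches)
  out <- res$table
  attr(out, "report") <- res$report
  out
}

ranked_bloom_sequences <- function(ranked_blooms) {
  if (is.data.frame(ranked_blooms)) {
    if (!all(c("rank", "sequence") %in% names(ranked_blooms))) {
      stop("ranked bloom data.frame needs 'rank' and 'sequence' columns")
    }
    ord <- order(ranked_blooms$rank)
    stats::setNames(ranked_blooms$sequence[ord],
                    paste0("bloom_", ranked_blooms$rank[ord]))
  } else {
    b <- as.character(ranked_blooms)
    if (is.null(names(ranked_blooms))) {
      names(b) <- if (length(b) > 0) paste0("bloom_", seq_along(b))
        else character(0)
    } else {
      names(b) <- names(ranked_blooms)
    }
    b
  }
}

#' Match and remove a bloom list in one step
#'
#' @param table A [feature_table()].
#' @param bloom_catalog Named character vector of bloom sequences.
#' @return As [filter_table()]: list of `table` and `report`.
#' @export
remove_blooms <- function(table, bloom_catalog) {
  matches <- match_blooms(table, bloom_catalog)
  filter_table(table, matches)
}
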