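#' Per-feature fold changes in room-temperature storage studies
#'
#' For every feature and every (study, subject, day > 0) room-temperature
#' sample, computes the log2 fold change of the feature's depth-normalized
#' count relative to that subject's frozen day-0 baseline. A minimum read
#' threshold guards against noise at the detection floor: comparisons where
#' both counts fall below the threshold are excluded, and a count below the
#' threshold on one side only is clamped up to the threshold, so genuine
#' large blooms rising from a near-zero baseline are scored finitely.
#'
#' @param table A [feature_table()] holding all storage-study samples.
#' @param metadata Metadata frame (see [read_metadata()]) with `study_id`,
#'   `condition`, `subject_id` and `day` for every sample in `table`.
#' @param read_threshold Detection floor, in reads (default 10).
#' @param depth_normalize If `TRUE` (default), both members of a comparison
#'   are rescaled to the smaller of the two sample depths before
#'   thresholding, so the read floor means the same thing on both sides.
#' @return An object of class `storage_fold_changes`: a list with
#'   `comparisons` (long data.frame: `feature_id`, `study_id`,
#'   `subject_id`, `day`, `c0`, `ct`, `log2fc`, `excluded`) and `max_fold`
#'   (data.frame: `feature_id`, `max_fold` on the linear scale, `NA`
#'   meaning the feature was excluded from every comparison, i.e. absent
#'   from the storage studies).
#' @export
storage_fold_changes <- function(table, metadata, read_threshold = 10,
                                 depth_normalize = TRUE) {
  x <- as_feature_table(table)
  md <- metadata[match(rownames(x), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) {
    stop("metadata is missing rows for sample(s): ",
         paste(utils::head(setdiff(rownames(x), metadata$sample_id), 5),
               collapse = ", "))
  }
  keys <- interaction(md$study_id, md$subject_id, drop = TRUE)
  comp <- list()
  for (k in levels(keys)) {
    idx <- which(keys == k)
    sub <- md[idx, , drop = FALSE]
    base_i <- idx[which(sub$condition == "frozen" & sub$day == 0)]
    if (length(base_i) == 0) {
      stop("subject '", sub$subject_id[1], "' in study '", sub$study_id[1],
           "' has no frozen day-0 baseline sample")
    }
    base_i <- base_i[1]
    rt_i <- idx[which(sub$condition == "room_temperature" & sub$day > 0)]
    c0_raw <- unclass(x)[base_i, ]
    d0 <- sum(c0_raw)
    for (i in rt_i) {
      ct_raw <- unclass(x)[i, ]
      dt <- sum(ct_raw)
      if (depth_normalize && d0 > 0 && dt > 0) {
        m <- min(d0, dt)
        c0 <- c0_raw * (m / d0)
        ct <- ct_raw * (m / dt)
      } else {
        c0 <- c0_raw
        ct <- ct_raw
      }
      excluded <- c0 < read_threshold & ct < read_threshold
      l2 <- log2(pmax(ct, read_threshold) / pmax(c0, read_threshold))
      l2[excluded] <- NA_real_
      comp[[length(comp) + 1L]] <- data.frame(
        feature_id = colnames(x),
        study_id = md$study_id[i],
        subject_id = md$subject_id[i],
        day = md$day[i],
        c0 = unname(c0), ct = unname(ct),
        log2fc = unname(l2), excluded = unname(excluded),
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(comp) > 0) do.call(rbind, comp) else
    data.frame(feature_id = character(0), study_id = character(0),
               subject_id = character(0), day = numeric(0), c0 = numeric(0),
               ct = numeric(0), log2fc = numeric(0), excluded = logical(0))
  max_l2 <- tapply(comparisons$log2fc,
                   factor(comparisons$feature_id, levels = colnames(x)),
                   function(v) if (all(is.na(v))) NA_real_ else
                     max(v, na.rm = TRUE))
  out <- list(
    comparisons = comparisons,
    max_fold = data.frame(feature_id = colnames(x),
                          max_fold = unname(2^as.numeric(max_l2)),
                          stringsAsFactors = FALSE),
    read_threshold = read_threshold,
    depth_normalize = depth_normalize)
  class(out) <- "storage_fold_changes"
  out
}

#' @export
print.storage_fold_changes <- function(x, ...) {
  n_obs <- sum(!is.na(x$max_fold$max_fold))
  cat(sprintf(
    "storage_fold_changes: %d features (%d observed, %d absent), %d comparisons, read threshold %g\n",
    nrow(x$max_fold), n_obs, nrow(x$max_fold) - n_obs,
    nrow(unique(x$comparisons[c("study_id", "subject_id", "day")])),
    x$read_threshold))
  invisible(x)
}

#' Cross-study fold changes of a shipped cohort against fresh-frozen cohorts
#'
#' Blooming bacteria are expected to sit at a higher relative frequency in
#' a room-temperature-shipped cohort than in every fresh-frozen cohort, so
#' each feature is scored by the minimum, over the frozen studies, of the
#' ratio of its mean relative frequency in the shipped (target) study to
#' its mean frequency in that frozen study. A pseudo-frequency floors the
#' denominator so features absent from a frozen study score finitely.
#'
#' @param target_table Feature table of the shipped study.
#' @param frozen_tables Non-empty list of feature tables of fresh-frozen
#'   studies, sharing a (merged, trimmed) feature space with the target.
#' @param pseudo_freq Denominator floor (default `1e-6`, about one read at
#'   a depth of a million).
#' @return Data.frame of class `cross_study_fold_changes` with columns
#'   `feature_id`, `target_freq`, `min_fold`. Features absent from the
#'   target get `min_fold = 0`.
#' @export
cross_study_fold_changes <- function(target_table, frozen_tables,
                                     pseudo_freq = 1e-6) {
  if (!is.list(frozen_tables) || length(frozen_tables) < 1) {
    stop("at least one frozen study table is required")
  }
  if (pseudo_freq <= 0) stop("pseudo_freq must be > 0")
  target <- as_feature_table(target_table)
  frozen <- lapply(frozen_tables, as_feature_table)
  features <- unique(c(colnames(target),
                       unlist(lapply(frozen, colnames))))
  mean_freq <- function(t) {
    f <- relative_frequencies(t)
    out <- stats::setNames(numeric(length(features)), features)
    if (nrow(f) > 0) out[colnames(f)] <- colMeans(f)
    out
  }
  target_freq <- mean_freq(target)
  frozen_freq <- vapply(frozen, mean_freq, numeric(length(features)))
  frozen_freq <- matrix(frozen_freq, nrow = length(features),
                        dimnames = list(features, names(frozen_tables)))
  ratios <- target_freq / pmax(frozen_freq, pseudo_freq)
  min_fold <- apply(ratios, 1, min)
  min_fold[target_freq == 0] <- 0
  out <- data.frame(feature_id = features,
                    target_freq = unname(target_freq),
                    min_fold = unname(min_fold),
                    stringsAsFactors = FALSE)
  attr(out, "frozen_freq") <- frozen_freq
  attr(out, "pseudo_freq") <- pseudo_freq
  class(out) <- c("cross_study_fold_changes", class(out))
  out
}

#' Select candidate blooms by the three-way threshold criterion
#'
#' A feature is selected as a candidate bloom if any of three rules fires:
#' \describe{
#'   \item{`both_axes`}{at least a `t_storage`-fold increase in the
#'     room-temperature storage studies AND at least a `t_cross`-fold
#'     higher frequency in the shipped cohort than in every fresh-frozen
#'     cohort;}
#'   \item{`storage_extreme`}{at least a `t_extreme`-fold increase within
#'     the storage studies alone;}
#'   \item{`cross_only`}{not observed in the storage studies at all, but
#'     at least a `t_cross`-fold change against every frozen cohort.}
#' }
#' When both `both_axes` and `storage_extreme` hold, `both_axes` is
#' recorded. Comparisons are inclusive (`>=`) by default.
#'
#' @param storage_fcs A [storage_fold_changes()] result (or its `max_fold`
#'   data.frame).
#' @param cross_fcs A [cross_study_fold_changes()] result.
#' @param t_cross,t_storage,t_extreme Selection thresholds (linear fold).
#' @param inclusive Use `>=` (default) rather than `>`.
#' @return Data.frame of selected candidates: `feature_id`,
#'   `max_storage_fold` (`NA` = absent from storage studies),
#'   `min_cross_fold`, `criterion`.
#' @export
select_candidates <- function(storage_fcs, cross_fcs, t_cross = 2,
                              t_storage = 2, t_extreme = 50,
                              inclusive = TRUE) {
  stopifnot(t_cross > 0, t_storage > 0, t_extreme > 0)
  sf <- if (inherits(storage_fcs, "storage_fold_changes"))
    storage_fcs$max_fold else storage_fcs
  features <- unique(c(sf$feature_id, cross_fcs$feature_id))
  storage <- sf$max_fold[match(features, sf$feature_id)]
  cross <- cross_fcs$min_fold[match(features, cross_fcs$feature_id)]
  cross[is.na(cross)] <- 0
  ge <- if (inclusive) `>=` else `>`
  both_axes <- !is.na(storage) & ge(storage, t_storage) & ge(cross, t_cross)
  storage_extreme <- !is.na(storage) & ge(storage, t_extreme)
  cross_only <- is.na(storage) & ge(cross, t_cross)
  criterion <- rep(NA_character_, length(features))
  criterion[storage_extreme] <- "storage_extreme"
  criterion[both_axes] <- "both_axes"   # wins over storage_extreme
  criterion[cross_only] <- "cross_only"
  sel <- !is.na(criterion)
  data.frame(feature_id = features[sel],
             max_storage_fold = storage[sel],
             min_cross_fold = cross[sel],
             criterion = criterion[sel],
             stringsAsFactors = FALSE)
}

#' Rank candidate blooms by severity
#'
#' Severity weighs how much of the shipped cohort a candidate occupies by
#' how specific it is to shipping: `severity = mean target relative
#' frequency x log2(max(min_cross_fold, 1) + 1)`. This abundance-weighted
#' score is this package's convention; a precomputed ranking may be used
#' anywhere a ranked bloom list is accepted. Ties are broken
#' lexicographically by sequence.
#'
#' @param candidates Output of [select_candidates()].
#' @param target_table Feature table of the shipped study, used for
#'   abundance weighting.
#' @return The candidates with `sequence`, `severity` and `rank` columns,
#'   ordered by increasing rank (decreasing severity).
#' @export
rank_candidates <- function(candidates, target_table) {
  if (nrow(candidates) == 0) {
    out <- candidates
    out$sequence <- character(0)
    out$severity <- numeric(0)
    out$rank <- integer(0)
    return(out)
  }
  freq <- relative_frequencies(target_table)
  mean_freq <- stats::setNames(colMeans(freq), colnames(freq))
  f <- mean_freq[candidates$feature_id]
  f[is.na(f)] <- 0
  out <- candidates
  out$sequence <- candidates$feature_id
  out$severity <- unname(f * log2(pmax(out$min_cross_fold, 1) + 1))
  ord <- order(-out$severity, out$sequence)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full bloom-detection pipeline
#'
#' Convenience wrapper: storage fold changes on the storage-study table,
#' cross-study fold changes of the shipped cohort against the frozen
#' cohorts (after merging to a shared trimmed feature space), three-way
#' selection, and severity ranking.
#'
#' @param storage_table,storage_metadata Storage-study inputs
#'   (see [storage_fold_changes()]). May be `NULL` if only cohort data are
#'   available, in which case every feature is treated as absent from the
#'   storage studies.
#' @param target_table Shipped-cohort feature table.
#' @param frozen_tables List of fresh-frozen cohort tables.
#' @param read_threshold,pseudo_freq,t_cross,t_storage,t_extreme See the
#'   stage functions.
#' @param trim_length Trim length for cross-table sequence matching;
#'   default the global minimum feature length.
#' @return Ranked candidate data.frame (see [rank_candidates()]), with the
#'   per-feature scores of all features in attribute `"scores"` (a Fig
#'   1E-style scatter of max storage fold vs min cross-study fold).
#' @export
detect_blooms <- function(storage_table, storage_metadata, target_table,
                          frozen_tables, read_threshold = 10,
                          pseudo_freq = 1e-6, t_cross = 2, t_storage = 2,
                          t_extreme = 50, trim_length = NULL) {
  all_tables <- c(list(target = target_table), frozen_tables,
                  if (!is.null(storage_table)) list(storage = storage_table))
  if (is.null(trim_length)) {
    trim_length <- min(unlist(lapply(all_tables,
                                     function(t) nchar(colnames(t)))))
  }
  target_t <- trim_features(target_table, trim_length)
  frozen_t <- lapply(frozen_tables, trim_features, trim_length = trim_length)
  cross <- cross_study_fold_changes(target_t, frozen_t,
                                    pseudo_freq = pseudo_freq)
  if (!is.null(storage_table)) {
    storage_t <- trim_features(storage_table, trim_length)
    storage <- storage_fold_changes(storage_t, storage_metadata,
                                    read_threshold = read_threshold)
    sf <- storage$max_fold
  } else {
    sf <- data.frame(feature_id = character(0), max_fold = numeric(0))
  }
  cand <- select_candidates(sf, cross, t_cross = t_cross,
                            t_storage = t_storage, t_extreme = t_extreme)
  ranked <- rank_candidates(cand, target_t)
  scores <- data.frame(
    feature_id = cross$feature_id,
    max_storage_fold = sf$max_fold[match(cross$feature_id, sf$feature_id)],
    min_cross_fold = cross$min_fold,
    selected = cross$feature_id %in% ranked$feature_id,
    stringsAsFactors = FALSE)
  attr(ranked, "scores") <- scores
  attr(ranked, "trim_length") <- trim_length
  ranked
}

#' Write ranked bloom candidates as TSV and FASTA
#'
#' The TSV mirrors the published candidate-bloom table (rank, sequence,
#' criterion, fold changes, severity); the FASTA carries the sequences
#' with rank-based headers, ready for [match_blooms()]-style filtering of
#' other tables.
#'
#' @param ranked Output of [rank_candidates()] / [detect_blooms()].
#' @param tsv_path,fasta_path Output paths (`NULL` to skip either).
#' @return Invisibly, `ranked`.
#' @export
write_candidates <- function(ranked, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path)) {
    cols <- c("rank", "feature_id", "sequence", "criterion",
              "max_storage_fold", "min_cross_fold", "severity")
    utils::write.table(ranked[, cols], tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta_path)) {
    seqs <- stats::setNames(ranked$sequence,
                            paste0("bloom_", ranked$rank))
    write_fasta(seqs, fasta_path)
  }
  invisible(ranked)
}

#' Read a ranked bloom list from TSV or FASTA
#'
#' Accepts either the TSV written by [write_candidates()] or a bloom
#' FASTA (ranked by file order, mirroring the published bloom list).
#'
#' @param path Path to a candidates TSV or a FASTA file.
#' @return Named character vector of bloom sequences in rank order.
#' @export
read_bloom_list <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (startsWith(first, ">")) {
    return(read_fasta(path))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           colClasses = "character")
  if (!all(c("rank", "sequence") %in% names(tab))) {
    stop("bloom TSV must have 'rank' and 'sequence' columns")
  }
  tab <- tab[order(as.integer(tab$rank)), , drop = FALSE]
  stats::setNames(toupper(tab$sequence), paste0("bloom_", tab$rank))
}
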