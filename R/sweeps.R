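#' Kruskal-Wallis age-diversity test across nested filter depths
#'
#' Evaluates how deeply a ranked bloom list must be filtered before a
#' known biological signal -- the effect of age on alpha diversity --
#' becomes detectable. For each depth `k` in `depths` the table is
#' filtered down to blooms `1..k`, rarefied (same seed at every depth, so
#' depths differ only by the filter), per-sample observed richness is
#' computed, and a Kruskal-Wallis test is run across age categories.
#'
#' @param table Feature table of the cohort to test (typically the
#'   shipped study).
#' @param metadata Metadata frame supplying `age_category` for the tested
#'   samples; samples without an age category are ignored.
#' @param ranked_blooms Ranked bloom list (see [nested_filter()]).
#' @param rarefaction_depth Even-sampling depth. Default `NULL` uses 90%
#'   of the median per-sample total after filtering the full ranked list,
#'   balancing read retention against sample loss at deep filtering.
#' @param seed Integer seed for rarefaction.
#' @param depths Integer vector of filter depths (default `0:n_blooms`).
#' @return Data.frame of class `sweep_result`: one row per depth with
#'   `depth`, `statistic` (H), `p_value`, `neg_log10_p`, `n_samples`.
#' @export
age_diversity_sweep <- function(table, metadata, ranked_blooms,
                                rarefaction_depth = NULL, seed,
                                depths = NULL) {
  x <- as_feature_table(table)
  seqs <- ranked_bloom_sequences(ranked_blooms)
  if (is.null(depths)) depths <- 0:length(seqs)
  md <- metadata[match(rownames(x), metadata$sample_id), , drop = FALSE]
  has_age <- !is.na(md$age_category)
  if (length(unique(md$age_category[has_age])) < 2) {
    stop("need at least two age categories")
  }
  x <- feature_table(unclass(x)[has_age, , drop = FALSE])
  md <- md[has_age, , drop = FALSE]
  if (is.null(rarefaction_depth)) {
    full <- nested_filter(x, seqs, length(seqs))
    rarefaction_depth <- max(1L, floor(0.9 * stats::median(rowSums(full))))
  }
  rows <- lapply(depths, function(k) {
    filtered <- nested_filter(x, seqs, k)
    rar <- rarefy(filtered, rarefaction_depth, seed = seed)
    rich <- observed_richness(rar)
    age <- md$age_category[match(rownames(rar), md$sample_id)]
    groups <- split(as.numeric(rich), age)
    groups <- groups[lengths(groups) > 0]
    kw <- kruskal_wallis(groups)
    data.frame(depth = k, statistic = kw$statistic, p_value = kw$p_value,
               neg_log10_p = -log10(kw$p_value), n_samples = length(rich))
  })
  out <- do.call(rbind, rows)
  attr(out, "rarefaction_depth") <- rarefaction_depth
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", class(out))
  out
}

#' Mean cross-study Bray-Curtis distances across nested filter depths
#'
#' For every pair of studies and every filter depth, draws random
#' cross-study sample pairs (with replacement; re-drawn per depth with a
#' per-depth seed `seed + depth`) and reports the mean Bray-Curtis
#' distance on filtered relative frequencies. Shipped-versus-frozen
#' series are expected to fall as blooms are removed; frozen-versus-
#' frozen series should stay flat.
#'
#' @param merged_table Feature table holding the samples of all studies
#'   (shared, trimmed feature space).
#' @param metadata Metadata frame supplying `study_id` per sample.
#' @param ranked_blooms Ranked bloom list (see [nested_filter()]).
#' @param depths Integer vector of filter depths (default `0:n_blooms`).
#' @param n_pairs Random sample pairs per (study pair, depth).
#' @param seed Integer base seed.
#' @return Data.frame of class `sweep_result`: `depth`, `study_a`,
#'   `study_b`, `mean_distance`, `se_distance` (Monte-Carlo standard
#'   error), `n_pairs`.
#' @export
cross_study_distance_sweep <- function(merged_table, metadata,
                                       ranked_blooms, depths = NULL,
                                       n_pairs = 1000, seed) {
  x <- as_feature_table(merged_table)
  seqs <- ranked_bloom_sequences(ranked_blooms)
  if (is.null(depths)) depths <- 0:length(seqs)
  md <- metadata[match(rownames(x), metadata$sample_id), , drop = FALSE]
  studies <- sort(unique(md$study_id[!is.na(md$study_id)]))
  if (length(studies) < 2) stop("need samples from at least two studies")
  pairs <- utils::combn(studies, 2, simplify = FALSE)
  rows <- list()
  for (k in depths) {
    filtered <- nested_filter(x, seqs, k)
    freq <- relative_frequencies(filtered)
    study_of <- md$study_id[match(rownames(freq), md$sample_id)]
    for (pr in pairs) {
      ia <- which(study_of == pr[1])
      ib <- which(study_of == pr[2])
      if (length(ia) == 0 || length(ib) == 0) {
        warning("study pair ", pr[1], " vs ", pr[2], " skipped at depth ",
                k, ": a study has no surviving samples")
        next
      }
      d <- with_seed(seed + k, {
        sa <- sample(ia, n_pairs, replace = TRUE)
        sb <- sample(ib, n_pairs, replace = TRUE)
        fa <- freq[sa, , drop = FALSE]
        fb <- freq[sb, , drop = FALSE]
        rowSums(abs(fa - fb)) / rowSums(fa + fb)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        depth = k, study_a = pr[1], study_b = pr[2],
        mean_distance = mean(d),
        se_distance = stats::sd(d) / sqrt(length(d)),
        n_pairs = n_pairs, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", class(out))
  out
}

#' Mean class-level taxonomy distribution per study
#'
#' Sums each sample's relative frequencies by taxonomic class (features
#' missing from the taxonomy fall under `"unclassified"`), then averages
#' the class profiles over the samples of each study, unweighted. Each
#' study's class means sum to 1.
#'
#' @param table A [feature_table()].
#' @param taxonomy Taxonomy data.frame (see [read_taxonomy()]), or a
#'   named character vector mapping feature identifier to class label.
#' @param metadata Metadata frame supplying `study_id` per sample.
#' @return Matrix of mean class frequencies, studies x classes.
#' @export
class_taxonomy_summary <- function(table, taxonomy, metadata) {
  x <- as_feature_table(table)
  freq <- relative_frequencies(x)
  if (is.data.frame(taxonomy)) {
    cls_map <- stats::setNames(lineage_class(taxonomy$lineage),
                               taxonomy$feature_id)
  } else {
    cls_map <- taxonomy
  }
  cls <- cls_map[colnames(freq)]
  cls[is.na(cls)] <- "unclassified"
  by_class <- t(rowsum(t(freq), group = factor(cls)))
  study <- metadata$study_id[match(rownames(by_class), metadata$sample_id)]
  if (anyNA(study)) {
    stop("metadata is missing study_id for sample(s): ",
         paste(utils::head(rownames(by_class)[is.na(study)], 5),
               collapse = ", "))
  }
  means <- rowsum(by_class, group = factor(study)) /
    as.vector(table(factor(study)))
  means[, order(-colMeans(means)), drop = FALSE]
}
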