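# Shared fixture builders. Everything is generated in code at test time.

# A small valid feature table with DNA feature identifiers.
toy_table <- function(counts = matrix(c(3, 1, 0, 5), 2, 2),
                      samples = c("s1", "s2"),
                      features = c("ACGTAA", "TTGGCC")) {
  dimnames(counts) <- list(samples, features)
  feature_table(counts)
}

# A random valid sequence-keyed table (deterministic per seed).
random_table <- function(seed, n_samples = 6, n_features = 12,
                         seq_len = 20, max_count = 50) {
  withr::with_seed(seed, {
    feats <- debloom::simulate_sequences(n_features, seq_len,
                                         seed = seed + 17L)
    m <- matrix(rpois(n_samples * n_features, lambda = max_count / 5),
                n_samples, n_features,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                unname(feats)))
    feature_table(m)
  })
}

# Paired storage-study fixture: one subject, explicit counts at day 0
# (frozen) and day 1 (room temperature).
paired_storage <- function(c0, ct, features = NULL) {
  stopifnot(length(c0) == length(ct))
  if (is.null(features)) {
    features <- vapply(seq_along(c0), function(i)
      paste(rep(c("A", "C", "G", "T")[(i %% 4) + 1], 8), collapse = ""),
      character(1))
    features <- paste0(features, strrep("A", seq_along(c0)))
  }
  m <- rbind(d0 = c0, d1 = ct)
  colnames(m) <- features
  md <- data.frame(sample_id = c("d0", "d1"), study_id = "stor",
                   condition = c("frozen", "room_temperature"),
                   subject_id = "subj1", day = c(0, 1),
                   age_category = NA_character_)
  list(table = feature_table(m), metadata = md)
}

# One-sample-per-study cohort tables with exact relative frequencies.
freq_tables <- function(target_freq, frozen_freqs, depth = 1000,
                        features = NULL) {
  n <- length(target_freq)
  if (is.null(features)) {
    features <- vapply(seq_len(n), function(i)
      paste0(strrep("ACGT", 5), strrep("A", i)), character(1))
  }
  mk <- function(freqs, id) {
    m <- matrix(round(freqs * depth), 1, n,
                dimnames = list(id, features))
    feature_table(m)
  }
  list(target = mk(target_freq, "t1"),
       frozen = lapply(seq_along(frozen_freqs), function(i)
         mk(frozen_freqs[[i]], paste0("f", i))))
}
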