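#' Configuration for the compositional bloom simulator
#'
#' The simulator emulates the statistical structure of the two data
#' designs the detection procedure consumes: (i) small paired storage
#' studies (frozen day-0 baseline per subject, room-temperature samples at
#' later days) and (ii) multi-study cohorts sharing a feature space, one
#' shipped at room temperature with per-sample transit times and several
#' fresh-frozen. A small set of planted bloom features grows exponentially
#' with time at room temperature, acting multiplicatively on relative
#' frequencies followed by renormalization -- the minimal compositional
#' model of fast-growing taxa distorting everyone else's relative
#' abundance. An optional age effect lowers baseline richness by zeroing a
#' category-specific random subset of non-bloom features before
#' normalization, so the planted effect is exactly the alpha metric under
#' test. Sequencing noise is pure multinomial.
#'
#' @param n_features Number of features (exact sequences).
#' @param n_blooms Number of planted bloom features.
#' @param depth Reads per sample (every sample totals exactly this).
#' @param theta Total Dirichlet concentration controlling between-sample
#'   compositional variability (larger = more similar samples).
#' @param abundance_exponent Power-law exponent of the non-bloom
#'   rank-abundance curve (`p_i` proportional to `i^-s`).
#' @param bloom_baseline_freq Baseline relative frequency of each bloom
#'   feature (blooms such as Enterobacteriaceae are ordinarily present at
#'   modest frequency in fresh-frozen stool).
#' @param bloom_growth_rates Per-bloom growth rate, in doublings per day
#'   at room temperature; length `n_blooms`.
#' @param n_storage_studies,n_subjects,storage_days Storage design:
#'   studies, subjects per study, and the room-temperature sampling days
#'   (each subject also contributes a frozen day-0 baseline).
#' @param n_frozen_studies,samples_per_study Cohort design: number of
#'   fresh-frozen studies and samples per study. A scalar applies to every
#'   study; a vector of length `n_frozen_studies + 1` gives the shipped
#'   study's size first, then each frozen study's.
#' @param shipping_days Integer vector of possible transit times (days) a
#'   shipped sample spends at room temperature; drawn uniformly.
#' @param age_categories,age_masked_features Age-effect design: category
#'   labels and, per category, how many non-bloom features are zeroed for
#'   samples of that category (disjoint subsets, drawn once per
#'   simulation). All zeros disables the effect.
#' @param sequence_length Length of the simulated exact sequences.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_features = 500,
                       n_blooms = 5,
                       depth = 5000,
                       theta = 2000,
                       abundance_exponent = 0.5,
                       bloom_baseline_freq = 0.003,
                       bloom_growth_rates = c(2.4, 2.2, 2.0, 1.8, 1.6),
                       n_storage_studies = 2,
                       n_subjects = 5,
                       storage_days = c(1, 2, 4, 7),
                       n_frozen_studies = 3,
                       samples_per_study = 50,
                       shipping_days = 1:8,
                       age_categories = c("20s", "60s"),
                       age_masked_features = c(30, 0),
                       sequence_length = 100) {
  cfg <- list(n_features = n_features, n_blooms = n_blooms, depth = depth,
              theta = theta, abundance_exponent = abundance_exponent,
              bloom_baseline_freq = bloom_baseline_freq,
              bloom_growth_rates = bloom_growth_rates,
              n_storage_studies = n_storage_studies,
              n_subjects = n_subjects, storage_days = storage_days,
              n_frozen_studies = n_frozen_studies,
              samples_per_study = samples_per_study,
              shipping_days = shipping_days,
              age_categories = age_categories,
              age_masked_features = age_masked_features,
              sequence_length = sequence_length)
  if (n_blooms >= n_features) {
    stop("n_blooms must be smaller than n_features")
  }
  if (length(bloom_growth_rates) != n_blooms) {
    stop("bloom_growth_rates must have length n_blooms")
  }
  if (any(bloom_growth_rates < 0)) stop("growth rates must be >= 0")
  if (n_blooms * bloom_baseline_freq >= 1) {
    stop("bloom baseline frequencies exceed the total composition")
  }
  if (length(age_masked_features) != length(age_categories)) {
    stop("age_masked_features must have one entry per age category")
  }
  if (sum(age_masked_features) > n_features - n_blooms) {
    stop("age masking would exhaust the non-bloom features")
  }
  if (depth < 1 || theta <= 0) stop("depth and theta must be positive")
  if (!length(samples_per_study) %in% c(1L, n_frozen_studies + 1L)) {
    stop("samples_per_study must be a scalar or have one entry per study ",
         "(shipped first)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a catalog of distinct random DNA sequences
#'
#' @param n Number of sequences.
#' @param length Sequence length in bases.
#' @param seed Integer seed.
#' @return Named character vector (`seq_1` ... `seq_n`) of distinct
#'   uppercase DNA strings.
#' @export
simulate_sequences <- function(n, length, seed) {
  if (length < 1 || n < 1) stop("n and length must be positive")
  if (log(n) > length * log(4)) {
    stop("cannot generate ", n, " distinct sequences of length ", length)
  }
  with_seed(seed, {
    draw <- function(k) {
      vapply(seq_len(k), function(i) {
        paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
              collapse = "")
      }, character(1))
    }
    seqs <- draw(n)
    while (anyDuplicated(seqs)) {
      dup <- which(duplicated(seqs))
      seqs[dup] <- draw(length(dup))
    }
    stats::setNames(seqs, paste0("seq_", seq_len(n)))
  })
}

# Baseline Dirichlet parameters: blooms at a fixed modest frequency, the
# remaining mass spread over non-blooms along a power-law rank-abundance
# curve. Returns list(alpha, bloom_idx).
baseline_alpha <- function(config) {
  n <- config$n_features
  nb <- config$n_blooms
  p <- numeric(n)
  bloom_idx <- seq_len(nb)
  p[bloom_idx] <- config$bloom_baseline_freq
  nonbloom <- setdiff(seq_len(n), bloom_idx)
  w <- seq_along(nonbloom)^(-config$abundance_exponent)
  p[nonbloom] <- (1 - nb * config$bloom_baseline_freq) * w / sum(w)
  list(alpha = config$theta * p, bloom_idx = bloom_idx, p = p)
}

draw_composition <- function(alpha, masked = NULL) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (!is.null(masked)) g[masked] <- 0
  g / sum(g)
}

amplify <- function(p, bloom_idx, rates, t) {
  if (t <= 0) return(p)
  p[bloom_idx] <- p[bloom_idx] * 2^(rates * t)
  p / sum(p)
}

draw_counts <- function(p, depth) {
  as.numeric(stats::rmultinom(1, depth, p))
}

# uniform draw from a value set; immune to sample()'s scalar expansion
draw_from <- function(values) {
  if (length(values) == 1) return(values)
  values[sample.int(length(values), 1)]
}

#' Simulate paired room-temperature storage studies
#'
#' Per subject: a baseline composition drawn from the configured
#' Dirichlet; a frozen day-0 sample; and a room-temperature sample at
#' each configured day, with bloom features amplified by
#' `2^(rate * day)` and the composition renormalized.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param sequences Optional sequence catalog to reuse (to share a feature
#'   space with [simulate_cohort_studies()]); default generates one from
#'   `seed`.
#' @return List with `table` ([feature_table()], sequence-keyed),
#'   `metadata` (see [read_metadata()] columns) and `truth` (bloom
#'   sequences, rates, per-subject baselines are not recorded).
#' @export
simulate_storage_study <- function(config, seed, sequences = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sequences)) {
    sequences <- simulate_sequences(config$n_features,
                                    config$sequence_length, seed)
  }
  base <- baseline_alpha(config)
  counts <- list(); md <- list()
  with_seed(seed + 1L, {
    for (st in seq_len(config$n_storage_studies)) {
      study <- paste0("storage", st)
      for (subj in seq_len(config$n_subjects)) {
        subject <- paste0(study, "_subj", subj)
        p0 <- draw_composition(base$alpha)
        sid <- paste0(subject, "_d0")
        counts[[sid]] <- draw_counts(p0, config$depth)
        md[[sid]] <- data.frame(sample_id = sid, study_id = study,
                                condition = "frozen", subject_id = subject,
                                day = 0, age_category = NA_character_,
                                stringsAsFactors = FALSE)
        for (t in config$storage_days) {
          pt <- amplify(p0, base$bloom_idx, config$bloom_growth_rates, t)
          sid <- paste0(subject, "_d", t)
          counts[[sid]] <- draw_counts(pt, config$depth)
          md[[sid]] <- data.frame(sample_id = sid, study_id = study,
                                  condition = "room_temperature",
                                  subject_id = subject, day = t,
                                  age_category = NA_character_,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  })
  m <- do.call(rbind, counts)
  colnames(m) <- unname(sequences)
  list(table = feature_table(m),
       metadata = do.call(rbind, c(md, list(make.row.names = FALSE))),
       truth = list(
         bloom_sequences = unname(sequences[base$bloom_idx]),
         bloom_rates = config$bloom_growth_rates,
         baseline_freq = base$p))
}

#' Simulate a multi-study cohort (one shipped, several fresh-frozen)
#'
#' All studies share the feature space and baseline composition model.
#' Frozen-study samples are drawn at shipping time 0. Shipped-study
#' samples receive a per-sample transit time drawn uniformly from
#' `config$shipping_days`, with bloom features amplified accordingly.
#' Each sample is assigned an age category uniformly at random; a
#' category's masked feature subset (drawn once, disjoint across
#' categories, never a bloom) is zeroed before normalization, lowering
#' that category's baseline richness.
#'
#' @inheritParams simulate_storage_study
#' @return List with `tables` (named list of per-study
#'   [feature_table()]s; the shipped study is named `"shipped"`),
#'   `metadata`, and `truth` (bloom sequences and rates, per-sample
#'   shipping times and age categories, per-category masked features).
#' @export
simulate_cohort_studies <- function(config, seed, sequences = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sequences)) {
    sequences <- simulate_sequences(config$n_features,
                                    config$sequence_length, seed)
  }
  base <- baseline_alpha(config)
  studies <- c("shipped", if (config$n_frozen_studies > 0)
    paste0("frozen", seq_len(config$n_frozen_studies)))
  shipped <- c(TRUE, rep(FALSE, config$n_frozen_studies))
  n_per <- rep_len(config$samples_per_study, length(studies))
  tables <- list(); md <- list()
  masked_sets <- stats::setNames(vector("list", length(config$age_categories)),
                                 config$age_categories)
  with_seed(seed + 2L, {
    pool <- setdiff(seq_len(config$n_features), base$bloom_idx)
    for (a in seq_along(config$age_categories)) {
      m <- config$age_masked_features[a]
      if (m > 0) {
        masked_sets[[a]] <- sort(sample(pool, m))
        pool <- setdiff(pool, masked_sets[[a]])
      } else {
        masked_sets[[a]] <- integer(0)
      }
    }
    for (s in seq_along(studies)) {
      rows <- matrix(0, nrow = n_per[s], ncol = config$n_features)
      ids <- character(n_per[s])
      for (i in seq_len(n_per[s])) {
        sid <- sprintf("%s_s%03d", studies[s], i)
        age <- draw_from(config$age_categories)
        t <- if (shipped[s]) draw_from(config$shipping_days) else 0
        p <- draw_composition(base$alpha, masked = masked_sets[[age]])
        p <- amplify(p, base$bloom_idx, config$bloom_growth_rates, t)
        rows[i, ] <- draw_counts(p, config$depth)
        ids[i] <- sid
        md[[sid]] <- data.frame(
          sample_id = sid, study_id = studies[s],
          condition = if (shipped[s]) "room_temperature" else "frozen",
          subject_id = sid, day = t, age_category = age,
          stringsAsFactors = FALSE)
      }
      dimnames(rows) <- list(ids, unname(sequences))
      tables[[studies[s]]] <- feature_table(rows)
    }
  })
  metadata <- do.call(rbind, c(md, list(make.row.names = FALSE)))
  list(tables = tables,
       metadata = metadata,
       truth = list(
         bloom_sequences = unname(sequences[base$bloom_idx]),
         bloom_rates = config$bloom_growth_rates,
         baseline_freq = base$p,
         masked_features = lapply(masked_sets, function(i)
           unname(sequences[i])),
         shipping_day = stats::setNames(metadata$day, metadata$sample_id),
         age_category = stats::setNames(metadata$age_category,
                                        metadata$sample_id)))
}

#' Simulate the full detection benchmark (storage + cohort, shared features)
#'
#' Generates one sequence catalog and uses it for both a storage-study
#' dataset and a multi-study cohort, so the two designs share their
#' feature space exactly as paired real studies processed with a common
#' primer would.
#'
#' @inheritParams simulate_storage_study
#' @return List with `storage` (see [simulate_storage_study()]), `cohort`
#'   (see [simulate_cohort_studies()]), `sequences`, and `truth` (the
#'   cohort's ground truth).
#' @export
simulate_benchmark <- function(config, seed) {
  sequences <- simulate_sequences(config$n_features,
                                  config$sequence_length, seed)
  storage <- simulate_storage_study(config, seed, sequences = sequences)
  cohort <- simulate_cohort_studies(config, seed, sequences = sequences)
  list(storage = storage, cohort = cohort, sequences = sequences,
       truth = cohort$truth)
}

#' Assign class-level taxonomy labels to simulated features
#'
#' Bloom features are labeled Gammaproteobacteria (the class the
#' fast-growing room-temperature taxa overwhelmingly belong to); the
#' remaining features are assigned common gut classes at fixed
#' proportions. Lineages are Greengenes-style strings down to class.
#'
#' @param sequences Sequence catalog (named character vector).
#' @param bloom_sequences Character vector of the planted bloom sequences.
#' @param seed Integer seed.
#' @return Taxonomy data.frame (`feature_id`, `lineage`), usable with
#'   [class_taxonomy_summary()].
#' @export
simulate_taxonomy <- function(sequences, bloom_sequences, seed) {
  classes <- c("Bacteroidia", "Clostridia", "Bacilli", "Actinobacteria",
               "Verrucomicrobiae")
  weights <- c(0.35, 0.40, 0.10, 0.10, 0.05)
  lineage_of <- function(cls) {
    phylum <- c(Bacteroidia = "Bacteroidetes", Clostridia = "Firmicutes",
                Bacilli = "Firmicutes", Actinobacteria = "Actinobacteria",
                Verrucomicrobiae = "Verrucomicrobia",
                Gammaproteobacteria = "Proteobacteria")[cls]
    sprintf("k__Bacteria; p__%s; c__%s", phylum, cls)
  }
  seqs <- unname(sequences)
  cls <- with_seed(seed, {
    sample(classes, length(seqs), replace = TRUE, prob = weights)
  })
  cls[seqs %in% bloom_sequences] <- "Gammaproteobacteria"
  data.frame(feature_id = seqs, lineage = lineage_of(cls),
             stringsAsFactors = FALSE)
}
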