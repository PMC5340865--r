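#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, to control for unequal sequencing effort before alpha-diversity
#' comparison. Samples with fewer than `depth` reads are dropped and
#' recorded in the `"dropped_samples"` attribute. Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param table A [feature_table()].
#' @param depth Target depth in reads (>= 1).
#' @param seed Integer seed.
#' @return The rarefied [feature_table()]; every row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  if (length(depth) != 1 || is.na(depth) || depth < 1) {
    stop("rarefaction depth must be a positive integer")
  }
  depth <- as.integer(depth)
  x <- as_feature_table(table)
  totals <- rowSums(x)
  keep <- totals >= depth
  m <- unclass(x)[keep, , drop = FALSE]
  with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      if (sum(m[i, ]) == depth) next
      reads <- rep.int(seq_len(ncol(m)), m[i, ])
      kept <- sample(reads, depth)
      m[i, ] <- tabulate(kept, nbins = ncol(m))
    }
  })
  out <- feature_table(m)
  attr(out, "dropped_samples") <- rownames(x)[!keep]
  attr(out, "depth") <- depth
  out
}

#' Observed richness (number of detected features)
#'
#' @param x A counts vector, or a [feature_table()] (per-sample richness).
#' @return Integer vector of the number of features with count > 0.
#' @export
observed_richness <- function(x) {
  if (is.matrix(x)) {
    return(stats::setNames(as.integer(rowSums(unclass(x) > 0)), rownames(x)))
  }
  if (any(x < 0, na.rm = TRUE)) stop("counts must be non-negative")
  as.integer(sum(x > 0))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC(u, v) = sum(|u - v|) / sum(u + v)`, bounded in `[0, 1]`. Not a
#' true metric (the triangle inequality can fail), but the standard
#' ecological dissimilarity for compositional microbiome comparisons.
#'
#' @param u,v Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return The dissimilarity, a scalar in `[0, 1]`.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (any(u < 0) || any(v < 0)) stop("abundances must be non-negative")
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("Bray-Curtis is undefined for two all-zero vectors")
  sum(abs(u - v)) / tot
}

#' Pairwise Bray-Curtis distance matrix on relative frequencies
#'
#' Counts are converted to within-sample relative frequencies first, so
#' distances are invariant to sequencing depth. Zero-total samples are
#' dropped (see [relative_frequencies()]).
#'
#' @param table A [feature_table()] with >= 2 samples.
#' @param method Dissimilarity index, passed to [vegan::vegdist()].
#' @param normalize Convert counts to relative frequencies first
#'   (default `TRUE`).
#' @return A symmetric matrix with zero diagonal and sample identifiers
#'   as dimnames.
#' @export
distance_matrix <- function(table, method = "bray", normalize = TRUE) {
  x <- as_feature_table(table)
  m <- if (normalize) relative_frequencies(x) else unclass(x)
  if (nrow(m) < 2) stop("need at least two (non-empty) samples")
  d <- as.matrix(vegan::vegdist(m, method = method))
  diag(d) <- 0
  d
}

#' Principal-coordinate analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and scales eigenvectors by
#' the square roots of the positive eigenvalues. Negative eigenvalues
#' (possible for non-Euclidean dissimilarities like Bray-Curtis) are
#' reported but excluded from the coordinates and from the
#' proportion-explained denominator.
#'
#' @param dm Symmetric distance matrix (or `dist`).
#' @param n_axes Number of axes to return (default all positive axes).
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, sorted decreasing), `proportion_explained`
#'   (over positive eigenvalues).
#' @export
pcoa <- function(dm, n_axes = NULL) {
  d <- as.matrix(dm)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(d)
  a <- -0.5 * d^2
  centered <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(centered, symmetric = TRUE)
  eigenvalues <- e$values
  pos <- which(eigenvalues > max(eigenvalues) * 1e-10 & eigenvalues > 0)
  if (is.null(n_axes)) {
    n_axes <- length(pos)
  } else if (n_axes > length(pos)) {
    warning("requested ", n_axes, " axes but only ", length(pos),
            " positive eigenvalues; truncating")
    n_axes <- length(pos)
  }
  axes <- pos[seq_len(n_axes)]
  coords <- e$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(eigenvalues[axes]), nrow = length(axes))
  dimnames(coords) <- list(rownames(d),
                           paste0("PC", seq_len(ncol(coords))))
  structure(list(
    coordinates = coords,
    eigenvalues = eigenvalues,
    proportion_explained = eigenvalues[pos] / sum(eigenvalues[pos])
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  pe <- utils::head(x$proportion_explained, 3)
  cat("proportion explained:",
      paste(sprintf("%.1f%%", 100 * pe), collapse = ", "), "...\n")
  invisible(x)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square approximation on `k - 1`
#' degrees of freedom (the standard large-sample test); optionally a
#' Monte-Carlo permutation p-value for small samples.
#'
#' @param groups List of >= 2 non-empty numeric vectors (total n >= 3).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations for the permutation p.
#' @param seed Seed for the permutation p (required for that method).
#' @return List with `statistic` (H), `p_value`, `df`, `method`.
#' @export
kruskal_wallis <- function(groups, method = c("chisq", "permutation"),
                           n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least two groups")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must be non-empty")
  if (sum(sizes) < 3) stop("need at least 3 observations in total")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), sizes))
  if (diff(range(values)) == 0) {
    # every observation tied: no rank variation, H is 0 by convention
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L,
                method = method))
  }
  kt <- stats::kruskal.test(values, labels)
  h <- unname(kt$statistic)
  p <- kt$p.value
  if (method == "permutation") {
    if (is.null(seed)) stop("permutation method requires a seed")
    h_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        unname(stats::kruskal.test(values, sample(labels))$statistic)
      }, numeric(1))
    })
    p <- (1 + sum(h_perm >= h - 1e-12)) / (n_perm + 1)
  }
  list(statistic = h, p_value = p, df = unname(kt$parameter),
       method = method)
}
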