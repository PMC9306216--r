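# Ecology and group-comparison statistics for the regional and dietary
# contrasts: alpha diversity, Bray-Curtis/PCoA, permutation AMOVA,
# rank-sum tests and differential enrichment.

#' Richness of an abundance vector
#'
#' Count of entities with strictly positive abundance (no rarefaction).
#'
#' @param x Non-negative numeric vector.
#' @return Integer richness; 0 for an all-zero vector.
#' @export
richness <- function(x) {
  if (any(x < 0)) stop("negative abundances", call. = FALSE)
  sum(x > 0)
}

#' Shannon index of an abundance vector
#'
#' \eqn{-\sum p_i \ln p_i} over the positive proportions (natural log, the
#' vegan default). An all-zero vector returns 0 by convention.
#'
#' @param x Non-negative numeric vector.
#' @return Shannon index.
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("negative abundances", call. = FALSE)
  if (sum(x) == 0) return(0)
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Bray-Curtis distance matrix between samples
#'
#' \eqn{d(i,j) = \sum|x_i - x_j| / \sum(x_i + x_j)} over entities, computed
#' with \code{vegan::vegdist}. A pair of all-zero samples has no defined
#' quotient; the distance is set to 0 by convention (identical emptiness).
#'
#' @param profiles Entity x sample abundance matrix (samples are columns).
#' @return Symmetric matrix of distances in [0, 1] with zero diagonal and
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(profiles) {
  m <- t(as.matrix(profiles))
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  d <- as.matrix(d)
  d[!is.finite(d)] <- 0  # all-zero sample pairs
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres \eqn{-d^2/2}, eigendecomposes, and scales coordinates by
#' the square root of the eigenvalues (\code{stats::cmdscale}). Negative
#' eigenvalues are dropped — no Lingoes/Cailliez correction — and their
#' total magnitude is reported; if fewer than \code{k} positive axes exist,
#' fewer are returned with a warning.
#'
#' @param d Distance matrix (matrix or \code{dist}).
#' @param k Number of axes requested (default 2).
#' @return List of class \code{vc_ordination}: \code{coordinates} (samples x
#'   axes), \code{eigenvalues} (positive, non-increasing),
#'   \code{proportion_explained}, \code{negative_eigenvalue_magnitude}.
#' @export
pcoa <- function(d, k = 2) {
  stopifnot(k >= 1)
  dm <- as.matrix(d)
  n <- nrow(dm)
  sc <- suppressWarnings(stats::cmdscale(dm, k = min(k, n - 1), eig = TRUE))
  eig <- sc$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)]
  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalue(s); returning ",
            min(length(pos), k), " axes")
  }
  if (length(pos) == 0L) {
    # fully degenerate configuration: all points coincide
    coords <- matrix(0, n, k,
                     dimnames = list(rownames(dm), paste0("PCo", seq_len(k))))
  } else {
    keep <- seq_len(min(k, length(pos)))
    coords <- sc$points[, keep, drop = FALSE]
    colnames(coords) <- paste0("PCo", keep)
  }
  structure(
    list(coordinates = coords,
         eigenvalues = pos,
         proportion_explained = pos / sum(pos),
         negative_eigenvalue_magnitude = sum(abs(eig[eig < 0]))),
    class = "vc_ordination")
}

# within-group sum of squared distances, each group normalised by its size
amova_ss_within <- function(d2, group_idx) {
  s <- 0
  for (idx in group_idx) {
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' Permutation AMOVA (analysis of molecular variance)
#'
#' The Excoffier squared-distance decomposition as popularised by mothur:
#' \eqn{SS_{total} = \sum_{i<j} d^2_{ij}/N}, \eqn{SS_{within}} sums the
#' per-group quantity with \eqn{n_g} in the denominator, and
#' \eqn{F_s = (SS_{among}/(k-1)) / (SS_{within}/(N-k))}. Significance is
#' assessed by permuting group labels, with the add-one estimator
#' \eqn{p = (1 + \#\{F_s^* \ge F_s\}) / (1 + B)}, so p has resolution
#' \eqn{1/(B+1)} and is never zero. The permutation stream is reproducible
#' for a fixed seed and invariant to group renaming.
#'
#' @param d Distance matrix (matrix or \code{dist}) with sample ids.
#' @param groups Group labels, either named by sample id or aligned with the
#'   matrix order. At least two groups with at least two samples each.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Optional integer seed for the permutation stream.
#' @return List of class \code{vc_amova}: \code{Fs}, \code{ss_among},
#'   \code{ss_within}, \code{ss_total}, \code{df_among}, \code{df_within},
#'   \code{p_value}, \code{n_permutations}, \code{seed}.
#' @export
amova <- function(d, groups, n_permutations = 1000, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), rownames(dm))) {
      stop("group labels do not match distance matrix sample ids",
           call. = FALSE)
    }
    groups <- groups[rownames(dm)]
  } else if (length(groups) != n) {
    stop("group labels do not match distance matrix sample ids",
         call. = FALSE)
  }
  groups <- as.factor(as.character(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 samples (offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")", call. = FALSE)
  }
  d2 <- dm^2
  k <- length(sizes)
  ss_total <- sum(d2) / (2 * n)
  idx <- split(seq_len(n), groups)
  ss_within <- amova_ss_within(d2, idx)
  ss_among <- ss_total - ss_within
  df_among <- k - 1
  df_within <- n - k
  fs <- (ss_among / df_among) / (ss_within / df_within)

  gsizes <- lengths(idx)
  perm_fs <- withr::with_seed(
    if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed, {
      vapply(seq_len(n_permutations), function(b) {
        perm <- sample.int(n)
        pidx <- split(perm, rep.int(seq_along(gsizes), gsizes))
        ssw <- amova_ss_within(d2, pidx)
        ((ss_total - ssw) / df_among) / (ssw / df_within)
      }, 0)
    })
  p <- (1 + sum(perm_fs >= fs - 1e-12)) / (1 + n_permutations)
  structure(
    list(Fs = fs, ss_among = ss_among, ss_within = ss_within,
         ss_total = ss_total, df_among = df_among, df_within = df_within,
         p_value = p, n_permutations = n_permutations, seed = seed),
    class = "vc_amova")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact two-sided p by enumeration of the rank-sum distribution when the
#' pooled size is at most 12 and there are no ties; otherwise the normal
#' approximation with midranks, tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return List of class \code{vc_ranktest}: \code{statistic} (Mann-Whitney
#'   W for \code{x}), \code{p_value}, \code{method} ("exact" or
#'   "normal-approximation"), \code{tie_corrected}.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 12
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  structure(
    list(statistic = unname(wt$statistic),
         p_value = min(1, unname(wt$p.value)),
         method = if (exact) "exact" else "normal-approximation",
         tie_corrected = !exact && ties),
    class = "vc_ranktest")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control via \code{stats::p.adjust}.
#'
#' @param pvalues Numeric vector of p values in [0, 1].
#' @return Adjusted p values (monotone, capped at 1).
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential enrichment between two groups
#'
#' Per entity (genome, vitamin, taxon...): Wilcoxon rank-sum p value and the
#' direction of enrichment, i.e. the group with the larger median (ties give
#' direction \code{"none"}). Entities with p below \code{alpha} are flagged;
#' BH-adjusted p values are reported alongside but the flag uses the raw p,
#' matching the conventional P < 0.05 screen.
#'
#' @param abundance Entity x sample matrix.
#' @param groups Two-level group labels, named by sample id or aligned with
#'   columns; each group needs at least 2 samples.
#' @param alpha Significance threshold on the raw p (default 0.05).
#' @return data.frame: \code{entity}, per-group medians, \code{p_value},
#'   \code{p_adjusted}, \code{direction}, \code{significant}; plus a
#'   \code{"summary"} attribute with counts of significant entities per
#'   direction.
#' @export
differential_enrichment <- function(abundance, groups, alpha = 0.05) {
  abundance <- as.matrix(abundance)
  if (!is.null(names(groups))) {
    groups <- groups[colnames(abundance)]
  }
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  i1 <- groups == g1; i2 <- groups == g2
  res <- lapply(seq_len(nrow(abundance)), function(i) {
    x <- abundance[i, i1]; y <- abundance[i, i2]
    p <- rank_sum_test(x, y)$p_value
    m1 <- median(x); m2 <- median(y)
    dir <- if (m1 > m2) g1 else if (m2 > m1) g2 else "none"
    c(m1 = m1, m2 = m2, p = p, dir = dir)
  })
  out <- data.frame(
    entity = if (is.null(rownames(abundance)))
      as.character(seq_len(nrow(abundance))) else rownames(abundance),
    stringsAsFactors = FALSE)
  out[[paste0("median_", g1)]] <- as.numeric(vapply(res, `[[`, "", "m1"))
  out[[paste0("median_", g2)]] <- as.numeric(vapply(res, `[[`, "", "m2"))
  out$p_value <- as.numeric(vapply(res, `[[`, "", "p"))
  out$p_adjusted <- bh_adjust(out$p_value)
  out$direction <- vapply(res, `[[`, "", "dir")
  out$significant <- out$p_value < alpha & out$direction != "none"
  counts <- table(factor(out$direction[out$significant], levels = c(g1, g2)))
  attr(out, "summary") <- as.list(counts)
  out
}
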