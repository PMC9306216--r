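# LEfSe-style linear discriminant analysis effect sizes for two-group
# feature contrasts (e.g. CAZy GH-family counts between diet groups).

# unit-norm first linear discriminant; falls back to the standardised
# mean-difference direction when the LDA fit degenerates (collinearity,
# zero within-class variance)
discriminant_direction <- function(x, grp) {
  w <- tryCatch({
    fit <- suppressWarnings(MASS::lda(x, grouping = grp))
    fit$scaling[, 1]
  }, error = function(e) {
    m1 <- colMeans(x[grp == levels(grp)[1], , drop = FALSE])
    m2 <- colMeans(x[grp == levels(grp)[2], , drop = FALSE])
    s <- apply(x, 2, stats::sd)
    (m1 - m2) / ifelse(s > 0, s, 1)
  })
  nrm <- sqrt(sum(w^2))
  if (!is.finite(nrm) || nrm == 0) rep(0, ncol(x)) else w / nrm
}

#' LEfSe-style LDA effect sizes
#'
#' For each feature of a two-group abundance table: a Wilcoxon rank-sum
#' screen p value, and an effect size on the log10 scale computed the LEfSe
#' way — samples are scaled so features sum to one million (abundances live
#' on a [1, 1e6]-style axis), a one-dimensional linear discriminant is
#' fitted on bootstrap subsamples (two-thirds of each group, \code{B}
#' rounds), and the per-feature effect is the average of half the sum of the
#' feature's raw between-class difference and its coefficient-weighted
#' projected difference, signed towards the enriched group:
#' \code{score = sign * log10(1 + |effect|)}. A feature is significant when
#' \code{|score| > threshold} and the screen p is below \code{alpha}.
#' Constant features get score 0 and are never significant.
#'
#' @param features Feature x sample abundance matrix.
#' @param groups Two-level labels (named by sample id or aligned with
#'   columns); each group needs at least 3 samples.
#' @param threshold Absolute score threshold (default 3).
#' @param alpha Screen significance level (default 0.05).
#' @param B Bootstrap rounds (default 30).
#' @param seed Optional integer seed for the bootstrap stream.
#' @return data.frame: \code{feature}, \code{score} (signed; positive =
#'   enriched in the first group level), \code{p_value}, \code{significant},
#'   \code{enriched_in}.
#' @export
lda_effect_size <- function(features, groups, threshold = 3, alpha = 0.05,
                            B = 30, seed = NULL) {
  features <- as.matrix(features)
  if (!is.null(names(groups))) groups <- groups[colnames(features)]
  grp <- as.factor(as.character(groups))
  if (nlevels(grp) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(grp) < 3)) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  # per-sample total-sum scaling to the LEfSe 1e6 axis
  totals <- colSums(features)
  scaled <- sweep(features, 2, ifelse(totals > 0, 1e6 / totals, 0), `*`)
  x <- t(scaled)  # samples x features

  pvals <- apply(features, 1, function(row) {
    if (length(unique(row)) == 1L) NA_real_
    else rank_sum_test(row[grp == levels(grp)[1]],
                       row[grp == levels(grp)[2]])$p_value
  })

  i1 <- which(grp == levels(grp)[1]); i2 <- which(grp == levels(grp)[2])
  n1 <- max(2L, ceiling(2 * length(i1) / 3))
  n2 <- max(2L, ceiling(2 * length(i2) / 3))
  eff <- withr::with_seed(
    if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed, {
      boots <- vapply(seq_len(B), function(b) {
        sub <- c(sample(i1, n1), sample(i2, n2))
        xs <- x[sub, , drop = FALSE]
        gs <- droplevels(grp[sub])
        w <- discriminant_direction(xs, gs)
        proj <- drop(xs %*% w)
        d_proj <- mean(proj[gs == levels(gs)[1]]) -
          mean(proj[gs == levels(gs)[2]])
        raw <- colMeans(xs[gs == levels(gs)[1], , drop = FALSE]) -
          colMeans(xs[gs == levels(gs)[2], , drop = FALSE])
        0.5 * (w * d_proj + raw)
      }, numeric(ncol(x)))
      rowMeans(matrix(boots, nrow = ncol(x)))
    })

  constant <- apply(features, 1, function(row) length(unique(row)) == 1L)
  score <- sign(eff) * log10(1 + abs(eff))
  score[constant] <- 0
  sig <- !constant & !is.na(pvals) & abs(score) > threshold & pvals < alpha
  data.frame(
    feature = if (is.null(rownames(features)))
      as.character(seq_len(nrow(features))) else rownames(features),
    score = score,
    p_value = pvals,
    significant = sig,
    enriched_in = ifelse(score > 0, levels(grp)[1],
                         ifelse(score < 0, levels(grp)[2], "none")),
    stringsAsFactors = FALSE, row.names = NULL)
}
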