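# ROC/AUC machinery, specificity thresholds, stratified bootstrap
# confidence intervals, frequency-class enrichment, call agreement and
# approach-disagreement clustering.

# AUC by the rank (Mann-Whitney) statistic with midpoint tie handling;
# exactly equals trapezoidal integration of the ROC curve
.auc_rank <- function(scores, labels) {
  y <- as.integer(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the ROC curve
#'
#' @param scores numeric scores; higher means more deleterious unless
#'   `higher_is_deleterious = FALSE`.
#' @param labels binary labels (1 = positive/deleterious).
#' @param higher_is_deleterious score orientation.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, higher_is_deleterious = TRUE) {
  if (!higher_is_deleterious) scores <- -scores
  .auc_rank(scores, labels)
}

#' ROC curve over all score thresholds
#'
#' A variant is called deleterious when its (oriented) score is `>=` the
#' threshold. Sensitivity is the proportion of positives called
#' deleterious, specificity the proportion of negatives called neutral.
#' AUC uses the midpoint convention for ties (rank-statistic form,
#' identical to trapezoidal integration).
#'
#' @inheritParams auc
#' @return An object of class `roc_curve` with `thresholds` (including
#'   `Inf`), `sensitivity`, `specificity`, `auc`, and class counts.
#' @export
roc_curve <- function(scores, labels, higher_is_deleterious = TRUE) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (anyNA(scores)) stop("missing scores are not allowed in roc_curve")
  s <- if (higher_is_deleterious) scores else -scores
  th <- c(Inf, sort(unique(s), decreasing = TRUE))
  sens <- vapply(th, function(t) mean(s[y == 1L] >= t), numeric(1L))
  spec <- vapply(th, function(t) mean(s[y == 0L] < t), numeric(1L))
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = .auc_rank(s, y), n_pos = sum(y == 1L),
                 n_neg = sum(y == 0L),
                 higher_is_deleterious = higher_is_deleterious,
                 oriented = !higher_is_deleterious),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve:", x$n_pos, "positives,", x$n_neg, "negatives; AUC =",
      format(x$auc, digits = 4), "\n")
  if (!is.null(x$ci))
    cat("  ", 100 * x$ci$level, "% CI: [", format(x$ci$low, digits = 4),
        ", ", format(x$ci$high, digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Calling threshold at a target specificity
#'
#' Returns the most permissive threshold (most variants called) whose
#' specificity is at least `target`, together with the sensitivity achieved
#' there. The all-neutral threshold (`Inf`) has specificity 1, so a
#' qualifying threshold always exists; `reached` flags whether any variant
#' is actually called at it.
#'
#' @param curve a [roc_curve()].
#' @param target required specificity (default 0.95).
#' @return List with `threshold` (on the oriented score scale),
#'   `sensitivity`, `specificity` and `reached`.
#' @export
threshold_at_specificity <- function(curve, target = 0.95) {
  ok <- curve$specificity >= target
  idx <- which(ok)
  best <- idx[which.max(curve$sensitivity[idx])]
  list(threshold = curve$thresholds[best],
       sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best],
       reached = is.finite(curve$thresholds[best]) ||
         curve$sensitivity[best] > 0)
}

#' Binary deleterious calls at a threshold
#'
#' @param scores numeric scores (same orientation convention as
#'   [roc_curve()]).
#' @param threshold calling threshold on the oriented scale.
#' @param higher_is_deleterious score orientation.
#' @return Integer vector of 0/1 calls (`NA` kept for missing scores).
#' @export
call_at_threshold <- function(scores, threshold,
                              higher_is_deleterious = TRUE) {
  s <- if (higher_is_deleterious) scores else -scores
  as.integer(s >= threshold)
}

# one stratified resample of indices, preserving class counts
.stratified_resample <- function(y) {
  pos <- which(y == 1L); neg <- which(y == 0L)
  c(pos[sample.int(length(pos), replace = TRUE)],
    neg[sample.int(length(neg), replace = TRUE)])
}

#' Stratified bootstrap confidence interval for an AUC
#'
#' Each replicate resamples positives and negatives separately with
#' replacement so every replicate has the original class counts; the
#' interval is the percentile interval of the replicate AUCs. Replicates
#' with an undefined AUC are redrawn and counted.
#'
#' @inheritParams auc
#' @param n_reps number of bootstrap replicates (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return List with `low`, `high`, `level`, `auc` (point estimate),
#'   `replicates`, and `n_redrawn`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_reps = 2000L, level = 0.95,
                             seed = 1L, higher_is_deleterious = TRUE) {
  y <- as.integer(labels)
  if (min(table(y)) < 2L) stop("both classes need >= 2 members")
  s <- if (higher_is_deleterious) scores else -scores
  reps <- numeric(n_reps)
  n_redrawn <- 0L
  .with_seed(seed, {
    for (b in seq_len(n_reps)) {
      repeat {
        idx <- .stratified_resample(y)
        a <- .auc_rank(s[idx], y[idx])
        if (!is.na(a)) break
        n_redrawn <- n_redrawn + 1L
      }
      reps[b] <- a
    }
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(low = qs[1L], high = qs[2L], level = level,
       auc = .auc_rank(s, y), replicates = reps, n_redrawn = n_redrawn)
}

#' Paired stratified bootstrap test of an AUC difference
#'
#' Resamples variants (stratified by class) jointly for both score sets,
#' giving a percentile interval for `AUC(a) - AUC(b)`; the difference is
#' reported significant when the interval excludes 0.
#'
#' @param scores_a,scores_b numeric score vectors over the same variants
#'   (already oriented so higher = deleterious).
#' @param labels binary labels.
#' @param n_reps bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return List with `delta_auc`, `low`, `high`, `significant`.
#' @export
auc_difference_test <- function(scores_a, scores_b, labels,
                                n_reps = 2000L, level = 0.95, seed = 1L) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must align")
  y <- as.integer(labels)
  deltas <- numeric(n_reps)
  .with_seed(seed, {
    for (b in seq_len(n_reps)) {
      idx <- .stratified_resample(y)
      deltas[b] <- .auc_rank(scores_a[idx], y[idx]) -
        .auc_rank(scores_b[idx], y[idx])
    }
  })
  qs <- stats::quantile(deltas, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(delta_auc = .auc_rank(scores_a, y) - .auc_rank(scores_b, y),
       low = qs[1L], high = qs[2L], level = level,
       significant = qs[1L] > 0 || qs[2L] < 0, replicates = deltas)
}

# frequency classes over minor allele counts (n = 80 chromosomes)
.mac_class <- function(mac) {
  if (any(mac < 1L)) stop("minor allele count of 0 is not a variant")
  cut(mac, breaks = c(0.5, 1.5, 2.5, 4.5, 8.5, Inf),
      labels = c("1", "2", "3-4", "5-8", ">8"))
}

#' Proportion of variants called deleterious per frequency class
#'
#' Classes are defined by minor allele count with the standard edges
#' `1`, `2`, `3-4`, `5-8`, `>8`. Missing calls are excluded from both the
#' numerator and the denominator.
#'
#' @param calls variants x approaches matrix of 0/1 calls (NA = missing).
#' @param minor_allele_counts integer vector of minor allele counts, one
#'   per variant (all `>= 1`).
#' @return Approaches x classes matrix of proportions (`NaN` where a class
#'   has no non-missing calls).
#' @export
proportion_deleterious_by_class <- function(calls, minor_allele_counts) {
  calls <- as.matrix(calls)
  if (length(minor_allele_counts) != nrow(calls))
    stop("one minor allele count per variant required")
  cls <- .mac_class(minor_allele_counts)
  out <- sapply(levels(cls), function(lv) {
    rows <- cls == lv
    colMeans(calls[rows, , drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = ncol(calls),
                                       dimnames = list(colnames(calls),
                                                       levels(cls)))
  out
}

#' Cumulative agreement of deleterious calls across approaches
#'
#' Over variants with a complete (non-missing) call from every approach,
#' counts how many are called deleterious by at least `k` approaches for
#' every `k`.
#'
#' @param calls variants x approaches matrix of 0/1 calls (NA = missing).
#' @return List with `n_called` / `prop_called` (named by `>=k`),
#'   `n_complete` and `n_excluded` (rows dropped for missing calls).
#' @export
call_agreement_summary <- function(calls) {
  calls <- as.matrix(calls)
  complete <- stats::complete.cases(calls)
  cc <- calls[complete, , drop = FALSE]
  k <- seq_len(ncol(cc))
  votes <- rowSums(cc)
  n_called <- vapply(k, function(kk) sum(votes >= kk), integer(1L))
  names(n_called) <- paste0(">=", k)
  list(n_called = n_called, prop_called = n_called / nrow(cc),
       n_complete = nrow(cc), n_excluded = sum(!complete))
}

#' Pairwise disagreement counts between approaches
#'
#' Entry `(i, j)` is the number of variants where approaches `i` and `j`
#' both made a call and the calls differ (pairwise-complete).
#'
#' @param calls variants x approaches matrix of 0/1 calls (NA = missing).
#' @return Symmetric matrix of disagreement counts with zero diagonal.
#' @export
disagreement_distance <- function(calls) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (m < 2L) stop("need at least 2 approaches")
  D <- matrix(0, m, m, dimnames = list(colnames(calls), colnames(calls)))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      both <- !is.na(calls[, i]) & !is.na(calls[, j])
      D[i, j] <- D[j, i] <- sum(calls[both, i] != calls[both, j])
    }
  }
  D
}

#' Hierarchical clustering of approaches with bootstrap support
#'
#' Approaches are clustered by average-linkage (UPGMA) agglomeration on
#' their pairwise disagreement distances. Support for each internal node is
#' the fraction of variant-resampled bootstrap trees containing the same
#' bipartition of approaches.
#'
#' @param calls variants x approaches matrix of 0/1 calls (NA = missing);
#'   at least 3 approaches.
#' @param n_boot bootstrap replicates (0 skips support values).
#' @param seed integer seed.
#' @param method linkage passed to [stats::hclust()].
#' @return List with the `hclust` object, an `ape::phylo` tree whose node
#'   labels are support fractions, and the observed distance matrix.
#' @export
cluster_approaches <- function(calls, n_boot = 2000L, seed = 1L,
                               method = "average") {
  calls <- as.matrix(calls)
  if (ncol(calls) < 3L)
    stop("need at least 3 approaches for clustering")
  D <- disagreement_distance(calls)
  hc <- stats::hclust(stats::as.dist(D), method = method)
  phy <- ape::as.phylo(hc)
  support <- NULL
  if (n_boot > 0L) {
    boot_trees <- vector("list", n_boot)
    .with_seed(seed, {
      for (b in seq_len(n_boot)) {
        rows <- sample.int(nrow(calls), replace = TRUE)
        Db <- disagreement_distance(calls[rows, , drop = FALSE])
        boot_trees[[b]] <- ape::as.phylo(
          stats::hclust(stats::as.dist(Db), method = method))
      }
    })
    class(boot_trees) <- "multiPhylo"
    counts <- ape::prop.clades(phy, boot_trees, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    support <- counts / n_boot
    phy$node.label <- format(round(support, 3))
  }
  list(hclust = hc, tree = phy, support = support, distance = D)
}
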