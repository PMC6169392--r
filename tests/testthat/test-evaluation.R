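test_that("AUC equals brute-force pair counting and handles boundaries", {
  # perfect separation and all-ties
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)

  set.seed(13)
  for (i in 1:50) {
    n_pos <- sample(3:8, 1)
    n_neg <- sample(3:9, 1)
    scores <- sample(seq(0, 1, by = 0.1), n_pos + n_neg, replace = TRUE)
    labels <- c(rep(1, n_pos), rep(0, n_neg))
    expect_equal(auc(scores, labels), brute_force_auc(scores, labels))
  }
})

test_that("roc_curve agrees with pROC and is monotone", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- c(rnorm(40, 1), rnorm(60))
  labels <- c(rep(1, 40), rep(0, 60))
  rc <- roc_curve(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(rc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  # tightening the threshold can only lower sensitivity / raise specificity
  expect_true(all(diff(rc$sensitivity) >= 0))   # thresholds stored high->low
  expect_true(all(diff(rc$specificity) <= 0))
  # orientation flag flips the curve coherently
  rc_flip <- roc_curve(-scores, labels, higher_is_deleterious = FALSE)
  expect_equal(rc_flip$auc, rc$auc, tolerance = 1e-12)
  expect_error(roc_curve(scores, rep(1, 100)), "both classes")
})

test_that("AUC is invariant to strictly increasing transforms", {
  set.seed(21)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  a0 <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), a0)
  expect_equal(auc(rank(scores), labels), a0)
})

test_that("threshold selection honours the specificity target", {
  # 10 negatives with distinct scores: 95% specificity needs all excluded
  scores <- c(0.95, 0.85, seq(0.1, 1.0, by = 0.1))
  labels <- c(1, 1, rep(0, 10))
  rc <- roc_curve(scores, labels)
  th <- threshold_at_specificity(rc, 0.95)
  expect_gte(th$specificity, 0.95)
  calls <- call_at_threshold(scores, th$threshold)
  expect_equal(sum(calls[labels == 0]), 0)   # no negative called

  # target 0: most permissive threshold calls everything
  th0 <- threshold_at_specificity(rc, 0)
  expect_equal(th0$sensitivity, 1)

  # monotone transform leaves the calls unchanged
  rc2 <- roc_curve(exp(scores), labels)
  th2 <- threshold_at_specificity(rc2, 0.95)
  expect_equal(call_at_threshold(exp(scores), th2$threshold), calls)
})

test_that("stratified bootstrap preserves class counts and nests the AUC", {
  scores <- c(rnorm(30, 2), rnorm(40))
  labels <- c(rep(1, 30), rep(0, 40))
  # class counts preserved in every replicate (assert on the resampler)
  y <- labels
  codonLRT:::.with_seed(5, {
    for (i in 1:50) {
      idx <- codonLRT:::.stratified_resample(y)
      expect_equal(sum(y[idx] == 1), 30)
      expect_equal(sum(y[idx] == 0), 40)
    }
  })
  ci <- bootstrap_auc_ci(scores, labels, n_reps = 200, seed = 3)
  expect_lte(ci$low, ci$auc)
  expect_gte(ci$high, ci$auc)
  # perfectly separated data pins the interval at 1
  sep <- bootstrap_auc_ci(c(2, 3, 4, -1, -2, -3), c(1, 1, 1, 0, 0, 0),
                          n_reps = 100, seed = 1)
  expect_equal(c(sep$low, sep$high), c(1, 1))
  # reproducible
  expect_identical(bootstrap_auc_ci(scores, labels, 100, seed = 9)$low,
                   bootstrap_auc_ci(scores, labels, 100, seed = 9)$low)
})

test_that("the paired AUC-difference test is antisymmetric and calibrated", {
  set.seed(31)
  labels <- c(rep(1, 200), rep(0, 200))
  a <- ifelse(labels == 1, 1, 0) + rnorm(400, sd = 0.2)  # near perfect
  b <- rnorm(400)                                        # uninformative
  d <- auc_difference_test(a, b, labels, n_reps = 300, seed = 2)
  expect_true(d$significant)
  expect_gt(d$low, 0)
  # identical scores: exactly zero difference
  d0 <- auc_difference_test(a, a, labels, n_reps = 100, seed = 2)
  expect_equal(d0$delta_auc, 0)
  expect_equal(c(d0$low, d0$high), c(0, 0))
  # antisymmetry
  d_ba <- auc_difference_test(b, a, labels, n_reps = 300, seed = 2)
  expect_equal(d_ba$delta_auc, -d$delta_auc)
  expect_error(auc_difference_test(a[-1], b, labels), "align")
})

test_that("frequency classes use the printed minor-allele-count edges", {
  mac <- c(1, 2, 3, 4, 5, 8, 9, 40)
  cls <- codonLRT:::.mac_class(mac)
  expect_equal(as.character(cls),
               c("1", "2", "3-4", "3-4", "5-8", "5-8", ">8", ">8"))
  expect_error(codonLRT:::.mac_class(0), "not a variant")

  calls <- cbind(a = c(1, 1, 0, 1, 0, 1, 0, 1),
                 b = c(1, NA, 1, 1, 1, 0, 0, 0))
  prop <- proportion_deleterious_by_class(calls, mac)
  expect_equal(dim(prop), c(2L, 5L))
  expect_equal(prop["a", "1"], 1)
  expect_equal(prop["a", "3-4"], 0.5)
  expect_equal(prop["b", "2"], NaN)        # only call was missing
  # all-deleterious calls give proportion 1 everywhere they are observed
  all1 <- matrix(1, 8, 2)
  expect_true(all(proportion_deleterious_by_class(all1, mac) == 1))
  # brute-force recount on a random toy matrix
  set.seed(17)
  toy <- matrix(rbinom(60, 1, 0.5), 20, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  toy[sample(60, 6)] <- NA
  mac20 <- sample(1:40, 20, replace = TRUE)
  p <- proportion_deleterious_by_class(toy, mac20)
  for (ap in colnames(toy)) for (lv in colnames(p)) {
    rows <- as.character(codonLRT:::.mac_class(mac20)) == lv
    expect_equal(p[ap, lv], mean(toy[rows, ap], na.rm = TRUE))
  }
})

test_that("call agreement and disagreement distances match hand tallies", {
  calls <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 1), c = c(1, 1, 1, 0))
  ag <- call_agreement_summary(calls)
  expect_equal(unname(ag$n_called), c(4L, 2L, 1L))
  expect_equal(ag$n_complete, 4L)

  # identical columns: all-or-none; complementary columns: >=1 but never >=2
  same <- cbind(a = c(1, 0, 1), b = c(1, 0, 1))
  ag_same <- call_agreement_summary(same)
  expect_equal(unname(ag_same$n_called), c(2L, 2L))
  comp <- cbind(a = rep(1, 100), b = rep(0, 100))
  ag_comp <- call_agreement_summary(comp)
  expect_equal(unname(ag_comp$prop_called), c(1, 0))
  expect_equal(disagreement_distance(comp)["a", "b"], 100)
  expect_equal(disagreement_distance(same)["a", "b"], 0)

  # random matrix vs brute-force double loop, with missing entries
  set.seed(29)
  M <- matrix(rbinom(120, 1, 0.5), 30, 4,
              dimnames = list(NULL, paste0("m", 1:4)))
  M[sample(120, 10)] <- NA
  D <- disagreement_distance(M)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:3) for (j in (i + 1):4) {
    d <- 0
    for (r in 1:30)
      if (!is.na(M[r, i]) && !is.na(M[r, j]) && M[r, i] != M[r, j])
        d <- d + 1
    expect_equal(D[i, j], d)
  }
  # rows with missing calls are excluded listwise from the summary
  expect_equal(call_agreement_summary(M)$n_complete +
                 call_agreement_summary(M)$n_excluded, 30L)
})

test_that("approach clustering recovers planted structure with high support", {
  set.seed(3)
  base <- rbinom(400, 1, 0.5)
  flip <- function(x, p) ifelse(runif(length(x)) < p, 1 - x, x)
  calls <- cbind(a1 = base, a2 = flip(base, 0.02),
                 b1 = 1 - base, b2 = flip(1 - base, 0.02))
  res <- cluster_approaches(calls, n_boot = 200, seed = 1)
  expect_s3_class(res$tree, "phylo")
  expect_true(all(res$support >= 0 & res$support <= 1))
  # the planted pairs are sister in the tree
  pairs <- ape::prop.part(res$tree)
  tip_sets <- lapply(pairs, function(p) sort(res$tree$tip.label[p]))
  expect_true(list(c("a1", "a2")) %in% tip_sets ||
                list(c("b1", "b2")) %in% tip_sets)
  expect_error(cluster_approaches(calls[, 1:2]), "at least 3")

  # two identical approaches cluster with support ~ 1
  calls3 <- cbind(x = base, y = base, z = 1 - base)
  res3 <- cluster_approaches(calls3, n_boot = 100, seed = 2)
  h <- res3$hclust
  first_pair <- sort(colnames(calls3)[-h$merge[1, ]])
  expect_equal(first_pair, c("x", "y"))
})
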