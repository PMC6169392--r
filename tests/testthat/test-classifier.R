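test_that("the default logistic models carry the published coefficients", {
  un <- logistic_model("unmasked")
  expect_equal(unname(coef(un)),
               c(-2.407, -0.2139, -0.2056, 0.07368, -0.1236))
  ma <- logistic_model("masked")
  expect_equal(unname(coef(ma)),
               c(-2.453, -0.1904, -0.1459, 0.2199, -0.2951))
  expect_error(logistic_model("custom"), "named coefficient")
})

test_that("features follow the masked/unmasked specifications", {
  site <- data.frame(p_value = 1e-16, constraint = 10, Rn = 30, An = 0,
                     masked = FALSE)
  expect_equal(unname(features_from_site(site, "unmasked")[1, ]),
               c(-16, 10, 30, 0))
  site2 <- data.frame(p_value = 1e-3, constraint = 0.2, Rn = 3, An = 5,
                      masked = TRUE)
  f2 <- features_from_site(site2, "masked")
  expect_equal(unname(f2[1, ]), c(-3, 0.2, 5, 2))
  site3 <- data.frame(p_value = 0.1, constraint = 1, Rn = 4, An = 4,
                      masked = TRUE)
  expect_equal(features_from_site(site3, "masked")[1, "absdiff_RnAn"],
               c(absdiff_RnAn = 0))
  expect_error(features_from_site(site, "masked"), "does not match")
})

test_that("predicted probabilities match independent evaluation of the
           printed formulas on a grid including the cap corners", {
  un <- logistic_model("unmasked")
  ma <- logistic_model("masked")
  grid <- expand.grid(lp = c(-16, -8, -1, 0), w = c(0, 0.5, 5, 10),
                      a = c(0, 3, 30), b = c(0, 5, 12))
  # independent arithmetic straight from the printed coefficient values
  eta_un <- -2.407 - 0.2139 * grid$lp - 0.2056 * grid$w +
    0.07368 * grid$a - 0.1236 * grid$b
  eta_ma <- -2.453 - 0.1904 * grid$lp - 0.1459 * grid$w +
    0.2199 * pmax(grid$a, grid$b) - 0.2951 * abs(grid$a - grid$b)
  X_un <- cbind(log10_p = grid$lp, constraint = grid$w, Rn = grid$a,
                An = grid$b)
  X_ma <- cbind(log10_p = grid$lp, constraint = grid$w,
                max_RnAn = pmax(grid$a, grid$b),
                absdiff_RnAn = abs(grid$a - grid$b))
  expect_equal(predict_probability(X_un, un), 1 / (1 + exp(-eta_un)),
               tolerance = 1e-12)
  expect_equal(predict_probability(X_ma, ma), 1 / (1 + exp(-eta_ma)),
               tolerance = 1e-12)
  # all-zero features give the inverse-logit of the intercept
  expect_equal(predict_probability(rep(0, 4), un), plogis(-2.407),
               tolerance = 1e-12)
})

test_that("probabilities are monotone in each feature with the printed sign", {
  un <- logistic_model("unmasked")
  base <- c(log10_p = -4, constraint = 2, Rn = 10, An = 2)
  p0 <- predict_probability(base, un)
  bump <- function(f) {
    x <- base; x[f] <- x[f] + 1
    predict_probability(x, un)
  }
  expect_lt(bump("log10_p"), p0)     # coefficient -0.2139
  expect_lt(bump("constraint"), p0)  # coefficient -0.2056
  expect_gt(bump("Rn"), p0)          # coefficient +0.07368
  expect_lt(bump("An"), p0)          # coefficient -0.1236
})

test_that("fit_logistic recovers generating coefficients and handles nulls", {
  set.seed(41)
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  eta <- 0.5 + 1 * X[, 1] - 2 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  mod <- fit_logistic(X, y)
  expect_false(isTRUE(mod$separation))
  expect_lt(abs(coef(mod)[["(Intercept)"]] - 0.5), 0.15)
  expect_lt(abs(coef(mod)[["x1"]] - 1), 0.15)
  expect_lt(abs(coef(mod)[["x2"]] + 2), 0.15)

  # labels independent of features: slopes near 0
  y0 <- rbinom(n, 1, 0.4)
  mod0 <- fit_logistic(X, y0)
  fit_glm <- glm(y0 ~ X, family = binomial())
  se <- sqrt(diag(vcov(fit_glm)))[2:3]
  expect_true(all(abs(coef(mod0)[c("x1", "x2")]) < 3 * se))

  # single-class input is a contract violation
  expect_error(fit_logistic(X[1:10, ], rep(1, 10)), "each class")

  # perfect separation falls back to ridge and is flagged
  Xs <- cbind(x1 = c(rep(-1, 20), rep(1, 20)))
  ys <- c(rep(0, 20), rep(1, 20))
  mods <- fit_logistic(Xs, ys)
  expect_true(mods$separation)
  expect_true(all(is.finite(coef(mods))))
})

test_that("cross-validation is stratified, seeded, and close to full fit", {
  # perfectly separable data
  sep <- simulate_score_table(60, 60, n_approaches = 1,
                              signal_strengths = 50, correlation = 0,
                              seed = 2)
  cv <- cross_validate(as.matrix(sep$scores), sep$labels, k = 10, seed = 1)
  expect_equal(cv$mean_auc, 1.0)

  # shuffled labels give chance-level AUC
  null <- simulate_score_table(1000, 1000, n_approaches = 2,
                               signal_strengths = 0, correlation = 0,
                               seed = 3)
  cv0 <- cross_validate(as.matrix(null$scores), null$labels, k = 10,
                        seed = 1)
  expect_gt(cv0$mean_auc, 0.45)
  expect_lt(cv0$mean_auc, 0.55)

  # reproducible given the seed
  cv_a <- cross_validate(as.matrix(null$scores), null$labels, seed = 7)
  cv_b <- cross_validate(as.matrix(null$scores), null$labels, seed = 7)
  expect_identical(cv_a, cv_b)
  expect_error(cross_validate(as.matrix(null$scores)[1:12, ],
                              c(rep(1, 9), 0, 0, 0), k = 10), "class")
})

test_that("gerp_codon_score matches genetic-code enumeration on all pairs", {
  scores <- c(1.3, -0.2, 2.9)
  # independent oracle: enumerate single-nucleotide neighbours directly
  oracle <- function(codon, alt_aa) {
    nt <- strsplit(codon, "")[[1]]
    qual <- logical(3)
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == nt[p]) next
      x <- nt; x[p] <- b
      if (isTRUE(GENETIC_CODE_UNIVERSAL[paste(x, collapse = "")] == alt_aa))
        qual[p] <- TRUE
    }
    if (any(qual)) mean(scores[qual]) else mean(scores[1:2])
  }
  for (codon in sense_codons()) {
    ref <- translate_codons(codon)
    for (alt in setdiff(AMINO_ACIDS, ref)) {
      expect_equal(gerp_codon_score(codon, alt, scores),
                   oracle(codon, alt))
    }
  }
  # canonical examples: ATG(M) -> I via position 3; ATG -> W needs 2 changes
  expect_equal(gerp_codon_score("ATG", "I", scores), scores[3])
  expect_equal(gerp_codon_score("ATG", "W", scores), mean(scores[1:2]))
  expect_equal(gerp_codon_score("ATG", "I", c(0, 0, 0)), 0)
  expect_error(gerp_codon_score("TAA", "M", scores), "sense codon")
})

test_that("the logistic ensemble combines scores sensibly", {
  tab <- simulate_score_table(300, 300, n_approaches = 7,
                              signal_strengths = c(2, 1.5, 1, 1, 0.8, 0.5,
                                                   0.3),
                              correlation = 0.4, seed = 5)
  single_auc <- vapply(tab$scores, function(s) auc(s, tab$labels), 1)
  ens <- ensemble_combine(tab$scores, tab$labels, seed = 1)
  expect_gte(ens$cv_auc, max(single_auc) - 0.02)
  expect_equal(ens$n_removed, 0L)

  # single column: combined AUC equals that column's AUC
  one <- ensemble_combine(tab$scores[1], tab$labels, seed = 1)
  expect_equal(one$full_auc, single_auc[[1]], tolerance = 1e-12)

  # rows with missing scores are removed, not imputed
  miss <- tab$scores
  miss[1:10, 2] <- NA
  ens_m <- ensemble_combine(miss, tab$labels, seed = 1)
  expect_equal(ens_m$n_removed, 10L)
  expect_true(all(is.na(ens_m$probabilities[1:10])))

  # duplicated identical columns preserve the predicted ranking
  dup <- cbind(tab$scores[1], dup = tab$scores[[1]])
  ens_d <- ensemble_combine(dup, tab$labels, seed = 1)
  expect_equal(order(ens_d$probabilities), order(one$probabilities))
})
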