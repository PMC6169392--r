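# Deleterious-probability scoring: the two published logistic models over
# LRT-derived features, refitting with stratified cross-validation, the
# per-codon GERP score combination rule, and the logistic ensemble
# combiner over external approach scores.

.printed_coefficients <- list(
  unmasked = c(`(Intercept)` = -2.407, log10_p = -0.2139,
               constraint = -0.2056, Rn = 0.07368, An = -0.1236),
  masked = c(`(Intercept)` = -2.453, log10_p = -0.1904,
             constraint = -0.1459, max_RnAn = 0.2199, absdiff_RnAn = -0.2951)
)

#' Logistic deleterious-probability model
#'
#' The default coefficient vectors are the published full-data fits for the
#' unmasked model
#' \deqn{logit(p) = -2.407 - 0.2139\,\log_{10}p_{LRT} - 0.2056\,\omega
#'   + 0.07368\,R_n - 0.1236\,A_n}
#' and the masked model
#' \deqn{logit(p) = -2.453 - 0.1904\,\log_{10}p_{LRT} - 0.1459\,\omega
#'   + 0.2199\,\max(R_n,A_n) - 0.2951\,|R_n - A_n|.}
#'
#' @param mode `"unmasked"`, `"masked"` or `"custom"`.
#' @param coefficients named coefficient vector (intercept first); required
#'   for `mode = "custom"`, ignored otherwise.
#' @return An object of class `logistic_model`.
#' @export
logistic_model <- function(mode = c("unmasked", "masked", "custom"),
                           coefficients = NULL) {
  mode <- match.arg(mode)
  if (mode == "custom") {
    if (is.null(coefficients) || is.null(names(coefficients)))
      stop("custom models need a named coefficient vector")
  } else {
    coefficients <- .printed_coefficients[[mode]]
  }
  structure(list(mode = mode, coefficients = coefficients,
                 features = names(coefficients)[-1L]),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model (", x$mode, "):\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.logistic_model <- function(object, ...) object$coefficients

#' Feature vectors from per-site LRT results
#'
#' Unmasked features are `(log10 p, constraint, Rn, An)`; the masked model
#' replaces `Rn` and `An` with `max(Rn, An)` and `|Rn - An|`. Caps are
#' assumed already applied, so `log10 p >= -16` and `constraint <= 10`.
#'
#' @param sites data frame with columns `p_value`, `constraint`, `Rn`, `An`
#'   and `masked` (e.g. from [run_gene()]).
#' @param mode `"unmasked"` or `"masked"`; must agree with the rows'
#'   `masked` flag when present.
#' @return Numeric feature matrix, one row per site.
#' @export
features_from_site <- function(sites, mode = c("unmasked", "masked")) {
  mode <- match.arg(mode)
  if (!is.null(sites$masked) &&
      any(sites$masked != (mode == "masked")))
    stop("mode '", mode, "' does not match the sites' masked flag")
  lp <- log10(sites$p_value)
  if (mode == "unmasked") {
    cbind(log10_p = lp, constraint = sites$constraint,
          Rn = sites$Rn, An = sites$An)
  } else {
    cbind(log10_p = lp, constraint = sites$constraint,
          max_RnAn = pmax(sites$Rn, sites$An),
          absdiff_RnAn = abs(sites$Rn - sites$An))
  }
}

#' Deleterious probability from a logistic model
#'
#' @param features numeric feature matrix (or vector for a single site)
#'   whose columns match the model's feature names.
#' @param model a [logistic_model()].
#' @return Probabilities in `(0, 1)`.
#' @export
predict_probability <- function(features, model) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL,
                                                                 names(features)))
  if (ncol(features) != length(model$features))
    stop("feature dimension mismatch: model expects ",
         length(model$features))
  if (!is.null(colnames(features)) &&
      !identical(colnames(features), model$features))
    features <- features[, model$features, drop = FALSE]
  eta <- drop(cbind(1, features) %*% model$coefficients)
  stats::plogis(eta)
}

# tiny-ridge IRLS, used when glm reports separation
.ridge_logistic <- function(X, y, lambda = 1e-6, tol = 1e-8,
                            max_iter = 200L) {
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(Xd))
  pen <- diag(lambda, ncol(Xd)); pen[1L, 1L] <- 0
  for (i in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(Xd, w * Xd) + pen, crossprod(Xd, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new); break
    }
    beta <- drop(beta_new)
  }
  stats::setNames(drop(beta), colnames(Xd))
}

#' Fit a logistic regression by maximum likelihood
#'
#' IRLS via [stats::glm.fit()] with convergence tolerance `1e-8`. Under
#' perfect separation the fit falls back to a tiny ridge penalty
#' (`1e-6`) and the result is flagged.
#'
#' @param features numeric matrix of predictors (no missing values).
#' @param labels binary vector (0/1 or logical), at least two examples of
#'   each class.
#' @return A [logistic_model()] with `mode = "custom"`, carrying a
#'   `separation` flag.
#' @export
fit_logistic <- function(features, labels) {
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need at least 2 examples of each class")
  if (anyNA(features)) stop("missing feature values are not allowed")
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  if (fit$deviance < 1e-6) sep <- TRUE     # training data fit perfectly
  if (sep || !fit$converged || anyNA(beta)) {
    sep <- TRUE
    beta <- .ridge_logistic(X, y)
  }
  mod <- logistic_model("custom", coefficients = beta)
  mod$separation <- sep
  mod
}

# stratified fold ids: seeded shuffle within each class, then round-robin
.stratified_folds <- function(labels, k, seed) {
  y <- as.integer(labels)
  folds <- integer(length(y))
  .with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validated AUC of a logistic model
#'
#' Folds are stratified by label (seeded shuffle within each class, then
#' round-robin assignment). The model is refit on each training split and
#' scored by AUC on the held-out fold.
#'
#' @param features numeric predictor matrix.
#' @param labels binary labels.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return List with `mean_auc` and the per-fold `fold_auc`.
#' @export
cross_validate <- function(features, labels, k = 10L, seed = 1L) {
  y <- as.integer(labels)
  if (length(y) < k) stop("n < k")
  if (min(table(y)) < k)
    stop("each class needs at least k members for stratified folding")
  X <- as.matrix(features)
  folds <- .stratified_folds(y, k, seed)
  aucs <- vapply(seq_len(k), function(f) {
    train <- folds != f
    mod <- fit_logistic(X[train, , drop = FALSE], y[train])
    p <- predict_probability(X[!train, , drop = FALSE], mod)
    auc(p, y[!train])
  }, numeric(1L))
  list(mean_auc = mean(aucs), fold_auc = aucs)
}

#' Per-codon conservation score from nucleotide-level GERP scores
#'
#' If the amino acid substitution can arise from a single nucleotide change
#' at one or more codon positions, the score is the mean of the scores at
#' the qualifying positions; otherwise it is the average of the scores at
#' the first and second codon positions.
#'
#' @param ref_codon reference sense codon (3 letters).
#' @param alt_aa alternate amino acid, different from the codon's.
#' @param pos_scores numeric length-3 vector of per-position scores.
#' @return A single combined score.
#' @export
gerp_codon_score <- function(ref_codon, alt_aa, pos_scores) {
  ref_codon <- toupper(ref_codon)
  ref_aa <- translate_codons(ref_codon)
  if (is.na(ref_aa) || ref_aa == "*")
    stop("ref_codon must be a sense codon, got '", ref_codon, "'")
  if (!alt_aa %in% AMINO_ACIDS || alt_aa == ref_aa)
    stop("alt_aa must be a standard amino acid different from the codon's")
  stopifnot(length(pos_scores) == 3L, is.numeric(pos_scores))
  nt <- strsplit(ref_codon, "")[[1L]]
  qualifying <- logical(3L)
  for (p in 1:3) {
    for (n in NUCLEOTIDES) {
      if (n == nt[p]) next
      alt <- nt; alt[p] <- n
      if (isTRUE(translate_codons(paste(alt, collapse = "")) == alt_aa))
        qualifying[p] <- TRUE
    }
  }
  if (any(qualifying)) mean(pos_scores[qualifying])
  else mean(pos_scores[1:2])
}

#' Logistic ensemble over external approach scores
#'
#' Rows with any missing approach score are removed before fitting. The
#' combiner is an unpenalised logistic regression on the raw scores and is
#' assessed by stratified 10-fold cross-validated AUC.
#'
#' @param scores data frame or matrix with one numeric column per approach
#'   (key columns `gene`, `codon_pos`, `ref_aa`, `alt_aa` are ignored if
#'   present).
#' @param labels binary labels, one per row of `scores`.
#' @param k folds for the cross-validated AUC.
#' @param seed integer seed.
#' @return List with the fitted `model`, `probabilities` (NA for removed
#'   rows), `cv_auc`, `full_auc`, the number of rows removed for
#'   missingness, and the approach columns used.
#' @export
ensemble_combine <- function(scores, labels, k = 10L, seed = 1L) {
  df <- as.data.frame(scores)
  key <- c("gene", "codon_pos", "ref_aa", "alt_aa")
  cols <- setdiff(names(df), key)
  num <- cols[vapply(df[cols], is.numeric, logical(1L))]
  if (length(num) < 1L) stop("no numeric approach columns")
  X <- as.matrix(df[num])
  y <- as.integer(labels)
  complete <- stats::complete.cases(X)
  if (min(table(y[complete])) < 2L)
    stop("fewer than 2 complete rows in one class")
  Xc <- X[complete, , drop = FALSE]
  yc <- y[complete]
  mod <- fit_logistic(Xc, yc)
  p <- rep(NA_real_, nrow(X))
  p[complete] <- predict_probability(Xc, mod)
  cv <- cross_validate(Xc, yc, k = k, seed = seed)
  list(model = mod, probabilities = p, cv_auc = cv$mean_auc,
       fold_auc = cv$fold_auc, full_auc = auc(p[complete], yc),
       n_removed = sum(!complete), approaches = num)
}
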