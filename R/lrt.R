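# Per-codon likelihood ratio test of selective constraint, in reference-
# masked and unmasked modes, with the capping rules and the alignment
# features (Rn, An) consumed by the logistic classifiers.

#' Mask the query sequence
#'
#' Replaces the entire query sequence with `N` (missing data), so that
#' likelihoods and allele counts no longer see the reference allele. This
#' removes reference bias: an unmasked query always contributes its own
#' allele as evidence of conservation. Idempotent.
#'
#' @param aln a [codon_alignment()].
#' @return The masked alignment.
#' @export
mask_query <- function(aln) {
  seqs <- .aln_sequences(aln)
  seqs[aln$query_id] <- strrep("N", nchar(seqs[aln$query_id]))
  codon_alignment(seqs, query_id = aln$query_id)
}

#' Cap a raw p-value and a site omega
#'
#' p-values below `1e-16` are set to `1e-16` and constraint (site dN/dS)
#' values above 10 are set to 10, so the downstream logistic features are
#' bounded.
#'
#' @param p_raw raw p-value(s) in `[0, 1]`.
#' @param omega_site site omega estimate(s), `>= 0`.
#' @return A list with capped `p_value` and `constraint`.
#' @export
apply_caps <- function(p_raw, omega_site) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE),
            all(omega_site >= 0, na.rm = TRUE))
  list(p_value = pmax(p_raw, 1e-16), constraint = pmin(omega_site, 10))
}

#' Count reference and alternate amino acids at a codon column
#'
#' `Rn` is the number of alignment sequences whose translated codon at the
#' column equals the query reference amino acid, `An` the number matching
#' the alternate (mutant) amino acid. Gap, missing and ambiguous codons are
#' excluded from all counts. In unmasked mode the query row itself is
#' counted; in masked mode it is excluded.
#'
#' @param aln a [codon_alignment()].
#' @param codon_pos alignment codon column (1-based).
#' @param ref_aa,alt_aa single-letter amino acids.
#' @param masked logical; exclude the query row from counting.
#' @return A list with `Rn`, `An`, `n_ungapped`.
#' @export
count_alleles <- function(aln, codon_pos, ref_aa, alt_aa, masked = FALSE) {
  stopifnot(ref_aa %in% AMINO_ACIDS, alt_aa %in% AMINO_ACIDS,
            codon_pos >= 1L, codon_pos <= aln$n_codons)
  rows <- if (masked) setdiff(aln$species, aln$query_id) else aln$species
  col <- aln$codons[rows, codon_pos]
  aa <- translate_codons(col)
  aa[aa == "*"] <- NA_character_
  list(Rn = sum(aa == ref_aa, na.rm = TRUE),
       An = sum(aa == alt_aa, na.rm = TRUE),
       n_ungapped = sum(!is.na(aa)))
}

#' Likelihood ratio test of constraint at one codon
#'
#' With branch lengths fixed at the gene fit's (capped) values, compares the
#' neutral model (omega = 1) against a model with a free site-specific
#' omega. The LRT statistic `2 (lnL_alt - lnL_null)` is floored at 0 and the
#' raw p-value comes from the chi-square distribution with 1 degree of
#' freedom, then capped via [apply_caps()].
#'
#' @param fit a [fit_gene()] result.
#' @param codon_pos alignment codon column (1-based).
#' @param masked logical; compute on the query-masked alignment.
#' @param omega_bounds search range for the site omega.
#' @return A one-row data frame with `lnL_null`, `lnL_alt`, `lrt_stat`,
#'   `p_value` (floored), `omega_site`, `constraint` (capped), `n_ungapped`,
#'   `masked` and a `degenerate` flag. Columns with 0 or 1 resolved
#'   sequences are flagged degenerate with `p_value = 1` rather than
#'   raising an error.
#' @export
lrt_site <- function(fit, codon_pos, masked = FALSE,
                     omega_bounds = c(1e-6, 50)) {
  stopifnot(inherits(fit, "gene_fit"),
            codon_pos >= 1L, codon_pos <= fit$n_codons)
  states <- fit$states[, codon_pos, drop = FALSE]
  if (masked) states[fit$query_id, ] <- NA_integer_
  tips <- fit$tree$tip.label
  n_ungapped <- sum(!is.na(states[tips, ]))
  if (n_ungapped <= 1L) {
    return(data.frame(codon_pos = codon_pos, masked = masked,
                      lnL_null = NA_real_, lnL_alt = NA_real_, lrt_stat = 0,
                      p_value = 1, omega_site = NA_real_,
                      constraint = NA_real_, n_ungapped = n_ungapped,
                      degenerate = TRUE))
  }
  ll_at <- function(w) {
    m <- codon_model(w, fit$pi_nt)
    sum(.pruning_loglik(states, fit$tree, m))
  }
  lnL_null <- ll_at(1)
  opt <- stats::optimize(function(lw) ll_at(exp(lw)),
                         lower = log(omega_bounds[1L]),
                         upper = log(omega_bounds[2L]),
                         maximum = TRUE, tol = 1e-8)
  omega_site <- exp(opt$maximum)
  lnL_alt <- opt$objective
  if (lnL_null > lnL_alt) {               # omega = 1 is nested in the range
    lnL_alt <- lnL_null
    omega_site <- 1
  }
  lrt_stat <- max(0, 2 * (lnL_alt - lnL_null))
  p_raw <- stats::pchisq(lrt_stat, df = 1L, lower.tail = FALSE)
  caps <- apply_caps(p_raw, omega_site)
  data.frame(codon_pos = codon_pos, masked = masked, lnL_null = lnL_null,
             lnL_alt = lnL_alt, lrt_stat = lrt_stat, p_value = caps$p_value,
             omega_site = omega_site, constraint = caps$constraint,
             n_ungapped = n_ungapped, degenerate = FALSE)
}

#' Run the per-codon LRT for all variants of a gene
#'
#' Filters ambiguous homologs, fits the gene once ([fit_gene()]) and reuses
#' the fit for every variant, producing one masked and one unmasked result
#' per variant (or the requested mode only). Variant codon positions are
#' 1-based indices on the query's ungapped CDS. `Rn`/`An` are attached per
#' mode via [count_alleles()]. A variant whose stated reference amino acid
#' disagrees with the query's translated codon is flagged (`ref_mismatch`),
#' not dropped; a variant whose position falls outside the alignment yields
#' a per-variant error record without affecting the others.
#'
#' @param aln a [codon_alignment()].
#' @param tree an `ape::phylo` topology over (a subset of) the alignment
#'   species.
#' @param variants data frame of variant records
#'   (see [read_variant_table()]).
#' @param mode `"both"`, `"masked"` or `"unmasked"`.
#' @param fit optionally, a precomputed [fit_gene()] result to reuse.
#' @param gene_id gene identifier stamped on the output rows.
#' @return A data frame with one row per variant x mode, carrying the LRT
#'   fields, `Rn`, `An`, `n_ungapped`, flags and any per-variant `error`.
#' @export
run_gene <- function(aln, tree, variants, mode = c("both", "masked",
                                                   "unmasked"),
                     fit = NULL, gene_id = NULL) {
  mode <- match.arg(mode)
  validate_variants(variants)
  if (is.null(gene_id)) gene_id <- unique(variants$gene)[1L]
  .check_tree_alignment(tree, aln)
  aln <- filter_ambiguous_sequences(aln)
  keep <- intersect(aln$species, tree$tip.label)
  tree <- ape::keep.tip(tree, keep)
  if (is.null(fit)) fit <- fit_gene(aln, tree)
  aln_masked <- mask_query(aln)
  modes <- switch(mode, both = c(FALSE, TRUE), masked = TRUE,
                  unmasked = FALSE)
  cols <- query_codon_column(aln, variants$codon_pos)
  q_aa <- translate_codons(aln$codons[aln$query_id, ])

  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    col <- cols[i]
    for (m in modes) {
      if (is.na(col)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene_id, codon_pos = v$codon_pos, ref_aa = v$ref_aa,
          alt_aa = v$alt_aa, masked = m, lnL_null = NA_real_,
          lnL_alt = NA_real_, lrt_stat = NA_real_, p_value = NA_real_,
          omega_site = NA_real_, constraint = NA_real_, Rn = NA_integer_,
          An = NA_integer_, n_ungapped = NA_integer_, degenerate = NA,
          ref_mismatch = NA,
          error = "codon_pos beyond the query CDS")
        next
      }
      res <- lrt_site(fit, col, masked = m)
      cnt <- count_alleles(if (m) aln_masked else aln, col, v$ref_aa,
                           v$alt_aa, masked = m)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene_id, codon_pos = v$codon_pos, ref_aa = v$ref_aa,
        alt_aa = v$alt_aa, masked = m, lnL_null = res$lnL_null,
        lnL_alt = res$lnL_alt, lrt_stat = res$lrt_stat,
        p_value = res$p_value, omega_site = res$omega_site,
        constraint = res$constraint, Rn = cnt$Rn, An = cnt$An,
        n_ungapped = res$n_ungapped, degenerate = res$degenerate,
        ref_mismatch = !is.na(q_aa[col]) && q_aa[col] != v$ref_aa,
        error = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site LRT predictions from a fitted gene
#'
#' `predict` method running [lrt_site()] for each variant and, when
#' requested, attaching deleterious probabilities from the printed logistic
#' models.
#'
#' @param object a [fit_gene()] result.
#' @param variants data frame of variants (codon positions are alignment
#'   columns resolved by the caller, or ungapped CDS positions when `aln`
#'   is supplied).
#' @param aln the alignment the gene was fitted to (needed for `Rn`/`An`
#'   and CDS-position mapping).
#' @param mode `"both"`, `"masked"` or `"unmasked"`.
#' @param type `"site"` for raw LRT fields, `"probability"` to add the
#'   deleterious probability of the matching printed model.
#' @param ... unused.
#' @return A data frame as in [run_gene()], plus `prob_deleterious` when
#'   `type = "probability"`.
#' @export
predict.gene_fit <- function(object, variants, aln,
                             mode = c("both", "masked", "unmasked"),
                             type = c("probability", "site"), ...) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  res <- run_gene(aln, object$tree, variants, mode = mode, fit = object)
  if (type == "probability") {
    res$prob_deleterious <- NA_real_
    for (m in unique(res$masked)) {
      sel <- which(res$masked == m & !res$degenerate & is.na(res$error))
      if (!length(sel)) next
      mod <- logistic_model(if (m) "masked" else "unmasked")
      X <- features_from_site(res[sel, ], mode = if (m) "masked" else
        "unmasked")
      res$prob_deleterious[sel] <- predict_probability(X, mod)
    }
  }
  res
}
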