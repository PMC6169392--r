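# Muse-Gaut (MG94 x F1x4) codon substitution model and the phylogenetic
# likelihood engine (Felsenstein pruning with per-site rescaling).
#
# Branch lengths are measured in expected synonymous substitutions per codon
# site (dS units): the generator is scaled so that the synonymous flux at
# stationarity equals one, which makes "total dS" the tree length.

#' Build an MG94-style codon substitution model
#'
#' Single-nucleotide codon changes occur at a rate proportional to the
#' frequency of the target nucleotide (F1x4), multiplied by `omega` when the
#' change is nonsynonymous. The generator is scaled so the expected
#' synonymous substitution rate at stationarity is 1, giving branch lengths
#' in dS units.
#'
#' @param omega nonsynonymous/synonymous rate ratio, `>= 0`.
#' @param pi_nt length-4 vector of nucleotide frequencies (A, C, G, T);
#'   must be strictly positive and sum to 1.
#' @return An object of class `codon_model` with the 61x61 generator `Q`,
#'   the codon stationary distribution `pi_codon`, and a spectral
#'   decomposition used for fast transition probabilities.
#' @export
codon_model <- function(omega, pi_nt = rep(0.25, 4)) {
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega < 0)
    stop("omega must be a single nonnegative number")
  if (length(pi_nt) != 4L || any(!is.finite(pi_nt)) || any(pi_nt <= 0))
    stop("pi_nt must be 4 strictly positive frequencies")
  if (abs(sum(pi_nt) - 1) > 1e-8)
    stop("pi_nt must sum to 1")
  pi_nt <- pi_nt / sum(pi_nt)
  cd <- .code()

  # F1x4 codon stationary distribution over the 61 sense codons
  nt_idx <- matrix(match(cd$codon_nt, NUCLEOTIDES), nrow = 61L)
  pi_codon <- pi_nt[nt_idx[, 1L]] * pi_nt[nt_idx[, 2L]] * pi_nt[nt_idx[, 3L]]
  pi_codon <- pi_codon / sum(pi_codon)

  p <- cd$pairs
  Q <- matrix(0, 61L, 61L)
  rate <- pi_nt[p$target] * ifelse(p$syn, 1, omega)
  Q[cbind(p$from, p$to)] <- rate
  diag(Q) <- -rowSums(Q)

  # dS scaling: expected synonymous flux at stationarity = 1
  syn_flux <- sum(pi_codon[p$from[p$syn]] * rate[p$syn])
  Q <- Q / syn_flux

  # spectral decomposition of the reversible generator
  d <- sqrt(pi_codon)
  B <- Q * outer(d, 1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(omega = omega, pi_nt = pi_nt, pi_codon = pi_codon, Q = Q,
                 eig_values = eig$values,
                 eig_V = eig$vectors / d,          # D^-1 V
                 eig_W = t(eig$vectors * d)),      # V' D
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat("MG94 x F1x4 codon model: omega =", format(x$omega),
      "; pi_nt =", paste(format(x$pi_nt, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Codon transition probability matrix
#'
#' @param model a [codon_model()].
#' @param t branch length in dS units, `>= 0`.
#' @return A 61x61 row-stochastic matrix `P(t) = exp(Qt)`.
#' @export
transition_probabilities <- function(model, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length t must be a single nonnegative number")
  P <- model$eig_V %*% (exp(model$eig_values * t) * model$eig_W)
  P[P < 0] <- 0
  P / rowSums(P)
}

# action of P(t) on a 61 x S matrix without forming P
.p_action <- function(model, t, M) {
  model$eig_V %*% (exp(model$eig_values * t) * (model$eig_W %*% M))
}

# action of t(P(t)) on a 61 x S matrix
.pt_action <- function(model, t, M) {
  t(model$eig_W) %*% (exp(model$eig_values * t) * (t(model$eig_V) %*% M))
}

# Codon state matrix (species x columns, 1..61, NA = gap/missing/ambiguous).
# Stop codons in the data are handled per `stop_action`: "error" names the
# offending species/site, "mask" sets them to missing with a warning.
.codon_state_matrix <- function(aln, stop_action = c("error", "mask")) {
  stop_action <- match.arg(stop_action)
  st <- matrix(.codon_state(aln$codons), nrow = nrow(aln$codons),
               dimnames = dimnames(aln$codons))
  is_stop <- matrix(translate_codons(aln$codons) == "*",
                    nrow = nrow(aln$codons))
  is_stop[is.na(is_stop)] <- FALSE
  if (any(is_stop)) {
    w <- which(is_stop, arr.ind = TRUE)
    desc <- paste0(aln$species[w[, 1L]], "@codon", w[, 2L], collapse = ", ")
    if (stop_action == "error")
      stop("stop codon(s) in alignment: ", desc)
    warning("stop codon(s) set to missing: ", desc)
  }
  st
}


# fast per-column maxima of a numeric matrix
.col_max <- function(M) {
  M[cbind(max.col(t(M), ties.method = "first"), seq_len(ncol(M)))]
}

# Pruning log-likelihood, vectorised over sites.
# states: n_species x S integer matrix with rownames covering tree tips.
# Returns a length-S vector of per-site log-likelihoods.
.pruning_loglik <- function(states, tree, model, edge_lengths = NULL) {
  tree <- stats::reorder(tree, "postorder")
  if (is.null(edge_lengths)) edge_lengths <- tree$edge.length
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- ncol(states)
  tipstate <- states[tree$tip.label, , drop = FALSE]

  part <- vector("list", ntip + nnode)
  logsc <- numeric(S)
  parents <- tree$edge[, 1L]
  children <- tree$edge[, 2L]

  node_part <- function(node) {
    es <- which(parents == node)
    M <- matrix(1, 61L, S)
    for (e in es) {
      ch <- children[e]
      if (ch <= ntip) {
        st <- tipstate[ch, ]
        tipM <- matrix(0, 61L, S)
        obs <- !is.na(st)
        tipM[cbind(st[obs], which(obs))] <- 1
        tipM[, !obs] <- 1
        contrib <- .p_action(model, edge_lengths[e], tipM)
      } else {
        contrib <- .p_action(model, edge_lengths[e], part[[ch]])
      }
      contrib[contrib < 0] <- 0
      M <- M * contrib
    }
    M
  }

  # postorder over internal nodes: unique() keeps first occurrence order,
  # which in a postorder edge list is child-before-parent
  for (node in unique(parents)) {
    M <- node_part(node)
    mx <- .col_max(M)
    zero <- mx == 0
    mx[zero] <- 1
    part[[node]] <- M / rep(mx, each = 61L)
    logsc <- logsc + log(mx)
    logsc[zero] <- -Inf
  }
  root <- ntip + 1L
  lik <- colSums(part[[root]] * model$pi_codon)
  log(lik) + logsc
}

#' Log-likelihood of a single codon column
#'
#' Felsenstein pruning under a [codon_model()] with the tree's branch
#' lengths. Gap, `N` and other unresolvable codons are treated as missing
#' data (partial likelihood of all ones). A column whose tree tips are all
#' missing has log-likelihood 0.
#'
#' @param aln a [codon_alignment()].
#' @param tree an `ape::phylo` with branch lengths in dS units; tips must be
#'   a subset of the alignment species.
#' @param model a [codon_model()].
#' @param codon_pos alignment codon column index (may be a vector).
#' @return Numeric vector of per-column log-likelihoods.
#' @export
site_log_likelihood <- function(aln, tree, model, codon_pos) {
  .check_tree_alignment(tree, aln)
  states <- .codon_state_matrix(aln, stop_action = "error")
  .pruning_loglik(states[, codon_pos, drop = FALSE], tree, model)
}

# up/down partials for fast per-branch optimisation.
# Returns per-edge A (61 x S conditional on the parent state, all data
# outside the child subtree, root prior folded in), the child's down
# partial, and a per-edge log-scale vector.
.updown <- function(states, tree, model, edge_lengths) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- ncol(states)
  tipstate <- states[tree$tip.label, , drop = FALSE]
  parents <- tree$edge[, 1L]
  children <- tree$edge[, 2L]
  nedge <- nrow(tree$edge)

  tip_mat <- function(i) {
    st <- tipstate[i, ]
    M <- matrix(0, 61L, S)
    obs <- !is.na(st)
    M[cbind(st[obs], which(obs))] <- 1
    M[, !obs] <- 1
    M
  }

  down <- vector("list", ntip + nnode)
  dscale <- vector("list", ntip + nnode)
  contrib <- vector("list", nedge)

  for (node in unique(parents)) {           # postorder
    es <- which(parents == node)
    M <- matrix(1, 61L, S)
    sc <- numeric(S)
    for (e in es) {
      ch <- children[e]
      if (ch <= ntip) {
        down[[ch]] <- tip_mat(ch)
        dscale[[ch]] <- numeric(S)
      }
      cb <- .p_action(model, edge_lengths[e], down[[ch]])
      cb[cb < 0] <- 0
      contrib[[e]] <- cb
      M <- M * cb
      sc <- sc + dscale[[ch]]
    }
    mx <- .col_max(M)
    mx[mx == 0] <- 1
    down[[node]] <- M / rep(mx, each = 61L)
    dscale[[node]] <- sc + log(pmax(mx, .Machine$double.xmin))
  }

  root <- ntip + 1L
  up <- vector("list", ntip + nnode)
  uscale <- vector("list", ntip + nnode)
  up[[root]] <- matrix(model$pi_codon, 61L, S)
  uscale[[root]] <- numeric(S)

  A <- vector("list", nedge)
  Ascale <- vector("list", nedge)
  for (e in rev(seq_len(nedge))) {          # preorder
    p <- parents[e]; ch <- children[e]
    sibs <- setdiff(which(parents == p), e)
    M <- up[[p]]
    sc <- uscale[[p]]
    for (s in sibs) {
      M <- M * contrib[[s]]
      sc <- sc + dscale[[children[s]]]
    }
    mx <- .col_max(M)
    mx[mx == 0] <- 1
    M <- M / rep(mx, each = 61L)
    sc <- sc + log(mx)
    A[[e]] <- M
    Ascale[[e]] <- sc
    if (ch > ntip) {
      U <- .pt_action(model, edge_lengths[e], M)
      U[U < 0] <- 0
      up[[ch]] <- U
      uscale[[ch]] <- sc
    }
  }
  list(A = A, Ascale = Ascale, down = down, dscale = dscale,
       parents = parents, children = children, ntip = ntip)
}


# action of Q P(t) on a 61 x S matrix (derivative of P(t) wrt t)
.qp_action <- function(model, t, M) {
  lam <- model$eig_values
  model$eig_V %*% ((lam * exp(lam * t)) * (model$eig_W %*% M))
}

# gradient of the total log-likelihood wrt every branch length, from a
# single up/down pass; per-site scale factors cancel in the ratio
.branch_gradient <- function(ud, model, edge_lengths) {
  nedge <- length(ud$A)
  g <- numeric(nedge)
  for (e in seq_len(nedge)) {
    ch <- ud$children[e]
    D <- ud$down[[ch]]
    lik <- colSums(ud$A[[e]] * .p_action(model, edge_lengths[e], D))
    dlik <- colSums(ud$A[[e]] * .qp_action(model, edge_lengths[e], D))
    g[e] <- sum(dlik / pmax(lik, .Machine$double.xmin))
  }
  g
}

# total log-likelihood of branch e as a function of its length, given
# precomputed up/down partials
.edge_loglik <- function(ud, model, e, t) {
  ch <- ud$children[e]
  lik <- colSums(ud$A[[e]] * .p_action(model, t, ud$down[[ch]]))
  sum(log(pmax(lik, .Machine$double.xmin)) + ud$Ascale[[e]] +
        ud$dscale[[ch]])
}

#' Fit per-gene branch lengths and a gene-wide omega
#'
#' Jointly maximises the likelihood of the whole-gene codon alignment over
#' all branch lengths (dS units) and a single gene-wide dN/dS ratio: a
#' bounded line search over omega seeds a joint bounded quasi-Newton ascent
#' on the log scale, using analytic branch-length gradients from the
#' pruning partials. After convergence every branch length is
#' capped at `cap_ds` (spuriously long branches indicate saturated
#' synonymous divergence) and the reported log-likelihood is re-evaluated at
#' the capped values.
#'
#' Nucleotide frequencies are estimated by counting (F1x4). Stop codons in
#' homolog sequences are set to missing with a warning.
#'
#' @param aln a [codon_alignment()], already passed through
#'   [filter_ambiguous_sequences()].
#' @param tree an `ape::phylo` topology whose tips are a subset of the
#'   alignment species; input branch lengths, if any, seed the search.
#' @param cap_ds cap applied to every estimated branch length (default 3).
#' @param omega_init starting value for the gene-wide omega.
#' @param maxit iteration cap for the quasi-Newton ascent.
#' @param restarts maximum number of additional random restarts if a start
#'   fails to converge.
#' @return An object of class `gene_fit`: the tree with estimated (capped)
#'   branch lengths, `omega`, `pi_nt`, `total_ds`, `logLik`, convergence
#'   diagnostics, and the codon state matrix reused by [lrt_site()].
#' @export
fit_gene <- function(aln, tree, cap_ds = 3, omega_init = 0.5,
                     maxit = 500L, restarts = 3L) {
  .check_tree_alignment(tree, aln)
  .counters$fit_gene <- .counters$fit_gene + 1L
  keep <- intersect(aln$species, tree$tip.label)
  if (length(keep) < 3L)
    stop("need at least 3 usable sequences shared between tree and alignment")
  states_full <- withCallingHandlers(
    .codon_state_matrix(aln, stop_action = "mask"),
    warning = function(w) invokeRestart("muffleWarning"))
  # re-emit a single warning if stops were masked
  n_stop <- sum(translate_codons(aln$codons) == "*", na.rm = TRUE)
  if (n_stop > 0L)
    warning(n_stop, " stop codon(s) in homologs set to missing")
  informative <- colSums(!is.na(states_full[tree$tip.label, , drop = FALSE])) >= 2L
  if (!any(informative))
    stop("no codon column with >= 2 resolved states; cannot fit gene")
  states <- states_full

  # F1x4 frequencies by nucleotide counting over unambiguous characters
  chars <- strsplit(paste0(aln$codons[tree$tip.label, ], collapse = ""), "")[[1L]]
  chars <- chars[chars %in% NUCLEOTIDES]
  cnt <- table(factor(chars, levels = NUCLEOTIDES))
  pi_nt <- as.numeric(cnt) + 1  # add-one smoothing guards zero frequencies
  pi_nt <- pi_nt / sum(pi_nt)

  tree <- stats::reorder(tree, "postorder")
  nedge <- nrow(tree$edge)
  init_bl <- tree$edge.length
  if (is.null(init_bl) || any(!is.finite(init_bl)) || all(init_bl == 0))
    init_bl <- rep(0.1, nedge)
  init_bl <- pmin(pmax(init_bl, 1e-3), 5)

  bl_lo <- 1e-8; bl_hi <- 50
  w_lo <- 1e-6; w_hi <- 50

  full_ll <- function(bl, omega) {
    m <- codon_model(omega, pi_nt)
    sum(.pruning_loglik(states, tree, m, edge_lengths = bl))
  }

  run_start <- function(bl, omega) {
    # warm-up omega pass, then joint quasi-Newton ascent over
    # (log branch lengths, log omega) with analytic branch gradients
    o <- stats::optimize(function(lw) full_ll(bl, exp(lw)),
                         lower = log(w_lo), upper = log(w_hi),
                         maximum = TRUE, tol = 1e-6)
    if (o$objective > full_ll(bl, omega)) omega <- exp(o$maximum)

    negll <- function(par) {
      -full_ll(exp(par[seq_len(nedge)]), exp(par[nedge + 1L]))
    }
    neggrad <- function(par) {
      blv <- exp(par[seq_len(nedge)])
      w <- exp(par[nedge + 1L])
      m <- codon_model(w, pi_nt)
      ud <- .updown(states, tree, m, blv)
      gb <- .branch_gradient(ud, m, blv) * blv      # chain rule to log scale
      h <- 1e-5
      gw <- (full_ll(blv, exp(par[nedge + 1L] + h)) -
               full_ll(blv, exp(par[nedge + 1L] - h))) / (2 * h)
      -c(gb, gw)
    }
    par0 <- c(log(bl), log(omega))
    opt <- stats::optim(par0, negll, neggrad, method = "L-BFGS-B",
                        lower = c(rep(log(bl_lo), nedge), log(w_lo)),
                        upper = c(rep(log(bl_hi), nedge), log(w_hi)),
                        control = list(maxit = maxit, factr = 1e7))
    list(bl = exp(opt$par[seq_len(nedge)]),
         omega = exp(opt$par[nedge + 1L]), logLik = -opt$value,
         converged = opt$convergence == 0L, iter = opt$counts[["function"]])
  }

  best <- run_start(init_bl, omega_init)
  tries <- 0L
  while (!best$converged && tries < restarts) {
    tries <- tries + 1L
    jbl <- init_bl * exp(stats::runif(nedge, -1, 1))
    cand <- run_start(pmin(pmax(jbl, bl_lo), bl_hi),
                      exp(stats::runif(1, log(0.05), log(2))))
    if (cand$logLik > best$logLik || cand$converged) best <- cand
  }

  bl <- pmin(best$bl, cap_ds)
  ll_capped <- full_ll(bl, best$omega)
  fitted_tree <- tree
  fitted_tree$edge.length <- bl
  structure(list(tree = fitted_tree, omega = best$omega, pi_nt = pi_nt,
                 total_ds = sum(bl), logLik = ll_capped,
                 logLik_uncapped = best$logLik, converged = best$converged,
                 iterations = best$iter, restarts = tries,
                 n_codons = ncol(states), states = states,
                 species = aln$species, query_id = aln$query_id),
            class = "gene_fit")
}

.counters <- new.env(parent = emptyenv())
.counters$fit_gene <- 0L

#' @export
print.gene_fit <- function(x, ...) {
  cat("gene_fit:", length(x$tree$tip.label), "taxa,", x$n_codons, "codons\n")
  cat("  omega =", format(x$omega, digits = 4),
      "; total dS =", format(x$total_ds, digits = 4),
      "; logLik =", format(x$logLik, digits = 8), "\n")
  cat("  converged:", x$converged, "(", x$iterations,
      "likelihood evaluations,", x$restarts, "restarts )\n")
  invisible(x)
}

#' @export
summary.gene_fit <- function(object, ...) {
  out <- list(omega = object$omega, total_ds = object$total_ds,
              logLik = object$logLik,
              branch_lengths = object$tree$edge.length,
              n_capped = sum(object$tree$edge.length >= 3 - 1e-12),
              pi_nt = object$pi_nt, converged = object$converged)
  class(out) <- "summary.gene_fit"
  out
}

#' @export
print.summary.gene_fit <- function(x, ...) {
  cat("Gene-wide dN/dS (omega):", format(x$omega, digits = 4), "\n")
  cat("Total dS (tree length):", format(x$total_ds, digits = 4),
      "over", length(x$branch_lengths), "branches (", x$n_capped,
      "at the cap )\n")
  cat("log-likelihood:", format(x$logLik, digits = 8), "\n")
  invisible(x)
}

#' @export
coef.gene_fit <- function(object, ...) {
  c(omega = object$omega,
    stats::setNames(object$tree$edge.length,
                    paste0("branch", seq_along(object$tree$edge.length))))
}

#' @export
logLik.gene_fit <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- length(object$tree$edge.length) + 1L
  class(val) <- "logLik"
  val
}
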