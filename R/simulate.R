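# Forward simulation of codon alignments on a phylogeny with site-specific
# omega, labelled benchmark variant sets, and synthetic approach score
# tables. This is the test harness for every other module: it emulates the
# statistical structure the LRT assumes (neutral sites with dN = dS vs
# constrained sites with dN = omega dS, omega << 1).

#' Default benchmark tree
#'
#' A pure-birth topology rescaled to a fixed tree length, emulating the
#' regime where per-gene alignments carry total dS in the tens of
#' synonymous substitutions per site — deep enough that neutral sites
#' accumulate plenty of synonymous change.
#'
#' @param n_tips number of species (default 12).
#' @param total_ds tree length in dS units (default 20).
#' @param seed integer seed for the random topology.
#' @return An `ape::phylo` with tips `sp1..spN`.
#' @export
default_benchmark_tree <- function(n_tips = 12L, total_ds = 20,
                                   seed = 1L) {
  tr <- .with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tr$tip.label <- paste0("sp", seq_len(n_tips))
  tr$edge.length <- tr$edge.length * total_ds / sum(tr$edge.length)
  tr
}

#' Simulation configuration
#'
#' @param tree `ape::phylo` with branch lengths in dS units (>= 3 tips).
#' @param n_codons number of codon sites.
#' @param omega_map per-site omega vector of length `n_codons`; default is
#'   an even mixture of constrained sites (omega drawn from
#'   `constrained_range`) and neutral sites (omega = 1).
#' @param pi_nt nucleotide frequencies (A, C, G, T).
#' @param seed integer seed; together with the config it fully determines
#'   all outputs.
#' @param query_id which tip is the query/reference (default: first tip).
#' @param gap_rate per-sequence, per-codon probability that a non-query
#'   codon is replaced by a gap, emulating sparse alignment columns.
#' @param constrained_frac fraction of sites constrained when `omega_map`
#'   is not given.
#' @param constrained_range omega range for constrained sites.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(tree, n_codons, omega_map = NULL,
                              pi_nt = rep(0.25, 4), seed = 1L,
                              query_id = tree$tip.label[1L],
                              gap_rate = 0.15, constrained_frac = 0.5,
                              constrained_range = c(0.01, 0.2)) {
  if (length(tree$tip.label) < 3L) stop("tree needs >= 3 tips")
  if (!query_id %in% tree$tip.label) stop("query_id must be a tree tip")
  if (is.null(omega_map)) {
    omega_map <- .with_seed(seed + 1L, {
      n_con <- round(constrained_frac * n_codons)
      w <- rep(1, n_codons)
      con_sites <- sample.int(n_codons, n_con)
      w[con_sites] <- stats::runif(n_con, constrained_range[1L],
                                   constrained_range[2L])
      w
    })
  }
  if (length(omega_map) != n_codons || any(omega_map < 0))
    stop("omega_map must be length n_codons with nonnegative entries")
  structure(list(tree = tree, n_codons = n_codons, omega_map = omega_map,
                 pi_nt = pi_nt, seed = seed, query_id = query_id,
                 gap_rate = gap_rate),
            class = "simulation_config")
}

#' Simulate a codon alignment on a phylogeny
#'
#' The root codon of each site is drawn from the model's stationary
#' distribution; evolution proceeds along each branch by the transition
#' probabilities of the site's omega-specific MG94 model, over the 61-state
#' sense-codon chain (stop codons cannot arise). Gaps are then injected
#' into non-query sequences at `gap_rate`.
#'
#' @param config a [simulation_config()].
#' @return A [codon_alignment()] with attributes `omega_map` (true per-site
#'   omega) and `config`.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- stats::reorder(config$tree, "postorder")
  S <- config$n_codons
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  groups <- split(seq_len(S), config$omega_map)
  states <- matrix(NA_integer_, ntip + nnode, S)
  root <- ntip + 1L

  .with_seed(config$seed, {
    for (g in names(groups)) {
      m <- codon_model(as.numeric(g), config$pi_nt)
      sites <- groups[[g]]
      states[root, sites] <- sample.int(61L, length(sites), replace = TRUE,
                                        prob = m$pi_codon)
      for (e in rev(seq_len(nrow(tree$edge)))) {       # preorder
        p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        P <- transition_probabilities(m, tree$edge.length[e])
        parent_states <- states[p, sites]
        for (ps in unique(parent_states)) {
          at <- sites[parent_states == ps]
          states[ch, at] <- sample.int(61L, length(at), replace = TRUE,
                                       prob = P[ps, ])
        }
      }
    }
    codons <- .code()$sense_codons
    seqs <- vapply(seq_len(ntip), function(i) {
      cs <- codons[states[i, ]]
      if (config$gap_rate > 0 && tree$tip.label[i] != config$query_id) {
        gap <- stats::runif(S) < config$gap_rate
        cs[gap] <- "---"
      }
      paste0(cs, collapse = "")
    }, character(1L))
  })
  names(seqs) <- tree$tip.label
  aln <- codon_alignment(seqs, query_id = config$query_id)
  attr(aln, "omega_map") <- config$omega_map
  attr(aln, "config") <- config
  aln
}

#' Simulate alignments from a fitted gene model
#'
#' @param object a [fit_gene()] result.
#' @param nsim number of alignments.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of [codon_alignment()]s evolved on the fitted tree under
#'   the fitted gene-wide omega.
#' @export
simulate.gene_fit <- function(object, nsim = 1L, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i) {
    cfg <- simulation_config(object$tree, object$n_codons,
                             omega_map = rep(object$omega, object$n_codons),
                             pi_nt = object$pi_nt, seed = seed + i - 1L,
                             query_id = object$query_id, gap_rate = 0)
    simulate_alignment(cfg)
  })
}

# minor allele count spectra on n chromosomes: neutral ~ 1/i, deleterious
# skewed toward singletons (~ 1/i^2)
.draw_mac <- function(n, n_chrom, deleterious) {
  i <- seq_len(n_chrom %/% 2L)
  w <- if (deleterious) 1 / i^2 else 1 / i
  sample(i, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate a labelled benchmark of deleterious and neutral variants
#'
#' Evolves one gene alignment on the (default) benchmark tree with a
#' site-specific omega map, then places "deleterious" variants at
#' constrained sites (low omega) and "neutral" variants at omega = 1 sites.
#' Alternate amino acids are drawn among single-nucleotide neighbours of
#' the query codon (any other amino acid as a flagged fallback). Minor
#' allele counts on `n_chrom` chromosomes follow a 1/i neutral spectrum,
#' skewed toward singletons for deleterious variants.
#'
#' @param n_deleterious,n_neutral numbers of variants of each class.
#' @param seed integer seed.
#' @param config optional [simulation_config()]; by default a 12-taxon
#'   pure-birth tree with total dS 20 and
#'   `n_codons = n_deleterious + n_neutral`.
#' @param n_chrom chromosomes in the notional SNP panel (default 80).
#' @return List with `alignment`, `tree`, `variants` (data frame with
#'   `gene`, `codon_pos` on the query CDS, `ref_aa`, `alt_aa`, `label`,
#'   `mac`, `site_omega`, `single_nt`), and `config`.
#' @export
simulate_benchmark <- function(n_deleterious, n_neutral, seed = 1L,
                               config = NULL, n_chrom = 80L) {
  stopifnot(n_deleterious >= 1L, n_neutral >= 1L)
  if (is.null(config)) {
    tree <- default_benchmark_tree(seed = seed)
    n_codons <- n_deleterious + n_neutral
    omega_map <- .with_seed(seed + 1L, {
      w <- rep(1, n_codons)
      con <- sample.int(n_codons, n_deleterious)
      w[con] <- stats::runif(n_deleterious, 0.01, 0.2)
      w
    })
    config <- simulation_config(tree, n_codons, omega_map = omega_map,
                                seed = seed)
  }
  aln <- simulate_alignment(config)
  w <- attr(aln, "omega_map")
  con_sites <- which(w < 1)
  neu_sites <- which(w == 1)
  if (length(con_sites) < n_deleterious || length(neu_sites) < n_neutral)
    stop("requested more variants than available sites of that class")

  # map alignment columns to query CDS positions (query has no gaps here)
  q_aa <- translate_codons(aln$codons[config$query_id, ])
  q_codon <- aln$codons[config$query_id, ]
  cd <- .code()

  pick_alt <- function(col) {
    st <- .codon_state(q_codon[col])
    if (is.na(st)) return(NULL)
    nb <- cd$pairs$to[cd$pairs$from == st & !cd$pairs$syn]
    cand <- unique(cd$codon_aa[nb])
    single <- TRUE
    if (!length(cand)) {
      cand <- setdiff(AMINO_ACIDS, cd$codon_aa[st])
      single <- FALSE
    }
    list(aa = cand, single = single)
  }

  vars <- .with_seed(seed + 2L, {
    place <- function(sites, n, label) {
      sites <- sites[!is.na(.codon_state(q_codon[sites]))]
      if (length(sites) < n)
        stop("requested more variants than available sites")
      chosen <- sample(sites, n)
      rows <- lapply(chosen, function(col) {
        alt <- pick_alt(col)
        data.frame(gene = "simgene", codon_pos = col,
                   ref_aa = q_aa[col],
                   alt_aa = sample(alt$aa, 1L), label = label,
                   site_omega = w[col], single_nt = alt$single)
      })
      do.call(rbind, rows)
    }
    v <- rbind(place(con_sites, n_deleterious, "positive"),
               place(neu_sites, n_neutral, "negative"))
    v$mac <- NA_integer_
    v$mac[v$label == "positive"] <-
      .draw_mac(sum(v$label == "positive"), n_chrom, TRUE)
    v$mac[v$label == "negative"] <-
      .draw_mac(sum(v$label == "negative"), n_chrom, FALSE)
    v
  })
  rownames(vars) <- NULL
  list(alignment = aln, tree = config$tree, variants = vars,
       config = config)
}

#' Simulate a table of correlated approach scores
#'
#' Each approach's score is `signal * latent + noise`, where the latent
#' signal is 1 for positives and 0 for negatives, and noise is shared
#' across approaches with weight `sqrt(correlation)`.
#'
#' @param n_pos,n_neg class sizes.
#' @param n_approaches number of score columns.
#' @param signal_strengths per-approach signal scale (recycled).
#' @param correlation noise correlation between approaches, in `[0, 1)`.
#' @param seed integer seed.
#' @return List with `scores` (data frame `approach1..K`) and `labels`
#'   (0/1).
#' @export
simulate_score_table <- function(n_pos, n_neg, n_approaches = 7L,
                                 signal_strengths = 2, correlation = 0.3,
                                 seed = 1L) {
  stopifnot(correlation >= 0, correlation < 1, n_pos >= 1L, n_neg >= 1L)
  signal_strengths <- rep_len(signal_strengths, n_approaches)
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  scores <- .with_seed(seed, {
    shared <- stats::rnorm(n)
    sapply(seq_len(n_approaches), function(a) {
      signal_strengths[a] * labels + sqrt(correlation) * shared +
        sqrt(1 - correlation) * stats::rnorm(n)
    })
  })
  colnames(scores) <- paste0("approach", seq_len(n_approaches))
  list(scores = as.data.frame(scores), labels = labels)
}
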