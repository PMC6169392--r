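# small fixtures built in code, shared across test files

toy_tree <- function() ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.3);")

toy_alignment <- function() {
  codon_alignment(c(A = "ATGAAACTT", B = "ATGAAGCTT", C = "ATAAACCTG"),
                  query_id = "A")
}

# brute-force site likelihood: enumerate all internal-node states, using
# only transition_probabilities() (independent of the pruning code path)
brute_force_site_ll <- function(aln, tree, model, codon_pos) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- codonLRT:::.codon_state_matrix(aln)[tree$tip.label, codon_pos]
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probabilities(model, tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:61), nnode)))
  p <- model$pi_codon[grid[, 1L]]          # column j is node ntip + j
  node_states <- function(node) {
    if (node <= ntip) rep(states[node], nrow(grid)) else grid[, node - ntip]
  }
  for (e in seq_len(nrow(tree$edge))) {
    ch_node <- tree$edge[e, 2L]
    if (ch_node <= ntip && is.na(states[ch_node])) next   # missing tip
    pa <- node_states(tree$edge[e, 1L])
    ch <- node_states(ch_node)
    p <- p * Ps[[e]][cbind(pa, ch)]
  }
  log(sum(p))
}

# AUC by explicit concordant/tied pair counting over all pos x neg pairs
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

small_gene_fit <- function() {
  tr <- default_benchmark_tree(n_tips = 8, total_ds = 10, seed = 3)
  cfg <- simulation_config(tr, 40, omega_map = c(rep(1, 20), rep(0.05, 20)),
                           seed = 17, gap_rate = 0.1)
  aln <- simulate_alignment(cfg)
  list(aln = aln, tree = tr, fit = fit_gene(aln, tr))
}
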