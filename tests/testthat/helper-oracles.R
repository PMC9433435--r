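# Independent brute-force oracles used by the property-style tests.
# These deliberately avoid the package's pruning/Fitch code paths.

# exhaustive minimum-change score over all internal labelings
oracle_parsimony_steps <- function(tree, tip_states, k) {
  td <- tidy_tree(tree)
  n_tip <- tree$n_tip
  internal <- which(!td$is_tip)
  st <- integer(nrow(td))
  st[seq_len(n_tip)] <- tip_states
  grid <- expand.grid(rep(list(seq_len(k)), length(internal)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st[internal] <- as.integer(grid[g, ])
    ch <- which(!is.na(td$parent))
    steps <- sum(st[td$parent[ch]] != st[ch])
    if (steps < best) best <- steps
  }
  best
}

# brute-force Mk likelihood: sum over all internal-state assignments
oracle_mk_likelihood <- function(tree, tip_states, Q, root_prior) {
  td <- tidy_tree(tree)
  n_tip <- tree$n_tip
  k <- nrow(Q)
  P <- lapply(seq_len(nrow(td)), function(i) {
    if (is.na(td$parent[i])) return(NULL)
    as.matrix(Matrix::expm(Q * td$branch_length[i]))  # independent of the eigen path
  })
  internal <- which(!td$is_tip)
  st <- integer(nrow(td))
  st[seq_len(n_tip)] <- tip_states
  grid <- expand.grid(rep(list(seq_len(k)), length(internal)))
  tot <- 0
  root <- tree$root
  for (g in seq_len(nrow(grid))) {
    st[internal] <- as.integer(grid[g, ])
    pr <- root_prior[st[root]]
    for (i in which(!is.na(td$parent))) {
      pr <- pr * P[[i]][st[td$parent[i]], st[i]]
    }
    tot <- tot + pr
  }
  tot
}

# random rooted tree (optionally with polytomies) as a dated_tree
random_test_tree <- function(n_tip, polytomy = FALSE) {
  phy <- ape::rtree(n_tip, rooted = TRUE)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.1, 2)
  if (polytomy && n_tip >= 4) {
    phy <- ape::di2multi(phy, tol = stats::quantile(phy$edge.length, 0.3))
    phy$edge.length <- pmax(phy$edge.length, 0.05)
  }
  parse_tree(phy)
}

# brute-force codon likelihood on a rooted 3-taxon tree ((A,B),C) by
# explicit matrix exponentials and state sums
oracle_codon_loglik_3tax <- function(kappa, omega, pi, t_ab, t_in, t_c,
                                     states_abc, code) {
  m <- gy94_rate_matrix(kappa, omega, pi, code)
  P <- function(t) as.matrix(Matrix::expm(m$Q * t / m$rate))
  Pa <- P(t_ab); Pin <- P(t_in); Pc <- P(t_c)
  sum(vapply(seq_len(ncol(states_abc)), function(s) {
    inner <- Pa[, states_abc[1, s]] * Pa[, states_abc[2, s]]
    log(sum(pi * as.vector(Pin %*% inner) * Pc[, states_abc[3, s]]))
  }, 0))
}

# minimal codon_asr-like object from simulation truth (ancestral sequences
# known exactly), for physchem calibration without refitting
asr_from_truth <- function(tree, truth, gene = "g", code = genetic_code(5)) {
  structure(list(node_codons = truth$node_codons, tree = tree, gene = gene,
                 code = code,
                 posterior = NULL, anc_mask = rep(FALSE, ncol(truth$node_codons))),
            class = "codon_asr")
}
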