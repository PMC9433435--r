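#' Synthetic data generators
#'
#' Birth-death trees, Mk discrete traits and Gillespie GY94 codon
#' evolution with recorded truth (true internal states and per-branch
#' substitution events), so that every pipeline stage can be exercised and
#' calibrated without external sequence data. All generators are
#' deterministic under a fixed seed.
#'
#' @name synthetic_data
NULL

#' Simulate an ultrametric birth-death tree
#'
#' Conditioned on the number of tips via [ape::rphylo()], then rescaled so
#' the root age equals `root_age` (Ma).
#'
#' @param n_tips Number of terminal taxa.
#' @param lambda,mu Birth and death rates (lambda > mu >= 0).
#' @param root_age Root age in Ma.
#' @param seed Integer seed.
#' @return A `dated_tree` with tip labels `t1..tn`.
#' @export
simulate_bd_tree <- function(n_tips, lambda = 1, mu = 0, root_age = 400,
                             seed = 1) {
  stopifnot(lambda > mu, mu >= 0, n_tips >= 2)
  set.seed(seed)
  phy <- ape::rphylo(n_tips, lambda, mu)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * root_age / depth
  parse_tree(phy, require_ultrametric = TRUE, tol = 1e-6)
}

#' Simulate a discrete trait under an Mk process
#'
#' Exponential waiting times and jumps per the rate matrix along every
#' branch (Gillespie), recording the true node states and the per-branch
#' event counts.
#'
#' @param tree A `dated_tree`.
#' @param Q k x k rate matrix (rows sum to 0), or a single rate for Mk1.
#' @param root_state State name at the root.
#' @param states State names (length k).
#' @param seed Integer seed.
#' @return List: `traits` (a `trait_table` over the tips), `node_states`
#'   (character over all nodes), `events` (tibble `node`, `n_events` per
#'   branch), `Q`, `seed`.
#' @export
simulate_mk_trait <- function(tree, Q, root_state, states, seed = 1) {
  k <- length(states)
  if (length(Q) == 1) Q <- mk_rate_matrix(Q, k, "mk1")
  stopifnot(nrow(Q) == k, max(abs(rowSums(Q))) < 1e-8)
  set.seed(seed)
  n_all <- tree$n_tip + tree$n_node
  st <- integer(n_all)
  st[tree$root] <- match(root_state, states)
  if (is.na(st[tree$root])) stop("root_state not in states")
  po <- tree_postorder_edges(tree)
  ev <- integer(n_all)
  # preorder over edges: parents before children
  ord <- rev(seq_len(nrow(po$edge)))
  for (e in ord) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    i <- st[par]
    t_left <- po$length[e]
    n_ev <- 0L
    repeat {
      r <- -Q[i, i]
      if (r <= 0) break
      w <- rexp(1, r)
      if (w > t_left) break
      t_left <- t_left - w
      p <- Q[i, ]; p[i] <- 0
      i <- sample.int(k, 1, prob = p)
      n_ev <- n_ev + 1L
    }
    st[ch] <- i
    ev[ch] <- n_ev
  }
  traits <- trait_table(tree$phylo$tip.label, states[st[seq_len(tree$n_tip)]],
                        states = states)
  list(traits = traits, node_states = states[st],
       events = tibble(node = seq_len(n_all), n_events = ev),
       Q = Q, states = states, seed = seed)
}

# per-codon leave-rate components and neighbour lists for Gillespie moves
gy94_sim_structure <- function(pi, code) {
  ty <- code$pair_type
  n <- length(code$sense)
  A <- B <- C <- D <- numeric(n)  # syn_tv, syn_ts, nonsyn_tv, nonsyn_ts
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    j <- which(ty[i, ] != 0L)
    t <- ty[i, j]
    A[i] <- sum(pi[j[t == 2L]])
    B[i] <- sum(pi[j[t == 1L]])
    C[i] <- sum(pi[j[t == 4L]])
    D[i] <- sum(pi[j[t == 3L]])
    nb[[i]] <- list(j = j, ts = t %in% c(1L, 3L), ns = t %in% c(3L, 4L),
                    pij = pi[j])
  }
  list(A = A, B = B, C = C, D = D, nb = nb)
}

#' Simulate a codon alignment under GY94 (Gillespie)
#'
#' Event-level simulation along every branch from a root sequence drawn
#' from the target codon frequencies, so true per-branch synonymous and
#' nonsynonymous event counts exist for oracle comparisons. Branch
#' durations are in Ma; `rate` sets the expected substitutions per codon
#' per Ma at the baseline omega, per-branch multipliers raise the
#' nonsynonymous rate on designated branches, and `site_omegas` allows an
#' M1a/M2a-style site mixture.
#'
#' @param tree A `dated_tree`.
#' @param n_codons Alignment length L (codons).
#' @param kappa Transition/transversion ratio.
#' @param omega Baseline nonsynonymous/synonymous ratio.
#' @param rate Expected substitutions per codon per Ma at the baseline
#'   omega.
#' @param pi Codon frequencies over sense codons (default uniform).
#' @param branch_multiplier Named numeric vector (names = child node ids)
#'   multiplying omega on those branches; unnamed branches use 1.
#' @param site_omegas Optional length-L vector of per-site omega values
#'   (overrides `omega` per site; the baseline `omega` still sets the rate
#'   normalisation).
#' @param seed Integer seed.
#' @param gene Gene name.
#' @param code A [genetic_code()].
#' @return List: `aln` (a `codon_alignment` over the tips), `truth` (list
#'   with `node_codons`, `branch_events` tibble of per-branch `syn`,
#'   `nonsyn` counts, `site_omegas`), `params`.
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 4, omega = 0.2,
                                     rate = 0.001, pi = NULL,
                                     branch_multiplier = NULL,
                                     site_omegas = NULL, seed = 1,
                                     gene = "gene1", code = genetic_code(5)) {
  n <- length(code$sense)
  if (is.null(pi)) pi <- rep(1 / n, n)
  stopifnot(abs(sum(pi) - 1) < 1e-8)
  if (is.null(site_omegas)) site_omegas <- rep(omega, n_codons)
  stopifnot(length(site_omegas) == n_codons)
  set.seed(seed)
  sim <- gy94_sim_structure(pi, code)
  norm <- gy94_rate_matrix(kappa, omega, pi, code)$rate
  n_all <- tree$n_tip + tree$n_node
  seqs <- matrix(0L, n_all, n_codons)
  seqs[tree$root, ] <- sample.int(n, n_codons, replace = TRUE, prob = pi)
  po <- tree_postorder_edges(tree)
  syn_ev <- nonsyn_ev <- numeric(n_all)
  mult <- rep(1, n_all)
  if (!is.null(branch_multiplier)) {
    idx <- as.integer(names(branch_multiplier))
    if (anyNA(idx)) stop("branch_multiplier must be named by child node id")
    if (any(idx < 1 | idx > n_all)) stop("invalid omega map key(s)")
    mult[idx] <- branch_multiplier
  }
  for (e in rev(seq_len(nrow(po$edge)))) {  # preorder
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    Tb <- po$length[e] * rate / norm
    cur <- seqs[par, ]
    om <- site_omegas * mult[ch]
    Rtot <- sim$A[cur] + kappa * sim$B[cur] + om * (sim$C[cur] + kappa * sim$D[cur])
    t1 <- rexp(n_codons, pmax(Rtot, 1e-300))
    active <- which(t1 <= Tb & Rtot > 0)
    for (s in active) {
      i <- cur[s]
      t <- t1[s]
      repeat {
        nbi <- sim$nb[[i]]
        w <- nbi$pij * ifelse(nbi$ts, kappa, 1) * ifelse(nbi$ns, om[s], 1)
        pick <- sample.int(length(nbi$j), 1, prob = w)
        if (nbi$ns[pick]) nonsyn_ev[ch] <- nonsyn_ev[ch] + 1
        else syn_ev[ch] <- syn_ev[ch] + 1
        i <- nbi$j[pick]
        Ri <- sim$A[i] + kappa * sim$B[i] + om[s] * (sim$C[i] + kappa * sim$D[i])
        if (Ri <= 0) break
        t <- t + rexp(1, Ri)
        if (t > Tb) break
      }
      cur[s] <- i
    }
    seqs[ch, ] <- cur
  }
  tip_seqs <- vapply(seq_len(tree$n_tip), function(i) {
    paste(code$sense[seqs[i, ]], collapse = "")
  }, "")
  names(tip_seqs) <- tree$phylo$tip.label
  aln <- codon_alignment(tip_seqs, code = code, gene = gene)
  node_codons <- matrix(code$sense[seqs], n_all, n_codons)
  list(aln = aln,
       truth = list(node_codons = node_codons,
                    branch_events = tibble(node = seq_len(n_all),
                                           syn = syn_ev, nonsyn = nonsyn_ev)[-tree$root, ],
                    site_omegas = site_omegas),
       params = list(kappa = kappa, omega = omega, rate = rate, pi = pi,
                     branch_multiplier = branch_multiplier, seed = seed,
                     gene = gene))
}

#' Build a full shift scenario bundle
#'
#' Designates derived-state clades on a (simulated or supplied) tree,
#' multiplies omega on the branches of those clades by `omega_multiplier`
#' (1.0 = null scenario), and simulates trait table plus per-gene codon
#' alignments. The bundle carries the full truth needed for power and
#' type-I studies of [shift_vs_sister()].
#'
#' @param n_tips,root_age,lambda,mu Tree settings (ignored when `tree`
#'   given).
#' @param tree Optional `dated_tree`.
#' @param n_shifts Number of derived clades.
#' @param max_clade_size Largest clade (in tips) eligible for a shift.
#' @param omega_multiplier Omega multiplier on shift branches.
#' @param n_genes,n_codons,kappa,omega,rate Codon simulation settings.
#' @param ancestral_state,derived_states State names.
#' @param seed Integer seed.
#' @return List of class `shift_scenario`: `tree`, `traits`, `alignments`,
#'   `truth` (per gene), `shift_origins` (node ids), `shift_branches`,
#'   `params`.
#' @export
make_shift_scenario <- function(n_tips = 16, root_age = 400, lambda = 1,
                                mu = 0, tree = NULL, n_shifts = 3,
                                max_clade_size = 3, omega_multiplier = 1,
                                n_genes = 3, n_codons = 200, kappa = 4,
                                omega = 0.2, rate = 0.001,
                                ancestral_state = "hemiedaphic",
                                derived_states = c("epiedaphic", "euedaphic",
                                                   "aquatic", "myrmecophilous"),
                                seed = 1) {
  if (is.null(tree)) tree <- simulate_bd_tree(n_tips, lambda, mu, root_age, seed)
  set.seed(seed + 1000L)
  td <- tidy_tree(tree)
  n_all <- tree$n_tip + tree$n_node
  clade_size <- vapply(seq_len(n_all), function(v) length(node_tips(tree, v)), 0L)
  candidates <- setdiff(which(clade_size <= max_clade_size), tree$root)
  # exclude children of the root so every shift has a sister side
  candidates <- candidates[td$parent[candidates] != tree$root]
  chosen <- integer(0)
  for (attempt in seq_len(20)) {  # greedy placement, re-shuffled on failure
    cand <- candidates[sample.int(length(candidates))]
    chosen <- integer(0)
    blocked <- integer(0)
    for (v in cand) {
      if (length(chosen) == n_shifts) break
      sub <- c(v, node_descendants(tree, v))
      anc <- v
      p <- td$parent[v]
      while (!is.na(p)) { anc <- c(anc, p); p <- td$parent[p] }
      # divergence nodes of chosen events must stay in the ancestral state
      if (length(intersect(c(sub, anc, td$parent[v]), blocked))) next
      chosen <- c(chosen, v)
      blocked <- union(blocked, c(sub, td$parent[v]))
    }
    if (length(chosen) == n_shifts) break
  }
  if (length(chosen) < n_shifts) {
    stop("could not place ", n_shifts, " disjoint shift clades; tree too small")
  }
  state <- rep(ancestral_state, tree$n_tip)
  mult <- numeric(0)
  shift_branches <- integer(0)
  for (i in seq_along(chosen)) {
    v <- chosen[i]
    tips <- node_tips(tree, v)
    state[tips] <- derived_states[(i - 1) %% length(derived_states) + 1]
    br <- c(v, node_descendants(tree, v))
    shift_branches <- union(shift_branches, br)
  }
  mult <- setNames(rep(omega_multiplier, length(shift_branches)),
                   shift_branches)
  traits <- trait_table(tree$phylo$tip.label, state,
                        states = unique(c(ancestral_state, derived_states)))
  sims <- lapply(seq_len(n_genes), function(g) {
    simulate_codon_alignment(tree, n_codons, kappa = kappa, omega = omega,
                             rate = rate, branch_multiplier = mult,
                             seed = seed + 7L * g, gene = paste0("gene", g))
  })
  structure(
    list(tree = tree, traits = traits,
         alignments = lapply(sims, `[[`, "aln"),
         truth = lapply(sims, `[[`, "truth"),
         shift_origins = chosen, shift_branches = sort(shift_branches),
         params = list(n_tips = n_tips, root_age = root_age,
                       omega_multiplier = omega_multiplier, n_genes = n_genes,
                       n_codons = n_codons, kappa = kappa, omega = omega,
                       rate = rate, seed = seed)),
    class = "shift_scenario")
}

#' Write a scenario bundle to disk
#'
#' Emits newick, per-gene FASTA, trait TSV and a provenance JSON
#' (parameters + seed) into `dir`.
#'
#' @param bundle A `shift_scenario`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             traits = file.path(dir, "traits.tsv"),
             provenance = file.path(dir, "provenance.json"))
  write_dated_tree(bundle$tree, paths["tree"])
  write_trait_table(bundle$traits, paths["traits"])
  for (aln in bundle$alignments) {
    p <- file.path(dir, paste0(aln$gene, ".fasta"))
    write_codon_alignment(aln, p)
    paths[aln$gene] <- p
  }
  jsonlite::write_json(bundle$params, paths["provenance"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
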