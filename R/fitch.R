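#' Fitch/Hartigan parsimony ancestral state reconstruction
#'
#' Minimum-change reconstruction of a discrete character on a rooted tree.
#' Polytomies are handled natively with Hartigan's generalisation: at a node
#' the preliminary set is the set of states carried by the largest number of
#' child sets, and each child outside that majority costs one step. On
#' bifurcating trees this reduces to Fitch's intersection/union rule.
#'
#' One most-parsimonious labeling is resolved top-down: the root takes a
#' state from its down-pass set (preferring `prefer_state` when optimal,
#' else the first state in the state-set order); every other node keeps its
#' parent's state when that state is in its down-pass set, else falls back
#' to the same tie-break. Ties at the root are reported in
#' `root_candidates`.
#'
#' @param tree A `dated_tree`.
#' @param traits A `trait_table` covering every terminal.
#' @param prefer_state Optional state name used to break ties (typically the
#'   putative ancestral state).
#' @return Object of class `parsimony_asr`: list with `node_states` (tibble:
#'   `node`, `label`, `state`, `state_set` list-column), `total_steps`,
#'   `states`, `root_state`, `root_candidates`.
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,(C:1,D:1):1);")
#' tt <- trait_table(c("A","B","C","D"), c("hemi","eu","hemi","hemi"))
#' fitch_parsimony(tr, tt)$total_steps  # 1
#' @export
fitch_parsimony <- function(tree, traits, prefer_state = NULL) {
  stopifnot(inherits(tree, "dated_tree"))
  states <- trait_states(traits)
  k <- length(states)
  tip_state <- states_for_tree(tree, traits)
  n_tip <- tree$n_tip
  n_all <- n_tip + tree$n_node
  kids <- tree_children(tree)

  # down-pass: sets as logical k-vectors
  sets <- matrix(FALSE, n_all, k, dimnames = list(NULL, states))
  sets[cbind(seq_len(n_tip), match(tip_state, states))] <- TRUE
  steps <- 0L
  for (v in tree_postorder(tree)) {
    ch <- kids[[v]]
    votes <- colSums(sets[ch, , drop = FALSE])
    mx <- max(votes)
    sets[v, ] <- votes == mx
    steps <- steps + (length(ch) - mx)
  }

  # top-down resolution
  pick <- function(set_v, parent_state = NULL) {
    opts <- states[set_v]
    if (!is.null(parent_state) && parent_state %in% opts) return(parent_state)
    if (!is.null(prefer_state) && prefer_state %in% opts) return(prefer_state)
    opts[1]
  }
  state <- character(n_all)
  state[seq_len(n_tip)] <- tip_state
  root <- tree$root
  root_candidates <- states[sets[root, ]]
  state[root] <- pick(sets[root, ])
  td <- tidy_tree(tree)
  # preorder: parents before children
  pre <- rev(tree_postorder(tree))
  for (v in pre) {
    for (c in kids[[v]]) {
      if (c > n_tip) state[c] <- pick(sets[c, ], state[v])
    }
  }

  realized <- sum(state[td$parent[!is.na(td$parent)]] != state[which(!is.na(td$parent))])
  structure(
    list(node_states = tibble(node = seq_len(n_all),
                              label = c(tree$phylo$tip.label, rep("", tree$n_node)),
                              state = state,
                              state_set = lapply(seq_len(n_all), function(i) states[sets[i, ]])),
         total_steps = as.integer(steps), realized_steps = as.integer(realized),
         states = states, root_state = state[root],
         root_candidates = root_candidates, tree = tree),
    class = "parsimony_asr")
}

#' @export
print.parsimony_asr <- function(x, ...) {
  cat("<parsimony_asr>", x$total_steps, "steps, root state:", x$root_state,
      if (length(x$root_candidates) > 1)
        paste0("(tied: ", paste(x$root_candidates, collapse = "/"), ")") else "", "\n")
  invisible(x)
}

#' Enumerate life-form shift events on a resolved reconstruction
#'
#' A shift event is a maximal subtree whose root node is reconstructed in a
#' state other than `ancestral_state` while its parent (if any) is in
#' `ancestral_state`. Member taxa are the descendant terminals that carry
#' the event's derived state along an unbroken derived-state path from the
#' origin. Sister branches are the other child lineages of the divergence
#' node (the origin's parent) reconstructed in the ancestral state.
#'
#' @param rec A `parsimony_asr`.
#' @param ancestral_state State regarded as ancestral.
#' @return Tibble with one row per event: `event`, `derived_state`,
#'   `origin` (node id), `divergence_node`, `members` and `sister_nodes`
#'   (list-columns), `n_members`.
#' @export
count_state_shifts <- function(rec, ancestral_state) {
  stopifnot(inherits(rec, "parsimony_asr"))
  if (!ancestral_state %in% rec$states) {
    stop("ancestral_state '", ancestral_state, "' not in state set")
  }
  tree <- rec$tree
  st <- rec$node_states$state
  td <- tidy_tree(tree)
  kids <- tree_children(tree)
  parent_state <- st[td$parent]  # NA for the root
  origins <- which(st != ancestral_state &
                     (is.na(parent_state) | parent_state == ancestral_state))
  origins <- origins[order(tree$node_age[origins], decreasing = TRUE)]
  rows <- lapply(seq_along(origins), function(i) {
    o <- origins[i]
    ds <- st[o]
    # members: tips reachable from origin through derived-state nodes only
    members <- integer(0)
    stack <- o
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (st[v] != ds) next
      if (v <= tree$n_tip) members <- c(members, v)
      else stack <- c(stack, kids[[v]])
    }
    div <- td$parent[o]
    sisters <- if (is.na(div)) integer(0) else setdiff(kids[[div]], o)
    sisters <- sisters[st[sisters] == ancestral_state]
    n_mem <- length(members)
    tibble(event = i, derived_state = ds, origin = o,
           divergence_node = if (is.na(div)) NA_integer_ else div,
           members = list(sort(tree$phylo$tip.label[members])),
           sister_nodes = list(sisters),
           n_members = n_mem)
  })
  if (!length(rows)) {
    return(tibble(event = integer(), derived_state = character(),
                  origin = integer(), divergence_node = integer(),
                  members = list(), sister_nodes = list(), n_members = integer()))
  }
  bind_rows(rows)
}

#' Retention index of a life-form state
#'
#' The character is recoded to presence/absence of `state`; `s` is the
#' observed number of binary Fitch steps, `g = min(n1, n0)` the maximum
#' steps any tree could require, and `r` (1 when both states occur, else 0)
#' the minimum. RI = (g - s) / (g - r); 1 means no homoplasy, 0 maximal
#' homoplasy. For an autapomorphic state (one carrier) g = s = r = 1 and
#' the ratio is 0/0: by convention the RI is reported as 0 with
#' `defined = FALSE`.
#'
#' @param tree A `dated_tree`.
#' @param traits A `trait_table`.
#' @param state State name, or `NULL` to compute all states.
#' @return Tibble: `state`, `g`, `s`, `r`, `ri`, `defined`.
#' @export
retention_index <- function(tree, traits, state = NULL) {
  if (is.null(state)) {
    return(bind_rows(lapply(trait_states(traits),
                            function(s) retention_index(tree, traits, s))))
  }
  tip_state <- states_for_tree(tree, traits)
  pres <- ifelse(tip_state == state, "present", "absent")
  n1 <- sum(pres == "present"); n0 <- sum(pres == "absent")
  g <- min(n1, n0)
  r <- as.integer(n1 > 0 && n0 > 0)
  bin <- trait_table(names(tip_state), pres,
                     states = c("absent", "present")[c(n0 > 0, n1 > 0)])
  s <- if (n1 == 0 || n0 == 0) 0L else fitch_parsimony(tree, bin)$total_steps
  defined <- g > r
  tibble(state = state, g = as.integer(g), s = as.integer(s), r = r,
         ri = if (defined) (g - s) / (g - r) else 0,
         defined = defined)
}
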