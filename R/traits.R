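#' Life-form trait tables
#'
#' A trait table maps each terminal taxon to one discrete state. The shipped
#' scheme is the springtail life-form classification (aquatic,
#' myrmecophilous, euedaphic, hemiedaphic, epiedaphic) but any discrete
#' state set with k >= 2 states is accepted, so the same machinery serves
#' e.g. latitudinal groupings.
#'
#' @name trait_table
NULL

#' The five springtail life-form states
#'
#' Habitat-stratification categories: aquatic (water surfaces),
#' myrmecophilous (ant nests), euedaphic (true soil), hemiedaphic
#' (decomposed litter), epiedaphic (vegetation and upper litter).
#' @return Character vector of the five state names.
#' @export
lifeform_states <- function() {
  c("aquatic", "myrmecophilous", "euedaphic", "hemiedaphic", "epiedaphic")
}

#' Construct a trait table
#'
#' @param taxon Character vector of taxon labels.
#' @param state Character vector of states, same length.
#' @param states Ordered state set. `NULL` infers the set from the data
#'   (open state set); if given, unknown states are an error.
#' @return A tibble of class `trait_table` with columns `taxon`, `state` and
#'   a `states` attribute (ordered state names).
#' @export
trait_table <- function(taxon, state, states = NULL) {
  taxon <- as.character(taxon); state <- as.character(state)
  stopifnot(length(taxon) == length(state))
  if (anyDuplicated(taxon)) {
    stop("duplicate taxon in trait table: ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "))
  }
  if (is.null(states)) {
    states <- sort(unique(state))
  } else if (!all(state %in% states)) {
    stop("unknown state(s): ", paste(setdiff(state, states), collapse = ", "),
         " (pass states = NULL for an open state set)")
  }
  if (length(states) < 2) stop("trait table needs k >= 2 states")
  out <- tibble(taxon = taxon, state = state)
  attr(out, "states") <- states
  class(out) <- c("trait_table", class(out))
  out
}

#' Read a taxon -> state table from TSV
#'
#' Two columns (taxon, state). A header line is auto-detected by default:
#' if the first row's second field is a known state it is treated as data.
#'
#' @param path TSV path.
#' @param header `TRUE`, `FALSE`, or `NA` to auto-detect.
#' @param states Ordered state set; `NULL` for an open state set.
#' @return A `trait_table`.
#' @export
read_trait_table <- function(path, header = NA, states = NULL) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", strip.white = TRUE)
  if (ncol(raw) < 2) stop("trait table must have two tab-separated columns")
  raw <- raw[, 1:2]
  if (is.na(header)) {
    header <- tolower(raw[1, 1]) %in% c("taxon", "species", "label") ||
      (!is.null(states) && !(raw[1, 2] %in% states))
  }
  if (isTRUE(header)) raw <- raw[-1, , drop = FALSE]
  trait_table(raw[, 1], raw[, 2], states = states)
}

#' @export
write_trait_table <- function(traits, path) {
  write.table(as.data.frame(traits[, c("taxon", "state")]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' States of a trait table
#' @param traits A `trait_table`.
#' @export
trait_states <- function(traits) attr(traits, "states")

# states as a vector indexed by tip order of a tree
states_for_tree <- function(tree, traits) {
  st <- traits$state[match(tree$phylo$tip.label, traits$taxon)]
  if (anyNA(st)) {
    stop("untraited terminal(s): ",
         paste(tree$phylo$tip.label[is.na(st)], collapse = ", "))
  }
  setNames(st, tree$phylo$tip.label)
}

#' Cross-validate tree, traits and alignments
#'
#' Checks that every tip is traited, that traits carry no taxa missing from
#' the tree, and that each alignment's taxa match the tree. With
#' `prune = TRUE` tips absent from the trait table are dropped from the
#' returned tree instead of raising an error (silent pruning hides data
#' bugs, so the default is a hard error).
#'
#' @param tree A `dated_tree`.
#' @param traits A `trait_table`.
#' @param alignments Optional list of `codon_alignment` objects.
#' @param prune Drop untraited tips instead of erroring.
#' @return Invisibly, a list with the (possibly pruned) `tree` and a tibble
#'   `report` of per-check messages.
#' @export
validate_inputs <- function(tree, traits, alignments = list(), prune = FALSE) {
  tips <- tree$phylo$tip.label
  missing_trait <- setdiff(tips, traits$taxon)
  extra_trait <- setdiff(traits$taxon, tips)
  msgs <- tibble(check = character(), detail = character())
  if (length(missing_trait)) {
    if (prune) {
      phy <- ape::drop.tip(tree$phylo, missing_trait)
      tree <- new_dated_tree(phy)
      msgs <- bind_rows(msgs, tibble(check = "pruned_tips",
                                     detail = paste(missing_trait, collapse = ", ")))
    } else {
      stop("tips without a trait state: ", paste(missing_trait, collapse = ", "),
           " (use prune = TRUE to drop them)")
    }
  }
  if (length(extra_trait)) {
    msgs <- bind_rows(msgs, tibble(check = "traits_not_in_tree",
                                   detail = paste(extra_trait, collapse = ", ")))
  }
  for (aln in alignments) {
    bad <- setdiff(tree$phylo$tip.label, aln$taxa)
    if (length(bad)) {
      stop("alignment '", aln$gene, "' missing taxa: ", paste(bad, collapse = ", "))
    }
  }
  invisible(list(tree = tree, report = msgs))
}
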