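#' Per-taxon selection summary across genes
#'
#' Aggregates a branch change table over genes for each terminal branch:
#' summed counts, pooled omega (counts and site totals summed before the
#' ratio), nonsynonymous proportion, and the selection classification.
#'
#' @param changes A `branch_change_table`.
#' @param tol Neutrality half-width for [classify_selection()].
#' @return Tibble per terminal taxon: `label`, `dN`, `dS`, `omega`, `P`,
#'   `selection`.
#' @export
taxon_selection_summary <- function(changes, tol = 0.05) {
  changes |>
    filter(.data$is_terminal) |>
    group_by(.data$node, .data$label) |>
    summarise(dN = sum(.data$dN), dS = sum(.data$dS),
              N = sum(.data$N), S = sum(.data$S), .groups = "drop") |>
    mutate(omega = branch_omega(.data$dN, .data$dS, .data$N, .data$S),
           P = ifelse(.data$dN + .data$dS > 0,
                      .data$dN / (.data$dN + .data$dS), NA_real_),
           selection = classify_selection(.data$omega, tol)) |>
    select("label", "dN", "dS", "omega", "P", "selection")
}

#' Run the full shift-versus-selection analysis
#'
#' Convenience wrapper chaining the pipeline stages: parsimony ancestral
#' reconstruction of the life-form trait, shift-event enumeration,
#' per-gene ancestral codon reconstruction (M0), branch change counting,
#' per-branch nonsynonymous proportions, the shift-versus-sister
#' comparison, the proportion-versus-age regression, and gene/complex
#' summaries.
#'
#' @param tree A `dated_tree`.
#' @param traits A `trait_table`.
#' @param alignments List of `codon_alignment` objects (one per gene).
#' @param ancestral_state Optional; defaults to the parsimony root state.
#' @param n_starts Optimisation starts for the per-gene M0 fits.
#' @param complex_map Gene -> OXPHOS complex map, or `NULL` to skip the
#'   complex summary.
#' @return List of class `shift_analysis` with elements `parsimony`,
#'   `events`, `reconstructions`, `changes`, `proportions`, `comparison`,
#'   `regression`, `gene_pct`, `complex_pct`, `taxa`.
#' @export
run_shift_analysis <- function(tree, traits, alignments,
                               ancestral_state = NULL, n_starts = 2,
                               complex_map = NULL) {
  rec <- fitch_parsimony(tree, traits, prefer_state = ancestral_state)
  anc <- if (is.null(ancestral_state)) rec$root_state else ancestral_state
  events <- count_state_shifts(rec, anc)
  recons <- lapply(alignments, reconstruct_ancestral_codons, tree = tree,
                   n_starts = n_starts)
  changes <- branch_change_table(recons, alignments)
  props <- branch_proportions(changes, tree, rec, ancestral_state = anc)
  comparison <- if (nrow(events)) shift_vs_sister(events, props, tree, rec)
  regression <- tryCatch(regression_vs_age(props), error = function(e) NULL)
  structure(
    list(parsimony = rec, events = events, reconstructions = recons,
         changes = changes, proportions = props, comparison = comparison,
         regression = regression,
         gene_pct = gene_pct_summary(changes),
         complex_pct = if (!is.null(complex_map))
           complex_summary(changes, complex_map),
         taxa = taxon_selection_summary(changes)),
    class = "shift_analysis")
}

#' @export
print.shift_analysis <- function(x, ...) {
  cat("<shift_analysis>", nrow(x$events), "shift events; root state",
      x$parsimony$root_state, "\n")
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
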