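#' Marginal ancestral codon reconstruction
#'
#' Per-site marginal maximum-likelihood codon states at every internal node
#' under a GY94 model (by default the M0 fit to the gene), via the up-down
#' pruning algorithm over the sense codons. Sites that are masked in a tip
#' contribute a flat partial for that tip; sites masked in every tip are
#' masked at the ancestors too.
#'
#' @param tree A `dated_tree`.
#' @param aln A `codon_alignment`.
#' @param params `NULL` (fit M0 first), a `site_model_fit`, or a named list
#'   with `kappa`, `omega`, `rho` (and optionally `pi`).
#' @param n_starts Starts for the internal M0 fit when `params` is `NULL`.
#' @return Object of class `codon_asr`: `node_codons` (node x site
#'   character matrix; tips carry the observed codons, `NA` where masked),
#'   `posterior` (node x site reconstruction posteriors; 1 at unmasked
#'   tips), `anc_mask` (sites masked across all tips), `params`, `tree`,
#'   `gene`.
#' @export
reconstruct_ancestral_codons <- function(tree, aln, params = NULL, n_starts = 2) {
  code <- aln$code
  if (is.null(params)) params <- fit_site_model(tree, aln, "M0", n_starts = n_starts)
  if (inherits(params, "site_model_fit")) {
    stopifnot(params$model == "M0")
    kappa <- params$kappa; omega <- params$omegas[1]
    rho <- params$rho; pi <- params$pi
  } else {
    kappa <- params$kappa; omega <- params$omega
    rho <- params$rho
    pi <- if (!is.null(params$pi)) params$pi else codon_frequencies(aln)
  }
  n <- length(code$sense)
  L <- aln$n_codon
  m <- gy94_rate_matrix(kappa, omega, pi, code)
  scale <- rho / m$rate
  po <- tree_postorder_edges(tree)
  # shared eigen-decomposition for all edges
  sq <- sqrt(pi)
  B <- (sq %o% (1 / sq)) * m$Q
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  P_edge <- lapply(po$length * scale, function(t) {
    P <- outer(1 / sq, sq) * (eg$vectors %*% (exp(eg$values * t) * t(eg$vectors)))
    P[P < 0] <- 0
    P
  })

  tips <- tree$phylo$tip.label
  tidx <- match(tips, aln$taxa)
  state <- matrix(match(aln$codons[tidx, , drop = FALSE], code$sense),
                  nrow = length(tips))
  state[aln$mask[tidx, , drop = FALSE]] <- NA_integer_
  anc_mask <- apply(is.na(state), 2, all)

  n_all <- tree$n_tip + tree$n_node
  part <- vector("list", n_all)
  for (i in seq_len(tree$n_tip)) {
    Lp <- matrix(0, n, L)
    ok <- !is.na(state[i, ])
    Lp[cbind(state[i, ok], which(ok))] <- 1
    Lp[, !ok] <- 1
    part[[i]] <- Lp
  }
  edges_by_parent <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  edge_down <- vector("list", nrow(po$edge))
  for (v in unique(po$edge[, 1])) {
    acc <- matrix(1, n, L)
    for (e in edges_by_parent[[as.character(v)]]) {
      edge_down[[e]] <- P_edge[[e]] %*% part[[po$edge[e, 2]]]
      acc <- acc * edge_down[[e]]
    }
    mx <- apply(acc, 2, max)
    mx[mx <= 0] <- 1
    part[[v]] <- acc / rep(mx, each = n)
  }

  U <- vector("list", n_all)
  U[[tree$root]] <- matrix(pi, n, L)
  marg <- vector("list", n_all)
  for (v in rev(unique(po$edge[, 1]))) {
    es <- edges_by_parent[[as.character(v)]]
    for (e in es) {
      ch <- po$edge[e, 2]
      sib <- U[[v]]
      for (e2 in setdiff(es, e)) sib <- sib * edge_down[[e2]]
      u <- crossprod(P_edge[[e]], sib)
      mx <- apply(u, 2, max)
      mx[mx <= 0] <- 1
      U[[ch]] <- u / rep(mx, each = n)
    }
  }

  node_codons <- matrix(NA_character_, n_all, L)
  posterior <- matrix(NA_real_, n_all, L)
  node_codons[seq_len(tree$n_tip), ] <- ifelse(is.na(state), NA, code$sense[state])
  posterior[seq_len(tree$n_tip), ][!is.na(state)] <- 1
  for (v in (tree$n_tip + 1):n_all) {
    M <- U[[v]] * part[[v]]
    cs <- colSums(M)
    cs[cs <= 0] <- 1
    M <- M / rep(cs, each = n)
    best <- apply(M, 2, which.max)
    node_codons[v, ] <- code$sense[best]
    posterior[v, ] <- M[cbind(best, seq_len(L))]
    node_codons[v, anc_mask] <- NA_character_
    posterior[v, anc_mask] <- NA_real_
  }
  structure(
    list(node_codons = node_codons, posterior = posterior,
         anc_mask = anc_mask, tree = tree, gene = aln$gene, code = code,
         params = list(kappa = kappa, omega = omega, rho = rho, pi = pi),
         tip_mask = is.na(state)),
    class = "codon_asr")
}

#' @export
print.codon_asr <- function(x, ...) {
  cat("<codon_asr>", x$gene, "-", ncol(x$node_codons), "codon sites,",
      "mean reconstruction posterior",
      format(mean(x$posterior[-(seq_len(x$tree$n_tip)), ], na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Per-branch synonymous/nonsynonymous change counts
#'
#' Sums [pathway_count()] over the sites of every branch, comparing the
#' (reconstructed) parent sequence with the child sequence. Sites masked at
#' either end of a branch are skipped (pairwise-complete). Per-gene site
#' totals `N` and `S` from [site_counts()] convert counts into the rate
#' ratio `omega = (dN/N)/(dS/S)`; `P = dN/(dN+dS)` is the nonsynonymous
#' proportion. `omega` is `NA` (undefined, not infinite) when `dS = 0`, and
#' `P` is `NA` when a branch has no changes at all.
#'
#' @param recon A `codon_asr` (or a list of them, one per gene).
#' @param aln The matching `codon_alignment` (or list).
#' @return Tibble of class `branch_change_table`: one row per branch x
#'   gene with `gene`, `node` (child node id), `label`, `is_terminal`,
#'   `branch_length`, `parent_age`, `dN`, `dS`, `N`, `S`, `gene_size`,
#'   `omega`, `P`.
#' @export
branch_change_table <- function(recon, aln) {
  if (inherits(recon, "codon_asr")) {
    recon <- list(recon); aln <- list(aln)
  }
  stopifnot(length(recon) == length(aln))
  out <- purrr::map2(recon, aln, function(rc, al) {
    tree <- rc$tree
    code <- rc$code
    sc <- site_counts(al)
    td <- tidy_tree(tree)
    po <- tree_postorder_edges(tree)
    n_tip <- tree$n_tip
    pcm <- pathway_count_matrices(code)
    rows <- lapply(seq_len(nrow(po$edge)), function(e) {
      par <- po$edge[e, 1]; ch <- po$edge[e, 2]
      pseq <- rc$node_codons[par, ]
      cseq <- rc$node_codons[ch, ]
      use <- which(!is.na(pseq) & !is.na(cseq) & pseq != cseq)
      idx <- cbind(match(pseq[use], code$sense), match(cseq[use], code$sense))
      dn <- sum(pcm$ND[idx]); ds <- sum(pcm$SD[idx])
      tibble(gene = rc$gene, node = ch,
             label = if (ch <= n_tip) tree$phylo$tip.label[ch] else "",
             is_terminal = ch <= n_tip,
             branch_length = po$length[e],
             parent_age = tree$node_age[par],
             dN = dn, dS = ds)
    })
    bind_rows(rows) |>
      mutate(N = attr(sc, "N"), S = attr(sc, "S"),
             gene_size = al$n_codon,
             omega = branch_omega(.data$dN, .data$dS, .data$N, .data$S),
             P = ifelse(.data$dN + .data$dS > 0,
                        .data$dN / (.data$dN + .data$dS), NA_real_))
  })
  out <- bind_rows(out)
  class(out) <- c("branch_change_table", class(out))
  out
}

#' Branch-level omega from counts and site totals
#'
#' `omega = (dN/N) / (dS/S)`; undefined (`NA`) when `dS = 0`.
#'
#' @param dN,dS Change counts.
#' @param N,S Nonsynonymous and synonymous site totals (must be positive).
#' @return Numeric vector.
#' @export
branch_omega <- function(dN, dS, N, S) {
  if (any(N <= 0) || any(S <= 0)) stop("site totals must be positive")
  ifelse(dS > 0, (dN / N) / (dS / S), NA_real_)
}

#' The 13 mitochondrial protein-coding genes by OXPHOS complex
#'
#' @return Tibble `gene`, `complex` (I = nad1-6 + nad4l, III = cytb,
#'   IV = cox1-3, V = atp6 + atp8).
#' @export
default_complex_map <- function() {
  tibble(
    gene = c(paste0("nad", 1:6), "nad4l", "cytb", paste0("cox", 1:3),
             "atp6", "atp8"),
    complex = c(rep("I", 7), "III", rep("IV", 3), "V", "V"))
}

#' Standardised nonsynonymous percentages per gene
#'
#' @param changes A `branch_change_table`.
#' @return Tibble per gene: `gene`, `total_dN`, `gene_size`, `n_branches`,
#'   `pct` (see [standardized_gene_pct()]), ranked by `pct`.
#' @export
gene_pct_summary <- function(changes) {
  changes |>
    group_by(.data$gene) |>
    summarise(total_dN = sum(.data$dN), gene_size = .data$gene_size[1],
              n_branches = dplyr::n_distinct(.data$node), .groups = "drop") |>
    mutate(pct = standardized_gene_pct(.data$total_dN, .data$gene_size,
                                       .data$n_branches)) |>
    arrange(desc(.data$pct)) |>
    mutate(rank = dplyr::row_number())
}

#' Standardised nonsynonymous percentages per OXPHOS complex
#'
#' Counts and gene sizes are summed within complexes before applying the
#' standardisation formula; genes absent from the map are excluded with a
#' warning.
#'
#' @param changes A `branch_change_table`.
#' @param complex_map Tibble `gene`, `complex`; see [default_complex_map()].
#' @return Tibble per complex: `complex`, `total_dN`, `total_size`,
#'   `n_branches`, `pct`, `rank`.
#' @export
complex_summary <- function(changes, complex_map = default_complex_map()) {
  unknown <- setdiff(unique(changes$gene), complex_map$gene)
  if (length(unknown)) {
    warning("genes not in complex map, excluded: ", paste(unknown, collapse = ", "))
    changes <- filter(changes, !.data$gene %in% unknown)
  }
  if (!nrow(changes)) stop("no genes left after applying the complex map")
  g <- gene_pct_summary(changes) |>
    left_join(complex_map, by = "gene")
  if (dplyr::n_distinct(g$n_branches) > 1) {
    warning("genes contribute unequal branch counts; using per-complex maximum")
  }
  g |>
    group_by(.data$complex) |>
    summarise(total_dN = sum(.data$total_dN),
              total_size = sum(.data$gene_size),
              n_branches = max(.data$n_branches), .groups = "drop") |>
    mutate(pct = standardized_gene_pct(.data$total_dN, .data$total_size,
                                       .data$n_branches)) |>
    arrange(desc(.data$pct)) |>
    mutate(rank = dplyr::row_number())
}
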