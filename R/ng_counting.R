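#' Synonymous and nonsynonymous site counting
#'
#' Per-codon site opportunities in the Nei-Gojobori style: each of the
#' three positions contributes a synonymous fraction equal to the share of
#' synonymous changes among its non-stop single-nucleotide neighbours
#' (stop neighbours are excluded from the denominator, each position is
#' scaled to one site), and the nonsynonymous complement.
#'
#' @param codon Sense codon (three letters over A/C/G/T).
#' @param code A [genetic_code()].
#' @return Named numeric `c(s = , n = )` with `s + n = 3`.
#' @examples
#' ng_sites("TTT")  # s = 1/3: only TTC is synonymous among 9 neighbours
#' @export
ng_sites <- function(codon, code = genetic_code(5)) {
  codon <- toupper(codon)
  aa <- code$map[[codon]]
  if (is.null(aa)) stop("not a codon: ", codon)
  if (aa == "*") stop("stop codon has no site counts: ", codon)
  ci <- strsplit(codon, "")[[1]]
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; nonstop <- 0L
    for (nt in setdiff(nts, ci[pos])) {
      cj <- ci; cj[pos] <- nt
      aj <- code$map[[paste(cj, collapse = "")]]
      if (aj == "*") next
      nonstop <- nonstop + 1L
      if (aj == aa) syn <- syn + 1L
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(s = s, n = 3 - s)
}

#' Site totals of a codon alignment
#'
#' Sums [ng_sites()] over unmasked codons per sequence; the gene-level
#' totals `S` and `N` (used to normalise branch counts into rates) are the
#' means over sequences.
#'
#' @param aln A `codon_alignment`.
#' @return Tibble per taxon (`taxon`, `s`, `n`, `n_codons`) with attributes
#'   `S` and `N` (gene-level means).
#' @export
site_counts <- function(aln) {
  code <- aln$code
  per_codon <- vapply(code$sense, ng_sites, numeric(2), code = code)
  rows <- lapply(seq_along(aln$taxa), function(i) {
    ok <- !aln$mask[i, ]
    idx <- match(aln$codons[i, ok], code$sense)
    tibble(taxon = aln$taxa[i], s = sum(per_codon["s", idx]),
           n = sum(per_codon["n", idx]), n_codons = sum(ok))
  })
  out <- bind_rows(rows)
  attr(out, "S") <- mean(out$s)
  attr(out, "N") <- mean(out$n)
  out
}

# enumerate all minimal single-step pathways a -> b avoiding stop codons;
# returns list of codon vectors (a, ..., b); attr "blocked_all" when every
# ordering passes through a stop
codon_paths <- function(a, b, code = genetic_code(5)) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  diff_pos <- which(ca != cb)
  d <- length(diff_pos)
  if (d == 0) return(list(a))
  orders <- if (d == 1) list(diff_pos) else {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      do.call(c, lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }))
    }
    perms(diff_pos)
  }
  paths <- lapply(orders, function(ord) {
    cur <- ca
    path <- paste(cur, collapse = "")
    for (p in ord) {
      cur[p] <- cb[p]
      path <- c(path, paste(cur, collapse = ""))
    }
    path
  })
  ok <- vapply(paths, function(p) {
    inter <- p[-c(1, length(p))]
    length(inter) == 0 || !any(code$map[inter] == "*")
  }, logical(1))
  if (any(ok)) {
    structure(paths[ok], blocked_all = FALSE)
  } else {
    structure(paths, blocked_all = TRUE)
  }
}

#' Pathway-averaged change counts between two codons
#'
#' Averages the number of nonsynonymous and synonymous single-nucleotide
#' steps over all minimal pathways between the codons that avoid stop
#' codons. Identical codons give (0, 0). When every ordering is blocked by
#' a stop, each differing position is classified independently in the
#' context of `codon_a` and the result is flagged
#' (`attr(, "fallback") = TRUE`).
#'
#' @param codon_a,codon_b Sense codons.
#' @param code A [genetic_code()].
#' @return Named numeric `c(nd = , sd = )`; `nd + sd` equals the number of
#'   differing positions.
#' @examples
#' pathway_count("TTT", "GTA")  # (1.5, 0.5): two pathways averaged
#' @export
pathway_count <- function(codon_a, codon_b, code = genetic_code(5)) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (codon_a == codon_b) return(c(nd = 0, sd = 0))
  paths <- codon_paths(codon_a, codon_b, code)
  if (isTRUE(attr(paths, "blocked_all"))) {
    ca <- strsplit(codon_a, "")[[1]]; cb <- strsplit(codon_b, "")[[1]]
    nd <- 0
    for (p in which(ca != cb)) {
      ci <- ca; ci[p] <- cb[p]
      aj <- code$map[[paste(ci, collapse = "")]]
      if (aj == "*" || aj != code$map[[codon_a]]) nd <- nd + 1
    }
    return(structure(c(nd = nd, sd = sum(ca != cb) - nd), fallback = TRUE))
  }
  counts <- vapply(paths, function(p) {
    aa <- code$map[p]
    steps <- length(p) - 1
    nd <- sum(aa[-length(aa)] != aa[-1])
    c(nd, steps - nd)
  }, numeric(2))
  c(nd = mean(counts[1, ]), sd = mean(counts[2, ]))
}

# pathway-averaged amino-acid replacements between two codons: tibble of
# (from, to, weight) over nonsynonymous steps, weights summing to the
# pathway-averaged nd; memoised per codon pair
pathway_aa_changes <- function(codon_a, codon_b, code = genetic_code(5)) {
  key <- paste0("aa_", code$id)
  if (is.null(.collemsel_cache[[key]])) {
    .collemsel_cache[[key]] <- new.env(parent = emptyenv())
  }
  memo <- .collemsel_cache[[key]]
  pair <- paste0(codon_a, codon_b)
  hit <- memo[[pair]]
  if (!is.null(hit)) return(hit)
  out <- pathway_aa_changes_impl(codon_a, codon_b, code)
  memo[[pair]] <- out
  out
}

pathway_aa_changes_impl <- function(codon_a, codon_b, code = genetic_code(5)) {
  if (codon_a == codon_b) {
    return(tibble(from = character(), to = character(), weight = numeric()))
  }
  paths <- codon_paths(codon_a, codon_b, code)
  if (isTRUE(attr(paths, "blocked_all"))) {
    # classify per position in the context of codon_a, skipping stops
    ca <- strsplit(codon_a, "")[[1]]; cb <- strsplit(codon_b, "")[[1]]
    out <- list()
    for (p in which(ca != cb)) {
      ci <- ca; ci[p] <- cb[p]
      aj <- code$map[[paste(ci, collapse = "")]]
      ai <- code$map[[codon_a]]
      if (aj != "*" && aj != ai) {
        out[[length(out) + 1]] <- tibble(from = ai, to = aj, weight = 1)
      }
    }
    return(if (length(out)) bind_rows(out) else
      tibble(from = character(), to = character(), weight = numeric()))
  }
  w <- 1 / length(paths)
  out <- lapply(paths, function(p) {
    aa <- code$map[p]
    ch <- which(aa[-length(aa)] != aa[-1])
    if (!length(ch)) return(NULL)
    tibble(from = unname(aa[ch]), to = unname(aa[ch + 1]), weight = w)
  })
  out <- bind_rows(out)
  if (!nrow(out)) return(tibble(from = character(), to = character(), weight = numeric()))
  out |> group_by(.data$from, .data$to) |>
    summarise(weight = sum(.data$weight), .groups = "drop")
}

# cached pathway-averaged (nd, sd) for every ordered sense-codon pair
pathway_count_matrices <- function(code = genetic_code(5)) {
  key <- paste0("ndsd_", code$id)
  if (!is.null(.collemsel_cache[[key]])) return(.collemsel_cache[[key]])
  n <- length(code$sense)
  ND <- SD <- matrix(0, n, n, dimnames = list(code$sense, code$sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pc <- pathway_count(code$sense[i], code$sense[j], code)
      ND[i, j] <- pc[["nd"]]; SD[i, j] <- pc[["sd"]]
    }
  }
  out <- list(ND = ND, SD = SD)
  .collemsel_cache[[key]] <- out
  out
}

#' Standardised percentage of nonsynonymous change
#'
#' The gene/complex-level report statistic: total number of nonsynonymous
#' changes / (gene size x total number of branches) x 100. Gene size is in
#' codons (configurable upstream by passing nucleotide lengths instead).
#'
#' @param total_nonsyn_changes Summed nonsynonymous changes.
#' @param gene_size Alignment length (codons).
#' @param n_branches Number of branches contributing counts.
#' @return Percentage.
#' @examples
#' standardized_gene_pct(6, 100, 3)  # 2
#' @export
standardized_gene_pct <- function(total_nonsyn_changes, gene_size, n_branches) {
  if (any(gene_size <= 0)) stop("gene_size must be positive")
  if (any(n_branches <= 0)) stop("n_branches must be positive")
  total_nonsyn_changes / (gene_size * n_branches) * 100
}
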