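#' Amino-acid physicochemical properties
#'
#' Twenty numeric amino-acid property scales used for radical-change
#' detection, drawn at runtime from the published AAindex compilation
#' shipped with seqinr. Each property is registered under its
#' selection-on-amino-acid-properties name together with its AAindex
#' accession, including the three properties most often reported for
#' mitochondrial genes: equilibrium constant (ionisation of COOH),
#' solvent accessible reduction ratio, and buriedness.
#'
#' @return Named list: property name -> named numeric vector over the 20
#'   one-letter amino acids.
#' @param properties Character vector of property names to keep (default
#'   all 20).
#' @export
aa_property_table <- function(properties = NULL) {
  key <- "aa_properties"
  if (is.null(.collemsel_cache[[key]])) {
    env <- new.env()
    utils::data("aaindex", package = "seqinr", envir = env)
    aaindex <- env$aaindex
    map <- aa_property_sources()
    tabs <- lapply(seq_len(nrow(map)), function(i) {
      v <- aaindex[[map$aaindex_id[i]]]$I
      names(v) <- vapply(names(v), function(n) seqinr::a(n), "")
      v[order(names(v))]
    })
    names(tabs) <- map$property
    .collemsel_cache[[key]] <- tabs
  }
  tabs <- .collemsel_cache[[key]]
  if (is.null(properties)) return(tabs)
  missing <- setdiff(properties, names(tabs))
  if (length(missing)) stop("unknown property: ", paste(missing, collapse = ", "))
  tabs[properties]
}

#' @rdname aa_property_table
#' @export
aa_property_sources <- function() {
  tibble(
    property = c(
      "alpha-helical tendencies",
      "average number of surrounding residues",
      "beta-structure tendencies",
      "bulkiness",
      "buriedness",
      "chromatographic index",
      "coil tendencies",
      "composition",
      "equilibrium constant (ionisation of COOH)",
      "hydropathy",
      "isoelectric point",
      "long-range non-bonded energy",
      "molecular volume",
      "molecular weight",
      "normalized consensus hydrophobicity",
      "partial specific volume",
      "polar requirement",
      "polarity",
      "short- and medium-range non-bonded energy",
      "solvent accessible reduction ratio"),
    aaindex_id = c(
      "CHOP780201", "PONP800108", "CHOP780202", "ZIMJ680102", "CHOC760103",
      "WEBA780101", "CHAM830101", "GRAR740101", "FASG760105", "KYTJ820101",
      "ZIMJ680104", "OOBM770103", "GRAR740103", "FASG760101", "EISD840101",
      "COHE430101", "WOEC730101", "GRAR740102", "OOBM770102", "PONP800107"))
}

#' Magnitude categories for one property
#'
#' Enumerates every single-nucleotide nonsynonymous change between sense
#' codons under the code, takes the absolute property difference of each,
#' and divides the range [0, max|delta|] into 8 equal-width bins: category
#' 1 is the most conservative change, category 8 the most radical.
#'
#' @param values Named numeric vector of property values per amino acid.
#' @param code A [genetic_code()].
#' @return List of class `property_categories`: `breaks` (9 bin edges),
#'   `max_delta`, `category` (n_sense x n_sense integer matrix, NA where
#'   the codon pair is not a one-step nonsynonymous change), `values`.
#' @export
build_categories <- function(values, code = genetic_code(5)) {
  aa <- code$aa
  v <- values[aa]
  if (anyNA(v)) stop("property lacks values for amino acid(s): ",
                     paste(setdiff(unique(aa), names(values)), collapse = ", "))
  ns <- code$pair_type == 3L | code$pair_type == 4L
  delta <- abs(outer(v, v, "-"))
  md <- max(delta[ns])
  if (md <= 0) stop("property has zero range over the code's amino acids")
  cat_m <- matrix(NA_integer_, nrow(ns), ncol(ns))
  cat_m[ns] <- category_of_delta(delta[ns], md)
  structure(list(breaks = seq(0, md, length.out = 9), max_delta = md,
                 category = cat_m, values = values),
            class = "property_categories")
}

# category 1..8 for |delta| given the maximum; the maximal change is 8
category_of_delta <- function(delta, max_delta) {
  cat <- ceiling(delta / (max_delta / 8))
  cat[cat < 1L] <- 1L
  cat[cat > 8L] <- 8L
  as.integer(cat)
}

#' Neutral expected category distribution
#'
#' Distribution of magnitude categories over all single-nucleotide
#' nonsynonymous changes under neutrality, each change weighted by the
#' source codon's frequency divided by its number of non-stop
#' single-nucleotide neighbours. Uniform codon frequencies (unweighted
#' enumeration) are the default.
#'
#' @param values Property values per amino acid (or a `property_categories`).
#' @param code A [genetic_code()].
#' @param codon_freqs Optional frequency vector over sense codons.
#' @return Numeric vector `p_1 .. p_8` summing to 1.
#' @export
expected_category_probs <- function(values, code = genetic_code(5),
                                    codon_freqs = NULL) {
  cats <- if (inherits(values, "property_categories")) values
  else build_categories(values, code)
  n <- length(code$sense)
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / n, n)
  w_source <- codon_freqs / code$n_nonstop_neighbors
  ns <- which(!is.na(cats$category), arr.ind = TRUE)
  w <- w_source[ns[, 1]]
  p <- vapply(1:8, function(c8) {
    sum(w[cats$category[ns] == c8])
  }, 0)
  p / sum(p)
}

#' Binomial z-scores for observed category counts
#'
#' z_c = (O_c - N p_c) / sqrt(N p_c (1 - p_c)). Significance at the
#' one-sided p < 0.001 threshold |z| > 3.09 (the 0.999 standard-normal
#' quantile). When no changes were observed (N = 0) all z are reported as
#' 0 with `attr(, "undefined") = TRUE`.
#'
#' @param observed Observed counts per category (length 8; fractional
#'   pathway-averaged counts allowed).
#' @param expected_p Expected probabilities per category.
#' @return Numeric z vector with attribute `undefined`.
#' @export
category_z <- function(observed, expected_p) {
  stopifnot(length(observed) == length(expected_p))
  N <- sum(observed)
  if (N == 0) return(structure(rep(0, length(observed)), undefined = TRUE))
  denom <- sqrt(N * expected_p * (1 - expected_p))
  z <- ifelse(denom > 0, (observed - N * expected_p) / denom,
              ifelse(observed - N * expected_p == 0, 0, Inf))
  structure(z, undefined = FALSE)
}

#' The radical-change z threshold
#'
#' One-sided standard-normal critical value at p < 0.001 (3.09 to the
#' printed precision).
#' @export
radical_z_threshold <- function() qnorm(0.999)

# amino-acid replacements implied by a codon ASR: one row per branch x
# site x (from, to) with pathway-averaged weights
aa_replacements <- function(recon) {
  tree <- recon$tree
  code <- recon$code
  po <- tree_postorder_edges(tree)
  rows <- list()
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    pseq <- recon$node_codons[par, ]; cseq <- recon$node_codons[ch, ]
    ok <- which(!is.na(pseq) & !is.na(cseq) & pseq != cseq)
    for (s in ok) {
      reps <- pathway_aa_changes(pseq[s], cseq[s], code)
      if (nrow(reps)) {
        rows[[length(rows) + 1]] <-
          mutate(reps, site = s, node = ch, .before = 1)
      }
    }
  }
  if (!length(rows)) {
    return(tibble(site = integer(), node = integer(), from = character(),
                  to = character(), weight = numeric()))
  }
  bind_rows(rows)
}

#' Sliding-window scan for radical physicochemical changes
#'
#' Tallies the amino-acid replacements inferred along all branches of a
#' codon ancestral reconstruction into the 8 magnitude categories of each
#' property, whole-gene and in a sliding window (default 15 codons,
#' advancing one codon at a time), and computes binomial z-scores against
#' the neutral expectation. A gene is flagged as showing radical positive
#' selection for a property when category 7 or 8 has z > 3.09; when both
#' are significant the category-8 z is reported.
#'
#' @param recon A `codon_asr`.
#' @param properties Named list of property value vectors
#'   (default [aa_property_table()]).
#' @param window Window width in codons; a window longer than the gene
#'   collapses to a single whole-gene window.
#' @param codon_freqs Optional codon frequencies for the neutral
#'   expectation (default unweighted).
#' @return Object of class `physchem_scan`: `gene_profiles` (property x
#'   category tibble: `expected_p`, `observed`, `z`, `signif`,
#'   `p_bonferroni`), `window_profiles` (per property, window and
#'   category), `flags` (per property: `radical`, `category`, `z`),
#'   `replacements`, `window`.
#' @export
radical_change_scan <- function(recon, properties = aa_property_table(),
                                window = 15, codon_freqs = NULL) {
  code <- recon$code
  L <- ncol(recon$node_codons)
  if (window > L) window <- L
  reps <- aa_replacements(recon)
  gene_rows <- list(); win_rows <- list(); flag_rows <- list()
  for (pn in names(properties)) {
    cats <- build_categories(properties[[pn]], code)
    p_exp <- expected_category_probs(cats, code, codon_freqs)
    rep_cat <- if (nrow(reps)) {
      category_of_delta(abs(cats$values[reps$from] - cats$values[reps$to]),
                        cats$max_delta)
    } else integer(0)
    # per-site category tallies (fractional weights allowed)
    O_site <- matrix(0, L, 8)
    if (nrow(reps)) {
      for (r in seq_len(nrow(reps))) {
        O_site[reps$site[r], rep_cat[r]] <-
          O_site[reps$site[r], rep_cat[r]] + reps$weight[r]
      }
    }
    O_gene <- colSums(O_site)
    z_gene <- category_z(O_gene, p_exp)
    gene_rows[[pn]] <- tibble(
      property = pn, category = 1:8, expected_p = p_exp, observed = O_gene,
      z = as.numeric(z_gene),
      signif = abs(as.numeric(z_gene)) > radical_z_threshold())
    starts <- seq_len(L - window + 1)
    cum <- rbind(0, apply(O_site, 2, cumsum))
    O_win <- cum[starts + window, , drop = FALSE] - cum[starts, , drop = FALSE]
    N_win <- rowSums(O_win)
    Ep <- outer(N_win, p_exp)
    denom <- sqrt(Ep * rep(1 - p_exp, each = length(starts)))
    Z_win <- ifelse(denom > 0, (O_win - Ep) / denom, 0)
    Z_win[N_win == 0, ] <- 0
    win_rows[[pn]] <- tibble(
      property = pn,
      start = rep(starts, times = 8), end = rep(starts + window - 1, times = 8),
      category = rep(1:8, each = length(starts)),
      observed = as.vector(O_win), z = as.vector(Z_win))
    z7 <- as.numeric(z_gene)[7]; z8 <- as.numeric(z_gene)[8]
    thr <- radical_z_threshold()
    radical <- z7 > thr || z8 > thr
    flag_rows[[pn]] <- tibble(
      property = pn, radical = radical,
      category = if (z8 > thr) 8L else if (z7 > thr) 7L else NA_integer_,
      z = if (z8 > thr) z8 else if (z7 > thr) z7 else NA_real_)
  }
  gene_profiles <- bind_rows(gene_rows)
  n_tests <- nrow(gene_profiles)
  gene_profiles <- mutate(gene_profiles,
    p_one_sided = 1 - pnorm(.data$z),
    p_bonferroni = pmin(1, (1 - pnorm(.data$z)) * n_tests))
  structure(
    list(gene_profiles = gene_profiles,
         window_profiles = bind_rows(win_rows),
         flags = bind_rows(flag_rows),
         replacements = reps, window = window, gene = recon$gene),
    class = "physchem_scan")
}

#' @export
print.physchem_scan <- function(x, ...) {
  cat("<physchem_scan>", x$gene, "-", nrow(x$flags), "properties, window",
      x$window, "codons;", sum(x$flags$radical), "flagged radical\n")
  invisible(x)
}
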