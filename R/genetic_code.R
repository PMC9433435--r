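#' Genetic code tables bound to codon machinery
#'
#' Builds a genetic-code object from an NCBI translation-table id. The default
#' is table 5, the invertebrate mitochondrial code used for arthropod
#' mitogenomes (TGA = Trp, AGA/AGG = Ser, ATA = Met; stops TAA and TAG, so 62
#' sense codons). The object carries the codon -> amino-acid map plus the
#' derived single-nucleotide neighbourhood structure (synonymous/nonsynonymous
#' x transition/transversion classification of every one-step codon change)
#' used by the site counting, GY94 and physicochemical modules.
#'
#' @param id NCBI translation table id (integer or character), e.g. 5 or 1.
#' @return An object of class `genetic_code`: a list with elements `id`,
#'   `map` (named character over all 64 codons, `*` = stop), `stops`, `sense`
#'   (sense codons in fixed order), `aa` (amino acid per sense codon),
#'   `pair_type` (n_sense x n_sense integer matrix; 0 = not a single-nt
#'   neighbour, 1 = synonymous transition, 2 = synonymous transversion,
#'   3 = nonsynonymous transition, 4 = nonsynonymous transversion) and
#'   `n_nonstop_neighbors` (per sense codon, how many of its 9 single-nt
#'   neighbours are not stops).
#' @examples
#' code <- genetic_code(5)
#' translate_codon("TGA", code)  # "W" under the invertebrate mitochondrial code
#' @export
genetic_code <- function(id = 5) {
  key <- paste0("code_", id)
  if (!is.null(.collemsel_cache[[key]])) return(.collemsel_cache[[key]])
  map <- Biostrings::getGeneticCode(as.character(id))
  map <- setNames(as.character(map), names(map))
  codons <- names(map)
  stops <- codons[map == "*"]
  sense <- codons[map != "*"]
  n <- length(sense)
  nts <- c("A", "C", "G", "T")
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  sense_idx <- setNames(seq_len(n), sense)
  pair_type <- matrix(0L, n, n, dimnames = list(sense, sense))
  n_nonstop <- setNames(integer(n), sense)
  for (i in seq_len(n)) {
    ci <- strsplit(sense[i], "")[[1]]
    for (pos in 1:3) {
      for (nt in setdiff(nts, ci[pos])) {
        cj <- ci
        cj[pos] <- nt
        cod_j <- paste(cj, collapse = "")
        if (map[[cod_j]] == "*") next
        n_nonstop[i] <- n_nonstop[i] + 1L
        j <- sense_idx[[cod_j]]
        syn <- map[[sense[i]]] == map[[cod_j]]
        ts <- is_transition(ci[pos], nt)
        pair_type[i, j] <- if (syn && ts) 1L else if (syn) 2L
        else if (ts) 3L else 4L
      }
    }
  }
  obj <- structure(
    list(id = id, map = map, stops = stops, sense = sense,
         aa = setNames(map[sense], sense), pair_type = pair_type,
         n_nonstop_neighbors = n_nonstop),
    class = "genetic_code")
  .collemsel_cache[[key]] <- obj
  obj
}

#' Translate a single codon
#'
#' @param codon Three-letter codon over A/C/G/T.
#' @param code A [genetic_code()] object.
#' @return One-letter amino acid, or `"*"` for a stop codon.
#' @export
translate_codon <- function(codon, code = genetic_code(5)) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("codon must be three characters over A/C/G/T (ambiguity codes must be masked by the caller): ", codon)
  }
  unname(code$map[[codon]])
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table", x$id, "-", length(x$sense), "sense codons, stops:",
      paste(x$stops, collapse = ", "), "\n")
  invisible(x)
}

# split codons into position characters, vectorised
codon_chars <- function(codons) {
  do.call(rbind, strsplit(codons, ""))
}
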