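#' In-frame codon alignments
#'
#' A `codon_alignment` holds an in-frame codon matrix over taxa, bound to a
#' genetic code. Sites containing gaps or ambiguity codes in a sequence are
#' flagged in a per-taxon mask and are dropped from site totals and change
#' counts downstream. In-frame stop codons under the bound code are an
#' error.
#'
#' @name codon_alignment
NULL

#' Construct a codon alignment from nucleotide sequences
#'
#' @param seqs Named character vector of equal-length nucleotide sequences
#'   (length divisible by 3).
#' @param code A [genetic_code()] object (default NCBI table 5).
#' @param gene Gene name.
#' @return A `codon_alignment`: list with `gene`, `taxa`, `codons`
#'   (taxa x L character matrix), `mask` (taxa x L logical, `TRUE` =
#'   gap/ambiguity), `code`.
#' @export
codon_alignment <- function(seqs, code = genetic_code(5), gene = "gene") {
  seqs <- toupper(vapply(seqs, paste, "", collapse = ""))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by taxon")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("sequences have unequal lengths")
  if (lens[1] %% 3 != 0) stop("alignment length ", lens[1], " not divisible by 3")
  L <- unname(lens[1] / 3)
  codons <- t(vapply(seqs, function(s) {
    substring(s, seq(1, lens[1], 3), seq(3, lens[1], 3))
  }, character(L)))
  if (L == 1) codons <- matrix(codons, ncol = 1, dimnames = list(names(seqs), NULL))
  rownames(codons) <- names(seqs)
  mask <- !matrix(grepl("^[ACGT]{3}$", codons), nrow = nrow(codons),
                  dimnames = dimnames(codons))
  stops_hit <- !mask & matrix(codons %in% code$stops, nrow = nrow(codons))
  if (any(stops_hit)) {
    w <- which(stops_hit, arr.ind = TRUE)[1, ]
    stop("in-frame stop codon ", codons[w[1], w[2]], " in '",
         rownames(codons)[w[1]], "' at codon ", w[2],
         " under genetic code ", code$id)
  }
  structure(list(gene = gene, taxa = rownames(codons), codons = codons,
                 mask = mask, code = code, n_codon = L),
            class = "codon_alignment")
}

#' Read an in-frame codon alignment from FASTA
#'
#' @param path FASTA file of aligned nucleotide sequences.
#' @param code Genetic code id or [genetic_code()] object; default table 5.
#' @param gene Gene name; defaults to the file name without extension.
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, code = 5, gene = NULL) {
  if (!inherits(code, "genetic_code")) code <- genetic_code(code)
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           whole.header = FALSE)
  seqs <- vapply(fa, function(x) as.character(x)[1], "")
  names(seqs) <- names(fa)
  codon_alignment(seqs, code = code, gene = gene)
}

#' Write a codon alignment to FASTA
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln$codons, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", aln$taxa), seqs)), path)
  invisible(path)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment>", x$gene, "-", length(x$taxa), "taxa x", x$n_codon,
      "codons, code", x$code$id, "-", sum(x$mask), "masked cells\n")
  invisible(x)
}

#' Translate a codon alignment to amino acids
#'
#' Masked cells become `X`.
#' @param aln A `codon_alignment`.
#' @return Character matrix of one-letter amino acids.
#' @export
translate_alignment <- function(aln) {
  out <- matrix("X", nrow = nrow(aln$codons), ncol = aln$n_codon,
                dimnames = dimnames(aln$codons))
  ok <- !aln$mask
  out[ok] <- aln$code$map[aln$codons[ok]]
  out
}
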