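#' Packaged springtail example data
#'
#' A 35-taxon dated tree (32 collembolan species + 3 outgroup taxa) with
#' the clade structure and approximate node ages of the springtail
#' mitogenome study system, and the matching life-form table: an
#' epiedaphic four-taxon Symphypleona clade (crown ca. 290 Ma) plus the
#' epiedaphic Salina celebensis lineage (ca. 115 Ma), two euedaphic
#' origins (Tullbergia bisetosa ca. 287 Ma; the Onychiurus orientalis +
#' Orthonychiurus folsomi pair, crown ca. 192 Ma), the aquatic Podura
#' aquatica (ca. 225 Ma), the myrmecophilous Cyphoderus albinus
#' (ca. 170 Ma), and 22 hemiedaphic taxa. The topology within the
#' hemiedaphic taxa is a plausible interpolation and is not itself a
#' result; branch lengths are in Ma.
#'
#' @return `example_tree()` a `dated_tree`; `example_traits()` a
#'   `trait_table`; `example_outgroups()` the three outgroup labels;
#'   `example_ingroup_tree()` the 32-taxon collembolan clade.
#' @export
example_tree <- function() {
  read_dated_tree(system.file("extdata", "fig1_topology.nwk",
                              package = "collemsel", mustWork = TRUE),
                  require_ultrametric = TRUE)
}

#' @rdname example_tree
#' @export
example_traits <- function() {
  read_trait_table(system.file("extdata", "life_forms.tsv",
                               package = "collemsel", mustWork = TRUE),
                   header = TRUE, states = lifeform_states())
}

#' @rdname example_tree
#' @export
example_outgroups <- function() {
  c("Daphnia_pulex", "Japyx_solifugus", "Trigoniophthalmus_alternatus")
}

#' @rdname example_tree
#' @export
example_ingroup_tree <- function() {
  tr <- example_tree()
  parse_tree(ape::drop.tip(tr$phylo, example_outgroups()),
             require_ultrametric = TRUE)
}
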