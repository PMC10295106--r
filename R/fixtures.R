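#' Packaged bird-louse karyotype fixtures
#'
#' Karyotypes of ten bird-louse species (families Menoponidae and
#' Laemobothriidae) shipped as `.karyo` documents under `inst/extdata`. The
#' chromosome counts, gene censuses, per-chromosome gene counts, NCR
#' placements and every published shared/derived cluster and rearrangement
#' set are reproduced exactly; where a within-chromosome order is not fixed
#' by those constraints the fixture is a synthetic reconstruction and its
#' header says so. [transcription_lint()] pins the fixtures to the published
#' counts.
#'
#' @param species Optional character vector of species ids to load.
#' @return Named list of [karyotype()] objects.
#' @export
#' @examples
#' names(lice_karyotypes())
lice_karyotypes <- function(species = NULL) {
  dir <- system.file("extdata", package = "mitokaryo")
  files <- list.files(dir, pattern = "\\.karyo$", full.names = TRUE)
  ks <- lapply(files, read_karyo)
  names(ks) <- vapply(ks, function(k) k$species_id, character(1L))
  if (!is.null(species)) {
    miss <- setdiff(species, names(ks))
    if (length(miss)) stop("no fixture for: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    ks <- ks[species]
  }
  ks
}

#' Packaged phylogeny fixtures
#'
#' Fixed 23-taxon tree topologies for the two-family bird-louse system (one
#' from a maximum-likelihood analysis, one from a Bayesian analysis; the
#' five ingroup clades are identical, the inter-clade arrangement differs)
#' plus the 4-taxon Laemobothriidae subtree. Branch lengths are unit lengths
#' (the source topologies are consumed as fixed inputs; no tree inference is
#' performed here).
#'
#' @param which `"ml"`, `"bi"` or `"laemobothriidae"`.
#' @return A `phylo` object.
#' @export
lice_tree <- function(which = c("ml", "bi", "laemobothriidae")) {
  which <- match.arg(which)
  if (which == "laemobothriidae") {
    return(parse_newick(paste0(
      "((Laemobothrion_sp1,Laemobothrion_sp3),",
      "(Laemobothrion_sp2,Laemobothrion_tinnunculi));")))
  }
  f <- system.file("extdata", paste0(which, "_tree.nwk"),
                   package = "mitokaryo")
  parse_newick(readLines(f, warn = FALSE))
}

#' Packaged tip states of the fragmentation character
#'
#' @return Tibble `tip`, `state` (0 = single chromosome, 1 = fragmented) for
#'   the 23 taxa of [lice_tree()].
#' @export
lice_tip_states <- function() {
  f <- system.file("extdata", "tip_states.tsv", package = "mitokaryo")
  tibble::as_tibble(utils::read.delim(f, stringsAsFactors = FALSE))
}

#' Reference single-chromosome arrangement
#'
#' The arrangement used by [run_paper_analysis()] to screen shared clusters
#' for derived status: the single-chromosome karyotype of Laemobothrion
#' sp. 1, standing in for the unfragmented organization ancestral to the
#' group. Any single-chromosome karyotype can be supplied instead to
#' [derived_clusters()].
#'
#' @return A [karyotype()].
#' @export
reference_arrangement <- function() {
  lice_karyotypes("Laemobothrion_sp1")[[1]]
}

# md5 checksums of the packaged fixture files (provenance pinning)
fixture_checksums <- function() {
  dir <- system.file("extdata", package = "mitokaryo")
  files <- list.files(dir, full.names = TRUE)
  tibble::tibble(file = basename(files),
                 md5 = unname(tools::md5sum(files)))
}
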