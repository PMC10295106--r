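#' The canonical 37-gene bilaterian mitochondrial complement
#'
#' Bilaterian animal mitochondrial genomes carry 37 genes: 13 protein-coding
#' genes, 2 ribosomal RNA genes and 22 transfer RNA genes. All karyotype
#' operations in this package validate gene symbols against this namespace.
#' tRNA genes are stored under their single-letter amino-acid abbreviations
#' (with `L1`/`L2` and `S1`/`S2` disambiguating the two leucine and serine
#' isoacceptors), the convention used in mitochondrial gene-map figures;
#' `trn`-prefixed aliases (e.g. `"trnA"`, `"trnL1"`) are accepted on input.
#'
#' @return A tibble with columns `gene` (symbol) and `class`
#'   (`"pcg"`, `"rrna"` or `"trna"`), 37 rows.
#' @export
#' @examples
#' mt_genes()
#' dplyr::count(mt_genes(), class)
mt_genes <- function() {
  tibble::tibble(
    gene = c(
      "atp6", "atp8", "cob", "cox1", "cox2", "cox3",
      "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
      "rrnS", "rrnL",
      "A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
      "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y"
    ),
    class = c(
      rep("pcg", 13L), rep("rrna", 2L), rep("trna", 22L)
    )
  )
}

# symbol vector, in canonical order
mt_gene_symbols <- function() mt_genes()$gene

#' Normalize a gene symbol against the mt namespace
#'
#' Accepts canonical symbols and `trn`-prefixed tRNA aliases (`"trnA"` for
#' `"A"` etc.). Symbols are case-sensitive.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of canonical symbols.
#' @keywords internal
normalize_gene <- function(x) {
  canon <- mt_gene_symbols()
  trna <- canon[mt_genes()$class == "trna"]
  alias <- stats::setNames(trna, paste0("trn", trna))
  out <- ifelse(x %in% names(alias), alias[x], x)
  bad <- setdiff(unique(out), canon)
  if (length(bad) > 0L) {
    stop("unknown mt gene symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

# trn-prefixed identifier used in GRIMM-style export
grimm_gene_id <- function(x) {
  trna <- mt_genes()$gene[mt_genes()$class == "trna"]
  ifelse(x %in% trna, paste0("trn", x), x)
}
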