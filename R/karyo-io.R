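#' Parse a karyotype document
#'
#' The `.karyo` dialect is a small UTF-8 text format: `#` starts a comment,
#' `species:` and `host:` lines carry metadata, and every other non-blank
#' line describes one circular chromosome as `LABEL: tok tok ...`, where each
#' token is a gene symbol (`-`-prefixed for reverse transcription
#' orientation), a `trn`-prefixed tRNA alias, or `NCR:<len>` for a
#' non-coding region of `<len>` bp. An optional `size=<bp>` token records the
#' chromosome's total size as metadata.
#'
#' @param text Character scalar (whole document) or vector of lines.
#' @return A validated [karyotype()].
#' @export
#' @examples
#' parse_karyo(c("species: toy", "M1: E nad4L nad4", "M2: -cox1 NCR:120"))
parse_karyo <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  species <- NA_character_
  host <- NULL
  chroms <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (grepl("^species:", line)) {
      species <- trimws(sub("^species:", "", line))
      next
    }
    if (grepl("^host:", line)) {
      host <- trimws(sub("^host:", "", line))
      next
    }
    if (!grepl(":", line, fixed = TRUE)) {
      stop("line ", i, ": expected 'LABEL: tokens', got '", line, "'",
           call. = FALSE)
    }
    label <- trimws(sub(":.*$", "", line))
    body <- trimws(sub("^[^:]*:", "", line))
    toks <- strsplit(body, "[[:space:]]+")[[1]]
    toks <- toks[toks != ""]
    size_bp <- NULL
    is_size <- grepl("^size=", toks)
    if (any(is_size)) {
      size_bp <- as.integer(sub("^size=", "", toks[is_size][1L]))
      toks <- toks[!is_size]
    }
    mc <- tryCatch(
      minichromosome(label, toks, size_bp = size_bp),
      error = function(e) {
        stop("line ", i, " (", label, "): ", conditionMessage(e),
             call. = FALSE)
      }
    )
    chroms <- c(chroms, list(mc))
  }
  if (length(chroms) == 0L) stop("no chromosome lines found", call. = FALSE)
  if (is.na(species)) species <- "unnamed"
  karyotype(species, chroms, host = host)
}

#' Read a `.karyo` file
#'
#' @param path File path.
#' @return A [karyotype()].
#' @export
read_karyo <- function(path) {
  parse_karyo(readLines(path, warn = FALSE))
}

#' Write a karyotype in the `.karyo` dialect
#'
#' @param k A [karyotype()].
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the document lines.
#' @export
write_karyo <- function(k, path = NULL) {
  stopifnot(inherits(k, "karyotype"))
  lines <- c(
    paste0("species: ", k$species_id),
    if (!is.null(k$host)) paste0("host: ", k$host),
    vapply(k$chromosomes, function(mc) {
      paste0(mc$label, ": ", format_minichromosome(mc),
             if (!is.null(mc$size_bp)) paste0(" size=", mc$size_bp))
    }, character(1L))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Export karyotypes as GRIMM-style signed gene orders
#'
#' One genome per block: a `>species` header followed by one line per
#' chromosome of signed gene identifiers (tRNAs written with their `trn`
#' prefix); non-coding regions are dropped. This is the interchange format
#' consumed by classical genome-rearrangement tools.
#'
#' @param karyotypes A [karyotype()] or list of karyotypes.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the document lines.
#' @export
write_grimm <- function(karyotypes, path = NULL) {
  if (inherits(karyotypes, "karyotype")) karyotypes <- list(karyotypes)
  lines <- unlist(lapply(unname(karyotypes), function(k) {
    c(paste0(">", k$species_id),
      vapply(unname(k$chromosomes), function(mc) {
        g <- mc_genes(mc)
        paste(paste0(ifelse(g$strand < 0L, "-", ""), grimm_gene_id(g$gene)),
              collapse = " ")
      }, character(1L)))
  }))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
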