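#' Build a circular mitochondrial minichromosome
#'
#' A minichromosome is a circular ordered sequence of oriented genes and
#' non-coding regions (NCRs). The stored left-to-right order is one arbitrary
#' linearization of the circle; equality of chromosomes is defined on
#' [canonical_form()], which is invariant under rotation and full reversal.
#'
#' @param label Chromosome label, e.g. `"M1"`.
#' @param tokens Character vector describing the elements in circular order:
#'   a gene symbol (optionally `-`-prefixed for reverse transcription
#'   orientation relative to the written linearization), or `"NCR:<len>"` for
#'   a non-coding region of `<len>` bp.
#' @param size_bp Optional total chromosome size in bp (metadata only).
#' @return An object of class `minichromosome`.
#' @export
#' @examples
#' minichromosome("M1", c("E", "nad4L", "nad4"))
#' minichromosome("M2", c("cox2", "cox1", "NCR:50", "atp6", "atp8"))
minichromosome <- function(label, tokens, size_bp = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nchar(label) > 0L)
  stopifnot(is.character(tokens), length(tokens) > 0L)
  is_ncr <- grepl("^NCR:", tokens)
  strand <- ifelse(grepl("^-", tokens), -1L, 1L)
  sym <- sub("^-", "", tokens)
  len <- rep(NA_integer_, length(tokens))
  if (any(is_ncr)) {
    if (any(strand[is_ncr] < 0L)) {
      stop("non-coding regions carry no orientation", call. = FALSE)
    }
    len[is_ncr] <- as.integer(sub("^NCR:", "", sym[is_ncr]))
    if (any(is.na(len[is_ncr]) | len[is_ncr] < 1L)) {
      stop("NCR length must be an integer >= 1", call. = FALSE)
    }
  }
  gene <- rep(NA_character_, length(tokens))
  gene[!is_ncr] <- normalize_gene(sym[!is_ncr])
  if (sum(!is_ncr) < 1L) {
    stop("minichromosome '", label, "' contains no gene", call. = FALSE)
  }
  if (anyDuplicated(gene[!is_ncr])) {
    stop("duplicate gene within minichromosome '", label, "'", call. = FALSE)
  }
  if (!is.null(size_bp)) {
    size_bp <- as.integer(size_bp)
    if (size_bp < sum(len, na.rm = TRUE)) {
      stop("total_size_bp smaller than summed NCR lengths", call. = FALSE)
    }
  }
  structure(
    list(
      label = label,
      elements = tibble::tibble(
        type = ifelse(is_ncr, "ncr", "gene"),
        gene = gene,
        strand = ifelse(is_ncr, NA_integer_, strand),
        length = len
      ),
      size_bp = size_bp
    ),
    class = "minichromosome"
  )
}

#' @export
print.minichromosome <- function(x, ...) {
  cat("<minichromosome ", x$label, "> ", format_minichromosome(x), "\n",
      sep = "")
  invisible(x)
}

format_minichromosome <- function(mc) {
  el <- mc$elements
  tok <- ifelse(
    el$type == "ncr", paste0("NCR:", el$length),
    paste0(ifelse(el$strand < 0L, "-", ""), el$gene)
  )
  paste(tok, collapse = " ")
}

# gene-only view: tibble(gene, strand), circular order preserved
mc_genes <- function(mc) {
  el <- mc$elements[mc$elements$type == "gene", c("gene", "strand")]
  tibble::as_tibble(el)
}

#' Assemble a mitochondrial karyotype
#'
#' A karyotype is a species' complete mitochondrial genome described as a set
#' of circular (mini)chromosomes of oriented genes. No gene may occur more
#' than once across chromosomes, mirroring the single-copy gene complement
#' observed in the described louse karyotypes.
#'
#' @param species_id Species identifier.
#' @param chromosomes List of [minichromosome()] objects.
#' @param host Optional host species (metadata).
#' @return An object of class `karyotype`.
#' @export
#' @examples
#' k <- karyotype("toy", list(
#'   minichromosome("M1", c("E", "nad4L", "nad4")),
#'   minichromosome("M2", c("cox1", "-cox2"))
#' ))
#' fragmentation_state(k)
karyotype <- function(species_id, chromosomes, host = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  stopifnot(is.list(chromosomes), length(chromosomes) >= 1L)
  ok <- vapply(chromosomes, inherits, logical(1L), "minichromosome")
  if (!all(ok)) stop("all chromosomes must be minichromosome objects",
                     call. = FALSE)
  labels <- vapply(chromosomes, function(m) m$label, character(1L))
  if (anyDuplicated(labels)) {
    stop("duplicate chromosome labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  names(chromosomes) <- labels
  genes <- unlist(lapply(chromosomes, function(m) mc_genes(m)$gene))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    stop("gene(s) present on more than one chromosome: ",
         paste(sort(dup), collapse = ", "), call. = FALSE)
  }
  structure(
    list(species_id = species_id, host = host, chromosomes = chromosomes),
    class = "karyotype"
  )
}

#' @export
print.karyotype <- function(x, ...) {
  ng <- nrow(karyotype_genes(x))
  cat("<karyotype> ", x$species_id,
      if (!is.null(x$host)) paste0(" (ex ", x$host, ")"), ": ",
      length(x$chromosomes), " chromosome(s), ", ng, " genes\n", sep = "")
  for (mc in x$chromosomes) {
    cat("  ", mc$label, ": ", format_minichromosome(mc), "\n", sep = "")
  }
  invisible(x)
}

#' Flat gene table of a karyotype
#'
#' @param k A [karyotype()].
#' @return Tibble with one row per gene: `chromosome`, `position` (index in
#'   the written gene-only order), `gene`, `strand` (+1/-1).
#' @export
karyotype_genes <- function(k) {
  purrr::map_dfr(k$chromosomes, function(mc) {
    g <- mc_genes(mc)
    tibble::tibble(
      chromosome = mc$label,
      position = seq_len(nrow(g)),
      gene = g$gene,
      strand = g$strand
    )
  })
}

#' Census of the 37-gene complement in a karyotype
#'
#' Partitions the canonical namespace into genes present somewhere in the
#' karyotype and genes not identified, e.g. 23 present / 14 missing for a
#' louse karyotype in which 14 tRNA genes were not found.
#'
#' @param k A [karyotype()].
#' @return Tibble with columns `gene`, `class`, `present` (logical) and
#'   `chromosome` (`NA` for missing genes); attribute-free, 37 rows.
#' @export
#' @examples
#' k <- karyotype("toy", list(minichromosome("M1", c("rrnL", "rrnS"))))
#' sum(gene_census(k)$present)
gene_census <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  tab <- karyotype_genes(k)
  dplyr::left_join(mt_genes(), tab[, c("gene", "chromosome")], by = "gene") |>
    dplyr::mutate(present = !is.na(.data$chromosome))
}

#' Fragmentation state of a karyotype
#'
#' The binary character mapped on phylogenies: `"single"` when the whole gene
#' complement sits on one chromosome, `"fragmented"` when it is distributed
#' over two or more minichromosomes.
#'
#' @param k A [karyotype()].
#' @return `"single"` or `"fragmented"`.
#' @export
fragmentation_state <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  if (length(k$chromosomes) >= 2L) "fragmented" else "single"
}

# signed token encoding of a gene-only sequence
signed_tokens <- function(gene, strand) {
  paste0(ifelse(strand < 0L, "-", ""), gene)
}

# reverse a signed gene-only sequence (order flipped, strands negated)
reverse_signed <- function(gene, strand) {
  list(gene = rev(gene), strand = -rev(strand))
}

#' Canonical form of a minichromosome
#'
#' Drops non-coding regions and returns the lexicographically least signed
#' gene sequence over all rotations of the written order and all rotations of
#' its full reversal (reversal flips every orientation). Two circular
#' chromosomes describe the same molecule iff their canonical forms are
#' identical; the written linearization and strand are arbitrary.
#'
#' @param mc A [minichromosome()].
#' @return Character vector of signed gene tokens (e.g. `c("E","nad4L")`,
#'   `"-"`-prefixed for reverse orientation).
#' @export
#' @examples
#' a <- minichromosome("x", c("E", "nad4L", "nad4"))
#' b <- minichromosome("y", c("nad4", "E", "nad4L"))
#' identical(canonical_form(a), canonical_form(b))
canonical_form <- function(mc) {
  stopifnot(inherits(mc, "minichromosome"))
  g <- mc_genes(mc)
  candidates <- circular_frames(g$gene, g$strand)
  keys <- vapply(candidates, function(fr) {
    paste(signed_tokens(fr$gene, fr$strand), collapse = "-")
  }, character(1L))
  best <- candidates[[order(keys)[1L]]]
  signed_tokens(best$gene, best$strand)
}

# all rotations of (gene,strand) and of its full reversal
circular_frames <- function(gene, strand) {
  n <- length(gene)
  rot <- function(g, s) {
    lapply(seq_len(n) - 1L, function(k) {
      idx <- ((seq_len(n) - 1L + k) %% n) + 1L
      list(gene = g[idx], strand = s[idx])
    })
  }
  rv <- reverse_signed(gene, strand)
  c(rot(gene, strand), rot(rv$gene, rv$strand))
}

# do two minichromosomes describe the same circular molecule?
same_chromosome <- function(a, b) {
  identical(canonical_form(a), canonical_form(b))
}
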