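#' Genes translocated between homologous chromosome units
#'
#' After pairing chromosomes ([match_chromosomes()]) and absorbing split or
#' merged chromosomes into one homologous unit each
#' ([detect_split_merge()]), a gene shared by both karyotypes is called
#' translocated when its chromosome assignment crosses unit boundaries.
#' Moves within a unit are positional shuffles, reported separately by
#' [compare_karyotypes()] as repositioned genes. Genes sitting on orphan
#' chromosomes (no homology on the other side) are excluded from the call
#' and flagged.
#'
#' @param a,b [karyotype()] objects.
#' @param h Optional `chromosome_homology`; recomputed when `NULL`.
#' @param sm Optional split/merge grouping from [detect_split_merge()].
#' @return Tibble: `gene`, `chromosome_a`, `chromosome_b`, `status`
#'   (`"translocated"` or `"orphan"`), sorted by gene.
#' @export
translocated_genes <- function(a, b, h = NULL, sm = NULL) {
  ctx <- comparison_context(a, b, h, sm)
  tab <- ctx$shared
  tab$unit_a <- unname(ctx$units$unit_a[tab$chromosome_a])
  tab$unit_b <- unname(ctx$units$unit_b[tab$chromosome_b])
  orphan <- is.na(tab$unit_a) | is.na(tab$unit_b)
  moved <- !orphan & tab$unit_a != tab$unit_b
  out <- tab[moved | orphan,
             c("gene", "chromosome_a", "chromosome_b")]
  out$status <- ifelse(orphan[moved | orphan], "orphan", "translocated")
  dplyr::arrange(tibble::as_tibble(out), .data$status, .data$gene)
}

#' Genes with inverted transcription orientation
#'
#' Circular chromosomes have no absolute strand, so orientation change is
#' assessed frame-relatively: for every chromosome of `b` a reading frame
#' (as written, or fully reversed) is fixed by maximizing the number of
#' orientation-concordant genes shared with its homologous anchor chromosome
#' in `a` (ties resolve to the written frame of `a`). A shared gene whose
#' orientation is then discordant between the two karyotypes is called
#' inverted; a translocated gene is assessed in its destination unit, so a
#' gene can be both translocated and inverted.
#'
#' @inheritParams translocated_genes
#' @return Tibble: `gene`, `chromosome_a`, `chromosome_b`, sorted by gene.
#' @export
inverted_genes <- function(a, b, h = NULL, sm = NULL) {
  ctx <- comparison_context(a, b, h, sm)
  tab <- ctx$shared
  tab$unit_a <- unname(ctx$units$unit_a[tab$chromosome_a])
  tab$unit_b <- unname(ctx$units$unit_b[tab$chromosome_b])
  ok <- !is.na(tab$unit_a) & !is.na(tab$unit_b)
  tab <- tab[ok, , drop = FALSE]
  frames <- b_chromosome_frames(ctx)
  disc <- frames[tab$chromosome_b] * tab$strand_b != tab$strand_a
  out <- tab[disc, c("gene", "chromosome_a", "chromosome_b")]
  dplyr::arrange(tibble::as_tibble(out), .data$gene)
}

# Shared-gene table + homology units for one comparison; memoized plumbing.
comparison_context <- function(a, b, h = NULL, sm = NULL) {
  if (is.null(h)) h <- match_chromosomes(a, b)
  if (is.null(sm)) sm <- detect_split_merge(a, b, h)
  ta <- karyotype_genes(a)
  tb <- karyotype_genes(b)
  shared <- dplyr::inner_join(ta, tb, by = "gene",
                              suffix = c("_a", "_b"))
  list(a = a, b = b, h = h, sm = sm,
       shared = shared,
       units = homology_units(a, b, h, sm))
}

# Reading frame (+1 as written, -1 reversed) per chromosome of b, chosen to
# maximize orientation concordance with its anchor chromosome in a.
b_chromosome_frames <- function(ctx) {
  anchors <- ctx$units$frame_anchor
  frames <- stats::setNames(rep(1, length(anchors)), names(anchors))
  sh <- ctx$shared
  for (lb in names(anchors)) {
    la <- anchors[lb]
    if (is.na(la)) next
    rows <- sh$chromosome_b == lb & sh$chromosome_a == la
    if (!any(rows)) next
    conc_fwd <- sum(sh$strand_a[rows] == sh$strand_b[rows])
    conc_rev <- sum(sh$strand_a[rows] == -sh$strand_b[rows])
    frames[lb] <- if (conc_rev > conc_fwd) -1 else 1
  }
  frames
}

#' Full pairwise rearrangement report
#'
#' Composes chromosome matching, split/merger detection, shared- and
#' derived-cluster extraction and the translocation/inversion calls into one
#' report describing how two mitochondrial karyotypes differ.
#'
#' @param a,b [karyotype()] objects.
#' @param reference Optional reference [karyotype()]; when given, shared
#'   clusters are additionally screened with [derived_clusters()].
#' @param min_len Minimum shared-cluster length (genes).
#' @return An object of class `karyotype_comparison`: a list with
#'   `species` (ids), `chromosome_count_delta` (`|A| - |B|`), `homology`,
#'   `split_merge` (tibble of one-vs-many groups), `orphans`, `clusters`,
#'   `derived` (or `NULL`), `translocated`, `inverted`, `repositioned`
#'   (character vector of within-unit moves), and
#'   `shared_whole_chromosomes` (count of clusters spanning a whole
#'   chromosome on both sides).
#' @export
#' @examples
#' k <- karyotype("toy", list(minichromosome("M1", c("E", "nad4L", "nad4"))))
#' compare_karyotypes(k, k)$chromosome_count_delta
compare_karyotypes <- function(a, b, reference = NULL, min_len = 2L) {
  h <- match_chromosomes(a, b)
  sm <- detect_split_merge(a, b, h)
  ctx <- comparison_context(a, b, h, sm)
  clusters <- shared_clusters(a, b, min_len = min_len)
  tra <- translocated_genes(a, b, h, sm)
  inv <- inverted_genes(a, b, h, sm)
  rep_genes <- repositioned_genes(ctx, clusters, tra, inv)
  structure(
    list(
      species = c(a = a$species_id, b = b$species_id),
      chromosome_count_delta =
        length(a$chromosomes) - length(b$chromosomes),
      homology = h,
      split_merge = sm$groups,
      orphans = sm$orphans,
      clusters = clusters,
      derived = if (!is.null(reference))
        derived_clusters(clusters, reference),
      translocated = tra,
      inverted = inv,
      repositioned = rep_genes,
      shared_whole_chromosomes =
        sum(clusters$whole_a & clusters$whole_b)
    ),
    class = "karyotype_comparison"
  )
}

# Within-unit positional moves: same-unit shared genes that are
# orientation-concordant yet belong to no maximal shared run.
repositioned_genes <- function(ctx, clusters, tra, inv) {
  tab <- ctx$shared
  tab$unit_a <- unname(ctx$units$unit_a[tab$chromosome_a])
  tab$unit_b <- unname(ctx$units$unit_b[tab$chromosome_b])
  same_unit <- !is.na(tab$unit_a) & !is.na(tab$unit_b) &
    tab$unit_a == tab$unit_b
  in_run <- tab$gene %in% unlist(lapply(clusters$genes, function(tok) {
    sub("^-", "", tok)
  }))
  cand <- tab$gene[same_unit & !in_run]
  sort(setdiff(cand, c(tra$gene, inv$gene)))
}

#' @export
print.karyotype_comparison <- function(x, ...) {
  cat("<karyotype_comparison> ", x$species["a"], " vs ", x$species["b"],
      "\n", sep = "")
  cat("  chromosome count delta:", x$chromosome_count_delta, "\n")
  cat("  split/merge groups:", nrow(x$split_merge), "\n")
  cat("  shared clusters:", nrow(x$clusters),
      "(whole-chromosome on both sides:", x$shared_whole_chromosomes,
      ")\n")
  tr <- x$translocated$gene[x$translocated$status == "translocated"]
  cat("  translocated:", if (length(tr)) paste(sort(tr), collapse = ", ")
      else "none", "\n")
  cat("  inverted:", if (nrow(x$inverted))
    paste(sort(x$inverted$gene), collapse = ", ") else "none", "\n")
  if (length(x$repositioned))
    cat("  repositioned within units:",
        paste(x$repositioned, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a single rearrangement event from a parent/child pair
#'
#' Convenience classifier used to validate the simulator: given two
#' karyotypes assumed to differ by at most one event, infers the event class
#' and the affected gene block from the comparison report.
#'
#' @param parent,child [karyotype()] objects.
#' @return List with `class` (`"fission"`, `"fusion"`, `"translocation"`,
#'   `"inversion"` or `"none"`) and `genes` (affected gene block; for
#'   fission/fusion the genes of the split/merged unit).
#' @export
infer_single_event <- function(parent, child) {
  cmp <- compare_karyotypes(parent, child)
  delta <- cmp$chromosome_count_delta
  tr <- cmp$translocated$gene[cmp$translocated$status == "translocated"]
  if (delta == -1L && nrow(cmp$split_merge) == 1L) {
    g <- cmp$split_merge[1, ]
    labs <- if (g$one_side == "a") g$many_labels[[1]] else g$one_label
    genes <- sort(unname(unlist(lapply(child$chromosomes[labs],
                                       function(m) mc_genes(m)$gene))))
    return(list(class = "fission", genes = genes))
  }
  if (delta == 1L && nrow(cmp$split_merge) == 1L) {
    g <- cmp$split_merge[1, ]
    labs <- if (g$one_side == "b") g$many_labels[[1]] else g$one_label
    genes <- sort(unname(unlist(lapply(parent$chromosomes[labs],
                                       function(m) mc_genes(m)$gene))))
    return(list(class = "fusion", genes = genes))
  }
  if (delta == 0L && length(tr) > 0L) {
    return(list(class = "translocation", genes = sort(tr)))
  }
  if (delta == 0L && nrow(cmp$inverted) > 0L) {
    return(list(class = "inversion", genes = sort(cmp$inverted$gene)))
  }
  list(class = "none", genes = character())
}
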