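#' Maximal shared gene clusters between two karyotypes
#'
#' A shared cluster is a maximal run of two or more oriented genes that is
#' contiguous (non-coding regions ignored, other genes breaking contiguity)
#' in the circular gene order of a chromosome of each karyotype, in either
#' reading frame: a run and its full reversal (order flipped, every
#' orientation inverted) describe the same cluster, because a circular
#' molecule has no absolute strand. Runs spanning an entire chromosome on
#' both sides are flagged: such whole-chromosome clusters are shared
#' minichromosomes, the strongest of the derived characters.
#'
#' @param a,b [karyotype()] objects.
#' @param min_len Minimum run length in genes (default 2; singleton sharing
#'   is vacuous).
#' @return Tibble with one row per cluster: `cluster` (canonical
#'   dash-separated id), `genes` (list-column of signed tokens in the frame
#'   of `a`), `length`, `chromosome_a`, `start_a`, `chromosome_b`, `start_b`,
#'   `whole_a`, `whole_b`.
#' @export
#' @examples
#' k <- karyotype("toy", list(minichromosome("M1", c("E", "nad4L", "nad4"))))
#' shared_clusters(k, k)
shared_clusters <- function(a, b, min_len = 2L) {
  stopifnot(inherits(a, "karyotype"), inherits(b, "karyotype"),
            min_len >= 2L)
  out <- list()
  for (ca in a$chromosomes) for (cb in b$chromosomes) {
    runs <- chromosome_shared_runs(ca, cb, min_len)
    if (!is.null(runs)) out[[length(out) + 1L]] <- runs
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      cluster = character(), genes = list(), length = integer(),
      chromosome_a = character(), start_a = integer(),
      chromosome_b = character(), start_b = integer(),
      whole_a = logical(), whole_b = logical()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$cluster, .data$chromosome_a, .data$start_a)
}

# Maximal common oriented circular runs between one chromosome of each side.
chromosome_shared_runs <- function(ca, cb, min_len) {
  A <- mc_genes(ca)
  B <- mc_genes(cb)
  n <- nrow(A)
  m <- nrow(B)
  if (n < 2L || m < 2L) return(NULL)
  posB <- stats::setNames(seq_len(m), B$gene)
  nxt <- function(i, k) (i %% k) + 1L
  # edge i: adjacency A[i] -> A[next(i)]; matched forward / in flipped frame
  eF <- logical(n)
  eR <- logical(n)
  for (i in seq_len(n)) {
    j <- nxt(i, n)
    g <- A$gene[i]; h <- A$gene[j]
    p <- posB[g]; q <- posB[h]
    if (is.na(p) || is.na(q)) next
    eF[i] <- (nxt(p, m) == q) &&
      B$strand[p] == A$strand[i] && B$strand[q] == A$strand[j]
    eR[i] <- (nxt(q, m) == p) &&
      B$strand[p] == -A$strand[i] && B$strand[q] == -A$strand[j]
  }
  runs <- rbind(circular_true_runs(eF), circular_true_runs(eR))
  if (is.null(runs) || nrow(runs) == 0L) return(NULL)
  # drop runs strictly contained in a longer run found in the other frame
  keep <- rep(TRUE, nrow(runs))
  covered <- function(r, s) {
    # is edge-interval r contained in s? compare covered edge sets
    er <- ((r[1] - 1L + seq_len(r[2])) - 1L) %% n + 1L
    es <- ((s[1] - 1L + seq_len(s[2])) - 1L) %% n + 1L
    all(er %in% es)
  }
  for (i in seq_len(nrow(runs))) for (j in seq_len(nrow(runs))) {
    if (i != j && runs[i, 2] < runs[j, 2] &&
        covered(runs[i, ], runs[j, ])) keep[i] <- FALSE
  }
  runs <- runs[keep, , drop = FALSE]
  res <- list()
  seen <- character()
  for (r in seq_len(nrow(runs))) {
    s <- runs[r, 1]
    len_e <- runs[r, 2]
    whole_a <- len_e >= n
    ng <- if (whole_a) n else len_e + 1L
    if (ng < min_len) next
    idx <- ((s - 1L + seq_len(ng) - 1L) %% n) + 1L
    genes <- A$gene[idx]
    strands <- A$strand[idx]
    tok <- signed_tokens(genes, strands)
    rv <- reverse_signed(genes, strands)
    tokr <- signed_tokens(rv$gene, rv$strand)
    cl <- if (whole_a) {
      paste(canonical_form(ca), collapse = "-")
    } else {
      min(paste(tok, collapse = "-"), paste(tokr, collapse = "-"))
    }
    whole_b <- ng == m
    key <- paste(cl, ca$label, cb$label)
    if (key %in% seen) next
    seen <- c(seen, key)
    sb <- unname(posB[genes[1L]])
    res[[length(res) + 1L]] <- tibble::tibble(
      cluster = cl, genes = list(tok), length = ng,
      chromosome_a = ca$label, start_a = idx[1L],
      chromosome_b = cb$label, start_b = sb,
      whole_a = whole_a, whole_b = whole_b)
  }
  if (length(res) == 0L) return(NULL)
  dplyr::bind_rows(res)
}

# maximal circular runs of TRUE: matrix with columns (start, length), where
# start indexes the first TRUE edge; a full circle collapses to one run
circular_true_runs <- function(e) {
  n <- length(e)
  if (!any(e)) return(NULL)
  if (all(e)) return(matrix(c(1L, n), 1L, 2L))
  # rotate so position 1 is FALSE, then scan linear runs
  off <- which(!e)[1L]
  er <- e[((seq_len(n) - 1L + off - 1L) %% n) + 1L]
  r <- rle(er)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- cbind(starts[r$values], r$lengths[r$values])
  # map back to original indexing
  res[, 1] <- ((res[, 1] - 1L + off - 1L) %% n) + 1L
  res
}

#' Screen shared clusters against a reference arrangement
#'
#' Retains only the clusters that do not occur (same contiguity and relative
#' orientation semantics, rotation- and reversal-aware) in a designated
#' reference karyotype. A cluster absent from the reference arrangement is a
#' derived character: a candidate synapomorphy created by the fragmentation
#' or rearrangement history rather than retained from the ancestor.
#'
#' @param clusters Tibble from [shared_clusters()].
#' @param reference A [karyotype()] holding the reference (e.g. ancestral or
#'   outgroup) arrangement.
#' @return The subset of `clusters` not present in `reference`.
#' @export
derived_clusters <- function(clusters, reference) {
  stopifnot(inherits(reference, "karyotype"))
  if (nrow(clusters) == 0L) return(clusters)
  keep <- !vapply(clusters$genes, function(tok) {
    karyotype_contains_run(reference, tok)
  }, logical(1L))
  clusters[keep, , drop = FALSE]
}

# does any chromosome of k contain the signed run (in either frame)?
karyotype_contains_run <- function(k, tokens) {
  for (mc in k$chromosomes) {
    g <- mc_genes(mc)
    n <- nrow(g)
    if (n < length(tokens)) next
    frames <- list(
      signed_tokens(g$gene, g$strand),
      {
        rv <- reverse_signed(g$gene, g$strand)
        signed_tokens(rv$gene, rv$strand)
      }
    )
    for (fr in frames) {
      doubled <- c(fr, fr)
      for (s in seq_len(n)) {
        if (identical(doubled[s:(s + length(tokens) - 1L)], tokens)) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}
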