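#' Chromosome homology between two karyotypes
#'
#' Pairs the chromosomes of two karyotypes by shared gene content, using an
#' exact maximum-weight one-to-one matching in which the weight of a pair is
#' the number of genes the two chromosomes share. Zero-weight pairings are
#' excluded; ties between optimal matchings are broken deterministically
#' toward the lexicographically smallest `(label_a, label_b)` pairs.
#'
#' @param a,b [karyotype()] objects sharing at least one gene.
#' @return A list of class `chromosome_homology`: `pairs` (tibble `label_a`,
#'   `label_b`, `weight`), `unmatched_a`, `unmatched_b` (label vectors) and
#'   `weight_matrix`.
#' @export
#' @examples
#' k <- karyotype("toy", list(minichromosome("M1", c("E", "nad4L", "nad4"))))
#' match_chromosomes(k, k)$pairs
match_chromosomes <- function(a, b) {
  stopifnot(inherits(a, "karyotype"), inherits(b, "karyotype"))
  ga <- lapply(a$chromosomes, function(m) mc_genes(m)$gene)
  gb <- lapply(b$chromosomes, function(m) mc_genes(m)$gene)
  if (length(intersect(unlist(ga), unlist(gb))) == 0L) {
    stop("karyotypes share no gene: no homology can be established",
         call. = FALSE)
  }
  la <- sort(names(ga))
  lb <- sort(names(gb))
  w <- matrix(0L, length(la), length(lb), dimnames = list(la, lb))
  for (i in la) for (j in lb) {
    w[i, j] <- length(intersect(ga[[i]], gb[[j]]))
  }
  n <- length(la)
  memo <- new.env(parent = emptyenv())
  # best total weight matching A chromosomes i..n into the B subset `mask`
  best <- function(i, mask) {
    if (i > n) return(0L)
    key <- paste0(i, ":", paste(mask, collapse = ""))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- best(i + 1L, mask) # leave A[i] unmatched
    for (j in seq_along(lb)) {
      if (mask[j] && w[i, j] > 0L) {
        m2 <- mask
        m2[j] <- FALSE
        res <- max(res, w[i, j] + best(i + 1L, m2))
      }
    }
    memo[[key]] <- res
    res
  }
  mask <- rep(TRUE, length(lb))
  total <- best(1L, mask)
  pairs <- list()
  for (i in seq_len(n)) {
    taken <- FALSE
    for (j in seq_along(lb)) {
      if (mask[j] && w[i, j] > 0L) {
        m2 <- mask
        m2[j] <- FALSE
        if (w[i, j] + best(i + 1L, m2) == total) {
          pairs[[length(pairs) + 1L]] <-
            tibble::tibble(label_a = la[i], label_b = lb[j],
                           weight = w[i, j])
          total <- total - w[i, j]
          mask <- m2
          taken <- TRUE
          break
        }
      }
    }
    if (!taken && best(i + 1L, mask) != total) {
      stop("internal error in matching reconstruction") # nocov
    }
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(label_a = character(), label_b = character(),
                   weight = integer())
  structure(
    list(
      pairs = pairs,
      unmatched_a = setdiff(la, pairs$label_a),
      unmatched_b = setdiff(lb, pairs$label_b),
      weight_matrix = w
    ),
    class = "chromosome_homology"
  )
}

#' @export
print.chromosome_homology <- function(x, ...) {
  cat("<chromosome_homology> ", nrow(x$pairs), " pair(s)\n", sep = "")
  print(x$pairs)
  if (length(x$unmatched_a))
    cat("unmatched in A:", paste(x$unmatched_a, collapse = ", "), "\n")
  if (length(x$unmatched_b))
    cat("unmatched in B:", paste(x$unmatched_b, collapse = ", "), "\n")
  invisible(x)
}

#' Group unmatched chromosomes into split/merger units
#'
#' A chromosome left unmatched by [match_chromosomes()] is attributed to the
#' matched pair whose opposite-side partner shares the most genes with it
#' (ties broken by label). Each resulting one-versus-many group is the
#' signature of a chromosome split on one side or a merger on the other,
#' e.g. one chromosome of one species relating to two minichromosomes of its
#' congener. Unmatched chromosomes sharing no gene with any partner are
#' flagged as orphans and left ungrouped.
#'
#' @param a,b [karyotype()] objects.
#' @param h A `chromosome_homology` from [match_chromosomes()]; recomputed
#'   when `NULL`.
#' @return A list with `groups` (tibble: `one_side`, `one_label`,
#'   `many_labels` list-column) and `orphans` (tibble: `side`, `label`).
#' @export
detect_split_merge <- function(a, b, h = NULL) {
  if (is.null(h)) h <- match_chromosomes(a, b)
  ga <- lapply(a$chromosomes, function(m) mc_genes(m)$gene)
  gb <- lapply(b$chromosomes, function(m) mc_genes(m)$gene)
  attach_one <- function(label, side) {
    # genes of the unmatched chromosome
    genes <- if (side == "a") ga[[label]] else gb[[label]]
    if (nrow(h$pairs) == 0L) return(NA_character_)
    # share with the *partner* (opposite side) of every matched pair
    share <- vapply(seq_len(nrow(h$pairs)), function(k) {
      partner <- if (side == "a") gb[[h$pairs$label_b[k]]] else
        ga[[h$pairs$label_a[k]]]
      length(intersect(genes, partner))
    }, integer(1L))
    if (max(share) == 0L) return(NA_character_)
    cand <- which(share == max(share))
    anchor <- if (side == "a") h$pairs$label_a else h$pairs$label_b
    k <- cand[order(anchor[cand])][1L]
    paste0(h$pairs$label_a[k], "|", h$pairs$label_b[k])
  }
  att <- dplyr::bind_rows(
    tibble::tibble(side = "a", label = h$unmatched_a),
    tibble::tibble(side = "b", label = h$unmatched_b)
  )
  att$unit <- vapply(seq_len(nrow(att)), function(i) {
    attach_one(att$label[i], att$side[i])
  }, character(1L))
  orphans <- att[is.na(att$unit), c("side", "label")]
  att <- att[!is.na(att$unit), , drop = FALSE]
  groups <- list()
  for (u in unique(att$unit)) {
    lab <- strsplit(u, "|", fixed = TRUE)[[1]]
    add_a <- att$label[att$unit == u & att$side == "a"]
    add_b <- att$label[att$unit == u & att$side == "b"]
    many_a <- sort(c(lab[1], add_a))
    many_b <- sort(c(lab[2], add_b))
    if (length(many_a) == 1L) {
      groups[[length(groups) + 1L]] <- tibble::tibble(
        one_side = "a", one_label = many_a,
        many_side = "b", many_labels = list(many_b))
    } else if (length(many_b) == 1L) {
      groups[[length(groups) + 1L]] <- tibble::tibble(
        one_side = "b", one_label = many_b,
        many_side = "a", many_labels = list(many_a))
    } else {
      # attachments on both sides of one pair: report as a many-vs-many unit
      groups[[length(groups) + 1L]] <- tibble::tibble(
        one_side = "a", one_label = many_a[1],
        many_side = "b", many_labels = list(many_b))
    }
  }
  groups <- if (length(groups)) dplyr::bind_rows(groups) else
    tibble::tibble(one_side = character(), one_label = character(),
                   many_side = character(), many_labels = list())
  list(groups = groups, orphans = tibble::as_tibble(orphans))
}

# Homologous-unit assignment used by the gene-level classifiers.
# Returns per-side named vectors: chromosome label -> unit id (NA = orphan),
# plus, per B chromosome, the A chromosome anchoring its reading frame.
homology_units <- function(a, b, h, sm) {
  unit_a <- stats::setNames(rep(NA_character_, length(a$chromosomes)),
                            names(a$chromosomes))
  unit_b <- stats::setNames(rep(NA_character_, length(b$chromosomes)),
                            names(b$chromosomes))
  frame_anchor <- stats::setNames(rep(NA_character_, length(b$chromosomes)),
                                  names(b$chromosomes))
  if (nrow(h$pairs) > 0L) {
    for (k in seq_len(nrow(h$pairs))) {
      u <- paste0(h$pairs$label_a[k], "|", h$pairs$label_b[k])
      unit_a[h$pairs$label_a[k]] <- u
      unit_b[h$pairs$label_b[k]] <- u
      frame_anchor[h$pairs$label_b[k]] <- h$pairs$label_a[k]
    }
  }
  if (nrow(sm$groups) > 0L) {
    for (k in seq_len(nrow(sm$groups))) {
      g <- sm$groups[k, ]
      if (g$one_side == "a") {
        u <- unit_a[g$one_label]
        for (lb in g$many_labels[[1]]) {
          unit_b[lb] <- u
          if (is.na(frame_anchor[lb])) frame_anchor[lb] <- g$one_label
        }
      } else {
        u <- unit_b[g$one_label]
        for (la in g$many_labels[[1]]) unit_a[la] <- u
      }
    }
  }
  list(unit_a = unit_a, unit_b = unit_b, frame_anchor = frame_anchor)
}
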