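#' Parse a Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]: requires uniquely
#' labelled tips, balanced parentheses, and fills in unit branch lengths when
#' the source tree carries none. Polytomies are accepted.
#'
#' @param text Newick string (or vector of lines forming one).
#' @return An [ape::read.tree()] `phylo` object, rooted as written.
#' @export
#' @examples
#' parse_newick("((A,B),(C,D));")
parse_newick <- function(text) {
  txt <- paste(text, collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string", call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

# tip states as an integer vector (0/1) ordered like tree$tip.label;
# accepts a named vector or a two-column data frame (tip, state)
as_tip_states <- function(tree, states) {
  if (is.data.frame(states)) {
    tipcol <- intersect(c("tip", "species_id", "label"), names(states))[1]
    if (is.na(tipcol) || !"state" %in% names(states)) {
      stop("tip-state table needs a tip/species_id column and a state column",
           call. = FALSE)
    }
    states <- stats::setNames(states$state, states[[tipcol]])
  }
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss) > 0L) {
    stop("missing state for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s <- as.integer(states[tree$tip.label])
  if (any(!s %in% c(0L, 1L))) {
    stop("states must be 0 (single) or 1 (fragmented)", call. = FALSE)
  }
  stats::setNames(s, tree$tip.label)
}

#' Minimum number of independent fragmentation origins on a tree
#'
#' Counts state changes of the binary fragmentation character under Fitch
#' parsimony (unit-cost Sankoff dynamic programming, so polytomies are
#' handled natively) and reports the number of gains (0 to 1 transitions,
#' i.e. independent origins of the fragmented state) across all
#' most-parsimonious reconstructions. By default the root is constrained to
#' state 0, reflecting that the single-chromosome organization is ancestral
#' to animals; pass `root_state = NA` for an unconstrained root.
#'
#' When losses are deemed biologically implausible (a fragmented genome
#' reassembling into one circle), set `irreversible = TRUE`: 1 -> 0 edges
#' are then forbidden and the count is the minimum number of independent
#' gains explaining the tips, the reading under which origin tallies like
#' "two origins on this topology, three on that one" are made.
#'
#' @param tree A rooted `phylo`.
#' @param states Tip states (named 0/1 vector or tibble `tip`/`state`).
#' @param root_state 0, 1, or `NA` (unconstrained).
#' @param irreversible Forbid 1 -> 0 changes (Camin-Sokal style counting).
#' @return List: `score` (parsimony score under the root constraint),
#'   `min_gains`, `max_gains` (range of 0->1 edges over all MPRs),
#'   `root_state`.
#' @export
#' @examples
#' tr <- parse_newick("((sp1,sp3),(sp2,tinnunculi));")
#' st <- c(sp1 = 0, sp3 = 0, sp2 = 0, tinnunculi = 1)
#' fitch_origins(tr, st)$min_gains
fitch_origins <- function(tree, states, root_state = 0,
                          irreversible = FALSE) {
  s <- as_tip_states(tree, states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tot <- ntip + nnode
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(INF, tot, 2L)
  gmin <- matrix(0L, tot, 2L)
  gmax <- matrix(0L, tot, 2L)
  for (i in seq_len(ntip)) {
    cost[i, s[i] + 1L] <- 0L
  }
  # postorder over internal nodes
  ord <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
  for (v in ord) {
    for (sv in 0:1) {
      tot_cost <- 0L
      tot_gmin <- 0L
      tot_gmax <- 0L
      for (c in kids[[as.character(v)]]) {
        opts <- vapply(0:1, function(t) {
          edge_cost <- if (sv == t) 0L else
            if (irreversible && sv == 1L && t == 0L) INF else 1L
          min(cost[c, t + 1L] + edge_cost, INF)
        }, integer(1L))
        mc <- min(opts)
        tot_cost <- tot_cost + mc
        ts <- which(opts == mc) - 1L
        gm <- vapply(ts, function(t) {
          gmin[c, t + 1L] + as.integer(sv == 0L && t == 1L)
        }, integer(1L))
        gM <- vapply(ts, function(t) {
          gmax[c, t + 1L] + as.integer(sv == 0L && t == 1L)
        }, integer(1L))
        tot_gmin <- tot_gmin + min(gm)
        tot_gmax <- tot_gmax + max(gM)
      }
      cost[v, sv + 1L] <- tot_cost
      gmin[v, sv + 1L] <- tot_gmin
      gmax[v, sv + 1L] <- tot_gmax
    }
  }
  allowed <- if (is.na(root_state)) 0:1 else as.integer(root_state)
  sc <- min(cost[root, allowed + 1L])
  opt <- allowed[cost[root, allowed + 1L] == sc]
  list(
    score = sc,
    min_gains = min(gmin[root, opt + 1L]),
    max_gains = max(gmax[root, opt + 1L]),
    root_state = root_state
  )
}

#' Tally independent fragmentation origins across lineage groups
#'
#' Sums per-group minimum origin counts (each typically computed with
#' [fitch_origins()] on that group's subtree) into an overall "at least N
#' independent origins" statement, with the per-group breakdown retained.
#'
#' @param groups Tibble/data frame with columns `group` and `min_origins`,
#'   or a named numeric vector.
#' @return List: `total` (integer) and `breakdown` (tibble).
#' @export
#' @examples
#' origin_tally(c(`eutherian mammal lice` = 1, Amblycera = 4, Ischnocera = 9))
origin_tally <- function(groups) {
  if (is.data.frame(groups)) {
    bd <- tibble::tibble(group = groups$group,
                         min_origins = as.integer(groups$min_origins))
  } else if (length(groups) == 0L) {
    bd <- tibble::tibble(group = character(), min_origins = integer())
  } else {
    bd <- tibble::tibble(group = names(groups),
                         min_origins = as.integer(groups))
  }
  if (any(bd$min_origins < 0L)) {
    stop("origin counts must be non-negative", call. = FALSE)
  }
  list(total = sum(bd$min_origins), breakdown = bd)
}
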