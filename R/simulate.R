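#' Configuration for the karyotype evolution simulator
#'
#' Rates are expected events per unit branch length for each rearrangement
#' class. Moved or inverted segments take a length uniform on
#' `[1, max_block]` genes; cut, insertion and fusion positions are uniform
#' over inter-gene boundaries; reinsertion and fusion orientation is uniform
#' over the two frames. These distributions are simulator conventions: the
#' rearrangement vocabulary (split, merger, translocation, inversion) comes
#' from observed karyotype differences, which do not constrain the rates.
#'
#' @param fission,fusion,translocation,inversion Non-negative rates.
#' @param max_block Maximum length (genes) of a translocated or inverted
#'   block.
#' @param root_karyotype Root [karyotype()]; default is the full 37-gene
#'   complement on a single circular chromosome.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fission = 0.2, fusion = 0.1, translocation = 0.3,
                       inversion = 0.3, max_block = 3L,
                       root_karyotype = NULL) {
  rates <- c(fission = fission, fusion = fusion,
             translocation = translocation, inversion = inversion)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (max_block < 1L) stop("max_block must be >= 1", call. = FALSE)
  if (is.null(root_karyotype)) {
    root_karyotype <- karyotype(
      "root", list(minichromosome("M1", mt_gene_symbols())))
  }
  structure(
    list(rates = rates, max_block = as.integer(max_block),
         root_karyotype = root_karyotype),
    class = "sim_config"
  )
}

# --- element-level editing -------------------------------------------------
# chromosomes are edited as their `elements` tibbles; rotation is free on a
# circle, so blocks are always rotated into a non-wrapping frame first

rotate_rows <- function(el, k) {
  n <- nrow(el)
  if (n == 0L || k %% n == 0L) return(el)
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  el[idx, , drop = FALSE]
}

flip_rows <- function(el) {
  el <- el[rev(seq_len(nrow(el))), , drop = FALSE]
  el$strand <- -el$strand
  el
}

gene_rows <- function(el) which(el$type == "gene")

new_mc_from_elements <- function(label, el) {
  tok <- ifelse(el$type == "ncr", paste0("NCR:", el$length),
                paste0(ifelse(!is.na(el$strand) & el$strand < 0L, "-", ""),
                       el$gene))
  minichromosome(label, tok)
}

ncr_placeholder <- function() {
  tibble::tibble(type = "ncr", gene = NA_character_,
                 strand = NA_integer_, length = 1L)
}

#' Apply one rearrangement event to a karyotype
#'
#' Deterministic core of the simulator: applies a fully parameterized
#' fission, fusion, translocation or inversion. Gene content is conserved by
#' construction and asserted. Used both by [evolve_on_tree()] (which draws
#' the parameters) and by [replay_events()].
#'
#' @param k A [karyotype()].
#' @param class Event class.
#' @param params Named list of event parameters as recorded in the event
#'   log: fission needs `chrom`, `cut1` < `cut2` (gene positions cut after),
#'   `new_labels` (2); fusion needs `chrom1`, `chrom2`, `rot1`, `rot2`,
#'   `flip2`, `new_label`; translocation needs `chrom`, `start`, `len`,
#'   `dest`, `dest_pos`, `flip`; inversion needs `chrom`, `start`, `len`.
#' @return The rearranged [karyotype()].
#' @export
apply_event <- function(k, class, params) {
  before <- sort(karyotype_genes(k)$gene)
  chroms <- k$chromosomes
  if (class == "fission") {
    el <- chroms[[params$chrom]]$elements
    g <- gene_rows(el)
    r1 <- g[params$cut1]
    r2 <- g[params$cut2]
    seg1 <- el[(r1 + 1L):r2, , drop = FALSE]
    seg2_idx <- c(if (r2 < nrow(el)) (r2 + 1L):nrow(el), seq_len(r1))
    seg2 <- el[seg2_idx, , drop = FALSE]
    chroms[[params$chrom]] <- NULL
    chroms[[params$new_labels[1]]] <- new_mc_from_elements(
      params$new_labels[1], dplyr::bind_rows(seg1, ncr_placeholder()))
    chroms[[params$new_labels[2]]] <- new_mc_from_elements(
      params$new_labels[2], dplyr::bind_rows(seg2, ncr_placeholder()))
  } else if (class == "fusion") {
    el1 <- rotate_rows(chroms[[params$chrom1]]$elements, params$rot1)
    el2 <- rotate_rows(chroms[[params$chrom2]]$elements, params$rot2)
    if (isTRUE(params$flip2)) el2 <- flip_rows(el2)
    chroms[[params$chrom1]] <- NULL
    chroms[[params$chrom2]] <- NULL
    chroms[[params$new_label]] <- new_mc_from_elements(
      params$new_label, dplyr::bind_rows(el1, el2))
  } else if (class == "translocation") {
    el <- chroms[[params$chrom]]$elements
    g <- gene_rows(el)
    # rotate so the block starts at the first element row
    el <- rotate_rows(el, g[params$start] - 1L)
    g <- gene_rows(el)
    block_rows <- seq_len(g[params$len])
    block <- el[intersect(block_rows, gene_rows(el)), , drop = FALSE]
    rest <- el[-seq_len(g[params$len]), , drop = FALSE]
    if (isTRUE(params$flip)) block <- flip_rows(block)
    del <- chroms[[params$dest]]$elements
    gd <- gene_rows(del)
    at <- gd[params$dest_pos]
    del <- dplyr::bind_rows(
      del[seq_len(at), , drop = FALSE], block,
      if (at < nrow(del)) del[(at + 1L):nrow(del), , drop = FALSE])
    chroms[[params$chrom]] <- new_mc_from_elements(params$chrom, rest)
    chroms[[params$dest]] <- new_mc_from_elements(params$dest, del)
  } else if (class == "inversion") {
    el <- chroms[[params$chrom]]$elements
    g <- gene_rows(el)
    el <- rotate_rows(el, g[params$start] - 1L)
    g <- gene_rows(el)
    span <- seq_len(g[params$len])
    el[span, ] <- flip_rows(el[span, , drop = FALSE])
    chroms[[params$chrom]] <- new_mc_from_elements(params$chrom, el)
  } else {
    stop("unknown event class '", class, "'", call. = FALSE)
  }
  out <- karyotype(k$species_id, chroms, host = k$host)
  after <- sort(karyotype_genes(out)$gene)
  stopifnot(identical(before, after)) # conservation invariant
  out
}

# draw parameters for one event; NULL when the class is impossible
draw_event_params <- function(k, class, max_block, label_counter) {
  sizes <- vapply(k$chromosomes, function(m) nrow(mc_genes(m)), integer(1L))
  labs <- names(k$chromosomes)
  if (class == "fission") {
    ok <- labs[sizes >= 2L]
    if (length(ok) == 0L) return(NULL)
    chrom <- sample_one(ok)
    n <- sizes[chrom]
    cuts <- sort(sample.int(n, 2L))
    list(chrom = chrom, cut1 = cuts[1], cut2 = cuts[2],
         new_labels = paste0("c", label_counter + 1:2))
  } else if (class == "fusion") {
    if (length(labs) < 2L) return(NULL)
    pick <- sample(labs, 2L)
    list(chrom1 = pick[1], chrom2 = pick[2],
         rot1 = sample.int(nrow(k$chromosomes[[pick[1]]]$elements), 1L) - 1L,
         rot2 = sample.int(nrow(k$chromosomes[[pick[2]]]$elements), 1L) - 1L,
         flip2 = stats::runif(1) < 0.5,
         new_label = paste0("c", label_counter + 1L))
  } else if (class == "translocation") {
    ok <- labs[sizes >= 2L]
    if (length(labs) < 2L || length(ok) == 0L) return(NULL)
    chrom <- sample_one(ok)
    n <- sizes[chrom]
    len <- sample.int(min(max_block, n - 1L), 1L)
    dest <- sample_one(setdiff(labs, chrom))
    list(chrom = chrom, start = sample.int(n, 1L), len = len,
         dest = dest,
         dest_pos = sample.int(sizes[dest], 1L),
         flip = stats::runif(1) < 0.5)
  } else if (class == "inversion") {
    ok <- labs[sizes >= 2L]
    if (length(ok) == 0L) return(NULL)
    chrom <- sample_one(ok)
    n <- sizes[chrom]
    len <- sample.int(min(max_block, n - 1L), 1L)
    list(chrom = chrom, start = sample.int(n, 1L), len = len)
  }
}

sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Evolve karyotypes along a tree
#'
#' Simulates mitochondrial karyotype evolution: on each branch the number of
#' events is Poisson with mean `total rate x branch length`, each event's
#' class is drawn proportionally to the configured rates, and its parameters
#' are drawn uniformly (see [sim_config()]). Impossible draws (e.g. a fusion
#' on a single-chromosome genome) are resampled and recorded as skipped.
#' Gene content is conserved by every event. Identical seeds give identical
#' output.
#'
#' @param tree A rooted `phylo`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed (required for reproducibility).
#' @return List of class `karyo_sim`: `node_karyotypes` (list indexed by
#'   node number; tips carry tip labels as species ids), `tip_karyotypes`,
#'   `events` (tibble log with one row per applied or skipped event), and
#'   the inputs.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' sim <- evolve_on_tree(tr, sim_config(), seed = 1)
#' names(sim$tip_karyotypes)
evolve_on_tree <- function(tree, cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  total_rate <- sum(cfg$rates)
  karyos <- vector("list", ntip + tree$Nnode)
  karyos[[root]] <- cfg$root_karyotype
  log <- list()
  label_counter <- 0L
  edge_ord <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_len <- tree$edge.length[match(
    paste(edge_ord[, 1], edge_ord[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2]))]
  for (k in seq_len(nrow(edge_ord))) {
    u <- edge_ord[k, 1]
    v <- edge_ord[k, 2]
    cur <- karyos[[u]]
    n_ev <- if (total_rate > 0) stats::rpois(1L, total_rate * edge_len[k])
            else 0L
    if (n_ev > 0L) {
      for (i in seq_len(n_ev)) {
        applied <- FALSE
        for (try in seq_len(20L)) {
          class <- sample(names(cfg$rates), 1L,
                          prob = cfg$rates / total_rate)
          params <- draw_event_params(cur, class, cfg$max_block,
                                      label_counter)
          if (is.null(params)) {
            log[[length(log) + 1L]] <- tibble::tibble(
              node = v, event = i, class = class, skipped = TRUE,
              genes = list(character()), params = list(NULL))
            next
          }
          if (class == "fission") label_counter <- label_counter + 2L
          if (class == "fusion") label_counter <- label_counter + 1L
          block <- event_gene_block(cur, class, params)
          cur <- apply_event(cur, class, params)
          log[[length(log) + 1L]] <- tibble::tibble(
            node = v, event = i, class = class, skipped = FALSE,
            genes = list(block), params = list(params))
          applied <- TRUE
          break
        }
      }
    }
    cur$species_id <- if (v <= ntip) tree$tip.label[v] else paste0("node", v)
    karyos[[v]] <- cur
  }
  tips <- karyos[seq_len(ntip)]
  names(tips) <- tree$tip.label
  structure(
    list(
      node_karyotypes = karyos,
      tip_karyotypes = tips,
      events = if (length(log)) dplyr::bind_rows(log) else
        tibble::tibble(node = integer(), event = integer(),
                       class = character(), skipped = logical(),
                       genes = list(), params = list()),
      tree = tree, config = cfg, seed = seed
    ),
    class = "karyo_sim"
  )
}

# the gene block an event touches, for ground-truth bookkeeping
event_gene_block <- function(k, class, params) {
  if (class == "fission") {
    el <- k$chromosomes[[params$chrom]]$elements
    g <- gene_rows(el)
    seg1 <- el[(g[params$cut1] + 1L):g[params$cut2], , drop = FALSE]
    sort(seg1$gene[seg1$type == "gene"])
  } else if (class == "fusion") {
    sort(mc_genes(k$chromosomes[[params$chrom2]])$gene)
  } else {
    g <- mc_genes(k$chromosomes[[params$chrom]])
    idx <- ((params$start - 1L + seq_len(params$len) - 1L) %% nrow(g)) + 1L
    sort(g$gene[idx])
  }
}

#' Replay an event log from a root karyotype
#'
#' Reapplies the logged (non-skipped) events branch by branch, reproducing
#' every node's karyotype exactly; used to verify that the event log is a
#' complete, deterministic description of a simulation.
#'
#' @param sim A `karyo_sim` from [evolve_on_tree()].
#' @return List of node karyotypes in the same layout as
#'   `sim$node_karyotypes`.
#' @export
replay_events <- function(sim) {
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  karyos <- vector("list", ntip + tree$Nnode)
  karyos[[root]] <- sim$config$root_karyotype
  edge_ord <- ape::reorder.phylo(tree, "cladewise")$edge
  ev <- sim$events[!sim$events$skipped, , drop = FALSE]
  for (k in seq_len(nrow(edge_ord))) {
    u <- edge_ord[k, 1]
    v <- edge_ord[k, 2]
    cur <- karyos[[u]]
    rows <- which(ev$node == v)
    for (r in rows) {
      cur <- apply_event(cur, ev$class[r], ev$params[[r]])
    }
    cur$species_id <- if (v <= ntip) tree$tip.label[v] else paste0("node", v)
    karyos[[v]] <- cur
  }
  karyos
}

#' Simulate the binary fragmentation character on a tree
#'
#' Forward simulation of the two-state chain: the root draws its state (or
#' takes `root_state`), and each branch transitions with the closed-form
#' probabilities of the model.
#'
#' @param tree A rooted `phylo`.
#' @param model An [mk_model()].
#' @param root_state 0, 1, or `NA` to draw from the model's root prior.
#' @param seed Integer seed.
#' @return Named integer vector of tip states (0/1), plus attribute
#'   `node_states` with the internal-node states.
#' @export
simulate_binary_character <- function(tree, model, root_state = 0,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- integer(ntip + tree$Nnode)
  states[root] <- if (is.na(root_state)) {
    stats::rbinom(1L, 1L, mk_root_prior(model)[2])
  } else as.integer(root_state)
  edge_ord <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_len <- tree$edge.length[match(
    paste(edge_ord[, 1], edge_ord[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2]))]
  for (k in seq_len(nrow(edge_ord))) {
    u <- edge_ord[k, 1]
    v <- edge_ord[k, 2]
    P <- mk_pmat(model$q01, model$q10, edge_len[k])
    states[v] <- stats::rbinom(1L, 1L, P[states[u] + 1L, 2L])
  }
  out <- stats::setNames(states[seq_len(ntip)], tree$tip.label)
  attr(out, "node_states") <- states[(ntip + 1L):(ntip + tree$Nnode)]
  out
}

#' An integration-scale synthetic dataset of louse-like karyotype evolution
#'
#' Builds a 23-tip study system modelled on a two-family bird-louse
#' phylogeny: a 19-tip ingroup in five clades (3, 2, 2, 2 and 10 tips) plus
#' a 4-tip outgroup, unit branch lengths. The binary fragmentation character
#' is placed with three irreversible gains (the common ancestor of clades 2
#' and 3, one tip of clade 4, and one outgroup tip), and karyotypes are
#' evolved from a single 37-gene circular root chromosome.
#'
#' @param seed Integer seed.
#' @return List: `tree`, `states` (tibble `tip`, `state`), `n_gains`,
#'   `gain_tips` (tips carrying the derived state), `sim` (a `karyo_sim`).
#' @export
make_paper_like_dataset <- function(seed = 1L) {
  clade1 <- "(in01:1,(in02:1,in03:1):1)"
  clade2 <- "(in04:1,in05:1)"
  clade3 <- "(in06:1,in07:1)"
  clade4 <- "(in08:1,in09:1)"
  clade5 <- paste0(
    "(in10:1,(in11:1,(in12:1,(in13:1,(in14:1,(in15:1,(in16:1,(in17:1,",
    "(in18:1,in19:1):1):1):1):1):1):1):1):1)")
  out <- "((out1:1,out2:1):1,(out3:1,out4:1):1)"
  nwk <- paste0(
    "(", out, ":1,(", clade5, ":1,(", clade1, ":1,((", clade2, ":1,",
    clade3, ":1):1,", clade4, ":1):1):1):1);")
  tree <- parse_newick(nwk)
  frag <- c("in04", "in05", "in06", "in07", "in09", "out4")
  states <- tibble::tibble(
    tip = tree$tip.label,
    state = as.integer(tree$tip.label %in% frag)
  )
  sim <- evolve_on_tree(tree, sim_config(), seed = seed)
  list(tree = tree, states = states, n_gains = 3L, gain_tips = frag,
       sim = sim)
}
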