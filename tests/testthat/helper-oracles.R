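# Random generators and independent brute-force oracles used across the
# suite. The oracles deliberately share no code with the implementation:
# occurrence checks are done by doubled-string search, matchings by
# exhaustive enumeration, tree likelihoods by summing over all internal
# state assignments.

random_karyotype <- function(n_genes = 10L, n_chrom = 3L,
                             rev_prob = 0.3, ncr_prob = 0.2) {
  genes <- sample(mt_genes()$gene, n_genes)
  cuts <- sort(sample(seq_len(n_genes - 1L), n_chrom - 1L))
  bounds <- c(0L, cuts, n_genes)
  chroms <- lapply(seq_len(n_chrom), function(i) {
    g <- genes[(bounds[i] + 1L):bounds[i + 1L]]
    tok <- paste0(ifelse(stats::runif(length(g)) < rev_prob, "-", ""), g)
    if (stats::runif(1) < ncr_prob) {
      at <- sample(length(tok), 1L)
      tok <- append(tok, paste0("NCR:", sample(50:500, 1L)), after = at)
    }
    minichromosome(paste0("K", i), tok)
  })
  karyotype("rand", chroms)
}

# signed-token circular sequence of a chromosome (written frame)
mc_tokens <- function(mc) {
  g <- mitokaryo:::mc_genes(mc)
  paste0(ifelse(g$strand < 0, "-", ""), g$gene)
}

flip_tokens <- function(tok) {
  core <- sub("^-", "", rev(tok))
  neg <- !grepl("^-", rev(tok))
  paste0(ifelse(neg, "-", ""), core)
}

canonical_run_id <- function(tok) {
  min(paste(tok, collapse = "-"), paste(flip_tokens(tok), collapse = "-"))
}

# canonical id of a whole circle: least over all rotations of both frames
canonical_circle_id <- function(tok) {
  n <- length(tok)
  ids <- character()
  for (fr in list(tok, flip_tokens(tok))) {
    for (r in seq_len(n)) {
      rot <- fr[((seq_len(n) - 1 + r - 1) %% n) + 1]
      ids <- c(ids, paste(rot, collapse = "-"))
    }
  }
  min(ids)
}

# does `run` occur contiguously (circularly, either frame) in chromosome cb?
oracle_run_occurs <- function(run, cb) {
  tok <- mc_tokens(cb)
  m <- length(tok)
  if (length(run) > m) return(FALSE)
  for (fr in list(tok, flip_tokens(tok))) {
    doubled <- c(fr, fr)
    for (s in seq_len(m)) {
      if (identical(doubled[s:(s + length(run) - 1L)], run)) return(TRUE)
    }
  }
  FALSE
}

# brute-force maximal common runs between two chromosomes -> canonical ids
oracle_shared_runs <- function(ca, cb, min_len = 2L) {
  tok <- mc_tokens(ca)
  n <- length(tok)
  if (n < min_len) return(character())
  doubled <- c(tok, tok)
  common <- list()
  for (s in seq_len(n)) {
    for (len in min_len:n) {
      run <- doubled[s:(s + len - 1L)]
      if (oracle_run_occurs(run, cb)) {
        common[[length(common) + 1L]] <- c(s, len)
      }
    }
  }
  if (length(common) == 0L) return(character())
  keep <- vapply(common, function(r) {
    if (r[2] == n) return(TRUE)
    # extensible on either end (still common) => not maximal
    left <- c(((r[1] - 2L) %% n) + 1L, r[2] + 1L)
    ext <- function(rr) {
      if (rr[2] > n) return(FALSE)
      oracle_run_occurs(doubled[rr[1]:(rr[1] + rr[2] - 1L)], cb)
    }
    !ext(c(r[1], r[2] + 1L)) && !ext(left)
  }, logical(1L))
  ids <- vapply(common[keep], function(r) {
    run <- doubled[r[1]:(r[1] + r[2] - 1L)]
    if (r[2] == n) canonical_circle_id(run) else canonical_run_id(run)
  }, character(1L))
  sort(unique(ids))
}

oracle_all_shared_runs <- function(a, b, min_len = 2L) {
  ids <- character()
  for (ca in a$chromosomes) for (cb in b$chromosomes) {
    ids <- c(ids, oracle_shared_runs(ca, cb, min_len))
  }
  sort(unique(ids))
}

# exhaustive maximum-weight one-to-one matching value
oracle_matching_weight <- function(a, b) {
  ga <- lapply(a$chromosomes, function(m) mitokaryo:::mc_genes(m)$gene)
  gb <- lapply(b$chromosomes, function(m) mitokaryo:::mc_genes(m)$gene)
  n <- length(ga)
  m <- length(gb)
  w <- outer(seq_len(n), seq_len(m), Vectorize(function(i, j) {
    length(intersect(ga[[i]], gb[[j]]))
  }))
  best <- 0L
  assign_next <- function(i, used, acc) {
    if (i > n) {
      best <<- max(best, acc)
      return(invisible())
    }
    assign_next(i + 1L, used, acc) # skip
    for (j in seq_len(m)) {
      if (!used[j] && w[i, j] > 0L) {
        used[j] <- TRUE
        assign_next(i + 1L, used, acc + w[i, j])
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, m), 0L)
  best
}

# enumerate internal labelings: minimum changes + gain range, root fixed
oracle_fitch <- function(tree, states, root_state = 0) {
  s <- mitokaryo:::as_tip_states(tree, states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  combos <- expand.grid(rep(list(0:1), nnode))
  best <- Inf
  gains <- integer()
  for (r in seq_len(nrow(combos))) {
    lab <- c(s, as.integer(combos[r, ]))
    if (!is.na(root_state) && lab[ntip + 1L] != root_state) next
    ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    g <- sum(lab[tree$edge[, 1]] == 0L & lab[tree$edge[, 2]] == 1L)
    if (ch < best) {
      best <- ch
      gains <- g
    } else if (ch == best) {
      gains <- c(gains, g)
    }
  }
  list(score = best, min_gains = min(gains), max_gains = max(gains))
}

# enumerate internal labelings: exact Mk likelihood
oracle_mk_loglik <- function(tree, states, model) {
  s <- mitokaryo:::as_tip_states(tree, states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  prior <- mitokaryo:::mk_root_prior(model)
  combos <- expand.grid(rep(list(0:1), nnode))
  lik <- 0
  for (r in seq_len(nrow(combos))) {
    lab <- c(s, as.integer(combos[r, ]))
    p <- prior[lab[ntip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      P <- mitokaryo:::mk_pmat(model$q01, model$q10, tree$edge.length[e])
      p <- p * P[lab[tree$edge[e, 1]] + 1L, lab[tree$edge[e, 2]] + 1L]
    }
    lik <- lik + p
  }
  log(lik)
}

# enumerate internal labelings: exact marginal P(state | tips) per node
oracle_marginals <- function(tree, states, model) {
  s <- mitokaryo:::as_tip_states(tree, states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  prior <- mitokaryo:::mk_root_prior(model)
  combos <- expand.grid(rep(list(0:1), nnode))
  post <- matrix(0, nnode, 2L)
  for (r in seq_len(nrow(combos))) {
    lab <- c(s, as.integer(combos[r, ]))
    p <- prior[lab[ntip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      P <- mitokaryo:::mk_pmat(model$q01, model$q10, tree$edge.length[e])
      p <- p * P[lab[tree$edge[e, 1]] + 1L, lab[tree$edge[e, 2]] + 1L]
    }
    for (v in seq_len(nnode)) {
      post[v, lab[ntip + v] + 1L] <- post[v, lab[ntip + v] + 1L] + p
    }
  }
  sweep(post, 1L, rowSums(post), "/")
}

# a random rooted tree with exponential-ish branch lengths
random_tree <- function(ntip, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(ntip)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  tr
}

# root karyotype used by the event-recovery harness: four chromosomes over
# the full 37-gene complement (sizes 10/10/9/8)
recovery_root <- function() {
  g <- mt_genes()$gene
  karyotype("root", list(
    minichromosome("A", g[1:10]),
    minichromosome("B", g[11:20]),
    minichromosome("C", g[21:29]),
    minichromosome("D", g[30:37])
  ))
}

# expected recovered gene set for each event class
expected_event_genes <- function(k, class, params) {
  if (class == "fission") {
    sort(mitokaryo:::mc_genes(k$chromosomes[[params$chrom]])$gene)
  } else if (class == "fusion") {
    sort(c(mitokaryo:::mc_genes(k$chromosomes[[params$chrom1]])$gene,
           mitokaryo:::mc_genes(k$chromosomes[[params$chrom2]])$gene))
  } else {
    mitokaryo:::event_gene_block(k, class, params)
  }
}
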