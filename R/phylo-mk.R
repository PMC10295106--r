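#' Two-state Markov (Mk) model of the fragmentation character
#'
#' Continuous-time 2-state Markov chain for a binary character on a tree:
#' `Mk1` has one symmetric rate (`q01 = q10`), `AsymmMk` has separate gain
#' (`q01`, single to fragmented) and loss (`q10`) rates, in expected events
#' per unit branch length.
#'
#' @param kind `"Mk1"` or `"AsymmMk"`.
#' @param q01 Gain rate (0 -> 1), `>= 0`.
#' @param q10 Loss rate (1 -> 0); ignored (set to `q01`) for Mk1.
#' @param root_prior `"uniform"` (0.5/0.5, the conventional default for
#'   likelihood ancestral state reconstruction), `"stationary"`, or a
#'   probability pair `c(p0, p1)`.
#' @return An object of class `mk_model`.
#' @export
#' @examples
#' mk_model("Mk1", q01 = 0.1)
mk_model <- function(kind = c("Mk1", "AsymmMk"), q01, q10 = q01,
                     root_prior = "uniform") {
  kind <- match.arg(kind)
  if (kind == "Mk1") q10 <- q01
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0", call. = FALSE)
  structure(
    list(kind = kind, q01 = q01, q10 = q10, root_prior = root_prior),
    class = "mk_model"
  )
}

#' @export
print.mk_model <- function(x, ...) {
  cat("<mk_model ", x$kind, "> q01 = ", signif(x$q01, 6),
      ", q10 = ", signif(x$q10, 6), "\n", sep = "")
  invisible(x)
}

mk_root_prior <- function(model) {
  if (is.numeric(model$root_prior)) {
    p <- model$root_prior
    if (length(p) != 2L || abs(sum(p) - 1) > 1e-9) {
      stop("root prior must be a probability pair summing to 1",
           call. = FALSE)
    }
    return(p)
  }
  switch(model$root_prior,
    uniform = c(0.5, 0.5),
    stationary = {
      tot <- model$q01 + model$q10
      if (tot == 0) c(0.5, 0.5) else c(model$q10, model$q01) / tot
    },
    stop("unknown root prior '", model$root_prior, "'", call. = FALSE)
  )
}

# closed-form 2x2 transition probability matrix over time t
mk_pmat <- function(q01, q10, t) {
  tot <- q01 + q10
  if (tot == 0 || t == 0) return(diag(2))
  e <- exp(-tot * t)
  matrix(c(
    (q10 + q01 * e) / tot, (q01 - q01 * e) / tot,
    (q10 - q10 * e) / tot, (q01 + q10 * e) / tot
  ), 2L, 2L, byrow = TRUE)
}

# scaled postorder partial likelihoods; returns list(partials, logscale)
mk_partials <- function(tree, s, model) {
  ntip <- length(tree$tip.label)
  tot <- ntip + tree$Nnode
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  partial <- matrix(0, tot, 2L)
  logscale <- numeric(tot)
  for (i in seq_len(ntip)) partial[i, s[i] + 1L] <- 1
  ord <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
  for (v in ord) {
    L <- c(1, 1)
    for (ei in kids[[as.character(v)]]) {
      c_node <- tree$edge[ei, 2]
      P <- mk_pmat(model$q01, model$q10, tree$edge.length[ei])
      L <- L * as.vector(P %*% partial[c_node, ])
      logscale[v] <- logscale[v] + logscale[c_node]
    }
    sc <- sum(L)
    if (sc == 0) {
      partial[v, ] <- 0
      logscale[v] <- -Inf
    } else {
      partial[v, ] <- L / sc
      logscale[v] <- logscale[v] + log(sc)
    }
  }
  list(partial = partial, logscale = logscale,
       kids = kids, ord = ord, ntip = ntip)
}

#' Log-likelihood of tip states under an Mk model
#'
#' Felsenstein pruning over the two-state chain, with transition
#' probabilities from the closed-form 2x2 matrix exponential and the model's
#' root prior combined at the root. Data that are impossible under the model
#' (e.g. both states present as the rates go to zero) yield `-Inf`.
#'
#' @param tree A rooted `phylo` with finite branch lengths.
#' @param states Tip states (named 0/1 vector or tibble `tip`/`state`).
#' @param model An [mk_model()].
#' @return Log-likelihood (scalar).
#' @export
#' @examples
#' tr <- parse_newick("(A:1,B:1);")
#' mk_loglik(tr, c(A = 0, B = 1), mk_model("Mk1", 0.5))
mk_loglik <- function(tree, states, model) {
  s <- as_tip_states(tree, states)
  pr <- mk_partials(tree, s, model)
  root <- length(tree$tip.label) + 1L
  lik <- sum(mk_root_prior(model) * pr$partial[root, ])
  if (lik == 0 || is.infinite(pr$logscale[root])) return(-Inf)
  log(lik) + pr$logscale[root]
}

#' Fit Mk rates by maximum likelihood
#'
#' Maximizes [mk_loglik()] over the rate(s): bounded scalar optimization on
#' the log-rate for Mk1, bounded quasi-Newton (L-BFGS-B, started from the
#' Mk1 optimum so the nested model's likelihood is never exceeded downward)
#' for AsymmMk. Rates are bounded to `[1e-9, 1e3]`.
#'
#' @inheritParams mk_loglik
#' @param kind `"Mk1"` or `"AsymmMk"`.
#' @param root_prior Passed to [mk_model()].
#' @param bounds Rate bounds (length 2).
#' @param tol Convergence tolerance on the log-rate scale.
#' @return An object of class `mk_fit`: the fitted [mk_model()] plus
#'   `loglik`, `convergence` (0 = converged) and bookkeeping.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' fit_mk(tr, c(A = 0, B = 0, C = 1, D = 1), kind = "Mk1")
fit_mk <- function(tree, states, kind = c("Mk1", "AsymmMk"),
                   root_prior = "uniform", bounds = c(1e-9, 1e3),
                   tol = 1e-8) {
  kind <- match.arg(kind)
  s <- as_tip_states(tree, states)
  lb <- log(bounds[1])
  ub <- log(bounds[2])
  ll1 <- function(lq) {
    mk_loglik(tree, s, mk_model("Mk1", exp(lq), root_prior = root_prior))
  }
  o1 <- stats::optimize(ll1, c(lb, ub), maximum = TRUE, tol = tol)
  # no-change data drive the rate to the lower bound; optimize() never
  # reaches the interval ends, so snap when the boundary is at least as good
  if (ll1(lb) >= o1$objective) o1 <- list(maximum = lb, objective = ll1(lb))
  if (kind == "Mk1") {
    model <- mk_model("Mk1", exp(o1$maximum), root_prior = root_prior)
    return(structure(
      list(model = model, loglik = o1$objective, convergence = 0L,
           n_tips = length(s), kind = kind),
      class = "mk_fit"
    ))
  }
  ll2 <- function(lq) {
    mk_loglik(tree, s,
              mk_model("AsymmMk", exp(lq[1]), exp(lq[2]),
                       root_prior = root_prior))
  }
  init <- c(o1$maximum, o1$maximum)
  o2 <- tryCatch(
    stats::optim(init, ll2, method = "L-BFGS-B",
                 lower = c(lb, lb), upper = c(ub, ub),
                 control = list(fnscale = -1, factr = 1e4)),
    error = function(e) NULL
  )
  conv <- if (is.null(o2)) 1L else o2$convergence
  if (is.null(o2) || o2$value < o1$objective) {
    # report best-so-far (the nested Mk1 optimum) on failure
    par <- init
    val <- o1$objective
    if (!is.null(o2) && o2$value >= val) {
      par <- o2$par
      val <- o2$value
    }
  } else {
    par <- o2$par
    val <- o2$value
  }
  model <- mk_model("AsymmMk", exp(par[1]), exp(par[2]),
                    root_prior = root_prior)
  structure(
    list(model = model, loglik = val, convergence = conv,
         n_tips = length(s), kind = kind),
    class = "mk_fit"
  )
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("<mk_fit> ", x$kind, ", logLik = ", signif(x$loglik, 8), "\n",
      sep = "")
  print(x$model)
  invisible(x)
}

#' Tidy an Mk fit
#'
#' @param x An `mk_fit`.
#' @param ... Unused.
#' @return Tibble with one row per free rate: `term`, `estimate`.
#' @export
tidy.mk_fit <- function(x, ...) {
  if (x$kind == "Mk1") {
    tibble::tibble(term = "q", estimate = x$model$q01)
  } else {
    tibble::tibble(term = c("q01", "q10"),
                   estimate = c(x$model$q01, x$model$q10))
  }
}

#' One-row summary of an Mk fit
#'
#' @param x An `mk_fit`.
#' @param ... Unused.
#' @return Tibble: `kind`, `logLik`, `df`, `n_tips`, `convergence`.
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, logLik = x$loglik,
                 df = if (x$kind == "Mk1") 1L else 2L,
                 n_tips = x$n_tips, convergence = x$convergence)
}

#' Generic for broom-style tidying
#' @param x Object.
#' @param ... Passed on.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic for broom-style one-row summaries
#' @param x Object.
#' @param ... Passed on.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Marginal ancestral state reconstruction
#'
#' Per-node marginal posterior probability of each state given the tips, the
#' tree and an Mk model, computed by the standard two-pass (inside/outside)
#' construction: each node's marginal combines the partial likelihoods of
#' all subtrees incident to it with the root prior, which is equivalent to
#' re-rooting at every node.
#'
#' @inheritParams mk_loglik
#' @param model An [mk_model()] or fitted `mk_fit`.
#' @return An object of class `mk_asr`: tibble `nodes` (`node`,
#'   `prob_single`, `prob_fragmented`), the `model`, and `loglik`.
#' @export
#' @examples
#' tr <- parse_newick("(A:1,B:1);")
#' marginal_asr(tr, c(A = 0, B = 1), mk_model("Mk1", 0.3))
marginal_asr <- function(tree, states, model) {
  if (inherits(model, "mk_fit")) model <- model$model
  s <- as_tip_states(tree, states)
  pr <- mk_partials(tree, s, model)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  prior <- mk_root_prior(model)
  lik_root <- sum(prior * pr$partial[root, ])
  ll <- if (lik_root == 0) -Inf else log(lik_root) + pr$logscale[root]
  tot <- ntip + tree$Nnode
  # outside pass: out[v, s] (scaled), preorder over edges
  out <- matrix(0, tot, 2L)
  out[root, ] <- prior
  edge_ord <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_len <- tree$edge.length[match(
    paste(edge_ord[, 1], edge_ord[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2]))]
  for (k in seq_len(nrow(edge_ord))) {
    u <- edge_ord[k, 1]
    v <- edge_ord[k, 2]
    P <- mk_pmat(model$q01, model$q10, edge_len[k])
    # contribution of u's other children
    sib_msg <- c(1, 1)
    for (ei in pr$kids[[as.character(u)]]) {
      w <- tree$edge[ei, 2]
      if (w == v) next
      Pw <- mk_pmat(model$q01, model$q10, tree$edge.length[ei])
      sib_msg <- sib_msg * as.vector(Pw %*% pr$partial[w, ])
    }
    msg <- out[u, ] * sib_msg
    out[v, ] <- as.vector(t(P) %*% msg)
    sc <- sum(out[v, ])
    if (sc > 0) out[v, ] <- out[v, ] / sc
  }
  nodes <- (ntip + 1L):tot
  marg <- t(vapply(nodes, function(v) {
    m <- out[v, ] * pr$partial[v, ]
    if (sum(m) == 0) c(NA_real_, NA_real_) else m / sum(m)
  }, numeric(2L)))
  structure(
    list(
      nodes = tibble::tibble(node = nodes,
                             prob_single = marg[, 1],
                             prob_fragmented = marg[, 2]),
      model = model,
      loglik = ll,
      tree = tree
    ),
    class = "mk_asr"
  )
}

#' @export
print.mk_asr <- function(x, ...) {
  cat("<mk_asr> ", x$model$kind, ", logLik = ", signif(x$loglik, 8),
      "\n", sep = "")
  print(x$nodes)
  invisible(x)
}
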