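test_that("newick parsing validates input and round-trips", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(tr$edge.length, rep(1, 6))
  rt <- parse_newick(write_newick(tr))
  expect_setequal(rt$tip.label, tr$tip.label)
  expect_error(parse_newick("((A,B);"), "parenthes")
  expect_error(parse_newick("((A,A),B);"), "duplicate")
})

test_that("Fitch origin counting matches exhaustive enumeration on random
           trees", {
  set.seed(5)
  for (i in 1:40) {
    ntip <- sample(4:8, 1)
    tr <- random_tree(ntip)
    st <- stats::setNames(sample(0:1, ntip, replace = TRUE), tr$tip.label)
    for (rs in c(0, 1, NA)) {
      got <- fitch_origins(tr, st, root_state = rs)
      want <- oracle_fitch(tr, st, root_state = rs)
      expect_equal(got$score, want$score)
      expect_equal(got$min_gains, want$min_gains)
      expect_equal(got$max_gains, want$max_gains)
    }
  }
})

test_that("the Laemobothriidae subtree needs exactly one origin and all-0
           tips need none", {
  tr <- lice_tree("laemobothriidae")
  st <- c(Laemobothrion_sp1 = 0, Laemobothrion_sp3 = 0,
          Laemobothrion_sp2 = 0, Laemobothrion_tinnunculi = 1)
  expect_equal(fitch_origins(tr, st)$min_gains, 1L)
  st0 <- stats::setNames(rep(0, 4), names(st))
  expect_equal(fitch_origins(tr, st0)$min_gains, 0L)
  expect_error(fitch_origins(tr, st[-1]), "missing state")
})

test_that("irreversible counting forbids losses", {
  # one deep gain + one reversal is cheapest when losses are allowed
  tr <- parse_newick("(((A:1,B:1):1,C:1):1,D:1);")
  st <- c(A = 1, B = 1, C = 0, D = 0)
  rev_ok <- fitch_origins(tr, st)
  expect_equal(rev_ok$min_gains, 1L)
  irr <- fitch_origins(tr, st, irreversible = TRUE)
  expect_equal(irr$min_gains, 1L)
  # on the packaged ML topology the irreversible reading gives the
  # published two origins within Menoponidae
  ml <- lice_tree("ml")
  meno <- ape::drop.tip(ml, grep("^Laemobothrion", ml$tip.label,
                                 value = TRUE))
  st2 <- lice_tip_states()
  expect_equal(
    fitch_origins(meno, st2[st2$tip %in% meno$tip.label, ],
                  irreversible = TRUE)$min_gains, 2L)
})

test_that("origin tally sums per-group minima with a breakdown", {
  t1 <- origin_tally(c(`eutherian mammal lice` = 1, Amblycera = 4,
                       Ischnocera = 9))
  expect_equal(t1$total, 14L)
  expect_equal(nrow(t1$breakdown), 3L)
  expect_equal(origin_tally(tibble::tibble(group = character(),
                                           min_origins = integer()))$total,
               0L)
  expect_error(origin_tally(c(a = -1)), "non-negative")
})

test_that("pruning log-likelihood matches closed forms and limits", {
  q <- 0.4
  t <- 1.3
  # two tips, one zero-length: conditioning the root on the zero-length
  # tip's state makes the tree a single branch of length t
  tr <- parse_newick(sprintf("(A:%f,B:0.0);", t))
  m <- mk_model("Mk1", q, root_prior = c(1, 0))
  expect_equal(mk_loglik(tr, c(A = 1, B = 0), m),
               log((1 - exp(-2 * q * t)) / 2), tolerance = 1e-12)
  expect_equal(mk_loglik(tr, c(A = 0, B = 0), m),
               log((1 + exp(-2 * q * t)) / 2), tolerance = 1e-12)
  # q -> 0 with both states present is impossible
  expect_equal(mk_loglik(tr, c(A = 1, B = 0), mk_model("Mk1", 0)), -Inf)
  # zero-length branch with conflicting states is impossible
  tr0 <- parse_newick("(A:0,B:0);")
  expect_equal(mk_loglik(tr0, c(A = 1, B = 0), mk_model("Mk1", 0.5)),
               -Inf)
})

test_that("pruning equals enumeration over internal states on small
           trees, for symmetric and asymmetric rates", {
  set.seed(41)
  for (i in 1:30) {
    ntip <- sample(3:6, 1)
    tr <- random_tree(ntip)
    st <- stats::setNames(sample(0:1, ntip, replace = TRUE), tr$tip.label)
    m <- mk_model("AsymmMk", stats::runif(1, 0.05, 2),
                  stats::runif(1, 0.05, 2),
                  root_prior = sample(c("uniform", "stationary"), 1))
    expect_equal(mk_loglik(tr, st, m), oracle_mk_loglik(tr, st, m),
                 tolerance = 1e-10)
  }
})

test_that("an independent Mk implementation agrees on the fixture data", {
  skip_if_not_installed("phytools")
  ml <- lice_tree("ml")
  st <- lice_tip_states()
  x <- stats::setNames(
    c("single", "fragmented")[st$state + 1], st$tip)
  q <- 0.11
  m <- mk_model("Mk1", q)
  fit <- phytools::fitMk(ml, x[ml$tip.label], model = "ER", pi = "equal",
                         fixedQ = matrix(c(-q, q, q, -q), 2, 2))
  expect_equal(mk_loglik(ml, st, m), as.numeric(stats::logLik(fit)),
               tolerance = 1e-6)
})

test_that("fitted rates: boundary at no-change data, recovery under the
           generating model, AsymmMk nests Mk1", {
  tr <- random_tree(16, seed = 2)
  st0 <- stats::setNames(rep(0, 16), tr$tip.label)
  f0 <- fit_mk(tr, st0, kind = "Mk1")
  expect_equal(f0$model$q01, 1e-9)
  set.seed(3)
  deltas <- replicate(20, {
    st <- simulate_binary_character(tr, mk_model("Mk1", 0.6),
                                    root_state = NA)
    f1 <- fit_mk(tr, st, kind = "Mk1")
    f2 <- fit_mk(tr, st, kind = "AsymmMk")
    f2$loglik - f1$loglik
  })
  expect_true(all(deltas >= -1e-8))
})

test_that("marginal reconstructions are normalized and equal the
           enumeration oracle", {
  set.seed(43)
  for (i in 1:15) {
    ntip <- sample(3:6, 1)
    tr <- random_tree(ntip)
    st <- stats::setNames(sample(0:1, ntip, replace = TRUE), tr$tip.label)
    m <- mk_model("AsymmMk", stats::runif(1, 0.1, 1.5),
                  stats::runif(1, 0.1, 1.5))
    asr <- marginal_asr(tr, st, m)
    expect_true(all(abs(asr$nodes$prob_single +
                          asr$nodes$prob_fragmented - 1) < 1e-9))
    want <- oracle_marginals(tr, st, m)
    expect_equal(asr$nodes$prob_fragmented, want[, 2], tolerance = 1e-9)
  }
})

test_that("marginal reconstruction symmetry and limit cases", {
  tr <- parse_newick("(A:1,B:1);")
  asr <- marginal_asr(tr, c(A = 0, B = 1), mk_model("Mk1", 0.3))
  expect_equal(asr$nodes$prob_single, 0.5, tolerance = 1e-12)
  # q -> 0 with all tips single: ancestor surely single
  tr4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  st0 <- c(A = 0, B = 0, C = 0, D = 0)
  asr0 <- marginal_asr(tr4, st0, mk_model("Mk1", 1e-9))
  expect_true(all(asr0$nodes$prob_single > 1 - 1e-6))
})

test_that("tidy and glance summarize fits in broom style", {
  tr <- random_tree(8, seed = 9)
  st <- simulate_binary_character(tr, mk_model("Mk1", 0.5), seed = 10)
  f <- fit_mk(tr, st, kind = "AsymmMk")
  td <- tidy(f)
  expect_equal(td$term, c("q01", "q10"))
  gl <- glance(f)
  expect_equal(gl$df, 2L)
  expect_equal(gl$logLik, f$loglik)
})
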