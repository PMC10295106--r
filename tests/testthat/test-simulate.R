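test_that("all-zero rates leave every node karyotype equal to the root", {
  tr <- random_tree(5, seed = 1)
  cfg <- sim_config(0, 0, 0, 0)
  sim <- evolve_on_tree(tr, cfg, seed = 1)
  root_cf <- lapply(cfg$root_karyotype$chromosomes, canonical_form)
  for (k in sim$tip_karyotypes) {
    expect_equal(lapply(k$chromosomes, canonical_form), root_cf)
  }
  expect_equal(sum(!sim$events$skipped), 0L)
})

test_that("gene content is conserved at every simulated tip", {
  tr <- random_tree(8, seed = 4)
  sim <- evolve_on_tree(tr, sim_config(), seed = 4)
  for (k in sim$tip_karyotypes) {
    expect_setequal(karyotype_genes(k)$gene, mt_genes()$gene)
  }
})

test_that("fission and fusion change the chromosome count by exactly one
           and are recovered as a split/merge pair", {
  root <- recovery_root()
  set.seed(6)
  p <- mitokaryo:::draw_event_params(root, "fission", 3L, 0L)
  child <- apply_event(root, "fission", p)
  expect_equal(length(child$chromosomes), length(root$chromosomes) + 1L)
  sm <- detect_split_merge(root, child)
  expect_equal(nrow(sm$groups), 1L)
  expect_setequal(sm$groups$many_labels[[1]], p$new_labels)
  # the cut junctions carry NCR placeholders
  for (lab in p$new_labels) {
    expect_true(any(child$chromosomes[[lab]]$elements$type == "ncr"))
  }
  pf <- mitokaryo:::draw_event_params(child, "fusion", 3L, 10L)
  fused <- apply_event(child, "fusion", pf)
  expect_equal(length(fused$chromosomes), length(child$chromosomes) - 1L)
})

test_that("identical seeds reproduce identical simulations and the event
           log replays exactly", {
  tr <- random_tree(6, seed = 8)
  s1 <- evolve_on_tree(tr, sim_config(), seed = 99)
  s2 <- evolve_on_tree(tr, sim_config(), seed = 99)
  expect_identical(s1$events$class, s2$events$class)
  expect_identical(
    lapply(s1$tip_karyotypes, function(k)
      lapply(k$chromosomes, canonical_form)),
    lapply(s2$tip_karyotypes, function(k)
      lapply(k$chromosomes, canonical_form)))
  s3 <- evolve_on_tree(tr, sim_config(), seed = 100)
  expect_false(identical(s1$events, s3$events))
  rep <- replay_events(s1)
  expect_identical(
    lapply(rep, function(k) lapply(k$chromosomes, canonical_form)),
    lapply(s1$node_karyotypes, function(k)
      lapply(k$chromosomes, canonical_form)))
})

test_that("binary character simulation inherits the root state at zero
           rates, is seed-reproducible, and approaches stationarity", {
  tr <- random_tree(10, seed = 12)
  st <- simulate_binary_character(tr, mk_model("Mk1", 0), root_state = 1,
                                  seed = 1)
  expect_true(all(st == 1))
  a <- simulate_binary_character(tr, mk_model("Mk1", 0.7), seed = 5)
  b <- simulate_binary_character(tr, mk_model("Mk1", 0.7), seed = 5)
  expect_identical(a, b)
  # long single branch: tip state frequency tends to the stationary
  # frequency q01/(q01+q10) = 2/3
  long <- parse_newick("(A:50,B:50);")
  m <- mk_model("AsymmMk", 0.2, 0.1)
  set.seed(77)
  freq <- mean(replicate(4000, {
    simulate_binary_character(long, m, root_state = 0)[["A"]]
  }))
  expect_equal(freq, 2 / 3, tolerance = 0.05)
})

test_that("the integration dataset mirrors the study design", {
  ds <- make_paper_like_dataset(seed = 2)
  expect_equal(ape::Ntip(ds$tree), 23L)
  expect_equal(sum(grepl("^out", ds$tree$tip.label)), 4L)
  # irreversible parsimony recovers the constructed number of gains
  expect_equal(fitch_origins(ds$tree, ds$states,
                             irreversible = TRUE)$min_gains, ds$n_gains)
  expect_true(fitch_origins(ds$tree, ds$states)$min_gains <= ds$n_gains)
  # evolved tips conserve the complement
  for (k in ds$sim$tip_karyotypes[1:4]) {
    expect_equal(sum(gene_census(k)$present), 37L)
  }
  ds2 <- make_paper_like_dataset(seed = 3)
  expect_false(identical(ds$sim$events, ds2$sim$events))
})

test_that("plot builders return ggplot objects", {
  ks <- lice_karyotypes("Austromenopon_sp2")
  expect_s3_class(plot_karyotype(ks[[1]]), "ggplot")
  tr <- parse_newick("(A:1,B:1);")
  asr <- marginal_asr(tr, c(A = 0, B = 1), mk_model("Mk1", 0.3))
  expect_s3_class(ggplot2::autoplot(asr), "ggplot")
})
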