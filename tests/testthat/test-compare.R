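ks <- lice_karyotypes()

test_that("chromosome matching equals exhaustive search on random toys", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_karyotype(n_genes = sample(6:12, 1),
                          n_chrom = sample(2:3, 1))
    b <- random_karyotype(n_genes = sample(6:12, 1),
                          n_chrom = sample(2:3, 1))
    shared <- length(intersect(karyotype_genes(a)$gene,
                               karyotype_genes(b)$gene))
    if (shared == 0) {
      expect_error(match_chromosomes(a, b), "no gene")
      next
    }
    h <- match_chromosomes(a, b)
    expect_equal(sum(h$pairs$weight), oracle_matching_weight(a, b))
    expect_true(all(h$pairs$weight >= 1))
    expect_equal(anyDuplicated(h$pairs$label_a), 0L)
    expect_equal(anyDuplicated(h$pairs$label_b), 0L)
  }
})

test_that("a karyotype matched against itself is the identity matching", {
  for (nm in c("Actornithophilus_sp1", "Myrsidea_sp1")) {
    h <- match_chromosomes(ks[[nm]], ks[[nm]])
    expect_equal(h$pairs$label_a, h$pairs$label_b)
    expect_length(h$unmatched_a, 0L)
    expect_length(h$unmatched_b, 0L)
  }
})

test_that("shared clusters equal the brute-force run enumeration", {
  set.seed(13)
  for (i in 1:20) {
    a <- random_karyotype(n_genes = sample(6:10, 1),
                          n_chrom = sample(1:3, 1), rev_prob = 0.4)
    b <- random_karyotype(n_genes = sample(6:10, 1),
                          n_chrom = sample(1:3, 1), rev_prob = 0.4)
    got <- sort(unique(shared_clusters(a, b)$cluster))
    expect_equal(got, oracle_all_shared_runs(a, b))
    # symmetry as cluster sets
    expect_equal(got, sort(unique(shared_clusters(b, a)$cluster)))
  }
})

test_that("every chromosome is a whole shared cluster in self-comparison", {
  set.seed(17)
  k <- random_karyotype(n_genes = 15, n_chrom = 3)
  cl <- shared_clusters(k, k)
  whole <- cl[cl$whole_a & cl$whole_b & cl$chromosome_a == cl$chromosome_b, ]
  # chromosomes with >= 2 genes each appear as a whole-chromosome cluster
  sizes <- vapply(k$chromosomes, function(m) nrow(m$elements), integer(1))
  expect_setequal(unique(whole$chromosome_a),
                  names(sizes)[vapply(k$chromosomes, function(m)
                    sum(m$elements$type == "gene") >= 2, logical(1))])
  cmp <- compare_karyotypes(k, k)
  expect_equal(cmp$chromosome_count_delta, 0L)
  expect_equal(nrow(cmp$split_merge), 0L)
  expect_equal(sum(cmp$translocated$status == "translocated"), 0L)
  expect_equal(nrow(cmp$inverted), 0L)
  expect_length(cmp$repositioned, 0L)
})

test_that("the two Austromenopon karyotypes share the six published
           derived clusters", {
  cl <- shared_clusters(ks$Austromenopon_sp1, ks$Austromenopon_sp2)
  want <- c("cox2-cox1-atp6-atp8", "nad2-nad5-I", "nad3-Y",
            "rrnL-rrnS-L1", "nad4L-nad4-E", "P-K-S1")
  want_ids <- vapply(strsplit(want, "-(?=[^-])", perl = TRUE),
                     canonical_run_id, character(1))
  expect_setequal(cl$cluster, want_ids)
  expect_equal(sum(cl$length), 18L) # the six strings carry 18 genes
  # all six are derived relative to the reference arrangement
  expect_equal(nrow(derived_clusters(cl, reference_arrangement())), 6L)
})

test_that("the two Actornithophilus karyotypes reproduce the published
           worked example", {
  cmp <- compare_karyotypes(ks$Actornithophilus_sp1,
                            ks$Actornithophilus_sp2,
                            reference = reference_arrangement())
  expect_equal(cmp$chromosome_count_delta, -1L)
  expect_equal(nrow(cmp$split_merge), 1L)
  # the split/merger is M2 of sp. 1 vs M2+M3 of sp. 2
  expect_equal(cmp$split_merge$one_label, "M2")
  expect_setequal(cmp$split_merge$many_labels[[1]], c("M2", "M3"))
  tra <- cmp$translocated$gene[cmp$translocated$status == "translocated"]
  expect_setequal(tra, c("Q", "W", "L1", "nad5", "D", "L2"))
  expect_setequal(cmp$inverted$gene, c("A", "Q", "W"))
  expect_equal(cmp$shared_whole_chromosomes, 1L)
  # the shared whole minichromosome is E-nad4L-nad4 (M1 in both)
  whole <- cmp$clusters[cmp$clusters$whole_a & cmp$clusters$whole_b, ]
  expect_equal(whole$chromosome_a, "M1")
  expect_equal(whole$chromosome_b, "M1")
  # five derived clusters beyond the shared whole chromosome
  other <- cmp$derived[!(cmp$derived$whole_a & cmp$derived$whole_b), ]
  want <- c("V-K-cob-nad1", "nad6-H-S2", "nad2-S1-F", "Y-atp8-atp6-N",
            "G-I-cox2-cox1-C-cox3")
  want_ids <- vapply(strsplit(want, "-(?=[^-])", perl = TRUE),
                     canonical_run_id, character(1))
  expect_setequal(other$cluster, want_ids)
  # gene sets are invariant under argument swap
  rev_cmp <- compare_karyotypes(ks$Actornithophilus_sp2,
                                ks$Actornithophilus_sp1)
  expect_equal(rev_cmp$chromosome_count_delta, 1L)
  expect_setequal(
    rev_cmp$translocated$gene[rev_cmp$translocated$status ==
                                "translocated"], tra)
  expect_setequal(rev_cmp$inverted$gene, cmp$inverted$gene)
})

test_that("Actornithophilus M1 minichromosomes are identical in content
           and the sp.1 census misses exactly trnP and trnR", {
  expect_equal(canonical_form(ks$Actornithophilus_sp1$chromosomes$M1),
               canonical_form(ks$Actornithophilus_sp2$chromosomes$M1))
  cen <- gene_census(ks$Actornithophilus_sp1)
  expect_setequal(cen$gene[!cen$present], c("P", "R"))
})

test_that("the two Myrsidea species share one whole minichromosome and the
           nine-gene protein-coding cluster", {
  cl <- shared_clusters(ks$Myrsidea_sp1, ks$Myrsidea_sp2)
  whole <- cl[cl$whole_a & cl$whole_b, ]
  expect_equal(nrow(whole), 1L)
  expect_equal(whole$cluster, canonical_circle_id(
    c("Y", "nad5", "L1", "nad3", "S1", "cox2", "cox1", "cox3")))
  expect_true(canonical_run_id(
    c("G", "cob", "Q", "atp6", "atp8", "nad4L", "nad4", "nad6", "nad1"))
    %in% cl$cluster)
})

test_that("Laemobothrion comparisons match the published arrangement
           statements", {
  same <- compare_karyotypes(ks$Laemobothrion_sp1, ks$Laemobothrion_sp3)
  expect_equal(same$chromosome_count_delta, 0L)
  expect_equal(sum(same$translocated$status == "translocated"), 0L)
  expect_equal(nrow(same$inverted), 0L)
  expect_length(same$repositioned, 0L)
  expect_true(same$shared_whole_chromosomes >= 1L)

  moved <- compare_karyotypes(ks$Laemobothrion_sp2, ks$Laemobothrion_sp1)
  expect_equal(moved$chromosome_count_delta, 0L)
  expect_equal(sum(moved$translocated$status == "translocated"), 0L)
  expect_equal(nrow(moved$inverted), 0L)
  expect_setequal(moved$repositioned,
                  c("nad3", "G", "W", "V", "F", "M", "Q"))
})

test_that("derived screening drops clusters present in the reference", {
  cl <- shared_clusters(ks$Laemobothrion_sp1, ks$Laemobothrion_sp3)
  # identical arrangements: every cluster occurs in sp1 itself
  expect_equal(nrow(derived_clusters(cl, ks$Laemobothrion_sp1)), 0L)
})

test_that("orphan chromosomes are excluded from translocation calls", {
  a <- parse_karyo(c("M1: cox1 cox2 nad1", "M2: rrnL rrnS"))
  b <- parse_karyo(c("M1: cox1 cox2 nad1", "M2: atp6 atp8"))
  tra <- translocated_genes(a, b)
  expect_equal(sum(tra$status == "translocated"), 0L)
  sm <- detect_split_merge(a, b)
  expect_true(nrow(sm$orphans) >= 1L)
})

test_that("single simulated events are classified with their exact block", {
  set.seed(99)
  root <- recovery_root()
  classes <- c("fission", "fusion", "translocation", "inversion")
  for (i in 1:60) {
    cls <- classes[(i %% 4) + 1]
    p <- mitokaryo:::draw_event_params(root, cls, 3L, 0L)
    child <- apply_event(root, cls, p)
    inf <- infer_single_event(root, child)
    expect_equal(inf$class, cls)
    expect_equal(inf$genes, expected_event_genes(root, cls, p))
  }
})
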