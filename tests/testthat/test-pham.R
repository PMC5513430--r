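test_that("protein_pairwise scores identity, containment and rejects empties", {
  set.seed(1)
  p <- rand_protein(100)
  e <- protein_pairwise(p, p, ids = c("x", "y"))
  expect_equal(e$percent_identity, 100)
  expect_equal(e$coverage, 1)
  # containment: full protein vs its first half
  half <- substr(p, 1, 50)
  e2 <- protein_pairwise(p, half)
  expect_equal(e2$percent_identity, 100)
  expect_equal(e2$coverage, 1)
  # canonical id order regardless of argument order
  e3 <- protein_pairwise(p, half, ids = c("zzz", "aaa"))
  expect_equal(e3$query_id, "aaa")
  expect_equal(e3$subject_id, "zzz")
  expect_error(protein_pairwise("", p), "empty")
})

test_that("unrelated random proteins rarely reach half coverage", {
  set.seed(202)
  cov <- vapply(1:100, function(i) {
    protein_pairwise(rand_protein(200), rand_protein(200))$coverage
  }, 0)
  expect_gt(mean(cov < 0.5), 0.95)
})

test_that("build_phams groups by single linkage with deterministic ids", {
  set.seed(5)
  a <- rand_protein(200)
  c_ <- rand_protein(200)
  pr <- data.frame(protein_id = c("pA", "pB", "pC"),
                   phage_id = c("g1", "g2", "g3"),
                   translation = c(a, a, c_), stringsAsFactors = FALSE)
  pt <- build_phams(pr)
  expect_length(pt$phams, 2L)
  expect_equal(partition_of_pham_table(pt),
               canon_partition(list(c("pA", "pB"), "pC")))

  # transitive chain: B bridges A and C although A-C fail the thresholds
  bridge <- paste0(substr(a, 1, 120), substr(c_, 1, 120))
  pr2 <- data.frame(protein_id = c("pA", "pB", "pC"),
                    phage_id = c("g1", "g2", "g3"),
                    translation = c(a, bridge, c_), stringsAsFactors = FALSE)
  direct <- protein_pairwise(a, c_)
  expect_true(direct$percent_identity < 32.5 || direct$coverage < 0.5)
  pt2 <- build_phams(pr2)
  expect_length(pt2$phams, 1L)

  # n unrelated proteins -> n phams, all orphams
  pr3 <- data.frame(protein_id = paste0("q", 1:6),
                    phage_id = paste0("g", 1:6),
                    translation = vapply(1:6, function(i) rand_protein(150), ""),
                    stringsAsFactors = FALSE)
  pt3 <- build_phams(pr3)
  expect_length(pt3$phams, 6L)
  expect_setequal(orphams(pt3), names(pt3$phams))

  # partition property
  expect_equal(sum(lengths(pt3$phams)), nrow(pr3))
  expect_false(anyDuplicated(unlist(pt3$phams)) > 0)

  # determinism: identical inputs give identical serializations
  pt3b <- build_phams(pr3)
  expect_identical(pt3$membership, pt3b$membership)
})

test_that("pham ids are ordered by size then smallest member id", {
  set.seed(9)
  big <- rand_protein(150); small <- rand_protein(150)
  pr <- data.frame(
    protein_id = c("z1", "z2", "z3", "a1", "a2"),
    phage_id = paste0("g", 1:5),
    translation = c(big, big, big, small, small),
    stringsAsFactors = FALSE
  )
  pt <- build_phams(pr)
  expect_equal(unname(pt$phams[["pham_0001"]]), c("z1", "z2", "z3"))
  expect_equal(unname(pt$phams[["pham_0002"]]), c("a1", "a2"))
})

test_that("lowering the identity threshold only merges phams", {
  set.seed(31)
  base <- replicate(6, rand_protein(160))
  prots <- c(base, vapply(base, function(p) mutate_protein(p, 0.45), ""))
  pr <- data.frame(protein_id = sprintf("p%02d", seq_along(prots)),
                   phage_id = sprintf("g%02d", seq_along(prots)),
                   translation = prots, stringsAsFactors = FALSE)
  strict <- build_phams(pr, pham_params(min_identity = 60))
  loose <- build_phams(pr, pham_params(min_identity = 30))
  expect_lte(length(loose$phams), length(strict$phams))
  # refinement: each strict pham sits inside one loose pham
  loose_of <- setNames(loose$membership$pham_id, loose$membership$protein_id)
  for (mem in strict$phams) {
    expect_length(unique(loose_of[mem]), 1L)
  }
})

test_that("single-linkage components equal the brute-force closure", {
  for (sd in c(101, 102, 103)) {
    set.seed(sd)
    base <- replicate(5, rand_protein(120))
    prots <- c(base,
               vapply(sample(base, 8, replace = TRUE),
                      function(p) mutate_protein(p, runif(1, 0.1, 0.5)), ""),
               replicate(5, rand_protein(120)))
    pr <- data.frame(protein_id = sprintf("p%02d", seq_along(prots)),
                     phage_id = sprintf("g%02d", seq_along(prots)),
                     translation = prots, stringsAsFactors = FALSE)
    pt <- build_phams(pr)
    expect_equal(partition_of_pham_table(pt), bf_pham_partition(pr))
  }
})

test_that("the k-mer prefilter does not change results", {
  sim <- simulate_pangenome(sim_config(seed = 77, K = 2, sizes = c(3L, 3L),
                                       n_singletons = 1L))
  pr <- collect_proteins(sim$genomes)
  with_pf <- build_phams(pr, pham_params(prefilter = TRUE))
  without_pf <- build_phams(pr, pham_params(prefilter = FALSE))
  expect_identical(with_pf$membership, without_pf$membership)
})

test_that("attach_external counts matches without touching the partition", {
  set.seed(55)
  a <- rand_protein(180); b <- rand_protein(180)
  pr <- data.frame(protein_id = c("pA1", "pA2", "pB"),
                   phage_id = c("g1", "g2", "g3"),
                   translation = c(a, a, b), stringsAsFactors = FALSE)
  pt <- build_phams(pr)
  before <- pt$membership

  # empty external set: flag flips, nothing else changes
  pt0 <- attach_external(pt, data.frame(protein_id = character(),
                                        genus = character(),
                                        translation = character()), pr)
  expect_true(pt0$external_attached)
  expect_identical(pt0$membership, before)
  expect_true(all(pt0$external_members == 0L))

  # one exact copy + two mutated copies of a, one unrelated protein
  ext <- data.frame(
    protein_id = c("e1", "e2", "e3", "e4"),
    genus = c("Mycobacterium", "Gordonia", "Gordonia", "Rhodococcus"),
    translation = c(a, mutate_protein(a, 0.2), mutate_protein(a, 0.2),
                    rand_protein(180)),
    stringsAsFactors = FALSE
  )
  pt2 <- attach_external(pt, ext, pr)
  pham_a <- pt2$membership$pham_id[pt2$membership$protein_id == "pA1"]
  expect_equal(unname(pt2$external_members[pham_a]), 3L)
  expect_setequal(pt2$external_genera[[pham_a]], c("Mycobacterium", "Gordonia"))
  expect_identical(pt2$membership, before)
})

test_that("orphams require a lone gene in a lone phage and no external hit", {
  mem <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p5"),
    phage_id = c("g1", "g2", "g2", "g3", "g3"),
    pham_id = c("ph1", "ph1", "ph2", "ph3", "ph4"),
    stringsAsFactors = FALSE
  )
  pt <- pham_table(mem, external_members = c(ph3 = 1L))
  # ph1 multi-phage, ph3 externally matched -> only ph2 and ph4 are orphams
  expect_setequal(orphams(pt), c("ph2", "ph4"))
  # two identical proteins in different phages are never orphams
  expect_false("ph1" %in% orphams(pt))
})

test_that("pham TSV export carries the orpham flag", {
  mem <- data.frame(protein_id = c("p1", "p2"), phage_id = c("g1", "g2"),
                    pham_id = c("ph1", "ph2"), stringsAsFactors = FALSE)
  pt <- pham_table(mem)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pham_tsv(pt, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 2L)
  expect_true(all(back$is_orpham))
})
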