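# A small constructed universe used across the diversity tests:
# clusters X = {g1, g2}, Y = {g3, g4}, singleton s1.
make_universe <- function() {
  mem <- data.frame(
    protein_id = sprintf("p%02d", 1:12),
    phage_id = c("g1", "g1", "g1", "g2", "g2", "g3", "g3", "g4", "g4", "g4",
                 "s1", "s1"),
    pham_id = c("core_x", "acc1", "shared_xy", "core_x", "orph_g2",
                "core_y", "shared_xy", "core_y", "acc2", "ext_hit",
                "orph_s1", "shared_xs"),
    stringsAsFactors = FALSE
  )
  mem <- rbind(mem, data.frame(protein_id = "p13", phage_id = "g1",
                               pham_id = "shared_xs"))
  pt <- pham_table(mem, external_members = c(ext_hit = 2L),
                   external_genera = list(ext_hit = c("Gordonia")))
  ids <- c("g1", "g2", "g3", "g4", "s1")
  ani <- diag(1, 5); dimnames(ani) <- list(ids, ids)
  ani["g1", "g2"] <- ani["g2", "g1"] <- 0.95
  ani["g3", "g4"] <- ani["g4", "g3"] <- 0.95
  asg <- assign_clusters(ids, fake_ani_matrix(ani))
  list(pt = pt, asg = asg, mem = pt$membership)
}

test_that("cluster-identifier phams match a brute-force scan", {
  u <- make_universe()
  # brute force by definition, for every cluster
  for (cl in names(u$asg$clusters)) {
    members <- u$asg$clusters[[cl]]
    others <- setdiff(u$asg$assignment$genome_id, members)
    universe <- unique(u$mem$pham_id[u$mem$phage_id %in% members])
    bf <- Filter(function(p) {
      carriers <- unique(u$mem$phage_id[u$mem$pham_id == p])
      all(members %in% carriers) && !any(others %in% carriers)
    }, universe)
    got <- cluster_identifier_phams(cl, u$asg, u$pt)
    expect_setequal(got$phams, bf)
    expect_equal(got$percent, 100 * length(bf) / length(universe))
  }
  # cluster X = {g1, g2}: core_x in both members and nowhere else
  gx <- cluster_identifier_phams("AK", u$asg, u$pt)
  expect_true("core_x" %in% gx$phams)
  expect_false("acc1" %in% gx$phams)       # in one member only
  expect_false("shared_xy" %in% gx$phams)  # present in another cluster
})

test_that("identifier percent is 100 for a fully private identical pair", {
  mem <- data.frame(protein_id = paste0("p", 1:6),
                    phage_id = c("a", "a", "b", "b", "z", "z"),
                    pham_id = c("ph1", "ph2", "ph1", "ph2", "q1", "q2"),
                    stringsAsFactors = FALSE)
  pt <- pham_table(mem)
  ids <- c("a", "b", "z")
  ani <- diag(1, 3); dimnames(ani) <- list(ids, ids)
  ani["a", "b"] <- ani["b", "a"] <- 0.95
  asg <- assign_clusters(ids, fake_ani_matrix(ani))
  expect_equal(cluster_identifier_phams("AK", asg, pt)$percent, 100)
})

test_that("identifier phams are not computed for singletons", {
  u <- make_universe()
  got <- cluster_identifier_phams("s1", u$asg, u$pt)
  expect_false(got$computed)
  expect_true(is.na(got$percent))
})

test_that("orpham percentages follow the truth of the universe", {
  u <- make_universe()
  # s1 universe = {orph_s1, shared_xs}: only orph_s1 is an orpham
  o <- orpham_percent("s1", u$pt, u$asg)
  expect_equal(o$percent, 50)
  expect_equal(o$orphams, "orph_s1")
  # a genome whose phams are all shared has 0%
  o2 <- orpham_percent("g3", u$pt)
  expect_equal(o2$percent, 0)
  # all-unique unrelated genome: 100%
  mem <- data.frame(protein_id = c("q1", "q2"), phage_id = "solo",
                    pham_id = c("u1", "u2"), stringsAsFactors = FALSE)
  expect_equal(orpham_percent("solo", pham_table(mem))$percent, 100)
  # definition label records whether an external reference was attached
  expect_match(orpham_percent("g3", u$pt)$definition, "no external members")
})

test_that("planted orpham fraction is recovered from a simulator truth table", {
  sim <- simulate_pangenome(sim_config(seed = 81, K = 2, sizes = c(3L, 3L),
                                       n_singletons = 1L))
  tpt <- truth_pham_table(sim)
  expect_setequal(orphams(tpt), sim$truth$orphams)
  # scope percentages agree with direct counting on the truth table
  gt <- sim$truth$gene_truth
  for (gid in unique(gt$phage_id)[1:3]) {
    universe <- unique(gt$pham[gt$phage_id == gid])
    expected <- 100 * sum(universe %in% sim$truth$orphams) / length(universe)
    expect_equal(orpham_percent(gid, tpt)$percent, expected)
  }
})

test_that("inter-cluster sharing percentages match exhaustive counting", {
  u <- make_universe()
  # X universe: core_x, acc1, shared_xy, orph_g2, shared_xs ->
  # shared with others: shared_xy (Y) and shared_xs (s1) = 2/5
  expect_equal(intercluster_shared_percent("AK", u$asg, u$pt)$percent, 40)
  # fully isolated cluster
  mem <- data.frame(protein_id = paste0("p", 1:4),
                    phage_id = c("a", "b", "c", "d"),
                    pham_id = c("ph1", "ph1", "ph2", "ph2"),
                    stringsAsFactors = FALSE)
  pt <- pham_table(mem)
  ids <- c("a", "b", "c", "d")
  ani <- diag(1, 4); dimnames(ani) <- list(ids, ids)
  ani["a", "b"] <- ani["b", "a"] <- 0.95
  ani["c", "d"] <- ani["d", "c"] <- 0.95
  asg <- assign_clusters(ids, fake_ani_matrix(ani))
  expect_equal(intercluster_shared_percent("AK", asg, pt)$percent, 0)
  # clusters with identical pham sets -> 100
  mem2 <- data.frame(protein_id = paste0("q", 1:4),
                     phage_id = c("a", "b", "c", "d"),
                     pham_id = c("ph1", "ph1", "ph1", "ph1"),
                     stringsAsFactors = FALSE)
  expect_equal(intercluster_shared_percent("AK", asg, pham_table(mem2))$percent,
               100)
})

test_that("external sharing uses the attached reference and errors without", {
  u <- make_universe()
  # Y universe: core_y, shared_xy, acc2, ext_hit -> only ext_hit external
  e <- external_shared_percent("AL", u$asg, u$pt)
  expect_equal(e$percent, 25)
  expect_equal(e$phams, "ext_hit")
  mem <- data.frame(protein_id = "p1", phage_id = "a", pham_id = "ph1",
                    stringsAsFactors = FALSE)
  pt_no_ext <- pham_table(mem)
  pt_no_ext$external_attached <- FALSE
  expect_error(external_shared_percent("a", u$asg, pt_no_ext), "external")
})

test_that("external set equal to one member's proteome mirrors its coverage", {
  set.seed(83)
  prots <- replicate(5, rand_protein(150))
  pr <- data.frame(protein_id = sprintf("p%d", 1:10),
                   phage_id = rep(c("m1", "m2"), each = 5),
                   translation = c(prots, prots), stringsAsFactors = FALSE)
  pt <- build_phams(pr)
  ext <- data.frame(protein_id = paste0("e", 1:5), genus = "Rhodococcus",
                    translation = prots, stringsAsFactors = FALSE)
  pt <- attach_external(pt, ext, pr)
  ids <- c("m1", "m2")
  ani <- matrix(c(1, 0.95, 0.95, 1), 2, 2, dimnames = list(ids, ids))
  asg <- assign_clusters(ids, fake_ani_matrix(ani))
  # every pham of the cluster is covered by the external copy of m1
  expect_equal(external_shared_percent("AK", asg, pt)$percent, 100)
})

test_that("pairwise cluster sharing equals a hand-enumerated table", {
  u <- make_universe()
  tab <- pairwise_cluster_sharing_table(u$asg, u$pt)
  # diagonal = universe sizes: X 5, Y 4, s1 2
  expect_equal(unname(diag(tab$counts)[c("AK", "AL", "s1")]), c(5, 4, 2))
  expect_equal(tab$counts["AK", "AL"], 1)  # shared_xy
  expect_equal(tab$counts["AK", "s1"], 1)  # shared_xs
  expect_equal(tab$counts["AL", "s1"], 0)
  expect_equal(tab$counts, t(tab$counts))
  expect_equal(tab$fraction_of_row["AK", "AL"], 1 / 5)
  expect_equal(tab$fraction_of_row["AL", "AK"], 1 / 4)
})

test_that("diversity report is consistent and order/label invariant", {
  u <- make_universe()
  rep1 <- diversity_report(u$asg, u$pt)
  expect_setequal(rep1$cluster, c("AK", "AL", "s1"))
  expect_true(all(rep1$pct_identifier + rep1$pct_shared_other_cluster <= 100,
                  na.rm = TRUE))
  # identifier sets of different clusters are disjoint
  sets <- lapply(names(u$asg$clusters), function(cl) {
    cluster_identifier_phams(cl, u$asg, u$pt)$phams
  })
  expect_length(intersect(sets[[1]], sets[[2]]), 0L)
  # relabeling phams leaves all percentages unchanged
  relab <- u$pt$membership
  map <- setNames(sprintf("zz_%03d", seq_along(unique(relab$pham_id))),
                  unique(relab$pham_id))
  relab$pham_id <- unname(map[relab$pham_id])
  em <- setNames(u$pt$external_members, map[names(u$pt$external_members)])
  pt2 <- pham_table(relab, external_members = em)
  rep2 <- diversity_report(u$asg, pt2)
  expect_equal(rep1[, -1], rep2[, -1])
})
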