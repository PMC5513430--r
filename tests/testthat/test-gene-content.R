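test_that("presence matrix cells reflect pham membership exactly", {
  mem <- data.frame(
    protein_id = sprintf("p%d", 1:7),
    phage_id = c("g1", "g1", "g1", "g2", "g2", "g3", "g3"),
    pham_id = c("phA", "phB", "phB", "phA", "phC", "phC", "phD"),
    stringsAsFactors = FALSE
  )
  pt <- pham_table(mem)
  m <- presence_matrix(pt)
  expect_equal(dim(m), c(3L, 4L))
  # row sum = distinct phams per genome (g1 has two genes in phB)
  expect_equal(unname(rowSums(m)), c(2, 2, 2))
  # column sums recount: genomes containing each pham
  recount <- vapply(colnames(m), function(p) {
    length(unique(mem$phage_id[mem$pham_id == p]))
  }, 0)
  expect_equal(colSums(m), recount)
  expect_error(presence_matrix(pt, c("g1", "nope")), "absent")
  # identical pham sets give identical rows
  mem2 <- rbind(mem, data.frame(protein_id = c("p8", "p9"), phage_id = "g4",
                                pham_id = c("phA", "phB")))
  m2 <- presence_matrix(pham_table(mem2))
  expect_equal(unname(m2["g4", ]), unname(m2["g1", ]))
})

test_that("Jaccard distances match hand computation and degenerate cases", {
  m <- rbind(g1 = c(1, 1, 1, 0), g2 = c(0, 1, 1, 1), g3 = c(1, 1, 1, 0),
             g4 = c(0, 0, 0, 1))
  colnames(m) <- paste0("ph", 1:4)
  d <- as.matrix(gene_content_distance(m))
  expect_equal(d["g1", "g2"], 0.5)  # 1 - 2/4
  expect_equal(d["g1", "g3"], 0)    # identical pham sets
  expect_equal(d["g1", "g4"], 1)    # disjoint
  expect_error(gene_content_distance(rbind(a = c(1, 0), b = c(0, 0))),
               "empty pham set")
})

test_that("Jaccard distance is a metric on random presence matrices", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(4:8, 1); p <- sample(6:20, 1)
    m <- matrix(rbinom(n * p, 1, 0.4), n, p,
                dimnames = list(paste0("g", 1:n), paste0("ph", 1:p)))
    m[rowSums(m) == 0, 1] <- 1
    d <- as.matrix(gene_content_distance(m))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, n))
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
    # d = 0 iff identical pham sets
    same <- which(d == 0, arr.ind = TRUE)
    for (r in seq_len(nrow(same))) {
      expect_equal(unname(m[same[r, 1], ]), unname(m[same[r, 2], ]))
    }
  }
})

test_that("shared-fraction metric is available and bounded", {
  m <- rbind(g1 = c(1, 1, 1, 0), g2 = c(0, 1, 1, 1))
  colnames(m) <- paste0("ph", 1:4)
  d <- as.matrix(gene_content_distance(m, metric = "shared-fraction"))
  expect_equal(d["g1", "g2"], 1 - (2 / 3 + 2 / 3) / 2)
})

test_that("neighbor joining matches the 3-taxon closed form", {
  ids <- c("a", "b", "c")
  m <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(m) <- 0
  tr <- nj_tree(as.dist(m))
  expect_s3_class(tr, "phylo")
  # all-equal distances: every pendant edge is d/2 = 0.25
  expect_equal(sort(tr$edge.length), rep(0.25, 3))
})

test_that("neighbor joining recovers an additive 4-taxon tree", {
  # tree ((A:1,B:2):1,(C:1.5,D:2.5)); additive path distances below
  ids <- c("A", "B", "C", "D")
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m["A", "B"] <- m["B", "A"] <- 3
  m["A", "C"] <- m["C", "A"] <- 3.5
  m["A", "D"] <- m["D", "A"] <- 4.5
  m["B", "C"] <- m["C", "B"] <- 4.5
  m["B", "D"] <- m["D", "B"] <- 5.5
  m["C", "D"] <- m["D", "C"] <- 4
  tr <- nj_tree(as.dist(m))
  # NJ reproduces additive distances exactly
  got <- as.matrix(ape::cophenetic.phylo(tr))[ids, ids]
  expect_equal(got, m, tolerance = 1e-10)
})

test_that("negative NJ branch lengths are clamped to zero", {
  set.seed(72)
  n <- 6
  m <- matrix(runif(n * n, 0.1, 0.9), n, n,
              dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  tr <- nj_tree(as.dist(m))
  expect_true(all(tr$edge.length >= 0))
})

test_that("NEXUS export round-trips dimensions for both block types", {
  m <- rbind(g1 = c(1, 0, 1), g2 = c(0, 1, 1))
  colnames(m) <- paste0("ph", 1:3)
  f <- withr::local_tempfile(fileext = ".nex")
  export_nexus(m, f)
  txt <- readLines(f)
  expect_equal(txt[1], "#NEXUS")
  expect_true(any(grepl("DIMENSIONS NTAX=2;", txt)))
  expect_true(any(grepl("DIMENSIONS NCHAR=3;", txt)))
  expect_true(any(grepl("'g1' 101", txt)))

  d <- dist(m, method = "binary")
  f2 <- withr::local_tempfile(fileext = ".nex")
  export_nexus(d, f2)
  txt2 <- readLines(f2)
  expect_true(any(grepl("BEGIN DISTANCES;", txt2)))

  bad <- m; rownames(bad) <- c("x", "x")
  expect_error(export_nexus(bad, withr::local_tempfile()), "collision")
})

test_that("representative matrix picks largest genomes unless overridden", {
  set.seed(73)
  gs <- list(genome("a1", rand_dna(3000)), genome("a2", rand_dna(5000)),
             genome("b1", rand_dna(2000)))
  ids <- c("a1", "a2", "b1")
  ani <- diag(1, 3); dimnames(ani) <- list(ids, ids)
  ani["a1", "a2"] <- ani["a2", "a1"] <- 0.95
  asg <- assign_clusters(ids, fake_ani_matrix(ani))
  mem <- data.frame(protein_id = paste0("p", 1:3), phage_id = ids,
                    pham_id = c("ph1", "ph1", "ph2"), stringsAsFactors = FALSE)
  pt <- pham_table(mem)
  rm1 <- representative_matrix(asg, pt, gs)
  expect_setequal(rownames(rm1), c("a2", "b1"))  # a2 is larger
  rm2 <- representative_matrix(asg, pt, gs, representatives = c(AK = "a1"))
  expect_setequal(rownames(rm2), c("a1", "b1"))
  expect_error(representative_matrix(asg, pt, gs,
                                     representatives = c(AK = "b1")),
               "not a member")
})
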