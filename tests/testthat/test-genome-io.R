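test_that("genome construction normalizes and validates", {
  g <- genome("g1", "acgtACGT")
  expect_equal(g$sequence, "ACGTACGT")
  expect_equal(genome_length(g), 8L)
  expect_error(genome("g2", ""), "empty")
  expect_error(genome("g3", "ACGTQ"), "non-nucleotide")
  # gene intervals must lie within [0, length)
  expect_error(genome("g4", "ACGTACGT",
                      data.frame(gene_id = "x", start = 2, end = 12, strand = "+")),
               "outside")
  expect_error(genome("g5", "ACGTACGT",
                      data.frame(gene_id = "x", start = 5, end = 5, strand = "+")),
               "outside|empty")
  # genes come back sorted by start
  g6 <- genome("g6", strrep("ACGT", 30),
               data.frame(gene_id = c("b", "a"), start = c(60, 3),
                          end = c(90, 33), strand = c("+", "-")))
  expect_equal(g6$genes$gene_id, c("a", "b"))
})

test_that("gc_content matches hand values and is strand-invariant", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("AAAA"), 0)
  # ambiguity codes excluded from numerator and denominator
  expect_equal(gc_content("ATGCNNRY"), 50)
  expect_error(gc_content("NNNN"), "undefined")
  set.seed(42)
  for (i in 1:10) {
    s <- rand_dna(500, gc = runif(1, 0.3, 0.7))
    expect_equal(gc_content(s), gc_content(revcomp(s)))
  }
})

test_that("genome metrics table reports exact lengths and CDS counts", {
  set.seed(7)
  gs <- list(genome("a", rand_dna(1500)), toy_genome("b"),
             genome("c", rand_dna(333)))
  m <- genome_metrics_table(gs)
  expect_equal(nrow(m), 3L)
  expect_equal(m$length_bp, c(1500L, 600L, 333L))
  expect_equal(m$n_genes, c(0L, 2L, 0L))
  expect_equal(m$pct_gc, round(vapply(gs, gc_content, 0), 1))
  expect_error(genome_metrics_table(list()), "at least one")
})

test_that("FASTA round-trips and normalizes case; duplicates rejected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some phage", "acgt"), f)
  gs <- read_fasta(f)
  expect_length(gs, 1L)
  expect_equal(gs$g1$sequence, "ACGT")
  expect_equal(nrow(gs$g1$genes), 0L)

  set.seed(11)
  orig <- lapply(1:5, function(i) genome(paste0("s", i), rand_dna(200 + i)))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(orig, f2)
  back <- read_fasta(f2)
  expect_equal(vapply(back, `[[`, "", "sequence"),
               setNames(vapply(orig, `[[`, "", "sequence"),
                        vapply(orig, `[[`, "", "id")))

  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGT", ">g1", "TTTT"), f3)
  expect_error(read_fasta(f3), "duplicate")
  f4 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f4)
  expect_error(read_fasta(f4), "no records")
})

test_that("GenBank writer/reader round-trips annotated genomes", {
  set.seed(3)
  sim <- simulate_pangenome(sim_config(seed = 21, K = 1, sizes = 2L,
                                       n_singletons = 0L,
                                       genes_per_genome = c(4L, 5L)))
  for (g in sim$genomes) {
    f <- withr::local_tempfile(fileext = ".gbk")
    write_genbank(g, f)
    g2 <- read_genbank(f)
    expect_equal(g2$sequence, g$sequence)
    expect_equal(g2$genes$start, g$genes$start)
    expect_equal(g2$genes$end, g$genes$end)
    expect_equal(g2$genes$strand, g$genes$strand)
    expect_equal(g2$genes$translation, g$genes$translation)
    expect_equal(g2$id, g$id)
  }
})

test_that("GenBank parser handles strands, joins, and fallback translation", {
  gb <- c(
    "LOCUS       TESTPHAGE        120 bp    DNA     linear   PHG 01-JAN-2000",
    "DEFINITION  test phage.",
    "ACCESSION   AB123456",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             7..27",
    '                     /locus_tag="cdsA"',
    '                     /translation="MKVLATR"',
    "     CDS             complement(31..60)",
    '                     /locus_tag="cdsB"',
    "     CDS             join(70..81,85..96)",
    '                     /locus_tag="cdsC"',
    '                     /translation="MHELLQWW"',
    "ORIGIN",
    paste0("        1 ", strrep("atggcagttacgcgtaaata", 3)),
    paste0("       61 ", strrep("atggcagttacgcgtaaata", 3)),
    "//"
  )
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, f)
  g <- read_genbank(f)
  expect_equal(g$accession, "AB123456")
  expect_equal(nrow(g$genes), 3L)
  expect_equal(g$genes$strand, c("+", "-", "+"))
  # 1-based inclusive converted to 0-based half-open
  expect_equal(g$genes$start, c(6L, 30L, 69L))
  expect_equal(g$genes$end, c(27L, 60L, 96L))
  # join collapsed to its envelope and flagged
  expect_true(g$genes$compound[3])
  expect_false(any(g$genes$compound[1:2]))
  # /translation trusted verbatim; absent -> translated with code 11
  expect_equal(g$genes$translation[1], "MKVLATR")
  cds_b <- revcomp(substr(g$sequence, 31, 60))
  expect_equal(g$genes$translation[2], phamlin:::.translate_cds(cds_b))
})

test_that("GenBank parser rejects malformed records with diagnostics", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       X  10 bp", "FEATURES", "     CDS             1..6"), f)
  expect_error(read_genbank(f), "ORIGIN")
  f2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       X  10 bp",
               "FEATURES             Location/Qualifiers",
               "     CDS             2..400",
               "ORIGIN",
               "        1 acgtacgtac",
               "//"), f2)
  expect_error(read_genbank(f2), "past sequence end")
})
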