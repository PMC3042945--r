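make_hit <- function(q, s, bits, taxon, evalue = 1e-30, aln = 100) {
  tibble::tibble(qseqid = q, sseqid = s, pident = 90, length = aln,
                 mismatch = 5L, gapopen = 0L, qstart = 1L, qend = 300L,
                 sstart = 1L, send = 100L, evalue = evalue, bitscore = bits,
                 staxids = as.character(taxon))
}

test_that("load_hits filters by e-value and keeps the top n by bitscore", {
  expect_identical(nrow(load_hits(make_hit("q", "s", 100, "1")[0, ])), 0L)

  hits <- dplyr::bind_rows(lapply(1:15, function(i) {
    make_hit("q1", sprintf("s%02d", i), bits = 50 + i, taxon = "1")
  }))
  kept <- load_hits(hits, top_n = 10)
  expect_identical(nrow(kept), 10L)
  expect_setequal(kept$sseqid, sprintf("s%02d", 6:15))
  expect_true(all(diff(kept$bitscore) <= 0))

  # mixed e-values: retained set equals a naive filter-and-sort
  withr::with_seed(6, {
    big <- dplyr::bind_rows(lapply(1:40, function(i) {
      make_hit(sample(c("qa", "qb"), 1), sprintf("x%02d", i),
               bits = runif(1, 40, 200),
               taxon = "1", evalue = 10^-runif(1, 5, 40))
    }))
  })
  kept2 <- load_hits(big, evalue_max = 1e-10, top_n = 10)
  naive <- big[big$evalue <= 1e-10, ]
  naive <- naive[order(naive$qseqid, -naive$bitscore, naive$sseqid), ]
  naive <- do.call(rbind, lapply(split(naive, naive$qseqid), head, 10))
  expect_equal(nrow(kept2), nrow(naive))
  expect_identical(kept2$sseqid, naive$sseqid)
})

test_that("malformed hit files error with a line number", {
  path <- tempfile(fileext = ".tsv")
  ok <- paste(c("q1", "s1", "90.0", "100", "5", "0", "1", "300", "1", "100",
                "1e-30", "150", "131"), collapse = "\t")
  bad <- paste(c("q2", "s2", "not_a_number", "100", "5", "0", "1", "300",
                 "1", "100", "1e-30", "150", "131"), collapse = "\t")
  writeLines(c(ok, bad), path)
  expect_error(load_hits(path), "line 2")

  short <- tempfile(fileext = ".tsv")
  writeLines(paste(rep("x", 12), collapse = "\t"), short)
  expect_error(load_hits(short), "taxon column")
})

test_that("taxonomy_tree validates structure", {
  tree <- toy_taxonomy()
  expect_s3_class(tree, "taxonomy_tree")
  bad <- tibble::tibble(taxon_id = c("1", "2"), parent_id = c("2", "1"),
                        rank = "x", name = "y")
  expect_error(taxonomy_tree(bad), "root")
})

test_that("LCA assignment honours the qualifying-hit rules", {
  tree <- toy_taxonomy()
  # two qualifying hits only: LCA not assigned, best hit still set
  h2 <- dplyr::bind_rows(make_hit("q", "s1", 200, "131"),
                         make_hit("q", "s2", 195, "132"))
  a2 <- assign_lca(h2, tree)
  expect_identical(a2$best_hit_taxon, "131")
  expect_true(is.na(a2$lca_taxon))

  # three hits to the same species
  h3 <- dplyr::bind_rows(make_hit("q", "s1", 200, "101"),
                         make_hit("q", "s2", 195, "101"),
                         make_hit("q", "s3", 190, "101"))
  expect_identical(assign_lca(h3, tree)$lca_taxon, "101")

  # hits below the 0.9 x top window or <= 75 bits do not qualify
  h4 <- dplyr::bind_rows(make_hit("q", "s1", 200, "131"),
                         make_hit("q", "s2", 185, "132"),
                         make_hit("q", "s3", 150, "21"))  # outside window
  a4 <- assign_lca(h4, tree)
  expect_true(is.na(a4$lca_taxon))
  h5 <- dplyr::bind_rows(make_hit("q", "s1", 80, "131"),
                         make_hit("q", "s2", 78, "132"),
                         make_hit("q", "s3", 75, "71"))  # 75 is not > 75
  a5 <- assign_lca(h5, tree)
  expect_true(is.na(a5$lca_taxon))
  h6 <- dplyr::bind_rows(make_hit("q", "s1", 80, "131"),
                         make_hit("q", "s2", 78, "132"),
                         make_hit("q", "s3", 76, "71"))
  expect_identical(assign_lca(h6, tree)$lca_taxon, "6")  # land plants
})

test_that("LCA equals the brute-force ancestor-set oracle", {
  tree <- toy_taxonomy()
  tips <- c(gametotk:::toy_plant_tips(), gametotk:::toy_contam_tips(),
            "141", "151")
  withr::with_seed(99, {
    for (i in 1:50) {
      taxa <- sample(tips, sample(3:6, 1), replace = TRUE)
      hits <- dplyr::bind_rows(lapply(seq_along(taxa), function(j) {
        make_hit("q", sprintf("s%d", j), 200 - j, taxa[j])
      }))
      got <- assign_lca(hits, tree)$lca_taxon
      expect_identical(got, oracle_lca(tree, taxa))
    }
  })
})

test_that("taxonomic summary respects clade nesting", {
  tree <- toy_taxonomy()
  asg <- tibble::tibble(
    query_id = sprintf("q%d", 1:6),
    best_hit_taxon = c("131", "101", "21", "71", "132", "91"),
    lca_taxon = c("13", "10", "2", "6", "11", NA))
  cats <- toy_taxonomy_categories()
  sm <- taxonomic_summary(asg, tree, cats)
  g <- function(nm, col) sm[[col]][sm$category == nm]
  expect_identical(g("Ferns", "n_best"), 1L)
  expect_identical(g("Angiosperms", "n_best"), 2L)
  # nested categories: child counts never exceed the parent's
  expect_lte(g("Ferns", "n_best"), g("Vascular plants", "n_best"))
  expect_lte(g("Vascular plants", "n_best"), g("Land plants", "n_best"))
  expect_lte(g("Land plants", "n_best"), g("Green plants", "n_best"))
  expect_lte(g("Green plants", "n_best"), g("Eukaryotes", "n_best"))
  expect_equal(g("Green plants", "pct_best"), 100 * 5 / 6)
  expect_error(taxonomic_summary(asg, tree, c(Nope = "9999")),
               "unknown category")
})

test_that("plastid screen merges hit intervals and counts overlapped genes", {
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:8),
                          start = seq(1, 7001, by = 1000),
                          end = seq(800, 7800, by = 1000))
  one <- tibble::tibble(qseqid = "u1", sstart = 100, send = 900)
  r1 <- plastid_screen(one, genes, genome_length = 10000)
  expect_identical(r1$flag, "putative_transcript")
  expect_identical(r1$n_genes, 1L)

  # merged span of 3501 bp crosses the 3.5 kb boundary (strictly greater)
  over <- tibble::tibble(qseqid = c("u2", "u2"),
                         sstart = c(1, 2000), send = c(2500, 3501))
  r2 <- plastid_screen(over, genes[1:3, ], genome_length = 10000)
  expect_identical(r2$span_bp, 3501L)
  expect_identical(r2$flag, "genomic_contamination")
  at <- tibble::tibble(qseqid = "u3", sstart = 1, send = 3500)
  expect_identical(
    plastid_screen(at, genes[1:4, ], genome_length = 10000)$flag,
    "putative_transcript")

  # 6 genes spanned -> contamination; 5 genes -> transcript
  six <- tibble::tibble(qseqid = "u4", sstart = 500, send = 5300)
  # span 4801 > 3500 would also flag; shrink per-gene hits instead
  six <- tibble::tibble(qseqid = rep("u4", 6),
                        sstart = genes$start[1:6] + 10,
                        send = genes$start[1:6] + 110)
  r6 <- plastid_screen(six, genes, genome_length = 10000)
  expect_identical(r6$n_genes, 6L)
  expect_identical(r6$flag, "genomic_contamination")
  five <- six[1:5, ]
  expect_identical(plastid_screen(five, genes, genome_length = 10000)$flag,
                   "putative_transcript")

  expect_error(plastid_screen(one, genes, genome_length = 500),
               "beyond the plastid genome")
})

test_that("GFF3 gene reading and reversed subject coordinates work", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t100\t400\t.\t+\t.\tID=gA",
               "chr\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=mA",
               "chr\tsrc\tgene\t900\t1400\t.\t-\t.\tID=gB"), gff)
  hits <- tibble::tibble(qseqid = "u1", sstart = 1200, send = 950)
  r <- plastid_screen(hits, gff, genome_length = 2000)
  expect_identical(r$span_bp, 251L)
  expect_identical(r$n_genes, 1L)
})
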