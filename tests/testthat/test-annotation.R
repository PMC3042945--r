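test_that("longest ORF handles textbook, degenerate and short inputs", {
  orf <- longest_orf(c(s = "ATGAAATAG"))
  expect_identical(orf$frame, "+1")
  expect_identical(orf$peptide, "MK")
  expect_identical(orf$start, 0L)
  expect_identical(orf$end, 6L)

  # degenerate stop-only frame: zero-length peptide, leftmost call
  allstop <- longest_orf(c(s = "TAA"))
  expect_identical(allstop$peptide, "")
  expect_identical(allstop$frame, "+1")
  expect_identical(allstop$start, 0L)
  expect_identical(allstop$end, 0L)

  expect_identical(nrow(longest_orf(c(s = "AC"))), 0L)
})

test_that("longest ORF equals the exhaustive six-frame oracle", {
  withr::with_seed(2025, {
    seqs <- vapply(1:100, function(i) random_dna_str(sample(60:300, 1)),
                   character(1))
  })
  names(seqs) <- sprintf("s%03d", seq_along(seqs))
  got <- longest_orf(seqs)
  for (id in names(seqs)) {
    want <- oracle_longest_orf(seqs[[id]])
    have <- got[got$seq_id == id, ]
    expect_identical(have$peptide, want$peptide)
    expect_identical(have$frame, want$frame)
    expect_identical(have$start, as.integer(want$start))
    expect_identical(have$end, as.integer(want$end))
    expect_identical((have$end - have$start) %% 3L, 0L)
    expect_false(grepl("*", have$peptide, fixed = TRUE))
  }
})

test_that("OBO parsing and slim mapping follow the true-path rule", {
  onto <- toy_ontology()
  path <- tempfile(fileext = ".obo")
  write_obo(onto, path)
  re <- read_obo(path)
  expect_identical(unname(sort(re$terms$id)), sort(onto$terms$id))
  expect_setequal(re$slim_subsets[["goslim_toy"]], onto$slim)

  slim <- onto$slim
  # a slim term maps to itself
  m1 <- map_to_slim(tibble::tibble(seq_id = "x", term_id = slim[1]), onto)
  expect_true(slim[1] %in% m1$slim_id)
  # a leaf maps to its slim ancestors
  leaf <- setdiff(onto$terms$id, onto$edges$to)[1]
  m2 <- map_to_slim(tibble::tibble(seq_id = "x", term_id = leaf), onto)
  expect_identical(sort(m2$slim_id),
                   sort(oracle_slim_map(leaf, onto$edges, slim)))
  expect_warning(
    map_to_slim(tibble::tibble(seq_id = "x", term_id = "GO:9999999"), onto),
    "unknown")
})

test_that("slim mapping equals the transitive-closure oracle on random DAGs", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      n <- 20
      ids <- sprintf("T%02d", 1:n)
      # random DAG: each node points to 1-2 earlier nodes
      edges <- dplyr::bind_rows(lapply(2:n, function(i) {
        k <- min(sample(1:2, 1), i - 1)
        tibble::tibble(from = ids[i],
                       to = sample(ids[seq_len(i - 1)], k),
                       type = sample(c("is_a", "part_of"), k, replace = TRUE))
      }))
      terms <- tibble::tibble(id = ids, name = ids, namespace = "bp")
      slim <- sample(ids, 6)
      g <- ontology_graph(terms, edges, slim = slim)
      pick <- sample(ids, 8)
      ann <- tibble::tibble(seq_id = sprintf("s%d", seq_along(pick)),
                            term_id = pick)
      got <- map_to_slim(ann, g)
      for (j in seq_along(pick)) {
        expect_setequal(got$slim_id[got$seq_id == ann$seq_id[j]],
                        oracle_slim_map(pick[j], edges, slim))
      }
    }
  })
})

test_that("slim mapping is monotone and is_a-only mode is narrower", {
  onto <- toy_ontology()
  leaves <- setdiff(onto$terms$id, onto$edges$to)
  ann1 <- tibble::tibble(seq_id = "x", term_id = leaves[1])
  ann2 <- tibble::tibble(seq_id = "x", term_id = leaves[1:3])
  m1 <- map_to_slim(ann1, onto)
  m2 <- map_to_slim(ann2, onto)
  expect_true(all(m1$slim_id %in% m2$slim_id))
  m_isa <- map_to_slim(ann2, onto, use_part_of = FALSE)
  expect_true(all(m_isa$slim_id %in% m2$slim_id))
})

test_that("enrichment: symmetric tables, oracle equivalence and BH control", {
  ann <- function(pre, n, term) {
    tibble::tibble(seq_id = sprintf("%s%03d", pre, seq_len(n)),
                   term_id = term)
  }
  # identical term frequencies: all p = 1, nothing significant
  te <- dplyr::bind_rows(ann("t", 5, "A"), ann("u", 5, "B"))
  re <- dplyr::bind_rows(ann("r", 5, "A"), ann("q", 5, "B"))
  er <- enrichment(te, re)
  expect_true(all(er$p == 1))
  expect_false(any(er$significant))
  expect_error(enrichment(te, te[0, ]), "empty")

  # direction flips when test and reference swap
  te2 <- dplyr::bind_rows(ann("t", 40, "A"), ann("u", 10, "B"))
  re2 <- dplyr::bind_rows(ann("r", 10, "A"), ann("q", 40, "B"))
  e12 <- enrichment(te2, re2)
  e21 <- enrichment(re2, te2)
  expect_equal(e12$p[order(e12$term_id)], e21$p[order(e21$term_id)])
  d12 <- e12$direction[order(e12$term_id)]
  d21 <- e21$direction[order(e21$term_id)]
  expect_identical(d12, dplyr::recode(d21, over = "under", under = "over"))

  # 50 random 2x2 tables vs the hypergeometric-sum and step-up BH oracles
  withr::with_seed(11, {
    tabs <- tibble::tibble(a = sample(0:30, 50, TRUE),
                           b = sample(1:50, 50, TRUE),
                           c = sample(0:30, 50, TRUE),
                           d = sample(1:50, 50, TRUE))
  })
  ps <- vapply(1:50, function(i) {
    fisher.test(matrix(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]), 2))$p.value
  }, numeric(1))
  oracle_ps <- vapply(1:50, function(i) {
    oracle_fisher_two_sided(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
  }, numeric(1))
  expect_equal(ps, oracle_ps, tolerance = 1e-7)
  expect_equal(p.adjust(ps, "BH"), oracle_bh(ps), tolerance = 1e-12)

  # q is non-decreasing in the rank of p
  er3 <- enrichment(te2, re2)
  expect_true(all(diff(er3$q[order(er3$p)]) >= -1e-12))
})

test_that("detection rate applies the strict residue threshold", {
  refs <- sprintf("g%03d", 1:357)
  hits <- tibble::tibble(ref_id = refs[1:333], aln_len = 100)
  dr <- detection_rate(hits, refs)
  expect_identical(dr$detected, 333L)
  expect_equal(dr$pct, 93.3, tolerance = 0.05)

  refs2 <- sprintf("t%03d", 1:959)
  hits2 <- tibble::tibble(ref_id = refs2[1:754], aln_len = 50)
  expect_equal(detection_rate(hits2, refs2)$pct, 78.6, tolerance = 0.05)

  # exactly 30 residues does not count; 31 does
  expect_identical(
    detection_rate(tibble::tibble(ref_id = "g", aln_len = 30), "g")$detected,
    0L)
  expect_identical(
    detection_rate(tibble::tibble(ref_id = "g", aln_len = 31), "g")$detected,
    1L)
  expect_identical(detection_rate(hits[0, ], refs)$detected, 0L)
  expect_error(detection_rate(hits, character()), "empty")
})

test_that("set overlap equals inclusion-exclusion on random sets", {
  a <- sprintf("x%02d", 1:20)
  b <- sprintf("x%02d", 11:30)
  expect_identical(
    set_overlap(list(A = a, B = sprintf("y%02d", 1:5)))$count[3], 0L)
  same <- set_overlap(list(A = a, B = a))
  expect_identical(same$count[same$region == "A&B"], 20L)

  withr::with_seed(21, {
    u <- sprintf("id%03d", 1:200)
    s3 <- list(A = sample(u, 80), B = sample(u, 60), C = sample(u, 90))
  })
  ov <- set_overlap(s3, universe = u)
  expect_identical(sum(ov$count), 200L)
  # bitmask oracle
  mem <- sapply(s3, function(s) u %in% s)
  key <- apply(mem, 1, function(r) if (!any(r)) "none"
               else paste(names(s3)[r], collapse = "&"))
  for (rg in ov$region) {
    expect_identical(ov$count[ov$region == rg], sum(key == rg),
                     info = rg)
  }
  expect_error(set_overlap(list(a = "1", b = "2", c = "3", d = "4")),
               "2 or 3")
})
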