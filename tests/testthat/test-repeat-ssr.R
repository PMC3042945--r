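test_that("SSR mining: thresholds, canonical motifs, embedded runs", {
  # 2.5 x ACGT: far below the tetranucleotide threshold
  expect_identical(nrow(find_ssrs(c(s = "ACGTACGTAC"))), 0L)

  # (AG) x 12 embedded in 100 bp
  withr::with_seed(1, {
    left <- random_dna_str(40)
    right <- random_dna_str(36)
  })
  s <- paste0(left, strrep("AG", 12), right)
  loci <- find_ssrs(c(s = s))
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$motif, "AG")
  expect_identical(loci$n_repeats, 12L)
  expect_identical(loci$end - loci$start, 24L)
  expect_identical(loci$start, 40L)

  # all four phase/strand spellings canonicalize identically
  for (m in c("GA", "CT", "TC")) {
    expect_identical(canonical_motif(m), "AG")
  }
  expect_identical(canonical_motif("TTA"), "AAT")

  # homopolymers are never reported as higher-order motifs
  expect_identical(nrow(find_ssrs(c(s = strrep("A", 60)))), 0L)

  # di-run of exactly 10 repeats passes, 9 does not
  expect_identical(nrow(find_ssrs(c(s = paste0(left, strrep("TG", 10),
                                               right)))), 1L)
  expect_identical(nrow(find_ssrs(c(s = paste0(left, strrep("TG", 9),
                                               right)))), 0L)
})

test_that("SSR finder matches the exhaustive brute-force oracle", {
  withr::with_seed(2024, {
    seqs <- vapply(1:60, function(i) {
      s <- random_dna_str(sample(80:300, 1))
      if (i %% 3 == 0) {
        k <- sample(2:5, 1)
        motif <- random_dna_str(k)
        reps <- sample(6:14, 1)
        pos <- sample(nchar(s) - 20, 1)
        s <- paste0(substr(s, 1, pos), strrep(motif, reps),
                    substr(s, pos + 1, nchar(s)))
      }
      s
    }, character(1))
  })
  names(seqs) <- sprintf("s%03d", seq_along(seqs))
  got <- find_ssrs(seqs)
  for (id in names(seqs)) {
    want <- oracle_ssrs(seqs[[id]])
    have <- got[got$seq_id == id, ]
    expect_identical(nrow(have), nrow(want))
    if (nrow(want)) {
      expect_identical(have$start, as.integer(want$start))
      expect_identical(have$end, as.integer(want$end))
      expect_identical(have$n_repeats, as.integer(want$n_repeats))
      expect_identical(have$motif_length, as.integer(want$motif_length))
    }
  }
})

test_that("canonical motifs are invariant under reverse complement", {
  withr::with_seed(8, {
    seqs <- vapply(1:20, function(i) {
      s <- random_dna_str(150)
      motif <- random_dna_str(sample(2:3, 1))
      paste0(substr(s, 1, 60), strrep(motif, 12), substr(s, 61, 150))
    }, character(1))
  })
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  fwd <- find_ssrs(seqs)
  rc <- find_ssrs(setNames(gametotk:::revcomp(seqs), names(seqs)))
  f <- fwd[order(fwd$seq_id, fwd$start), c("seq_id", "motif", "n_repeats")]
  r <- rc[order(rc$seq_id, rc$start), c("seq_id", "motif", "n_repeats")]
  r <- r[order(r$seq_id), ]
  expect_identical(dplyr::arrange(f, seq_id, motif, n_repeats),
                   dplyr::arrange(r, seq_id, motif, n_repeats))
})

test_that("flank check is inclusive at the boundary", {
  loci <- tibble::tibble(seq_id = "s", motif = "AG", motif_length = 2L,
                         n_repeats = 10L, start = c(0L, 20L, 25L),
                         end = c(20L, 40L, 45L),
                         left_flank = c(0L, 20L, 25L),
                         right_flank = c(40L, 20L, 15L))
  fc <- flank_check(loci, min_flank = 20)
  expect_identical(fc$amplifiable, c(FALSE, TRUE, FALSE))
  # random placements: flag equals direct arithmetic
  withr::with_seed(3, {
    rl <- tibble::tibble(seq_id = "s", motif = "AG", motif_length = 2L,
                         n_repeats = 10L,
                         left_flank = sample(0:60, 50, replace = TRUE),
                         right_flank = sample(0:60, 50, replace = TRUE))
  })
  expect_identical(flank_check(rl)$amplifiable,
                   rl$left_flank >= 20 & rl$right_flank >= 20)
})

test_that("repeat screening finds planted elements and summarizes classes", {
  empty <- screen_repeat_library(c(s = random_dna_str(500)),
                                 tibble::tibble(element_id = character(),
                                                repeat_class = character(),
                                                sequence = character()))
  expect_identical(nrow(empty$summary), 0L)

  withr::with_seed(14, {
    host <- random_dna_str(10000)
    element <- random_dna_str(500)
  })
  planted <- paste0(substr(host, 1, 4000), element,
                    substr(host, 4501, 10000))
  lib <- tibble::tibble(element_id = "el1", repeat_class = "LTR/Copia",
                        sequence = element)
  scr <- screen_repeat_library(c(s = planted), lib)
  expect_identical(nrow(scr$matches), 1L)
  expect_identical(scr$matches$start, 4000L)
  expect_identical(scr$matches$end, 4500L)
  expect_equal(scr$summary$total_length, 500L)
  expect_equal(scr$summary$pct_sequence, 5.00)

  # reverse-strand insertions are found too
  planted_rc <- paste0(substr(host, 1, 4000), gametotk:::revcomp(element),
                       substr(host, 4501, 10000))
  scr2 <- screen_repeat_library(c(s = planted_rc), lib)
  expect_identical(scr2$matches$strand, "-")

  expect_error(
    screen_repeat_library(c(s = host),
                          tibble::tibble(element_id = "x",
                                         repeat_class = "",
                                         sequence = element)),
    "class")
})

test_that("repeat class summary merges intervals and respects totals", {
  matches <- tibble::tibble(
    seq_id = c("u1", "u1", "u2"),
    repeat_class = c("LTR/Copia", "LTR/Copia", "LINE/L1"),
    start = c(0L, 50L, 10L), end = c(100L, 150L, 60L))
  sm <- repeat_class_summary(matches, total_bp = 1000)
  copia <- sm[sm$repeat_class == "LTR/Copia", ]
  expect_identical(copia$total_length, 150L)   # overlapping intervals merged
  expect_identical(copia$n_elements, 2L)
  expect_equal(copia$pct_sequence, 15)
  expect_lte(sum(sm$total_length), 1000)
})
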