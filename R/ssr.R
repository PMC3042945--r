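#' Canonical SSR motif
#'
#' The canonical representative of a repeat motif: the lexicographically
#' smallest string among all rotations of the motif and all rotations of its
#' reverse complement. Used so that e.g. AG/GA/CT/TC runs all report motif
#' "AG".
#'
#' @param motif A DNA string of length >= 1.
#' @return The canonical motif string.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    rots <- vapply(seq_len(k) - 1L, function(r) {
      paste0(substr(m, r + 1, k), substr(m, 1, r))
    }, character(1))
    rc <- revcomp(m)
    rots_rc <- vapply(seq_len(k) - 1L, function(r) {
      paste0(substr(rc, r + 1, k), substr(rc, 1, r))
    }, character(1))
    min(c(rots, rots_rc))
  }, character(1), USE.NAMES = FALSE)
}

# Is the k-mer a repetition of a shorter motif?
is_primitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 &&
        motif == strrep(substr(motif, 1, d), k / d)) {
      return(FALSE)
    }
  }
  TRUE
}

find_ssrs_one <- function(seq, min_repeats) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- list()
  for (k in as.integer(names(min_repeats))) {
    if (n < 2 * k) next
    eq <- ch[seq_len(n - k)] == ch[(k + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      L <- r$lengths[j]
      total <- L + k
      reps <- total %/% k
      if (reps < min_repeats[[as.character(k)]]) next
      i <- starts[j]                       # 1-based start of the run
      motif <- substr(seq, i, i + k - 1)
      if (!is_primitive(motif)) next       # found at a shorter motif length
      out[[length(out) + 1]] <- tibble(
        motif = canonical_motif(motif),
        motif_length = k,
        n_repeats = reps,
        start = i - 1L,                    # 0-based half-open
        end = i - 1L + k * reps
      )
    }
  }
  if (!length(out)) {
    return(tibble(motif = character(), motif_length = integer(),
                  n_repeats = integer(), start = integer(), end = integer()))
  }
  cand <- bind_rows(out) |>
    mutate(len = .data$end - .data$start) |>
    arrange(desc(.data$len), .data$motif_length, .data$start)
  # resolve overlaps: longest interval wins; ties favour the shorter motif
  keep <- logical(nrow(cand))
  taken_start <- integer()
  taken_end <- integer()
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  cand[keep, ] |>
    arrange(.data$start) |>
    select(-"len")
}

#' Mine perfect simple sequence repeats
#'
#' Reports maximal perfect tandem runs of 2-5 bp motifs meeting per-motif-
#' length minimum repeat counts (default: di >= 10, tri >= 9, tetra >= 7,
#' penta >= 6 repeats, i.e. strictly more than 9/8/6/5). Motifs are reported
#' in canonical form (see [canonical_motif()]); motifs that are repetitions
#' of a shorter motif (including homopolymers) are excluded, and overlapping
#' calls at different motif lengths are resolved to the longest interval
#' (ties going to the shorter motif). Flank lengths support downstream
#' primer-design screening.
#'
#' @param x Sequences: data frame with `seq_id`/`sequence`, or a (named)
#'   character vector.
#' @param min_repeats Named vector mapping motif length (as name) to the
#'   minimum repeat count (each >= 2).
#' @return A tibble `seq_id`, `motif`, `motif_length`, `n_repeats`,
#'   `start`, `end` (0-based half-open), `left_flank`, `right_flank`.
#' @export
find_ssrs <- function(x, min_repeats = c(`2` = 10, `3` = 9, `4` = 7,
                                         `5` = 6)) {
  if (any(min_repeats < 2)) abort("all `min_repeats` thresholds must be >= 2")
  tb <- as_seq_tbl(x)
  res <- map2(tb$seq_id, tb$sequence, function(id, s) {
    loci <- find_ssrs_one(s, min_repeats)
    if (nrow(loci)) {
      loci$seq_id <- id
      loci$left_flank <- loci$start
      loci$right_flank <- nchar(s) - loci$end
    }
    loci
  })
  out <- bind_rows(res)
  if (!nrow(out)) {
    return(tibble(seq_id = character(), motif = character(),
                  motif_length = integer(), n_repeats = integer(),
                  start = integer(), end = integer(),
                  left_flank = integer(), right_flank = integer()))
  }
  select(out, "seq_id", "motif", "motif_length", "n_repeats", "start",
         "end", "left_flank", "right_flank")
}

#' Flag SSR loci with sufficient flanking sequence
#'
#' A locus is potentially amplifiable when both flanks are at least
#' `min_flank` bp (inclusive), a simple proxy for primer-design
#' feasibility.
#'
#' @param loci Output of [find_ssrs()].
#' @param min_flank Minimum flank length (bp).
#' @return `loci` with an added logical `amplifiable` column.
#' @export
flank_check <- function(loci, min_flank = 20) {
  mutate(loci, amplifiable = .data$left_flank >= min_flank &
           .data$right_flank >= min_flank)
}

#' Screen sequences against a classified repeat library
#'
#' Local (Smith-Waterman style: match +1, mismatch -2, gap -3) alignment of
#' each library element, on both strands, against each sequence. Matches of
#' at least `min_len` alignment columns and `min_identity` identity are
#' kept; per-class intervals are merged before computing masked lengths.
#'
#' @param x Sequences (data frame or named character vector).
#' @param library The repeat library: a data frame with `element_id`,
#'   `repeat_class`, `sequence`, or a FASTA path whose description lines
#'   carry a `class=...` tag. Elements without a class label are an error.
#' @param min_identity Minimum alignment identity (matches / columns).
#' @param min_len Minimum alignment length (columns).
#' @return A list with `matches` (tibble: `seq_id`, `element_id`,
#'   `repeat_class`, `start`, `end`, `strand`, `identity`, `length`) and
#'   `summary` (see [repeat_class_summary()]).
#' @export
screen_repeat_library <- function(x, library, min_identity = 0.75,
                                  min_len = 30) {
  tb <- as_seq_tbl(x)
  lib <- read_repeat_library(library)
  total_bp <- sum(nchar(tb$sequence))
  if (nrow(lib) == 0 || nrow(tb) == 0) {
    matches <- tibble(seq_id = character(), element_id = character(),
                      repeat_class = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), length = integer())
    return(list(matches = matches,
                summary = repeat_class_summary(matches, total_bp)))
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  rows <- list()
  subjects <- Biostrings::DNAStringSet(setNames(tb$sequence, tb$seq_id))
  for (e in seq_len(nrow(lib))) {
    for (strand in c("+", "-")) {
      el <- if (strand == "+") lib$sequence[e] else revcomp(lib$sequence[e])
      aln <- Biostrings::pairwiseAlignment(
        pattern = subjects, subject = el,
        type = "local", substitutionMatrix = submat,
        gapOpening = 0, gapExtension = 3)
      cols <- Biostrings::nchar(aln)
      matches_n <- Biostrings::nmatch(aln)
      idn <- ifelse(cols > 0, matches_n / cols, 0)
      ok <- which(cols >= min_len & idn >= min_identity)
      if (length(ok)) {
        pat_rng <- Biostrings::pattern(aln)
        rows[[length(rows) + 1]] <- tibble(
          seq_id = tb$seq_id[ok],
          element_id = lib$element_id[e],
          repeat_class = lib$repeat_class[e],
          start = BiocGenerics::start(pat_rng)[ok] - 1L,
          end = BiocGenerics::end(pat_rng)[ok],
          strand = strand,
          identity = idn[ok],
          length = cols[ok]
        )
      }
    }
  }
  matches <- if (length(rows)) bind_rows(rows) else
    tibble(seq_id = character(), element_id = character(),
           repeat_class = character(), start = integer(), end = integer(),
           strand = character(), identity = numeric(), length = integer())
  # keep the best strand per (sequence, element, locus): drop the weaker of
  # two overlapping strand hits of the same element on the same sequence
  if (nrow(matches) > 1) {
    matches <- matches |>
      group_by(.data$seq_id, .data$element_id) |>
      arrange(desc(.data$identity * .data$length), .by_group = TRUE) |>
      group_modify(function(df, key) {
        keep <- rep(TRUE, nrow(df))
        for (i in seq_len(nrow(df))[-1]) {
          prior <- which(keep[seq_len(i - 1)])
          if (any(df$start[i] < df$end[prior] & df$end[i] > df$start[prior])) {
            keep[i] <- FALSE
          }
        }
        df[keep, ]
      }) |>
      ungroup() |>
      arrange(.data$seq_id, .data$start)
  }
  list(matches = matches,
       summary = repeat_class_summary(matches, total_bp))
}

#' Repeat-class summary
#'
#' Per repeat class: number of element matches, total masked length after
#' merging overlapping per-sequence intervals, and the masked percentage of
#' the total sequence length.
#'
#' @param matches A match tibble (`seq_id`, `repeat_class`, `start`, `end`).
#' @param total_bp Total length of the screened sequence set (bp).
#' @return A tibble `repeat_class`, `n_elements`, `total_length`,
#'   `pct_sequence`.
#' @export
repeat_class_summary <- function(matches, total_bp) {
  if (nrow(matches) == 0) {
    return(tibble(repeat_class = character(), n_elements = integer(),
                  total_length = integer(), pct_sequence = numeric()))
  }
  matches |>
    group_by(.data$repeat_class) |>
    group_modify(function(df, key) {
      masked <- df |>
        group_by(.data$seq_id) |>
        group_modify(function(d2, k2) {
          m <- IRanges::reduce(IRanges::IRanges(start = d2$start + 1,
                                                end = d2$end))
          tibble(bp = sum(IRanges::width(m)))
        }) |>
        ungroup()
      tibble(n_elements = nrow(df), total_length = sum(masked$bp))
    }) |>
    ungroup() |>
    mutate(pct_sequence = 100 * .data$total_length / total_bp)
}

read_repeat_library <- function(library) {
  if (is.character(library) && length(library) == 1) {
    set <- Biostrings::readDNAStringSet(library)
    desc <- names(set)
    cls <- regmatches(desc, regexpr("class=[^ ]+", desc))
    has <- grepl("class=", desc)
    if (!all(has)) {
      abort("repeat library element(s) without a class= label")
    }
    return(tibble(element_id = sub(" .*", "", desc),
                  repeat_class = sub("^class=", "", cls),
                  sequence = as.character(set)))
  }
  lib <- as_tibble(library)
  if (!all(c("element_id", "repeat_class", "sequence") %in% names(lib))) {
    abort("library needs element_id, repeat_class, sequence columns")
  }
  if (any(is.na(lib$repeat_class) | lib$repeat_class == "")) {
    abort("repeat library element(s) without a class= label")
  }
  lib
}
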