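#' Sequence-set length statistics
#'
#' The eight summary statistics reported for a sequence set: count, mean,
#' sd, mode, median, min, max and total length. The mode is the smallest
#' length attaining the maximal frequency.
#'
#' @param x Numeric lengths, a character vector of sequences, or a data
#'   frame with a `sequence` column.
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `mode`,
#'   `median`, `min`, `max`, `total`. An empty input gives `n = 0` and `NA`
#'   elsewhere.
#' @export
length_stats <- function(x) {
  lengths <- if (is.data.frame(x)) {
    nchar(x$sequence)
  } else if (is.character(x)) {
    nchar(x)
  } else {
    as.numeric(x)
  }
  if (length(lengths) == 0) {
    return(tibble(n = 0L, mean = NA_real_, sd = NA_real_, mode = NA_real_,
                  median = NA_real_, min = NA_real_, max = NA_real_,
                  total = NA_real_))
  }
  tab <- table(lengths)
  mode_val <- as.numeric(names(tab)[tab == max(tab)])[1]
  tibble(
    n = length(lengths),
    mean = mean(lengths),
    sd = sd(lengths),
    mode = mode_val,
    median = median(lengths),
    min = min(lengths),
    max = max(lengths),
    total = sum(lengths)
  )
}

#' Assembly summary report
#'
#' For an `assembly_result`, emits the standard per-pass summary rows and
#' asserts the read-conservation identity (reads assembled + discarded +
#' singletons = input reads) and the unigene-composition identity (primary
#' contigs + secondary contigs + singletons = unigenes), raising a hard
#' error on violation. For a data frame or named list of counts
#' (`reads_assembled`, `reads_discarded`, `reads_singleton`,
#' `n_primary_contigs`, `n_secondary_contigs`), the same identities are
#' applied to derive `total_reads` and `n_unigenes`.
#'
#' @param x An `assembly_result`, or counts (data frame / named list).
#' @param ... Unused.
#' @return A tibble of summary statistics.
#' @export
assembly_report <- function(x, ...) UseMethod("assembly_report")

#' @export
assembly_report.assembly_result <- function(x, ...) {
  st <- x$stats
  ok <- st$reads_assembled + st$reads_discarded + st$reads_singleton ==
    st$n_reads_in
  ok2 <- st$n_primary_contigs + st$n_secondary_contigs + st$reads_singleton ==
    st$n_unigenes
  if (!all(ok) || !all(ok2)) {
    abort("corrupt assembly: read-conservation identity violated")
  }
  st |>
    mutate(total_reads = .data$n_reads_in,
           total_mbp = .data$total_bp / 1e6) |>
    select("pass", "total_reads", "reads_assembled", "reads_discarded",
           "reads_singleton", "n_primary_contigs", "n_secondary_contigs",
           "n_unigenes", "mean_unigene_length", "max_unigene_length",
           "total_mbp", "mean_depth")
}

#' @export
assembly_report.default <- function(x, ...) {
  x <- as.list(x)
  need <- c("reads_assembled", "reads_discarded", "reads_singleton",
            "n_primary_contigs", "n_secondary_contigs")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("missing counts: ", paste(missing, collapse = ", ")))
  }
  tibble(
    reads_assembled = as.numeric(x$reads_assembled),
    reads_discarded = as.numeric(x$reads_discarded),
    reads_singleton = as.numeric(x$reads_singleton),
    n_primary_contigs = as.numeric(x$n_primary_contigs),
    n_secondary_contigs = as.numeric(x$n_secondary_contigs)
  ) |>
    mutate(
      total_reads = .data$reads_assembled + .data$reads_discarded +
        .data$reads_singleton,
      n_unigenes = .data$n_primary_contigs + .data$n_secondary_contigs +
        .data$reads_singleton
    )
}

#' Bootstrapped unigene accumulation curve
#'
#' Given the empirical reads-per-unigene distribution of an assembly, the
#' pooled reads (each labelled by its unigene) are shuffled and scanned one
#' at a time; the number of distinct unigenes detected after each draw is
#' averaged over `n_boot` replicate sample orders, with a percentile
#' confidence band. Milestones report the first draw at which the mean
#' curve reaches 90/95/99% of the unigene total; `last10_mean_reads` is the
#' per-replicate mean number of additional reads needed to detect each of
#' the last ten unigenes.
#'
#' @param counts Reads-per-unigene: a positive integer vector, or a data
#'   frame with an `n_reads` column.
#' @param n_boot Number of replicate random sample orders.
#' @param conf Confidence level for the percentile band.
#' @param seed Integer seed.
#' @param milestones Fractions of the unigene total to locate on the mean
#'   curve.
#' @return An object of class `accumulation_curve`: `curve` (tibble `draw`,
#'   `mean_detected`, `ci_low`, `ci_high`), `milestones` (tibble `fraction`,
#'   `draw`), `last10_mean_reads` (NA when fewer than 11 unigenes),
#'   `n_unigenes`, `n_reads`, `n_boot`, `conf`, `seed`.
#' @export
accumulation_curve <- function(counts, n_boot = 1000, conf = 0.95,
                               seed = NULL,
                               milestones = c(0.90, 0.95, 0.99)) {
  if (is.data.frame(counts)) counts <- counts$n_reads
  counts <- as.integer(counts)
  if (length(counts) == 0) abort("`counts` is empty")
  if (any(is.na(counts)) || any(counts < 1)) {
    abort("all reads-per-unigene counts must be >= 1")
  }
  U <- length(counts)
  total <- sum(counts)
  labels <- rep.int(seq_len(U), counts)
  det <- matrix(0L, nrow = total, ncol = n_boot)
  idx_u <- integer(n_boot)
  idx_u10 <- rep(NA_integer_, n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      perm <- if (total > 1) sample(labels) else labels
      d <- cumsum(!duplicated(perm))
      det[, b] <- d
      idx_u[b] <- match(U, d)
      if (U >= 11) idx_u10[b] <- match(U - 10L, d)
    }
  })
  alpha <- (1 - conf) / 2
  mean_detected <- rowMeans(det)
  qs <- t(apply(det, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  curve <- tibble(
    draw = seq_len(total),
    mean_detected = mean_detected,
    ci_low = qs[, 1],
    ci_high = qs[, 2]
  )
  ms <- tibble(
    fraction = milestones,
    draw = vapply(milestones, function(f) {
      hit <- which(mean_detected >= f * U)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
  )
  last10 <- if (U >= 11) mean((idx_u - idx_u10) / 10) else NA_real_
  structure(list(curve = curve, milestones = ms,
                 last10_mean_reads = last10,
                 n_unigenes = U, n_reads = total,
                 n_boot = n_boot, conf = conf, seed = seed),
            class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf(
    "<accumulation_curve> %d unigenes, %d reads, %d bootstrap replicates\n",
    x$n_unigenes, x$n_reads, x$n_boot))
  print(x$milestones)
  invisible(x)
}

#' @export
tidy.accumulation_curve <- function(x, ...) x$curve

#' @export
glance.accumulation_curve <- function(x, ...) {
  ms <- setNames(as.list(x$milestones$draw),
                 sprintf("draw_at_%d", round(100 * x$milestones$fraction)))
  as_tibble(c(list(n_unigenes = x$n_unigenes, n_reads = x$n_reads,
                   n_boot = x$n_boot,
                   last10_mean_reads = x$last10_mean_reads), ms))
}

#' Fixed-width histogram with optional tail pooling
#'
#' Bins are half-open `[k*w, (k+1)*w)`. When `clip = c(lo, hi)` is given,
#' all values in `[lo, hi)` are pooled into a single bin, as is done for
#' long read-depth tails in coverage histograms.
#'
#' @param values Numeric values.
#' @param bin_width Bin width (> 0).
#' @param clip Optional two-element numeric `c(lo, hi)` pooling range.
#' @return A tibble with `bin_start`, `bin_end`, `count`.
#' @export
bin_histogram <- function(values, bin_width, clip = NULL) {
  if (bin_width <= 0) abort("`bin_width` must be > 0")
  if (length(values) == 0) {
    return(tibble(bin_start = numeric(), bin_end = numeric(),
                  count = integer()))
  }
  pooled <- 0L
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2, clip[1] < clip[2])
    in_clip <- values >= clip[1] & values < clip[2]
    pooled <- sum(in_clip)
    values <- values[!in_clip]
  }
  out <- tibble(bin = floor(values / bin_width)) |>
    count(.data$bin, name = "count") |>
    mutate(bin_start = .data$bin * bin_width,
           bin_end = (.data$bin + 1) * bin_width) |>
    select("bin_start", "bin_end", "count")
  if (pooled > 0) {
    out <- bind_rows(out, tibble(bin_start = clip[1], bin_end = clip[2],
                                 count = pooled)) |>
      arrange(.data$bin_start)
  }
  out
}

#' Alignment identity of a query against a reference
#'
#' End-to-end identity of the query (e.g. an assembled consensus) against a
#' reference sequence: a global-local alignment (match +1, mismatch -1, gap
#' open 2, gap extension 1) aligning the whole query within the reference,
#' with identity = matches / alignment columns. The reverse complement is
#' tried when the forward strand falls below `rc_below`, and the better of
#' the two is returned.
#'
#' @param query,reference DNA strings.
#' @param try_rc Also consider the query's reverse complement.
#' @param rc_below Forward-strand identity below which the reverse
#'   complement is evaluated.
#' @return A single identity in `[0, 1]`.
#' @export
alignment_identity <- function(query, reference, try_rc = TRUE,
                               rc_below = 0.99) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1)
  one <- function(q) {
    a <- Biostrings::pairwiseAlignment(q, reference, type = "global-local",
                                       substitutionMatrix = submat,
                                       gapOpening = 2, gapExtension = 1)
    Biostrings::nmatch(a) / Biostrings::nchar(a)
  }
  fwd <- one(query)
  if (!try_rc || fwd >= rc_below) return(fwd)
  max(fwd, one(revcomp(query)))
}
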