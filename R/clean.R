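#' Trim adapter sequence from reads
#'
#' Scans every alignment offset of the adapter against each read. A hit
#' needs at least `min_match` overlapping bases with a mismatch fraction at
#' most `max_mismatch_rate`. Hits touching the 5' end remove the matched
#' prefix, hits touching the 3' end remove the matched suffix, and internal
#' full-length adapter matches truncate the read at the match start (the
#' bases downstream of an internal adapter are ligation artefacts).
#'
#' @param x A character vector of sequences, or a data frame with a
#'   `sequence` column.
#' @param adapter Adapter sequence (non-empty DNA string).
#' @param max_mismatch_rate Maximum allowed mismatch fraction within a match.
#' @param min_match Minimum overlap (bp) for a terminal partial match.
#' @return Same shape as `x`: a character vector, or the data frame with its
#'   `sequence` updated and `adapter5_trim`/`adapter3_trim` bp columns
#'   accumulated.
#' @export
trim_adapter <- function(x, adapter, max_mismatch_rate = 0.1, min_match = 8) {
  if (!is.character(adapter) || length(adapter) != 1 || nchar(adapter) == 0) {
    abort("`adapter` must be a single non-empty DNA string")
  }
  seqs <- if (is.data.frame(x)) x$sequence else as.character(x)
  res <- cpp_trim_adapter(seqs, adapter, max_mismatch_rate, as.integer(min_match))
  if (is.data.frame(x)) {
    x$sequence <- res$sequence
    x$adapter5_trim <- (x$adapter5_trim %||% 0L) + res$cut5
    x$adapter3_trim <- (x$adapter3_trim %||% 0L) + res$cut3
    x
  } else {
    out <- res$sequence
    names(out) <- names(x)
    out
  }
}

#' Trim polyA/T tails from reads
#'
#' Aggressive tail trimming from both ends for both A and T. Two rules per
#' end/base, iterated to a fixed point: a window rule (cut at the outermost
#' target-base position from which every full `window`-bp window has a
#' target-base fraction of at least `min_frac`) and a run rule (terminal
#' pure runs of at least `min_run` bp are removed).
#'
#' @inheritParams trim_adapter
#' @param window Sliding-window width (bp), >= 1.
#' @param min_frac Window target-base fraction in `(0.5, 1]`.
#' @param min_run Minimum terminal pure-run length to strip (bp).
#' @return Same shape as `x` (data frames accumulate `polya_trim` /
#'   `polyt_trim` bp columns).
#' @export
trim_polyat <- function(x, window = 10, min_frac = 0.8, min_run = 5) {
  if (window < 1) abort("`window` must be >= 1")
  if (min_frac <= 0.5 || min_frac > 1) abort("`min_frac` must be in (0.5, 1]")
  seqs <- if (is.data.frame(x)) x$sequence else as.character(x)
  res <- cpp_trim_polyat(seqs, as.integer(window), min_frac,
                         as.integer(min_run))
  if (is.data.frame(x)) {
    x$sequence <- res$sequence
    x$polya_trim <- (x$polya_trim %||% 0L) + res$polya
    x$polyt_trim <- (x$polyt_trim %||% 0L) + res$polyt
    x
  } else {
    out <- res$sequence
    names(out) <- names(x)
    out
  }
}

#' Clean a read library
#'
#' Applies adapter trimming and polyA/T trimming, iterated together to a
#' fixed point (so that tails exposed by adapter removal, and adapter
#' fragments exposed by tail removal, are caught), then a length filter.
#' The returned report reconciles exactly:
#' `n_in = n_out + n_discarded_short`.
#'
#' @param reads A data frame with `read_id` and `sequence` columns, or a
#'   character vector of sequences.
#' @param adapters Character vector of adapter sequences (may be empty).
#' @param max_mismatch_rate,min_match Adapter-matching parameters, see
#'   [trim_adapter()].
#' @param window,min_frac,min_run PolyA/T parameters, see [trim_polyat()].
#' @param min_len,max_len Length filter applied after trimming (bp). Reads
#'   shorter than `min_len` (or longer than `max_len`) are discarded and
#'   counted in `n_discarded_short`.
#' @param end_clip Fixed number of bases clipped from the 3' end before any
#'   other trimming (a stand-in for quality-based end clipping; 0 disables).
#' @return An object of class `cleaning_result`: a list with `reads` (the
#'   surviving reads plus per-read trim log columns) and `report` (a one-row
#'   tibble: `n_in`, `n_out`, `n_discarded_short`, `total_bp_in`,
#'   `total_bp_out`, `bp_removed`). [tidy()] returns the per-read log,
#'   [glance()] the report.
#' @export
clean_reads <- function(reads, adapters = character(),
                        max_mismatch_rate = 0.1, min_match = 8,
                        window = 10, min_frac = 0.8, min_run = 5,
                        min_len = 78, max_len = Inf, end_clip = 0) {
  if (min_len < 1) abort("`min_len` must be >= 1")
  tb <- as_seq_tbl(reads, id_col = "read_id", prefix = "read")
  n_in <- nrow(tb)
  total_bp_in <- sum(nchar(tb$sequence))
  tb$adapter5_trim <- 0L
  tb$adapter3_trim <- 0L
  tb$polya_trim <- 0L
  tb$polyt_trim <- 0L
  tb$endclip_trim <- 0L
  if (n_in > 0 && end_clip > 0) {
    clip <- pmin(nchar(tb$sequence), as.integer(end_clip))
    tb$sequence <- str_sub(tb$sequence, 1, nchar(tb$sequence) - clip)
    tb$endclip_trim <- clip
  }
  if (n_in > 0) {
    for (iter in seq_len(5)) {
      before <- tb$sequence
      for (ad in adapters) {
        tb <- trim_adapter(tb, ad, max_mismatch_rate, min_match)
      }
      tb <- trim_polyat(tb, window, min_frac, min_run)
      if (identical(tb$sequence, before)) break
    }
  }
  len <- nchar(tb$sequence)
  keep <- len >= min_len & len <= max_len
  out <- tb[keep, , drop = FALSE]
  report <- tibble(
    n_in = n_in,
    n_out = nrow(out),
    n_discarded_short = n_in - nrow(out),
    total_bp_in = total_bp_in,
    total_bp_out = sum(nchar(out$sequence)),
    bp_removed = total_bp_in - sum(nchar(out$sequence))
  )
  structure(list(reads = out, report = report,
                 params = list(adapters = adapters, min_len = min_len,
                               max_len = max_len, window = window,
                               min_frac = min_frac, min_run = min_run,
                               max_mismatch_rate = max_mismatch_rate,
                               min_match = min_match, end_clip = end_clip)),
            class = "cleaning_result")
}

#' @export
print.cleaning_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<cleaning_result> %d reads in, %d out, %d discarded; %.3f Mbp -> %.3f Mbp\n",
    r$n_in, r$n_out, r$n_discarded_short,
    r$total_bp_in / 1e6, r$total_bp_out / 1e6))
  invisible(x)
}

#' @export
tidy.cleaning_result <- function(x, ...) x$reads

#' @export
glance.cleaning_result <- function(x, ...) x$report
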