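#' Detect pairwise read overlaps
#'
#' Candidate pairs share at least one k-mer (either strand); each candidate
#' is verified by a banded alignment at the modal k-mer diagonal. Identity is
#' computed as matches divided by alignment columns, gap columns included.
#' Each qualifying pair is reported once.
#'
#' @param reads A data frame with `read_id`/`sequence` columns, or a
#'   character vector.
#' @param k K-mer size for candidate detection (>= 8).
#' @param min_overlap Minimum overlap length in alignment columns
#'   (>= `k`).
#' @param min_identity Minimum overlap identity in `[0, 1]`.
#' @param max_occ K-mers occurring in more than this many positions are
#'   treated as repeats and skipped during candidate detection.
#' @return A tibble with columns `read_a`, `read_b`, `orientation`
#'   (`"same"`/`"rc"`), `a_start`, `a_end`, `b_start`, `b_end` (0-based
#'   half-open on each read's own forward strand), `identity`, `length`.
#' @export
find_overlaps <- function(reads, k = 16, min_overlap = 40,
                          min_identity = 0.94, max_occ = 100) {
  if (k < 8) abort("`k` must be >= 8")
  if (min_overlap < k) abort("`min_overlap` must be >= `k`")
  tb <- as_seq_tbl(reads, id_col = "read_id", prefix = "read")
  ov <- cpp_find_overlaps(tb$sequence, as.integer(k), as.integer(min_overlap),
                          min_identity, as.integer(max_occ))
  tibble(
    read_a = tb$read_id[ov$a],
    read_b = tb$read_id[ov$b],
    orientation = ifelse(ov$strand == 1, "rc", "same"),
    a_start = ov$a_start, a_end = ov$a_end,
    b_start = ov$b_start, b_end = ov$b_end,
    identity = ov$identity, length = ov$length
  )
}

# Shared overlap -> layout -> consensus engine behind both assembly passes.
olc_engine <- function(seqs, k, min_overlap, min_identity, max_occ) {
  n <- length(seqs)
  ov <- cpp_find_overlaps(seqs, as.integer(k), as.integer(min_overlap),
                          min_identity, as.integer(max_occ))
  ord <- order(-ov$identity, -ov$length, ov$a, ov$b)
  lay <- cpp_layout(n, ov$a[ord], ov$b[ord], ov$strand[ord], ov$diag[ord],
                    nchar(seqs))
  comp <- match(lay$root, unique(lay$root))
  cpp_assemble_components(seqs, comp, lay$flip, lay$off, min_identity)
}

assembly_stats_row <- function(pass, n_reads_in, unigenes, members,
                               discarded) {
  contig_ids <- unigenes$unigene_id[unigenes$category != "singleton"]
  in_contig <- members$unigene_id %in% contig_ids
  tibble(
    pass = pass,
    n_reads_in = n_reads_in,
    reads_assembled = sum(in_contig),
    reads_discarded = length(discarded),
    reads_singleton = sum(unigenes$category == "singleton"),
    n_primary_contigs = sum(unigenes$category == "primary_contig"),
    n_secondary_contigs = sum(unigenes$category == "secondary_contig"),
    n_unigenes = nrow(unigenes),
    mean_unigene_length = if (nrow(unigenes)) mean(nchar(unigenes$consensus))
                          else NA_real_,
    max_unigene_length = if (nrow(unigenes)) max(nchar(unigenes$consensus))
                         else NA_integer_,
    total_bp = sum(nchar(unigenes$consensus)),
    mean_depth = if (nrow(unigenes))
      sum(members$end - members$start) / sum(nchar(unigenes$consensus))
    else NA_real_
  )
}

new_assembly_result <- function(unigenes, members, discarded, stats, params) {
  structure(list(unigenes = unigenes, members = members,
                 discarded = discarded, stats = stats, params = params),
            class = "assembly_result")
}

#' Primary greedy overlap-layout-consensus assembly
#'
#' Reads connected by overlaps at `min_identity` or better are laid out
#' greedily (overlaps processed by descending identity then length, with a
#' deterministic tie order) and polished into a per-column-vote consensus;
#' vote ties go to the earliest-placed read. A read whose alignment identity
#' against the polished consensus falls below `min_identity` is released to
#' singleton status by default, or discarded when
#' `discard_low_identity = TRUE`. Unconnected reads are retained as
#' singletons.
#'
#' @inheritParams find_overlaps
#' @param discard_low_identity Discard (rather than release to singletons)
#'   reads that fail the consensus-identity check.
#' @return An object of class `assembly_result`: a list with
#'   `unigenes` (tibble: `unigene_id`, `consensus`, `category`, `length`,
#'   `n_members`, `depth`), `members` (tibble: `unigene_id`, `read_id`,
#'   `start`, `end`, `strand`, `identity`; placements are 0-based half-open
#'   on the consensus), `discarded` (read ids), and `stats` (one row per
#'   pass). [tidy()] returns the unigene table, [glance()] the stats.
#' @export
assemble_primary <- function(reads, min_identity = 0.94, min_overlap = 40,
                             k = 16, max_occ = 100,
                             discard_low_identity = FALSE) {
  tb <- as_seq_tbl(reads, id_col = "read_id", prefix = "read")
  if (anyDuplicated(tb$read_id)) abort("read ids must be unique")
  n <- nrow(tb)
  if (n == 0) {
    unig <- tibble(unigene_id = character(), consensus = character(),
                   category = character(), length = integer(),
                   n_members = integer(), depth = numeric())
    memb <- tibble(unigene_id = character(), read_id = character(),
                   start = integer(), end = integer(), strand = character(),
                   identity = numeric())
    st <- assembly_stats_row("primary", 0L, unig, memb, character())
    return(new_assembly_result(unig, memb, character(), st,
                               list(min_identity = min_identity,
                                    min_overlap = min_overlap, k = k)))
  }
  res <- olc_engine(tb$sequence, k, min_overlap, min_identity, max_occ)

  placed <- !is.na(res$contig)
  memb <- tibble(
    contig = res$contig[placed],
    read_id = tb$read_id[placed],
    start = res$start[placed],
    end = res$end[placed],
    strand = ifelse(res$strand[placed] == 1, "-", "+"),
    identity = res$identity[placed]
  )
  n_members <- tabulate(memb$contig, nbins = length(res$consensus))
  released_idx <- which(!placed)
  discarded <- character()
  unig <- tibble(
    contig = seq_along(res$consensus),
    consensus = res$consensus,
    category = ifelse(n_members >= 2, "primary_contig", "singleton")
  )
  if (length(released_idx)) {
    if (discard_low_identity) {
      discarded <- tb$read_id[released_idx]
    } else {
      extra <- tibble(
        contig = length(res$consensus) + seq_along(released_idx),
        consensus = tb$sequence[released_idx],
        category = "singleton"
      )
      memb <- bind_rows(memb, tibble(
        contig = extra$contig,
        read_id = tb$read_id[released_idx],
        start = 0L,
        end = nchar(extra$consensus),
        strand = "+",
        identity = res$identity[released_idx]
      ))
      unig <- bind_rows(unig, extra)
    }
  }
  unig$unigene_id <- sprintf("unigene_%06d", seq_len(nrow(unig)))
  memb$unigene_id <- unig$unigene_id[memb$contig]
  memb <- select(memb, "unigene_id", "read_id", "start", "end", "strand",
                 "identity")
  unig <- unig |>
    mutate(length = nchar(.data$consensus),
           n_members = tabulate(match(memb$unigene_id, .data$unigene_id),
                                nbins = n())) |>
    select("unigene_id", "consensus", "category", "length", "n_members")
  unig$depth <- depth_from_members(unig, memb)
  st <- assembly_stats_row("primary", n, unig, memb, discarded)
  new_assembly_result(unig, memb, discarded, st,
                      list(min_identity = min_identity,
                           min_overlap = min_overlap, k = k,
                           discard_low_identity = discard_low_identity))
}

#' Secondary redundancy-reducing assembly
#'
#' Merges the unigene sequences of a primary assembly (contigs and
#' singletons alike) whenever they overlap by at least `min_overlap` bp at
#' `min_identity` or better, CAP3-style. Merged products are labelled
#' `secondary_contig`; unmerged unigenes keep their category. Member reads
#' of merged unigenes are unioned with placements lifted onto the merged
#' consensus. No reads are discarded in this step.
#'
#' @param primary An `assembly_result` from [assemble_primary()].
#' @inheritParams find_overlaps
#' @return An `assembly_result` whose `stats` has one row per pass.
#' @export
assemble_secondary <- function(primary, min_identity = 0.95,
                               min_overlap = 25, k = 12, max_occ = 100) {
  stopifnot(inherits(primary, "assembly_result"))
  pu <- primary$unigenes
  if (nrow(pu) == 0) {
    st <- primary$stats
    st2 <- st[nrow(st), ]
    st2$pass <- "secondary"
    out <- new_assembly_result(pu, primary$members, primary$discarded,
                               bind_rows(st, st2), primary$params)
    return(out)
  }
  res <- olc_engine(pu$consensus, max(8, min(k, min_overlap)), min_overlap,
                    min_identity, max_occ)
  # released inputs stay as their own unigene
  ncons <- length(res$consensus)
  rel <- which(is.na(res$contig))
  contig_of <- res$contig
  contig_of[rel] <- ncons + seq_along(rel)
  consensus <- c(res$consensus, pu$consensus[rel])
  start_of <- res$start; start_of[rel] <- 0L
  end_of <- res$end; end_of[rel] <- nchar(pu$consensus[rel])
  strand_of <- res$strand; strand_of[rel] <- 0L

  grp_size <- tabulate(contig_of, nbins = length(consensus))
  new_ids <- sprintf("unigene_%06d", seq_along(consensus))

  # categories: merged groups are secondary contigs, unmerged keep category
  category <- character(length(consensus))
  for (g in seq_along(consensus)) {
    inputs <- which(contig_of == g)
    category[g] <- if (length(inputs) >= 2) "secondary_contig"
                   else pu$category[inputs]
  }

  # lift member reads through their unigene's placement
  pm <- primary$members
  uidx <- match(pm$unigene_id, pu$unigene_id)
  g <- contig_of[uidx]
  us <- start_of[uidx]; ue <- end_of[uidx]
  uflip <- strand_of[uidx] == 1
  ulen <- nchar(pu$consensus)[uidx]
  # map read placement [rs, re) on the input unigene into the merged frame;
  # scale for small indel-driven length changes, then clamp
  scale <- (ue - us) / pmax(1L, ulen)
  rs <- pm$start; re <- pm$end
  new_start <- ifelse(uflip, us + round((ulen - re) * scale),
                      us + round(rs * scale))
  new_end <- ifelse(uflip, us + round((ulen - rs) * scale),
                    us + round(re * scale))
  new_start <- pmax(0L, pmin(as.integer(new_start),
                             nchar(consensus)[g] - 1L))
  new_end <- pmax(new_start + 1L, pmin(as.integer(new_end),
                                       nchar(consensus)[g]))
  flip_strand <- function(s, f) ifelse(f, ifelse(s == "+", "-", "+"), s)
  memb <- tibble(
    unigene_id = new_ids[g],
    read_id = pm$read_id,
    start = new_start,
    end = new_end,
    strand = flip_strand(pm$strand, uflip),
    identity = pm$identity
  ) |> arrange(.data$unigene_id, .data$start, .data$read_id)

  unig <- tibble(
    unigene_id = new_ids,
    consensus = consensus,
    category = category,
    length = nchar(consensus),
    n_members = tabulate(match(memb$unigene_id, new_ids),
                         nbins = length(new_ids))
  )
  unig$depth <- depth_from_members(unig, memb)
  st <- assembly_stats_row("secondary", primary$stats$n_reads_in[1], unig,
                           memb, character())
  new_assembly_result(unig, memb, primary$discarded,
                      bind_rows(primary$stats, st),
                      c(primary$params,
                        list(secondary_min_identity = min_identity,
                             secondary_min_overlap = min_overlap)))
}

depth_from_members <- function(unigenes, members) {
  bp <- members |>
    group_by(.data$unigene_id) |>
    summarise(bp = sum(.data$end - .data$start), .groups = "drop")
  bp_vec <- setNames(bp$bp, bp$unigene_id)[unigenes$unigene_id]
  bp_vec[is.na(bp_vec)] <- 0
  unname(bp_vec / pmax(1L, nchar(unigenes$consensus)))
}

#' Mean read-depth coverage
#'
#' Depth is the total placed member bases divided by the consensus length —
#' equivalently the mean of the per-base pileup. Singletons have depth 1.
#'
#' @param x An `assembly_result`, or a members data frame with
#'   `start`/`end` columns.
#' @param consensus_length Consensus length in bp (required when `x` is a
#'   members data frame).
#' @return For an `assembly_result`, a tibble `unigene_id`/`depth`;
#'   otherwise a single number.
#' @export
compute_depth <- function(x, consensus_length = NULL) {
  if (inherits(x, "assembly_result")) {
    return(tibble(unigene_id = x$unigenes$unigene_id,
                  depth = depth_from_members(x$unigenes, x$members)))
  }
  if (is.null(consensus_length) || consensus_length <= 0) {
    abort("`consensus_length` must be a positive number")
  }
  sum(x$end - x$start) / consensus_length
}

#' @export
print.assembly_result <- function(x, ...) {
  st <- x$stats[nrow(x$stats), ]
  cat(sprintf(
    "<assembly_result> pass '%s': %d unigenes (%d contigs, %d singletons) from %d reads\n",
    st$pass, st$n_unigenes,
    st$n_primary_contigs + st$n_secondary_contigs, st$reads_singleton,
    st$n_reads_in))
  invisible(x)
}

#' @export
tidy.assembly_result <- function(x, ...) x$unigenes

#' @export
glance.assembly_result <- function(x, ...) x$stats
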