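# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# Exact without-replacement expectation of distinct unigenes detected after
# t draws, for reads-per-unigene counts m: sum_i (1 - C(T-m_i, t)/C(T, t)).
oracle_expected_detected <- function(counts, t) {
  total <- sum(counts)
  vapply(t, function(tt) {
    sum(1 - exp(lchoose(total - counts, tt) - lchoose(total, tt)))
  }, numeric(1))
}

# Brute-force LCA: intersect full ancestor sets, take the deepest node.
oracle_lca <- function(tree, taxa) {
  parent <- setNames(tree$parent_id, tree$taxon_id)
  chain <- function(id) {
    out <- character()
    cur <- id
    repeat {
      out <- c(out, cur)
      if (parent[[cur]] == cur) break
      cur <- parent[[cur]]
    }
    out
  }
  chains <- lapply(unique(taxa), chain)
  common <- Reduce(intersect, chains)
  depths <- vapply(common, function(id) length(chain(id)), integer(1))
  common[which.max(depths)]
}

# Exhaustive SSR scan: every start, motif length and repeat count, then the
# same longest-interval overlap resolution the finder documents.
oracle_ssrs <- function(seq, min_repeats = c(`2` = 10, `3` = 9, `4` = 7,
                                             `5` = 6)) {
  n <- nchar(seq)
  cand <- list()
  for (k in as.integer(names(min_repeats))) {
    for (i in seq_len(max(0, n - 2 * k + 1))) {
      motif <- substr(seq, i, i + k - 1)
      # primitive motifs only
      prim <- TRUE
      for (d in seq_len(k - 1)) {
        if (k %% d == 0 && motif == strrep(substr(motif, 1, d), k / d)) {
          prim <- FALSE
          break
        }
      }
      if (!prim) next
      reps <- 1L
      while (i + (reps + 1) * k - 1 <= n &&
             substr(seq, i + reps * k, i + (reps + 1) * k - 1) == motif) {
        reps <- reps + 1L
      }
      if (reps < min_repeats[[as.character(k)]]) next
      # maximal runs only: reject if extendable one motif to the left
      if (i - k >= 1 && substr(seq, i - k, i - 1) == motif) next
      cand[[length(cand) + 1]] <- data.frame(
        motif_length = k, n_repeats = reps, start = i - 1L,
        end = i - 1L + k * reps, motif = motif)
    }
  }
  if (!length(cand)) {
    return(data.frame(motif_length = integer(), n_repeats = integer(),
                      start = integer(), end = integer(),
                      motif = character()))
  }
  cand <- do.call(rbind, cand)
  cand$len <- cand$end - cand$start
  cand <- cand[order(-cand$len, cand$motif_length, cand$start), ]
  keep <- rep(FALSE, nrow(cand))
  ts <- integer(); te <- integer()
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < te & cand$end[i] > ts)) {
      keep[i] <- TRUE
      ts <- c(ts, cand$start[i]); te <- c(te, cand$end[i])
    }
  }
  out <- cand[keep, ]
  out[order(out$start), c("motif_length", "n_repeats", "start", "end",
                          "motif")]
}

# Naive six-frame longest-ORF enumeration with a hand-rolled codon table
# walk (base R, no Biostrings).
oracle_longest_orf <- function(seq) {
  codon_table <- {
    bases <- c("T", "C", "A", "G")
    aas <- strsplit(paste0(
      "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
      "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
    g <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                     stringsAsFactors = FALSE)
    setNames(aas, paste0(g$b1, g$b2, g$b3))
  }
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  L <- nchar(seq)
  best <- NULL
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (fi in 1:6) {
    fwd <- fi <= 3
    off <- (fi - 1) %% 3
    src <- if (fwd) seq else rc(seq)
    ncod <- (L - off) %/% 3
    if (ncod < 1) next
    aa <- vapply(seq_len(ncod), function(ci) {
      codon_table[[substr(src, off + 3 * ci - 2, off + 3 * ci)]]
    }, character(1))
    stops <- c(0L, which(aa == "*"), ncod + 1L)
    for (si in seq_len(length(stops) - 1)) {
      s0 <- stops[si] + 1L
      e0 <- stops[si + 1] - 1L
      plen <- max(0L, e0 - s0 + 1L)
      weight <- plen + as.integer(stops[si + 1] <= ncod)
      if (is.null(best) || weight > best$weight) {
        a <- off + 3L * (s0 - 1L)
        b <- a + 3L * plen
        if (!fwd) { tmp <- a; a <- L - b; b <- L - tmp }
        pep <- if (plen > 0) paste(aa[s0:e0], collapse = "") else ""
        best <- list(frame = frames[fi], start = a, end = b,
                     peptide = pep, plen = plen, weight = weight)
      }
    }
  }
  best
}

# Two-sided Fisher probability as the sum of hypergeometric point masses
# no larger than the observed one.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b          # test size
  n <- c + d          # reference size
  k <- a + c          # term total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up Benjamini-Hochberg recomputation.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(1, q)
  out
}

# Transitive-closure slim mapping oracle on an edge list (child -> parent).
oracle_slim_map <- function(term, edges, slim) {
  reach <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    frontier <- setdiff(nxt, reach)
    reach <- union(reach, frontier)
  }
  intersect(reach, slim)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
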