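#' Simulation settings for a normalized 454-style cDNA read library
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate a
#' single normalized long-read cDNA sequencing run: ~2,000 expressed genes,
#' 50,000 single-end reads with mean length 372.6 bp (sd 96.36 bp), a
#' heavy-tailed (log-normal) expression law flattened by imperfect
#' normalization, 454-style substitution and homopolymer-indel errors,
#' library adapters, polyA/T tails, and a 1.8% contaminant spike.
#'
#' @param n_genes Number of transcripts to simulate.
#' @param gene_length_mean,gene_length_sd Log-normal transcript length law,
#'   in bp (arithmetic mean and sd); lengths are truncated at >= 200 bp.
#' @param abundance_sdlog Log-sd of the log-normal true-abundance law; larger
#'   values mean a more skewed pre-normalization library.
#' @param n_reads Number of reads to draw.
#' @param read_length_mean,read_length_sd,read_length_min,read_length_max
#'   Normal law for the sampled fragment length, with hard bounds (bp).
#' @param normalization_exponent Exponent in `[0, 1]` applied to true
#'   abundances before renormalization; 0 is perfect normalization (uniform
#'   read allocation), 1 leaves the expression skew untouched.
#' @param substitution_rate Per-base substitution error probability.
#' @param homopolymer_indel_rate Per-base probability, within homopolymer
#'   runs of >= 3 bp, of a +-1 bp indel (the dominant 454 error mode).
#' @param adapter_5p,adapter_3p Library adapter sequences.
#' @param adapter_5p_prob,adapter_3p_prob Probability that a read carries
#'   each adapter.
#' @param polyA_prob Probability that a read carries a polyA (forward-strand
#'   read, 3' end) or polyT (reverse-strand read, 5' end) tail.
#' @param polyA_length_mean Mean of the Poisson tail-length law (bp).
#' @param contaminant_fraction Fraction of reads spiked from a non-target
#'   library by [spike_contaminants()].
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_transcriptome()], [simulate_reads()],
#'   [spike_contaminants()]
#' @export
sim_config <- function(n_genes = 2000,
                       gene_length_mean = 1500,
                       gene_length_sd = 900,
                       abundance_sdlog = 1.5,
                       n_reads = 50000,
                       read_length_mean = 372.6,
                       read_length_sd = 96.36,
                       read_length_min = 40,
                       read_length_max = 624,
                       normalization_exponent = 0.25,
                       substitution_rate = 0.002,
                       homopolymer_indel_rate = 0.002,
                       adapter_5p = "GCCTCCCTCGCGCCATCAG",
                       adapter_3p = "GCCTTGCCAGCCCGCTCAG",
                       adapter_5p_prob = 1.0,
                       adapter_3p_prob = 0.25,
                       polyA_prob = 0.3,
                       polyA_length_mean = 18,
                       contaminant_fraction = 0.018,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c("normalization_exponent", "substitution_rate",
             "homopolymer_indel_rate", "adapter_5p_prob", "adapter_3p_prob",
             "polyA_prob", "contaminant_fraction")
  for (r in rates) {
    v <- cfg[[r]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single value in [0, 1]", r))
    }
  }
  if (cfg$n_genes < 0) abort("`n_genes` must be >= 0")
  if (cfg$n_reads < 0) abort("`n_reads` must be >= 0")
  if (cfg$gene_length_mean <= 0) abort("`gene_length_mean` must be positive")
  if (cfg$read_length_mean <= 0) abort("`read_length_mean` must be positive")
  if (cfg$read_length_min < 1 || cfg$read_length_max < cfg$read_length_min) {
    abort("read length bounds must satisfy 1 <= min <= max")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a ground-truth transcript set
#'
#' Draws `n_genes` transcripts with log-normal lengths (truncated at 200 bp)
#' and log-normal true abundances normalized to sum to one. This stands in
#' for the unknown transcriptome that a de novo EST project samples.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `transcript_id`, `sequence`,
#'   `true_abundance` (summing to 1).
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0) {
    return(tibble(transcript_id = character(), sequence = character(),
                  true_abundance = numeric()))
  }
  with_seed(config$seed, {
    m <- config$gene_length_mean
    s <- config$gene_length_sd
    sdlog <- sqrt(log(1 + (s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    lengths <- round(rlnorm(n, meanlog, sdlog))
    while (any(short <- lengths < 200)) {
      lengths[short] <- round(rlnorm(sum(short), meanlog, sdlog))
    }
    ab <- rlnorm(n, 0, config$abundance_sdlog)
    tibble(
      transcript_id = sprintf("tx_%05d", seq_len(n)),
      sequence = random_dna(n, lengths),
      true_abundance = ab / sum(ab)
    )
  })
}

# Apply substitution errors and +-1 bp homopolymer indels to fragments.
# Returns list(sequence, n_sub, n_indel).
apply_errors <- function(seqs, sub_rate, hp_rate) {
  n_sub <- integer(length(seqs))
  n_indel <- integer(length(seqs))
  if (sub_rate > 0) {
    lens <- nchar(seqs)
    k <- rbinom(length(seqs), lens, sub_rate)
    idx <- which(k > 0)
    for (i in idx) {
      ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
      pos <- sample.int(length(ch), k[i])
      for (p in pos) {
        ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
      }
      seqs[[i]] <- paste(ch, collapse = "")
    }
    n_sub <- k
  }
  if (hp_rate > 0) {
    runs <- gregexpr("([ACGT])\\1{2,}", seqs, perl = TRUE)
    for (i in seq_along(seqs)) {
      m <- runs[[i]]
      if (m[1] == -1) next
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      hit <- runif(length(starts)) < pmin(1, hp_rate * lens)
      if (!any(hit)) next
      ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
      # process right-to-left so earlier coordinates stay valid
      for (j in rev(which(hit))) {
        p <- starts[j]
        if (runif(1) < 0.5) {
          ch <- append(ch, ch[p], after = p)  # +1 duplication
        } else {
          ch <- ch[-p]                        # -1 contraction
        }
        n_indel[i] <- n_indel[i] + 1L
      }
      seqs[[i]] <- paste(ch, collapse = "")
    }
  }
  list(sequence = seqs, n_sub = n_sub, n_indel = n_indel)
}

# Shared fragment sampler used for both target and contaminant reads.
draw_reads <- function(transcripts, n_reads, config, id_prefix,
                       is_contaminant) {
  probs <- transcripts$true_abundance^config$normalization_exponent
  probs <- probs / sum(probs)
  counts <- as.integer(rmultinom(1, n_reads, probs))
  src <- rep.int(seq_len(nrow(transcripts)), counts)
  src <- sample(src)  # interleave sources
  n <- length(src)
  if (n == 0) {
    return(empty_reads())
  }
  tlen <- nchar(transcripts$sequence)[src]
  want <- pmin(pmax(round(rnorm(n, config$read_length_mean,
                                config$read_length_sd)),
                    config$read_length_min),
               config$read_length_max)
  len <- pmin(want, tlen)
  start <- floor(runif(n) * (tlen - len + 1))
  end <- start + len
  core <- str_sub(transcripts$sequence[src], start + 1, end)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  core[strand == "-"] <- revcomp(core[strand == "-"])
  err <- apply_errors(core, config$substitution_rate,
                      config$homopolymer_indel_rate)
  core <- err$sequence

  has_tail <- runif(n) < config$polyA_prob
  tail_len <- ifelse(has_tail, rpois(n, config$polyA_length_mean), 0L)
  polya_bp <- ifelse(strand == "+", tail_len, 0L)
  polyt_bp <- ifelse(strand == "-", tail_len, 0L)
  has5 <- runif(n) < config$adapter_5p_prob
  has3 <- runif(n) < config$adapter_3p_prob
  seq_out <- paste0(
    ifelse(has5, config$adapter_5p, ""),
    strrep("T", polyt_bp),
    core,
    strrep("A", polya_bp),
    ifelse(has3, config$adapter_3p, "")
  )
  tibble(
    read_id = sprintf("%s_%06d", id_prefix, seq_len(n)),
    sequence = seq_out,
    source_id = transcripts$transcript_id[src],
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    is_contaminant = is_contaminant,
    adapter5_bp = ifelse(has5, nchar(config$adapter_5p), 0L),
    adapter3_bp = ifelse(has3, nchar(config$adapter_3p), 0L),
    polya_bp = as.integer(polya_bp),
    polyt_bp = as.integer(polyt_bp),
    n_sub = as.integer(err$n_sub),
    n_indel = as.integer(err$n_indel)
  )
}

empty_reads <- function() {
  tibble(read_id = character(), sequence = character(),
         source_id = character(), start = integer(), end = integer(),
         strand = character(), is_contaminant = logical(),
         adapter5_bp = integer(), adapter3_bp = integer(),
         polya_bp = integer(), polyt_bp = integer(),
         n_sub = integer(), n_indel = integer())
}

#' Simulate a decorated read library with its truth table
#'
#' Allocates reads to transcripts by a multinomial law with probabilities
#' proportional to `true_abundance^normalization_exponent`, places each read
#' uniformly on its transcript, draws a random sequencing strand, applies
#' substitution and homopolymer-indel errors to the fragment, then decorates
#' it with adapters and polyA/T tails. The returned tibble is both the read
#' set (`read_id`, `sequence`) and the truth table: source interval (0-based
#' half-open, on the transcript), strand, and per-read decoration record.
#'
#' @param transcripts A transcript tibble from [simulate_transcriptome()].
#' @param config A [sim_config()].
#' @return A tibble with one row per read; columns `read_id`, `sequence`,
#'   `source_id`, `start`, `end`, `strand`, `is_contaminant`,
#'   `adapter5_bp`, `adapter3_bp`, `polya_bp`, `polyt_bp`, `n_sub`,
#'   `n_indel`.
#' @export
simulate_reads <- function(transcripts, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reads == 0) return(empty_reads())
  if (nrow(transcripts) == 0) {
    abort("cannot draw reads from an empty transcript set")
  }
  with_seed(config$seed + 1L, {
    draw_reads(transcripts, config$n_reads, config, "read", FALSE)
  })
}

#' Spike contaminant reads into a library
#'
#' Adds `round(fraction * nrow(reads))` reads drawn from a non-target
#' library (same fragment/decoration process), flagged
#' `is_contaminant = TRUE`.
#'
#' @param reads A read tibble from [simulate_reads()].
#' @param library A transcript tibble of contaminant source sequences (ids
#'   should not collide with transcript ids).
#' @param fraction Spike fraction in `[0, 1]`.
#' @param config A [sim_config()] supplying the read-length/error laws.
#' @param seed Seed for the contaminant draws.
#' @return The augmented read tibble.
#' @export
spike_contaminants <- function(reads, library,
                               fraction = sim_config()$contaminant_fraction,
                               config = sim_config(), seed = config$seed) {
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    abort("`fraction` must be a single value in [0, 1]")
  }
  n_add <- round(fraction * nrow(reads))
  if (n_add == 0) return(reads)
  if (nrow(library) == 0) abort("contaminant `library` is empty")
  spikes <- with_seed(seed + 2L, {
    draw_reads(library, n_add, config, "contam_read", TRUE)
  })
  bind_rows(reads, spikes)
}

#' Simulate a contaminant source library
#'
#' Random non-target sequences (bacterial-like insert lengths) used by
#' [spike_contaminants()]; ids are prefixed `contam_` so downstream truth
#' checks can recognize them.
#'
#' @param n_sources Number of contaminant source sequences.
#' @param mean_length Mean source length (bp).
#' @param seed Integer seed.
#' @return A transcript-set tibble.
#' @export
simulate_contaminant_library <- function(n_sources = 20, mean_length = 1200,
                                         seed = 99L) {
  with_seed(seed, {
    lengths <- pmax(300, round(rnorm(n_sources, mean_length, mean_length / 4)))
    ab <- rlnorm(n_sources, 0, 1)
    tibble(
      transcript_id = sprintf("contam_%03d", seq_len(n_sources)),
      sequence = random_dna(n_sources, lengths),
      true_abundance = ab / sum(ab)
    )
  })
}

#' Write a read truth table as TSV
#'
#' @param reads A read tibble from [simulate_reads()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(reads, path) {
  readr::write_tsv(select(reads, -"sequence"), path)
  invisible(path)
}
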