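BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore", "staxids")

#' Load tabular homology hits
#'
#' Reads the standard 12-column tabular hit format plus a subject taxon-id
#' column, filters to `evalue <= evalue_max`, and keeps the `top_n` hits per
#' query by descending bitscore (ties broken by subject id for
#' determinism).
#'
#' @param x Path to a tab-separated hit file, or a data frame already in
#'   that layout.
#' @param evalue_max E-value threshold.
#' @param top_n Hits retained per query.
#' @return A tibble of hits sorted by query, then descending bitscore.
#' @export
load_hits <- function(x, evalue_max = 1e-10, top_n = 10) {
  if (is.character(x) && length(x) == 1) {
    first <- readr::read_lines(x, n_max = 1)
    if (length(first) > 0 &&
        length(strsplit(first, "\t", fixed = TRUE)[[1]]) < 13) {
      abort(paste0("hit file '", x, "' lacks the subject taxon column ",
                   "(13 tab-separated columns required)"))
    }
    x <- suppressWarnings(
      readr::read_tsv(x, col_names = BLAST_COLS,
                      col_types = "ccdiiiiiiiddc", progress = FALSE))
    probs <- readr::problems(x)
    if (nrow(probs) > 0) {
      abort(sprintf("malformed hit row at line %d: expected %s, got %s",
                    probs$row[1], probs$expected[1], probs$actual[1]))
    }
  }
  x <- as_tibble(x)
  if (!all(BLAST_COLS %in% names(x))) {
    if (ncol(x) == length(BLAST_COLS)) {
      names(x) <- BLAST_COLS
    } else {
      abort("hit table must carry the 12 standard columns plus 'staxids'")
    }
  }
  x |>
    filter(.data$evalue <= evalue_max) |>
    arrange(.data$qseqid, desc(.data$bitscore), .data$sseqid) |>
    group_by(.data$qseqid) |>
    slice_head(n = top_n) |>
    ungroup()
}

#' Build and validate a taxonomy tree
#'
#' @param nodes A data frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`. The root must be self-parented and unique; cycles are
#'   rejected.
#' @return A `taxonomy_tree` tibble.
#' @export
taxonomy_tree <- function(nodes) {
  tr <- as_tibble(nodes)
  need <- c("taxon_id", "parent_id", "rank", "name")
  if (!all(need %in% names(tr))) {
    abort(paste0("taxonomy nodes need columns: ", paste(need, collapse = ", ")))
  }
  tr$taxon_id <- as.character(tr$taxon_id)
  tr$parent_id <- as.character(tr$parent_id)
  if (anyDuplicated(tr$taxon_id)) abort("duplicate taxon ids")
  roots <- tr$taxon_id[tr$taxon_id == tr$parent_id]
  if (length(roots) != 1) abort("taxonomy must have exactly one self-parented root")
  if (!all(tr$parent_id %in% tr$taxon_id)) abort("unresolvable parent ids")
  # cycle check: every node must reach the root
  parent <- setNames(tr$parent_id, tr$taxon_id)
  for (id in tr$taxon_id) {
    seen <- character()
    cur <- id
    while (cur != roots) {
      if (cur %in% seen) abort("taxonomy contains a cycle")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  structure(tr, class = c("taxonomy_tree", class(tr)))
}

#' Read an NCBI-style taxonomy dump
#'
#' Parses `nodes.dmp` and `names.dmp` (fields separated by `\t|\t`,
#' scientific names only) from a directory.
#'
#' @param dir Directory containing `nodes.dmp` and `names.dmp`.
#' @return A `taxonomy_tree`.
#' @export
read_taxdump <- function(dir) {
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  if (!file.exists(nodes_path)) abort(paste0("missing ", nodes_path))
  parse_dmp <- function(path) {
    lines <- readr::read_lines(path)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nd <- parse_dmp(nodes_path)
  nodes <- tibble(
    taxon_id = vapply(nd, `[`, character(1), 1),
    parent_id = vapply(nd, `[`, character(1), 2),
    rank = vapply(nd, `[`, character(1), 3)
  )
  nodes$name <- nodes$taxon_id
  if (file.exists(names_path)) {
    nm <- parse_dmp(names_path)
    cls <- vapply(nm, `[`, character(1), 4)
    sci <- grepl("scientific name", cls)
    name_map <- setNames(vapply(nm[sci], `[`, character(1), 2),
                         vapply(nm[sci], `[`, character(1), 1))
    hit <- nodes$taxon_id %in% names(name_map)
    nodes$name[hit] <- unname(name_map[nodes$taxon_id[hit]])
  }
  taxonomy_tree(nodes)
}

# Path from a taxon to the root (inclusive, taxon first).
tax_ancestors <- function(tree, id, parent = NULL) {
  parent <- parent %||% setNames(tree$parent_id, tree$taxon_id)
  out <- character()
  cur <- as.character(id)
  if (!cur %in% names(parent)) return(out)
  repeat {
    out <- c(out, cur)
    nxt <- parent[[cur]]
    if (nxt == cur) break
    cur <- nxt
  }
  out
}

# All descendants-or-self of a node.
tax_clade <- function(tree, id) {
  id <- as.character(id)
  kids <- split(tree$taxon_id, tree$parent_id)
  out <- character()
  queue <- id
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, cur)
    ch <- setdiff(kids[[cur]] %||% character(), cur)
    queue <- c(queue, ch)
  }
  unique(out)
}

#' Best-hit and lowest-common-ancestor taxonomic assignment
#'
#' Per query, the best-hit taxon is that of the single highest-bitscore hit.
#' Qualifying hits for the LCA must have `bitscore > min_bitscore` (strict)
#' and `bitscore >= (1 - top_fraction) * top bitscore` (a multiplicative
#' window below the query's top score); when at least `min_hits` hits
#' qualify, the LCA is the deepest taxonomy node ancestral to (or equal to)
#' all their taxa, otherwise the query is left unassigned (`NA`). Hit taxa
#' absent from the tree are treated as missing and reported via a warning.
#'
#' @param hits A hit tibble from [load_hits()].
#' @param tree A [taxonomy_tree()].
#' @param min_hits Minimum number of qualifying hits.
#' @param min_bitscore Strict lower bitscore bound for a qualifying hit.
#' @param top_fraction Relative window below the top bitscore.
#' @return A tibble `query_id`, `best_hit_taxon`, `lca_taxon` (NA = not
#'   assigned).
#' @export
assign_lca <- function(hits, tree, min_hits = 3, min_bitscore = 75,
                       top_fraction = 0.10) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  parent <- setNames(tree$parent_id, tree$taxon_id)
  depth_env <- new.env(parent = emptyenv())
  chain_cache <- new.env(parent = emptyenv())
  chain <- function(id) {
    ch <- chain_cache[[id]]
    if (is.null(ch)) {
      ch <- tax_ancestors(tree, id, parent)
      assign(id, ch, envir = chain_cache)
    }
    ch
  }
  lca_of <- function(taxa) {
    taxa <- unique(taxa)
    common <- chain(taxa[[1]])
    for (t in taxa[-1]) {
      common <- common[common %in% chain(t)]
      if (length(common) <= 1) break
    }
    if (length(common)) common[[1]] else NA_character_
  }
  unknown <- setdiff(unique(as.character(hits$staxids)), tree$taxon_id)
  if (length(unknown)) {
    warn(sprintf("%d hit taxon id(s) not in the taxonomy; treated as missing",
                 length(unknown)))
  }
  hits |>
    mutate(staxids = as.character(.data$staxids)) |>
    arrange(.data$qseqid, desc(.data$bitscore), .data$sseqid) |>
    group_by(.data$qseqid) |>
    group_modify(function(df, key) {
      top <- df$bitscore[1]
      best <- df$staxids[1]
      if (!best %in% tree$taxon_id) best <- NA_character_
      qual <- df$bitscore > min_bitscore &
        df$bitscore >= (1 - top_fraction) * top &
        df$staxids %in% tree$taxon_id
      lca <- if (sum(qual) >= min_hits) lca_of(df$staxids[qual])
             else NA_character_
      tibble(best_hit_taxon = best, lca_taxon = lca)
    }) |>
    ungroup() |>
    rename(query_id = "qseqid")
}

#' Taxonomic category summary
#'
#' Counts, per configured category (a named set of taxonomy nodes, possibly
#' nested), the queries whose best-hit and LCA assignments fall within that
#' clade, with percentages relative to the number of queries with hits.
#'
#' @param assignments Output of [assign_lca()].
#' @param tree A [taxonomy_tree()].
#' @param categories Named character vector mapping category label to a
#'   taxon id in the tree.
#' @return A tibble `category`, `n_best`, `pct_best`, `n_lca`, `pct_lca`.
#' @export
taxonomic_summary <- function(assignments, tree, categories) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  bad <- setdiff(as.character(categories), tree$taxon_id)
  if (length(bad)) {
    abort(paste0("unknown category node(s): ", paste(bad, collapse = ", ")))
  }
  n_queries <- nrow(assignments)
  rows <- map2(names(categories), as.character(categories), function(nm, id) {
    clade <- tax_clade(tree, id)
    nb <- sum(assignments$best_hit_taxon %in% clade, na.rm = TRUE)
    nl <- sum(assignments$lca_taxon %in% clade, na.rm = TRUE)
    tibble(category = nm, n_best = nb,
           pct_best = if (n_queries) 100 * nb / n_queries else 0,
           n_lca = nl,
           pct_lca = if (n_queries) 100 * nl / n_queries else 0)
  })
  bind_rows(rows)
}

#' Screen for plastid genomic-DNA contamination
#'
#' Per query, overlapping hit intervals on the plastid genome are merged;
#' a query is flagged `genomic_contamination` when its merged span exceeds
#' `max_span` bp (strictly) or it overlaps more than `max_genes` distinct
#' annotated genes, and `putative_transcript` otherwise.
#'
#' @param hits A hit tibble (needs `qseqid`, `sstart`, `send`; 1-based
#'   inclusive subject coordinates, possibly reversed).
#' @param genes Gene annotation: a data frame with `gene_id`, `start`,
#'   `end` (1-based inclusive), or a path to a GFF3 file whose `gene`
#'   features are used.
#' @param genome_length Plastid genome length (bp); annotation beyond it is
#'   an error.
#' @param max_span Maximum merged span (bp) for a transcript-like query.
#' @param max_genes Maximum number of distinct overlapped genes.
#' @return A tibble `query_id`, `span_bp`, `n_genes`, `flag`.
#' @export
plastid_screen <- function(hits, genes, genome_length = NULL,
                           max_span = 3500, max_genes = 5) {
  if (is.character(genes) && length(genes) == 1) genes <- read_gff_genes(genes)
  genes <- as_tibble(genes)
  if (!all(c("start", "end") %in% names(genes))) {
    abort("`genes` needs `start` and `end` columns (1-based inclusive)")
  }
  if (!"gene_id" %in% names(genes)) {
    genes$gene_id <- sprintf("gene_%03d", seq_len(nrow(genes)))
  }
  if (!is.null(genome_length) && nrow(genes) > 0 &&
      max(genes$end) > genome_length) {
    abort("gene annotation extends beyond the plastid genome length")
  }
  gene_ir <- IRanges::IRanges(start = genes$start, end = genes$end)
  hits |>
    mutate(lo = pmin(.data$sstart, .data$send),
           hi = pmax(.data$sstart, .data$send)) |>
    group_by(query_id = .data$qseqid) |>
    group_modify(function(df, key) {
      merged <- IRanges::reduce(IRanges::IRanges(start = df$lo, end = df$hi))
      span <- sum(IRanges::width(merged))
      ov <- IRanges::findOverlaps(merged, gene_ir)
      ng <- length(unique(genes$gene_id[S4Vectors::subjectHits(ov)]))
      tibble(span_bp = span, n_genes = ng,
             flag = if (span > max_span || ng > max_genes)
               "genomic_contamination" else "putative_transcript")
    }) |>
    ungroup()
}

# Minimal GFF3 gene reader (type == "gene"; ID=/Name= attribute).
read_gff_genes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene",
                 logical(1))
  fields <- fields[keep]
  tibble(
    gene_id = vapply(fields, function(f) {
      m <- regmatches(f[9], regexpr("(ID|Name)=[^;]+", f[9]))
      if (length(m)) sub("^(ID|Name)=", "", m) else f[9]
    }, character(1)),
    start = vapply(fields, function(f) as.integer(f[4]), integer(1)),
    end = vapply(fields, function(f) as.integer(f[5]), integer(1))
  )
}
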