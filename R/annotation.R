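#' Longest open reading frame over six frames
#'
#' For each sequence, translates all six reading frames and reports the
#' longest stop-to-stop (or frame-edge-bounded) segment; no start codon is
#' required. Segments are ranked by their stop-to-stop span in codons, a
#' terminating stop codon counting toward the span; ties go to the lowest
#' frame in the order +1, +2, +3, -1, -2, -3, then to the leftmost segment
#' within the frame. Reverse-frame intervals are reported on the forward
#' nucleotide sequence; the reported interval and peptide exclude the
#' bounding stops.
#'
#' @param x Sequences (data frame with `seq_id`/`sequence` or a named
#'   character vector). Sequences shorter than 3 nt yield no call.
#' @return A tibble `seq_id`, `frame` (one of `+1..+3`, `-1..-3`), `start`,
#'   `end` (0-based half-open nucleotide interval, length divisible by 3),
#'   `peptide` (no internal stop).
#' @export
longest_orf <- function(x) {
  tb <- as_seq_tbl(x)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  rows <- map2(tb$seq_id, tb$sequence, function(id, s) {
    L <- nchar(s)
    if (L < 3) return(NULL)
    best <- NULL
    rc <- revcomp(s)
    for (fi in seq_along(frames)) {
      fwd <- fi <= 3
      off <- (fi - 1) %% 3
      src <- if (fwd) s else rc
      ncod <- (L - off) %/% 3
      if (ncod < 1) next
      sub <- substr(src, off + 1, off + 3 * ncod)
      codons <- substring(sub, seq(1, 3 * ncod - 2, 3), seq(3, 3 * ncod, 3))
      aa <- unname(Biostrings::GENETIC_CODE[codons])
      aa[is.na(aa)] <- "X"
      stops <- c(0L, which(aa == "*"), ncod + 1L)
      seg_start <- head(stops, -1) + 1L   # codon index of first aa
      seg_end <- tail(stops, -1) - 1L     # codon index of last aa
      lens <- pmax(0L, seg_end - seg_start + 1L)
      # span weight: a right-bounding stop codon counts toward the span
      weight <- lens + as.integer(tail(stops, -1) <= ncod)
      jbest <- which.max(weight)          # leftmost maximal segment
      plen <- lens[jbest]
      if (is.null(best) || weight[jbest] > best$weight) {
        a <- off + 3L * (seg_start[jbest] - 1L)      # 0-based nt on src
        b <- a + 3L * plen
        if (!fwd) { tmp <- a; a <- L - b; b <- L - tmp }
        pep <- if (plen > 0) {
          paste(aa[seg_start[jbest]:seg_end[jbest]], collapse = "")
        } else ""
        best <- list(frame = frames[fi], start = a, end = b, peptide = pep,
                     plen = plen, weight = weight[jbest])
      }
    }
    if (is.null(best)) return(NULL)
    tibble(seq_id = id, frame = best$frame,
           start = as.integer(best$start), end = as.integer(best$end),
           peptide = best$peptide)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(seq_id = character(), frame = character(),
                  start = integer(), end = integer(), peptide = character())
  }
  out
}

#' Load an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas (id, name, namespace, `is_a`, `relationship:
#' part_of`, `subset` tags); obsolete terms are skipped. The typed edge
#' graph must be acyclic.
#'
#' @param path Path to an OBO 1.2 file.
#' @param slim Optional character vector of slim term ids; when `NULL`, any
#'   `subset:` tags found are retained in `slim_subsets` instead.
#' @return An object of class `ontology_graph`: a list with `terms` (tibble
#'   `id`, `name`, `namespace`), `edges` (tibble `from`, `to`, `type`),
#'   `slim` (character vector or NULL) and `slim_subsets` (named list).
#' @export
read_obo <- function(path, slim = NULL) {
  lines <- readr::read_lines(path)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NA_character_, name = NA_character_,
                  namespace = NA_character_, is_a = character(),
                  part_of = character(), subsets = character(),
                  obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (startsWith(ln, "[")) {          # e.g. [Typedef]
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    key <- kv[1]
    val <- sub(" !.*$", "", paste(kv[-1], collapse = ": "))
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, trimws(val))
    else if (key == "subset") cur$subsets <- c(cur$subsets, trimws(val))
    else if (key == "is_obsolete" && trimws(val) == "true") cur$obsolete <- TRUE
    else if (key == "relationship") {
      parts <- strsplit(trimws(val), "[ \t]+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        cur$part_of <- c(cur$part_of, parts[2])
      }
    }
  }
  terms <- flush(cur, terms)
  term_tbl <- tibble(
    id = vapply(terms, `[[`, character(1), "id"),
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace")
  )
  edges <- bind_rows(map(terms, function(t) {
    bind_rows(
      if (length(t$is_a)) tibble(from = t$id, to = t$is_a, type = "is_a"),
      if (length(t$part_of)) tibble(from = t$id, to = t$part_of,
                                    type = "part_of")
    )
  }))
  if (nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(), type = character())
  }
  edges <- filter(edges, .data$to %in% term_tbl$id)
  subsets <- map(terms, `[[`, "subsets")
  slim_subsets <- list()
  all_tags <- unique(unlist(subsets))
  for (tag in all_tags) {
    slim_subsets[[tag]] <- term_tbl$id[vapply(subsets, function(s) tag %in% s,
                                              logical(1))]
  }
  ontology_graph(term_tbl, edges, slim = slim, slim_subsets = slim_subsets)
}

#' Construct an ontology graph
#'
#' @param terms Tibble with `id`, `name`, `namespace`.
#' @param edges Tibble with `from`, `to`, `type` (`is_a` / `part_of`),
#'   child pointing to parent.
#' @param slim Optional character vector of slim term ids (must exist in
#'   `terms`).
#' @param slim_subsets Optional named list of subset-tag term sets.
#' @return An `ontology_graph` object.
#' @export
ontology_graph <- function(terms, edges, slim = NULL, slim_subsets = list()) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = TRUE,
    vertices = terms$id)
  if (!igraph::is_dag(g)) abort("ontology graph contains a cycle")
  if (!is.null(slim)) {
    missing <- setdiff(slim, terms$id)
    if (length(missing)) {
      abort(paste0("slim term(s) not in the ontology: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  structure(list(terms = terms, edges = edges, graph = g, slim = slim,
                 slim_subsets = slim_subsets),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms, %d edges, %s slim terms\n",
              nrow(x$terms), nrow(x$edges),
              if (is.null(x$slim)) "no" else length(x$slim)))
  invisible(x)
}

#' Map annotations onto a GO-slim vocabulary
#'
#' Each annotated term contributes every slim term among its
#' ancestors-or-self, following the true-path rule over `is_a` (and, by
#' default, `part_of`) edges. Namespaces are kept separate by construction
#' since slim terms carry their own namespace. Unknown term ids are skipped
#' with a warning.
#'
#' @param annotations Tibble with `seq_id`, `term_id`.
#' @param graph An [ontology_graph()].
#' @param slim Slim term ids; defaults to `graph$slim`.
#' @param use_part_of Traverse `part_of` edges as well as `is_a`.
#' @return A tibble `seq_id`, `slim_id` (distinct pairs).
#' @export
map_to_slim <- function(annotations, graph, slim = graph$slim,
                        use_part_of = TRUE) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (is.null(slim)) abort("no slim set supplied")
  g <- graph$graph
  if (!use_part_of) {
    keep <- which(graph$edges$type == "is_a")
    g <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
  }
  ann <- as_tibble(annotations)
  known <- ann$term_id %in% graph$terms$id
  if (!all(known)) {
    warn(sprintf("%d annotation(s) with unknown term ids skipped",
                 sum(!known)))
    ann <- ann[known, ]
  }
  if (nrow(ann) == 0) return(tibble(seq_id = character(),
                                    slim_id = character()))
  uterms <- unique(ann$term_id)
  d <- igraph::distances(g, v = uterms, to = slim, mode = "out")
  reach <- map(seq_along(uterms), function(i) slim[is.finite(d[i, ])])
  names(reach) <- uterms
  ann |>
    mutate(slim_id = reach[.data$term_id]) |>
    select("seq_id", "slim_id") |>
    unnest("slim_id") |>
    distinct()
}

#' GO-slim enrichment by two-tailed Fisher's exact test
#'
#' For every term present in either set, builds the 2x2 table of annotated
#' sequences (the counting unit is the sequence, not the annotation), runs a
#' two-tailed Fisher's exact test, and controls the FDR across terms with
#' Benjamini-Hochberg. Direction is `over` when the term is relatively more
#' frequent in the test set, `under` when less, `none` at equality.
#'
#' @param test,reference Slim-mapped annotation tibbles (`seq_id` and a
#'   term column, `slim_id` or `term_id`).
#' @param alpha FDR level for the `significant` flag.
#' @return A tibble of class `enrichment_result`: `term_id`, `a` (test
#'   with), `b` (test without), `c` (reference with), `d` (reference
#'   without), `odds_ratio`, `p`, `q`, `direction`, `significant`.
#' @export
enrichment <- function(test, reference, alpha = 0.05) {
  term_col <- function(df) {
    if ("slim_id" %in% names(df)) "slim_id" else "term_id"
  }
  test <- as_tibble(test)
  reference <- as_tibble(reference)
  if (nrow(reference) == 0) abort("reference annotation set is empty")
  n_test <- n_distinct(test$seq_id)
  n_ref <- n_distinct(reference$seq_id)
  tt <- test |> distinct(.data$seq_id, term_id = .data[[term_col(test)]])
  rr <- reference |>
    distinct(.data$seq_id, term_id = .data[[term_col(reference)]])
  terms <- union(tt$term_id, rr$term_id)
  a <- table(factor(tt$term_id, levels = terms))
  cc <- table(factor(rr$term_id, levels = terms))
  res <- tibble(
    term_id = terms,
    a = as.integer(a),
    b = n_test - as.integer(a),
    c = as.integer(cc),
    d = n_ref - as.integer(cc)
  )
  res$p <- pmap_dbl_local(res, function(a, b, c, d) {
    fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
  })
  res$q <- p.adjust(res$p, method = "BH")
  res$odds_ratio <- (res$a * res$d) / pmax(1e-300, res$b * res$c)
  res$direction <- case_when(
    res$a * res$d > res$b * res$c ~ "over",
    res$a * res$d < res$b * res$c ~ "under",
    TRUE ~ "none"
  )
  res$significant <- res$q <= alpha & res$direction != "none"
  res <- arrange(res, .data$q, .data$p, .data$term_id)
  class(res) <- c("enrichment_result", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "n_test") <- n_test
  attr(res, "n_reference") <- n_ref
  res
}

pmap_dbl_local <- function(df, f) {
  vapply(seq_len(nrow(df)), function(i) {
    f(df$a[i], df$b[i], df$c[i], df$d[i])
  }, numeric(1))
}

#' Detection rate of a reference gene set
#'
#' A reference gene counts as detected when at least one hit against it has
#' an alignment longer than `min_aln_residues` residues (strictly).
#'
#' @param hits Tibble with `ref_id` and `aln_len` columns (alignment length
#'   in residues).
#' @param reference Character vector of reference gene ids (non-empty).
#' @param min_aln_residues Strict lower bound on alignment length.
#' @return A one-row tibble `detected`, `total`, `fraction`, `pct`.
#' @export
detection_rate <- function(hits, reference, min_aln_residues = 30) {
  if (length(reference) == 0) abort("reference gene list is empty")
  good <- hits |>
    filter(.data$aln_len > min_aln_residues, .data$ref_id %in% reference)
  detected <- n_distinct(good$ref_id)
  tibble(detected = detected, total = length(reference),
         fraction = detected / length(reference),
         pct = 100 * detected / length(reference))
}

#' Venn region counts for two or three sets
#'
#' Counts every exclusive Venn region; when a universe is supplied the
#' outside-all count is included.
#'
#' @param sets A named list of 2 or 3 character vectors.
#' @param universe Optional character vector containing all ids.
#' @return A tibble `region`, `count`; regions are named with `&` joins of
#'   the set names (exclusive regions), plus `"none"` for the universe
#'   remainder.
#' @export
set_overlap <- function(sets, universe = NULL) {
  k <- length(sets)
  if (k < 2 || k > 3) abort("set_overlap supports 2 or 3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  ids <- unique(c(unlist(sets), universe))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) {
    if (!any(r)) "none" else paste(names(sets)[r], collapse = "&")
  })
  combos <- unlist(map(seq_len(k), function(m) {
    apply(utils::combn(names(sets), m), 2, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = c(combos, "none")))
  out <- tibble(region = names(counts), count = as.integer(counts))
  if (is.null(universe)) out <- filter(out, .data$region != "none")
  out
}
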