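# Small, fully deterministic reference objects: a plant-centred taxonomy,
# a three-namespace ontology with a slim cut, and a toy plastid genome.
# These stand in for the NCBI taxonomy, the Gene Ontology and a chloroplast
# reference in tests and fixtures; all are synthetic.

#' Toy plant-centred taxonomy
#'
#' A fixed ~40-node taxonomy with the clades used in contamination
#' screening summaries: green plants, green algae, land plants, bryophytes,
#' vascular plants, lycophytes, ferns, seed plants (gymno/angiosperms),
#' animals, fungi and bacteria, each with a few species tips.
#'
#' @return A [taxonomy_tree()].
#' @export
toy_taxonomy <- function() {
  n <- function(id, parent, rank, name) {
    tibble(taxon_id = id, parent_id = parent, rank = rank, name = name)
  }
  nodes <- bind_rows(
    n("1", "1", "no rank", "root"),
    n("2", "1", "superkingdom", "Bacteria"),
    n("21", "2", "species", "Escherichia-like sp. 1"),
    n("22", "2", "species", "Bacillus-like sp. 2"),
    n("23", "2", "species", "Pseudomonas-like sp. 3"),
    n("3", "1", "superkingdom", "Eukaryota"),
    n("4", "3", "kingdom", "Viridiplantae"),
    n("5", "4", "phylum", "Chlorophyta"),
    n("51", "5", "species", "Chlamydomonas-like alga"),
    n("52", "5", "species", "Volvox-like alga"),
    n("6", "4", "clade", "Embryophyta"),
    n("7", "6", "phylum", "Bryophyta"),
    n("71", "7", "species", "Physcomitrella-like moss"),
    n("72", "7", "species", "Sphagnum-like moss"),
    n("8", "6", "clade", "Tracheophyta"),
    n("9", "8", "phylum", "Lycopodiophyta"),
    n("91", "9", "species", "Selaginella-like lycophyte"),
    n("10", "8", "class", "Polypodiopsida"),
    n("101", "10", "species", "Pteridium-like fern"),
    n("102", "10", "species", "Adiantum-like fern"),
    n("11", "8", "clade", "Spermatophyta"),
    n("12", "11", "clade", "Acrogymnospermae"),
    n("121", "12", "species", "Picea-like conifer"),
    n("122", "12", "species", "Pinus-like conifer"),
    n("13", "11", "clade", "Magnoliopsida"),
    n("131", "13", "species", "Arabidopsis-like angiosperm"),
    n("132", "13", "species", "Oryza-like angiosperm"),
    n("133", "13", "species", "Vitis-like angiosperm"),
    n("14", "3", "kingdom", "Metazoa"),
    n("141", "14", "species", "Drosophila-like animal"),
    n("142", "14", "species", "Homo-like animal"),
    n("15", "3", "kingdom", "Fungi"),
    n("151", "15", "species", "Saccharomyces-like fungus")
  )
  taxonomy_tree(nodes)
}

#' Standard category set for [taxonomic_summary()] on [toy_taxonomy()]
#' @return A named character vector of category taxon ids.
#' @export
toy_taxonomy_categories <- function() {
  c("Eukaryotes" = "3", "Green plants" = "4", "Green algae" = "5",
    "Land plants" = "6", "Bryophytes" = "7", "Vascular plants" = "8",
    "Lycophytes" = "9", "Ferns" = "10", "Seed plants" = "11",
    "Gymnosperms" = "12", "Angiosperms" = "13", "Animals" = "14",
    "Fungi" = "15", "Bacteria" = "2")
}

# Species tips for hit simulation.
toy_plant_tips <- function() c("51", "52", "71", "72", "91", "101", "102",
                               "121", "122", "131", "132", "133")
toy_contam_tips <- function() c("21", "22", "23")

#' Toy three-namespace ontology with a slim cut
#'
#' A fixed DAG shaped like a miniature Gene Ontology: one root per
#' namespace, a mid layer (the slim cut) and a leaf layer, with a sprinkle
#' of `part_of` edges and multiple parentage.
#'
#' @return An [ontology_graph()] with `slim` set to the mid-layer terms.
#' @export
toy_ontology <- function() {
  ns <- c(BP = "biological_process", CC = "cellular_component",
          MF = "molecular_function")
  terms <- list()
  edges <- list()
  slim <- character()
  tid <- function(i) sprintf("GO:%07d", i)
  i <- 0
  for (tag in names(ns)) {
    i <- i + 1
    root <- tid(i)
    terms[[root]] <- tibble(id = root, name = paste0(ns[tag], " root"),
                            namespace = ns[tag])
    mids <- character(4)
    for (m in 1:4) {
      i <- i + 1
      mids[m] <- tid(i)
      terms[[mids[m]]] <- tibble(id = mids[m],
                                 name = sprintf("%s mid %d", tag, m),
                                 namespace = ns[tag])
      edges[[length(edges) + 1]] <- tibble(from = mids[m], to = root,
                                           type = "is_a")
    }
    slim <- c(slim, mids)
    for (l in 1:8) {
      i <- i + 1
      leaf <- tid(i)
      terms[[leaf]] <- tibble(id = leaf,
                              name = sprintf("%s leaf %d", tag, l),
                              namespace = ns[tag])
      # each leaf under one or two mid terms; every fourth via part_of
      p1 <- mids[(l - 1) %% 4 + 1]
      edges[[length(edges) + 1]] <- tibble(
        from = leaf, to = p1, type = if (l %% 4 == 0) "part_of" else "is_a")
      if (l %% 3 == 0) {
        p2 <- mids[l %% 4 + 1]
        edges[[length(edges) + 1]] <- tibble(from = leaf, to = p2,
                                             type = "is_a")
      }
    }
  }
  ontology_graph(bind_rows(terms), bind_rows(edges), slim = slim)
}

#' Write an ontology graph as OBO 1.2
#'
#' @param graph An [ontology_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    t <- graph$terms[i, ]
    lines <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
               paste0("namespace: ", t$namespace))
    e <- graph$edges[graph$edges$from == t$id, ]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, if (e$type[j] == "is_a") {
        paste0("is_a: ", e$to[j])
      } else {
        paste0("relationship: part_of ", e$to[j])
      })
    }
    if (!is.null(graph$slim) && t$id %in% graph$slim) {
      lines <- c(lines, "subset: goslim_toy")
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Simulate leaf-term annotations for a set of sequences
#'
#' @param ids Sequence ids to annotate.
#' @param graph An [ontology_graph()].
#' @param mean_terms Mean number of terms per annotated sequence (Poisson,
#'   shifted to >= 1).
#' @param prob_annotated Probability that a sequence receives any
#'   annotation.
#' @param seed Integer seed.
#' @return A tibble `seq_id`, `term_id`.
#' @export
simulate_annotations <- function(ids, graph, mean_terms = 2,
                                 prob_annotated = 0.8, seed = 1L) {
  leaves <- setdiff(graph$terms$id, graph$edges$to)
  with_seed(seed, {
    rows <- map(ids, function(id) {
      if (runif(1) > prob_annotated) return(NULL)
      k <- 1L + rpois(1, mean_terms - 1)
      tibble(seq_id = id, term_id = sample(leaves, min(k, length(leaves))))
    })
    bind_rows(rows)
  })
}

#' Simulate tabular homology hits from known read provenance
#'
#' For each query (typically a unigene), emits 3-6 hits in the standard
#' 13-column tabular layout. Queries sourced from the target transcriptome
#' hit plant species tips of [toy_taxonomy()]; queries sourced from
#' contaminants hit bacterial tips. Bitscores decay from a random top score
#' so that best-hit and LCA assignment are exercised realistically.
#'
#' @param sources Tibble with `query_id`, `is_contaminant`.
#' @param seed Integer seed.
#' @param aln_mean Mean alignment length (residues).
#' @return A hit tibble in [load_hits()] layout.
#' @export
simulate_hits <- function(sources, seed = 1L, aln_mean = 150) {
  with_seed(seed, {
    rows <- map(seq_len(nrow(sources)), function(i) {
      q <- sources$query_id[i]
      tips <- if (isTRUE(sources$is_contaminant[i])) toy_contam_tips()
              else toy_plant_tips()
      nh <- sample(3:6, 1)
      top <- runif(1, 120, 400)
      bits <- round(top * (1 - 0.04 * (seq_len(nh) - 1)), 1)
      alen <- pmax(31L, as.integer(round(rnorm(nh, aln_mean, aln_mean / 4))))
      tibble(
        qseqid = q,
        sseqid = sprintf("sbj_%s_%02d", substr(rlang::hash(q), 1, 6),
                         seq_len(nh)),
        pident = round(runif(nh, 55, 98), 1),
        length = alen,
        mismatch = as.integer(round(alen * 0.1)),
        gapopen = 0L,
        qstart = 1L, qend = alen * 3L,
        sstart = 1L, send = alen,
        evalue = 10^(-runif(nh, 15, 60)),
        bitscore = bits,
        staxids = sample(tips, nh, replace = TRUE)
      )
    })
    bind_rows(rows)
  })
}

#' Toy plastid genome and gene annotation
#'
#' A deterministic random genome with evenly spaced single-exon genes,
#' standing in for a chloroplast reference in genomic-DNA contamination
#' screens.
#'
#' @param genome_length Genome length (bp).
#' @param n_genes Number of annotated genes.
#' @param seed Integer seed.
#' @return A list with `sequence` (string), `genes` (tibble `gene_id`,
#'   `start`, `end`, 1-based inclusive) and `length`.
#' @export
toy_plastid <- function(genome_length = 20000, n_genes = 10, seed = 7L) {
  with_seed(seed, {
    seqn <- random_dna(1, genome_length)
    span <- genome_length %/% n_genes
    genes <- tibble(
      gene_id = sprintf("pgene_%02d", seq_len(n_genes)),
      start = (seq_len(n_genes) - 1) * span + 101,
      end = (seq_len(n_genes) - 1) * span + span - 100
    )
    list(sequence = seqn, genes = genes, length = genome_length)
  })
}
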