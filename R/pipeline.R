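#' Pipeline configuration
#'
#' A nested configuration with one block per stage plus global settings.
#' Unknown keys are rejected, so configs round-trip safely through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed Global seed; every stochastic stage derives its stream from
#'   it.
#' @param ... Named overrides, e.g. `clean = list(min_len = 100)`,
#'   `curve = list(n_boot = 500)`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  base <- list(
    seed = as.integer(seed),
    clean = list(enabled = TRUE, min_len = 78, max_len = Inf,
                 window = 10, min_frac = 0.8, min_run = 5,
                 max_mismatch_rate = 0.1, min_match = 8),
    assemble = list(enabled = TRUE, id1 = 0.94, ovl1 = 40, k1 = 16,
                    id2 = 0.95, ovl2 = 25, k2 = 12),
    curve = list(enabled = TRUE, n_boot = 200, conf = 0.95),
    tax = list(enabled = TRUE, evalue_max = 1e-10, top_n = 10,
               min_hits = 3, min_bitscore = 75, top_frac = 0.10),
    ssr = list(enabled = TRUE, min_flank = 20),
    repeats = list(enabled = TRUE, min_identity = 0.75, min_len = 30),
    annotate = list(enabled = TRUE, alpha = 0.05)
  )
  overrides <- list(...)
  merge_checked(base, overrides, path = "config")
}

merge_checked <- function(base, overrides, path) {
  for (key in names(overrides)) {
    if (!key %in% names(base)) {
      abort(sprintf("unknown configuration key '%s.%s'", path, key))
    }
    if (is.list(base[[key]]) && is.list(overrides[[key]])) {
      base[[key]] <- merge_checked(base[[key]], overrides[[key]],
                                   paste0(path, ".", key))
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  base
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the YAML serialization.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  raw$seed <- NULL
  do.call(pipeline_config, c(list(seed = seed), raw))
}

#' Generate a complete synthetic input bundle
#'
#' Writes everything a full pipeline run consumes: decorated reads (FASTQ)
#' with their truth table, the true transcripts and contaminant library,
#' adapters, a taxonomy table, an OBO ontology with a slim cut, annotation
#' tables, a classified repeat library (elements planted verbatim in real
#' transcripts so the screen has true positives), a plastid genome with
#' GFF3 gene annotation, and a conserved-gene id list.
#'
#' @param preset `"tiny"` (~400 reads, seconds end to end) or
#'   `"paper-like-mini"` (2,000 genes, 50,000 reads, normalized skew on).
#' @param dir Output directory (created).
#' @param seed Integer seed; fixtures are byte-identical for a fixed
#'   preset/seed.
#' @return `dir`, invisibly; the directory layout is described in
#'   `fixture.yml`.
#' @export
make_fixture <- function(preset = c("tiny", "paper-like-mini"), dir,
                         seed = 1L) {
  preset <- tryCatch(match.arg(preset), error = function(e) {
    abort("unknown preset; available presets: tiny, paper-like-mini")
  })
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- switch(preset,
    "tiny" = sim_config(n_genes = 40, gene_length_mean = 800,
                        gene_length_sd = 300, n_reads = 400, seed = seed),
    "paper-like-mini" = sim_config(seed = seed)
  )
  tx <- simulate_transcriptome(cfg)
  reads <- simulate_reads(tx, cfg)
  contam <- simulate_contaminant_library(seed = seed + 3L)
  reads <- spike_contaminants(reads, contam, cfg$contaminant_fraction, cfg,
                              seed = cfg$seed)
  write_fastq(reads, file.path(dir, "reads.fastq"), id_col = "read_id")
  write_truth_tsv(reads, file.path(dir, "truth.tsv"))
  write_fasta(tx, file.path(dir, "transcripts.fasta"),
              id_col = "transcript_id")
  write_fasta(contam, file.path(dir, "contaminants.fasta"),
              id_col = "transcript_id")
  write_fasta(c(adapter_5p = cfg$adapter_5p, adapter_3p = cfg$adapter_3p),
              file.path(dir, "adapters.fasta"))
  readr::write_tsv(as_tibble(toy_taxonomy()), file.path(dir, "taxonomy.tsv"))
  onto <- toy_ontology()
  write_obo(onto, file.path(dir, "ontology.obo"))
  ann_test <- simulate_annotations(tx$transcript_id, onto, seed = seed + 11L)
  ref_ids <- sprintf("refgene_%05d", seq_len(max(200, nrow(tx))))
  ann_ref <- simulate_annotations(ref_ids, onto, mean_terms = 3,
                                  seed = seed + 12L)
  readr::write_tsv(ann_test, file.path(dir, "annotations_test.tsv"))
  readr::write_tsv(ann_ref, file.path(dir, "annotations_reference.tsv"))
  # repeat library: fragments of real transcripts, so screening has truth
  lib_classes <- c("LTR/Copia", "LTR/Gypsy", "LINE/L1", "DNA/En-Spm")
  donors <- with_seed(seed + 13L, {
    idx <- sample(nrow(tx), min(length(lib_classes), nrow(tx)))
    map(seq_along(idx), function(i) {
      s <- tx$sequence[idx[i]]
      L <- min(400, nchar(s))
      list(id = sprintf("rep_el_%02d", i), class = lib_classes[i],
           seq = substr(s, 1, L))
    })
  })
  lib_lines <- unlist(map(donors, function(d) {
    c(sprintf(">%s class=%s", d$id, d$class), d$seq)
  }))
  writeLines(lib_lines, file.path(dir, "repeat_library.fasta"))
  pl <- toy_plastid(seed = seed + 14L)
  write_fasta(c(plastid = pl$sequence), file.path(dir, "plastid.fasta"))
  gff <- c("##gff-version 3",
           sprintf("plastid\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                   pl$genes$start, pl$genes$end, pl$genes$gene_id))
  writeLines(gff, file.path(dir, "plastid.gff3"))
  uco <- with_seed(seed + 15L, {
    sample(tx$transcript_id, max(1, round(0.1 * nrow(tx))))
  })
  writeLines(sort(uco), file.path(dir, "uco_list.txt"))
  yaml::write_yaml(list(preset = preset, seed = as.integer(seed),
                        n_genes = cfg$n_genes, n_reads = cfg$n_reads,
                        contaminant_fraction = cfg$contaminant_fraction),
                   file.path(dir, "fixture.yml"))
  invisible(dir)
}

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  unname(tools::md5sum(paths))
}

#' Run the full characterization pipeline on a fixture directory
#'
#' Executes the stages clean, assemble, curve, tax, ssr, repeats and
#' annotate in order, writing each stage's artifacts plus a manifest entry
#' (input hashes, parameter hash, outputs). A completed stage whose input
#' and parameter hashes are unchanged is skipped on re-run; any stage
#' failure halts the pipeline with a stage-named error.
#'
#' @param fixture_dir Directory produced by [make_fixture()].
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return The run manifest as a tibble (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(fixture_dir, out_dir,
                         config = pipeline_config()) {
  need <- c("reads.fastq", "adapters.fasta", "taxonomy.tsv", "ontology.obo",
            "repeat_library.fasta", "truth.tsv")
  missing <- need[!file.exists(file.path(fixture_dir, need))]
  if (length(missing)) {
    abort(paste0("missing pipeline input(s): ",
                 paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(parent = emptyenv())
  manifest <- list()

  run_stage <- function(name, inputs, params, outputs, fn) {
    state_path <- file.path(out_dir, sprintf(".stage_%s.json", name))
    sig <- rlang::hash(list(inputs = hash_files(inputs), params = params))
    if (file.exists(state_path) && all(file.exists(outputs))) {
      old <- jsonlite::read_json(state_path)
      if (identical(old$sig, sig)) {
        manifest[[name]] <<- tibble(stage = name, status = "skipped",
                                    signature = sig,
                                    outputs = paste(outputs, collapse = ";"))
        return(invisible(NULL))
      }
    }
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    jsonlite::write_json(list(sig = sig), state_path, auto_unbox = TRUE)
    manifest[[name]] <<- tibble(stage = name, status = "done",
                                signature = sig,
                                outputs = paste(outputs, collapse = ";"))
    invisible(NULL)
  }
  fx <- function(f) file.path(fixture_dir, f)
  ox <- function(f) file.path(out_dir, f)

  # -- clean ---------------------------------------------------------------
  cleaned_path <- ox("cleaned.fasta")
  run_stage("clean", fx(c("reads.fastq", "adapters.fasta")), config$clean,
            c(cleaned_path, ox("clean_report.tsv")), function() {
    fq <- Biostrings::readDNAStringSet(fx("reads.fastq"), format = "fastq")
    reads <- tibble(read_id = sub(" .*", "", names(fq)),
                    sequence = as.character(fq))
    adapters <- read_fasta(fx("adapters.fasta"))$sequence
    cl <- clean_reads(reads, adapters = adapters,
                      max_mismatch_rate = config$clean$max_mismatch_rate,
                      min_match = config$clean$min_match,
                      window = config$clean$window,
                      min_frac = config$clean$min_frac,
                      min_run = config$clean$min_run,
                      min_len = config$clean$min_len,
                      max_len = config$clean$max_len)
    write_fasta(cl$reads, cleaned_path, id_col = "read_id")
    readr::write_tsv(cl$report, ox("clean_report.tsv"))
  })

  # -- assemble ------------------------------------------------------------
  layout_path <- ox("layout.tsv")
  run_stage("assemble", cleaned_path, config$assemble,
            c(ox("unigenes.fasta"), layout_path, ox("assembly_report.tsv")),
            function() {
    reads <- read_fasta(cleaned_path, id_col = "read_id")
    prim <- assemble_primary(reads, min_identity = config$assemble$id1,
                             min_overlap = config$assemble$ovl1,
                             k = config$assemble$k1)
    sec <- assemble_secondary(prim, min_identity = config$assemble$id2,
                              min_overlap = config$assemble$ovl2,
                              k = config$assemble$k2)
    desc <- sprintf("%s category=%s depth=%.2f", sec$unigenes$unigene_id,
                    sec$unigenes$category, sec$unigenes$depth)
    write_fasta(tibble(seq_id = desc, sequence = sec$unigenes$consensus),
                ox("unigenes.fasta"))
    readr::write_tsv(sec$members, layout_path)
    readr::write_tsv(assembly_report(sec), ox("assembly_report.tsv"))
    assign("assembly", sec, envir = env)
  })
  if (is.null(env$assembly)) {
    members <- readr::read_tsv(layout_path, show_col_types = FALSE)
  } else {
    members <- env$assembly$members
  }

  # -- curve ---------------------------------------------------------------
  run_stage("curve", layout_path, config$curve,
            c(ox("curve.tsv"), ox("milestones.json")), function() {
    counts <- count(members, .data$unigene_id, name = "n_reads")
    cv <- accumulation_curve(counts$n_reads, n_boot = config$curve$n_boot,
                             conf = config$curve$conf,
                             seed = config$seed + 20L)
    readr::write_tsv(cv$curve, ox("curve.tsv"))
    jsonlite::write_json(
      list(milestones = cv$milestones,
           last10_mean_reads = cv$last10_mean_reads),
      ox("milestones.json"), auto_unbox = TRUE, digits = NA)
  })

  # unigene provenance (majority member source), used by tax + annotate
  truth <- readr::read_tsv(fx("truth.tsv"), show_col_types = FALSE)
  sources <- members |>
    left_join(select(truth, "read_id", "source_id", "is_contaminant"),
              by = "read_id") |>
    group_by(query_id = .data$unigene_id) |>
    summarise(source_id = names(sort(table(.data$source_id),
                                     decreasing = TRUE))[1],
              is_contaminant = mean(.data$is_contaminant) > 0.5,
              .groups = "drop")

  # -- tax -----------------------------------------------------------------
  run_stage("tax", c(layout_path, fx("taxonomy.tsv")), config$tax,
            c(ox("tax_assignments.tsv"), ox("tax_summary.tsv")), function() {
    tree <- taxonomy_tree(readr::read_tsv(fx("taxonomy.tsv"),
                                          show_col_types = FALSE,
                                          col_types = readr::cols(
                                            taxon_id = "c", parent_id = "c")))
    hits <- simulate_hits(sources, seed = config$seed + 21L)
    hits <- load_hits(hits, evalue_max = config$tax$evalue_max,
                      top_n = config$tax$top_n)
    asg <- assign_lca(hits, tree, min_hits = config$tax$min_hits,
                      min_bitscore = config$tax$min_bitscore,
                      top_fraction = config$tax$top_frac)
    readr::write_tsv(asg, ox("tax_assignments.tsv"))
    readr::write_tsv(taxonomic_summary(asg, tree, toy_taxonomy_categories()),
                     ox("tax_summary.tsv"))
  })

  # -- ssr -----------------------------------------------------------------
  run_stage("ssr", ox("unigenes.fasta"), config$ssr, ox("ssr.tsv"),
            function() {
    unig <- read_fasta(ox("unigenes.fasta"))
    loci <- flank_check(find_ssrs(unig), min_flank = config$ssr$min_flank)
    readr::write_tsv(loci, ox("ssr.tsv"))
  })

  # -- repeats -------------------------------------------------------------
  run_stage("repeats", c(ox("unigenes.fasta"), fx("repeat_library.fasta")),
            config$repeats,
            c(ox("repeat_matches.tsv"), ox("repeat_summary.tsv")),
            function() {
    unig <- read_fasta(ox("unigenes.fasta"))
    scr <- screen_repeat_library(unig, fx("repeat_library.fasta"),
                                 min_identity = config$repeats$min_identity,
                                 min_len = config$repeats$min_len)
    readr::write_tsv(scr$matches, ox("repeat_matches.tsv"))
    m <- scr$matches
    writeLines(c("##gff-version 3", sprintf(
      "%s\tgametotk\trepeat_region\t%d\t%d\t%.3f\t%s\t.\tID=%s;class=%s",
      m$seq_id, m$start + 1L, m$end, m$identity, m$strand,
      m$element_id, m$repeat_class)), ox("repeat_matches.gff3"))
    readr::write_tsv(scr$summary, ox("repeat_summary.tsv"))
  })

  # -- annotate ------------------------------------------------------------
  run_stage("annotate",
            c(ox("unigenes.fasta"), fx("ontology.obo"),
              fx("annotations_test.tsv"), fx("annotations_reference.tsv"),
              fx("uco_list.txt")),
            config$annotate,
            c(ox("orfs.tsv"), ox("enrichment.tsv"), ox("detection.tsv")),
            function() {
    unig <- read_fasta(ox("unigenes.fasta"))
    readr::write_tsv(longest_orf(unig), ox("orfs.tsv"))
    onto <- read_obo(fx("ontology.obo"))
    slim <- onto$slim_subsets[["goslim_toy"]]
    ann_tx <- readr::read_tsv(fx("annotations_test.tsv"),
                              show_col_types = FALSE)
    ann_ref <- readr::read_tsv(fx("annotations_reference.tsv"),
                               show_col_types = FALSE)
    # transfer transcript annotations to unigenes via provenance
    ann_unig <- sources |>
      inner_join(ann_tx, by = c(source_id = "seq_id"),
                 relationship = "many-to-many") |>
      select(seq_id = "query_id", "term_id")
    er <- enrichment(map_to_slim(ann_unig, onto, slim),
                     map_to_slim(ann_ref, onto, slim),
                     alpha = config$annotate$alpha)
    readr::write_tsv(as_tibble(er), ox("enrichment.tsv"))
    uco <- readr::read_lines(fx("uco_list.txt"))
    det_hits <- members |>
      left_join(select(truth, "read_id", "source_id"), by = "read_id") |>
      distinct(ref_id = .data$source_id) |>
      mutate(aln_len = 100L)
    readr::write_tsv(detection_rate(det_hits, uco), ox("detection.tsv"))
  })

  mf <- bind_rows(manifest)
  jsonlite::write_json(mf, file.path(out_dir, "manifest.json"))
  mf
}
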