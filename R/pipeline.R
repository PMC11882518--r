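PIPELINE_PATH_KEYS <- c(
  "counts_small_rna", "counts_rna", "library_meta", "mirna_fasta",
  "utr_fasta", "de_vs_ba1", "de_vs_ba2", "go_terms", "go_annotation"
)

#' Configuration for the end-to-end candidate-ranking pipeline
#'
#' Bundles the input paths and all stage configurations in one validated
#' object, so the study-calibrated thresholds live in a single place. Use
#' [read_pipeline_config()] to load the same structure from a YAML file.
#'
#' @param counts_small_rna,counts_rna,library_meta,mirna_fasta,utr_fasta,de_vs_ba1,de_vs_ba2,go_terms,go_annotation
#'   Input file paths (see [simulate_dataset()] for the expected formats).
#' @param out_dir Directory for stage outputs and the manifest.
#' @param expression An [expression_config()].
#' @param prediction A [prediction_config()].
#' @param gene_set A [gene_set_config()].
#' @param enrichment_universe `"interaction"` or `"gene"`
#'   (see [mirna_set_enrichment()]).
#' @return A list of class `mirarch_pipeline_config`.
#' @export
pipeline_config <- function(counts_small_rna, counts_rna, library_meta,
                            mirna_fasta, utr_fasta, de_vs_ba1, de_vs_ba2,
                            go_terms, go_annotation, out_dir,
                            expression = expression_config(),
                            prediction = prediction_config(),
                            gene_set = gene_set_config(),
                            enrichment_universe = "interaction") {
  stopifnot(
    inherits(expression, "mirarch_expression_config"),
    inherits(prediction, "mirarch_prediction_config"),
    inherits(gene_set, "mirarch_gene_set_config"),
    enrichment_universe %in% c("interaction", "gene")
  )
  structure(
    list(
      counts_small_rna = counts_small_rna, counts_rna = counts_rna,
      library_meta = library_meta, mirna_fasta = mirna_fasta,
      utr_fasta = utr_fasta, de_vs_ba1 = de_vs_ba1, de_vs_ba2 = de_vs_ba2,
      go_terms = go_terms, go_annotation = go_annotation, out_dir = out_dir,
      expression = expression, prediction = prediction, gene_set = gene_set,
      enrichment_universe = enrichment_universe
    ),
    class = "mirarch_pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose top-level keys are the
#'   `pipeline_config()` arguments; the nested `expression`, `prediction`
#'   and `gene_set` maps override the corresponding configuration defaults.
#'   Unknown keys, at either level, are rejected before any stage runs.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c(PIPELINE_PATH_KEYS, "out_dir", "expression", "prediction",
             "gene_set", "enrichment_universe")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown pipeline config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  build <- function(key, ctor) {
    args <- raw[[key]]
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad) > 0) {
      abort(sprintf("Unknown key(s) in '%s' config: %s", key,
                    paste(bad, collapse = ", ")))
    }
    do.call(ctor, args)
  }
  args <- raw[intersect(names(raw), c(PIPELINE_PATH_KEYS, "out_dir",
                                      "enrichment_universe"))]
  args$expression <- build("expression", expression_config)
  args$prediction <- build("prediction", prediction_config)
  args$gene_set <- build("gene_set", gene_set_config)
  do.call(pipeline_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the candidate-ranking pipeline end to end
#'
#' Stages run in order: expression filtering (CPM thresholds on small RNA
#' and RNA counts), target prediction (seed scan, energy and site-count
#' filters), domain gene-set construction (DE and annotation-term rules),
#' and hypergeometric enrichment ranking. All stage outputs are written
#' under `config$out_dir` together with a provenance manifest (package
#' version, configuration, input and output checksums); a rerun on
#' identical inputs is bit-identical. Any stage failure aborts with a
#' stage-named error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `mirarch_pipeline` with the stage
#'   results (`expressed_mirnas`, `expressed_genes`, `sites`,
#'   `interactions`, `gene_set`, `enrichment`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mirarch_pipeline_config"))
  inputs <- unlist(config[PIPELINE_PATH_KEYS])
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    abort(sprintf("Missing input file(s): %s", paste(missing, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  expression <- run_stage("expression", {
    sm <- read_counts(config$counts_small_rna)
    rna <- read_counts(config$counts_rna)
    expressed_mirnas <- expressed_genes(sm, config$expression, "small_rna")
    expressed <- expressed_genes(rna, config$expression, "rna")
    writeLines(expressed_mirnas, out("expressed_mirnas.txt"))
    writeLines(expressed, out("expressed_genes.txt"))
    write_tsv_table(
      matrix_to_tibble(spearman_matrix(cpm(sm))),
      out("spearman_small_rna.tsv")
    )
    list(mirnas = expressed_mirnas, genes = expressed)
  })

  targets <- run_stage("targets", {
    mirnas <- read_rna_fasta(config$mirna_fasta)
    mirnas <- mirnas[mirnas$id %in% expression$mirnas, , drop = FALSE]
    utrs <- read_rna_fasta(config$utr_fasta)
    names(utrs)[names(utrs) == "id"] <- "gene_id"
    utrs <- utrs[utrs$gene_id %in% expression$genes, , drop = FALSE]
    sites <- scan_targets(mirnas, utrs, energy = TRUE, config = config$prediction)
    interactions <- filter_interactions(sites, config$prediction)
    write_tsv_table(sites, out("sites.tsv"))
    write_tsv_table(interactions, out("interactions.tsv"))
    list(sites = sites, interactions = interactions)
  })

  gene_set <- run_stage("gene_set", {
    gs <- build_domain_gene_set(
      read_de_table(config$de_vs_ba1),
      read_de_table(config$de_vs_ba2),
      read_tsv_table(config$go_terms, c("term_id", "fold_enrichment", "fdr")),
      read_tsv_table(config$go_annotation, c("gene_id", "term_id")),
      config$gene_set
    )
    writeLines(gs, out("gene_set.txt"))
    gs
  })

  enrichment <- run_stage("enrichment", {
    enr <- mirna_set_enrichment(targets$interactions, gene_set,
                                universe = config$enrichment_universe)
    write_tsv_table(enr, out("enrichment.tsv"))
    enr
  })

  run_stage("manifest", {
    output_files <- c("expressed_mirnas.txt", "expressed_genes.txt",
                      "spearman_small_rna.tsv", "sites.tsv",
                      "interactions.tsv", "gene_set.txt", "enrichment.tsv")
    manifest <- list(
      tool = "mirarch",
      version = as.character(utils::packageVersion("mirarch")),
      config = config_for_manifest(config),
      input_md5 = as.list(stats::setNames(
        unname(tools::md5sum(inputs)), basename(inputs))),
      output_md5 = as.list(stats::setNames(
        unname(tools::md5sum(vapply(output_files, out, character(1)))),
        output_files))
    )
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(structure(
    list(
      expressed_mirnas = expression$mirnas,
      expressed_genes = expression$genes,
      sites = targets$sites,
      interactions = targets$interactions,
      gene_set = gene_set,
      enrichment = enrichment,
      out_dir = config$out_dir
    ),
    class = "mirarch_pipeline"
  ))
}

# Flatten the configuration for the manifest: stage thresholds only (input
# identity is captured by content checksums, not paths, so a rerun of the
# same inputs and thresholds yields a bit-identical manifest wherever it
# runs). The energy parameter matrix is summarised by checksum.
config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg <- cfg[setdiff(names(cfg), c(PIPELINE_PATH_KEYS, "out_dir"))]
  cfg$expression <- unclass(cfg$expression)
  cfg$gene_set <- unclass(cfg$gene_set)
  pred <- unclass(cfg$prediction)
  pred$energy_params <- sprintf(
    "stack_md5:%s;init:%.2f;terminal_au:%.2f",
    substr(rlang::hash(pred$energy_params$stack), 1, 12),
    pred$energy_params$init, pred$energy_params$terminal_au
  )
  cfg$prediction <- pred
  cfg
}
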