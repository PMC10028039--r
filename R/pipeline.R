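# End-to-end screen orchestration: differential expression -> bottom-percentile
# downregulation -> compound exclusivity -> pathway enrichment -> intragenic
# binding sites -> survival, with a machine-readable stage trace.

.cfg_get <- function(config, name, default = NULL) {
  if (!is.null(config[[name]])) config[[name]] else default
}

.check_files <- function(paths) {
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("missing input file for '", nm, "': ", p)
  }
}

#' Run the full polyamide candidate screen
#'
#' Executes the filter chain on the inputs named by `config`:
#' per-compound differential expression versus control, selection of
#' significant bottom-percentile downregulated genes, compound-exclusivity
#' (Venn) selection, hypergeometric pathway enrichment with top-k gene
#' union, intragenic binding-site filtering against a genome scan, and
#' (when a survival cohort is supplied) the directional survival filter.
#' Stage outputs, a BED of binding sites, the final candidate list and a
#' JSON trace are written to `out_dir`.
#'
#' @param config a named list or the path to a YAML file with entries:
#'   `expression`, `samples` (TSVs), `gmt`, `genome` (FASTA),
#'   `annotation` (BED6/GFF3), optional `survival` (TSV), optional
#'   `registry` (TSV; default the bundled compound registry), `control`
#'   (default `"DMSO"`), `include_compounds`, `exclude_compounds`,
#'   `out_dir`, and optional threshold overrides `p_threshold`,
#'   `percentile`, `top_k_pathways`, `survival_alpha`, `de_method`,
#'   `exclusive_mode`.
#' @return A `pipeline_trace` object (invisibly written as
#'   `trace.json`): ordered stage records with input/output counts and
#'   parameters, per-stage gene lists, the configuration snapshot and the
#'   package version.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- .cfg_get(config, "out_dir", tempfile("screen_"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  registry_path <- .cfg_get(config, "registry",
                            system.file("extdata", "compounds.tsv",
                                        package = "piscreen"))
  .check_files(list(expression = config$expression,
                    samples = config$samples,
                    gmt = config$gmt, genome = config$genome,
                    annotation = config$annotation,
                    survival = config$survival,
                    registry = registry_path))
  control <- .cfg_get(config, "control", "DMSO")
  cfg <- screen_config(
    p_threshold = .cfg_get(config, "p_threshold", 1e-4),
    percentile = .cfg_get(config, "percentile", 0.20),
    include_compounds = unlist(.cfg_get(config, "include_compounds")),
    exclude_compounds = unlist(.cfg_get(config, "exclude_compounds",
                                        character(0))),
    top_k_pathways = .cfg_get(config, "top_k_pathways", 10L),
    survival_alpha = .cfg_get(config, "survival_alpha", 0.05),
    de_method = .cfg_get(config, "de_method", "moderated"),
    exclusive_mode = .cfg_get(config, "exclusive_mode", "union"))

  mat <- read_expression_matrix(config$expression, config$samples,
                                control = control)
  universe <- rownames(mat$values)
  registry <- load_compound_registry(registry_path)
  compounds <- compound_labels(mat)
  gmt <- read_gmt(config$gmt)
  if (!length(intersect(unique(unlist(gmt$sets)), universe)))
    stop("inconsistent gene namespaces: GMT members (e.g. ",
         paste(utils::head(unique(unlist(gmt$sets)), 3), collapse = ", "),
         ") share no identifiers with the expression matrix (e.g. ",
         paste(utils::head(universe, 3), collapse = ", "), ")")
  genes <- read_genes(config$annotation)
  if (!length(intersect(genes$gene_id, universe)))
    stop("inconsistent gene namespaces: annotation gene_ids (e.g. ",
         paste(utils::head(genes$gene_id, 3), collapse = ", "),
         ") share no identifiers with the expression matrix (e.g. ",
         paste(utils::head(universe, 3), collapse = ", "), ")")

  trace <- list(stages = list(), gene_lists = list(),
                config = c(config[!vapply(config, is.null, logical(1))],
                           list(resolved_thresholds = unclass(cfg))),
                version = as.character(utils::packageVersion("piscreen")))
  stage <- function(name, n_in, n_out, params = list(), genes = NULL) {
    trace$stages[[length(trace$stages) + 1L]] <<-
      list(stage = name, n_in = n_in, n_out = n_out, params = params)
    if (!is.null(genes)) trace$gene_lists[[name]] <<- genes
    message(sprintf("[piscreen] %-24s %6d -> %d", name, n_in, n_out))
  }

  down_sets <- list()
  for (cn in compounds) {
    de <- differential_expression(mat, cn, method = cfg$de_method)
    down <- downregulated_candidates(de, cfg)
    boundary <- stats::quantile(de$log2FC[de$log2FC < 0],
                                probs = cfg$percentile, type = 7,
                                names = FALSE)
    de$down <- de$log2FC < 0
    de$significant <- de$p < cfg$p_threshold
    de$bottom_percentile <- de$down & de$log2FC <= boundary
    de$selected <- de$gene %in% down
    utils::write.table(de, file.path(out_dir, paste0("de_", cn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    down_sets[[cn]] <- down
    stage(paste0("downregulated_", cn), nrow(de), length(down),
          list(p_threshold = cfg$p_threshold, percentile = cfg$percentile,
               de_method = cfg$de_method), genes = down)
  }

  exclusive <- select_exclusive(down_sets, cfg)
  stage("exclusivity", length(unique(unlist(down_sets))), length(exclusive),
        list(include = cfg$include_compounds,
             exclude = cfg$exclude_compounds, mode = cfg$exclusive_mode),
        genes = exclusive)

  enr <- hypergeometric_enrichment(exclusive, gmt$sets, universe)
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pathway_genes <- top_pathway_gene_union(enr, gmt$sets, exclusive,
                                          cfg$top_k_pathways)
  stage("pathway", length(exclusive), length(pathway_genes),
        list(top_k = cfg$top_k_pathways), genes = pathway_genes)

  inc_motifs <- registry[intersect(cfg$include_compounds, names(registry))]
  if (!length(inc_motifs))
    stop("no registry motifs for include_compounds: ",
         paste(cfg$include_compounds, collapse = ", "))
  sites <- do.call(rbind, lapply(names(inc_motifs), function(nm)
    scan_fasta(config$genome, inc_motifs[[nm]], name = nm)))
  write_sites_bed(sites, file.path(out_dir, "sites.bed"))
  counts <- annotate_sites(sites, genes)
  utils::write.table(
    data.frame(gene_id = names(counts), sites = unname(counts)),
    file.path(out_dir, "site_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  bound <- binding_site_filter(pathway_genes, counts)
  stage("binding_sites", length(pathway_genes), length(bound),
        list(motifs = vapply(inc_motifs, function(m) m$iupac, character(1))),
        genes = bound)

  if (!is.null(config$survival)) {
    cohort <- read_survival_cohort(config$survival)
    final <- survival_filter(bound, cohort, alpha = cfg$survival_alpha)
    stage("survival", length(bound), length(final),
          list(alpha = cfg$survival_alpha, dichotomize = "median"),
          genes = final)
  } else {
    final <- bound
    trace$stages[[length(trace$stages) + 1L]] <-
      list(stage = "survival", n_in = length(bound), n_out = length(bound),
           params = list(skipped = TRUE))
    message("[piscreen] survival                 skipped")
  }

  writeLines(final, file.path(out_dir, "final_candidates.txt"))
  for (nm in names(trace$gene_lists))
    writeLines(trace$gene_lists[[nm]],
               file.path(out_dir, paste0("genes_", nm, ".txt")))
  trace$final_candidates <- final
  trace$out_dir <- out_dir
  class(trace) <- "pipeline_trace"
  write_trace(trace, file.path(out_dir, "trace.json"))
  trace
}

#' @export
print.pipeline_trace <- function(x, ...) {
  cat("<pipeline_trace> piscreen", x$version, "\n")
  for (s in x$stages)
    cat(sprintf("  %-24s %6d -> %d%s\n", s$stage, s$n_in, s$n_out,
                if (isTRUE(s$params$skipped)) "  (skipped)" else ""))
  cat("final candidates:", paste(x$final_candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a pipeline trace to JSON
#'
#' @param trace a `pipeline_trace`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  jsonlite::write_json(unclass(trace), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a pipeline trace from JSON
#'
#' @param path JSON path written by [write_trace()].
#' @return A `pipeline_trace` object.
#' @export
read_trace <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  x$final_candidates <- as.character(unlist(x$final_candidates))
  x$gene_lists <- lapply(x$gene_lists, function(g) as.character(unlist(g)))
  class(x) <- "pipeline_trace"
  x
}

#' Stage counts of a pipeline trace
#'
#' @param trace a `pipeline_trace`.
#' @return Named integer vector of output counts per stage.
#' @export
stage_counts <- function(trace) {
  stats::setNames(vapply(trace$stages, function(s) as.integer(s$n_out),
                         integer(1)),
                  vapply(trace$stages, `[[`, character(1), "stage"))
}

#' Scan a genome for compound binding sites (subcommand core)
#'
#' @param config list (or YAML path) with `genome` (FASTA), and either
#'   `motifs` (named IUPAC strings) or `registry`/`compounds`; optional
#'   `out_dir`.
#' @return List with `sites` (data frame) and `counts` per motif name;
#'   writes `sites.bed` and `site_counts_total.tsv` when `out_dir` given.
#' @export
run_scan <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .check_files(list(genome = config$genome))
  motifs <- config$motifs
  if (is.null(motifs)) {
    reg <- load_compound_registry(
      .cfg_get(config, "registry",
               system.file("extdata", "compounds.tsv", package = "piscreen")))
    keep <- .cfg_get(config, "compounds", names(reg))
    motifs <- lapply(reg[keep], function(m) m$iupac)
  }
  sites <- do.call(rbind, lapply(names(motifs), function(nm)
    scan_fasta(config$genome, motifs[[nm]], name = nm)))
  counts <- table(factor(sites$name, levels = names(motifs)))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sites_bed(sites, file.path(out_dir, "sites.bed"))
    utils::write.table(as.data.frame(counts),
                       file.path(out_dir, "site_counts_total.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = c("motif", "sites"))
  }
  list(sites = sites, counts = stats::setNames(as.integer(counts),
                                               names(motifs)))
}

#' Fit dose-response plates (subcommand core)
#'
#' @param config list (or YAML path) with `plate` (CSV path), optional
#'   `condition` filter and `out_dir`.
#' @return The [fit_4pl()] result; written as `fit.json` when `out_dir`
#'   is given.
#' @export
run_dose <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .check_files(list(plate = config$plate))
  plate <- read_plate_csv(config$plate, condition = config$condition)
  fit <- fit_4pl(plate)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(fit), file.path(config$out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  fit
}
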