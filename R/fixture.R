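# Bundled seeded end-to-end fixture: a complete synthetic study in which
# exactly three planted genes survive the whole filter chain.

#' Generate the bundled end-to-end screen fixture
#'
#' Writes, under `dir`, every input [run_screen()] needs: a 200-gene
#' expression matrix (three compounds + DMSO control, 3 replicates,
#' planted log2 effect -2 at noise sd 0.05), a 12-set GMT, a synthetic
#' chromosome with binding sites of the two included compounds planted in
#' five candidate genes (background scrubbed of chance matches), the gene
#' annotation BED, a 150-patient survival cohort in which three of those
#' five genes carry hazard ratio 3.5 (high expression = worse survival)
#' and two are protective (HR 0.3), and a ready-to-run YAML config.
#'
#' The construction narrows 18 exclusivity candidates to 16 pathway genes,
#' 5 genes with intragenic sites, and finally the 3 hazard genes, so the
#' expected final candidate set is exactly `truth$final`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the default is the fixture's recorded seed and
#'   reproduces it byte-identically.
#' @return List with `config` (YAML path), `paths` of all written files and
#'   `truth` (expected gene sets per stage).
#' @export
gen_screen_fixture <- function(dir = tempfile("fixture_"),
                               seed = 20220943L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- .gene_ids(200L)

  planted <- list("KR12" = g[1:12],          # G0011/G0012 shared with CCC-002
                  "CCC-002" = g[11:25],
                  "CCC-003" = c(g[13:20], g[26:30]))
  expr <- gen_expression(seed, n_genes = 200L, reps = 3L,
                         planted = planted, effect = -2.0, sigma = 0.05)
  mat_tsv <- file.path(dir, "expression.tsv")
  ss_tsv <- file.path(dir, "samples.tsv")
  write_expression_matrix(expr$matrix, mat_tsv, ss_tsv)

  sets <- list(
    P01 = g[c(13, 14, 15)], P02 = g[c(16, 17)], P03 = g[c(18, 19, 20)],
    P04 = g[c(21, 22)], P05 = g[c(23, 24)], P06 = g[c(25, 26)],
    P07 = g[c(27, 101, 102)], P08 = g[c(28, 103, 104, 105)],
    P09 = g[c(21, 23, 25)], P10 = g[c(14, 18, 22, 106)],
    P11 = g[c(29, 30, 110:130)], P12 = g[150:160])
  gmt_path <- file.path(dir, "pathways.gmt")
  write_gmt(sets, gmt_path)

  # 18 candidate gene bodies of 300 bp spaced 100 bp apart on one contig
  cand <- g[13:30]
  starts <- 100L + (seq_along(cand) - 1L) * 400L
  genes <- data.frame(gene_id = cand, seq_id = "chr1", start = starts,
                      end = starts + 300L, strand = "+",
                      stringsAsFactors = FALSE)
  reg <- load_compound_registry()
  m002 <- reg[["CCC-002"]]$iupac
  m003 <- reg[["CCC-003"]]$iupac
  plant_at <- data.frame(
    seq_id = "chr1",
    start = starts[match(g[c(13, 15, 17, 14, 16)], cand)] + 120L,
    motif = c(m002, m002, m002, m003, m003),
    orientation = c("+", "-", "+", "+", "-"),
    stringsAsFactors = FALSE)
  genome <- gen_genome(seed, n_records = 1L,
                       length = max(genes$end) + 100L,
                       plant_at = plant_at, scrub_unplanted = TRUE)
  fasta <- file.path(dir, "genome.fa")
  write_fasta(genome$sequences, fasta)
  bed <- file.path(dir, "genes.bed")
  write_genes_bed(genes, bed)
  truth_bed <- file.path(dir, "truth_sites.bed")
  write_sites_bed(genome$truth, truth_bed)

  hr <- stats::setNames(c(3.5, 3.5, 3.5, 0.3, 0.3), g[13:17])
  surv <- gen_survival(seed + 1L, n_patients = 150L, genes = cand, hr = hr)
  surv_tsv <- file.path(dir, "survival.tsv")
  write_survival_cohort(surv$cohort, surv_tsv)

  config <- list(expression = mat_tsv, samples = ss_tsv,
                 gmt = gmt_path, genome = fasta, annotation = bed,
                 survival = surv_tsv, control = "DMSO",
                 include_compounds = c("CCC-002", "CCC-003"),
                 exclude_compounds = "KR12",
                 out_dir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)

  list(config = cfg_path,
       paths = list(expression = mat_tsv, samples = ss_tsv, gmt = gmt_path,
                    genome = fasta, annotation = bed, survival = surv_tsv,
                    truth_sites = truth_bed),
       truth = list(planted = planted,
                    exclusivity = g[13:30],
                    pathway = g[13:28],
                    binding = g[13:17],
                    final = g[13:15],
                    seed = seed))
}
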