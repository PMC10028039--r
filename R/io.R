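# Readers and writers for the plain-text formats the pipeline consumes:
# expression TSV + sample sheet, GMT gene sets, BED6 / minimal GFF3 gene
# intervals, BED6 site output, survival TSV, dose plate CSV.

#' Read a log2 expression matrix with its sample sheet
#'
#' @param matrix_tsv TSV: first column gene identifiers, remaining columns
#'   one per sample (header row of sample ids).
#' @param samples_tsv TSV with columns `sample`, `condition`.
#' @param control condition label of the vehicle control.
#' @return An `expression_matrix`: list with `values` (genes x samples
#'   numeric matrix), `conditions` (named by sample), `control`.
#' @export
read_expression_matrix <- function(matrix_tsv, samples_tsv,
                                   control = "DMSO") {
  tab <- utils::read.delim(matrix_tsv, check.names = FALSE,
                           stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  ss <- utils::read.delim(samples_tsv, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(ss)))
    stop("sample sheet needs columns: sample, condition")
  cond <- stats::setNames(ss$condition, ss$sample)
  expression_matrix(vals, cond, control = control)
}

#' Write an expression matrix and sample sheet
#'
#' @param mat an [expression_matrix()].
#' @param matrix_tsv,samples_tsv output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_matrix <- function(mat, matrix_tsv, samples_tsv) {
  df <- data.frame(gene = rownames(mat$values), mat$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ss <- data.frame(sample = names(mat$conditions),
                   condition = unname(mat$conditions))
  utils::write.table(ss, samples_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_tsv, samples_tsv))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description,
#' members.
#'
#' @param path GMT file.
#' @return List with `sets` (named list of character vectors) and
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed GMT line(s): ", paste(bad, collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate set_id in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- ids
  desc <- stats::setNames(vapply(parts, `[[`, character(1), 2L), ids)
  list(sets = sets, descriptions = desc)
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (default `"na"`).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write motif sites as BED6
#'
#' `name` = compound/motif label, `score` = 0, `strand` = orientation.
#' Coordinates are the native 0-based half-open site coordinates.
#'
#' @param sites site `data.frame` (needs a `name` column, e.g. from
#'   [scan_fasta()]).
#' @param path output BED file.
#' @return Invisibly, `path`.
#' @export
write_sites_bed <- function(sites, path) {
  nm <- if ("name" %in% names(sites)) sites$name else rep("site", nrow(sites))
  bed <- data.frame(sites$seq_id, sites$start, sites$end, nm, 0L,
                    sites$orientation)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene intervals from BED6 or minimal GFF3
#'
#' BED input is taken as-is (0-based half-open, name column = gene id).
#' GFF3 input keeps `gene`-type features only and converts the 1-based
#' closed coordinates to 0-based half-open; the gene id is taken from the
#' `ID=` or `gene_id=` attribute.
#'
#' @param path annotation file; format inferred from the extension
#'   (`.gff`/`.gff3` vs BED otherwise) unless `format` is given.
#' @param format `"bed"`, `"gff3"` or `NULL` (infer).
#' @return `data.frame` with `gene_id`, `seq_id`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "bed"
  if (format == "bed") {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(tab) < 4L) stop("BED gene annotation needs >= 4 columns")
    out <- data.frame(gene_id = as.character(tab[[4]]),
                      seq_id = as.character(tab[[1]]),
                      start = as.integer(tab[[2]]),
                      end = as.integer(tab[[3]]),
                      strand = if (ncol(tab) >= 6) as.character(tab[[6]])
                               else ".",
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(tab) < 9L) stop("GFF3 needs 9 columns")
    tab <- tab[tab[[3]] == "gene", , drop = FALSE]
    id <- sub(".*(?:^|;)\\s*(?:ID|gene_id)=([^;]+).*", "\\1", tab[[9]],
              perl = TRUE)
    out <- data.frame(gene_id = id, seq_id = as.character(tab[[1]]),
                      start = as.integer(tab[[4]]) - 1L,
                      end = as.integer(tab[[5]]),
                      strand = as.character(tab[[7]]),
                      stringsAsFactors = FALSE)
  }
  if (any(out$start >= out$end)) stop("gene interval with start >= end")
  if (anyDuplicated(out$gene_id)) stop("duplicate gene_id in annotation")
  out
}

#' Write gene intervals as BED6
#'
#' @param genes `data.frame` as returned by [read_genes()].
#' @param path output BED file.
#' @return Invisibly, `path`.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- data.frame(genes$seq_id, genes$start, genes$end, genes$gene_id, 0L,
                    if ("strand" %in% names(genes)) genes$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output FASTA.
#' @param width line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a survival cohort TSV
#'
#' Columns: `patient`, `time`, `event`, then one numeric column per gene.
#'
#' @param path TSV file.
#' @return A `survival_cohort`: list with `patients`, `time`, `event` and
#'   `expr` (patients x genes matrix).
#' @export
read_survival_cohort <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("patient", "time", "event")
  if (!all(need %in% names(tab)))
    stop("survival TSV needs columns: ", paste(need, collapse = ", "))
  expr <- as.matrix(tab[, setdiff(names(tab), need), drop = FALSE])
  rownames(expr) <- tab$patient
  survival_cohort(tab$patient, tab$time, tab$event, expr)
}

#' Write a survival cohort TSV
#'
#' @param cohort a [survival_cohort()].
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
write_survival_cohort <- function(cohort, path) {
  df <- data.frame(patient = cohort$patients, time = cohort$time,
                   event = cohort$event, cohort$expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dose plate CSV
#'
#' Columns: `dose`, `response`; optional `replicate`, `condition`.
#'
#' @param path CSV file.
#' @param condition optional filter on the `condition` column.
#' @return `data.frame` with at least `dose` and `response`.
#' @export
read_plate_csv <- function(path, condition = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("dose", "response") %in% names(tab)))
    stop("plate CSV needs columns: dose, response")
  if (!is.null(condition)) {
    if (!"condition" %in% names(tab)) stop("no condition column to filter on")
    tab <- tab[tab$condition == condition, , drop = FALSE]
  }
  tab
}

#' Write a dose plate CSV
#'
#' @param plate `data.frame` with `dose`, `response` (and optionally
#'   `replicate`, `condition`).
#' @param path output CSV.
#' @return Invisibly, `path`.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
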