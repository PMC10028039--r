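# Per-compound differential expression versus control and the
# candidate-selection filters of the screen: significance + bottom-percentile
# downregulation, and compound-exclusivity (Venn) selection.

#' Construct an expression matrix object
#'
#' @param values genes x samples numeric matrix of log2 intensities, with
#'   row and column names.
#' @param conditions named character vector, sample -> condition label.
#' @param control condition label of the control (e.g. `"DMSO"`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, conditions, control = "DMSO") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene identifiers must be present and unique")
  if (is.null(colnames(values))) stop("sample identifiers must be present")
  missing <- setdiff(colnames(values), names(conditions))
  if (length(missing))
    stop("samples without condition labels: ", paste(missing, collapse = ", "))
  conditions <- conditions[colnames(values)]
  if (!control %in% conditions)
    stop("control condition '", control, "' has no samples")
  structure(list(values = values, conditions = conditions,
                 control = control),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  print(table(x$conditions))
  invisible(x)
}

#' Compounds present in an expression matrix
#'
#' @param mat an [expression_matrix()].
#' @return Condition labels other than the control.
#' @export
compound_labels <- function(mat) {
  setdiff(unique(unname(mat$conditions)), mat$control)
}

.group_values <- function(mat, condition) {
  mat$values[, names(mat$conditions)[mat$conditions == condition],
             drop = FALSE]
}

# vectorised two-sample t statistics per gene; deterministic zero-variance
# convention: p = 1 when the mean difference is 0, p = 0 otherwise (a
# noiseless difference is unambiguous evidence)
.t_rows <- function(a, b, pooled = FALSE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  d <- m1 - m2
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- ifelse(se2 > 0,
              2 * stats::pt(-abs(d) / sqrt(se2), df),
              ifelse(d == 0, 1, 0))
  list(diff = d, p = as.numeric(p))
}

.moderated_p <- function(a, b) {
  # limma empirical-Bayes moderated t for the two-group comparison;
  # falls back to the deterministic zero-variance rule if the residual
  # variances are degenerate (e.g. exactly noiseless synthetic data)
  x <- cbind(a, b)
  grp <- factor(rep(c("A", "B"), c(ncol(a), ncol(b))), levels = c("B", "A"))
  design <- stats::model.matrix(~grp)
  fit <- limma::lmFit(x, design)
  p <- tryCatch({
    eb <- limma::eBayes(fit)
    pv <- eb$p.value[, "grpA"]
    if (anyNA(pv)) stop("degenerate variances")
    pv
  }, error = function(e) {
    d <- rowMeans(a) - rowMeans(b)
    ifelse(abs(d) > 0, 0, 1)
  })
  as.numeric(p)
}

#' Differential expression of one compound versus control
#'
#' Per gene, the log2 fold change is the mean log2 intensity difference
#' (compound minus control). P-values come from a moderated t statistic by
#' default: per-gene variances are shrunk toward a pooled prior estimated
#' across all genes (empirical Bayes), the standard treatment for
#' few-replicate microarray designs. Plain Welch and pooled-variance
#' two-sample t tests are available via `method`.
#'
#' @param mat an [expression_matrix()].
#' @param compound condition label to compare against the control.
#' @param method `"moderated"` (default), `"welch"` or `"pooled"`.
#' @return `data.frame` with columns `gene`, `compound`, `log2FC`, `p`.
#' @export
differential_expression <- function(mat, compound,
                                    method = c("moderated", "welch",
                                               "pooled")) {
  stopifnot(inherits(mat, "expression_matrix"))
  method <- match.arg(method)
  if (!compound %in% mat$conditions)
    stop("no samples for compound '", compound, "'")
  a <- .group_values(mat, compound)
  b <- .group_values(mat, mat$control)
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("need >= 2 replicates per condition for testing; ",
         "use descriptive-only summaries (group means) for n = 1 designs")
  res <- switch(method,
    welch = .t_rows(a, b, pooled = FALSE),
    pooled = .t_rows(a, b, pooled = TRUE),
    moderated = list(diff = rowMeans(a) - rowMeans(b),
                     p = .moderated_p(a, b)))
  data.frame(gene = rownames(mat$values),
             compound = rep(compound, nrow(mat$values)),
             log2FC = unname(res$diff),
             p = unname(res$p),
             stringsAsFactors = FALSE)
}

#' Screen configuration
#'
#' Holds the thresholds of the candidate screen. Defaults follow the
#' screening procedure: significance cut p < 1e-4, bottom 20-percentile of
#' downregulated genes, top 10 enriched pathways, survival level 0.05.
#'
#' @param p_threshold raw p-value significance level.
#' @param percentile lower-tail fraction of downregulated genes kept.
#' @param include_compounds,exclude_compounds labels for exclusivity
#'   selection.
#' @param top_k_pathways number of best-ranked pathways whose members are
#'   retained.
#' @param survival_alpha level of the survival filter.
#' @param de_method differential-expression statistic, see
#'   [differential_expression()].
#' @param exclusive_mode `"union"` (genes hit by any included compound) or
#'   `"intersection"` (genes hit by all of them), both minus the excluded
#'   compounds' genes.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(p_threshold = 1e-4, percentile = 0.20,
                          include_compounds = character(0),
                          exclude_compounds = character(0),
                          top_k_pathways = 10L, survival_alpha = 0.05,
                          de_method = "moderated",
                          exclusive_mode = c("union", "intersection")) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            percentile > 0, percentile <= 1,
            top_k_pathways >= 1, survival_alpha > 0, survival_alpha < 1)
  if (length(intersect(include_compounds, exclude_compounds)))
    stop("include and exclude compound lists overlap")
  structure(list(p_threshold = p_threshold, percentile = percentile,
                 include_compounds = include_compounds,
                 exclude_compounds = exclude_compounds,
                 top_k_pathways = as.integer(top_k_pathways),
                 survival_alpha = survival_alpha,
                 de_method = de_method,
                 exclusive_mode = match.arg(exclusive_mode)),
            class = "screen_config")
}

#' Select significantly downregulated bottom-percentile candidates
#'
#' Keeps genes with `log2FC < 0`, `p < p_threshold`, and `log2FC` at or
#' below the `percentile` quantile of the log2 fold changes among the
#' downregulated genes (linear-interpolation quantile; boundary ties kept).
#' The percentile population is the downregulated set, not all genes.
#'
#' @param res result of [differential_expression()] for one compound.
#' @param cfg a [screen_config()].
#' @return Sorted character vector of gene identifiers.
#' @export
downregulated_candidates <- function(res, cfg = screen_config()) {
  stopifnot(all(c("gene", "log2FC", "p") %in% names(res)))
  down <- res$log2FC < 0
  if (!any(down)) {
    warning("no downregulated genes")
    return(character(0))
  }
  boundary <- stats::quantile(res$log2FC[down], probs = cfg$percentile,
                              type = 7, names = FALSE)
  keep <- down & res$p < cfg$p_threshold & res$log2FC <= boundary
  sort(res$gene[keep])
}

#' Full Venn partition of compound gene sets
#'
#' @param sets named list (>= 2 entries) of gene character vectors.
#' @return Named list of the `2^k - 1` pairwise-disjoint regions whose
#'   union is the union of the inputs; region names join member compounds
#'   with `&`.
#' @export
exclusivity_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  genes <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) genes %in% s,
                 logical(length(genes)))
  if (length(genes) == 1L) memb <- matrix(memb, nrow = 1L,
                                          dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(combos))) {
    mask <- unlist(combos[i, ])
    label <- paste(names(sets)[mask], collapse = "&")
    if (length(genes)) {
      hit <- apply(memb, 1, function(r) all(r == mask))
      out[[label]] <- genes[hit]
    } else out[[label]] <- character(0)
  }
  out
}

#' Exclusivity (Venn) selection of candidate genes
#'
#' Genes downregulated by the included compounds but by none of the
#' excluded ones. Default semantics: union of the included sets minus the
#' union of the excluded sets; `mode = "intersection"` instead requires
#' membership in every included set.
#'
#' @param sets named list of per-compound gene sets.
#' @param cfg a [screen_config()] naming `include_compounds` and
#'   `exclude_compounds` (keys of `sets`).
#' @return Sorted character vector of selected genes.
#' @export
select_exclusive <- function(sets, cfg) {
  inc <- cfg$include_compounds
  exc <- cfg$exclude_compounds
  unknown <- setdiff(c(inc, exc), names(sets))
  if (length(unknown))
    stop("unknown compound label(s): ", paste(unknown, collapse = ", "))
  if (!length(inc)) stop("include_compounds is empty")
  base <- switch(cfg$exclusive_mode,
                 union = Reduce(union, sets[inc]),
                 intersection = Reduce(intersect, sets[inc]))
  drop <- if (length(exc)) Reduce(union, sets[exc]) else character(0)
  sort(setdiff(base, drop))
}

#' Collapse probe-level results to gene level
#'
#' Microarray matrices often carry several probes per gene. Following
#' standard practice, the probe with the smallest p-value represents the
#' gene; the returned rows are re-keyed by gene identifier.
#'
#' @param res probe-level [differential_expression()] results (the `gene`
#'   column holds probe identifiers).
#' @param probe_to_gene named character vector mapping probe -> gene;
#'   probes without a mapping are dropped.
#' @return Gene-level `data.frame` with the same columns, one row per gene.
#' @export
collapse_probes <- function(res, probe_to_gene) {
  gene <- probe_to_gene[res$gene]
  keep <- !is.na(gene)
  res <- res[keep, , drop = FALSE]
  gene <- gene[keep]
  o <- order(gene, res$p)
  res <- res[o, , drop = FALSE]
  gene <- gene[o]
  first <- !duplicated(gene)
  out <- res[first, , drop = FALSE]
  out$gene <- gene[first]
  rownames(out) <- NULL
  out
}
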