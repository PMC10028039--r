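# Post-screen narrowing filters: hypergeometric pathway enrichment,
# intragenic binding-site presence, and Kaplan-Meier survival association.

#' Hypergeometric gene-set enrichment
#'
#' For each set, the upper-tail probability of observing at least the
#' candidate overlap under hypergeometric sampling from the universe:
#' p = P(X >= k), X ~ Hypergeometric(N, K, n) with K the set size inside
#' the universe, n the candidate-list size and k the overlap.
#'
#' @param candidates character vector of candidate genes (must lie in
#'   `universe`).
#' @param sets named list of gene sets (each intersected with the universe
#'   before testing).
#' @param universe character vector, the tested gene universe.
#' @return `data.frame` with columns `set_id`, `k`, `K`, `n`, `N`, `p`,
#'   sorted by `p` ascending, ties broken by `set_id` (lexicographic).
#' @export
hypergeometric_enrichment <- function(candidates, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  out <- setdiff(candidates, universe)
  if (length(out))
    stop("candidates outside the universe, e.g.: ",
         paste(utils::head(out, 3), collapse = ", "))
  candidates <- unique(candidates)
  if (!length(candidates))
    warning("empty candidate list; all enrichment p-values are 1")
  N <- length(universe)
  n <- length(candidates)
  res <- do.call(rbind, lapply(names(sets), function(id) {
    s <- intersect(sets[[id]], universe)
    K <- length(s)
    k <- length(intersect(s, candidates))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res[order(res$p, res$set_id), , drop = FALSE]
}

#' Union of candidate genes in the top-ranked pathways
#'
#' @param results sorted output of [hypergeometric_enrichment()].
#' @param sets the gene-set list the enrichment was computed on.
#' @param candidates the candidate gene list.
#' @param k number of best-ranked sets to retain (saturates at the number
#'   of sets).
#' @return Sorted character vector: union over the k best sets of
#'   (set members intersected with candidates).
#' @export
top_pathway_gene_union <- function(results, sets, candidates, k) {
  if (k <= 0) stop("k must be positive")
  top <- utils::head(results$set_id, k)
  sort(unique(unlist(lapply(sets[top], intersect, y = candidates))))
}

#' Keep genes whose gene body contains a binding site
#'
#' @param genes character vector of gene identifiers.
#' @param site_counts named count vector (e.g. from [annotate_sites()]);
#'   genes absent from it count 0.
#' @return Sorted subset of `genes` with at least one intragenic site.
#' @export
binding_site_filter <- function(genes, site_counts) {
  counts <- site_counts[match(genes, names(site_counts))]
  counts[is.na(counts)] <- 0
  sort(genes[counts >= 1])
}

#' Two-group log-rank test
#'
#' The standard chi-square (1 df) log-rank statistic: at each distinct
#' event time, observed minus expected events in group A under the
#' hypergeometric model, with the usual tie-corrected variance term.
#'
#' @param time_a,event_a follow-up times and event indicators (1 = event,
#'   0 = censored) of group A.
#' @param time_b,event_b likewise for group B.
#' @return List with `statistic` (chi-square, 1 df), `p`, and the summed
#'   `observed`, `expected` (group A) and `variance`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b),
            length(time_a) > 0, length(time_b) > 0)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b) != 0
  grp <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  if (!any(event)) {
    warning("no events in either group")
    return(list(statistic = 0, p = 1, observed = 0, expected = 0,
                variance = 0))
  }
  times <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & grp)
    dj <- sum(event & time == t)
    d1j <- sum(event & time == t & grp)
    O <- O + d1j
    E <- E + dj * n1j / nj
    if (nj > 1)
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  if (V <= 0) {
    warning("zero log-rank variance")
    return(list(statistic = 0, p = 1, observed = O, expected = E,
                variance = V))
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E, variance = V)
}

#' Construct a survival cohort
#'
#' @param patients patient identifiers.
#' @param time follow-up times (> 0, any consistent unit).
#' @param event event indicators (1 = death/event, 0 = censored).
#' @param expr patients x genes numeric matrix of expression values.
#' @return An object of class `survival_cohort`.
#' @export
survival_cohort <- function(patients, time, event, expr) {
  expr <- as.matrix(expr)
  stopifnot(length(patients) == length(time),
            length(time) == length(event),
            nrow(expr) == length(patients))
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (anyNA(expr)) stop("missing expression values in cohort")
  structure(list(patients = as.character(patients), time = as.numeric(time),
                 event = as.integer(event), expr = expr),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat("<survival_cohort> ", length(x$patients), " patients, ",
      ncol(x$expr), " genes, ", sum(x$event), " events\n", sep = "")
  invisible(x)
}

# area under the Kaplan-Meier curve up to tau (restricted mean survival)
.km_area <- function(time, event, tau) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  t <- c(0, fit$time[fit$time <= tau], tau)
  s <- c(1, fit$surv[fit$time <= tau])
  sum(diff(t) * s)
}

#' Survival filter: keep genes whose high expression worsens survival
#'
#' Per gene, patients are dichotomized at the median expression (high =
#' above the median). A gene is kept iff the two-group log-rank p-value is
#' below `alpha` AND the high group has worse survival, judged by a smaller
#' Kaplan-Meier area up to the last follow-up time common to both groups.
#'
#' @param genes character vector of genes to test (must be columns of the
#'   cohort's expression matrix).
#' @param cohort a [survival_cohort()].
#' @param alpha significance level (default 0.05).
#' @return Sorted character vector of genes passing the filter.
#' @export
survival_filter <- function(genes, cohort, alpha = 0.05) {
  stopifnot(inherits(cohort, "survival_cohort"))
  missing <- setdiff(genes, colnames(cohort$expr))
  if (length(missing))
    stop("genes absent from cohort: ", paste(utils::head(missing, 3),
                                             collapse = ", "))
  kept <- character(0)
  for (g in genes) {
    x <- cohort$expr[, g]
    med <- stats::median(x)
    high <- x > med
    if (!any(high) || all(high)) {
      warning("constant expression for gene ", g, "; skipped")
      next
    }
    lr <- logrank_test(cohort$time[high], cohort$event[high],
                       cohort$time[!high], cohort$event[!high])
    if (lr$p >= alpha) next
    tau <- min(max(cohort$time[high]), max(cohort$time[!high]))
    worse <- .km_area(cohort$time[high], cohort$event[high], tau) <
             .km_area(cohort$time[!high], cohort$event[!high], tau)
    if (worse) kept <- c(kept, g)
  }
  sort(kept)
}
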