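# Seeded generators for every input the screen consumes, each emitting a
# ground-truth record alongside the data. All generators are pure functions
# of (seed, parameters): the same seed reproduces identical output.

.gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a synthetic genome with planted motif sites
#'
#' Draws iid uniform A/C/G/T background and plants concrete expansions of
#' the requested motifs at non-overlapping random positions and random
#' orientations. With `scrub_unplanted = TRUE`, background positions that
#' happen to match any planted motif are rejection-resampled away, so the
#' truth table is the exact site list (used by the bundled end-to-end
#' fixture, where exact planted-site recovery is required).
#'
#' @param seed integer seed.
#' @param n_records number of FASTA records.
#' @param length length of each record (>= 50 x motif length).
#' @param plant named integer vector, IUPAC motif -> number of sites to
#'   plant (spread over records at random).
#' @param plant_at optional exact placement: `data.frame` with `seq_id`,
#'   `start` (0-based), `motif`, and optionally `orientation`.
#' @param scrub_unplanted remove chance background matches to the planted
#'   motifs.
#' @param record_prefix FASTA record name prefix.
#' @return List with `sequences` (named character vector) and `truth`
#'   (site `data.frame` with `seq_id`, `start`, `end`, `orientation`,
#'   `matched`, `name` = motif), plus the `seed`.
#' @export
gen_genome <- function(seed, n_records = 1L, length = 10000L,
                       plant = NULL, plant_at = NULL,
                       scrub_unplanted = FALSE, record_prefix = "chr") {
  motifs <- unique(c(names(plant), plant_at$motif))
  if (!is.null(motifs) && length(motifs) &&
      length < 50L * max(nchar(motifs)))
    stop("record length must be >= 50 x motif length")
  withr::with_seed(seed, {
    ids <- paste0(record_prefix, seq_len(n_records))
    seqs <- lapply(seq_len(n_records), function(i)
      sample(c("A", "C", "G", "T"), length, replace = TRUE))
    names(seqs) <- ids
    occupied <- stats::setNames(
      rep(list(data.frame(start = integer(0), end = integer(0))), n_records),
      ids)
    truth <- list()
    place <- function(rec, start0, motif, ori) {
      w <- nchar(motif)
      concrete <- paste(vapply(.IUPAC[strsplit(motif, "")[[1]]],
                               function(s) if (length(s) == 1L) s
                                           else sample(s, 1L),
                               character(1)), collapse = "")
      fwd <- if (ori == "+") concrete else reverse_complement(concrete)
      seqs[[rec]][(start0 + 1L):(start0 + w)] <<-
        strsplit(fwd, "")[[1]]
      occupied[[rec]] <<- rbind(occupied[[rec]],
                                data.frame(start = start0,
                                           end = start0 + w))
      truth[[length(truth) + 1L]] <<-
        data.frame(seq_id = rec, start = start0, end = start0 + w,
                   orientation = ori, matched = fwd, name = motif,
                   stringsAsFactors = FALSE)
    }
    # random placements
    for (m in names(plant)) {
      w <- nchar(m)
      for (i in seq_len(plant[[m]])) {
        rec <- sample(ids, 1L)
        ok <- FALSE
        for (try in seq_len(1000L)) {
          s0 <- sample.int(length - w + 1L, 1L) - 1L
          occ <- occupied[[rec]]
          if (!nrow(occ) || all(s0 + w <= occ$start | s0 >= occ$end)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("infeasible packing: cannot place motif ", m)
        place(rec, s0, m, sample(c("+", "-"), 1L))
      }
    }
    # exact placements
    if (!is.null(plant_at)) {
      for (i in seq_len(nrow(plant_at))) {
        rec <- plant_at$seq_id[i]
        m <- plant_at$motif[i]
        ori <- if ("orientation" %in% names(plant_at))
          plant_at$orientation[i] else sample(c("+", "-"), 1L)
        s0 <- plant_at$start[i]
        w <- nchar(m)
        occ <- occupied[[rec]]
        if (nrow(occ) && any(s0 + w > occ$start & s0 < occ$end))
          stop("infeasible packing: exact placement overlaps a prior site")
        if (s0 < 0L || s0 + w > length)
          stop("exact placement outside the record")
        place(rec, s0, m, ori)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth)
      else data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      matched = character(0), name = character(0))
    if (scrub_unplanted && length(motifs)) {
      for (iter in seq_len(100L)) {
        dirty <- FALSE
        for (rec in ids) {
          s <- paste(seqs[[rec]], collapse = "")
          for (m in motifs) {
            hits <- scan_duplex(s, m, seq_id = rec)
            planted <- truth[truth$seq_id == rec & truth$name == m, ]
            spurious <- hits[!(hits$start %in% planted$start), ,
                             drop = FALSE]
            if (!nrow(spurious)) next
            dirty <- TRUE
            occ <- occupied[[rec]]
            for (j in seq_len(nrow(spurious))) {
              pos <- (spurious$start[j] + 1L):spurious$end[j]  # 1-based
              free <- pos[!vapply(pos, function(p)
                nrow(occ) > 0 && any(p > occ$start & p <= occ$end),
                logical(1))]
              if (!length(free))
                stop("cannot scrub a match fully inside planted sites")
              p <- free[[1L]]
              seqs[[rec]][p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              seqs[[rec]][p]), 1L)
            }
            s <- paste(seqs[[rec]], collapse = "")
          }
        }
        if (!dirty) break
        if (iter == 100L) stop("scrubbing did not converge")
      }
    }
    sequences <- vapply(seqs, paste, character(1), collapse = "")
    list(sequences = sequences, truth = truth, seed = seed)
  })
}

#' Acceptance-style overlapping planted gene sets
#'
#' The designed Venn structure of the synthetic screen: 50 planted genes
#' per compound with non-empty single-compound and pairwise regions
#' (KR12 with CCC-002; CCC-002 with CCC-003).
#'
#' @param n_genes universe size (>= 125).
#' @return Named list of gene-identifier sets for KR12, CCC-002, CCC-003.
#' @export
venn_planted_sets <- function(n_genes = 2000L) {
  stopifnot(n_genes >= 125L)
  g <- .gene_ids(n_genes)
  list("KR12" = g[1:50], "CCC-002" = g[41:90], "CCC-003" = g[76:125])
}

#' Generate a synthetic log2 expression matrix with planted effects
#'
#' Baseline per gene is Normal(8, 2) log2 units (mimicking normalized
#' single-channel intensities); compound samples add the planted (negative
#' for downregulation) effect on their planted genes; every measurement
#' carries Normal(0, sigma) replicate noise.
#'
#' @param seed integer seed.
#' @param n_genes number of genes (ids `G0001`, ...).
#' @param reps replicates per condition (>= 2).
#' @param compounds compound condition labels.
#' @param planted named list, compound -> character vector of planted
#'   genes (e.g. [venn_planted_sets()]); `NULL` plants nothing.
#' @param effect log2 effect added in compound samples on planted genes
#'   (scalar, or named by compound).
#' @param sigma replicate noise sd (log2 units).
#' @param control control condition label.
#' @param baseline_mean,baseline_sd baseline distribution parameters.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (planted sets, effects, sigma, seed).
#' @export
gen_expression <- function(seed, n_genes = 2000L, reps = 3L,
                           compounds = c("KR12", "CCC-002", "CCC-003"),
                           planted = NULL, effect = -2.0, sigma = 0.2,
                           control = "DMSO", baseline_mean = 8,
                           baseline_sd = 2) {
  if (reps < 2L) stop("need >= 2 replicates per condition")
  if (!is.null(planted)) {
    stopifnot(all(names(planted) %in% compounds))
    bad <- setdiff(unlist(planted), .gene_ids(n_genes))
    if (length(bad)) stop("planted genes outside the gene universe")
  }
  effects <- if (length(effect) == 1L && is.null(names(effect)))
    stats::setNames(rep(effect, length(compounds)), compounds)
  else effect
  withr::with_seed(seed, {
    genes <- .gene_ids(n_genes)
    conds <- c(control, compounds)
    samples <- unlist(lapply(conds, function(cn) paste0(cn, "_", seq_len(reps))))
    condition_of <- stats::setNames(rep(conds, each = reps), samples)
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    vals <- matrix(rep(baseline, length(samples)), nrow = n_genes,
                   dimnames = list(genes, samples))
    for (cn in names(planted)) {
      idx <- genes %in% planted[[cn]]
      vals[idx, condition_of == cn] <-
        vals[idx, condition_of == cn] + effects[[cn]]
    }
    vals <- vals + stats::rnorm(length(vals), 0, sigma)
    mat <- expression_matrix(vals, condition_of, control = control)
    list(matrix = mat,
         truth = list(planted = planted, effects = as.list(effects),
                      sigma = sigma, seed = seed))
  })
}

#' Generate a synthetic survival cohort with planted hazard genes
#'
#' Expression per patient and gene is Normal(0, 1). Event times are
#' exponential with hazard `lambda0` multiplied, for every gene with a
#' hazard ratio different from 1, by `hr^(expr > median)`. Censoring times
#' are Uniform(0, censor_horizon / lambda0); `censor_horizon = Inf`
#' disables censoring (the default horizon of 5 censors roughly 20% of
#' baseline patients).
#'
#' @param seed integer seed.
#' @param n_patients cohort size.
#' @param genes gene identifiers (cohort expression columns).
#' @param hr named numeric vector of per-gene hazard ratios (genes not
#'   named have HR 1).
#' @param lambda0 baseline hazard.
#' @param censor_horizon uniform-censoring horizon in units of
#'   `1 / lambda0`.
#' @return List with `cohort` (a [survival_cohort()]) and `truth`.
#' @export
gen_survival <- function(seed, n_patients = 100L, genes, hr = NULL,
                         lambda0 = 1, censor_horizon = 5) {
  if (!is.null(hr) && any(hr <= 0)) stop("hazard ratios must be positive")
  withr::with_seed(seed, {
    expr <- matrix(stats::rnorm(n_patients * length(genes)),
                   nrow = n_patients,
                   dimnames = list(sprintf("P%04d", seq_len(n_patients)),
                                   genes))
    hazard <- rep(lambda0, n_patients)
    for (g in names(hr)) {
      if (hr[[g]] == 1) next
      if (!g %in% genes) stop("hr gene not in cohort genes: ", g)
      high <- expr[, g] > stats::median(expr[, g])
      hazard <- hazard * ifelse(high, hr[[g]], 1)
    }
    t_event <- stats::rexp(n_patients, rate = hazard)
    c_time <- if (is.finite(censor_horizon))
      stats::runif(n_patients, 0, censor_horizon / lambda0)
    else rep(Inf, n_patients)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
    cohort <- survival_cohort(rownames(expr), time, event, expr)
    list(cohort = cohort,
         truth = list(hr = as.list(hr), lambda0 = lambda0,
                      censor_horizon = censor_horizon, seed = seed))
  })
}

#' Generate a synthetic viability plate from a 4PL curve
#'
#' Mean response follows the four-parameter logistic curve; measurements
#' carry multiplicative Gaussian noise with coefficient of variation `cv`.
#' Wells are laid out in triplicate by default, matching common WST assay
#' practice.
#'
#' @param seed integer seed.
#' @param ic50,hill,top,bottom curve parameters.
#' @param doses dose vector (> 0); default 8 log-spaced doses spanning two
#'   decades either side of the IC50.
#' @param reps replicate wells per dose.
#' @param cv coefficient of variation of the multiplicative noise.
#' @return List with `plate` (`data.frame` of `dose`, `response`,
#'   `replicate`) and `truth`.
#' @export
gen_plate <- function(seed, ic50, hill = 1, top = 100, bottom = 0,
                      doses = NULL, reps = 3L, cv = 0.05) {
  stopifnot(ic50 > 0, cv >= 0)
  if (is.null(doses))
    doses <- 10^seq(log10(ic50) - 2, log10(ic50) + 2, length.out = 8)
  if (any(doses <= 0)) stop("doses must be positive")
  withr::with_seed(seed, {
    d <- rep(doses, each = reps)
    mu <- response_4pl(d, ic50, hill, top, bottom)
    resp <- mu * (1 + stats::rnorm(length(d), 0, cv))
    plate <- data.frame(dose = d, response = resp,
                        replicate = rep(seq_len(reps), times = length(doses)))
    list(plate = plate,
         truth = list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                      doses = doses, reps = reps, cv = cv, seed = seed))
  })
}
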