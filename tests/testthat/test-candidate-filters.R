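test_that("hypergeometric enrichment matches closed-form cases", {
  universe <- paste0("g", 1:10)
  # full overlap of a 5-set with a 5-candidate list: p = 1/C(10,5)
  res <- hypergeometric_enrichment(universe[1:5],
                                   list(S = universe[1:5]), universe)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res[, c("k", "K", "n", "N")],
               data.frame(k = 5L, K = 5L, n = 5L, N = 10L),
               ignore_attr = TRUE)
  # N=4, K=2, n=2, k=1 -> 5/6
  u4 <- paste0("g", 1:4)
  res2 <- hypergeometric_enrichment(u4[2:3], list(S = u4[1:2]), u4)
  expect_equal(res2$p, 5 / 6, tolerance = 1e-12)
  # zero overlap -> upper tail at 0 is 1
  res3 <- hypergeometric_enrichment(u4[3:4], list(S = u4[1:2]), u4)
  expect_equal(res3$p, 1)
})

test_that("enrichment guards its preconditions", {
  u <- paste0("g", 1:6)
  expect_error(hypergeometric_enrichment("zz", list(S = u[1:2]), u),
               "outside the universe")
  expect_error(hypergeometric_enrichment(u[1], list(S = u[1]), character(0)),
               "empty universe")
  expect_warning(res <- hypergeometric_enrichment(character(0),
                                                  list(S = u[1:3]), u),
                 "empty candidate")
  expect_equal(res$p, 1)
})

test_that("enrichment p equals exhaustive enumeration on small universes", {
  for (N in c(3L, 6L, 9L)) {
    u <- paste0("g", seq_len(N))
    for (K in 0:N) for (n in 0:N) {
      k_max <- min(K, n)
      for (k in 0:k_max) {
        if (n - k > N - K) next
        cand <- c(u[seq_len(k)], u[K + seq_len(n - k)])
        res <- suppressWarnings(   # n = 0 warns by contract
          hypergeometric_enrichment(cand, list(S = u[seq_len(K)]), u))
        expect_equal(res$p, oracle_hyper_upper(k, K, n, N),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("results sort by p with lexicographic set_id tie-break", {
  u <- paste0("g", 1:12)
  sets <- list(zb = u[1:2], za = u[3:4], big = u[1:8])
  res <- hypergeometric_enrichment(u[c(1, 3)], sets, u)
  # za and zb have identical (k=1, K=2) p; za sorts first
  expect_equal(res$set_id[res$p == res$p[res$set_id == "za"]][1], "za")
  top1 <- top_pathway_gene_union(res, sets, u[c(1, 3)], 1)
  expect_setequal(top1, intersect(sets[[res$set_id[1]]], u[c(1, 3)]))
  # saturation at k >= number of sets
  expect_setequal(top_pathway_gene_union(res, sets, u[c(1, 3)], 99),
                  u[c(1, 3)])
  expect_error(top_pathway_gene_union(res, sets, u[1], 0), "positive")
})

test_that("binding_site_filter keeps genes with at least one site", {
  counts <- c(g1 = 2, g2 = 0, g3 = 1)
  expect_setequal(binding_site_filter(c("g1", "g2", "g3"), counts),
                  c("g1", "g3"))
  expect_length(binding_site_filter(c("g1", "g2"), c(g1 = 0, g2 = 0)), 0L)
  # absent gene counts as zero
  expect_setequal(binding_site_filter(c("g1", "g9"), counts), "g1")
})

test_that("log-rank statistic matches survival::survdiff and hand cases", {
  # identical groups
  lr0 <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)
  # fully separated event times, checked against the survival package
  lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(4, 5, 6), c(1, 1, 1))
  sd <- survival::survdiff(
    survival::Surv(c(1, 2, 3, 4, 5, 6), rep(1, 6)) ~ rep(1:2, each = 3))
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
  # random censored cohorts
  set.seed(21)
  for (i in 1:15) {
    ta <- rexp(25); tb <- rexp(25, 1.7)
    ea <- rbinom(25, 1, 0.8); eb <- rbinom(25, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) next
    lr <- logrank_test(ta, ea, tb, eb)
    sd <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, each = 25))
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
  }
  # single event total: one-row risk table, (O-E)^2/V
  lr1 <- logrank_test(1, 1, 2, 0)
  expect_equal(lr1$statistic, (1 - 0.5)^2 / 0.25, tolerance = 1e-12)
  # no events at all
  expect_warning(lrn <- logrank_test(c(1, 2), c(0, 0), c(3), c(0)),
                 "no events")
  expect_equal(lrn$p, 1)
})

test_that("log-rank is invariant under common time rescaling", {
  set.seed(22)
  ta <- rexp(30); tb <- rexp(30, 2)
  ea <- rbinom(30, 1, 0.9); eb <- rbinom(30, 1, 0.9)
  a <- logrank_test(ta, ea, tb, eb)
  b <- logrank_test(ta * 37.5, ea, tb * 37.5, eb)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("survival filter keeps harmful and drops protective genes", {
  hr <- c(bad = 3.5, prot = 0.2, none = 1)
  sv <- gen_survival(31, n_patients = 200, genes = names(hr), hr = hr)
  kept <- survival_filter(names(hr), sv$cohort, alpha = 0.05)
  expect_true("bad" %in% kept)
  expect_false("prot" %in% kept)   # direction rule despite a small p
  # protective gene is significant but in the wrong direction
  x <- sv$cohort$expr[, "prot"]
  high <- x > median(x)
  lr <- logrank_test(sv$cohort$time[high], sv$cohort$event[high],
                     sv$cohort$time[!high], sv$cohort$event[!high])
  expect_lt(lr$p, 0.05)
  # constant expression is skipped with a warning
  cohort2 <- survival_cohort(sv$cohort$patients, sv$cohort$time,
                             sv$cohort$event,
                             cbind(sv$cohort$expr,
                                   flat = rep(1, 200)))
  expect_warning(k2 <- survival_filter("flat", cohort2), "constant")
  expect_length(k2, 0L)
  expect_error(survival_filter("missing", sv$cohort), "absent")
})
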