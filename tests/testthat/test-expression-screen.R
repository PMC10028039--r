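make_mat <- function(values, conds, control = "DMSO") {
  expression_matrix(values, conds, control = control)
}

test_that("log2 fold change is the mean difference versus control", {
  vals <- rbind(g1 = c(4, 4, 6, 6),
                g2 = c(5, 6, 5, 6))
  colnames(vals) <- c("t1", "t2", "c1", "c2")
  mat <- make_mat(vals, c(t1 = "X", t2 = "X", c1 = "DMSO", c2 = "DMSO"))
  de <- differential_expression(mat, "X", method = "welch")
  expect_equal(de$log2FC, c(-2, 0))
  expect_equal(de$p[2], 1)         # identical groups
  expect_true(all(de$p >= 0 & de$p <= 1))
})

test_that("welch and pooled p-values match stats::t.test to 1e-12", {
  a <- c(1.0, 1.1, 0.9); b <- c(2.0, 2.1, 1.9)
  set.seed(11)
  vals <- rbind(g1 = c(a, b),
                matrix(rnorm(5 * 6, 8), nrow = 5,
                       dimnames = list(paste0("r", 1:5), NULL)))
  colnames(vals) <- c("t1", "t2", "t3", "c1", "c2", "c3")
  conds <- setNames(rep(c("X", "DMSO"), each = 3), colnames(vals))
  mat <- make_mat(vals, conds)
  for (method in c("welch", "pooled")) {
    de <- differential_expression(mat, "X", method = method)
    for (g in rownames(vals)) {
      x <- vals[g, 1:3]; y <- vals[g, 4:6]
      ref <- t.test(x, y, var.equal = (method == "pooled"))
      expect_equal(de$p[de$gene == g], unname(ref$p.value),
                   tolerance = 1e-12)
      expect_equal(de$log2FC[de$gene == g], unname(mean(x) - mean(y)),
                   tolerance = 1e-12)
    }
  }
  expect_equal(de$log2FC[de$gene == "g1"], -1)
})

test_that("moderated p-values agree with the variance structure", {
  set.seed(12)
  ge <- gen_expression(5, n_genes = 300, reps = 3,
                       planted = list("KR12" = sprintf("G%04d", 1:20)),
                       effect = -2, sigma = 0.2)
  de <- differential_expression(ge$matrix, "KR12", method = "moderated")
  planted <- de$gene %in% sprintf("G%04d", 1:20)
  expect_lt(max(de$p[planted]), 1e-6)
  expect_gt(min(de$p[!planted]), 1e-6)
})

test_that("DE requires replicates and a known compound", {
  vals <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("t1", "c1")))
  mat <- make_mat(vals, c(t1 = "X", c1 = "DMSO"))
  expect_error(differential_expression(mat, "X"), "2 replicates")
  expect_error(differential_expression(mat, "Y"), "no samples")
})

test_that("downregulated_candidates keeps the significant bottom percentile", {
  res <- data.frame(gene = paste0("g", 1:10),
                    compound = "X",
                    log2FC = -(1:10),
                    p = 1e-6)
  got <- downregulated_candidates(res, screen_config(percentile = 0.20))
  expect_setequal(got, c("g9", "g10"))   # boundary quantile is -8.2
  # the raw p filter removes otherwise-extreme genes
  res$p[10] <- 0.01
  expect_setequal(downregulated_candidates(res, screen_config()), "g9")
  # upregulated-only input
  up <- data.frame(gene = "g1", compound = "X", log2FC = 2, p = 1e-9)
  expect_warning(out <- downregulated_candidates(up, screen_config()),
                 "no downregulated")
  expect_length(out, 0L)
  # boundary ties are kept
  tie <- data.frame(gene = paste0("g", 1:5), compound = "X",
                    log2FC = c(-2, -2, -2, -2, -2), p = 1e-9)
  expect_length(downregulated_candidates(tie, screen_config()), 5L)
})

test_that("candidate selection is monotone in its thresholds", {
  set.seed(13)
  res <- data.frame(gene = paste0("g", 1:400), compound = "X",
                    log2FC = rnorm(400), p = runif(400)^3)
  loose_p <- downregulated_candidates(res, screen_config(p_threshold = 0.05))
  tight_p <- downregulated_candidates(res, screen_config(p_threshold = 0.001))
  expect_true(all(tight_p %in% loose_p))
  wide_q <- downregulated_candidates(res, screen_config(p_threshold = 0.05,
                                                        percentile = 0.5))
  narrow_q <- downregulated_candidates(res, screen_config(p_threshold = 0.05,
                                                          percentile = 0.1))
  expect_true(all(narrow_q %in% wide_q))
})

test_that("exclusivity partition covers the union with disjoint regions", {
  part <- exclusivity_partition(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_setequal(part[["A"]], "g1")
  expect_setequal(part[["B"]], "g3")
  expect_setequal(part[["A&B"]], "g2")
  # shared-by-all gene lands only in the triple region
  p3 <- exclusivity_partition(list(A = c("s", "a"), B = c("s", "b"),
                                   C = c("s")))
  expect_setequal(p3[["A&B&C"]], "s")
  expect_false("s" %in% unlist(p3[c("A&B", "A&C", "B&C")]))
  expect_length(p3, 7L)
  # random families: pairwise disjoint, union preserved
  set.seed(14)
  for (i in 1:20) {
    fam <- replicate(sample(2:4, 1),
                     sample(paste0("g", 1:15), sample(0:10, 1)),
                     simplify = FALSE)
    names(fam) <- paste0("S", seq_along(fam))
    part <- exclusivity_partition(fam)
    all_genes <- unlist(part)
    expect_equal(anyDuplicated(all_genes), 0L)
    expect_setequal(all_genes, unique(unlist(fam)))
  }
})

test_that("select_exclusive applies union and intersection semantics", {
  sets <- list(CCC002 = c("g1", "g2"), CCC003 = c("g2", "g3"),
               KR12 = "g1")
  cfg <- screen_config(include_compounds = c("CCC002", "CCC003"),
                       exclude_compounds = "KR12")
  expect_setequal(select_exclusive(sets, cfg), c("g2", "g3"))
  cfg_i <- screen_config(include_compounds = c("CCC002", "CCC003"),
                         exclude_compounds = "KR12",
                         exclusive_mode = "intersection")
  expect_setequal(select_exclusive(sets, cfg_i), "g2")
  # no exclusions -> union of includes
  cfg_u <- screen_config(include_compounds = c("CCC002", "CCC003"))
  expect_setequal(select_exclusive(sets, cfg_u), c("g1", "g2", "g3"))
  # everything excluded
  cfg_x <- screen_config(include_compounds = "KR12",
                         exclude_compounds = "CCC002")
  expect_length(select_exclusive(sets, cfg_x), 0L)
  expect_error(select_exclusive(sets, screen_config(
    include_compounds = "nope")), "unknown compound")
})

test_that("screen_config validates its thresholds", {
  expect_error(screen_config(p_threshold = 0), "p_threshold")
  expect_error(screen_config(percentile = 1.5))
  expect_error(screen_config(include_compounds = "A",
                             exclude_compounds = "A"), "overlap")
})

test_that("probe-level results collapse to the best probe per gene", {
  res <- data.frame(gene = c("p1", "p2", "p3", "p4"), compound = "X",
                    log2FC = c(-1, -3, -2, 0.5), p = c(0.2, 1e-6, 1e-3, 0.9))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")   # p4 unmapped
  out <- collapse_probes(res, map)
  expect_setequal(out$gene, c("gA", "gB"))
  expect_equal(out$log2FC[out$gene == "gA"], -3)  # smallest-p probe wins
  expect_equal(out$p[out$gene == "gB"], 1e-3)
})
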