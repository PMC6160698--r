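test_that("quantile normalization matches the per-rank-mean definition", {
  out <- quantile_normalize(cbind(c(2, 6, 10), c(4, 8, 6)))
  expect_equal(out[, 1], c(3, 6, 9))
  expect_equal(out[, 2], c(3, 9, 6))

  one <- matrix(c(5, 1, 7), 3, 1)
  expect_equal(quantile_normalize(one), one)

  set.seed(42)
  m <- matrix(rnorm(60), 10, 6)
  qn <- quantile_normalize(m)
  # identical sorted value multiset in every column
  ref <- sort(qn[, 1])
  for (j in 2:6) expect_equal(sort(qn[, j]), ref)
  expect_equal(unname(colMeans(qn)), rep(mean(colMeans(qn)), 6))
  # idempotence
  expect_equal(quantile_normalize(qn), qn)

  # ties get the mean of the reference values at their tied ranks
  tied <- cbind(c(1, 1, 5), c(2, 4, 6))
  ref_dist <- rowMeans(cbind(sort(tied[, 1]), sort(tied[, 2])))
  out2 <- quantile_normalize(tied)
  expect_equal(out2[1:2, 1], rep(mean(ref_dist[1:2]), 2))

  expect_error(quantile_normalize(matrix(c(1, NA), 1)), "missing")
})

test_that("quantile normalization agrees with limma on tie-free input", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(rnorm(200), 40, 5)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("presence filter keeps rows flagged in at least min_present samples", {
  m <- matrix(1, 3, 6, dimnames = list(c("a", "b", "c"), NULL))
  flags <- rbind(rep(c(TRUE, FALSE), c(3, 3)),
                 rep(c(TRUE, FALSE), c(2, 4)),
                 rep(TRUE, 6))
  suppressMessages(kept <- presence_filter(m, flags, 3))
  expect_equal(rownames(kept), c("a", "c"))   # 3-of-6 boundary retained
  expect_equal(rownames(presence_filter(m, flags, 0)), c("a", "b", "c"))
  expect_error(presence_filter(m, flags, 7), "exceeds")
})

test_that("differential test computes fold change and two-sided p", {
  samples <- data.frame(sample = c("T1", "T2", "T3", "N1", "N2", "N3"),
                        group = rep(c("tumor", "normal"), each = 3),
                        pair = rep(c("P1", "P2", "P3"), 2))
  set.seed(1)
  jit <- rnorm(6, sd = 1e-3)
  m <- rbind(flat = rep(4, 6),
             up = c(5, 5, 5, 3, 3, 3) + jit)
  colnames(m) <- samples$sample
  expect_warning(tab <- differential_test(m, samples), "zero variance")
  expect_equal(tab$log2_fc[1], 0)
  expect_equal(tab$p_value[1], 1)
  expect_equal(tab$fold_change[2], 4, tolerance = 0.01)

  sel <- select_differential(tab, 1.5, 0.05)
  expect_equal(sel$table$direction[1], "ns")
  expect_equal(sel$up, "up")
})

test_that("row t statistics match stats::t.test to 1e-10", {
  samples <- data.frame(sample = sprintf("S%d", 1:8),
                        group = rep(c("tumor", "normal"), each = 4),
                        pair = rep(sprintf("P%d", 1:4), 2))
  set.seed(3)
  m <- matrix(rnorm(80), 10, 8, dimnames = list(sprintf("g%d", 1:10),
                                                samples$sample))
  welch <- differential_test(m, samples)
  paired <- differential_test(m, samples, paired = TRUE)
  for (i in 1:10) {
    expect_equal(welch$p_value[i],
                 t.test(m[i, 1:4], m[i, 5:8])$p.value, tolerance = 1e-10)
    expect_equal(paired$p_value[i],
                 t.test(m[i, 1:4], m[i, 5:8], paired = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("volcano selection uses strict thresholds and disjoint calls", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    fold_change = c(1.5, 4, 0.5, 2),
                    p_value = c(0.001, 0.2, 0.01, 0.01))
  tab$log2_fc <- log2(tab$fold_change)
  sel <- select_differential(tab, 1.5, 0.05)
  expect_false("a" %in% sel$up)      # fold change exactly 1.5 excluded
  expect_false("b" %in% sel$up)      # both conditions required
  expect_equal(sel$up, "d")
  expect_equal(sel$down, "c")
  expect_length(intersect(sel$up, sel$down), 0)
})

test_that("external intersection keeps same-direction genes only", {
  ext <- data.frame(gene = c("A", "C", "E", "D", "F"),
                    direction = c("up", "up", "up", "down", "down"))
  out <- intersect_external(c("A", "B", "C"), "D", ext)
  expect_setequal(out$up, c("A", "C"))
  expect_equal(out$down, "D")

  # direction mismatch drops the gene
  flip <- data.frame(gene = "A", direction = "down")
  expect_equal(intersect_external("A", character(0), flip)$up, character(0))
  # case-insensitive symbol matching
  lower <- data.frame(gene = "a", direction = "up")
  expect_equal(intersect_external("A", character(0), lower)$up, "A")
  expect_warning(
    out0 <- intersect_external("A", "B", ext[0, ]), "empty")
  expect_length(out0$up, 0)
  expect_error(intersect_external("A", "B",
                                  data.frame(gene = "A", direction = "sideways")),
               "direction")
})

test_that("hierarchical clustering merges identical rows first and splits blocks", {
  set.seed(5)
  base <- rnorm(10)
  m <- rbind(a = base, b = base, c = rnorm(10), d = rnorm(10))
  cl <- hierarchical_cluster(m)
  first <- cl$row_hclust$merge[1, ]
  expect_setequal(first, c(-1, -2))   # distance 0 merges first

  two <- hierarchical_cluster(m[1:3, ][c(1, 3), ])
  expect_equal(nrow(two$row_hclust$merge), 1)

  expect_error(hierarchical_cluster(rbind(rep(1, 5), rnorm(5))),
               "zero-variance")

  # two planted correlated blocks are the top-level split
  f1 <- rnorm(20); f2 <- rnorm(20)
  blk <- rbind(x1 = f1 + rnorm(20, sd = 0.1), x2 = f1 + rnorm(20, sd = 0.1),
               y1 = f2 + rnorm(20, sd = 0.1), y2 = f2 + rnorm(20, sd = 0.1))
  cb <- hierarchical_cluster(blk)
  top <- stats::cutree(cb$row_hclust, k = 2)
  expect_equal(unname(top["x1"]), unname(top["x2"]))
  expect_equal(unname(top["y1"]), unname(top["y2"]))
  expect_false(top[["x1"]] == top[["y1"]])
})
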