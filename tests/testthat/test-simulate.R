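test_that("simulation is deterministic and honors the DE contract", {
  cfg <- sim_config(n_lncrna = 40, n_pcg = 30, n_pairs = 5,
                    de_fraction = 0.2, seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth$de_genes, b$truth$de_genes)

  expect_equal(dim(a$matrix), c(70, 10))
  expect_true(all(a$truth$de_genes$gene %in% rownames(a$matrix)))

  none <- simulate_expression(sim_config(n_lncrna = 20, n_pcg = 10,
                                         de_fraction = 0, seed = 3))
  expect_equal(nrow(none$truth$de_genes), 0)
})

test_that("planted fold changes average to the configured effect", {
  cfg <- sim_config(n_lncrna = 200, n_pcg = 100, n_pairs = 100,
                    de_fraction = 0.1, log2_effect = 2, noise_sd = 0.5,
                    n_modules = 0, seed = 5)
  sim <- simulate_expression(cfg)
  de <- sim$truth$de_genes
  tum <- sim$samples$group == "tumor"
  lfc <- rowMeans(sim$matrix[de$gene, tum]) -
    rowMeans(sim$matrix[de$gene, !tum])
  up <- de$direction == "up"
  # mean observed log2 FC within 3 standard errors of the planted effect
  se <- 0.5 * sqrt(2 / 100) / sqrt(sum(up))
  expect_lt(abs(mean(lfc[up]) - 2), 3 * 0.5 * sqrt(2 / 100))
  expect_lt(abs(mean(lfc[!up]) + 2), 3 * 0.5 * sqrt(2 / 100))
})

test_that("planted modules are internally correlated above background", {
  cfg <- sim_config(n_lncrna = 50, n_pcg = 50, n_pairs = 30,
                    de_fraction = 0, n_modules = 2, module_size = 10,
                    module_corr = 0.7, seed = 9)
  sim <- simulate_expression(cfg)
  mm <- sim$truth$module_membership
  expect_setequal(unique(unname(mm)), c(0L, 1L))   # ids dense from 0
  cors <- cor(t(sim$matrix))
  within <- c()
  for (m in 0:1) {
    g <- names(mm)[mm == m]
    cc <- cors[g, g]
    within <- c(within, cc[upper.tri(cc)])
  }
  other <- setdiff(rownames(sim$matrix), names(mm))
  between <- cors[names(mm), other]
  expect_gt(mean(abs(within)), mean(abs(between)))
  expect_lt(abs(mean(within) - 0.7), 0.1)

  # every module contains a lncRNA hub for guilt-by-association
  bt <- setNames(sim$genes$biotype, sim$genes$gene)
  for (m in 0:1) {
    expect_true(any(bt[names(mm)[mm == m]] == "lncRNA"))
  }
})

test_that("reusing planted truth yields an independent cohort of the same biology", {
  cfg <- sim_config(n_lncrna = 30, n_pcg = 30, n_pairs = 5,
                    de_fraction = 0.2, n_modules = 1, module_size = 6,
                    seed = 19)
  a <- simulate_expression(cfg)
  cfg2 <- cfg; cfg2$seed <- 99L; cfg2$n_pairs <- 8L
  b <- simulate_expression(cfg2, truth = a$truth)
  expect_identical(b$truth$de_genes, a$truth$de_genes)
  expect_identical(b$truth$module_membership, a$truth$module_membership)
  expect_equal(ncol(b$matrix), 16)
  expect_false(isTRUE(all.equal(b$matrix[, 1:10], a$matrix)))
  # planted effects persist in the reused cohort
  tum <- b$samples$group == "tumor"
  de <- b$truth$de_genes
  lfc <- rowMeans(b$matrix[de$gene, tum]) - rowMeans(b$matrix[de$gene, !tum])
  expect_true(all(sign(lfc) == ifelse(de$direction == "up", 1, -1)))
})

test_that("oversized module demand is rejected", {
  cfg <- sim_config(n_lncrna = 5, n_pcg = 5, n_modules = 3, module_size = 4)
  expect_error(simulate_expression(cfg), "exceeds")
})

test_that("GO generator plants one dominant signature term per module", {
  cfg <- sim_config(n_lncrna = 10, n_pcg = 30, n_pairs = 4, de_fraction = 0,
                    n_modules = 1, module_size = 10, n_go_terms = 5,
                    go_background_rate = 0, seed = 21)
  sim <- simulate_expression(cfg)
  sets <- simulate_go(sim$truth, cfg, sim$genes$gene)
  sig <- sets[["GO:SIG0001"]]
  members <- names(sim$truth$module_membership)
  expect_gte(length(intersect(sig, members)), 8)   # >= 80% of 10
  # zero background rate: only the signature term is emitted
  expect_equal(names(sets), "GO:SIG0001")

  cfg0 <- sim_config(n_lncrna = 10, n_pcg = 10, n_modules = 0,
                     n_go_terms = 4, go_background_rate = 0.5, seed = 2)
  sim0 <- simulate_expression(cfg0)
  sets0 <- simulate_go(sim0$truth, cfg0, sim0$genes$gene)
  expect_true(all(grepl("^GO:BG", names(sets0))))

  bad <- cfg
  bad$n_go_terms <- 0L
  expect_error(simulate_go(sim$truth, bad, sim$genes$gene), "n_go_terms")
})

test_that("miRNA generator plants opposite-direction pairs plus decoys", {
  cfg <- sim_config(n_lncrna = 20, n_pcg = 20, de_fraction = 0.5,
                    mirna_count = 10, seed = 13)
  sim <- simulate_expression(cfg)
  mir <- simulate_mirna(sim$truth, cfg)
  expect_equal(nrow(mir$pairs), 20)
  expect_equal(sum(mir$pairs$planted), 10)

  gd <- setNames(sim$truth$de_genes$direction, sim$truth$de_genes$gene)
  md <- setNames(mir$mirna_directions$direction, mir$mirna_directions$mirna)
  planted <- mir$pairs[mir$pairs$planted, ]
  decoys <- mir$pairs[!mir$pairs$planted, ]
  expect_true(all(md[planted$mirna] != gd[planted$target]))
  expect_true(all(md[decoys$mirna] == gd[decoys$target]))

  # the opposite-direction filter keeps exactly the planted pairs
  kept <- filter_mirna_targets(mir$pairs, mir$mirna_directions,
                               data.frame(gene = names(gd),
                                          direction = unname(gd)))
  expect_setequal(paste(kept$mirna, kept$target),
                  paste(planted$mirna, planted$target))

  bad <- cfg; bad$mirna_count <- 0L
  expect_error(simulate_mirna(sim$truth, bad), "mirna_count")
})

test_that("Cq generator plants the tumor shift but not in the reference gene", {
  s <- simulate_cq(40, effect_dcq = 2, sd = 0.5, seed = 4)
  tum <- s$cq[s$cq$tissue == "tumor", ]
  nor <- s$cq[s$cq$tissue == "normal", ]
  dcq_t <- delta_cq(tum$cq, tum$reference_cq)
  dcq_n <- delta_cq(nor$cq, nor$reference_cq)
  expect_lt(abs(mean(dcq_t - dcq_n) - 2), 0.5)
  # reference gene has no planted group effect
  expect_gt(t.test(tum$reference_cq, nor$reference_cq)$p.value, 0.01)
  expect_equal(nrow(s$covariates), 40)

  expect_error(simulate_cq(1, sd = 1), "at least 2")
  expect_error(simulate_cq(10, sd = 0), "'sd'")
  expect_error(simulate_cq(10, covariate_effects = c(nope = 1)), "unknown")
})

test_that("planted covariate effects shift the later category's delta-Cq", {
  s <- simulate_cq(200, effect_dcq = 0, sd = 0.5,
                   covariate_effects = c(invasion = 2), seed = 8)
  tum <- s$cq[s$cq$tissue == "tumor", ]
  dcq <- setNames(delta_cq(tum$cq, tum$reference_cq), tum$patient)
  tab <- association_table(dcq, s$covariates)
  inv <- tab[tab$characteristic == "invasion", ]
  expect_lt(inv$p[1], 0.001)
  expect_gt(inv$mean[inv$category == "T4"],
            inv$mean[inv$category == "T1-T3"])
})
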