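test_that("fpkm matches its unit definition and handles edge cases", {
  # one sample of 1e6 reads total; gene of 1000 bp with 10 reads -> FPKM 10
  counts <- toy_matrix(matrix(c(10, 1e6 - 10, 0), 3, 1), "raw_counts")
  lens <- c(g01 = 1000, g02 = 2000, g03 = 500)
  f <- fpkm(counts, lens)
  expect_equal(f$values["g01", 1], 10)
  expect_equal(f$values["g03", 1], 0)   # all-zero gene stays zero
  expect_equal(f$layer, "fpkm")
  expect_error(fpkm(counts, lens[-1]), "annotation mismatch")
  zero <- toy_matrix(matrix(0, 2, 1), "raw_counts")
  expect_error(fpkm(zero, c(g01 = 1, g02 = 1)), "zero-depth")
  expect_error(fpkm(f, lens), "raw_counts")
})

test_that("recovered FPKM tracks the simulator's latent FPKM", {
  sim <- tiny_sim(seed = 1, dispersion = 0.1)
  f <- fpkm(sim$counts, sim$gene_lengths)
  expect_gt(cor(as.vector(f$values),
                as.vector(sim$truth$expected_fpkm)), 0.99)
})

test_that("signature QC flags mislabeled samples and low mapping", {
  sim <- tiny_sim(seed = 2)
  f <- fpkm(sim$counts, sim$gene_lengths)
  st <- sim$samples
  clean <- qc_signature_check(f, marker_catalog(sim$truth), st)
  expect_equal(sum(grepl("signature_mismatch", clean$qc_flags)), 0L)
  # swap the label of one B sample to NK: its B markers stay top-enriched,
  # which no longer matches the claimed cell type
  swapped <- st
  i <- which(swapped$cell_type == "B")[1]
  j <- which(swapped$cell_type == "NK" &
               swapped$donor_id == swapped$donor_id[i] &
               swapped$condition == swapped$condition[i])
  swapped$cell_type[c(i, j)] <- c("NK", "B")
  flagged <- qc_signature_check(f, marker_catalog(sim$truth), swapped)
  expect_true(grepl("signature_mismatch",
                    flagged$qc_flags[flagged$sample_id ==
                                       swapped$sample_id[i]]))
  # mapped fraction 0.49 against the 50% threshold
  mf <- stats::setNames(rep(1, nrow(st)), st$sample_id)
  mf[st$sample_id[1]] <- 0.49
  low <- qc_signature_check(f, marker_catalog(sim$truth), st,
                            min_mapped_fraction = 0.5, mapped_fraction = mf)
  expect_true(grepl("low_mapping", low$qc_flags[1]))
  expect_error(qc_signature_check(f, gene_set_catalog(list(X = "g")), st),
               "config error")
})

test_that("PCA outlier flagging catches gross outliers and nothing else", {
  sim <- tiny_sim(seed = 3)
  f <- fpkm(sim$counts, sim$gene_lengths)
  st <- sim$samples
  none <- pca_outlier_flag(f, st, k_sd = 4)
  n_base <- sum(grepl("pca_outlier", none$qc_flags))
  # a sample scaled 100x becomes a PC outlier in its stratum
  v <- f$values
  v[, 5] <- v[, 5] * 100
  burst <- expression_matrix(v, "fpkm")
  flagged <- pca_outlier_flag(burst, st, k_sd = 4)
  expect_true(grepl("pca_outlier",
                    flagged$qc_flags[flagged$sample_id == colnames(v)[5]]))
  # an infinite threshold can never flag
  inf <- pca_outlier_flag(burst, st, k_sd = Inf)
  expect_equal(sum(grepl("pca_outlier", inf$qc_flags)), 0L)
  # identical samples have zero PC spread and are never flagged
  same <- toy_matrix(matrix(rep(c(1, 5, 2, 8), 6), 4, 6), "fpkm")
  st_same <- sample_table(data.frame(
    sample_id = samples(same), donor_id = paste0("d", 1:6), group = "HD",
    cell_type = "Th", condition = "steady"))
  expect_equal(sum(grepl("pca_outlier",
                         pca_outlier_flag(same, st_same)$qc_flags)), 0L)
})

test_that("percentile gene filter follows the stated inclusive convention", {
  # totals 1..100: the 45-99.5 band keeps totals 45..99, i.e. 55 genes
  v <- matrix(1:100, 100, 1)
  m <- toy_matrix(v, "fpkm", genes = sprintf("g%03d", 1:100))
  kept <- filter_genes(m, lo_pct = 45, hi_pct = 99.5)
  expect_equal(nrow(kept$values), 55L)
  expect_equal(range(kept$values[, 1]), c(45, 99))
  expect_equal(nrow(filter_genes(m, lo_pct = 0, hi_pct = 100)$values), 100L)
  # brute-force convention check on irregular totals
  set.seed(1)
  v2 <- matrix(rpois(80, 40) * runif(80), 80, 1)
  m2 <- toy_matrix(v2, "fpkm", genes = sprintf("h%03d", 1:80))
  expected <- oracle_filter_keep(
    stats::setNames(rowSums(m2$values), genes(m2)), 30, 90)
  expect_setequal(genes(filter_genes(m2, lo_pct = 30, hi_pct = 90)),
                  expected)
  # coding restriction: percentiles are computed on the coding subset only
  coding <- sprintf("g%03d", 1:50)
  kept_c <- filter_genes(m, coding_genes = coding, lo_pct = 0, hi_pct = 100)
  expect_setequal(genes(kept_c), coding)
  # keep-list genes survive regardless of the band
  kept_k <- filter_genes(m, lo_pct = 45, hi_pct = 99.5, keep_genes = "g001")
  expect_true("g001" %in% genes(kept_k))
})

test_that("relative expression is a paired log2 ratio with sign symmetry", {
  v <- rbind(gA = c(4, 1, 2, 2),   # samples: d1 aCD3, d1 PBS, d2 aCD3, d2 PBS
             gB = c(8, 2, 2, 2))
  m <- toy_matrix(v, "fpkm", genes = c("gA", "gB"),
                  samples = c("d1_Th_aCD3", "d1_Th_PBS",
                              "d2_Th_aCD3", "d2_Th_PBS"))
  st <- sample_table(data.frame(
    sample_id = samples(m), donor_id = rep(c("d1", "d2"), each = 2),
    group = "HD", cell_type = "Th",
    condition = rep(c("aCD3", "PBS"), 2)))
  rel <- relative_expression(m, st, pseudocount = 0)
  expect_equal(rel$matrix$values["gA", "d1_Th"], 2)   # log2(4/1)
  expect_equal(rel$matrix$values["gB", "d2_Th"], 0)   # identical values
  expect_equal(rel$matrix$layer, "relative")
  # swapping the aCD3/PBS roles flips every sign
  st_sw <- st
  st_sw$condition <- rev(st$condition)
  rel_sw <- relative_expression(m, st_sw, pseudocount = 0)
  expect_equal(rel_sw$matrix$values, -rel$matrix$values)
  # unpaired aCD3 samples are dropped and reported
  st_un <- st[-2, ]
  rel_un <- relative_expression(m, st_un, pseudocount = 0)
  expect_equal(rel_un$unpaired, "d1_Th_aCD3")
  expect_equal(ncol(rel_un$matrix$values), 1L)
})

test_that("planted stimulation response is recovered on the relative layer", {
  sim <- simulate_dataset(simulation_config(seed = 4))
  f <- fpkm(sim$counts, sim$gene_lengths)
  rel <- relative_expression(f, sim$samples, pseudocount = 0.1)
  hd <- rel$samples$sample_id[rel$samples$group == "HD"]
  stim <- sim$truth$stim_genes
  est <- rowMeans(rel$matrix$values[names(stim), hd])
  # program-level recovery: the mean across same-effect genes absorbs
  # per-gene counting noise; FPKM's compositional shift stays within band
  expect_lt(abs(mean(est[stim > 0]) - stim[stim > 0][1]), 0.2)
  expect_lt(abs(mean(est[stim < 0]) - stim[stim < 0][1]), 0.2)
  expect_gt(cor(est, stim), 0.97)
})

test_that("centralization matches its closed form and is median-zero", {
  m <- toy_matrix(matrix(c(1, 2, 3), 3, 1), "fpkm")
  cen <- centralize(m)
  expect_equal(unname(cen$values[, 1]), c(-1, 0, 1))  # median 2, SD 1
  sim <- tiny_sim(seed = 5)
  f <- fpkm(sim$counts, sim$gene_lengths)
  cc <- centralize(f)
  expect_lt(max(abs(apply(cc$values, 2, median))), 1e-12)
  # affine copies of a sample centralize identically
  x <- runif(50) * 10
  two <- toy_matrix(cbind(x, 3 * x + 7), "fpkm")
  cen2 <- centralize(two)
  expect_equal(cen2$values[, 1], cen2$values[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)
  flat <- toy_matrix(matrix(1, 3, 1), "fpkm")
  expect_error(centralize(flat), "degenerate")
})
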