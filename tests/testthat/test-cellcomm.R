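test_that("lr_table validates schema, uniqueness and vocabulary", {
  df <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                   category = c("Cytokines", "others"))
  expect_s3_class(lr_table(df), "LRTable")
  expect_error(lr_table(df[, 1:2]), "missing columns")
  expect_error(lr_table(rbind(df, df[1, ])), "duplicate")
  df$category[1] <- "Interleukins"
  expect_error(lr_table(df), "unknown category")
})

# one donor, one sender (Th), one receiver (B); 100 up-regulated genes with
# known ranks so the top-10% boundary is exact
lr_fixture <- function() {
  genes <- sprintf("g%03d", 1:201)
  rel_v <- matrix(c(seq(100, 1), rep(-1, 101),    # d1_Th: ranks 1..100 up
                    rep(0.5, 201)), 201, 2)       # d1_B: irrelevant sender
  rel <- toy_matrix(rel_v, "relative", genes = genes,
                    samples = c("d1_Th", "d1_B"))
  fp_v <- matrix(5, 201, 2)
  fp_v[201, ] <- 0.5                              # g201 not expressed
  fp <- toy_matrix(fp_v, "fpkm", genes = genes,
                   samples = c("d1_Th_aCD3", "d1_B_aCD3"))
  st <- sample_table(data.frame(
    sample_id = samples(fp), donor_id = "d1", group = "HD",
    cell_type = c("Th", "B"), condition = "aCD3"))
  list(rel = rel, fp = fp, st = st)
}

test_that("ligand top-10% and receptor-expression rules are exact", {
  fx <- lr_fixture()
  lr <- lr_table(data.frame(
    ligand = c("g005", "g010", "g011", "g005"),
    receptor = c("g150", "g150", "g150", "g201"),
    category = "Cytokines"))
  occ <- detect_interactions(fx$rel, fx$fp, fx$st, lr, senders = "Th")
  det <- occ$detections[occ$detections$receiver == "B", ]
  get <- function(l, r) det$detected[det$ligand == l & det$receptor == r]
  expect_true(get("g005", "g150"))    # rank 5 of 100 up genes
  expect_true(get("g010", "g150"))    # rank 10 = floor(0.1 * 100), in
  expect_false(get("g011", "g150"))   # rank 11, out
  expect_false(get("g005", "g201"))   # receptor below 1 FPKM
})

test_that("absent LR genes are skipped and detection is frac-monotone", {
  fx <- lr_fixture()
  lr <- lr_table(data.frame(ligand = c("g005", "NOPE"),
                            receptor = c("g150", "g150"),
                            category = "others"))
  expect_message(occ <- detect_interactions(fx$rel, fx$fp, fx$st, lr,
                                            senders = "Th"), "skipped")
  expect_false("NOPE" %in% occ$detections$ligand)
  # enlarging the top fraction never removes a detection
  sim <- tiny_sim(seed = 20)
  f <- fpkm(sim$counts, sim$gene_lengths)
  rel <- relative_expression(f, sim$samples)
  lr2 <- simulate_lr_table(sim$truth, 10, seed = 2)
  occ_a <- detect_interactions(rel$matrix, f, sim$samples, lr2,
                               ligand_top_fraction = 0.05)
  occ_b <- detect_interactions(rel$matrix, f, sim$samples, lr2,
                               ligand_top_fraction = 0.20)
  key <- function(d) paste(d$sender, d$receiver, d$ligand, d$donor)
  a <- occ_a$detections; b <- occ_b$detections
  expect_true(all(b$detected[match(key(a)[a$detected], key(b))]))
})

test_that("interaction Fisher test equals the enumeration oracle", {
  # the study's reference occurrence: 5/13 healthy vs 8/9 disease donors
  det <- data.frame(
    sender = "Th", receiver = "B", ligand = "L", receptor = "R",
    category = "Cytokines",
    donor = sprintf("d%02d", 1:22),
    group = rep(c("HD", "SLE"), c(13, 9)),
    detected = c(rep(c(TRUE, FALSE), c(5, 8)), rep(c(TRUE, FALSE), c(8, 1))))
  occ <- structure(list(detections = det, donors = unique(det$donor)),
                   class = "InteractionOccurrence")
  res <- interaction_group_test(occ, "HD", "SLE")
  tab <- matrix(c(5, 8, 8, 1), 2)
  expect_equal(res$p, oracle_fisher_two_sided(tab), tolerance = 1e-12)
  expect_equal(res$p, stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  expect_equal(res$direction, "up")
  # label swap keeps p, flips direction
  swap <- interaction_group_test(occ, "SLE", "HD")
  expect_equal(swap$p, res$p, tolerance = 1e-12)
  expect_equal(swap$direction, "down")
  # identical fractions -> p = 1
  det2 <- det
  det2$group <- rep(c("HD", "SLE"), each = 11)
  det2$detected <- rep(rep(c(TRUE, FALSE), c(5, 6)), 2)
  occ2 <- structure(list(detections = det2), class = "InteractionOccurrence")
  expect_equal(interaction_group_test(occ2, "HD", "SLE")$p, 1)
})

test_that("Fisher p equals enumeration for random small margins", {
  set.seed(21)
  for (i in 1:30) {
    m <- sample(2:30, 1); n <- sample(2:30, 1)
    k <- sample(1:(m + n - 1), 1)
    x <- max(0, k - n):min(k, m)
    x_obs <- sample(x, 1)
    tab <- matrix(c(x_obs, m - x_obs, k - x_obs, n - (k - x_obs)), 2)
    expect_equal(stats::fisher.test(tab)$p.value,
                 oracle_fisher_two_sided(tab), tolerance = 1e-12)
  }
})

test_that("communication-gene enrichment handles its boundary cases", {
  uni <- sprintf("u%03d", 1:100)
  comm <- uni[1:20]
  # up list = all communication genes -> smallest possible one-tail p
  res <- comm_gene_enrichment(comm, character(0), comm, uni)
  expect_equal(res$p[res$direction == "up"],
               1 / choose(100, 20), tolerance = 1e-12)
  expect_equal(res$p[res$direction == "down"], 1)  # empty list
  # up list disjoint from comm genes -> no evidence of enrichment
  res2 <- comm_gene_enrichment(uni[90:99], character(0), comm, uni)
  expect_gte(res2$p[res2$direction == "up"], 0.5)
})

test_that("compare_activity dispatches the test family by layer", {
  set.seed(22)
  v <- matrix(rnorm(3 * 12), 3, 12,
              dimnames = list(c("IL6", "TNF", "IFNG"),
                              sprintf("s%02d", 1:12)))
  st <- sample_table(data.frame(
    sample_id = colnames(v), donor_id = sprintf("d%02d", 1:12),
    group = rep(c("HD", "SLE"), each = 6), cell_type = "Th",
    condition = "steady"))
  steady <- compare_activity(activity_matrix(v, "steady"), st, "HD", "SLE")
  expect_true(all(steady$test == "wilcoxon"))
  stim <- compare_activity(activity_matrix(v, "stimulated"), st,
                           "HD", "SLE")
  expect_true(all(stim$test == "t"))
  # identical groups: Wilcoxon p = 1, t-statistic ~ 0
  v2 <- cbind(v[, 1:6], v[, 1:6])
  colnames(v2) <- sprintf("s%02d", 1:12)
  same <- compare_activity(activity_matrix(v2, "steady"), st, "HD", "SLE")
  expect_true(all(same$p == 1))
  expect_error(compare_activity(activity_matrix(v[, 1:5], "steady"),
                                st[1:5, ], "HD", "SLE"), "underpowered")
})

test_that("signature_activity projects target sets onto Z-scores", {
  sim <- tiny_sim(seed = 23)
  f <- fpkm(sim$counts, sim$gene_lengths)
  rel <- relative_expression(f, sim$samples)
  act <- signature_activity(rel$matrix,
                            list(STIM = names(sim$truth$stim_genes)),
                            layer = "stimulated")
  expect_equal(dim(act$values), c(1L, ncol(rel$matrix$values)))
  expect_equal(unname(rowMeans(act$values)), 0, tolerance = 1e-12)
})
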