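test_that("GMT write/read is the identity and parse errors are located", {
  cat0 <- gene_set_catalog(list(S1 = c("g1", "g2"), S2 = c("g3")),
                           description = c(S1 = "first", S2 = "second"))
  path <- tempfile(fileext = ".gmt"); on.exit(unlink(path))
  write_gmt(cat0, path)
  back <- read_gmt(path)
  expect_identical(back$sets, cat0$sets)
  expect_identical(unname(back$description[names(cat0$sets)]),
                   unname(cat0$description))
  writeLines(c("S1\td\tg1", "S1\td\tg2"), path)
  expect_error(read_gmt(path), "line 2.*duplicate|duplicate")
  writeLines("S1\tonly-two-fields", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("filter_sets applies the 3..500 bounds after universe reduction", {
  cat0 <- gene_set_catalog(list(
    too_small = c("a", "b"),
    at_max = sprintf("m%03d", 1:500),
    over_max = sprintf("o%03d", 1:501),
    shrunk = c("a", "b", "c", "zz")))   # zz unexpressed -> size 3
  uni <- c("a", "b", "c", sprintf("m%03d", 1:500), sprintf("o%03d", 1:501))
  kept <- filter_sets(cat0, uni, 3, 500)
  expect_setequal(names(kept$sets), c("at_max", "shrunk"))
  expect_equal(length(kept$sets$shrunk), 3L)
})

test_that("ora equals exhaustive enumeration on small universes", {
  uni <- sprintf("u%02d", 1:10)
  cat0 <- gene_set_catalog(list(S = uni[1:5]))
  res <- ora(uni[1:5], cat0, uni, min_size = 3, max_size = 300)
  expect_equal(res$p, 1 / choose(10, 5))   # = 1/252, all draws enumerated
  expect_equal(res$p, oracle_hyper_upper(5, 5, 10, 5), tolerance = 1e-12)
  # random small instances against the enumeration oracle
  set.seed(5)
  for (i in 1:25) {
    N <- sample(6:20, 1)
    K <- sample(3:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    uni <- sprintf("x%02d", seq_len(N))
    cat_i <- gene_set_catalog(list(S = uni[seq_len(K)]))
    query <- sample(uni, n)
    k <- length(intersect(query, uni[seq_len(K)]))
    p <- ora(query, cat_i, uni, min_size = 1, max_size = 300)$p
    expect_equal(p, oracle_hyper_upper(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("ora applies the size rule and zero-overlap convention", {
  uni <- sprintf("u%03d", 1:400)
  cat0 <- gene_set_catalog(list(
    tiny = uni[1:2],                     # < 3 in-universe -> forced p = 1
    oversize = uni[1:301],               # > 300 -> forced p = 1
    disjoint = uni[301:320],
    real = uni[1:20]))
  res <- ora(uni[1:20], cat0, uni)
  expect_equal(res$p[res$set == "tiny"], 1)
  expect_true(res$forced[res$set == "tiny"])
  expect_equal(res$p[res$set == "oversize"], 1)
  expect_equal(res$p[res$set == "disjoint"], 1)  # P(X >= 0) = 1
  expect_false(res$forced[res$set == "disjoint"])
  expect_lt(res$p[res$set == "real"], 1e-20)
  expect_warning(ora(c(uni[1:5], "absent"), cat0, uni), "outside")
  expect_error(ora("a", cat0, character(0)), "empty universe")
})

test_that("BH q-values are invariant to input row order", {
  set.seed(6)
  uni <- sprintf("u%03d", 1:200)
  sets <- lapply(1:12, function(i) sample(uni, sample(5:50, 1)))
  names(sets) <- sprintf("S%02d", 1:12)
  query <- sample(uni, 30)
  r1 <- ora(query, gene_set_catalog(sets), uni)
  perm <- sample(length(sets))
  r2 <- ora(query, gene_set_catalog(sets[perm]), uni)
  expect_equal(r1$q[match(r2$set, r1$set)], r2$q)
})

test_that("activity classification follows the clinical banding", {
  expect_equal(classify_activity(1)$class, "Low")
  expect_equal(classify_activity(3)$class, "Low")
  expect_equal(classify_activity(4)$class, "Moderate")
  expect_equal(classify_activity(7)$class, "Moderate")
  expect_equal(classify_activity(8)$class, "High")
  expect_equal(classify_activity(14)$class, "High")
  z <- classify_activity(0)
  expect_equal(z$class, "Low")
  expect_true(z$zero_score)
  expect_error(classify_activity(-1), ">= 0")
  # the High boundary is configurable
  expect_equal(classify_activity(8, high_cutoff = 9)$class, "Moderate")
})

test_that("ks_regscore matches the brute-force CDF oracle", {
  vals <- c(a = 3, b = 4, c = 1, d = 2)
  r <- ks_regscore(vals, c("a", "b"))
  expect_equal(r$D, 1)                       # complete separation, set high
  vals2 <- c(a = 1, b = 3, c = 2, d = 4)
  r2 <- ks_regscore(vals2, c("a", "b"))
  expect_equal(abs(r2$D), 0.5)
  expect_equal(r2$D, oracle_ks_signed(vals2[c("a", "b")],
                                      vals2[c("c", "d")]))
  set.seed(7)
  for (i in 1:50) {
    n <- sample(6:60, 1)
    vals <- stats::setNames(rnorm(n), sprintf("g%03d", seq_len(n)))
    m <- sample(2:(n - 2), 1)
    set <- sample(names(vals), m)
    r <- ks_regscore(vals, set)
    expect_equal(r$D, oracle_ks_signed(vals[set], vals[setdiff(names(vals),
                                                               set)]),
                 tolerance = 1e-12)
  }
  expect_error(ks_regscore(stats::setNames(rep(1, 5), letters[1:5]), "a"),
               "degenerate|no variation")
})

test_that("ks_regscore is near zero for random subsets", {
  set.seed(8)
  vals <- stats::setNames(rnorm(500), sprintf("g%03d", 1:500))
  Ds <- replicate(200, ks_regscore(vals, sample(names(vals), 100))$abs_D)
  expect_lt(mean(Ds), 0.12)
  expect_gt(mean(replicate(
    200, ks_regscore(vals, sample(names(vals), 10))$p) > 0.05), 0.7)
})

test_that("activity_profile orders classes and excludes unscored donors", {
  sim <- simulate_dataset(simulation_config(seed = 12))
  f <- fpkm(sim$counts, sim$gene_lengths)
  cen <- centralize(f[, intersect(
    sim$samples$sample_id[sim$samples$condition == "steady"],
    samples(f))])
  cat0 <- filter_sets(simulate_genesets(sim$truth, 5, seed = 1),
                      genes(cen), 3, 500)
  reg <- activity_profile(cen, sim$samples, cat0)
  expect_false("HD" %in% reg$group)
  expect_true(all(levels(reg$activity_class) ==
                    c("Low", "Moderate", "High")))
  # monotone default effect: planted IFN set rises Low -> High (SLE, Th)
  sub <- reg[reg$set == "IFN_TYPE_I_SYNTH" & reg$group == "SLE" &
               reg$cell_type == "Th", ]
  expect_equal(as.character(sub$activity_class),
               c("Low", "Moderate", "High"))
  expect_true(all(diff(sub$D) > 0))
})

test_that("driver_genes ranks by consecutive-class sensitivity", {
  # 3 classes x 4 samples each; gene dA moves 10x more than the others
  classes <- rep(c("Low", "Moderate", "High"), each = 4)
  v <- matrix(rnorm(10 * 12, sd = 0.01), 10, 12)
  shift <- c(Low = 0, Moderate = 5, High = 10)
  v[1, ] <- v[1, ] + shift[classes]
  v[2, ] <- v[2, ] + shift[classes] / 10
  m <- toy_matrix(v, "centralized",
                  genes = c("dA", "dB", sprintf("n%02d", 1:8)))
  st <- sample_table(data.frame(
    sample_id = samples(m), donor_id = sprintf("d%02d", 1:12),
    group = "SLE", cell_type = "Th", condition = "steady",
    activity_score = c(1, 1, 2, 3, 5, 5, 6, 7, 9, 10, 11, 12)[order(classes,
      decreasing = FALSE) * 0 + seq_len(12)],
    activity_class = classes))
  top <- driver_genes(m, st, genes(m), top_fraction = 0.10)
  expect_equal(top, "dA", ignore_attr = TRUE)
  # a constant gene has zero sensitivity and is never selected
  sens <- attr(driver_genes(m, st, genes(m), top_fraction = 1),
               "sensitivity")
  expect_lt(sens[["n05"]], 0.1)
  expect_equal(names(sens)[1], "dA")
  expect_error(driver_genes(m, st[st$activity_class == "Low", ], genes(m)),
               "2 populated")
})
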