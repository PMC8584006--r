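test_that("fold change and t-test have the stated closed forms", {
  q <- make_quant(list(
    s1 = list(A = c(8, 8, 8), B = c(8, 8, 8)),       # identical vectors
    s2 = list(A = c(4, 4, 4), B = c(2, 2, 2)),       # exact doubling
    s3 = list(A = c(10, 12, 14), B = c(10, 12, 14))  # same mean and spread
  ))
  r <- log2_ratio_and_test(q, c("A", "B"))
  expect_equal(r$log2fc[1], 0)
  expect_equal(r$p[1], 1)
  expect_equal(r$log2fc[2], 1)
  expect_equal(r$p[2], 0)   # zero variance, nonzero difference
  expect_equal(r$log2fc[3], 0)
  expect_equal(r$p[3], 1)

  # agrees with stats::t.test on generic data
  set.seed(1)
  q2 <- make_quant(list(s1 = list(A = 2^rnorm(3, 10), B = 2^rnorm(3, 9))))
  r2 <- log2_ratio_and_test(q2, c("A", "B"))
  tt <- t.test(log2(q2$intensities[1, 1:3]), log2(q2$intensities[1, 4:6]),
               var.equal = TRUE)
  expect_equal(r2$p, tt$p.value)
  rw <- log2_ratio_and_test(q2, c("A", "B"), var_equal = FALSE)
  tw <- t.test(log2(q2$intensities[1, 1:3]), log2(q2$intensities[1, 4:6]))
  expect_equal(rw$p, tw$p.value)

  one_rep <- quant_table(matrix(c(1, 2, 3), 1, 3,
                                dimnames = list("s", c("a1", "a2", "b1"))),
                         c(a1 = "A", a2 = "A", b1 = "B"))
  expect_error(log2_ratio_and_test(one_rep, c("A", "B")), "2 replicates")
})

test_that("classification applies the dual ratio/p gate with >= boundaries", {
  expect_identical(classify(log2(2.0), 0.01), "up")
  expect_identical(classify(0, 0.0001), "ns")
  # boundary enumeration of the four (ratio, p) quadrants
  grid <- expand.grid(lfc = c(log2(1.5), log2(1.5) - 1e-9, -log2(1.5),
                              -log2(1.5) + 1e-9, 0),
                      p = c(0.049, 0.05, 0.2))
  got <- classify(grid$lfc, grid$p)
  want <- ifelse(grid$p < 0.05 & grid$lfc >= log2(1.5), "up",
                 ifelse(grid$p < 0.05 & grid$lfc <= -log2(1.5), "down", "ns"))
  expect_identical(got, want)
  expect_identical(classify(log2(1.5), 0.049), "up")
  expect_identical(classify(log2(1.5), 0.05), "ns")

  # monotone: raising p or shrinking |log2fc| never creates a call
  set.seed(2)
  lfc <- rnorm(200); p <- runif(200)
  s1 <- classify(lfc, p)
  s2 <- classify(lfc * 0.9, pmin(1, p * 1.2))
  expect_true(all(!(s1 == "ns" & s2 != "ns")))
})

test_that("null simulation gives uniform p-values and controlled type-I error", {
  cfg <- sim_config(seed = 23, n_proteins = 600, planted_activities = list(),
                    substrates_per_kinase = 5)
  st <- simulate_phospho_study(cfg)
  d <- phospho_diff(st$quant, c("AC-B4", "AC-MG"))
  expect_gt(suppressWarnings(ks.test(d$p, "punif"))$p.value, 0.01)
  alpha <- attr(d, "alpha")
  bound <- alpha + 3 * sqrt(alpha * (1 - alpha) / nrow(d))
  expect_lte(mean(d$status != "ns"), bound)
  # q-values are reported but selection uses raw p
  expect_equal(d$q, p.adjust(d$p, "BH"))
})

test_that("residue distribution reproduces printed percentages and a tally oracle", {
  res <- residue_distribution(rep(c("S", "T", "Y"), c(4017, 592, 233)))
  expect_equal(res$percent, c(83, 12, 5))
  expect_equal(sum(res$count), 4842)

  single <- residue_distribution("S")
  expect_equal(single$percent, c(100, 0, 0))

  set.seed(3)
  for (i in 1:20) {
    v <- sample(c("S", "T", "Y"), sample(5:500, 1), replace = TRUE,
                prob = c(0.7, 0.2, 0.1))
    got <- residue_distribution(v)
    want <- vapply(c("S", "T", "Y"), function(r) {
      floor(100 * sum(v == r) / length(v) + 0.5)   # independent tally + round
    }, numeric(1))
    expect_equal(got$percent, unname(want))
  }
})

test_that("sites-per-protein histogram reproduces printed percentages", {
  sites <- data.frame(protein_id = c(
    rep(sprintf("a%04d", 1:1306), 1),
    rep(sprintf("b%04d", 1:505), 2),
    rep(sprintf("c%04d", 1:426), 3),
    rep(sprintf("d%04d", 1:90), 7)))
  h <- sites_per_protein_histogram(sites)
  expect_equal(h$count, c(1306, 505, 516, 90))
  expect_equal(h$percent[1:3], c(56.1, 21.7, 22.2))

  h1 <- sites_per_protein_histogram(data.frame(protein_id = letters))
  expect_equal(h1$percent, c(100, 0, 0, 0))

  # fuzz against a brute-force group-and-count oracle
  set.seed(4)
  for (i in 1:20) {
    s <- data.frame(protein_id = sample(sprintf("p%02d", 1:40),
                                        sample(40:300, 1), replace = TRUE))
    h <- sites_per_protein_histogram(s)
    per <- as.integer(table(s$protein_id))
    expect_equal(h$count, c(sum(per == 1), sum(per == 2), sum(per >= 3),
                            sum(per >= 7)))
    expect_equal(sum(h$count[1:3]), length(per))
  }
})

test_that("overlap counts equal set algebra on every Venn cell", {
  mk <- function(ids) data.frame(site_id = ids,
                                 status = rep("up", length(ids)))
  same <- list(A = mk(letters[1:5]), B = mk(letters[1:5]), C = mk(letters[1:5]))
  oc <- overlap_counts(same)
  expect_equal(unname(oc["A&B&C"]), 5)
  expect_equal(sum(oc[c("A", "B", "C")]), 0)

  disj <- list(A = mk(letters[1:3]), B = mk(letters[4:6]), C = mk(letters[7:9]))
  expect_equal(unname(overlap_counts(disj)["A&B&C"]), 0)

  set.seed(5)
  for (i in 1:25) {
    sets <- lapply(1:3, function(j) sample(letters, sample(0:15, 1)))
    names(sets) <- c("A", "B", "C")
    oc <- overlap_counts(sets)
    # inclusion-exclusion oracle on explicit membership
    u <- unique(unlist(sets))
    inA <- u %in% sets$A; inB <- u %in% sets$B; inC <- u %in% sets$C
    expect_equal(unname(oc["A"]), sum(inA & !inB & !inC))
    expect_equal(unname(oc["B"]), sum(!inA & inB & !inC))
    expect_equal(unname(oc["C"]), sum(!inA & !inB & inC))
    expect_equal(unname(oc["A&B"]), sum(inA & inB & !inC))
    expect_equal(unname(oc["A&C"]), sum(inA & !inB & inC))
    expect_equal(unname(oc["B&C"]), sum(!inA & inB & inC))
    expect_equal(unname(oc["A&B&C"]), sum(inA & inB & inC))
  }
})

test_that("union accounting matches explicit set construction", {
  expect_equal(union_size(6965, 2327, 1436), 7856)
  expect_equal(union_size(10, 0, 0), 10)
  expect_error(union_size(5, 3, 4), "n_shared")
  set.seed(6)
  for (i in 1:20) {
    a <- sample(1000, sample(50:200, 1))
    b <- c(sample(a, sample(0:min(30, length(a)), 1)), sample(2000:3000, 40))
    b <- unique(b)
    expect_equal(union_size(length(a), length(b), length(intersect(a, b))),
                 length(union(a, b)))
  }
})
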