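# brute-force running-sum oracle: explicit loop over the ranked list
es_oracle <- function(ranked, set, weight = 1) {
  N <- length(ranked)
  hits <- names(ranked) %in% set
  nh <- sum(hits)
  w <- abs(ranked)^weight
  denom <- sum(w[hits])
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hits[i]) {
      cur + (if (denom > 0) w[i] / denom else 1 / nh)
    } else {
      cur - 1 / (N - nh)
    }
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

ranked_fixture <- function(n, seed) {
  set.seed(seed)
  v <- rnorm(n)
  names(v) <- sprintf("s%03d", seq_len(n))
  v[order(-v, names(v), method = "radix")]
}

test_that("rank metrics order by value with lexicographic tie-break", {
  d <- structure(data.frame(site_id = c("b", "a", "c"), log2fc = c(0, 0, 0),
                            ratio = 1, p = 1, q = 1, status = "ns"),
                 comparison = c("X", "Y"), class = c("phos_diff", "data.frame"))
  expect_identical(names(rank_metric(d)), c("a", "b", "c"))

  d2 <- structure(data.frame(site_id = c("a", "b", "c"), log2fc = c(0, 2, -1),
                             ratio = 1, p = 1, q = 1, status = "ns"),
                  comparison = c("X", "Y"), class = c("phos_diff", "data.frame"))
  expect_identical(names(rank_metric(d2)), c("b", "a", "c"))

  # per-sample mode: z-scored log2 intensity across sites
  q <- make_quant(list(s1 = list(A = c(8, 8), B = c(1, 1)),
                       s2 = list(A = c(2, 2), B = c(1, 1)),
                       s3 = list(A = c(4, 4), B = c(1, 1))))
  r <- rank_metric(q, sample = "A_R1")
  expect_identical(names(r), c("s1", "s3", "s2"))
  l <- log2(q$intensities[, "A_R1"])
  expect_equal(unname(r["s1"]), unname((l - mean(l))[1] / sd(l)))
  expect_error(rank_metric(q, sample = "nope"), "sample")
})

test_that("enrichment score has the stated extremes and matches the oracle", {
  r <- ranked_fixture(10, 13)
  # every site a substrate: running sum peaks at +1
  expect_equal(enrichment_score(r, names(r))$es, 1)
  # singleton substrate at the exact bottom, unweighted: full -1 excursion
  expect_equal(enrichment_score(r, names(r)[10], weight_exponent = 0)$es, -1)
  expect_error(enrichment_score(r, "absent"), "intersect")

  set.seed(14)
  for (i in 1:500) {
    r <- ranked_fixture(8, 1000 + i)
    set <- sample(names(r), 3)
    w <- sample(c(0, 1), 1)
    got <- enrichment_score(r, set, w)
    want <- es_oracle(r, set, w)
    expect_equal(abs(got$es), abs(want), tolerance = 1e-12)
    # sign is only determined when max and min excursions do not tie
    rs <- got$running_sum
    if (abs(max(rs) + min(rs)) > 1e-9) {
      expect_equal(got$es, want, tolerance = 1e-12)
    }
  }
})

test_that("enrichment score agrees with the fgsea statistic", {
  skip_if_not_installed("fgsea")
  set.seed(15)
  for (i in 1:20) {
    r <- ranked_fixture(50, 2000 + i)
    set <- sample(names(r), 6)
    es <- enrichment_score(r, set, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(unname(r), which(names(r) %in% set),
                               gseaParam = 1)
    expect_equal(es, ref, tolerance = 1e-9)
  }
})

test_that("unweighted ES is rank-invariant and negates under list reversal", {
  r <- ranked_fixture(40, 16)
  set <- sample(names(r), 5)
  es0 <- enrichment_score(r, set, weight_exponent = 0)$es
  # strictly monotone transform of the values leaves ES unchanged at weight 0
  r2 <- sort(exp(r) + 3, decreasing = TRUE)
  expect_equal(enrichment_score(r2, set, weight_exponent = 0)$es, es0)
  # reversing the ranked list negates ES exactly at weight 0
  rrev <- rev(r)
  expect_equal(enrichment_score(rrev, set, weight_exponent = 0)$es, -es0)
})

test_that("permutation normalisation is seeded and handles the null score", {
  r <- ranked_fixture(100, 17)
  set <- sample(names(r), 5)
  es <- enrichment_score(r, set)$es
  a <- normalize_and_test(es, r, set, n_permutations = 200, seed = 5)
  b <- normalize_and_test(es, r, set, n_permutations = 200, seed = 5)
  expect_identical(a, b)
  expect_equal(sign(a$nes), sign(es))
  z <- normalize_and_test(0, r, set, n_permutations = 200, seed = 5)
  expect_equal(z$nes, 0)
  expect_equal(z$p_perm, 1)
  expect_error(normalize_and_test(es, r, set, n_permutations = 10), "100")
})

test_that("a strongly activated kinase is significant across seeds", {
  r <- ranked_fixture(1000, 18)
  top <- names(r)[sample(100, 10)]    # all substrates in the top decile
  es <- enrichment_score(r, top)$es
  expect_gt(es, 0)
  for (seed in 1:20) {
    nt <- normalize_and_test(es, r, top, n_permutations = 1000, seed = seed)
    expect_lte(nt$p_perm, 0.01)
    expect_gte(nt$nes, 1)
  }
})

test_that("state classification uses the symmetric NES threshold", {
  expect_identical(classify_state(c(1.8, -1.8, 0.4, -0.4, 1, -1, 0, NA)),
                   c("activated", "inhibited", "indeterminate", "indeterminate",
                     "activated", "inhibited", "indeterminate", "indeterminate"))
})

test_that("ksea recovers planted kinase states on a synthetic study", {
  st <- simulate_phospho_study(sim_config(seed = 19))
  d <- phospho_diff(st$quant, c("AC-B4", "AC-MG"))
  fit <- ksea(d, st$truth$edges, n_permutations = 500, seed = 2)
  m <- merge(fit$table, st$truth$kinases, by = "kinase")
  planted <- m[m$state.y != "null", ]
  expect_equal(nrow(planted), 5)
  expect_true(all(planted$state.x == planted$state.y))
  expect_true(all(planted$p_perm < 0.05))
  # skipped kinases are reported, not silently dropped
  expect_equal(nrow(fit$table) + nrow(fit$skipped),
               length(unique(st$truth$edges$kinase)))
  # comparison-mode ranking equals sorting the differential table externally
  ext <- d$log2fc[order(-d$log2fc, d$site_id, method = "radix")]
  expect_equal(unname(fit$ranked), ext)
})

test_that("ksea accessors expose scores and summaries", {
  st <- small_study(seed = 20)
  d <- phospho_diff(st$quant, c("AC-B4", "AC-MG"))
  fit <- ksea(d, st$truth$edges, n_permutations = 200, seed = 2)
  expect_named(coef(fit), fit$table$kinase)
  s <- summary(fit, top_k = 3)
  expect_lte(nrow(s$activated), 3)
  expect_true(all(s$activated$state == "activated"))
  expect_output(print(fit), "KSEA")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
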