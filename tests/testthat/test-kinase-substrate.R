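# independent scorer: double loop over exemplars and positions
score_oracle <- function(exemplars, window) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  tot <- 0
  for (ex in exemplars) {
    for (j in 1:13) {
      a <- substring(window, j, j); b <- substring(ex, j, j)
      if (a != "_" && b != "_") tot <- tot + B[a, b]
    }
  }
  tot / length(exemplars)
}

test_that("similarity scoring matches self-similarity, pads and the oracle", {
  ex <- make_windows(1, "S", fixed = list(`1` = "P"))
  kp <- kinase_profile("K1", ex)
  B <- local({e <- new.env()
              utils::data("BLOSUM62", package = "Biostrings", envir = e)
              e$BLOSUM62})
  self <- sum(diag(B[strsplit(ex, "")[[1]], strsplit(ex, "")[[1]]]))
  expect_equal(score_site(kp, ex), self)

  pad_only <- paste0(strrep("_", 6), "S", strrep("_", 6))
  kp_pad <- kinase_profile("K2", "AAAAAASAAAAAA")
  expect_equal(score_site(kp_pad, strrep("_", 13)), 0)
  expect_equal(score_site(kp_pad, pad_only), unname(B["S", "S"]))

  set.seed(21)
  kp3 <- kinase_profile("K3", make_windows(4, "S"))
  for (i in 1:20) {
    w <- make_windows(1, "S")
    expect_equal(score_site(kp3, w), score_oracle(kp3$exemplar_windows, w))
  }
  expect_error(kinase_profile("K", character(0)), "exemplar")
})

test_that("threshold calibration hits the requested background pass rate", {
  set.seed(22)
  kp <- kinase_profile("K1", make_windows(5, "S", fixed = list(`1` = "P",
                                                               `-3` = "R")))
  bg <- make_windows(10000, "S")
  all_pass <- calibrate_threshold(kp, bg, fpr = 1)
  sc <- phosflow:::score_windows(kp, bg)
  expect_equal(all_pass$threshold, min(sc))
  none <- calibrate_threshold(kp, bg, fpr = 1e-9)
  expect_equal(none$threshold, max(sc))

  cal <- calibrate_threshold(kp, bg, fpr = 0.05)
  fresh <- make_windows(10000, "S")
  realized <- mean(phosflow:::score_windows(kp, fresh) >= cal$threshold)
  expect_lt(abs(realized - 0.05), 0.007)
  expect_error(calibrate_threshold(kp, make_windows(50, "S")), "200")
})

test_that("PPI filtering is a subset operation and fpr is anti-monotone", {
  st <- simulate_phospho_study(
    sim_config(seed = 23, n_proteins = 300, n_kinases = 5,
               motif_library = multi_determinant_motif_library(5),
               substrates_per_kinase = 10))
  bg <- unlist(lapply(c("S", "T", "Y"), function(r)
    proteome_windows(st$proteome, r)))
  profs <- lapply(split(st$exemplars, st$exemplars$kinase_id), function(d)
    kinase_profile(d$kinase_id[1], d$window))

  cal05 <- lapply(profs, calibrate_threshold, background_windows = bg, fpr = 0.05)
  cal01 <- lapply(profs, calibrate_threshold, background_windows = bg, fpr = 0.01)
  all_rel <- predict_relations(cal05, st$sites, st$ppi, require_ppi = FALSE)
  ppi_rel <- predict_relations(cal05, st$sites, st$ppi, require_ppi = TRUE)
  strict <- predict_relations(cal01, st$sites, st$ppi, require_ppi = FALSE)
  key <- function(d) paste(d$kinase_id, d$site_id)
  expect_true(all(key(ppi_rel) %in% key(all_rel)))
  expect_true(all(key(strict) %in% key(all_rel)))

  # empty PPI with the filter on leaves only kinase self-substrates
  none <- predict_relations(cal05, st$sites,
                            data.frame(protein_a = character(0),
                                       protein_b = character(0)),
                            require_ppi = TRUE)
  prot_of <- st$sites$protein_id[match(none$site_id, st$sites$site_id)]
  expect_true(all(prot_of == none$kinase_id))
  expect_error(predict_relations(profs, st$sites, st$ppi), "not calibrated")
})

test_that("planted kinase-substrate relations are recovered accurately", {
  st <- simulate_phospho_study(
    sim_config(seed = 24, n_proteins = 600, n_kinases = 10,
               motif_library = multi_determinant_motif_library(10),
               substrates_per_kinase = 15))
  bg <- unlist(lapply(c("S", "T", "Y"), function(r)
    proteome_windows(st$proteome, r)))
  profs <- lapply(split(st$exemplars, st$exemplars$kinase_id), function(d)
    kinase_profile(d$kinase_id[1], d$window))
  profs <- lapply(profs, calibrate_threshold, background_windows = bg,
                  fpr = 0.05)
  rel <- predict_relations(profs, st$sites, st$ppi, require_ppi = TRUE)
  truth_keys <- paste(st$truth$edges$kinase, st$truth$edges$site_id)
  pred_keys <- paste(rel$kinase_id, rel$site_id)
  expect_gte(mean(pred_keys %in% truth_keys), 0.8)   # precision
  expect_gte(mean(truth_keys %in% pred_keys), 0.8)   # recall
})

test_that("catalogue census reproduces printed percentages and a tally oracle", {
  set.seed(26)
  catalogue <- data.frame(
    protein_id = sprintf("K%04d", 1:1137),
    family = sample(c("AGC", "CAMK", "CK1", "CMGC", "STE", "TKL", "RLK"),
                    1137, replace = TRUE))
  detected <- c(sprintf("K%04d", 1:196), sprintf("X%04d", 1:2131))
  cen <- kinase_census(detected, catalogue)
  expect_equal(cen$n_detected_members, 196)
  expect_equal(cen$pct_of_detected, 8.4)    # 196 / 2327
  expect_equal(cen$pct_of_catalogue, 17.2)  # 196 / 1137

  # phosphatase-style family shares: 5 of 11 detected members are STPP
  pcat <- data.frame(protein_id = sprintf("P%02d", 1:40),
                     family = rep(c("STPP", "PP2A", "PP2C", "PBMP"), 10))
  pdet <- c(sprintf("P%02d", c(1, 5, 9, 13, 17)),   # 5 STPP
            sprintf("P%02d", c(2, 3, 4, 6, 7, 8)))  # 6 others
  pc <- kinase_census(pdet, pcat)
  expect_equal(pc$families$share_of_detected[pc$families$family == "STPP"], 45.5)

  set.seed(25)
  for (i in 1:10) {
    cat2 <- data.frame(protein_id = sprintf("q%03d", 1:80),
                       family = sample(LETTERS[1:4], 80, replace = TRUE))
    det2 <- sample(sprintf("q%03d", 1:120), 50)
    cen2 <- kinase_census(det2, cat2)
    for (f in cen2$families$family) {
      members <- cat2$protein_id[cat2$family == f]
      expect_equal(cen2$families$detected[cen2$families$family == f],
                   length(intersect(det2, members)))
    }
    expect_equal(cen2$n_detected_members,
                 length(intersect(det2, cat2$protein_id)))
  }
})
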