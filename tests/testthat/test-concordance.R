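test_that("eligibility filter applies abundance, presence, both-cohort and chromosome rules", {
  ids <- c("ok", "low_rpm", "one_cohort", "chrY_gene")
  vals <- matrix(0.19, 4, 20, dimnames = list(ids, paste0("s", 1:20)))
  cohA <- paste0("s", 1:10); cohB <- paste0("s", 11:20)
  vals["ok", c(1:2, 11:12)] <- 0.2            # 2/10 > 10% in both cohorts
  vals["low_rpm", ] <- 0.19                   # never reaches 0.2
  vals["one_cohort", 1:5] <- 5                # abundant in cohort A only
  vals["chrY_gene", ] <- 100
  em <- expression_matrix(vals, "RPM",
                          feature_meta = data.frame(
                            chrom = c("chr1", "chr1", "chr2", "chrY")))
  elig <- de_eligibility_filter(em, list(A = cohA, B = cohB))
  expect_identical(elig, "ok")
  # strict >10%: 1/10 samples is not enough, 2/10 is
  vals2 <- matrix(0, 2, 10, dimnames = list(c("a", "b"), paste0("s", 1:10)))
  vals2["a", 1] <- 1; vals2["b", 1:2] <- 1
  em2 <- expression_matrix(vals2, "RPM")
  expect_identical(de_eligibility_filter(em2, list(all = paste0("s", 1:10))), "b")
  # circRNA count threshold
  cvals <- matrix(4L, 1, 10, dimnames = list("circ1", paste0("s", 1:10)))
  emc <- expression_matrix(cvals, "count")
  expect_length(de_eligibility_filter(emc, list(all = paste0("s", 1:10))), 0)
  expect_error(de_eligibility_filter(
    expression_matrix(vals2, "TPM"), list(all = paste0("s", 1:10))),
    class = "placentatools_unit_mismatch")
})

test_that("bootstrap fold changes are exactly 1 under case == control", {
  set.seed(101)
  m <- matrix(rexp(50 * 6), 50, 6, dimnames = list(paste0("t", 1:50), NULL))
  b <- bootstrap_fold_changes(m, m, n_boot = 50, seed = 3)
  expect_equal(unname(b$fc), rep(1, 50))
  expect_equal(unname(b$log2_fc), rep(0, 50))
  expect_true(all(b$n_dropped == 0))
})

test_that("bootstrap fold changes match an independent re-implementation on the same stream", {
  set.seed(102)
  case <- matrix(rexp(30 * 20, 0.5), 30, 20, dimnames = list(paste0("t", 1:30), NULL))
  ctl <- matrix(rexp(30 * 20, 0.5), 30, 20, dimnames = list(paste0("t", 1:30), NULL))
  ctl[3, ] <- 0   # transcript with undefined FC in every replicate
  b <- bootstrap_fold_changes(case, ctl, n_boot = 200, seed = 7)
  oracle <- oracle_bootstrap_fc(case, ctl, n_boot = 200, seed = 7)
  expect_identical(b$fc, oracle)
  expect_equal(unname(b$n_dropped["t3"]), 200)
  expect_true(is.na(b$fc["t3"]))
})

test_that("bootstrap recovers planted two-fold effects within Monte-Carlo error", {
  sim <- simulate_paired_cohort(n_pairs_a = 82, n_pairs_b = 40, n_features = 300,
                                planted_up_a = 30, planted_up_b = 30,
                                overlap_frac = 0.5, effect_log2 = 1,
                                noise_sigma = 0.25, seed = 202)
  ca <- sim$cohort_a
  case <- sim$matrix$values[, ca$sample_id[ca$role == "case"]]
  ctl <- sim$matrix$values[, ca$sample_id[ca$role == "control"]]
  b <- bootstrap_fold_changes(case, ctl, n_boot = 2000, seed = 5)
  planted <- sim$truth$params$planted_a
  for (t in planted[1:10]) {
    # sampling noise across pairs dominates; 3 SE on the pairwise mean ratio
    se <- sd(case[t, ] / ctl[t, ]) / sqrt(ncol(case))
    expect_lt(abs(b$fc[t] - 2), 3 * max(se, b$mc_se[t]))
  }
  bg <- setdiff(rownames(case), planted)
  expect_lt(abs(mean(b$fc[bg]) - 1), 0.05)
})

test_that("top-ranked selection reproduces the worked subset arithmetic", {
  set.seed(103)
  n <- 15257
  lfc <- setNames(rnorm(n, 0, 0.5), sprintf("t%05d", 1:n))
  ab <- setNames(rexp(n), names(lfc))
  ts5 <- select_top_ranked(lfc, ab, top_frac = 0.05)
  expect_equal(ts5$k_abund, 5000L)
  expect_length(ts5$ids, 250L)
  ts3 <- select_top_ranked(lfc, ab, top_frac = 0.03)
  expect_length(ts3$ids, 150L)
  # ratio 1, top_frac 1 selects everything
  all_sel <- select_top_ranked(lfc, ab, abundance_subset_ratio = 1, top_frac = 1)
  expect_length(all_sel$ids, n)
  # signs carry the fold-change direction
  expect_true(all(ts5$signs == ifelse(lfc[ts5$ids] >= 0, 1, -1)))
})

test_that("top-ranked selection breaks ties by ID and ignores input order", {
  lfc <- c(b = 1, a = 1, c = -1, d = 0.5, e = -0.2, f = 0.1)
  ab <- setNames(rep(1, 6), names(lfc))
  sel <- select_top_ranked(lfc, ab, abundance_subset_ratio = 1, top_frac = 0.5)
  expect_identical(sel$ids, c("a", "b", "c"))  # |1|,|1|,|-1|: a before b by ID
  perm <- c("f", "c", "a", "e", "b", "d")
  sel2 <- select_top_ranked(lfc[perm], ab[perm], abundance_subset_ratio = 1,
                            top_frac = 0.5)
  expect_identical(sel2$ids, sel$ids)
})

test_that("overlap concordance builds the printed matrix geometry", {
  mk_set <- function(ids, signs, background) {
    structure(list(ids = ids, signs = setNames(signs, ids),
                   k_abund = length(background), abundance_ids = background,
                   top_frac = NA), class = "top_set")
  }
  bg <- sprintf("t%04d", 1:5214)
  a <- mk_set(bg[1:250], rep(1, 250), bg)
  b_ids <- c(bg[1:92], bg[3000:3157])
  b <- mk_set(b_ids, c(rep(1, 92), rep(-1, 158)), bg)
  res <- overlap_concordance_test(a, b)
  expect_equal(res$n_same, 92)
  expect_equal(res$table, matrix(c(92, 158, 158, 4806), 2, 2, byrow = TRUE))
  expect_equal(signif(res$p, 3), 3.98e-62)
  # identical sets, identical signs: maximal sharing
  full <- overlap_concordance_test(a, a)
  expect_equal(full$n_same, 250)
  expect_lt(full$p, res$p)
  # small disjoint sets from a small background: P near 1 (enumeration oracle)
  bg20 <- sprintf("x%02d", 1:20)
  s1 <- mk_set(bg20[1:3], rep(1, 3), bg20)
  s2 <- mk_set(bg20[4:6], rep(1, 3), bg20)
  res0 <- overlap_concordance_test(s1, s2)
  expect_equal(res0$p, oracle_fisher_2x2(0, 3, 3, 14))
  expect_gt(res0$p, 0.5)
})

test_that("fisher_exact_2x2 matches hand enumeration and stats::fisher.test", {
  # (2,1;1,2): five tables with probs 1/20, 9/20, 9/20, 1/20 (x = 0..3) -> P = 1
  expect_equal(fisher_exact_2x2(matrix(c(2, 1, 1, 2), 2, 2)), 1.0)
  # extreme table requires log-space point masses
  p <- fisher_exact_2x2(matrix(c(92, 158, 158, 4806), 2, 2, byrow = TRUE))
  expect_equal(p, fisher.test(matrix(c(92, 158, 158, 4806), 2, 2,
                                     byrow = TRUE))$p.value,
               tolerance = 1e-10)
  expect_equal(signif(fisher_exact_2x2(matrix(c(17, 99, 6, 283), 2, 2,
                                              byrow = TRUE)), 2), 4.6e-6)
  # zero margin
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2, 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2, 2)),
               class = "placentatools_negative_cell")
})

test_that("BH adjustment matches the step-up recipe", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(104)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "placentatools_bad_p")
})

test_that("correlation screen matches the rank-transform oracle and applies thresholds", {
  set.seed(105)
  n <- 8
  A <- matrix(rnorm(3 * n), 3, n, dimnames = list(c("m1", "m2", "m3"), paste0("s", 1:n)))
  B <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("g1", "g2"), paste0("s", 1:n)))
  scr <- correlation_screen(A, B, rho_threshold = 0)
  for (i in rownames(A)) for (j in rownames(B)) {
    expect_equal(scr$rho[i, j], oracle_spearman(A[i, ], B[j, ]),
                 tolerance = 1e-12)
  }
  # identity: x vs x
  self <- correlation_screen(A, A["m1", , drop = FALSE], rho_threshold = 0.9)
  expect_equal(self$rho["m1", "m1"], 1)
  # threshold removes weak pairs
  A2 <- rbind(x = 1:8)
  colnames(A2) <- paste0("s", 1:8)
  B2 <- rbind(weak = c(2, 8, 1, 7, 3, 6, 4, 5))
  colnames(B2) <- paste0("s", 1:8)
  rho <- cor(1:8, B2[1, ], method = "spearman")
  expect_lt(abs(rho), 0.4)  # fixture has a sub-threshold correlation
  scr2 <- correlation_screen(A2, B2, rho_threshold = 0.4)
  expect_equal(nrow(scr2$pairs), 0)
  # constant vectors report NA, not an error
  C <- rbind(const = rep(1, 8))
  colnames(C) <- colnames(B)
  scr3 <- correlation_screen(C, B, rho_threshold = 0.4)
  expect_true(all(is.na(scr3$rho)))
})
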