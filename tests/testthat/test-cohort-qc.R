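panel_matrix <- function(n_samples = 6, marker_level = 10, bg = 5) {
  genes <- c(marker_panel()$genes, paste0("bg", 1:3))
  vals <- matrix(bg, length(genes), n_samples,
                 dimnames = list(genes, paste0("s", 1:n_samples)))
  vals[marker_panel()$genes, ] <- marker_level
  vals
}

test_that("contamination flagging fires on fold-over-median with a marker quorum", {
  vals <- panel_matrix()
  em0 <- expression_matrix(vals, "RPKM")
  expect_length(flag_contaminated_samples(em0)$flagged, 0)  # identical samples
  vals25 <- vals; vals25[marker_panel()$genes, "s1"] <- 25 * 10
  expect_identical(flag_contaminated_samples(expression_matrix(vals25, "RPKM"))$flagged,
                   "s1")
  vals19 <- vals; vals19[marker_panel()$genes, "s1"] <- 19 * 10
  expect_length(flag_contaminated_samples(expression_matrix(vals19, "RPKM"))$flagged, 0)
  # quorum: elevation on 3 of 7 markers is below the default majority of 4
  vals3 <- vals; vals3[marker_panel()$genes[1:3], "s2"] <- 30 * 10
  expect_length(flag_contaminated_samples(expression_matrix(vals3, "RPKM"))$flagged, 0)
  vals4 <- vals; vals4[marker_panel()$genes[1:4], "s2"] <- 30 * 10
  expect_identical(flag_contaminated_samples(expression_matrix(vals4, "RPKM"))$flagged,
                   "s2")
  # invariance to sample order and uniform rescaling
  perm <- c(3, 1, 2, 6, 5, 4)
  expect_identical(flag_contaminated_samples(
    expression_matrix(vals4[, perm] * 7, "RPKM"))$flagged, "s2")
  # zero-median markers are skipped, not fatal
  vz <- vals4; vz["IGFBP1", ] <- 0
  res <- flag_contaminated_samples(expression_matrix(vz, "RPKM"))
  expect_identical(res$skipped_markers, "IGFBP1")
  expect_error(flag_contaminated_samples(
    expression_matrix(vals[1:3, ], "RPKM")), class = "placentatools_missing_marker")
})

mk_subjects <- function(ids, labor, GA, sex, caesarean, smoking, BMI, age) {
  data.frame(sample_id = ids, labor = labor, GA = GA, sex = sex,
             caesarean = caesarean, smoking = smoking, BMI = BMI, age = age,
             stringsAsFactors = FALSE)
}

test_that("matching prefers a perfect twin and respects priority order", {
  case <- mk_subjects("case1", TRUE, 38, "F", FALSE, FALSE, 24, 30)
  ctls <- mk_subjects(c("twin", "near"),
                      c(TRUE, TRUE), c(38, 37.5), c("F", "F"),
                      c(FALSE, FALSE), c(FALSE, FALSE), c(24, 24), c(30, 30))
  m <- match_case_control(case, ctls)
  expect_identical(m$control_id, "twin")
  expect_identical(m$relaxed, "")
  # GA (priority 2) outranks BMI (priority 6)
  ctls2 <- mk_subjects(c("gaClose", "bmiClose"),
                       c(TRUE, TRUE), c(38.5, 40), c("F", "F"),
                       c(FALSE, FALSE), c(FALSE, FALSE), c(34, 24), c(30, 30))
  m2 <- match_case_control(case, ctls2)
  expect_identical(m2$control_id, "gaClose")
})

test_that("exact criteria relax lowest-priority-first and controls are used once", {
  case <- mk_subjects(c("c1", "c2"), c(TRUE, TRUE), c(38, 38), c("F", "F"),
                      c(FALSE, FALSE), c(FALSE, FALSE), c(24, 24), c(30, 30))
  # only one control matches labor+sex+caesarean exactly; the second case must
  # fall back to a smoking-mismatched control (smoking = priority 5, relaxed
  # before caesarean/sex/labor)
  ctls <- mk_subjects(c("exact1", "smoker"),
                      c(TRUE, TRUE), c(38, 38), c("F", "F"),
                      c(FALSE, FALSE), c(FALSE, TRUE), c(24, 24), c(30, 30))
  m <- match_case_control(case, ctls)
  expect_identical(m$control_id, c("exact1", "smoker"))
  expect_identical(m$relaxed, c("", "smoking"))
  expect_identical(attr(m, "unmatched_cases"), character(0))
  # exhausted pool leaves cases unmatched
  m2 <- match_case_control(rbind(case, case), ctls)
  expect_length(attr(m2, "unmatched_cases"), 2)
  expect_error(match_case_control(case, ctls[0, ]),
               class = "placentatools_empty_pool")
})

test_that("matching is deterministic and monotone under criterion relaxation", {
  set.seed(301)
  n <- 30
  cases <- mk_subjects(sprintf("case%02d", 1:15), sample(c(TRUE, FALSE), 15, TRUE),
                       runif(15, 36, 41), sample(c("M", "F"), 15, TRUE),
                       sample(c(TRUE, FALSE), 15, TRUE),
                       sample(c(TRUE, FALSE), 15, TRUE),
                       runif(15, 19, 35), runif(15, 20, 42))
  ctls <- mk_subjects(sprintf("ctl%02d", 1:n), sample(c(TRUE, FALSE), n, TRUE),
                      runif(n, 36, 41), sample(c("M", "F"), n, TRUE),
                      sample(c(TRUE, FALSE), n, TRUE),
                      sample(c(TRUE, FALSE), n, TRUE),
                      runif(n, 19, 35), runif(n, 20, 42))
  m1 <- match_case_control(cases, ctls)
  m2 <- match_case_control(cases, ctls)
  expect_identical(m1, m2)
  expect_false(anyDuplicated(m1$control_id) > 0)
  # dropping criteria never reduces the number of matched cases
  full <- nrow(m1)
  for (k in c(5, 3, 1)) {
    crit <- match_criteria()[1:k, ]
    class(crit) <- c("match_criteria", "data.frame")
    expect_gte(nrow(match_case_control(cases, ctls, crit)), full)
  }
})

test_that("pair exclusion applies enabled rules and logs the firing rule", {
  pairs <- data.frame(case_id = paste0("c", 1:6), control_id = paste0("k", 1:6),
                      case_sex = c("M", "M", "F", "F", "M", "F"),
                      control_sex = c("M", "F", "F", "F", "M", "F"),
                      contamination_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                      case_comorbidities = c(NA, NA, NA, "PE", "essential_htn,smoker", NA),
                      stringsAsFactors = FALSE)
  res <- exclude_mismatched_pairs(pairs,
                                  rules = list(sex_mismatch = TRUE,
                                               contamination = TRUE,
                                               comorbidities = c("PE", "essential_htn",
                                                                 "gestational_htn")))
  expect_identical(res$retained$case_id, c("c1", "c6"))
  expect_identical(res$log$rule,
                   c("sex_mismatch", "contamination", "comorbidity", "comorbidity"))
  # no rules enabled: identity
  res0 <- exclude_mismatched_pairs(pairs, rules = list())
  expect_identical(res0$retained, pairs)
})

test_that("a 49-pair fixture with 9 rule-firing pairs reduces to 40", {
  set.seed(302)
  pairs <- data.frame(case_id = sprintf("c%02d", 1:49),
                      control_id = sprintf("k%02d", 1:49),
                      case_sex = "M", control_sex = "M",
                      contamination_flag = FALSE,
                      case_comorbidities = NA_character_,
                      stringsAsFactors = FALSE)
  pairs$control_sex[1:5] <- "F"              # fetal sex mismatches
  pairs$contamination_flag[6] <- TRUE        # decidual contamination
  pairs$case_comorbidities[7:9] <- c("PE", "essential_htn", "gestational_htn")
  res <- exclude_mismatched_pairs(pairs,
                                  rules = list(sex_mismatch = TRUE,
                                               contamination = TRUE,
                                               comorbidities = c("PE", "essential_htn",
                                                                 "gestational_htn")))
  expect_equal(nrow(res$retained), 40)
  expect_equal(nrow(res$log), 9)
})
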