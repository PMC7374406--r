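# LOOCV, region tallies, variable ranking and the seven-comparison report.

test_that("a perfectly separating variable classifies without error", {
  tab <- toy_cohort(n_case = 8, n_control = 8, gap = 200, sd = 0.1)
  spec <- comparison_spec("case-grp", "ctrl-grp",
                          variables = "lumbar_sitting_ae")
  cv <- dst_loocv(tab, spec)
  expect_equal(cv$accuracy, 1)
  expect_true(all(cv$results$correct))
  expect_true(all(cv$results$region == "dominant"))
})

test_that("identically distributed groups classify at chance level", {
  set.seed(77)
  vars <- variable_keys()$name
  n <- 400
  X <- matrix(rnorm(n * 18, 5, 1), n, 18, dimnames = list(NULL, vars))
  tab <- data.frame(group = rep(c("a", "b"), each = 200), X,
                    check.names = FALSE)
  tab$subject_id <- as.character(seq_len(n))
  acc <- dst_loocv(tab, comparison_spec("a", "b"))$accuracy
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("LOOCV agrees with an independent naive hold-one-out loop", {
  specs <- default_group_specs()
  specs <- lapply(specs[c("FP", "no-LBP")], function(s) {
    group_spec(s$group, 6L, s$params)
  })
  tab <- generate_cohort(specs, seed = 33)
  expect_equal(nrow(tab), 12L)
  spec <- comparison_spec("FP", "no-LBP")
  for (calib in c("posterior", "anchored")) {
    got <- dst_loocv(tab, spec, calibration = calib)$accuracy
    want <- oracle_loocv_accuracy(tab, "FP", "no-LBP", calibration = calib)
    expect_equal(got, want, info = calib)
  }
  # and with non-default bounds
  b <- uncertainty_bounds(0.2, 0.6)
  expect_equal(dst_loocv(tab, spec, bounds = b)$accuracy,
               oracle_loocv_accuracy(tab, "FP", "no-LBP",
                                     theta_L = 0.2, theta_U = 0.6))
})

test_that("per-subject masses from LOOCV match the naive pipeline", {
  specs <- lapply(default_group_specs()[c("PEP", "no-LBP")], function(s) {
    group_spec(s$group, 5L, s$params)
  })
  tab <- generate_cohort(specs, seed = 44)
  cv <- dst_loocv(tab, comparison_spec("PEP", "no-LBP"))
  vars <- variable_keys()$name
  X <- as.matrix(tab[, vars])
  is_case <- tab$group == "PEP"
  for (i in seq_len(nrow(tab))) {
    m <- oracle_subject_masses(
      X[i, ],
      X[setdiff(which(is_case), i), , drop = FALSE],
      X[setdiff(which(!is_case), i), , drop = FALSE],
      0.1, 0.8, 0.9, "posterior")
    expect_equal(unname(unlist(cv$results[i, c("m_case", "m_control",
                                               "m_theta")])),
                 m, tolerance = 1e-9)
  }
})

test_that("accuracy is symmetric under swapping case and control", {
  tab <- toy_cohort(n_case = 7, n_control = 9, gap = 4, sd = 1.5,
                    seed = 11)
  a <- dst_loocv(tab, comparison_spec("case-grp", "ctrl-grp"))
  b <- dst_loocv(tab, comparison_spec("ctrl-grp", "case-grp"))
  expect_false(any(a$results$tie)) # tie-free fixture
  expect_equal(a$accuracy, b$accuracy)
})

test_that("widening the group separation never hurts LOOCV accuracy", {
  accs <- vapply(c(0, 1, 2, 4, 8), function(gap) {
    tab <- toy_cohort(n_case = 10, n_control = 10, gap = gap, sd = 1,
                      seed = 55)
    dst_loocv(tab, comparison_spec("case-grp", "ctrl-grp"))$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[length(accs)], 1)
})

test_that("ranking finds the lone separating variable and orders ties canonically", {
  set.seed(21)
  vars <- variable_keys()$name
  n <- 16
  X <- matrix(rnorm(n * 18, 5, 1), n, 18, dimnames = list(NULL, vars))
  grp <- rep(c("case-grp", "ctrl-grp"), each = 8)
  X[grp == "case-grp", "pelvis_standing_ve"] <-
    X[grp == "case-grp", "pelvis_standing_ve"] + 100
  tab <- data.frame(subject_id = as.character(1:n), group = grp, X,
                    check.names = FALSE)
  rk <- rank_variables(tab, comparison_spec("case-grp", "ctrl-grp"))
  expect_equal(rk$name[1], "pelvis_standing_ve")
  expect_equal(rk$accuracy[1], 1)
  # ranking is invariant to the column order of the input table
  shuffled <- tab[, c("subject_id", "group", sample(vars))]
  rk2 <- rank_variables(shuffled, comparison_spec("case-grp", "ctrl-grp"))
  expect_equal(rk2$name, rk$name)
  expect_equal(rk2$accuracy, rk$accuracy)
})

test_that("all-vacuous variables classify everything as control", {
  vars <- variable_keys()$name
  n <- 12
  X <- matrix(rep(rep(c(1, 2, 2, 1), 3), 18), n, 18,
              dimnames = list(NULL, vars))
  tab <- data.frame(subject_id = as.character(1:n),
                    group = rep(c("case-grp", "ctrl-grp"), c(4, 8)), X,
                    check.names = FALSE)
  rk <- rank_variables(tab, comparison_spec("case-grp", "ctrl-grp"))
  # tie -> control for every subject, so accuracy = control fraction
  expect_true(all(rk$accuracy == 8 / 12))
})

test_that("region tallies match a manual count and conserve subjects", {
  res <- data.frame(
    true = c(rep("case", 6), rep("control", 4)),
    correct = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
                TRUE, TRUE, FALSE, TRUE),
    region = c("dominant", "dominant", "nondominant", "dominant",
               "nondominant", "nondominant", "dominant", "dominant",
               "dominant", "nondominant")
  )
  tal <- tally_regions(res)
  expect_equal(sum(tal$n), nrow(res))
  pick <- function(t, c, r) tal$n[tal$true == t & tal$correct == c &
                                    tal$region == r]
  expect_equal(pick("case", TRUE, "dominant"), 2L)
  expect_equal(pick("case", TRUE, "nondominant"), 2L)
  expect_equal(pick("case", FALSE, "dominant"), 1L)
  expect_equal(pick("case", FALSE, "nondominant"), 1L)
  expect_equal(pick("control", TRUE, "dominant"), 2L)
  expect_equal(pick("control", FALSE, "dominant"), 1L)
  expect_equal(tal$pct[tal$true == "case" & tal$correct &
                         tal$region == "dominant"], 100 * 2 / 6)
})

test_that("the seven-comparison report has the study structure", {
  co <- generate_cohort(seed = 4)
  rep1 <- run_seven_comparisons(co)
  expect_length(rep1$comparisons, 7L)
  expect_equal(rep1$summary$comparison,
               c("fp", "aep", "pep", "pooled", "fp-aep", "fp-pep",
                 "aep-pep"))
  # the pooled comparison uses all three subgroups as the case class
  pooled <- rep1$comparisons$pooled$spec
  expect_setequal(pooled$case, c("FP", "AEP", "PEP"))
  expect_equal(pooled$control, "no-LBP")
  expect_equal(rep1$comparisons$pooled$loocv$n_case, 86L)
  # deterministic given the table
  rep2 <- run_seven_comparisons(co)
  expect_identical(rep1$summary, rep2$summary)
  # a missing group is named
  no_pep <- co[co$group != "PEP", ]
  expect_error(run_seven_comparisons(no_pep), "PEP")
})

test_that("LOOCV refuses degenerate class sizes", {
  tab <- toy_cohort(n_case = 2, n_control = 8)
  expect_error(dst_loocv(tab, comparison_spec("case-grp", "ctrl-grp")),
               "at least 3")
  expect_error(comparison_spec("a", "a"), "disjoint")
})
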