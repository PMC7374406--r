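# Belief-function core: uncertainty bounds, confidence factors, the
# cf -> BoE map, Dempster combination, simplex geometry, decisions.

test_that("uncertainty bounds derive the linear-map controls", {
  b <- uncertainty_bounds(0.1, 0.8)
  expect_equal(b$B, 0.9)
  expect_equal(b$A, 0.4375)
  # derived controls satisfy the defining relation for random bounds
  set.seed(12)
  for (i in 1:20) {
    tl <- runif(1, 0, 0.5); tu <- runif(1, tl + 0.05, 1)
    bb <- uncertainty_bounds(tl, tu)
    expect_equal(1 - tu, bb$B * (1 - 2 * bb$A) / (1 - bb$A),
                 tolerance = 1e-12)
    expect_equal(bb$B, 1 - tl)
  }
  expect_error(uncertainty_bounds(0.5, 0.4), "theta_U")
  expect_error(uncertainty_bounds(-0.1, 0.8), "theta_L")
})

test_that("confidence factor is a calibrated monotone sigmoid", {
  shift <- 5; rate <- 2 * log(9) / 6
  expect_equal(confidence_factor(5, shift, rate), 0.5)
  expect_equal(confidence_factor(8, shift, rate), 0.9)
  expect_equal(confidence_factor(2, shift, rate), 0.1)
  expect_equal(confidence_factor(1e6, shift, rate), 1)
  expect_equal(confidence_factor(-1e6, shift, rate), 0)
  v <- seq(-10, 20, by = 0.5)
  expect_true(all(diff(confidence_factor(v, shift, rate)) > 0))
  # rate 0 marks a vacuous variable: cf constant at 0.5
  expect_equal(confidence_factor(v, shift, 0), rep(0.5, length(v)))
})

test_that("cf -> BoE map hits the prescribed uncertainty at its pins", {
  b <- uncertainty_bounds(0.1, 0.8)
  mid <- boe_from_cf(0.5, b)
  expect_equal(unname(mid[1:3]), c(0.1, 0.1, 0.8))
  hi <- boe_from_cf(1, b)
  expect_equal(unname(hi[1:3]), c(0.9, 0, 0.1))
  lo <- boe_from_cf(0, b)
  expect_equal(unname(lo[1:3]), c(0, 0.9, 0.1))
  # symmetry at the crossing for arbitrary bounds
  set.seed(7)
  for (i in 1:20) {
    bb <- uncertainty_bounds(runif(1, 0, 0.4), runif(1, 0.5, 1))
    m <- boe_from_cf(0.5, bb)
    expect_equal(m[["m_case"]], m[["m_control"]])
    expect_equal(m[["m_theta"]], bb$theta_U, tolerance = 1e-12)
    expect_equal(boe_from_cf(1, bb)[["m_theta"]], bb$theta_L,
                 tolerance = 1e-12)
  }
  expect_error(boe_from_cf(1.2, b), "cf")
})

test_that("Dempster combination matches the hand-worked example", {
  out <- combine_dempster(boe(0.6, 0.2, 0.2), boe(0.5, 0.3, 0.2))
  # K = 0.28; m_case = 0.52/0.72, m_control = 0.16/0.72, theta = 0.04/0.72
  expect_equal(unname(out[1:3]),
               c(0.52, 0.16, 0.04) / 0.72, tolerance = 1e-12)
})

test_that("vacuous BoE is the identity and total conflict errors", {
  x <- boe(0.55, 0.25, 0.2)
  expect_equal(unname(combine_dempster(x, vacuous_boe())[1:3]),
               unname(x[1:3]))
  expect_equal(unname(combine_dempster(vacuous_boe(), x)[1:3]),
               unname(x[1:3]))
  expect_error(combine_dempster(boe(1, 0, 0), boe(0, 1, 0)),
               "total conflict")
})

test_that("combination is commutative and associative with unit-sum output", {
  set.seed(31)
  for (i in 1:200) {
    a <- random_boe(); b <- random_boe(); c <- random_boe()
    ab <- combine_dempster(a, b)
    ba <- combine_dempster(b, a)
    expect_equal(unname(ab[1:3]), unname(ba[1:3]), tolerance = 1e-9)
    abc1 <- combine_dempster(combine_dempster(a, b), c)
    abc2 <- combine_dempster(a, combine_dempster(b, c))
    expect_equal(unname(abc1[1:3]), unname(abc2[1:3]), tolerance = 1e-9)
    expect_equal(sum(ab), 1, tolerance = 1e-12)
    expect_true(all(ab >= 0))
  }
})

test_that("combine_all is order-independent and handles edge lists", {
  single <- boe(0.4, 0.3, 0.3)
  expect_equal(unname(combine_all(list(single))[1:3]), unname(single[1:3]))
  vac18 <- replicate(18, vacuous_boe(), simplify = FALSE)
  expect_equal(unname(combine_all(vac18)[1:3]), c(0, 0, 1))
  set.seed(17)
  five <- replicate(5, random_boe(), simplify = FALSE)
  ref <- combine_all(five)
  for (p in 1:20) {
    perm <- sample(5)
    expect_equal(unname(combine_all(five[perm])[1:3]), unname(ref[1:3]),
                 tolerance = 1e-9)
  }
})

test_that("simplex embedding maps masses to barycentric coordinates", {
  pure_case <- simplex_coordinates(boe(1, 0, 0))
  expect_equal(c(pure_case$x, pure_case$y), c(1, 0))
  centroid <- simplex_coordinates(boe(1 / 3, 1 / 3, 1 / 3))
  expect_equal(c(centroid$x, centroid$y), c(0.5, sqrt(3) / 6))
  base_mid <- simplex_coordinates(boe(0.5, 0.5, 0))
  expect_equal(c(base_mid$x, base_mid$y), c(0.5, 0))
})

test_that("classification decisions follow the mass ordering", {
  d1 <- classify_boe(boe(0.7, 0.1, 0.2))
  expect_equal(d1[c("label", "region")],
               list(label = "case", region = "dominant"))
  d2 <- classify_boe(boe(0.3, 0.2, 0.5))
  expect_equal(d2[c("label", "region")],
               list(label = "case", region = "nondominant"))
  d3 <- classify_boe(boe(0.1, 0.7, 0.2))
  expect_equal(d3[c("label", "region")],
               list(label = "control", region = "dominant"))
  tie <- classify_boe(boe(0.3, 0.3, 0.4))
  expect_equal(tie$label, "control")
  expect_true(tie$tie)
})

test_that("anchored fit places cf = anchor at the class means", {
  set.seed(5)
  tab <- data.frame(
    group = rep(c("case-grp", "ctrl-grp"), each = 10)
  )
  for (v in variable_keys()$name) tab[[v]] <- rnorm(20, 5, 1)
  # engineer exact class means 8 and 2 on one variable
  tab$lumbar_sitting_ae <- rep(c(8, 2), each = 10) +
    rep(c(-1, 1), 10) * 0.5
  tab$lumbar_sitting_ae[1:10] <-
    tab$lumbar_sitting_ae[1:10] - mean(tab$lumbar_sitting_ae[1:10]) + 8
  tab$lumbar_sitting_ae[11:20] <-
    tab$lumbar_sitting_ae[11:20] - mean(tab$lumbar_sitting_ae[11:20]) + 2
  cv <- fit_control_variables(tab, "case-grp", "ctrl-grp",
                              calibration = "anchored")
  p <- cv$params[cv$params$name == "lumbar_sitting_ae", ]
  expect_equal(p$shift, 5)
  expect_equal(confidence_factor(8, p$shift, p$rate), 0.9)
  expect_equal(confidence_factor(2, p$shift, p$rate), 0.1)
  # swapping the classes negates the rate and reflects the cf
  cv2 <- fit_control_variables(tab, "ctrl-grp", "case-grp",
                               calibration = "anchored")
  p2 <- cv2$params[cv2$params$name == "lumbar_sitting_ae", ]
  expect_equal(p2$rate, -p$rate)
  expect_equal(confidence_factor(7, p2$shift, p2$rate),
               1 - confidence_factor(7, p$shift, p$rate))
})

test_that("posterior fit scales steepness by class overlap", {
  set.seed(6)
  tab <- data.frame(group = rep(c("case-grp", "ctrl-grp"), each = 200))
  for (v in variable_keys()$name) tab[[v]] <- rnorm(400, 5, 1)
  # same mean gap, different spreads: wide overlap must give shallower rate
  gap <- 2
  tab$lumbar_sitting_ae <- rnorm(400, 5, 0.5) +
    ifelse(tab$group == "case-grp", gap, 0)
  tab$lumbar_standing_ae <- rnorm(400, 5, 4) +
    ifelse(tab$group == "case-grp", gap, 0)
  cv <- fit_control_variables(tab, "case-grp", "ctrl-grp")
  p <- cv$params
  r_tight <- p$rate[p$name == "lumbar_sitting_ae"]
  r_wide <- p$rate[p$name == "lumbar_standing_ae"]
  expect_gt(r_tight, r_wide)
  expect_gt(r_wide, 0)
  # rate equals gap over pooled within-class variance
  mu1 <- mean(tab$lumbar_sitting_ae[tab$group == "case-grp"])
  mu0 <- mean(tab$lumbar_sitting_ae[tab$group == "ctrl-grp"])
  v1 <- mean((tab$lumbar_sitting_ae[tab$group == "case-grp"] - mu1)^2)
  v0 <- mean((tab$lumbar_sitting_ae[tab$group == "ctrl-grp"] - mu0)^2)
  expect_equal(r_tight, (mu1 - mu0) / ((v1 + v0) / 2), tolerance = 1e-12)
})

test_that("equal class means yield a vacuous variable", {
  tab <- data.frame(group = rep(c("a", "b"), each = 4))
  for (v in variable_keys()$name) tab[[v]] <- rep(c(1, 2, 2, 1), 2)
  cv <- fit_control_variables(tab, "a", "b")
  expect_true(all(cv$params$rate == 0))
  b <- subject_boe(setNames(rep(1.5, 18), variable_keys()$name), cv)
  expect_equal(unname(b[1:3]), c(0, 0, 1))
})

test_that("single-variable decision boundary sits at the sigmoid shift", {
  for (bounds in list(uncertainty_bounds(0.1, 0.8),
                      uncertainty_bounds(0.05, 0.5),
                      uncertainty_bounds(0.3, 0.95))) {
    for (rate in c(0.3, 1.5)) {
      shift <- 4.2
      v <- seq(shift - 3, shift + 3, by = 0.01)
      labels <- vapply(v, function(vi) {
        classify_boe(boe_from_cf(confidence_factor(vi, shift, rate),
                                 bounds))$label
      }, character(1))
      # control strictly below the shift, case strictly above
      expect_true(all(labels[v < shift - 1e-9] == "control"))
      expect_true(all(labels[v > shift + 1e-9] == "case"))
    }
  }
})

test_that("control variables round-trip through structured text", {
  co <- generate_cohort(seed = 2)
  cv <- fit_control_variables(co, c("FP", "AEP", "PEP"), "no-LBP")
  f <- tempfile(fileext = ".yaml")
  write_control_variables(cv, f)
  back <- read_control_variables(f)
  expect_equal(back$params$shift, cv$params$shift, tolerance = 1e-8)
  expect_equal(back$params$rate, cv$params$rate, tolerance = 1e-8)
  expect_equal(back$bounds$A, cv$bounds$A)
  expect_equal(back$case_label, cv$case_label)
  expect_equal(back$calibration, cv$calibration)
  # the fused BoE of a held subject agrees under both objects
  vals <- unlist(co[1, variable_keys()$name])
  expect_equal(unname(subject_boe(vals, back)[1:3]),
               unname(subject_boe(vals, cv)[1:3]), tolerance = 1e-6)
})
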