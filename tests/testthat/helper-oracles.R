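# Independent brute-force oracles used by the tests.  These are written
# from first principles with plain loops and must stay independent of the
# package's code paths.

# error statistics via explicit loops
oracle_ce <- function(target, x) {
  s <- 0
  for (xi in x) s <- s + xi
  s / length(x) - target
}

oracle_ae <- function(target, x) {
  s <- 0
  for (xi in x) s <- s + abs(xi - target)
  s / length(x)
}

oracle_ve <- function(target, x) {
  m <- 0
  for (xi in x) m <- m + xi
  m <- m / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  sqrt(s / length(x))
}

# naive reimplementation of the whole two-class DST pipeline for one
# subject, from scratch: class moments, sigmoid, linear belief map,
# pairwise Dempster fold
oracle_subject_masses <- function(xi, X_case, X_control, theta_L, theta_U,
                                  anchor, calibration) {
  B <- 1 - theta_L
  cc <- (1 - theta_U) / B
  A <- (1 - cc) / (2 - cc)
  m <- c(0, 0, 1) # case, control, theta
  for (j in seq_along(xi)) {
    mu1 <- mean(X_case[, j]); mu0 <- mean(X_control[, j])
    gap <- mu1 - mu0
    if (gap == 0) next
    rate <- if (calibration == "anchored") {
      2 * log(anchor / (1 - anchor)) / gap
    } else {
      v1 <- mean((X_case[, j] - mu1)^2)
      v0 <- mean((X_control[, j] - mu0)^2)
      s2 <- (v1 + v0) / 2
      if (s2 > 0) gap / s2 else sign(gap) * 1e6
    }
    shift <- (mu1 + mu0) / 2
    cf <- 1 / (1 + exp(-rate * (xi[j] - shift)))
    b_case <- max(0, B * (cf - A) / (1 - A))
    b_control <- max(0, B * (1 - A - cf) / (1 - A))
    b_theta <- 1 - b_case - b_control
    K <- m[1] * b_control + m[2] * b_case
    m <- c(m[1] * b_case + m[1] * b_theta + m[3] * b_case,
           m[2] * b_control + m[2] * b_theta + m[3] * b_control,
           m[3] * b_theta) / (1 - K)
  }
  m
}

# naive leave-one-out loop over a two-class table
oracle_loocv_accuracy <- function(table, case_groups, control_groups,
                                  theta_L = 0.1, theta_U = 0.8,
                                  anchor = 0.9,
                                  calibration = "posterior") {
  vars <- variable_keys()$name
  keep <- table$group %in% c(case_groups, control_groups)
  tab <- table[keep, , drop = FALSE]
  X <- as.matrix(tab[, vars])
  is_case <- tab$group %in% case_groups
  correct <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    train_case <- X[setdiff(which(is_case), i), , drop = FALSE]
    train_control <- X[setdiff(which(!is_case), i), , drop = FALSE]
    m <- oracle_subject_masses(X[i, ], train_case, train_control,
                               theta_L, theta_U, anchor, calibration)
    pred_case <- m[1] > m[2] # tie -> control
    correct[i] <- pred_case == is_case[i]
  }
  mean(correct)
}

# random proper BoE
random_boe <- function() {
  m <- stats::runif(3)
  m <- m / sum(m)
  boe(m[1], m[2], m[3])
}

# polyline of m equal chords inscribed in a circular arc of total central
# angle theta_deg, running with strictly decreasing y
arc_chords <- function(theta_deg, m, radius = 100) {
  th <- theta_deg * pi / 180
  # sweep symmetric about the x axis, from +th/2 down to -th/2
  ang <- seq(th / 2, -th / 2, length.out = m + 1)
  list(x = radius * cos(ang), y = radius * sin(ang))
}

# small two-class cohort table with all 18 variables; `gap` is added to
# the case group on two informative variables
toy_cohort <- function(n_case = 6, n_control = 6, gap = 8, sd = 1,
                       seed = 42) {
  vars <- variable_keys()$name
  set.seed(seed)
  n <- n_case + n_control
  X <- matrix(abs(rnorm(n * 18, 5, sd)), n, 18,
              dimnames = list(NULL, vars))
  X[seq_len(n_case), "lumbar_sitting_ae"] <-
    X[seq_len(n_case), "lumbar_sitting_ae"] + gap
  X[seq_len(n_case), "pelvis_standing_ve"] <-
    X[seq_len(n_case), "pelvis_standing_ve"] + gap / 2
  data.frame(
    subject_id = sprintf("T%02d", seq_len(n)),
    group = rep(c("case-grp", "ctrl-grp"), c(n_case, n_control)),
    X, check.names = FALSE
  )
}
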