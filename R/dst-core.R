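# Two-class Dempster-Shafer classifier core.  The frame of discernment is
# {case, control}; each input variable v contributes a body of evidence
# (BoE) with masses m({case}), m({control}) and m(theta) = m({case,
# control}), the uncertainty.  Three stages:
#   (1) v -> confidence factor cf(v) via a logistic sigmoid anchored on the
#       two class means;
#   (2) cf -> BoE via a piecewise-linear map with control parameters A, B
#       derived from chosen uncertainty bounds theta_L (at cf = 0 or 1) and
#       theta_U (at cf = 0.5);
#   (3) BoEs from all variables fused with Dempster's rule of combination.

#' Uncertainty bounds and derived control parameters
#'
#' The confidence-factor-to-belief mapping is pinned by two interpretable
#' quantities: `theta_U`, the uncertainty mass assigned when the evidence is
#' maximally ambiguous (cf = 0.5), and `theta_L`, the residual uncertainty
#' retained even for fully decisive evidence (cf = 0 or 1).  From these the
#' linear-map controls are derived as `B = 1 - theta_L` and `A` solving
#' `1 - theta_U = B (1 - 2A) / (1 - A)`.
#'
#' @param theta_L Minimum uncertainty, in `[0, 1)`; default 0.1.
#' @param theta_U Maximum uncertainty, in `(theta_L, 1]`; default 0.8.
#' @return An object of class `"uncertainty_bounds"` with elements
#'   `theta_L`, `theta_U`, `A`, `B`.
#' @examples
#' uncertainty_bounds(0.1, 0.8)  # A = 0.4375, B = 0.9
#' @export
uncertainty_bounds <- function(theta_L = 0.1, theta_U = 0.8) {
  stopifnot(length(theta_L) == 1L, length(theta_U) == 1L,
            is.finite(theta_L), is.finite(theta_U))
  if (theta_L < 0 || theta_L >= 1) {
    stop("theta_L must be in [0, 1)", call. = FALSE)
  }
  if (theta_U <= theta_L || theta_U > 1) {
    stop("theta_U must be in (theta_L, 1]", call. = FALSE)
  }
  B <- 1 - theta_L
  cc <- (1 - theta_U) / B
  A <- (1 - cc) / (2 - cc)
  structure(list(theta_L = theta_L, theta_U = theta_U, A = A, B = B),
            class = "uncertainty_bounds")
}

#' @export
print.uncertainty_bounds <- function(x, ...) {
  cat(sprintf(
    "Uncertainty bounds: theta_L = %.3f, theta_U = %.3f (A = %.4f, B = %.4f)\n",
    x$theta_L, x$theta_U, x$A, x$B))
  invisible(x)
}

#' Construct a body of evidence
#'
#' A BoE over the two-class frame: `m_case` supports the case class,
#' `m_control` the control class, and `m_theta` is the mass on the whole
#' frame (uncertainty).  Masses must be nonnegative and sum to 1.
#'
#' @param m_case,m_control,m_theta Belief masses.
#' @return Named numeric vector of class `"boe"`.
#' @export
boe <- function(m_case, m_control, m_theta = 1 - m_case - m_control) {
  m <- c(m_case = m_case, m_control = m_control, m_theta = m_theta)
  if (any(!is.finite(m)) || any(m < -1e-9) || abs(sum(m) - 1) > 1e-9) {
    stop("BoE masses must be nonnegative and sum to 1", call. = FALSE)
  }
  m <- pmax(m, 0)
  structure(m, class = "boe")
}

#' The vacuous body of evidence
#'
#' All mass on the frame: total ignorance, the identity element of
#' Dempster's rule.
#'
#' @return A [boe()] equal to `(0, 0, 1)`.
#' @export
vacuous_boe <- function() boe(0, 0, 1)

#' @export
print.boe <- function(x, ...) {
  cat(sprintf("BoE: m(case) = %.4f, m(control) = %.4f, m(theta) = %.4f\n",
              x[["m_case"]], x[["m_control"]], x[["m_theta"]]))
  invisible(x)
}

#' Sigmoid confidence factor
#'
#' Maps a variable value to a confidence factor in (0, 1) with the logistic
#' `cf(v) = 1 / (1 + exp(-rate (v - shift)))`.  `shift` is the value at
#' which cf = 0.5 (the single-variable decision boundary); the sign of
#' `rate` encodes which direction of the variable favours the case class.
#' `rate = 0` marks a vacuous variable: its evidence is total ignorance and
#' it is skipped during combination.
#'
#' @param v Variable value(s), degrees.
#' @param shift,rate Sigmoid parameters (degrees, per-degree).
#' @return Confidence factor(s) in `[0, 1]`; constant 0.5 when `rate = 0`.
#' @export
confidence_factor <- function(v, shift, rate) {
  stopifnot(is.finite(shift), is.finite(rate))
  stats::plogis(rate * (v - shift))
}

#' Convert a confidence factor into a body of evidence
#'
#' The piecewise-linear map with controls `A`, `B` from
#' [uncertainty_bounds()]:
#' `m_case = max(0, B (cf - A) / (1 - A))`,
#' `m_control = max(0, B (1 - A - cf) / (1 - A))`,
#' `m_theta = 1 - m_case - m_control`.
#' At cf = 0 or 1 the uncertainty equals `theta_L`; at cf = 0.5 it equals
#' `theta_U`, where the case and control masses cross.
#'
#' @param cf Confidence factor in `[0, 1]`.
#' @param bounds An [uncertainty_bounds()] object.
#' @return A [boe()].
#' @examples
#' boe_from_cf(0.5, uncertainty_bounds(0.1, 0.8))  # (0.1, 0.1, 0.8)
#' @export
boe_from_cf <- function(cf, bounds = uncertainty_bounds()) {
  stopifnot(inherits(bounds, "uncertainty_bounds"), length(cf) == 1L)
  if (!is.finite(cf) || cf < 0 || cf > 1) {
    stop("cf must lie in [0, 1]", call. = FALSE)
  }
  A <- bounds$A; B <- bounds$B
  m_case <- max(0, B * (cf - A) / (1 - A))
  m_control <- max(0, B * (1 - A - cf) / (1 - A))
  boe(m_case, m_control, 1 - m_case - m_control)
}

#' Dempster's rule of combination
#'
#' Conjunctive fusion of two bodies of evidence with renormalisation by
#' `1 - K`, where `K = a_case * b_control + a_control * b_case` is the
#' conflicting mass.  The vacuous BoE is the identity; total conflict
#' (`K = 1`) is an error.
#'
#' @param a,b [boe()] objects.
#' @return The combined [boe()].
#' @examples
#' combine_dempster(boe(0.6, 0.2, 0.2), boe(0.5, 0.3, 0.2))
#' @export
combine_dempster <- function(a, b) {
  stopifnot(inherits(a, "boe"), inherits(b, "boe"))
  K <- a[["m_case"]] * b[["m_control"]] + a[["m_control"]] * b[["m_case"]]
  if (K >= 1 - 1e-12) {
    stop(sprintf(
      "total conflict (K = 1) combining BoE (%.3f, %.3f, %.3f) with (%.3f, %.3f, %.3f)",
      a[["m_case"]], a[["m_control"]], a[["m_theta"]],
      b[["m_case"]], b[["m_control"]], b[["m_theta"]]), call. = FALSE)
  }
  m_case <- (a[["m_case"]] * b[["m_case"]] +
             a[["m_case"]] * b[["m_theta"]] +
             a[["m_theta"]] * b[["m_case"]]) / (1 - K)
  m_control <- (a[["m_control"]] * b[["m_control"]] +
                a[["m_control"]] * b[["m_theta"]] +
                a[["m_theta"]] * b[["m_control"]]) / (1 - K)
  m_theta <- a[["m_theta"]] * b[["m_theta"]] / (1 - K)
  boe(m_case, m_control, m_theta)
}

#' Combine a list of bodies of evidence
#'
#' Left fold of [combine_dempster()]; by associativity and commutativity of
#' the rule the result is order-independent up to floating-point noise.
#'
#' @param boes Non-empty list of [boe()] objects.
#' @return The fused [boe()].
#' @export
combine_all <- function(boes) {
  stopifnot(is.list(boes), length(boes) >= 1L)
  Reduce(combine_dempster, boes)
}

#' Fit classifier control variables from training data
#'
#' For each variable the sigmoid shift is the midpoint of the two class
#' means, so the single-variable decision boundary always sits halfway
#' between the classes.  The rate (steepness) is set by the chosen
#' `calibration`:
#'
#' * `"posterior"` (default): `rate = (mu_case - mu_control) / s2`, where
#'   `s2` is the pooled within-class variance (mean of the two class
#'   variances, population form).  With this rate the confidence factor is
#'   the equal-prior posterior probability of case membership under
#'   univariate normal class models with common variance: a variable whose
#'   classes overlap heavily yields cf near 0.5 — and hence, via the
#'   belief mapping, uncertainty near `theta_U` — while a well-separated
#'   variable yields decisive confidence.
#' * `"anchored"`: `rate = 2 log(anchor / (1 - anchor)) / (mu_case -
#'   mu_control)`, so cf equals `anchor` (default 0.9) exactly at the
#'   case-class mean and `1 - anchor` at the control-class mean, whatever
#'   the within-class spread.
#'
#' Either way a variable whose class means coincide gets `rate = 0` and
#' contributes a vacuous BoE.
#'
#' @param training A `cohort_table` (or data frame with `group` and the
#'   variable columns).
#' @param case_label,control_label Group label(s) defining the two classes;
#'   either may be a vector to pool subgroups (e.g.
#'   `case_label = c("FP", "AEP", "PEP")`).
#' @param bounds An [uncertainty_bounds()] object, shared across variables.
#' @param anchor Confidence factor assigned at the case mean under
#'   `calibration = "anchored"`, in (0.5, 1).
#' @param calibration `"posterior"` or `"anchored"` (see Details).
#' @param variables Character vector of variable names to include; default
#'   all 18.
#' @return An object of class `"control_variables"`: the per-variable
#'   sigmoid table plus the bounds and class labels.
#' @export
fit_control_variables <- function(training, case_label, control_label,
                                  bounds = uncertainty_bounds(),
                                  anchor = 0.9,
                                  calibration = c("posterior", "anchored"),
                                  variables = NULL) {
  calibration <- match.arg(calibration)
  stopifnot(is.data.frame(training), "group" %in% names(training),
            inherits(bounds, "uncertainty_bounds"),
            anchor > 0.5, anchor < 1)
  if (is.null(variables)) variables <- variable_keys()$name
  variables <- variable_keys()$name[variable_keys()$name %in% variables]
  missing <- setdiff(variables, names(training))
  if (length(missing) > 0L) {
    stop("training table is missing variables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  is_case <- training$group %in% case_label
  is_control <- training$group %in% control_label
  if (sum(is_case) < 2L || sum(is_control) < 2L) {
    stop("need at least 2 training subjects per class (case: ",
         sum(is_case), ", control: ", sum(is_control), ")", call. = FALSE)
  }
  X <- as.matrix(training[, variables, drop = FALSE])
  fit <- fit_sigmoids(X[is_case, , drop = FALSE],
                      X[is_control, , drop = FALSE], anchor, calibration)
  structure(
    list(params = data.frame(name = variables, shift = fit$shift,
                             rate = fit$rate),
         bounds = bounds, anchor = anchor, calibration = calibration,
         case_label = case_label, control_label = control_label),
    class = "control_variables"
  )
}

# matrix-level sigmoid fit shared by fit_control_variables() and the
# cross-validation loop
fit_sigmoids <- function(X_case, X_control, anchor,
                         calibration = "posterior") {
  mu_case <- colMeans(X_case)
  mu_control <- colMeans(X_control)
  if (any(!is.finite(mu_case)) || any(!is.finite(mu_control))) {
    stop("non-finite class means in training data", call. = FALSE)
  }
  gap <- mu_case - mu_control
  if (calibration == "anchored") {
    rate <- ifelse(gap == 0, 0, 2 * log(anchor / (1 - anchor)) / gap)
  } else {
    v_case <- colMeans(X_case^2) - mu_case^2
    v_control <- colMeans(X_control^2) - mu_control^2
    s2 <- (v_case + v_control) / 2
    # degenerate zero-spread, nonzero-gap variables saturate the sigmoid
    rate <- ifelse(gap == 0, 0,
                   ifelse(s2 > 0, gap / s2, sign(gap) * 1e6))
  }
  list(shift = unname((mu_case + mu_control) / 2), rate = unname(rate))
}

#' @export
print.control_variables <- function(x, ...) {
  cat("DST control variables: case = {",
      paste(x$case_label, collapse = ", "), "}, control = {",
      paste(x$control_label, collapse = ", "), "}\n", sep = "")
  print(x$bounds)
  print(x$params, ...)
  invisible(x)
}

#' Serialise control variables to structured text
#'
#' @param cv A `control_variables` object.
#' @param path File path (YAML).
#' @return `write_control_variables()` returns `path` invisibly;
#'   `read_control_variables()` the restored object.
#' @export
write_control_variables <- function(cv, path) {
  stopifnot(inherits(cv, "control_variables"))
  yaml::write_yaml(list(
    format = "spinedst-control-variables", version = 1L,
    case_label = as.list(cv$case_label),
    control_label = as.list(cv$control_label),
    anchor = cv$anchor,
    calibration = if (is.null(cv$calibration)) "posterior"
                  else cv$calibration,
    theta_L = cv$bounds$theta_L, theta_U = cv$bounds$theta_U,
    params = stats::setNames(
      lapply(seq_len(nrow(cv$params)),
             function(i) c(cv$params$shift[i], cv$params$rate[i])),
      cv$params$name)
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_control_variables
#' @export
read_control_variables <- function(path) {
  p <- yaml::read_yaml(path)
  if (!identical(p$format, "spinedst-control-variables")) {
    stop("not a spinedst control-variables file: ", path, call. = FALSE)
  }
  structure(
    list(params = data.frame(
           name = names(p$params),
           shift = vapply(p$params, function(v) as.numeric(v[1]), numeric(1)),
           rate = vapply(p$params, function(v) as.numeric(v[2]), numeric(1))),
         bounds = uncertainty_bounds(p$theta_L, p$theta_U),
         anchor = p$anchor,
         calibration = p$calibration,
         case_label = unlist(p$case_label),
         control_label = unlist(p$control_label)),
    class = "control_variables"
  )
}

#' Fuse a subject's variables into a final body of evidence
#'
#' Applies the three classifier stages to one subject: sigmoid confidence
#' factor per variable, linear mapping to a per-variable BoE, and Dempster
#' combination across variables in canonical order.  Vacuous variables
#' (rate 0) contribute the identity and are skipped.
#'
#' @param values Named numeric vector (or one-row data frame) holding the
#'   subject's variable values.
#' @param cv A `control_variables` object from [fit_control_variables()].
#' @return The subject's final [boe()].
#' @export
subject_boe <- function(values, cv) {
  stopifnot(inherits(cv, "control_variables"))
  if (is.data.frame(values)) values <- unlist(values[1, , drop = TRUE])
  v <- as.numeric(values[cv$params$name])
  if (any(is.na(v))) {
    stop("subject is missing values for: ",
         paste(cv$params$name[is.na(v)], collapse = ", "), call. = FALSE)
  }
  out <- vacuous_boe()
  for (i in seq_along(v)) {
    if (cv$params$rate[i] == 0) next
    cf <- confidence_factor(v[i], cv$params$shift[i], cv$params$rate[i])
    out <- combine_dempster(out, boe_from_cf(cf, cv$bounds))
  }
  out
}

# Fixed simplex geometry: control vertex left, case vertex right, theta
# apex; unit base, height sqrt(3)/2.  The decision boundary is the
# vertical median x = 0.5.
simplex_vertices <- function() {
  list(control = c(0, 0), case = c(1, 0), theta = c(0.5, sqrt(3) / 2))
}

#' Simplex-plot coordinates of a body of evidence
#'
#' Barycentric embedding of the BoE in an equilateral triangle with the
#' control class at the left vertex, the case class at the right vertex and
#' uncertainty (theta) at the apex.  The vertical median is the decision
#' boundary; the four plot regions are dominant/non-dominant crossed with
#' case/control (dominant where the winning class mass exceeds the
#' uncertainty mass).
#'
#' @param b A [boe()].
#' @return A list with `x`, `y` (planar coordinates) and `region` (one of
#'   `"dominant-control"`, `"dominant-case"`, `"nondominant-control"`,
#'   `"nondominant-case"`).
#' @export
simplex_coordinates <- function(b) {
  stopifnot(inherits(b, "boe"))
  V <- simplex_vertices()
  pt <- b[["m_control"]] * V$control + b[["m_case"]] * V$case +
    b[["m_theta"]] * V$theta
  cls <- classify_boe(b)
  list(x = pt[1], y = pt[2], region = paste(cls$region, cls$label, sep = "-"))
}

#' Classification decision from a body of evidence
#'
#' The predicted class is the one with the larger singleton mass; a tie is
#' resolved to control (conservative for the case class) and flagged.  The
#' decision is `dominant` when the winning mass also exceeds the
#' uncertainty mass `m_theta`, `nondominant` otherwise.
#'
#' @param b A [boe()].
#' @return A list with `label` (`"case"` or `"control"`), `region`
#'   (`"dominant"` or `"nondominant"`) and `tie` (logical).
#' @export
classify_boe <- function(b) {
  stopifnot(inherits(b, "boe"))
  tie <- b[["m_case"]] == b[["m_control"]]
  label <- if (b[["m_case"]] > b[["m_control"]]) "case" else "control"
  win <- max(b[["m_case"]], b[["m_control"]])
  region <- if (win > b[["m_theta"]]) "dominant" else "nondominant"
  list(label = label, region = region, tie = tie)
}
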