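# Synthetic cohorts with the marginal structure of the published group
# statistics: per group and per variable, independent normal draws with the
# printed mean/SD, truncated at zero (by rejection) for the nonnegative
# error statistics AE and VE.

#' Construct a group specification
#'
#' A group specification holds the sample size and the 18 per-variable
#' (mean, sd) pairs, in degrees, from which [generate_cohort()] draws
#' subjects.
#'
#' @param group Group label (e.g. `"no-LBP"`, `"FP"`).
#' @param n Number of subjects; must be at least 2.
#' @param params Data frame with columns `name`, `mean`, `sd` covering all 18
#'   canonical variable names (see [variable_keys()]); `sd` must be positive.
#' @return An object of class `"group_spec"`.
#' @seealso [default_group_specs()], [generate_cohort()]
#' @export
group_spec <- function(group, n, params) {
  stopifnot(is.character(group), length(group) == 1L, nzchar(group))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    stop("group '", group, "': n must be an integer >= 2", call. = FALSE)
  }
  if (!is.data.frame(params) ||
      !all(c("name", "mean", "sd") %in% names(params))) {
    stop("params must be a data frame with columns name, mean, sd",
         call. = FALSE)
  }
  canon <- variable_keys()$name
  missing <- setdiff(canon, params$name)
  if (length(missing) > 0L) {
    stop("group '", group, "': params missing variables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- params[match(canon, params$name), c("name", "mean", "sd")]
  rownames(params) <- NULL
  if (!all(is.finite(params$mean)) || !all(is.finite(params$sd))) {
    stop("group '", group, "': non-finite mean or sd", call. = FALSE)
  }
  if (any(params$sd < 0)) {
    stop("group '", group, "': sd must be nonnegative", call. = FALSE)
  }
  structure(list(group = group, n = n, params = params),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat("Group specification: ", x$group, " (n = ", x$n, ")\n", sep = "")
  print(x$params, ...)
  invisible(x)
}

# (mean, sd) pairs per variable, canonical row order, one column pair per
# group in the order no-LBP, FP, AEP, PEP.  Units: degrees.
default_param_table <- function() {
  vals <- c(
    # no-LBP        FP            AEP           PEP
    2.8, 1.7,   5.5, 3.7,   4.9, 3.1,   7.8, 5.0,  # thoracic_sitting_ae
    2.3, 1.6,   5.1, 1.6,   5.3, 1.7,   5.5, 1.6,  # thoracic_sitting_ve
    0.5, 2.3,  -3.2, 4.9,   4.7, 3.1,   7.5, 4.8,  # thoracic_sitting_ce
    2.6, 1.9,   5.3, 3.3,   5.6, 2.1,   5.8, 3.0,  # thoracic_standing_ae
    1.9, 1.2,   4.4, 2.7,   4.0, 1.9,   4.5, 1.9,  # thoracic_standing_ve
   -0.2, 2.8,   0.8, 4.5,   2.2, 4.1,   1.4, 5.2,  # thoracic_standing_ce
    1.8, 0.7,   7.7, 4.1,   5.7, 2.3,  10.6, 4.8,  # lumbar_sitting_ae
    1.9, 0.9,   4.8, 3.1,   3.8, 1.8,   3.7, 1.8,  # lumbar_sitting_ve
    0.2, 1.0,   3.2, 6.8,  -3.1, 4.1,  -8.4, 7.9,  # lumbar_sitting_ce
    1.8, 1.3,   6.3, 3.8,   6.2, 2.3,   7.2, 5.6,  # lumbar_standing_ae
    1.8, 1.3,   4.4, 3.0,   5.4, 4.8,   7.1, 5.8,  # lumbar_standing_ve
   -0.3, 0.9,  -1.5, 5.8,  -4.7, 2.7,  -4.8, 2.3,  # lumbar_standing_ce
    1.8, 1.3,   4.0, 3.0,   3.8, 2.6,   5.1, 1.3,  # pelvis_sitting_ae
    1.2, 0.6,   3.5, 1.5,   1.1, 0.6,   1.3, 1.0,  # pelvis_sitting_ve
    0.4, 1.9,  -3.1, 3.8,  -2.6, 3.5,  -3.1, 2.7,  # pelvis_sitting_ce
    0.8, 0.6,   2.2, 1.5,   2.4, 1.3,   1.8, 1.0,  # pelvis_standing_ae
    0.6, 0.6,   0.6, 0.3,   2.7, 1.2,   3.3, 1.0,  # pelvis_standing_ve
    0.3, 0.9,  -1.6, 1.7,  -2.9, 1.3,  -1.3, 1.0   # pelvis_standing_ce
  )
  m <- matrix(vals, nrow = 18, ncol = 8, byrow = TRUE)
  colnames(m) <- paste(rep(group_labels(), each = 2), c("mean", "sd"),
                       sep = ".")
  rownames(m) <- variable_keys()$name
  m
}

#' Default group specifications from the published cohort
#'
#' Returns the four study groups — pain-free controls (`no-LBP`, n = 28) and
#' the flexion (`FP`, n = 49), active-extension (`AEP`, n = 23) and
#' passive-extension (`PEP`, n = 14) low-back-pain subgroups — with the
#' published per-variable repositioning-error means and standard deviations
#' (degrees) for all 18 variables.  These are the defaults used by
#' [generate_cohort()] and the command-line driver.
#'
#' @return A named list of four [group_spec()] objects.
#' @examples
#' specs <- default_group_specs()
#' specs[["no-LBP"]]$params[specs[["no-LBP"]]$params$name == "lumbar_sitting_ae", ]
#' @export
default_group_specs <- function() {
  tab <- default_param_table()
  ns <- c("no-LBP" = 28L, "FP" = 49L, "AEP" = 23L, "PEP" = 14L)
  specs <- lapply(names(ns), function(g) {
    group_spec(g, ns[[g]], data.frame(
      name = rownames(tab),
      mean = tab[, paste0(g, ".mean")],
      sd = tab[, paste0(g, ".sd")]
    ))
  })
  names(specs) <- names(ns)
  specs
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic cohort table
#'
#' Draws each subject's 18 repositioning-error variables from per-group
#' normal distributions.  AE and VE variables, which are nonnegative by
#' definition, are redrawn until nonnegative (rejection sampling, preserving
#' the unimodal shape of the truncated normal rather than creating an atom
#' at zero).  Variables are independent by default; an optional
#' equicorrelation `rho` induces a shared within-subject component across
#' all 18 variables for robustness experiments.
#'
#' @param specs List of [group_spec()] objects; defaults to
#'   [default_group_specs()].
#' @param seed Integer seed; the output is a pure function of
#'   `(specs, seed, rho)`.
#' @param rho Equicorrelation across a subject's variables, in `[0, 1)`;
#'   default 0 (independent).  With `rho > 0` a rejected subject row is
#'   redrawn whole, preserving the correlation structure.
#' @param max_rounds Maximum redraw rounds before giving up on a
#'   pathological specification (e.g. an AE mean many SDs below zero).
#' @return A `cohort_table`: a data frame with columns `subject_id`,
#'   `group` and the 18 canonical variable columns, one row per subject.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' table(cohort$group)
#' @export
generate_cohort <- function(specs = default_group_specs(), seed, rho = 0,
                            max_rounds = 100L) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(length(rho) == 1L, rho >= 0, rho < 1)
  specs <- lapply(specs, function(s) {
    if (inherits(s, "group_spec")) s else group_spec(s$group, s$n, s$params)
  })
  nonneg <- variable_keys()$name %in% nonneg_variable_names()
  with_seed(seed, {
    blocks <- lapply(specs, function(s) {
      draw_group_block(s, rho, nonneg, max_rounds)
    })
    out <- do.call(rbind, blocks)
    out$subject_id <- sprintf("S%03d", seq_len(nrow(out)))
    out <- out[, c("subject_id", "group", variable_keys()$name)]
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

draw_group_block <- function(spec, rho, nonneg, max_rounds) {
  p <- nrow(spec$params)
  mu <- spec$params$mean
  sd <- spec$params$sd
  draw_rows <- function(k) {
    z <- matrix(stats::rnorm(k * p), nrow = k)
    if (rho > 0) {
      shared <- stats::rnorm(k)
      z <- sqrt(rho) * shared + sqrt(1 - rho) * z
    }
    sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
  }
  x <- draw_rows(spec$n)
  for (round in seq_len(max_rounds)) {
    bad <- x[, nonneg, drop = FALSE] < 0
    if (!any(bad)) break
    if (rho > 0) {
      # redraw whole offending rows to keep the correlation structure
      rows <- which(apply(bad, 1, any))
      x[rows, ] <- draw_rows(length(rows))
    } else {
      idx <- which(nonneg)
      for (j in seq_along(idx)) {
        r <- which(bad[, j])
        if (length(r) > 0L) {
          x[r, idx[j]] <- stats::rnorm(length(r), mu[idx[j]], sd[idx[j]])
        }
      }
    }
    if (round == max_rounds) {
      bad <- x[, nonneg, drop = FALSE] < 0
      if (any(bad)) {
        stop("group '", spec$group, "': rejection sampling failed to ",
             "produce nonnegative AE/VE after ", max_rounds,
             " rounds; check the specification means", call. = FALSE)
      }
    }
  }
  colnames(x) <- spec$params$name
  data.frame(group = spec$group, x, check.names = FALSE)
}

#' Generate a trial set with known bias and spread
#'
#' Draws `k` repositioning attempts from `Normal(target + bias, spread)`.
#' By construction the expected constant error equals `bias` and the
#' expected variable error approaches `spread` for large `k`, which makes
#' the output a convenient ground-truth input for the error statistics in
#' [error_triple()].
#'
#' @param target Target angle (degrees).
#' @param bias Systematic over/undershoot added to every attempt (degrees).
#' @param spread Attempt-to-attempt standard deviation (degrees, `>= 0`).
#' @param k Number of attempts; at least 2 (the variable error is undefined
#'   for a single attempt).
#' @param seed Integer seed.
#' @param region,position Optional tags carried on the returned set.
#' @return A [trial_set()].
#' @export
generate_trials <- function(target, bias = 0, spread = 1, k = 4L, seed,
                            region = NA_character_, position = NA_character_) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(is.finite(target), is.finite(bias), spread >= 0)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) {
    stop("k must be >= 2: the variable error is undefined otherwise",
         call. = FALSE)
  }
  attempts <- with_seed(seed, stats::rnorm(k, target + bias, spread))
  trial_set(target = target, attempts = attempts,
            region = region, position = position)
}

#' Write / read a cohort table as delimited text
#'
#' The on-disk format is a comma-separated file with header
#' `subject_id,group,<region>_<position>_<errortype>,...` (18 data columns
#' in canonical order).
#'
#' @param cohort A `cohort_table` (see [generate_cohort()]).
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a validated `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort_table(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_cohort_table(df)
}

#' Validate and coerce a data frame to a cohort table
#'
#' Checks that all 18 canonical variable columns are present and numeric
#' with no missing values, and that AE/VE columns are nonnegative.
#'
#' @param df A data frame with `subject_id`, `group` and the 18 variable
#'   columns.
#' @return The input, column-ordered canonically, with class
#'   `c("cohort_table", "data.frame")`.
#' @export
as_cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  canon <- variable_keys()$name
  missing <- setdiff(c("subject_id", "group", canon), names(df))
  if (length(missing) > 0L) {
    stop("cohort table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, c("subject_id", "group", canon)]
  vals <- as.matrix(df[, canon])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("cohort table contains missing or non-numeric values",
         call. = FALSE)
  }
  neg <- vals[, nonneg_variable_names(), drop = FALSE] < 0
  if (any(neg)) {
    stop("cohort table has negative AE/VE values (first offending row: ",
         which(apply(neg, 1, any))[1], ")", call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write / read group specifications as a YAML config
#'
#' Round-trips a list of [group_spec()] objects through a structured text
#' file: one block per group with `n` and an 18-entry `params` map of
#' `[mean, sd]` pairs.  A copy of the default (published) specification
#' ships with the package in `inst/extdata/default_group_specs.yaml`.
#'
#' @param specs Named list of [group_spec()] objects.
#' @param path File path.
#' @return `write_group_specs()` returns `path` invisibly;
#'   `read_group_specs()` returns the list of specs.
#' @export
write_group_specs <- function(specs, path) {
  payload <- list(
    format = "spinedst-group-specs",
    version = 1L,
    groups = lapply(unname(specs), function(s) {
      params <- stats::setNames(
        lapply(seq_len(nrow(s$params)),
               function(i) c(s$params$mean[i], s$params$sd[i])),
        s$params$name
      )
      list(group = s$group, n = s$n, params = params)
    })
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_group_specs
#' @export
read_group_specs <- function(path) {
  payload <- yaml::read_yaml(path)
  if (!identical(payload$format, "spinedst-group-specs")) {
    stop("not a spinedst group-spec file: ", path, call. = FALSE)
  }
  specs <- lapply(payload$groups, function(g) {
    params <- data.frame(
      name = names(g$params),
      mean = vapply(g$params, function(p) as.numeric(p[1]), numeric(1)),
      sd = vapply(g$params, function(p) as.numeric(p[2]), numeric(1))
    )
    group_spec(g$group, g$n, params)
  })
  names(specs) <- vapply(specs, function(s) s$group, character(1))
  specs
}
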