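# Classifier evaluation: leave-one-out cross-validation (LOOCV),
# dominant/non-dominant accounting on the simplex, single-variable
# discriminative ranking, and the battery of seven study comparisons.

#' Define a two-class comparison
#'
#' @param case Group label(s) forming the case class; a vector pools
#'   subgroups (e.g. `c("FP", "AEP", "PEP")`).
#' @param control Group label(s) forming the control class; must be
#'   disjoint from `case`.
#' @param variables Variable subset (canonical names); default all 18.
#' @param name Display name; defaults to `"<case> vs <control>"`.
#' @return An object of class `"comparison_spec"`.
#' @export
comparison_spec <- function(case, control, variables = NULL, name = NULL) {
  stopifnot(is.character(case), is.character(control),
            length(case) >= 1L, length(control) >= 1L)
  if (length(intersect(case, control)) > 0L) {
    stop("case and control groups must be disjoint", call. = FALSE)
  }
  if (is.null(name)) {
    name <- paste(paste(case, collapse = "+"), "vs",
                  paste(control, collapse = "+"))
  }
  if (!is.null(variables)) {
    bad <- setdiff(variables, variable_keys()$name)
    if (length(bad) > 0L) {
      stop("unknown variables: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    variables <- variable_keys()$name[variable_keys()$name %in% variables]
  }
  structure(list(case = case, control = control, variables = variables,
                 name = name),
            class = "comparison_spec")
}

#' The seven study comparisons
#'
#' The repositioning-sense classifiers evaluated in the study:
#' each low-back-pain subgroup against pain-free controls
#' (`fp`, `aep`, `pep`), all subgroups pooled against controls (`pooled`),
#' and the three between-subgroup contrasts (`fp-aep`, `fp-pep`,
#' `aep-pep`).
#'
#' @return Named list of seven [comparison_spec()] objects.
#' @export
seven_comparisons <- function() {
  list(
    "fp" = comparison_spec("FP", "no-LBP"),
    "aep" = comparison_spec("AEP", "no-LBP"),
    "pep" = comparison_spec("PEP", "no-LBP"),
    "pooled" = comparison_spec(c("FP", "AEP", "PEP"), "no-LBP",
                               name = "LBP (pooled) vs no-LBP"),
    "fp-aep" = comparison_spec("FP", "AEP"),
    "fp-pep" = comparison_spec("FP", "PEP"),
    "aep-pep" = comparison_spec("AEP", "PEP")
  )
}

# Extract the comparison's feature matrix and class indicator from a
# cohort table.
comparison_data <- function(table, spec) {
  stopifnot(is.data.frame(table), inherits(spec, "comparison_spec"))
  vars <- spec$variables
  if (is.null(vars)) vars <- variable_keys()$name
  missing <- setdiff(vars, names(table))
  if (length(missing) > 0L) {
    stop("cohort table is missing variables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (g in c(spec$case, spec$control)) {
    if (!any(table$group == g)) {
      stop("group '", g, "' is absent from the cohort table", call. = FALSE)
    }
  }
  keep <- table$group %in% c(spec$case, spec$control)
  sub <- table[keep, , drop = FALSE]
  list(
    X = as.matrix(sub[, vars, drop = FALSE]),
    is_case = sub$group %in% spec$case,
    subject_id = if ("subject_id" %in% names(sub)) sub$subject_id
                 else as.character(seq_len(nrow(sub))),
    group = sub$group,
    vars = vars
  )
}

# Fuse per-variable masses for one subject without building S3 objects;
# cf is the vector of confidence factors, rate flags vacuous variables.
fuse_subject <- function(cf, rate, A, B) {
  mc <- 0; mk <- 0; mt <- 1
  for (j in seq_along(cf)) {
    if (rate[j] == 0) next
    mcj <- max(0, B * (cf[j] - A) / (1 - A))
    mkj <- max(0, B * (1 - A - cf[j]) / (1 - A))
    mtj <- 1 - mcj - mkj
    K <- mc * mkj + mk * mcj
    if (K >= 1 - 1e-12) {
      stop("total conflict while combining evidence", call. = FALSE)
    }
    d <- 1 - K
    mc_new <- (mc * mcj + mc * mtj + mt * mcj) / d
    mk_new <- (mk * mkj + mk * mtj + mt * mkj) / d
    mt <- mt * mtj / d
    mc <- mc_new; mk <- mk_new
  }
  c(mc, mk, mt)
}

# classify + simplex embed a fused mass triple
decide <- function(m) {
  label <- if (m[1] > m[2]) "case" else "control"
  region <- if (max(m[1], m[2]) > m[3]) "dominant" else "nondominant"
  V <- simplex_vertices()
  pt <- m[2] * V$control + m[1] * V$case + m[3] * V$theta
  list(label = label, region = region, tie = m[1] == m[2],
       x = pt[1], y = pt[2])
}

# assemble the per-subject results data frame used by dst_loocv() and
# resubstitution paths
results_frame <- function(dat, masses, decisions) {
  data.frame(
    subject_id = dat$subject_id,
    group = dat$group,
    true = ifelse(dat$is_case, "case", "control"),
    predicted = vapply(decisions, `[[`, character(1), "label"),
    region = vapply(decisions, `[[`, character(1), "region"),
    tie = vapply(decisions, `[[`, logical(1), "tie"),
    m_case = masses[, 1], m_control = masses[, 2], m_theta = masses[, 3],
    x = vapply(decisions, `[[`, numeric(1), "x"),
    y = vapply(decisions, `[[`, numeric(1), "y"),
    correct = ifelse(dat$is_case, "case", "control") ==
      vapply(decisions, `[[`, character(1), "label")
  )
}

#' Leave-one-out cross-validation of the DST classifier
#'
#' For each subject in the comparison, the control variables (per-variable
#' sigmoid parameters) are refit on the remaining n - 1 subjects, the
#' held-out subject's variables are fused into a final body of evidence,
#' and the subject is classified.  A subject counts as correct when its
#' predicted class matches its true class, whether the decision falls in
#' the dominant or the non-dominant simplex region.
#'
#' @param table A `cohort_table`.
#' @param spec A [comparison_spec()].
#' @param bounds An [uncertainty_bounds()] object.
#' @param anchor Sigmoid anchor confidence (see [fit_control_variables()]).
#' @param calibration Sigmoid rate calibration, `"posterior"` (default) or
#'   `"anchored"` (see [fit_control_variables()]).
#' @return An object of class `"dst_loocv"`: list with `accuracy`
#'   (fraction correct), `results` (per-subject data frame with final
#'   masses, simplex coordinates, predicted/true labels, region), `spec`,
#'   `bounds`, `anchor`, `calibration`.
#' @export
dst_loocv <- function(table, spec, bounds = uncertainty_bounds(),
                      anchor = 0.9,
                      calibration = c("posterior", "anchored")) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(bounds, "uncertainty_bounds"),
            anchor > 0.5, anchor < 1)
  dat <- comparison_data(table, spec)
  n <- nrow(dat$X)
  n_case <- sum(dat$is_case)
  n_control <- n - n_case
  if (n_case < 3L || n_control < 3L) {
    stop("LOOCV needs at least 3 subjects per class (case: ", n_case,
         ", control: ", n_control, ")", call. = FALSE)
  }
  masses <- matrix(NA_real_, n, 3)
  decisions <- vector("list", n)
  case_idx <- which(dat$is_case)
  control_idx <- which(!dat$is_case)
  for (i in seq_len(n)) {
    xi <- dat$X[i, ]
    ci <- if (dat$is_case[i]) setdiff(case_idx, i) else case_idx
    ki <- if (dat$is_case[i]) control_idx else setdiff(control_idx, i)
    fit <- fit_sigmoids(dat$X[ci, , drop = FALSE],
                        dat$X[ki, , drop = FALSE], anchor, calibration)
    cf <- stats::plogis(fit$rate * (xi - fit$shift))
    masses[i, ] <- fuse_subject(cf, fit$rate, bounds$A, bounds$B)
    decisions[[i]] <- decide(masses[i, ])
  }
  results <- results_frame(dat, masses, decisions)
  structure(
    list(accuracy = mean(results$correct), results = results,
         spec = spec, bounds = bounds, anchor = anchor,
         calibration = calibration,
         n_case = n_case, n_control = n_control),
    class = "dst_loocv"
  )
}

#' @export
print.dst_loocv <- function(x, ...) {
  cat(sprintf("DST LOOCV — %s: accuracy %.2f%% (n = %d case, %d control)\n",
              x$spec$name, 100 * x$accuracy, x$n_case, x$n_control))
  print(tally_regions(x$results))
  invisible(x)
}

#' Resubstitution classification with fixed control variables
#'
#' Fits the control variables on the full comparison sample and classifies
#' the same subjects (no hold-out).  Used by the single-variable ranking.
#'
#' @inheritParams dst_loocv
#' @param variables Optional variable subset overriding the spec's.
#' @return Same structure as [dst_loocv()], class `"dst_resub"`.
#' @export
dst_resubstitution <- function(table, spec, bounds = uncertainty_bounds(),
                               anchor = 0.9,
                               calibration = c("posterior", "anchored"),
                               variables = NULL) {
  calibration <- match.arg(calibration)
  if (!is.null(variables)) {
    spec <- comparison_spec(spec$case, spec$control, variables = variables,
                            name = spec$name)
  }
  dat <- comparison_data(table, spec)
  fit <- fit_sigmoids(dat$X[dat$is_case, , drop = FALSE],
                      dat$X[!dat$is_case, , drop = FALSE], anchor,
                      calibration)
  n <- nrow(dat$X)
  masses <- matrix(NA_real_, n, 3)
  decisions <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- stats::plogis(fit$rate * (dat$X[i, ] - fit$shift))
    masses[i, ] <- fuse_subject(cf, fit$rate, bounds$A, bounds$B)
    decisions[[i]] <- decide(masses[i, ])
  }
  results <- results_frame(dat, masses, decisions)
  structure(
    list(accuracy = mean(results$correct), results = results, spec = spec,
         bounds = bounds, anchor = anchor, calibration = calibration,
         n_case = sum(dat$is_case), n_control = sum(!dat$is_case)),
    class = "dst_resub"
  )
}

#' Rank variables by single-variable discriminative accuracy
#'
#' Each variable is assessed alone: its sigmoid is fit on the whole
#' comparison sample (all n subjects) and the same n subjects are
#' classified from that single piece of evidence (resubstitution).  The
#' list is sorted by descending accuracy, ties broken by canonical
#' variable order.
#'
#' @inheritParams dst_loocv
#' @return Data frame with columns `name`, `region`, `position`,
#'   `error_type`, `accuracy`, sorted.
#' @export
rank_variables <- function(table, spec, bounds = uncertainty_bounds(),
                           anchor = 0.9,
                           calibration = c("posterior", "anchored")) {
  calibration <- match.arg(calibration)
  vars <- spec$variables
  if (is.null(vars)) vars <- variable_keys()$name
  acc <- vapply(vars, function(v) {
    dst_resubstitution(table, spec, bounds, anchor, calibration,
                       variables = v)$accuracy
  }, numeric(1))
  keys <- variable_keys()
  out <- keys[match(vars, keys$name), ]
  out$accuracy <- acc
  out <- out[order(-out$accuracy, match(out$name, keys$name)), ]
  rownames(out) <- NULL
  out
}

#' Tally dominant / non-dominant outcomes per true class
#'
#' Cross-tabulates classification results by true class, correctness and
#' simplex region, with percentages within each true class.
#'
#' @param results Per-subject results data frame (from [dst_loocv()] or
#'   [dst_resubstitution()]), needing columns `true`, `correct`, `region`.
#' @return Data frame with one row per (true class, correct, region)
#'   combination: `n` and `pct` (percentage of that true class).
#' @export
tally_regions <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("true", "correct", "region") %in% names(results)))
  grid <- expand.grid(true = unique(results$true),
                      correct = c(TRUE, FALSE),
                      region = c("dominant", "nondominant"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(t, c, r) {
    sum(results$true == t & results$correct == c & results$region == r)
  }, grid$true, grid$correct, grid$region)
  class_n <- tapply(rep(1, nrow(results)), results$true, sum)
  grid$pct <- 100 * grid$n / as.numeric(class_n[grid$true])
  grid <- grid[order(grid$true, -grid$correct, grid$region), ]
  rownames(grid) <- NULL
  grid
}

#' Run the seven study comparisons on one cohort
#'
#' For each comparison in [seven_comparisons()]: LOOCV accuracy and
#' per-subject results, dominant/non-dominant tallies, and the
#' single-variable ranking.  Deterministic given the table and
#' configuration.
#'
#' @inheritParams dst_loocv
#' @param comparisons Named list of [comparison_spec()]s; defaults to the
#'   seven study comparisons.
#' @return An object of class `"dst_report"`: per-comparison results plus
#'   a `summary` data frame (comparison, n per class, accuracy %,
#'   non-dominant counts).
#' @export
run_seven_comparisons <- function(table, bounds = uncertainty_bounds(),
                                  anchor = 0.9,
                                  calibration = c("posterior", "anchored"),
                                  comparisons = seven_comparisons()) {
  calibration <- match.arg(calibration)
  runs <- lapply(comparisons, function(spec) {
    cv <- dst_loocv(table, spec, bounds, anchor, calibration)
    list(spec = spec, loocv = cv, tally = tally_regions(cv$results),
         ranking = rank_variables(table, spec, bounds, anchor, calibration))
  })
  summary <- do.call(rbind, lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    res <- r$loocv$results
    data.frame(
      comparison = nm, name = r$spec$name,
      n_case = r$loocv$n_case, n_control = r$loocv$n_control,
      accuracy_pct = 100 * r$loocv$accuracy,
      nondominant_n = sum(res$region == "nondominant"),
      dominant_errors = sum(!res$correct & res$region == "dominant"),
      top_variable = r$ranking$name[1],
      top_accuracy_pct = 100 * r$ranking$accuracy[1]
    )
  }))
  rownames(summary) <- NULL
  structure(list(comparisons = runs, summary = summary),
            class = "dst_report")
}

#' @export
print.dst_report <- function(x, ...) {
  cat("DST classification report —", length(x$comparisons),
      "comparisons\n\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a classification report to a directory
#'
#' Writes `summary.tsv` (one row per comparison), a
#' `ranking_<comparison>.tsv` per comparison, and a simplex plot
#' `simplex_<comparison>.svg` per comparison.
#'
#' @param report A `dst_report` from [run_seven_comparisons()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dst_report <- function(report, dir) {
  stopifnot(inherits(report, "dst_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, "summary.tsv")
  utils::write.table(report$summary, files[1], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (nm in names(report$comparisons)) {
    r <- report$comparisons[[nm]]
    rk <- file.path(dir, paste0("ranking_", nm, ".tsv"))
    utils::write.table(r$ranking, rk, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, rk)
    sv <- file.path(dir, paste0("simplex_", nm, ".svg"))
    save_simplex_svg(plot_simplex(r$loocv), sv)
    files <- c(files, sv)
  }
  invisible(files)
}
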