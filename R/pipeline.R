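# End-to-end drivers: simulate a cohort to disk, classify a cohort file,
# and replicate simulate+classify across seeds.  These back the thin
# command-line script shipped in inst/cli/spine-dst.R.

#' Simulate a cohort and write it to disk
#'
#' Generates a synthetic cohort from group specifications (default: the
#' published group statistics) and writes it as a delimited cohort file.
#'
#' @param out Output file path.
#' @param seed Integer seed (required; the file is a pure function of
#'   specs + seed).
#' @param specs Group specifications; default [default_group_specs()].
#' @param group_sizes Optional named integer vector overriding group sizes,
#'   e.g. `c(FP = 200)`.
#' @param rho Equicorrelation passed to [generate_cohort()].
#' @return Invisibly, the generated `cohort_table`.
#' @export
run_simulate <- function(out, seed, specs = default_group_specs(),
                         group_sizes = NULL, rho = 0) {
  if (!is.null(group_sizes)) {
    for (g in names(group_sizes)) {
      if (!g %in% names(specs)) {
        stop("group size override for unknown group '", g, "'",
             call. = FALSE)
      }
      specs[[g]] <- group_spec(specs[[g]]$group,
                               as.integer(group_sizes[[g]]),
                               specs[[g]]$params)
    }
  }
  cohort <- generate_cohort(specs, seed = seed, rho = rho)
  message("simulated cohort: ",
          paste(sprintf("%s=%d", names(table(cohort$group)),
                        as.integer(table(cohort$group))), collapse = ", "),
          " -> ", out)
  write_cohort(cohort, out)
  invisible(cohort)
}

#' Classify a cohort file and write the report
#'
#' Reads a cohort table, runs the selected comparisons with LOOCV, and
#' writes the report (summary, rankings, simplex SVGs) to a directory.
#'
#' @param input Cohort file path or an in-memory `cohort_table`.
#' @param out_dir Report output directory.
#' @param comparison Which comparisons to run: `"all"` (default) or any of
#'   `"fp"`, `"aep"`, `"pep"`, `"pooled"`, `"fp-aep"`, `"fp-pep"`,
#'   `"aep-pep"` (several allowed).
#' @param bounds An [uncertainty_bounds()] object.
#' @param anchor Sigmoid anchor confidence.
#' @param calibration Sigmoid rate calibration (see
#'   [fit_control_variables()]).
#' @return The `dst_report`, invisibly.
#' @export
run_classify <- function(input, out_dir = NULL, comparison = "all",
                         bounds = uncertainty_bounds(), anchor = 0.9,
                         calibration = c("posterior", "anchored")) {
  calibration <- match.arg(calibration)
  cohort <- if (is.character(input)) read_cohort(input)
            else as_cohort_table(input)
  all_specs <- seven_comparisons()
  if (!identical(comparison, "all")) {
    bad <- setdiff(comparison, names(all_specs))
    if (length(bad) > 0L) {
      stop("unknown comparison(s): ", paste(bad, collapse = ", "),
           "; valid: all, ", paste(names(all_specs), collapse = ", "),
           call. = FALSE)
    }
    all_specs <- all_specs[comparison]
  }
  report <- run_seven_comparisons(cohort, bounds, anchor, calibration,
                                  comparisons = all_specs)
  if (!is.null(out_dir)) {
    files <- write_dst_report(report, out_dir)
    message("report written: ", length(files), " files under ", out_dir)
  }
  invisible(report)
}

#' Replicate simulate + classify across seeds
#'
#' Repeats cohort generation and LOOCV classification for seeds
#' `seed, seed + 1, ..., seed + n_reps - 1` and summarises the
#' per-comparison accuracy across replicates.
#'
#' @param n_reps Number of replicates (>= 1).
#' @param seed First seed.
#' @param specs Group specifications; default [default_group_specs()].
#' @param comparison As in [run_classify()].
#' @param bounds,anchor,calibration Classifier configuration.
#' @param rho Equicorrelation for the generator.
#' @return A list with `per_replicate` (long data frame: seed, comparison,
#'   accuracy) and `summary` (per comparison: mean accuracy %, standard
#'   error, min, max).
#' @export
run_replicate <- function(n_reps, seed, specs = default_group_specs(),
                          comparison = "all",
                          bounds = uncertainty_bounds(), anchor = 0.9,
                          calibration = c("posterior", "anchored"),
                          rho = 0) {
  calibration <- match.arg(calibration)
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L)
  all_specs <- seven_comparisons()
  if (!identical(comparison, "all")) all_specs <- all_specs[comparison]
  rows <- list()
  for (r in seq_len(n_reps)) {
    s <- seed + r - 1L
    cohort <- generate_cohort(specs, seed = s, rho = rho)
    for (nm in names(all_specs)) {
      acc <- dst_loocv(cohort, all_specs[[nm]], bounds, anchor,
                       calibration)$accuracy
      rows[[length(rows) + 1L]] <-
        data.frame(seed = s, comparison = nm, accuracy = acc)
    }
  }
  per_rep <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(all_specs), function(nm) {
    a <- per_rep$accuracy[per_rep$comparison == nm]
    data.frame(
      comparison = nm,
      n_reps = length(a),
      mean_accuracy_pct = 100 * mean(a),
      se_pct = 100 * stats::sd(a) / sqrt(length(a)),
      min_pct = 100 * min(a),
      max_pct = 100 * max(a)
    )
  }))
  rownames(summary) <- NULL
  list(per_replicate = per_rep, summary = summary)
}
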