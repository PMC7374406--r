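# Repositioning-error statistics.  A subject repeats a memorised target
# posture k times; the three classical motor-control error statistics
# summarise the attempts:
#   CE (constant error)  = mean(x) - T          signed bias, + = overshoot
#   AE (absolute error)  = mean(|x - T|)        error magnitude
#   VE (variable error)  = sqrt(mean((x - mean(x))^2))   consistency
# All use the population divisor k.  They satisfy mean((x-T)^2) = VE^2 + CE^2
# and AE >= |CE|.

#' Construct a trial set
#'
#' One subject's repositioning attempts toward a single target angle for one
#' region/position combination.
#'
#' @param target Target angle in degrees (positive = flexion).
#' @param attempts Numeric vector of repositioning attempts (degrees); at
#'   least 2 (the study protocol uses 4).
#' @param region,position Optional tags (`"thoracic"`/`"lumbar"`/`"pelvis"`,
#'   `"sitting"`/`"standing"`) used when assembling a cohort row.
#' @return An object of class `"trial_set"`.
#' @export
trial_set <- function(target, attempts, region = NA_character_,
                      position = NA_character_) {
  stopifnot(is.numeric(target), length(target) == 1L, is.finite(target),
            is.numeric(attempts))
  if (length(attempts) < 2L) {
    stop("a trial set needs at least 2 attempts", call. = FALSE)
  }
  if (any(!is.finite(attempts))) {
    stop("attempts must be finite", call. = FALSE)
  }
  structure(
    list(target = target, attempts = as.numeric(attempts),
         k = length(attempts), region = region, position = position),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  tag <- if (!is.na(x$region)) paste0(" [", x$region, ", ", x$position, "]")
         else ""
  cat("Trial set", tag, ": target ", x$target, " deg, ", x$k,
      " attempts\n", sep = "")
  cat("  attempts:", paste(round(x$attempts, 3), collapse = ", "), "\n")
  tr <- error_triple(x)
  cat(sprintf("  AE = %.3f  VE = %.3f  CE = %+.3f deg\n",
              tr[["ae"]], tr[["ve"]], tr[["ce"]]))
  invisible(x)
}

#' Constant error (signed bias)
#'
#' `CE = mean(attempts) - target`; positive values indicate overshoot toward
#' flexion, negative undershoot toward extension.
#'
#' @param trials A [trial_set()].
#' @return Signed error in degrees.
#' @examples
#' constant_error(trial_set(4, c(5, 7, 3, 9)))  # 2
#' @export
constant_error <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  mean(trials$attempts) - trials$target
}

#' Absolute error (magnitude)
#'
#' `AE = mean(|attempts - target|)`, the mean unsigned deviation from the
#' target.
#'
#' @inheritParams constant_error
#' @return Nonnegative error in degrees.
#' @examples
#' absolute_error(trial_set(4, c(5, 7, 3, 9)))  # 2.5
#' @export
absolute_error <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  mean(abs(trials$attempts - trials$target))
}

#' Variable error (consistency)
#'
#' The within-subject standard deviation of the attempts about their own
#' mean, with population divisor `k`:
#' `VE = sqrt(sum((x - mean(x))^2) / k)`.  It is independent of the target
#' and of any constant shift of the attempts.
#'
#' @inheritParams constant_error
#' @return Nonnegative spread in degrees.
#' @examples
#' variable_error(trial_set(4, c(5, 7, 3, 9)))  # sqrt(5)
#' @export
variable_error <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  x <- trials$attempts
  sqrt(mean((x - mean(x))^2))
}

#' All three error statistics at once
#'
#' @inheritParams constant_error
#' @return Named numeric vector with elements `ae`, `ve`, `ce`.
#' @export
error_triple <- function(trials) {
  c(ae = absolute_error(trials), ve = variable_error(trials),
    ce = constant_error(trials))
}

#' Assemble one cohort row from a subject's six trial sets
#'
#' Takes the subject's trial sets for all six region/position combinations
#' (3 regions x 2 positions) and produces the 18-variable feature row used
#' by the classifier.  Input order does not matter; sets are matched by
#' their `region`/`position` tags.
#'
#' @param trial_sets List of six [trial_set()] objects, each tagged with a
#'   distinct region/position combination.
#' @param subject_id Subject identifier carried into the row.
#' @param group Optional group label (default `NA`).
#' @return A one-row data frame with `subject_id`, `group` and the 18
#'   canonical variable columns.
#' @export
errors_from_trials <- function(trial_sets, subject_id = "S001",
                               group = NA_character_) {
  stopifnot(is.list(trial_sets))
  keys <- unique(variable_keys()[, c("region", "position")])
  slots <- paste(keys$region, keys$position, sep = "_")
  got <- vapply(trial_sets, function(ts) {
    stopifnot(inherits(ts, "trial_set"))
    paste(ts$region, ts$position, sep = "_")
  }, character(1))
  missing <- setdiff(slots, got)
  if (length(missing) > 0L) {
    stop("missing trial sets for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- got[duplicated(got)]
  if (length(dup) > 0L) {
    stop("duplicated trial sets for: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  row <- as.list(stats::setNames(rep(NA_real_, 18L), variable_keys()$name))
  for (ts in trial_sets) {
    tr <- error_triple(ts)
    for (e in c("ae", "ve", "ce")) {
      row[[variable_name(ts$region, ts$position, e)]] <- tr[[e]]
    }
  }
  out <- data.frame(subject_id = subject_id, group = group, row,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Read trial-level records and build a cohort table
#'
#' `read_trials()` parses a delimited text file with columns
#' `subject_id,region,position,target,trial_1..trial_k` (any `k >= 2`,
#' constant within the file).  `cohort_from_trials()` reduces such records
#' to one 18-variable row per subject via [errors_from_trials()].
#'
#' @param path Path to the trial-level CSV.
#' @param trials Data frame as returned by `read_trials()`.
#' @param groups Optional named character vector mapping `subject_id` to a
#'   group label.
#' @return `read_trials()`: a data frame of raw records.
#'   `cohort_from_trials()`: a `cohort_table`.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("subject_id", "region", "position", "target")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("trial file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  trial_cols <- grep("^trial_[0-9]+$", names(df), value = TRUE)
  if (length(trial_cols) < 2L) {
    stop("trial file needs at least 2 trial_<i> columns", call. = FALSE)
  }
  df
}

#' @rdname read_trials
#' @export
cohort_from_trials <- function(trials, groups = NULL) {
  trial_cols <- grep("^trial_[0-9]+$", names(trials), value = TRUE)
  rows <- lapply(split(trials, trials$subject_id), function(sub) {
    sets <- lapply(seq_len(nrow(sub)), function(i) {
      trial_set(sub$target[i], as.numeric(sub[i, trial_cols]),
                region = sub$region[i], position = sub$position[i])
    })
    sid <- sub$subject_id[1]
    grp <- if (!is.null(groups)) unname(groups[[sid]]) else NA_character_
    errors_from_trials(sets, subject_id = sid, group = grp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}
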