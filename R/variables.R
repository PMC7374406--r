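#' The 18 repositioning-error variables
#'
#' The classifier operates on 18 features per subject: three spinal regions
#' (thoracic, lumbar, pelvis) by two test positions (sitting, standing) by
#' three error statistics (AE = absolute error, VE = variable error,
#' CE = constant error).  This function returns the canonical key table; its
#' row order is the canonical variable order used everywhere in the package
#' (evidence combination order, tie-breaking in rankings, column order of
#' cohort files).
#'
#' @return A data frame with columns `region`, `position`, `error_type` and
#'   `name` (the lower-case underscore-joined column name, e.g.
#'   `"lumbar_sitting_ae"`), one row per variable, 18 rows.
#' @examples
#' variable_keys()
#' @export
variable_keys <- function() {
  grid <- expand.grid(
    error_type = c("ae", "ve", "ce"),
    position = c("sitting", "standing"),
    region = c("thoracic", "lumbar", "pelvis"),
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("region", "position", "error_type")]
  grid$name <- paste(grid$region, grid$position, grid$error_type, sep = "_")
  rownames(grid) <- NULL
  grid
}

#' Build a single variable name from its key parts
#'
#' @param region One of `"thoracic"`, `"lumbar"`, `"pelvis"`.
#' @param position One of `"sitting"`, `"standing"`.
#' @param error_type One of `"ae"`, `"ve"`, `"ce"` (case-insensitive).
#' @return The canonical column name, e.g. `"pelvis_standing_ve"`.
#' @export
variable_name <- function(region, position, error_type) {
  region <- match.arg(tolower(region), c("thoracic", "lumbar", "pelvis"))
  position <- match.arg(tolower(position), c("sitting", "standing"))
  error_type <- match.arg(tolower(error_type), c("ae", "ve", "ce"))
  paste(region, position, error_type, sep = "_")
}

# Names of the variables that are nonnegative by construction (error
# magnitudes and spreads); CE is signed.
nonneg_variable_names <- function() {
  keys <- variable_keys()
  keys$name[keys$error_type %in% c("ae", "ve")]
}

#' The study group labels
#'
#' `"no-LBP"` are pain-free controls; `"FP"`, `"AEP"` and `"PEP"` are the
#' flexion-pattern, active-extension-pattern and passive-extension-pattern
#' motor-control-impairment subgroups of non-specific low back pain.
#'
#' @return Character vector of the four group labels in canonical order.
#' @export
group_labels <- function() c("no-LBP", "FP", "AEP", "PEP")
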