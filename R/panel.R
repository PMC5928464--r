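#' Longitudinal panel of repeated exposure and outcome measures
#'
#' Validates a long-format table of subjects observed at scheduled visits
#' `t = 1, ..., T`, each visit carrying a single exposure measurement `X`,
#' an outcome `Y`, and optionally time-varying covariates. The panel must be
#' balanced: every subject contributes exactly the visits `1..T`, with no
#' gaps, duplicates, or missing values. For a binary exposure, `X` must be
#' coded 0/1 at every visit.
#'
#' The returned object is a `data.frame` (sorted by subject, then visit)
#' of class `"longitudinal_panel"` with attributes `n_subjects`,
#' `n_visits`, `covariates` and `exposure_type`. Exposure, outcome and
#' covariate histories are derived from it on demand when regression
#' designs are built; they are not stored.
#'
#' @param data a data.frame in long format.
#' @param id,time,exposure,outcome names of the subject-identifier, visit
#'   index, exposure and outcome columns.
#' @param covariates character vector naming time-varying covariate columns
#'   (may be empty).
#' @param exposure_type `"binary"` (default) or `"continuous"`.
#' @return a `longitudinal_panel`, a validated and canonically sorted
#'   data.frame with columns `id`, `t`, `X`, `Y` and any covariates.
#' @examples
#' pan <- generate_panel(dgp_params(scenario = 1, n = 20), seed = 1)
#' pan
#' @export
longitudinal_panel <- function(data, id = "id", time = "t", exposure = "X",
                               outcome = "Y", covariates = character(),
                               exposure_type = c("binary", "continuous")) {
  exposure_type <- match.arg(exposure_type)
  if (!is.data.frame(data)) stop("'data' must be a data.frame")
  need <- c(id, time, exposure, outcome, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- data.frame(id = data[[id]], t = as.integer(data[[time]]),
                   X = data[[exposure]], Y = data[[outcome]])
  for (cv in covariates) df[[cv]] <- data[[cv]]

  for (col in c("X", "Y", covariates)) {
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]]))) {
      stop("missing or non-finite values in column '", col, "'")
    }
  }
  if (exposure_type == "binary" && !all(df$X %in% c(0, 1))) {
    bad <- unique(df$X[!(df$X %in% c(0, 1))])
    stop("binary exposure must be coded 0/1; found value(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }

  df <- df[order(df$id, df$t), , drop = FALSE]
  rownames(df) <- NULL
  T_visits <- max(df$t)
  visits_by_id <- split(df$t, df$id)
  for (sid in names(visits_by_id)) {
    v <- visits_by_id[[sid]]
    if (anyDuplicated(v)) {
      stop("duplicated visit(s) for subject ", sid, ": t = ",
           paste(v[duplicated(v)], collapse = ", "))
    }
    if (!identical(sort(v), seq_len(T_visits))) {
      stop("subject ", sid, " does not have the full visit sequence 1..",
           T_visits, " (observed: ", paste(sort(v), collapse = ", "), ")")
    }
  }

  structure(df,
            class = c("longitudinal_panel", "data.frame"),
            n_subjects = length(visits_by_id),
            n_visits = T_visits,
            covariates = covariates,
            exposure_type = exposure_type)
}

#' @export
print.longitudinal_panel <- function(x, ...) {
  cat(sprintf("Longitudinal panel: %d subjects x %d visits, %s exposure\n",
              n_subjects(x), n_visits(x), exposure_type(x)))
  cv <- panel_covariates(x)
  if (length(cv)) cat("Time-varying covariates:", paste(cv, collapse = ", "), "\n")
  cat("First rows:\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Panel accessors
#'
#' @param panel a [longitudinal_panel()].
#' @return number of subjects, number of visits per subject, covariate
#'   names, or the exposure type.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
n_subjects <- function(panel) attr(panel, "n_subjects")

#' @rdname panel-accessors
#' @export
n_visits <- function(panel) attr(panel, "n_visits")

#' @rdname panel-accessors
#' @export
panel_covariates <- function(panel) attr(panel, "covariates")

#' @rdname panel-accessors
#' @export
exposure_type <- function(panel) attr(panel, "exposure_type")

# visit-major matrix of one panel column: n_subjects x (T+1), first column
# the pre-baseline value 0 (the zero-padding convention for t <= 0)
.panel_matrix <- function(panel, col) {
  n <- n_subjects(panel); T_v <- n_visits(panel)
  m <- matrix(panel[[col]], nrow = T_v, ncol = n)  # rows visits (subject-major sort)
  cbind(0, t(m))
}

#' Read and write panels as CSV
#'
#' Plain comma-separated long-format files with a header row; columns
#' `id`, `t`, `X`, `Y` and any further columns taken as time-varying
#' covariates (in file order). Writing then reading recovers the panel
#' exactly for integer columns and to numerical precision for reals.
#'
#' @param path file path.
#' @param exposure_type passed to [longitudinal_panel()].
#' @return `read_panel_csv` returns a validated [longitudinal_panel()];
#'   `write_panel_csv` invisibly returns `path`.
#' @export
read_panel_csv <- function(path, exposure_type = c("binary", "continuous")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("id", "t", "X", "Y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("panel CSV '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  covs <- setdiff(names(df), need)
  longitudinal_panel(df, covariates = covs,
                     exposure_type = match.arg(exposure_type))
}

#' @rdname read_panel_csv
#' @param panel a [longitudinal_panel()].
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}
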