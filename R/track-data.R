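#' @keywords internal
"_PACKAGE"

# Feature channels every representation carries at minimum.
.core_features <- c("timestamps", "xpos", "ypos")

#' Construct a tracking dataset
#'
#' A `track_data` object bundles a trial-level metadata table with one or
#' more named trajectory representations. Each representation is a 3-D
#' numeric array with dimensions trial x point x feature; trials shorter
#' than the array's point dimension are padded with `NA` (never zeros --
#' zero is a legal coordinate). The per-trial number of real points is
#' defined by the non-missing `timestamps` cells.
#'
#' @param trial_table data.frame with one row per trial; must contain a
#'   `trial_id` column with unique, non-empty values.
#' @param representations named list of 3-D arrays `[trial, point, feature]`.
#'   Feature dimnames must include `timestamps`, `xpos`, `ypos`; the first
#'   dimension's dimnames must equal `trial_table$trial_id`.
#' @param provenance list of operation records (created internally).
#' @return An object of class `track_data`.
#' @export
track_data <- function(trial_table, representations, provenance = list()) {
  stopifnot(is.data.frame(trial_table), is.list(representations))
  if (!"trial_id" %in% names(trial_table))
    stop("trial_table must contain a 'trial_id' column")
  ids <- as.character(trial_table$trial_id)
  if (anyDuplicated(ids) || any(!nzchar(ids)))
    stop("trial_id values must be unique and non-empty")
  trial_table$trial_id <- ids
  for (nm in names(representations)) {
    arr <- representations[[nm]]
    if (length(dim(arr)) != 3L)
      stop("representation '", nm, "' is not a 3-D array")
    if (!all(.core_features %in% dimnames(arr)[[3L]]))
      stop("representation '", nm, "' lacks core features ",
           paste(.core_features, collapse = ", "))
    if (!identical(dimnames(arr)[[1L]], ids))
      stop("representation '", nm, "' trial ids do not match trial_table")
  }
  structure(list(trial_table = trial_table,
                 representations = representations,
                 provenance = provenance),
            class = "track_data")
}

#' @export
print.track_data <- function(x, ...) {
  cat("<track_data>  ", nrow(x$trial_table), " trials\n", sep = "")
  cat("trial_table columns: ", paste(names(x$trial_table), collapse = ", "),
      "\n", sep = "")
  for (nm in names(x$representations)) {
    arr <- x$representations[[nm]]
    vl <- valid_lengths(x, nm)
    cat(sprintf("  $%s: %d x %d x %d [%s]; points per trial %d-%d\n",
                nm, dim(arr)[1L], dim(arr)[2L], dim(arr)[3L],
                paste(dimnames(arr)[[3L]], collapse = ","),
                min(vl), max(vl)))
  }
  cat(length(x$provenance), "provenance record(s)\n")
  invisible(x)
}

#' @export
summary.track_data <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Number of real (non-padding) points per trial
#'
#' @param ds A `track_data` object.
#' @param use Name of the representation.
#' @return Integer vector named by trial id.
#' @export
valid_lengths <- function(ds, use = "trajectories") {
  arr <- get_trajectories(ds, use)
  ts <- arr[, , "timestamps", drop = FALSE]
  out <- apply(!is.na(ts), 1L, sum)
  names(out) <- dimnames(arr)[[1L]]
  out
}

#' Extract a representation array
#'
#' @inheritParams valid_lengths
#' @return 3-D array `[trial, point, feature]`.
#' @export
get_trajectories <- function(ds, use = "trajectories") {
  stopifnot(inherits(ds, "track_data"))
  if (!use %in% names(ds$representations))
    stop("unknown representation '", use, "'; available: ",
         paste(names(ds$representations), collapse = ", "))
  ds$representations[[use]]
}

# Replace/add a representation without validation overhead.
set_trajectories <- function(ds, use, arr) {
  ds$representations[[use]] <- arr
  ds
}

# Append one provenance record. Every exported operation calls this once.
add_provenance <- function(ds, operation, params = list()) {
  ds$provenance[[length(ds$provenance) + 1L]] <-
    list(operation = operation, params = params,
         timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"))
  ds
}

# Valid point matrix of one trial as a data.frame of features.
trial_points <- function(arr, i) {
  keep <- !is.na(arr[i, , "timestamps"])
  arr[i, keep, , drop = FALSE][1, , , drop = TRUE]
}

#' Subset trials
#'
#' Filters the trial table and all trajectory representations consistently,
#' either by a logical predicate over trial-table columns or by an explicit
#' vector of trial ids.
#'
#' @param ds A `track_data` object.
#' @param subset Logical expression over `trial_table` columns (unquoted).
#' @param trial_ids Character vector of trial ids (alternative to `subset`).
#' @return A filtered `track_data` object.
#' @export
#' @examples
#' spec <- synth_spec(n_subjects = 2, seed = 1)
#' ds <- generate_tracking_data(spec)$data
#' subset_trials(ds, condition == "typical")
subset_trials <- function(ds, subset = NULL, trial_ids = NULL) {
  stopifnot(inherits(ds, "track_data"))
  expr <- substitute(subset)
  if (!is.null(trial_ids)) {
    miss <- setdiff(trial_ids, ds$trial_table$trial_id)
    if (length(miss))
      stop("unknown trial ids: ", paste(utils::head(miss, 5), collapse = ", "))
    keep <- ds$trial_table$trial_id %in% trial_ids
    label <- paste0("trial_ids[", length(trial_ids), "]")
  } else if (!is.null(expr)) {
    keep <- eval(expr, ds$trial_table, parent.frame())
    if (!is.logical(keep) || length(keep) != nrow(ds$trial_table))
      stop("subset predicate must yield one logical per trial")
    keep[is.na(keep)] <- FALSE
    label <- deparse(expr)
  } else stop("provide either 'subset' or 'trial_ids'")
  if (!any(keep)) stop("subset removes all trials; empty dataset is unusable")
  removed <- sum(!keep)
  tt <- ds$trial_table[keep, , drop = FALSE]
  rownames(tt) <- NULL
  reps <- lapply(ds$representations, function(a) {
    out <- a[keep, , , drop = FALSE]
    # drop padding columns that are now empty for every surviving trial
    vl <- apply(!is.na(out[, , "timestamps", drop = FALSE]), 1L, sum)
    out[, seq_len(max(vl)), , drop = FALSE]
  })
  out <- track_data(tt, reps, ds$provenance)
  add_provenance(out, "subset_trials",
                 list(predicate = label, removed = removed))
}

#' Plot trajectories
#'
#' Draws every trajectory of a representation as a line in x/y space,
#' optionally colored by a trial-table column.
#'
#' @param x A `track_data` object.
#' @param use Representation to draw.
#' @param color Optional trial-table column used to color lines.
#' @param alpha Line transparency in `[0, 1]`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.track_data <- function(x, use = "trajectories", color = NULL,
                            alpha = 0.25, ...) {
  arr <- get_trajectories(x, use)
  xr <- range(arr[, , "xpos"], na.rm = TRUE)
  yr <- range(arr[, , "ypos"], na.rm = TRUE)
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "xpos (px)",
                 ylab = "ypos (px)", ...)
  if (!is.null(color)) {
    grp <- as.factor(x$trial_table[[color]])
    pal <- grDevices::hcl.colors(nlevels(grp), "Dark 3")
    cols <- grDevices::adjustcolor(pal[as.integer(grp)], alpha.f = alpha)
  } else {
    cols <- rep(grDevices::adjustcolor("grey20", alpha.f = alpha),
                dim(arr)[1L])
  }
  for (i in seq_len(dim(arr)[1L]))
    graphics::lines(arr[i, , "xpos"], arr[i, , "ypos"], col = cols[i])
  invisible(x)
}

# Rebuild a representation array from a list of per-trial matrices whose
# columns are features. Pads with NA to the longest trial.
build_array <- function(mats, ids, features) {
  maxlen <- max(vapply(mats, nrow, 1L))
  arr <- array(NA_real_, dim = c(length(mats), maxlen, length(features)),
               dimnames = list(ids, NULL, features))
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    arr[i, seq_len(nrow(m)), ] <- m[, features, drop = FALSE]
  }
  arr
}

# Apply a per-trial transform f(matrix of valid points) -> matrix and rebuild.
map_trials <- function(arr, f) {
  ids <- dimnames(arr)[[1L]]
  features <- dimnames(arr)[[3L]]
  mats <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    keep <- !is.na(arr[i, , "timestamps"])
    m <- matrix(arr[i, keep, ], nrow = sum(keep),
                dimnames = list(NULL, features))
    mats[[i]] <- f(m, i)
  }
  features_out <- colnames(mats[[1L]])
  build_array(mats, ids, features_out)
}
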