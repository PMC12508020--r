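#' Import long-format trajectory logs
#'
#' Converts a long table (one row per recorded sample) into a [track_data()]
#' dataset. Rows are grouped into trials by the id columns, sorted by
#' timestamp within trial, and constant-per-trial columns are moved to the
#' trial table. Timestamps are shifted so that every trial starts at 0 (the
#' original offsets are kept in the provenance record); trajectory indices
#' such as initiation time and response time are trial-relative.
#'
#' @param data data.frame in long format.
#' @param id_columns character vector of columns that jointly identify a
#'   trial. The trial id is their values joined with `"_"`.
#' @param time_col,x_col,y_col column names of the timestamp (ms) and pixel
#'   coordinates.
#' @param screen_y_down set `TRUE` when the source uses screen coordinates
#'   (y grows downward); y is negated at import so that the package's
#'   mathematical y-up convention holds.
#' @param rep_name name under which the representation is stored.
#' @return A `track_data` object.
#' @details Rows with a missing coordinate are rejected (a message reports
#'   the count). Duplicate timestamps within a trial trigger a warning and
#'   only the first row is kept. Non-constant numeric extra columns become
#'   additional feature channels; non-numeric varying columns are dropped
#'   with a message.
#' @export
import_long <- function(data, id_columns, time_col = "timestamps",
                        x_col = "xpos", y_col = "ypos",
                        screen_y_down = FALSE, rep_name = "trajectories") {
  data <- as.data.frame(data)
  if (missing(id_columns) || length(id_columns) == 0L)
    stop("at least one id column is required")
  missing_cols <- setdiff(c(id_columns, time_col, x_col, y_col), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(data[[time_col]]))
    stop("time column '", time_col, "' must be numeric")

  bad <- is.na(data[[x_col]]) | is.na(data[[y_col]])
  if (any(bad)) {
    message(sum(bad), " row(s) with missing coordinates rejected")
    data <- data[!bad, , drop = FALSE]
  }
  if (screen_y_down) data[[y_col]] <- -data[[y_col]]

  id <- do.call(paste, c(lapply(id_columns, function(cn) data[[cn]]),
                         sep = "_"))
  ord <- order(match(id, unique(id)), data[[time_col]])
  data <- data[ord, , drop = FALSE]
  id <- id[ord]

  groups <- split(seq_len(nrow(data)), factor(id, levels = unique(id)))
  short <- names(groups)[vapply(groups, length, 1L) < 2L]
  if (length(short))
    stop("trial(s) with fewer than 2 samples: ",
         paste(utils::head(short, 5), collapse = ", "))

  other <- setdiff(names(data), c(id_columns, time_col, x_col, y_col))
  is_const <- vapply(other, function(cn) {
    v <- data[[cn]]
    all(vapply(groups, function(idx) length(unique(v[idx])) == 1L, TRUE))
  }, TRUE)
  meta_cols <- other[is_const]
  varying <- other[!is_const]
  extra_feats <- varying[vapply(varying, function(cn)
    is.numeric(data[[cn]]), TRUE)]
  dropped <- setdiff(varying, extra_feats)
  if (length(dropped))
    message("dropping non-numeric varying column(s): ",
            paste(dropped, collapse = ", "))

  n_dup <- 0L
  meta_rows <- vector("list", length(groups))
  mats <- vector("list", length(groups))
  offsets <- numeric(length(groups))

  for (g in seq_along(groups)) {
    rows <- data[groups[[g]], , drop = FALSE]
    dup <- duplicated(rows[[time_col]])
    if (any(dup)) { n_dup <- n_dup + sum(dup); rows <- rows[!dup, , drop = FALSE] }
    offsets[g] <- rows[[time_col]][1L]
    m <- cbind(timestamps = rows[[time_col]] - offsets[g],
               xpos = as.numeric(rows[[x_col]]),
               ypos = as.numeric(rows[[y_col]]))
    for (cn in extra_feats) m <- cbind(m, as.numeric(rows[[cn]]))
    colnames(m) <- c("timestamps", "xpos", "ypos", extra_feats)
    mats[[g]] <- m
    meta_rows[[g]] <- rows[1L, c(id_columns, meta_cols), drop = FALSE]
  }
  if (n_dup > 0L)
    warning(n_dup, " duplicate timestamp(s) within trials; kept first")

  tt <- do.call(rbind, meta_rows)
  rownames(tt) <- NULL
  tt <- cbind(trial_id = names(groups), tt, stringsAsFactors = FALSE)
  arr <- build_array(mats, names(groups),
                     c("timestamps", "xpos", "ypos", extra_feats))
  ds <- track_data(tt, stats::setNames(list(arr), rep_name))
  add_provenance(ds, "import_long",
                 list(id_columns = id_columns, n_trials = length(groups),
                      rejected_rows = sum(bad), duplicate_timestamps = n_dup,
                      time_offsets_range = range(offsets)))
}

#' Import wide-format trajectory logs
#'
#' One row per trial; each feature spans indexed columns named
#' `<prefix>_<k>` with 1-based `k` (e.g. `xpos_1 ... xpos_300`). Trailing
#' empty cells are padding; the number of real points per trial is the count
#' of non-empty coordinate cells, which must agree across features.
#'
#' @param data data.frame in wide format.
#' @param id_columns optional id columns (joined with `"_"`); defaults to
#'   the row number.
#' @param prefixes named character vector mapping the core features
#'   (`timestamps`, `xpos`, `ypos`) to their column prefixes.
#' @inheritParams import_long
#' @return A `track_data` object.
#' @export
import_wide <- function(data, id_columns = NULL,
                        prefixes = c(timestamps = "timestamps",
                                     xpos = "xpos", ypos = "ypos"),
                        screen_y_down = FALSE, rep_name = "trajectories") {
  data <- as.data.frame(data)
  stopifnot(all(c("timestamps", "xpos", "ypos") %in% names(prefixes)))
  cols <- lapply(prefixes, function(p) {
    rx <- paste0("^", p, "_([0-9]+)$")
    hits <- grep(rx, names(data), value = TRUE)
    if (!length(hits)) stop("no columns match prefix '", p, "_<k>'")
    hits[order(as.integer(sub(rx, "\\1", hits)))]
  })
  ids <- if (is.null(id_columns)) as.character(seq_len(nrow(data))) else
    do.call(paste, c(lapply(id_columns, function(cn) data[[cn]]), sep = "_"))

  mats <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    vals <- lapply(cols, function(cc) as.numeric(data[i, cc]))
    lens <- vapply(vals, function(v) {
      nn <- which(!is.na(v))
      if (!length(nn)) 0L else max(nn)
    }, 1L)
    if (length(unique(lens)) != 1L)
      stop("ragged feature groups for trial '", ids[i], "': lengths ",
           paste(names(lens), lens, sep = "=", collapse = ", "))
    L <- lens[[1L]]
    if (L < 2L) stop("trial '", ids[i], "' has fewer than 2 samples")
    m <- vapply(vals, function(v) v[seq_len(L)], numeric(L))
    if (anyNA(m)) stop("internal gaps in trajectory cells for trial '",
                       ids[i], "'")
    colnames(m) <- names(cols)
    m <- m[, c("timestamps", "xpos", "ypos"), drop = FALSE]
    m[, "timestamps"] <- m[, "timestamps"] - m[1L, "timestamps"]
    if (screen_y_down) m[, "ypos"] <- -m[, "ypos"]
    mats[[i]] <- m
  }
  traj_cols <- unlist(cols, use.names = FALSE)
  meta <- data[, setdiff(names(data), traj_cols), drop = FALSE]
  tt <- cbind(trial_id = ids, meta, stringsAsFactors = FALSE)
  rownames(tt) <- NULL
  arr <- build_array(mats, ids, c("timestamps", "xpos", "ypos"))
  ds <- track_data(tt, stats::setNames(list(arr), rep_name))
  add_provenance(ds, "import_wide",
                 list(prefixes = prefixes, n_trials = nrow(data)))
}

#' Read and row-bind all delimited files in a folder
#'
#' @param path directory containing the files.
#' @param pattern regular expression selecting files (default: CSV).
#' @param sep,dec field separator and decimal mark.
#' @return data.frame with the union of all columns plus a `source` column
#'   naming the originating file; cells absent from a file are `NA`.
#' @export
read_folder <- function(path, pattern = "\\.csv$", sep = ",", dec = ".") {
  files <- list.files(path, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop("no files matching '", pattern, "' in ", path)
  tabs <- lapply(files, function(f) {
    tab <- tryCatch(utils::read.table(f, header = TRUE, sep = sep, dec = dec,
                                      stringsAsFactors = FALSE),
                    error = function(e) stop("unreadable file '", basename(f),
                                             "': ", conditionMessage(e)))
    tab$source <- basename(f)
    tab
  })
  all_cols <- Reduce(union, lapply(tabs, names))
  tabs <- lapply(tabs, function(tab) {
    for (cn in setdiff(all_cols, names(tab))) tab[[cn]] <- NA
    tab[, all_cols, drop = FALSE]
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Export a representation to long format
#'
#' Padding cells are omitted; column names round-trip through
#' [import_long()] with `id_columns = "trial_id"`.
#'
#' @inheritParams valid_lengths
#' @return data.frame with `trial_id` plus one column per feature channel.
#' @export
export_long <- function(ds, use = "trajectories") {
  arr <- get_trajectories(ds, use)
  ids <- dimnames(arr)[[1L]]
  features <- dimnames(arr)[[3L]]
  vl <- valid_lengths(ds, use)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    k <- seq_len(vl[i])
    block <- as.data.frame(matrix(arr[i, k, ], nrow = vl[i],
                                  dimnames = list(NULL, features)))
    out[[i]] <- cbind(trial_id = ids[i], block, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge trial metadata with a measures table for export
#'
#' @param measures data.frame keyed by `trial_id` (e.g. from
#'   [compute_measures()]).
#' @param trial_table optional trial table (or a `track_data` object) to
#'   join on `trial_id`.
#' @return data.frame with one row per trial.
#' @export
export_measures <- function(measures, trial_table = NULL) {
  stopifnot("trial_id" %in% names(measures))
  if (is.null(trial_table)) return(measures)
  if (inherits(trial_table, "track_data")) trial_table <- trial_table$trial_table
  merge(trial_table, measures, by = "trial_id", sort = FALSE)
}
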