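# Flat delimited morphometry tables: one row per subject-timepoint, columns
# = covariate/clinical fields + the 82 registry regions (any column order).

#' Validate and classify a morphometry table
#'
#' Checks a data.frame against the 82-region registry layout: all ROI values
#' finite and strictly positive, group/timepoint labels valid, and every
#' patient follow-up row paired with a baseline row of the same subject.
#'
#' @param df data.frame with the registry ROI columns plus `subject_id`,
#'   `group` (`HC`/`patient`), `timepoint` (`baseline`/`followup`), `age`,
#'   `sex` (0 = female, 1 = male), `icv`, and optionally `vas_pre`,
#'   `vas_post`, `pain_duration`.
#' @param registry a `roi_registry`, by default [build_dk_registry()].
#' @return the table with ROI columns reordered into registry order, class
#'   `morphometry_table`.
#' @export
as_morphometry_table <- function(df, registry = build_dk_registry()) {
  stopifnot(is.data.frame(df))
  required_meta <- c("subject_id", "group", "timepoint", "age", "sex", "icv")
  missing_meta <- setdiff(required_meta, names(df))
  if (length(missing_meta))
    stop("missing required column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  missing_roi <- setdiff(registry$name, names(df))
  if (length(missing_roi))
    stop("missing ROI column(s): ", paste(missing_roi, collapse = ", "),
         call. = FALSE)
  for (opt in c("vas_pre", "vas_post", "pain_duration"))
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  for (num in c("age", "sex", "icv", "vas_pre", "vas_post", "pain_duration"))
    df[[num]] <- as.numeric(df[[num]])
  bad_group <- setdiff(unique(df$group), c("HC", "patient"))
  if (length(bad_group))
    stop("invalid group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  bad_tp <- setdiff(unique(df$timepoint), c("baseline", "followup"))
  if (length(bad_tp))
    stop("invalid timepoint label(s): ", paste(bad_tp, collapse = ", "),
         call. = FALSE)

  roi <- as.matrix(df[, registry$name, drop = FALSE])
  if (!is.numeric(roi))
    stop("non-numeric ROI values present", call. = FALSE)
  bad <- which(!is.finite(roi) | roi <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite or non-positive ROI value for subject '",
         df$subject_id[bad[1, 1]], "', ROI '",
         registry$name[bad[1, 2]], "'", call. = FALSE)

  fu <- df$group == "patient" & df$timepoint == "followup"
  bl_ids <- df$subject_id[df$group == "patient" & df$timepoint == "baseline"]
  orphan <- setdiff(df$subject_id[fu], bl_ids)
  if (length(orphan))
    stop("follow-up row(s) without a baseline row: ",
         paste(orphan, collapse = ", "), call. = FALSE)

  out <- cbind(df[, intersect(MORPHOMETRY_META_COLS, names(df)), drop = FALSE],
               as.data.frame(roi))
  rownames(out) <- NULL
  class(out) <- c("morphometry_table", "data.frame")
  out
}

#' Read a flat delimited morphometry table
#'
#' @param path file path to a CSV/TSV table, one row per subject-timepoint.
#' @param sep field delimiter; `","` (default) or `"\t"` etc.
#' @param registry a `roi_registry`.
#' @return a `morphometry_table` (see [as_morphometry_table()]); columns are
#'   reordered into registry order regardless of file order; unknown columns
#'   are dropped with a message.
#' @export
read_flat_table <- function(path, sep = ",", registry = build_dk_registry()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  unknown <- setdiff(names(df), c(MORPHOMETRY_META_COLS, registry$name))
  if (length(unknown))
    message("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  as_morphometry_table(df[, setdiff(names(df), unknown), drop = FALSE],
                       registry)
}

#' Write a morphometry table to a delimited file
#'
#' @param table a `morphometry_table`.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_flat_table <- function(table, path, sep = ",") {
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# split helpers used throughout the pipeline
cohort_rows <- function(table, group, timepoint = NULL) {
  keep <- table$group == group
  if (!is.null(timepoint)) keep <- keep & table$timepoint == timepoint
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

roi_matrix <- function(table, registry = build_dk_registry()) {
  m <- as.matrix(table[, registry$name, drop = FALSE])
  rownames(m) <- table$subject_id
  m
}
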