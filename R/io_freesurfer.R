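# FreeSurfer-style stats tables: aparc.stats per hemisphere (cortical
# thickness, ThickAvg column) and aseg.stats (subcortical Volume_mm3 plus
# the EstimatedTotalIntraCranialVol header measure). Only the whitespace-
# delimited text dialect is supported; surfaces/volumes are out of scope.

parse_fs_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  ch <- header[grepl("^# ColHeaders", header)]
  if (length(ch) != 1)
    stop("unparseable stats file (no ColHeaders line): ", path, call. = FALSE)
  cols <- strsplit(trimws(sub("^# ColHeaders", "", ch)), "\\s+")[[1]]
  if (!length(body)) stop("stats file has no body rows: ", path, call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(cols)))
    stop("unparseable stats body (field count mismatch): ", path,
         call. = FALSE)
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- cols
  list(header = header, table = tab)
}

fs_measure <- function(header, measure) {
  ln <- header[grepl(paste0("^# Measure ", measure, ","), header)]
  if (length(ln) != 1) return(NA_real_)
  parts <- strsplit(ln[1], ",")[[1]]
  as.numeric(trimws(parts[length(parts) - 1]))
}

#' Read FreeSurfer aparc/aseg stats tables into a morphometry row
#'
#' Parses the two hemisphere `aparc.stats` tables (mean cortical thickness,
#' `ThickAvg`) and the `aseg.stats` table (subcortical `Volume_mm3` and the
#' `EstimatedTotalIntraCranialVol` header measure) and assembles the 82
#' registry-ordered region values for one subject. Clinical fields are left
#' `NA`; bind the result into a cohort and fill them before analysis.
#'
#' @param aparc_left,aparc_right paths to `lh.aparc.stats` / `rh.aparc.stats`.
#' @param aseg path to `aseg.stats`.
#' @param subject_id subject identifier stored in the output row.
#' @param registry a `roi_registry`.
#' @return a one-row data.frame with `subject_id`, `icv` and the 82 ROI
#'   columns in registry order (`age`, `sex`, group and clinical fields `NA`).
#' @export
read_freesurfer_stats <- function(aparc_left, aparc_right, aseg,
                                  subject_id = "subject",
                                  registry = build_dk_registry()) {
  read_aparc <- function(path) {
    p <- parse_fs_stats(path)
    if (!all(c("StructName", "ThickAvg") %in% names(p$table)))
      stop("aparc table lacks StructName/ThickAvg columns: ", path,
           call. = FALSE)
    stats::setNames(as.numeric(p$table$ThickAvg), p$table$StructName)
  }
  lh <- read_aparc(aparc_left)
  rh <- read_aparc(aparc_right)

  aseg_p <- parse_fs_stats(aseg)
  if (!all(c("StructName", "Volume_mm3") %in% names(aseg_p$table)))
    stop("aseg table lacks StructName/Volume_mm3 columns: ", aseg,
         call. = FALSE)
  vols <- stats::setNames(as.numeric(aseg_p$table$Volume_mm3),
                          aseg_p$table$StructName)
  icv <- fs_measure(aseg_p$header, "EstimatedTotalIntraCranialVol")
  if (!is.finite(icv))
    stop("aseg header lacks EstimatedTotalIntraCranialVol measure: ", aseg,
         call. = FALSE)

  # FreeSurfer >= 7.2 renamed Left-Thalamus-Proper -> Left-Thalamus
  aseg_alias <- function(name) {
    if (name %in% names(vols)) return(name)
    alt <- sub("-Proper$", "", name)
    if (alt %in% names(vols)) return(alt)
    NA_character_
  }

  vals <- numeric(nrow(registry))
  for (k in seq_len(nrow(registry))) {
    r <- registry[k, ]
    if (r$kind == "cortical") {
      src <- if (r$hemisphere == "left") lh else rh
      if (!r$atlas_label %in% names(src))
        stop("aparc table missing region '", r$atlas_label, "' (",
             r$hemisphere, ")", call. = FALSE)
      vals[k] <- src[[r$atlas_label]]
    } else {
      nm <- aseg_alias(r$name)
      if (is.na(nm))
        stop("aseg table missing structure '", r$name, "'", call. = FALSE)
      vals[k] <- vols[[nm]]
    }
  }
  out <- data.frame(subject_id = subject_id, group = NA_character_,
                    timepoint = NA_character_, age = NA_real_, sex = NA_real_,
                    icv = icv, vas_pre = NA_real_, vas_post = NA_real_,
                    pain_duration = NA_real_, stringsAsFactors = FALSE)
  out[registry$name] <- as.list(vals)
  out
}

#' Write FreeSurfer-style stats fixtures for one morphometry row
#'
#' Emits `lh.aparc.stats`, `rh.aparc.stats` and `aseg.stats` text files in
#' the whitespace-delimited dialect that [read_freesurfer_stats()] parses,
#' so that a write-then-read round trip recovers the row's 82 region values
#' and intracranial volume exactly (to the 6-decimal formatting used).
#'
#' @param row one-row `morphometry_table` slice (or compatible data.frame).
#' @param out_dir output directory (created if needed).
#' @param registry a `roi_registry`.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_fixture_freesurfer <- function(row, out_dir,
                                     registry = build_dk_registry()) {
  stopifnot(nrow(row) == 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(x) sprintf("%.6f", x)

  aparc_lines <- function(hemi) {
    reg <- registry[registry$kind == "cortical" &
                      registry$hemisphere == hemi, ]
    c(sprintf("# Table of FreeSurfer cortical parcellation anatomical statistics (synthetic fixture)"),
      sprintf("# subjectname %s", row$subject_id),
      sprintf("# hemi %s", if (hemi == "left") "lh" else "rh"),
      "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd",
      sprintf("%s 1000 600 2000 %s 0.500000 0.100000 0.020000 10 1.000000",
              reg$atlas_label, num(as.numeric(row[, reg$name]))))
  }
  aseg_reg <- registry[registry$kind == "subcortical", ]
  aseg_lines <- c(
    "# Title Segmentation Statistics (synthetic fixture)",
    sprintf("# subjectname %s", row$subject_id),
    sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %s, mm^3",
            num(row$icv)),
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean normStdDev normMin normMax normRange",
    sprintf("%d %d 1000 %s %s 80.000000 10.000000 40.000000 120.000000 80.000000",
            seq_len(nrow(aseg_reg)), 9 + seq_len(nrow(aseg_reg)),
            num(as.numeric(row[, aseg_reg$name])), aseg_reg$name))

  paths <- c(aparc_left = file.path(out_dir, "lh.aparc.stats"),
             aparc_right = file.path(out_dir, "rh.aparc.stats"),
             aseg = file.path(out_dir, "aseg.stats"))
  writeLines(aparc_lines("left"), paths[["aparc_left"]])
  writeLines(aparc_lines("right"), paths[["aparc_right"]])
  writeLines(aseg_lines, paths[["aseg"]])
  invisible(paths)
}
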