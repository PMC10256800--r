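#' Load the packaged porcine study findings
#'
#' The package ships the per-subject, per-contour findings of the porcine
#' validation study as delimited tables: for the group B animals, the
#' ventilation change class at each of the nine analysis contours, the
#' ordinal trichrome collagen grade (with fixation-artifact flags) and
#' the H&E histologic diagnoses with strengths; for the group A animals,
#' the binary collagen findings and structural observations at the
#' maximum-dose and contralateral points.  Cell values that the study
#' reported only as ranges or group summaries were reconstructed from its
#' per-contour textual descriptions; the tables use exactly the schema of
#' the synthetic generator so every downstream stage runs unchanged on
#' either source.
#'
#' @param name `"groupA"` or `"groupB"`.
#' @return For `"groupB"`: list with `ventilation`, `collagen`,
#'   `diagnoses` data frames.  For `"groupA"`: list with `collagen` and
#'   `diagnoses` data frames (binary collagen stored as grades
#'   no-significant/mild for damage-rule compatibility).
#' @export
load_study_fixture <- function(name = c("groupB", "groupA")) {
  name <- match.arg(name)
  dir <- system.file("extdata", package = "lungfx")
  checks <- utils::read.csv(file.path(dir, "checksums.csv"),
                            stringsAsFactors = FALSE)
  grab <- function(fname) {
    path <- file.path(dir, fname)
    if (!file.exists(path))
      stop("packaging error: fixture ", fname, " missing", call. = FALSE)
    want <- checks$md5[checks$file == fname]
    got <- unname(tools::md5sum(path))
    if (length(want) != 1L || !identical(got, want))
      stop("packaging error: checksum mismatch for ", fname, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (name == "groupB") {
    list(ventilation = grab("groupB_ventilation.csv"),
         collagen = grab("groupB_collagen.csv"),
         diagnoses = grab("groupB_diagnoses.csv"))
  } else {
    raw <- grab("groupA_findings.csv")
    collagen <- raw[raw$observation == "collagen", ]
    collagen <- data.frame(subject = collagen$subject,
                           contour = collagen$contour,
                           grade_label = ifelse(collagen$present == 1,
                                                "mild", "no significant"),
                           artifact_suspect = FALSE)
    dg <- raw[raw$observation != "collagen" & raw$present == 1, ]
    diagnoses <- data.frame(subject = dg$subject, contour = dg$contour,
                            diagnosis = dg$observation,
                            strength_label = "mild")
    list(collagen = collagen, diagnoses = diagnoses)
  }
}
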