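# Ordinal histopathology modelling and biomarker-versus-pathology
# concordance.
#
# Collagen deposition on trichrome-stained sections is graded on a
# six-step ordinal scale (no significant ... severe); readings falling
# between two steps are recorded as hyphenated ranges and mapped to the
# midpoint.  H&E-based histologic diagnoses come from a closed vocabulary
# with the same strength scale.  Each subject x contour point is reduced
# to a damage class, the matched ventilation change class to a
# decline/no-decline class, and agreement is tallied under an explicit
# policy table.

collagen_scale <- c("no significant" = 0, "minimal" = 1, "mild" = 2,
                    "moderate" = 3, "marked" = 4, "severe" = 5)

#' Diagnosis vocabulary
#'
#' The closed set of histologic diagnoses recognised by the package.
#' @export
diagnosis_vocab <- function() {
  c("fibrosis", "inflammation", "chondrocyte_necrosis", "histiocytosis",
    "multinucleated_giant_cells", "bronchitis", "bronchial_ulceration",
    "type2_pneumocyte_hyperplasia", "alveolar_septa_thickening",
    "vascular_proliferation", "neovascularization", "vascular_necrosis",
    "multinucleated_macrophages", "proteinaceous_fluid", "mineralization",
    "red_blood_cell_proliferation")
}

#' Parse an ordinal collagen grade label
#'
#' Single labels map to integers 0-5 in scale order (no significant,
#' minimal, mild, moderate, marked, severe); hyphenated range labels such
#' as `"minimal-mild"` map to the midpoint (1.5).  Parsing is
#' case-insensitive and order-preserving.
#'
#' @param label character vector of grade labels.
#' @return numeric grades in `{0, 0.5, ..., 5}`.
#' @export
parse_collagen_grade <- function(label) {
  one <- function(lab) {
    key <- tolower(trimws(lab))
    if (key %in% names(collagen_scale)) return(unname(collagen_scale[key]))
    parts <- tolower(trimws(strsplit(key, "-")[[1]]))
    # "no significant" contains no hyphen; range labels have two known parts
    if (length(parts) == 2L && all(parts %in% names(collagen_scale)))
      return(mean(collagen_scale[parts]))
    stop("vocabulary error: unknown collagen grade ", sQuote(lab),
         "; accepted labels: ", paste(names(collagen_scale), collapse = ", "),
         " and hyphenated ranges of adjacent labels", call. = FALSE)
  }
  vapply(label, one, numeric(1), USE.NAMES = FALSE)
}

parse_strength <- parse_collagen_grade  # diagnoses use the same scale

#' Pathology damage class of one subject x contour
#'
#' `Damaged` when the collagen grade reaches Mild (2) or fibrosis is
#' present at strength >= 2, with artifact-suspect collagen findings
#' (e.g. fixation artifacts) excluded from the evidence; `NotDamaged`
#' when collagen is at most 0.5 and no diagnosis reaches strength 2;
#' `Intermediate` otherwise.  The class is monotone in the collagen
#' grade.
#'
#' @param collagen numeric collagen grade (from [parse_collagen_grade()]).
#' @param diagnoses data frame with columns `diagnosis` and `strength`
#'   (numeric) for this subject x contour; may have zero rows.
#' @param artifact_suspect whether the collagen finding was flagged as a
#'   suspected fixation artifact.
#' @return `"Damaged"`, `"Intermediate"` or `"NotDamaged"`.
#' @export
pathology_damage_class <- function(collagen, diagnoses = NULL,
                                   artifact_suspect = FALSE) {
  eff_collagen <- if (isTRUE(artifact_suspect)) 0 else collagen
  fib <- 0
  max_strength <- 0
  if (!is.null(diagnoses) && nrow(diagnoses)) {
    bad <- setdiff(diagnoses$diagnosis, diagnosis_vocab())
    if (length(bad))
      stop("vocabulary error: unknown diagnosis ", sQuote(bad[1]),
           call. = FALSE)
    f <- diagnoses$strength[diagnoses$diagnosis == "fibrosis"]
    if (length(f)) fib <- max(f)
    max_strength <- max(diagnoses$strength)
  }
  if (eff_collagen >= 2 || fib >= 2) return("Damaged")
  if (eff_collagen <= 0.5 && max_strength < 2) return("NotDamaged")
  "Intermediate"
}

#' Biomarker point class from a ventilation change class
#'
#' Concordance uses a binary biomarker reading: `Decline` exactly when
#' the change class is Decline; Stable and Increase both map to
#' `NoDecline`.
#'
#' @param change character or factor change class(es)
#'   (`Decline`/`Stable`/`Increase`).
#' @export
biomarker_point_class <- function(change) {
  change <- as.character(change)
  ok <- change %in% c("Decline", "Stable", "Increase")
  if (!all(ok))
    stop("value error: unknown change class ", sQuote(change[!ok][1]),
         call. = FALSE)
  ifelse(change == "Decline", "Decline", "NoDecline")
}

#' Default biomarker-vs-pathology agreement policy
#'
#' The operational agreement rule is a policy table over
#' (biomarker, pathology) pairs: Decline agrees with Damaged, NoDecline
#' agrees with NotDamaged, and an Intermediate pathology reading agrees
#' with NoDecline (sub-threshold tissue findings are not counted against
#' a biomarker that reports no decline); every other pair disagrees.
#' This rule is an interpretation -- published concordance tallies do not
#' print their rule -- and is exposed here so alternatives can be
#' substituted.
#'
#' @return data frame with columns `biomarker`, `pathology`, `agree`.
#' @export
default_agreement_policy <- function() {
  expand <- expand.grid(biomarker = c("Decline", "NoDecline"),
                        pathology = c("Damaged", "Intermediate",
                                      "NotDamaged"),
                        stringsAsFactors = FALSE)
  expand$agree <- with(expand,
    (biomarker == "Decline" & pathology == "Damaged") |
    (biomarker == "NoDecline" & pathology == "NotDamaged") |
    (biomarker == "NoDecline" & pathology == "Intermediate"))
  expand
}

#' Agreement of a biomarker class with a pathology class
#'
#' @param biomarker `"Decline"` or `"NoDecline"` (vectorised).
#' @param pathology `"Damaged"`, `"Intermediate"` or `"NotDamaged"`.
#' @param policy policy table, see [default_agreement_policy()].
#' @return logical vector.
#' @export
agreement <- function(biomarker, pathology,
                      policy = default_agreement_policy()) {
  key <- paste(biomarker, pathology)
  pol <- stats::setNames(policy$agree, paste(policy$biomarker,
                                             policy$pathology))
  if (any(!key %in% names(pol)))
    stop("value error: class pair outside policy table: ",
         sQuote(key[!key %in% names(pol)][1]), call. = FALSE)
  unname(pol[key])
}

#' Build the biomarker-vs-pathology concordance table
#'
#' Expects the study tables of one group: a ventilation table (one change
#' class per subject x contour), a collagen table and a diagnosis table.
#' Every subject x contour cell of the ventilation table becomes one
#' evaluation point; a missing collagen cell is a completeness error.
#'
#' @param ventilation data frame with columns `subject`, `contour`,
#'   `change_class`.
#' @param collagen data frame with columns `subject`, `contour`,
#'   `grade_label`, `artifact_suspect` (logical or 0/1).
#' @param diagnoses data frame with columns `subject`, `contour`,
#'   `diagnosis`, `strength_label`; may be empty.
#' @param policy agreement policy table.
#' @return list of class `concordance` with `table` (one row per point:
#'   subject, contour, biomarker_class, pathology_class, agree),
#'   `n_points`, `n_agree`, `rate`.
#' @export
build_concordance <- function(ventilation, collagen, diagnoses = NULL,
                              policy = default_agreement_policy()) {
  rows <- list()
  for (r in seq_len(nrow(ventilation))) {
    subj <- ventilation$subject[r]; cont <- ventilation$contour[r]
    ccell <- collagen[collagen$subject == subj & collagen$contour == cont, ]
    if (nrow(ccell) == 0L)
      stop("completeness error: no collagen record for subject ", subj,
           ", contour ", cont, call. = FALSE)
    if (nrow(ccell) > 1L)
      stop("completeness error: duplicate collagen records for subject ",
           subj, ", contour ", cont, call. = FALSE)
    dg <- if (is.null(diagnoses)) NULL else
      diagnoses[diagnoses$subject == subj & diagnoses$contour == cont, ]
    dgn <- if (!is.null(dg) && nrow(dg)) {
      data.frame(diagnosis = dg$diagnosis,
                 strength = parse_strength(dg$strength_label))
    } else NULL
    pc <- pathology_damage_class(parse_collagen_grade(ccell$grade_label),
                                 dgn,
                                 as.logical(ccell$artifact_suspect))
    bc <- biomarker_point_class(ventilation$change_class[r])
    rows[[r]] <- data.frame(subject = subj, contour = cont,
                            biomarker_class = bc, pathology_class = pc,
                            agree = agreement(bc, pc, policy))
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, n_points = nrow(tab),
                 n_agree = sum(tab$agree),
                 rate = sum(tab$agree) / nrow(tab)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance: %d/%d points agree (%.0f%%)\n", x$n_agree,
              x$n_points, 100 * x$rate))
  dis <- x$table[!x$table$agree, c("subject", "contour")]
  if (nrow(dis))
    cat("  disagreements:",
        paste(sprintf("(%s, %s)", dis$subject, dis$contour),
              collapse = ", "), "\n")
  invisible(x)
}

#' Tally diagnoses by contour
#'
#' Counts, per (contour, diagnosis) cell, the number of distinct subjects
#' in which the diagnosis was observed (duplicate records of one subject
#' count once).
#'
#' @param records data frame with columns `subject`, `contour`,
#'   `diagnosis` (one study group).
#' @return data frame `contour` x `diagnosis` -> `n_subjects`, including
#'   zero rows for unobserved combinations of the contours and diagnoses
#'   present in `records`.
#' @export
diagnosis_tally <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    return(data.frame(contour = character(0), diagnosis = character(0),
                      n_subjects = integer(0)))
  u <- unique(records[, c("subject", "contour", "diagnosis")])
  agg <- stats::aggregate(subject ~ contour + diagnosis, data = u,
                          FUN = function(s) length(unique(s)))
  names(agg)[3] <- "n_subjects"
  full <- expand.grid(contour = unique(records$contour),
                      diagnosis = unique(records$diagnosis),
                      stringsAsFactors = FALSE)
  out <- merge(full, agg, by = c("contour", "diagnosis"), all.x = TRUE)
  out$n_subjects[is.na(out$n_subjects)] <- 0L
  out[order(out$contour, out$diagnosis), , drop = FALSE]
}

#' Query one cell of a diagnosis tally
#' @param tally output of [diagnosis_tally()].
#' @param contour,diagnosis cell coordinates.
#' @export
tally_count <- function(tally, contour, diagnosis) {
  hit <- tally$contour == contour & tally$diagnosis == diagnosis
  if (!any(hit)) return(0L)
  tally$n_subjects[hit]
}

#' Two-tailed paired Student's t-test
#'
#' Computed on the paired differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample standard deviation
#' (n - 1 denominator) and a two-tailed p-value from the t distribution
#' with n - 1 degrees of freedom.  All-zero (or constant) differences are
#' degenerate: the test is flagged and `p = 1` is reported.
#'
#' @param x,y equal-length paired samples, `n >= 2`.
#' @return list with `t`, `p_two_tailed`, `n`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("paired_t_test: need equal-length samples with n >= 2",
         call. = FALSE)
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (s < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    if (all(d == 0))
      return(list(t = 0, p_two_tailed = 1, n = n, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p_two_tailed = NA_real_, n = n,
                degenerate = TRUE))
  }
  tstat <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  list(t = tstat, p_two_tailed = p, n = n, degenerate = FALSE)
}
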