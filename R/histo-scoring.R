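# Semiquantitative histology score panels, gradability assessment, and the
# B cell-rich/poor classification algorithm with its CD138 plasma-cell
# fallback to a deeper cutting level.

#' Construct a semiquantitative score panel
#'
#' One panel records the observer scores for a single sample at a single
#' cutting level: CD20, CD3, CD68 lining/sublining and CD138 on a 0–4
#' scale, the Krenn synovitis score on 0–9, and the tissue-quality flags
#' used for gradability (a clear synovial lining of CD68+ cells, a
#' recognizable sublining, artifactual changes).
#'
#' @param sample_id Sample identifier.
#' @param level Cutting level, 1 (initial) or 2 (deeper).
#' @param cd20 Integer 0–4.
#' @param cd3,cd68_lining,cd68_sublining,cd138 Integer 0–4 or `NA`.
#' @param krenn Integer 0–9 or `NA`.
#' @param has_lining,has_sublining,artifact Logical tissue-quality flags.
#' @return A one-row tibble of class `score_panel`.
#' @export
score_panel <- function(sample_id, level = 1L, cd20,
                        cd3 = NA_integer_, cd68_lining = NA_integer_,
                        cd68_sublining = NA_integer_, cd138 = NA_integer_,
                        krenn = NA_integer_,
                        has_lining = TRUE, has_sublining = TRUE,
                        artifact = FALSE) {
  check_score <- function(x, lo, hi, nm) {
    if (!is.na(x) && (!is_whole(x) || x < lo || x > hi)) {
      stop(nm, " must be an integer in ", lo, "..", hi, " or NA")
    }
    as.integer(x)
  }
  if (!level %in% c(1L, 2L)) stop("level must be 1 or 2")
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    level = as.integer(level),
    cd20 = check_score(cd20, 0, 4, "cd20"),
    cd3 = check_score(cd3, 0, 4, "cd3"),
    cd68_lining = check_score(cd68_lining, 0, 4, "cd68_lining"),
    cd68_sublining = check_score(cd68_sublining, 0, 4, "cd68_sublining"),
    cd138 = check_score(cd138, 0, 4, "cd138"),
    krenn = check_score(krenn, 0, 9, "krenn"),
    has_lining = isTRUE(has_lining),
    has_sublining = isTRUE(has_sublining),
    artifact = isTRUE(artifact)
  )
  if (is.na(out$cd20)) stop("cd20 score is required")
  class(out) <- c("score_panel", class(out))
  out
}

#' Assess whether a sample is gradable
#'
#' A sample is gradable when it shows either a clear synovial lining (CD68+
#' cells in a linear arrangement) or a recognizable sublining
#' (characteristic vessels and stroma), and carries no artifactual changes.
#'
#' @param panel A [score_panel()] (or any one-row data frame with
#'   `has_lining`, `has_sublining`, `artifact`).
#' @return `"graded"` or `"ungraded"`.
#' @export
assess_gradability <- function(panel) {
  stopifnot(all(c("has_lining", "has_sublining", "artifact") %in% names(panel)))
  ok <- (panel$has_lining | panel$has_sublining) & !panel$artifact
  ifelse(ok, "graded", "ungraded")
}

#' Classify a sample as B cell rich or poor
#'
#' Decision table on the initial cutting level: CD20 score >= 2 classifies
#' the sample as B cell rich; CD20 <= 1 with CD138 < 2 as B cell poor;
#' CD20 <= 1 with CD138 >= 2 (plasma-cell-rich but B cell-poor at level 1)
#' defers to the CD20 score of an additional stain at a deeper cutting
#' level. A missing CD138 score is treated as CD138 < 2 (no fallback).
#' Ungradable samples are returned as `"ungraded"`.
#'
#' @param level1 The level-1 [score_panel()].
#' @param level2 The deeper-cut panel, required only when the CD138
#'   fallback fires.
#' @param cd20_rich_min,cd138_fallback_min Classification cutoffs (defaults
#'   2 and 2).
#' @return A list of class `b_cell_status` with `status` (`"ungraded"`,
#'   `"poor"`, `"rich"`) and `basis` (which rule fired: `"gradability"`,
#'   `"level1_cd20"`, or `"cd138_fallback_level2_cd20"`).
#' @export
classify_b_cell_status <- function(level1, level2 = NULL,
                                   cd20_rich_min = 2L,
                                   cd138_fallback_min = 2L) {
  if (assess_gradability(level1) == "ungraded") {
    return(structure(list(status = "ungraded", basis = "gradability"),
                     class = "b_cell_status"))
  }
  cd138 <- level1$cd138
  if (level1$cd20 >= cd20_rich_min) {
    st <- list(status = "rich", basis = "level1_cd20")
  } else if (is.na(cd138) || cd138 < cd138_fallback_min) {
    st <- list(status = "poor", basis = "level1_cd20")
  } else {
    if (is.null(level2)) {
      stop("deeper-level CD20 required: CD138 >= ", cd138_fallback_min,
           " with CD20 <= ", cd20_rich_min - 1L, " at level 1")
    }
    st <- list(
      status = if (level2$cd20 >= cd20_rich_min) "rich" else "poor",
      basis = "cd138_fallback_level2_cd20"
    )
  }
  structure(st, class = "b_cell_status")
}

#' Dichotomize a marker score at a cutoff
#'
#' Mirrors the reporting convention "semiquantitative score >= 2" used for
#' CD3, CD68 lining/sublining, and CD138.
#'
#' @param panel A [score_panel()].
#' @param marker Column name of the marker score.
#' @param cutoff Score cutoff (default 2).
#' @return `"high"` if score >= cutoff, else `"low"`.
#' @export
dichotomize_panel <- function(panel, marker, cutoff = 2L) {
  if (!marker %in% names(panel)) stop("marker '", marker, "' not present in panel")
  v <- panel[[marker]]
  if (any(is.na(v))) stop("marker '", marker, "' is absent (NA) in panel")
  ifelse(v >= cutoff, "high", "low")
}

#' Sample disposition of a cohort of score panels
#'
#' Tallies gradable and ungradable samples and, among gradable ones, the
#' B cell-rich/poor split. Percentages follow the reporting conventions:
#' `gradable_rate = 100 * n_graded / n_total` and
#' `prevalence_rich = 100 * n_rich / n_graded`.
#'
#' @param panels A data frame of level-1 panels, one row per sample
#'   (columns as in [score_panel()]); an optional `level2` list-column or a
#'   separate `level2_panels` data frame (matched by `sample_id`) supplies
#'   deeper-cut panels for CD138-fallback samples.
#' @param level2_panels Optional data frame of level-2 panels.
#' @return A one-row tibble: `n_total`, `n_graded`, `n_ungraded`, `n_rich`,
#'   `n_poor`, `prevalence_rich`, `gradable_rate` (percent;
#'   `prevalence_rich` is `NA` with a warning when no sample is gradable).
#' @export
cohort_disposition <- function(panels, level2_panels = NULL) {
  stopifnot(is.data.frame(panels), nrow(panels) >= 1)
  if (anyDuplicated(panels$sample_id)) {
    stop("panels must contain one level-1 row per sample")
  }
  statuses <- vapply(seq_len(nrow(panels)), function(i) {
    l1 <- panels[i, ]
    l2 <- NULL
    if (!is.null(level2_panels)) {
      j <- which(level2_panels$sample_id == l1$sample_id)
      if (length(j) == 1L) l2 <- level2_panels[j, ]
    }
    classify_b_cell_status(l1, l2)$status
  }, character(1))
  n_total <- nrow(panels)
  n_graded <- sum(statuses != "ungraded")
  n_rich <- sum(statuses == "rich")
  prev <- if (n_graded == 0L) {
    warning("no gradable samples: prevalence undefined")
    NA_real_
  } else {
    100 * n_rich / n_graded
  }
  tibble::tibble(
    n_total = n_total,
    n_graded = n_graded,
    n_ungraded = n_total - n_graded,
    n_rich = n_rich,
    n_poor = n_graded - n_rich,
    prevalence_rich = prev,
    gradable_rate = 100 * n_graded / n_total
  )
}
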