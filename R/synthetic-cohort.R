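# Synthetic clinical cohorts stratified by B cell status, emulating the
# published group summaries for untreated early RA and TNFi-inadequate-
# responder established RA.

#' Published stratum parameters for the clinical comparison
#'
#' Returns the per-variable distribution parameters (mean, SD for
#' continuous; proportion for binary) of the B cell-poor and B cell-rich
#' strata, as printed for the two cohorts. These serve as generator inputs
#' for [generate_cohort()].
#'
#' @param cohort `"early"` (untreated early RA) or `"tnfi"` (established
#'   RA, TNFi inadequate responders).
#' @return A named list; each element has `type` ("continuous"/"binary")
#'   and `poor`/`rich` parameters (`c(mean, sd)` or a proportion).
#' @export
table_effects <- function(cohort = c("early", "tnfi")) {
  cohort <- match.arg(cohort)
  cont <- function(pm, ps, rm, rs) {
    list(type = "continuous", poor = c(mean = pm, sd = ps), rich = c(mean = rm, sd = rs))
  }
  bin <- function(pp, rp) list(type = "binary", poor = pp, rich = rp)
  if (cohort == "early") {
    list(
      das28 = cont(5.6, 1.38, 6.1, 1.2),
      tender_joint_count = cont(11.3, 7.3, 13, 7.7),
      swollen_joint_count = cont(7.1, 5.4, 8.8, 5.7),
      global_health_vas = cont(60.6, 28.6, 64.8, 25.2),
      esr = cont(34.6, 28.9, 49.5, 28.9),
      crp = cont(17.5, 32.7, 21.5, 24.2),
      krenn_score = cont(3, 1, 6, 1),
      acpa_pos = bin(0.598, 0.784),
      rf_pos = bin(0.62, 0.804)
    )
  } else {
    list(
      das28 = cont(5.6, 1.3, 5.7, 1.2),
      tender_joint_count = cont(12.5, 7.9, 11.2, 7.8),
      swollen_joint_count = cont(6.5, 5.1, 7.4, 5.1),
      global_health_vas = cont(65.2, 23.2, 66.8, 27.3),
      esr = cont(31.7, 24.4, 38.3, 27.2),
      crp = cont(19.9, 35.9, 26.4, 26.8),
      krenn_score = cont(2, 2, 6, 2),
      acpa_pos = bin(0.731, 0.764),
      rf_pos = bin(0.70, 0.722)
    )
  }
}

#' Specification for a synthetic clinical cohort
#'
#' @param n_patients Number of biopsied patients.
#' @param prevalence_rich Probability that a gradable patient is B cell
#'   rich, in \[0, 1\].
#' @param effects Per-variable stratum parameters, as from
#'   [table_effects()].
#' @param gradable_rate Probability that a biopsy yields gradable synovial
#'   tissue, in \[0, 1\].
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        prevalence_rich,
                        effects = table_effects("early"),
                        gradable_rate = 1,
                        seed = 1L) {
  stopifnot(
    is_whole(n_patients), n_patients >= 1,
    prevalence_rich >= 0, prevalence_rich <= 1,
    gradable_rate >= 0, gradable_rate <= 1,
    is.list(effects)
  )
  for (nm in names(effects)) {
    e <- effects[[nm]]
    if (!e$type %in% c("continuous", "binary")) {
      stop("effect '", nm, "' has unknown type ", e$type)
    }
    if (e$type == "binary" &&
        (any(unlist(e[c("poor", "rich")]) < 0) ||
         any(unlist(e[c("poor", "rich")]) > 1))) {
      stop("binary effect '", nm, "' has a proportion outside [0, 1]")
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      prevalence_rich = prevalence_rich,
      effects = effects,
      gradable_rate = gradable_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic clinical cohort
#'
#' Gradability is Bernoulli(`gradable_rate`); among gradable patients, B
#' cell status is Bernoulli(`prevalence_rich`). Continuous variables are
#' Gaussian with the stratum mean/SD, binary variables Bernoulli with the
#' stratum proportion; variables are generated independently (the published
#' summaries are marginal). Ungraded patients carry missing clinical strata
#' status but still receive variables drawn from the poor stratum so the
#' table is complete.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble (class `cohort_table`) with `patient_id`, `gradable`,
#'   `b_cell_status` (`"rich"`, `"poor"`, or `"ungraded"`), and one column
#'   per effect variable.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  withr::with_seed(spec$seed, {
    gradable <- stats::runif(n) < spec$gradable_rate
    rich <- gradable & (stats::runif(n) < spec$prevalence_rich)
    status <- ifelse(!gradable, "ungraded", ifelse(rich, "rich", "poor"))
    out <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      gradable = gradable,
      b_cell_status = status
    )
    for (nm in names(spec$effects)) {
      e <- spec$effects[[nm]]
      if (e$type == "continuous") {
        v <- ifelse(
          rich,
          stats::rnorm(n, e$rich[["mean"]], e$rich[["sd"]]),
          stats::rnorm(n, e$poor[["mean"]], e$poor[["sd"]])
        )
      } else {
        v <- ifelse(
          rich,
          stats::runif(n) < e$rich,
          stats::runif(n) < e$poor
        )
      }
      out[[nm]] <- v
    }
  })
  class(out) <- c("cohort_table", class(out))
  attr(out, "spec") <- spec
  out
}
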