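# Mixed-model selection and effect reporting on the subject-level results
# table, plus end-to-end parameter-recovery experiments.
#
# Model fitting is delegated to lm / lmerTest::lmer (ML throughout, since
# information criteria are compared across different fixed structures); this
# stage orchestrates the selection protocol rather than defining an
# estimator.

.fixed_formula <- function(outcome, structure) {
  rhs <- switch(structure,
    "age*group*paretic" = "age_years * group * paretic",
    "age*group" = "age_years * group",
    "age+group" = "age_years + group",
    "age" = "age_years",
    stop("unknown fixed structure: ", structure))
  stats::as.formula(paste(outcome, "~", rhs))
}

.fit_candidate <- function(formula, data, random_subject) {
  if (random_subject) {
    f <- stats::update(formula, . ~ . + (1 | subject))
    fit <- suppressMessages(lmerTest::lmer(f, data = data, REML = FALSE))
    if (lme4::isSingular(fit, tol = 1e-5))
      attr(fit, "singular") <- TRUE
    fit
  } else {
    stats::lm(formula, data = data)
  }
}

.term_table <- function(fit, alpha = 0.05) {
  co <- stats::coef(summary(fit))
  is_mixed <- inherits(fit, "merMod")
  out <- data.frame(
    term = rownames(co),
    estimate = co[, "Estimate"],
    t = co[, "t value"],
    df = if (is_mixed) co[, "df"] else rep(stats::df.residual(fit), nrow(co)),
    p = if (is_mixed) co[, "Pr(>|t|)"] else co[, "Pr(>|t|)"],
    row.names = NULL)
  out$sign <- ifelse(out$estimate > 0, "+", "-")
  out$significant <- out$p < alpha
  out
}

#' Select a mixed model for an outcome by the AIC/BIC protocol
#'
#' Two-step selection on a subject-level results table with age treated as a
#' continuous covariate. Step 1: the "beyond optimal" fixed structure (all
#' available interactions of age, group and paretic hand) is fitted with and
#' without a subject random intercept; the lower-AIC option decides the
#' random structure. Step 2: among the nested fixed structures
#' `age x group x paretic`, `age x group`, `age + group`, `age`, the
#' lowest-BIC fit is selected. All fits use maximum likelihood. Structures
#' involving a factor with fewer than two observed levels (e.g. `paretic` in
#' a single-hand cohort) are dropped from the candidate set and reported as
#' skipped; failed or singular fits are recorded, never silently dropped.
#'
#' @param table Data frame with columns `subject`, `age_years`, `group`,
#'   optionally `paretic`, and the outcome — typically from
#'   [summarize_subjects()].
#' @param outcome Outcome column name (default `"delta_v"`).
#' @param alpha Significance level for the effects table.
#' @param structures Optional character vector restricting the candidate
#'   fixed structures (default: all applicable). A single candidate is
#'   returned as selected without comparison.
#' @return An object of class `synergy_selection` with the AIC/BIC tables,
#'   the selected fit and its term-level effects.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_spec(n_per_group = 5, trials_per_subject = 4,
#'                                    seed = 2))
#' res <- summarize_subjects(analyze_trials(coh$trials))
#' select_synergy_model(res)
#' }
#' @export
select_synergy_model <- function(table, outcome = "delta_v", alpha = 0.05,
                                 structures = NULL) {
  stopifnot(is.data.frame(table))
  if (!outcome %in% names(table))
    stop("outcome column '", outcome, "' not found in the table")
  need <- c("subject", "age_years", "group")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  data <- table[stats::complete.cases(table[c(need, outcome)]), ]
  data$group <- stats::relevel(factor(data$group),
                               ref = if ("control" %in% data$group) "control"
                                     else levels(factor(data$group))[1])
  if (nlevels(data$group) < 2L)
    stop("need at least 2 groups with >= 2 subjects each")
  if (min(table(unique(data[c("subject", "group")])$group)) < 2L)
    stop("need at least 2 subjects per group")
  has_paretic <- "paretic" %in% names(data) &&
    length(unique(data$paretic)) >= 2L
  all_structures <- c(if (has_paretic) "age*group*paretic",
                      "age*group", "age+group", "age")
  skipped <- if (has_paretic) character(0) else "age*group*paretic"
  if (is.null(structures)) structures <- all_structures
  else if (!all(structures %in% all_structures))
    stop("unknown or inapplicable structure(s): ",
         paste(setdiff(structures, all_structures), collapse = ", "))

  # step 1: random structure by AIC on the beyond-optimal fixed structure
  f_beyond <- .fixed_formula(outcome, structures[1])
  notes <- character(0)
  fit_fix <- stats::lm(f_beyond, data = data)
  fit_mix <- tryCatch(.fit_candidate(f_beyond, data, TRUE),
                      error = function(e) e)
  if (inherits(fit_mix, "error")) {
    notes <- c(notes, paste("random-intercept fit failed:",
                            conditionMessage(fit_mix)))
    aic <- c(fixed_only = stats::AIC(fit_fix), random_subject = NA_real_)
    random_subject <- FALSE
  } else {
    if (isTRUE(attr(fit_mix, "singular")))
      notes <- c(notes, "random-intercept fit is singular")
    aic <- c(fixed_only = stats::AIC(fit_fix),
             random_subject = stats::AIC(fit_mix))
    random_subject <- aic["random_subject"] < aic["fixed_only"]
  }

  # step 2: fixed structure by BIC
  fits <- list()
  bic <- stats::setNames(rep(NA_real_, length(structures)), structures)
  for (s in structures) {
    f <- .fixed_formula(outcome, s)
    fit <- tryCatch(.fit_candidate(f, data, random_subject),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      notes <- c(notes, paste("fit failed for", s, ":", conditionMessage(fit)))
    } else {
      fits[[s]] <- fit
      bic[s] <- stats::BIC(fit)
    }
  }
  if (!length(fits)) stop("all candidate fits failed; cannot select a model")
  selected <- names(which.min(bic))
  structure(list(outcome = outcome, aic_by_random = aic,
                 random_subject = unname(random_subject),
                 bic_by_fixed = bic, selected = selected,
                 fit = fits[[selected]],
                 terms = .term_table(fits[[selected]], alpha),
                 alpha = alpha, skipped = skipped, notes = notes,
                 n = nrow(data)),
            class = "synergy_selection")
}

#' @export
print.synergy_selection <- function(x, ...) {
  cat("Model selection for outcome '", x$outcome, "' (n = ", x$n, ")\n",
      sep = "")
  cat("  step 1 (AIC): fixed-only ", sprintf("%.1f", x$aic_by_random[1]),
      " vs + (1|subject) ", sprintf("%.1f", x$aic_by_random[2]),
      " -> random subject intercept ",
      if (x$random_subject) "kept" else "dropped", "\n", sep = "")
  cat("  step 2 (BIC):\n")
  for (s in names(x$bic_by_fixed))
    cat(sprintf("    %-20s %s\n", s,
                ifelse(is.na(x$bic_by_fixed[s]), "failed",
                       sprintf("%.1f%s", x$bic_by_fixed[s],
                               if (s == x$selected) "  <- selected" else ""))))
  if (length(x$skipped))
    cat("  skipped (factor constant):", paste(x$skipped, collapse = ", "), "\n")
  for (msg in x$notes) cat("  note:", msg, "\n")
  sig <- x$terms[x$terms$significant & x$terms$term != "(Intercept)", ]
  if (nrow(sig)) {
    cat("  significant effects (alpha = ", x$alpha, "):\n", sep = "")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s: %s  t(%.0f) = %.2f, p = %.3g\n", sig$term[i],
                  sig$sign[i], sig$df[i], sig$t[i], sig$p[i]))
  } else cat("  no significant effects at alpha =", x$alpha, "\n")
  invisible(x)
}

#' @export
coef.synergy_selection <- function(object, ...) {
  if (inherits(object$fit, "merMod")) lme4::fixef(object$fit)
  else stats::coef(object$fit)
}

#' @export
summary.synergy_selection <- function(object, ...) object$terms

#' Term-level effects of the selected model
#'
#' One row per fixed-effect term with its estimate, sign, t statistic,
#' degrees of freedom (Satterthwaite for mixed fits), p value and a
#' significance flag — the sign-plus-significance reporting convention.
#'
#' @param selection A `synergy_selection` from [select_synergy_model()].
#' @param alpha Significance level.
#' @return Data frame of terms.
#' @export
effects_table <- function(selection, alpha = selection$alpha) {
  stopifnot(inherits(selection, "synergy_selection"))
  .term_table(selection$fit, alpha)
}

.group_slopes <- function(table, outcome = "delta_v") {
  # per-group OLS slope of the subject-mean outcome on age
  subj <- stats::aggregate(table[c(outcome, "age_years")],
                           table[c("subject", "group")], mean)
  out <- vapply(split(subj, subj$group), function(d)
    stats::coef(stats::lm(d[[outcome]] ~ d$age_years))[2], numeric(1))
  stats::setNames(out, sub("\\..*$", "", names(out)))
}

#' End-to-end parameter-recovery experiment
#'
#' For each replicate: simulate a cohort from `spec` (with a
#' replicate-specific seed), run the full analysis pipeline
#' ([analyze_trials()] then [summarize_subjects()]), regress the recovered
#' subject-mean synergy index on age within each group, and run
#' [select_synergy_model()]. Summarizes bias of the recovered age slopes
#' against the generating slopes and tallies the selection outcomes.
#'
#' @param spec A [cohort_spec()].
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param filter Passed to [ucm()] via [analyze_trials()].
#' @param select Run the model-selection stage per replicate? (Slightly
#'   slower; needed for selection/interaction summaries.)
#' @return An object of class `ucm_recovery`: `slopes` (one row per
#'   replicate x group: true and recovered slope), `summary` (per group:
#'   truth, mean recovered, bias, sd), and when `select = TRUE` a
#'   `selection` table (per replicate: random term kept, structure selected,
#'   and each non-reference group's age-interaction estimate/p from the
#'   selected model, `NA` when the selected structure has no interaction).
#' @export
recovery_experiment <- function(spec, n_replicates, seed = 1L,
                                filter = TRUE, select = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), n_replicates >= 1)
  slopes <- list(); selrows <- list()
  inter_groups <- setdiff(spec$groups, "control")
  for (r in seq_len(n_replicates)) {
    rspec <- spec
    rspec$seed <- as.integer(seed + r - 1L)
    coh <- simulate_cohort(rspec)
    res <- analyze_trials(coh$trials, filter = filter)
    subj <- summarize_subjects(res)
    rec <- .group_slopes(subj)
    true <- .group_slopes(stats::setNames(
      coh$subjects[c("subject", "group", "age_years", "dv_star")],
      c("subject", "group", "age_years", "delta_v")))
    slopes[[r]] <- data.frame(replicate = r, group = names(rec),
                              true_slope = unname(true[names(rec)]),
                              recovered_slope = unname(rec),
                              row.names = NULL)
    if (select) {
      sel <- select_synergy_model(subj)
      row <- data.frame(replicate = r, random_subject = sel$random_subject,
                        selected = sel$selected)
      for (g in inter_groups) {
        tm <- sel$terms[sel$terms$term == paste0("age_years:group", g), ]
        row[[paste0(g, "_age_est")]] <- if (nrow(tm)) tm$estimate else NA_real_
        row[[paste0(g, "_age_p")]] <- if (nrow(tm)) tm$p else NA_real_
      }
      selrows[[r]] <- row
    }
  }
  slopes <- do.call(rbind, slopes)
  smry <- do.call(rbind, lapply(split(slopes, slopes$group), function(d)
    data.frame(group = d$group[1], true_slope = mean(d$true_slope),
               mean_recovered = mean(d$recovered_slope),
               bias = mean(d$recovered_slope - d$true_slope),
               sd_recovered = stats::sd(d$recovered_slope),
               row.names = NULL)))
  # score truth against the generating parameters, not the realized draw
  smry$generating_slope <- spec$dv_age_slope[smry$group]
  structure(list(slopes = slopes, summary = smry,
                 selection = if (select) do.call(rbind, selrows),
                 spec = spec, n_replicates = n_replicates, seed = seed),
            class = "ucm_recovery")
}

#' @export
print.ucm_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicate(s)\n", x$n_replicates))
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$selection)) {
    cat("selected structures:\n")
    print(table(x$selection$selected))
    cat(sprintf("random subject intercept kept in %d/%d replicates\n",
                sum(x$selection$random_subject), x$n_replicates))
  }
  invisible(x)
}
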