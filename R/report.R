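#' Run the full validation pipeline
#'
#' Executes the complete psychometric validation of a polytomous scale in
#' the canonical order: (1) response summary and partial credit model fit
#' with infit/outfit statistics and Thurstonian thresholds; (2) model
#' assumption checks — unidimensionality (alpha, H, polychoric PCA with
#' parallel analysis), monotonicity over rest-score groups, and
#' measurement invariance (DIF) across binary groupings; (3) item category
#' severity; (4) external construct validity against continuous
#' validators. Stages whose inputs are unavailable (no covariates, no
#' validators) are skipped with a recorded reason. A stage that errors
#' leaves a failure record in its slot and the remaining stages still run.
#'
#' @param responses a coded `response_matrix`, or a path to a response CSV
#'   (read with `scale` and coded).
#' @param covariates optional data frame (or CSV path) with binary
#'   grouping columns and continuous validator columns.
#' @param scale a [scale_definition()], default [fast_scale()].
#' @param groupings,validators column names used by the DIF and external
#'   validity stages (defaults: auto-detected binary columns; the
#'   intersection of `wealth`/`wdds`/`bmi`).
#' @param minsize_divisors monotonicity sweep divisors, default
#'   `c(10, 50, 500)`.
#' @param n_reps parallel-analysis replicates.
#' @param seed integer seed controlling every stochastic step.
#' @param alpha significance level used throughout.
#' @param rule unidimensionality verdict rule, see
#'   [unidimensionality_verdict()].
#' @param fit_args list of extra arguments to [fit_pcm()].
#' @return An object of class `validation_report` with slots `summary`,
#'   `pcm`, `fit_statistics`, `thresholds`, `dimensionality`,
#'   `monotonicity`, `dif`, `external`, `verdicts`, `settings`.
#' @export
run_full_validation <- function(responses, covariates = NULL,
                                scale = fast_scale(),
                                groupings = NULL, validators = NULL,
                                minsize_divisors = c(10, 50, 500),
                                n_reps = 20L, seed = 1L, alpha = 0.05,
                                rule = "all", fit_args = list()) {
  if (is.character(responses))
    responses <- apply_coding(read_responses(responses, scale), scale)
  if (is.character(covariates)) covariates <- read_covariates(covariates)
  if (!isTRUE(attr(responses, "coded")))
    responses <- apply_coding(responses, scale)

  stage <- function(expr) {
    tryCatch(list(ok = TRUE, value = expr),
             error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  }
  skipped <- function(reason) list(ok = NA, reason = reason)

  summary_st <- stage(summarize_responses(responses))
  pcm_st <- stage(do.call(fit_pcm, c(list(responses), fit_args)))
  fit_ok <- pcm_st$ok
  fitstats_st <- if (fit_ok) stage(item_fit_statistics(pcm_st$value, responses))
                 else skipped("PCM fit unavailable")
  thr_st <- if (fit_ok) stage(thurstonian_thresholds(pcm_st$value))
            else skipped("PCM fit unavailable")
  scores_st <- if (fit_ok) stage(person_scores(pcm_st$value, responses))
               else skipped("PCM fit unavailable")
  dim_st <- stage(assess_dimensionality(responses, n_reps = n_reps,
                                        seed = seed, rule = rule))
  mono_st <- stage(monotonicity_sweep(responses,
                                      divisors = minsize_divisors,
                                      alpha = alpha))

  has_cov <- !is.null(covariates) && ncol(covariates) > 1L
  grouping_cols <- if (has_cov) {
    if (!is.null(groupings)) groupings
    else {
      cand <- setdiff(names(covariates), "respondent")
      cand[vapply(covariates[cand], function(v)
        length(unique(stats::na.omit(v))) == 2L, logical(1))]
    }
  } else character()
  dif_st <- if (length(grouping_cols))
    stage(dif_analysis(responses, covariates, groupings = grouping_cols,
                       alpha = alpha))
  else skipped("no binary grouping covariates supplied")

  validator_cols <- if (has_cov) {
    if (!is.null(validators)) validators
    else intersect(c("wealth", "wdds", "bmi"), names(covariates))
  } else character()
  ext_st <- if (length(validator_cols))
    stage(external_validity(responses, covariates,
                            validators = validator_cols))
  else skipped("no continuous validator covariates supplied")

  verdicts <- list(
    fit_acceptable = if (fitstats_st$ok %in% TRUE)
      all(fitstats_st$value$categories$in_acceptable) else NA,
    unidimensional = if (dim_st$ok %in% TRUE)
      dim_st$value$unidimensional else NA,
    alpha_acceptable = if (dim_st$ok %in% TRUE)
      dim_st$value$alpha_acceptable else NA,
    h_acceptable = if (dim_st$ok %in% TRUE)
      dim_st$value$H_acceptable else NA,
    monotone = if (mono_st$ok %in% TRUE)
      sum(mono_st$value[[1L]]$summary$significant) == 0L else NA,
    dif_practical = if (dif_st$ok %in% TRUE)
      any(dif_st$value$verdict == "practical") else NA,
    dif_statistical = if (dif_st$ok %in% TRUE)
      any(dif_st$value$verdict != "none") else NA,
    external_negative_trends = if (ext_st$ok %in% TRUE)
      all(vapply(ext_st$value, function(v)
        v$trend$direction == "negative" && v$trend$p_value < alpha,
        logical(1))) else NA)

  failed <- c(summary = summary_st$ok, pcm = pcm_st$ok,
              dimensionality = dim_st$ok, monotonicity = mono_st$ok,
              dif = dif_st$ok, external = ext_st$ok) %in% FALSE

  structure(list(summary = summary_st, pcm = pcm_st,
                 fit_statistics = fitstats_st, thresholds = thr_st,
                 person_scores = scores_st,
                 dimensionality = dim_st, monotonicity = mono_st,
                 dif = dif_st, external = ext_st, verdicts = verdicts,
                 any_failed = any(failed),
                 settings = list(minsize_divisors = minsize_divisors,
                                 n_reps = n_reps, seed = seed,
                                 alpha = alpha, rule = rule)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("== Scale validation report ==\n")
  if (x$summary$ok %in% TRUE) {
    s <- x$summary$value
    cat(sprintf("Respondents: %d (floor share %.1f%%)\n", s$n,
                100 * s$floor_proportion))
  }
  if (x$pcm$ok %in% TRUE) print(x$pcm$value)
  v <- x$verdicts
  cat("Verdicts:\n")
  for (nm in names(v))
    cat(sprintf("  %-26s %s\n", nm, format(v[[nm]])))
  invisible(x)
}

# Convert a report into plain lists for JSON serialization.
report_to_list <- function(report) {
  num <- function(x) if (is.numeric(x)) round(x, 10) else x
  out <- list(
    settings = report$settings,
    verdicts = report$verdicts,
    summary = if (report$summary$ok %in% TRUE) {
      s <- report$summary$value
      list(n = s$n, floor_proportion = num(s$floor_proportion),
           n_excluded = s$n_excluded,
           marginals = as.data.frame(as.table(s$marginals)))
    } else report$summary,
    pcm = if (report$pcm$ok %in% TRUE) {
      f <- report$pcm$value
      list(delta = f$delta, sigma = num(f$sigma), loglik = num(f$loglik),
           n_iter = f$n_iter, converged = f$converged, n_used = f$n_used)
    } else report$pcm,
    thresholds = if (report$thresholds$ok %in% TRUE)
      report$thresholds$value else report$thresholds,
    fit_statistics = if (report$fit_statistics$ok %in% TRUE)
      report$fit_statistics$value[c("items", "categories")]
      else report$fit_statistics,
    dimensionality = if (report$dimensionality$ok %in% TRUE) {
      d <- report$dimensionality$value
      list(alpha = num(d$alpha), H = num(d$H),
           observed_eigenvalues = num(d$observed_eigenvalues),
           variance_share = num(d$variance_share),
           parallel_mean = num(d$parallel$mean),
           parallel_min = num(d$parallel$min),
           parallel_max = num(d$parallel$max),
           criterion_a = d$criterion_a, criterion_b = d$criterion_b,
           criterion_c = d$criterion_c,
           unidimensional = d$unidimensional, rule = d$rule)
    } else report$dimensionality,
    monotonicity = if (report$monotonicity$ok %in% TRUE)
      lapply(report$monotonicity$value, function(m) m$summary)
      else report$monotonicity,
    dif = if (report$dif$ok %in% TRUE)
      as.data.frame(report$dif$value) else report$dif,
    external = if (report$external$ok %in% TRUE)
      lapply(report$external$value, function(v)
        list(z = num(v$trend$z), p_value = num(v$trend$p_value),
             direction = v$trend$direction, bins = v$bins))
      else report$external)
  out
}

#' Write a validation report to disk
#'
#' Writes `report.json` (machine-readable, deterministic for a fixed seed
#' and input), `report.txt` (the printed report) and CSV tables
#' (marginals, fit statistics, eigenvalues, monotonicity, DIF, trends)
#' into `dir`.
#'
#' @param report a [run_full_validation()] result.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_validation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_list(report), jp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  paths <- c(paths, jp)
  tp <- file.path(dir, "report.txt")
  writeLines(utils::capture.output(print(report)), tp)
  paths <- c(paths, tp)
  wcsv <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (report$summary$ok %in% TRUE)
    wcsv(as.data.frame(as.table(report$summary$value$marginals)),
         "marginals.csv")
  if (report$fit_statistics$ok %in% TRUE)
    wcsv(report$fit_statistics$value$categories, "fit_statistics.csv")
  if (report$dimensionality$ok %in% TRUE) {
    d <- report$dimensionality$value
    wcsv(data.frame(component = seq_along(d$observed_eigenvalues),
                    observed = d$observed_eigenvalues,
                    simulated_mean = d$parallel$mean,
                    simulated_min = d$parallel$min,
                    simulated_max = d$parallel$max), "eigenvalues.csv")
  }
  if (report$monotonicity$ok %in% TRUE)
    wcsv(do.call(rbind, lapply(names(report$monotonicity$value), function(nm)
      cbind(level = nm, report$monotonicity$value[[nm]]$summary))),
      "monotonicity.csv")
  if (report$dif$ok %in% TRUE)
    wcsv(as.data.frame(report$dif$value), "dif.csv")
  if (report$external$ok %in% TRUE)
    wcsv(do.call(rbind, lapply(report$external$value, function(v)
      data.frame(validator = v$validator, z = v$trend$z,
                 p_value = v$trend$p_value, direction = v$trend$direction))),
      "trends.csv")
  invisible(paths)
}
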