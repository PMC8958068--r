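#' Plan for one preprocessing effect
#'
#' The four perturbation analyses:
#' * **A** — raters: the 10 interpolators at fixed bin width; one analysis
#'   per voxel size.
#' * **B** — raters: the bin widths at fixed interpolator; one analysis per
#'   voxel size.
#' * **C** — raters: the voxel sizes at fixed interpolator; one analysis per
#'   bin width.
#' * **D** — raters: the voxel sizes at fixed bin width; one analysis per
#'   interpolator.
#'
#' @param effect one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param voxel_sizes,interps,bin_widths the grid actually extracted.
#' @param fixed_interp,fixed_bin the fixed items.
#' @return An object of class `effect_plan`.
#' @export
effect_plan <- function(effect, voxel_sizes = c(1, 1.3, 1.6, 1.9, 2.2, 2.5),
                        interps = interpolators(), bin_widths = 3:8,
                        fixed_interp = "BS", fixed_bin = 5) {
  effect <- match.arg(effect, c("A", "B", "C", "D"))
  p <- switch(effect,
    A = list(rater_var = "interpolator", raters = interps,
             cond_var = "voxel_size", conditions = voxel_sizes,
             fixed = list(bin_width = fixed_bin)),
    B = list(rater_var = "bin_width", raters = bin_widths,
             cond_var = "voxel_size", conditions = voxel_sizes,
             fixed = list(interpolator = fixed_interp)),
    C = list(rater_var = "voxel_size", raters = voxel_sizes,
             cond_var = "bin_width", conditions = bin_widths,
             fixed = list(interpolator = fixed_interp)),
    D = list(rater_var = "voxel_size", raters = voxel_sizes,
             cond_var = "interpolator", conditions = interps,
             fixed = list(bin_width = fixed_bin)))
  p$effect <- effect
  structure(p, class = "effect_plan")
}

# slice of the feature table this plan consumes, checked for completeness
effect_slice <- function(plan, features) {
  sl <- features
  for (nm in names(plan$fixed))
    sl <- sl[sl[[nm]] == plan$fixed[[nm]], , drop = FALSE]
  sl <- sl[sl[[plan$rater_var]] %in% plan$raters &
           sl[[plan$cond_var]] %in% plan$conditions, , drop = FALSE]
  subjects <- unique(sl$subject)
  need <- expand.grid(subject = subjects, rater = plan$raters,
                      condition = plan$conditions)
  have <- unique(sl[, c("subject", plan$rater_var, plan$cond_var)])
  if (nrow(have) < nrow(need)) {
    key <- function(df, a, b, c) paste(df[[a]], df[[b]], df[[c]], sep = "|")
    missing <- setdiff(key(need, "subject", "rater", "condition"),
                       key(have, "subject", plan$rater_var, plan$cond_var))
    stop(sprintf("completeness error: missing (subject, %s, %s) cells: %s",
                 plan$rater_var, plan$cond_var,
                 paste(utils::head(missing, 5), collapse = "; ")),
         call. = FALSE)
  }
  sl
}

#' Run one effect analysis over an extracted feature table
#'
#' For every feature and condition, builds the subjects x raters matrix and
#' computes the absolute-agreement ICC; for every feature, subject and
#' condition, the CV across raters, pooled as median (IQR) over subjects and
#' conditions; for effects B and C additionally the repeated-measures
#' correlation of each feature against the varied numeric covariate (bin
#' width for B, voxel size for C), Bonferroni-adjusted within each condition.
#'
#' @param plan an [effect_plan()] (or effect letter).
#' @param features long table from [extract_grid()].
#' @param bonferroni_family family size for the rmcorr adjustment.
#' @return An object of class `effect_result` with elements `icc` (long data
#'   frame feature x condition), `icc_matrix` (features x conditions), `cv`
#'   (per feature, subject, condition), `cv_summary` (pooled median/IQR per
#'   feature), and `rmcorr` (B/C only).
#' @export
run_effect <- function(plan, features, bonferroni_family = 105) {
  if (is.character(plan)) plan <- effect_plan(plan)
  stopifnot(inherits(plan, "effect_plan"))
  sl <- effect_slice(plan, features)
  reg <- feature_registry()
  subjects <- sort(unique(sl$subject))

  icc_rows <- list()
  cv_rows <- list()
  for (fn in reg$name) {
    ff <- sl[sl$feature_name == fn, , drop = FALSE]
    for (cond in plan$conditions) {
      fc <- ff[ff[[plan$cond_var]] == cond, , drop = FALSE]
      M <- matrix(NA_real_, length(subjects), length(plan$raters),
                  dimnames = list(subjects, plan$raters))
      for (r in seq_along(plan$raters)) {
        fr <- fc[fc[[plan$rater_var]] == plan$raters[r], , drop = FALSE]
        M[match(fr$subject, subjects), r] <- fr$value
      }
      res <- icc_a1(M)
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        feature_name = fn, condition = as.character(cond), icc = res$icc,
        stratum = res$stratum, stringsAsFactors = FALSE)
      for (s in subjects) {
        v <- M[match(s, subjects), ]
        cv <- cv_percent(v)
        cv_rows[[length(cv_rows) + 1L]] <- data.frame(
          feature_name = fn, subject = s, condition = as.character(cond),
          cv_percent = as.numeric(cv),
          undefined = isTRUE(attr(cv, "undefined")), stringsAsFactors = FALSE)
      }
    }
  }
  icc <- do.call(rbind, icc_rows)
  cv <- do.call(rbind, cv_rows)

  icc_matrix <- matrix(icc$icc, nrow = nrow(reg), byrow = TRUE,
                       dimnames = list(reg$name, as.character(plan$conditions)))

  cv_ok <- cv[!cv$undefined, , drop = FALSE]
  cv_summary <- do.call(rbind, lapply(reg$name, function(fn) {
    v <- cv_ok$cv_percent[cv_ok$feature_name == fn]
    data.frame(feature_name = fn,
               median_cv = if (length(v)) median(v) else NA_real_,
               iqr_cv = if (length(v)) quantile(v, 0.75, names = FALSE) -
                          quantile(v, 0.25, names = FALSE) else NA_real_,
               n_pooled = length(v), stringsAsFactors = FALSE)
  }))

  rm_tab <- NULL
  if (plan$effect %in% c("B", "C")) {
    covar <- plan$rater_var # numeric covariate: bin width (B) or voxel size (C)
    rm_rows <- list()
    for (fn in reg$name) {
      ff <- sl[sl$feature_name == fn, , drop = FALSE]
      for (cond in plan$conditions) {
        fc <- ff[ff[[plan$cond_var]] == cond, , drop = FALSE]
        rr <- tryCatch(rmcorr(as.numeric(fc[[covar]]), fc$value, fc$subject),
                       error = function(e) NULL)
        rm_rows[[length(rm_rows) + 1L]] <- data.frame(
          feature_name = fn, condition = as.character(cond),
          r_rm = if (is.null(rr)) NA_real_ else rr$r_rm,
          df = if (is.null(rr)) NA_integer_ else rr$df,
          p_raw = if (is.null(rr)) NA_real_ else rr$p_raw,
          stringsAsFactors = FALSE)
      }
    }
    rm_tab <- do.call(rbind, rm_rows)
    adj <- bonferroni(rm_tab$p_raw, bonferroni_family)
    rm_tab$p_adj <- adj$p_adj
    rm_tab$significant <- adj$significant
  }

  structure(list(effect = plan$effect, plan = plan, icc = icc,
                 icc_matrix = icc_matrix, cv = cv, cv_summary = cv_summary,
                 rmcorr = rm_tab),
            class = "effect_result")
}

#' @export
print.effect_result <- function(x, ...) {
  cat(sprintf("<effect_result %s> raters: %s; conditions: %s (%d)\n",
              x$effect, x$plan$rater_var, x$plan$cond_var,
              length(x$plan$conditions)))
  cat(sprintf("  ICC heatmap %d x %d; pooled CV over %d feature rows\n",
              nrow(x$icc_matrix), ncol(x$icc_matrix), nrow(x$cv_summary)))
  invisible(x)
}

#' Format pooled CVs as "median (IQR)" strings
#'
#' One-decimal "median (interquartile range)" rendering of a pooled CV
#' summary.
#'
#' @param cv_summary the `cv_summary` element of an [run_effect()] result.
#' @return Data frame with `feature_name` and `cv_label`.
#' @export
format_median_iqr <- function(cv_summary) {
  data.frame(feature_name = cv_summary$feature_name,
             cv_label = sprintf("%.1f (%.1f)", cv_summary$median_cv,
                                cv_summary$iqr_cv),
             stringsAsFactors = FALSE)
}

#' Select features with high CV despite high ICC
#'
#' The box-plot selection rule: features whose pooled median CV is at least
#' `cv_min` percent AND whose ICC is at least `icc_min` in every condition.
#'
#' @param result an [run_effect()] result.
#' @param cv_min median CV threshold (percent).
#' @param icc_min per-condition ICC threshold.
#' @return Character vector of feature names (possibly empty).
#' @export
select_high_cv_high_icc <- function(result, cv_min = 15, icc_min = 0.75) {
  stopifnot(inherits(result, "effect_result"))
  icc_ok <- rownames(result$icc_matrix)[
    apply(result$icc_matrix >= icc_min, 1, all)]
  cv_ok <- result$cv_summary$feature_name[
    !is.na(result$cv_summary$median_cv) & result$cv_summary$median_cv >= cv_min]
  intersect(icc_ok, cv_ok)
}

#' Write an effect result to disk
#'
#' Emits deterministic CSV tables (ICC heatmap, pooled CV with formatted
#' median (IQR) labels, per-cell CVs, rmcorr when present) plus a JSON
#' summary with the provenance fields.
#'
#' @param result an [run_effect()] result.
#' @param out_dir output directory (created if missing).
#' @param seed seed recorded for provenance.
#' @return Invisibly, the paths written.
#' @export
write_effect_result <- function(result, out_dir, seed = NA) {
  stopifnot(inherits(result, "effect_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(out_dir, paste0("effect_", result$effect))
  paths <- character(0)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    df
  }
  w <- function(df, suffix) {
    p <- paste0(pre, "_", suffix, ".csv")
    write.csv(fmt(df), p, row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(paths, w(result$icc, "icc"))
  cvs <- merge(result$cv_summary, format_median_iqr(result$cv_summary),
               by = "feature_name", sort = FALSE)
  paths <- c(paths, w(cvs, "cv_summary"), w(result$cv, "cv"))
  if (!is.null(result$rmcorr)) paths <- c(paths, w(result$rmcorr, "rmcorr"))
  meta <- list(effect = result$effect, seed = seed,
               package_version = as.character(utils::packageVersion("radrobust")),
               selected_high_cv_high_icc = select_high_cv_high_icc(result))
  mp <- paste0(pre, "_summary.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}
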