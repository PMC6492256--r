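#' Full-language learning analysis (accuracy and complexity over rounds)
#'
#' Scores every production against the target language, aggregates stem and
#' suffix accuracy as a mean of by-participant means per round, and computes
#' the conditioning-complexity and suffix-entropy table per participant x
#' round x word class.
#'
#' @param records Production record table (or a CSV path).
#' @param spec Target [language_spec()].
#' @param out_dir Optional directory; if given, the result tables are written
#'   as CSV alongside a JSON run manifest.
#' @return List of class `summary_report` with elements `accuracy`,
#'   `complexity` and `n_records`.
#' @export
run_exp1 <- function(records, spec = build_exp1_target(), out_dir = NULL) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_productions(records, spec)
  }
  records <- validate_productions(records, spec)
  scored <- score_productions(records, spec)
  acc <- aggregate_accuracy(scored)
  cx <- complexity_table(records, spec)
  report <- structure(list(accuracy = acc, complexity = cx,
                           n_records = nrow(records)),
                      class = "summary_report")
  if (!is.null(out_dir)) {
    write_report_tables(report, out_dir, prefix = "exp1")
  }
  report
}

#' Mixed-input condition comparison at the final round
#'
#' Computes the complexity table for each condition's records and summarises
#' mean complexity (with t-based 95% confidence intervals over participants)
#' per condition and word class at the phase of interest. Estimates and
#' intervals are reported rather than significance tests.
#'
#' @param records Production record table with a `condition` column.
#' @param spec Target [language_spec()].
#' @param phase Phase to compare (default 8).
#' @param out_dir Optional output directory.
#' @return List of class `summary_report` with `complexity` (per participant)
#'   and `condition_summary`.
#' @export
run_exp2 <- function(records, spec = build_exp1_target(), phase = 8,
                     out_dir = NULL) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_productions(records, spec)
  }
  if (!"condition" %in% names(records)) stop("records need a `condition` column")
  records <- records[as.character(records$phase) == as.character(phase), ,
                     drop = FALSE]
  conds <- unique(records$condition)
  cx <- do.call(rbind, lapply(conds, function(cd) {
    t <- complexity_table(records[records$condition == cd, , drop = FALSE], spec)
    t$condition <- cd
    t
  }))
  groups <- unique(cx[c("condition", "word_class")])
  summ <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- cx[cx$condition == groups$condition[i] &
              cx$word_class == groups$word_class[i], ]
    n <- nrow(g); m <- mean(g$complexity)
    half <- if (n < 2) 0 else stats::qt(0.975, n - 1) * stats::sd(g$complexity) / sqrt(n)
    tibble::tibble(condition = groups$condition[i],
                   word_class = groups$word_class[i], mean_complexity = m,
                   ci_low = m - half, ci_high = m + half, n = as.integer(n))
  }))
  report <- structure(list(complexity = cx, condition_summary = summ),
                      class = "summary_report")
  if (!is.null(out_dir)) write_report_tables(report, out_dir, prefix = "exp2")
  report
}

#' Dyadic interaction analysis
#'
#' Summarises communicative success and regularization proportions from the
#' trial log and builds the post-test 2x2 contingency table (complex
#' speakers regularizing at least one irregular item in the post-test, by
#' dyad type), with the uncorrected Pearson chi-square where defined. If a
#' margin of the table is zero the chi-square is refused and reported as
#' such rather than computed.
#'
#' @param trials Interaction trial table.
#' @param posttest Post-test production table.
#' @param out_dir Optional output directory.
#' @return List of class `summary_report` with `success`, `regularization`,
#'   `posttest_table` (counts), `chi2` (or `NULL`) and `chi2_message`.
#' @export
run_exp3 <- function(trials, posttest, out_dir = NULL) {
  succ <- communicative_success_summary(trials)
  reg <- regularization_summary(trials)
  post <- posttest[posttest$role == "complex" & posttest$item_type == "irregular", ,
                   drop = FALSE]
  by_sp <- stats::aggregate(regularized ~ speaker + dyad_type, post, any)
  tab <- table(factor(by_sp$dyad_type, levels = c("mixed", "complex")),
               factor(by_sp$regularized, levels = c(TRUE, FALSE)))
  chi <- tryCatch(chi2_2x2(tab), error = function(e) e)
  ok <- !inherits(chi, "error")
  report <- structure(list(success = succ, regularization = reg,
                           posttest_table = tab,
                           chi2 = if (ok) chi else NULL,
                           chi2_message = if (ok) NA_character_ else
                             conditionMessage(chi)),
                      class = "summary_report")
  if (!is.null(out_dir)) write_report_tables(report, out_dir, prefix = "exp3")
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]])) {
      cat("$", nm, " (", nrow(x[[nm]]), " rows)\n", sep = "")
      print(utils::head(as.data.frame(x[[nm]]), 6L), row.names = FALSE)
    } else if (nm == "chi2" && !is.null(x[[nm]])) {
      cat(sprintf("$chi2: X-squared(1) = %.3f, p = %.4f\n",
                  x$chi2$statistic, x$chi2$p_value))
    }
  }
  invisible(x)
}

write_report_tables <- function(report, out_dir, prefix) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    v <- report[[nm]]
    if (is.data.frame(v)) {
      utils::write.csv(v, file.path(out_dir, paste0(prefix, "_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' Write a JSON run manifest
#'
#' Records input descriptions, the seed and package version so that a
#' pipeline run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param inputs Named list describing the inputs.
#' @param seed The seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), seed = NA_integer_) {
  x <- list(package = "morphocomplex",
            version = as.character(utils::packageVersion("morphocomplex")),
            seed = seed, inputs = inputs,
            r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
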