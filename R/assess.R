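#' Cumulative weighted aggregation of one sibling group
#'
#' The value of an internal index under the cumulative relationship is
#' the weighted sum of its children's values — an exact dot product with
#' no clamping or rounding. With sibling weights summing to 1 this is a
#' convex combination, so the result lies between the smallest and
#' largest child value.
#'
#' @param values numeric vector of child values.
#' @param weights numeric vector of child weights, aligned with `values`.
#' @return The aggregated value (a scalar).
#' @export
#' @examples
#' aggregate_node(c(5, 0), c(0.6667, 0.3333))   # 3.3335
aggregate_node <- function(values, weights) {
  if (length(values) != length(weights))
    stop("`values` (length ", length(values), ") and `weights` (length ",
         length(weights), ") must align", call. = FALSE)
  sum(as.numeric(values) * as.numeric(weights))
}

#' Run a risk assessment
#'
#' Propagates tertiary scores up the hierarchy: every secondary index is
#' the weighted sum of its tertiary children, every primary index of its
#' (unrounded) secondaries, and the total value R of the (unrounded)
#' primaries. Rounding to four decimals happens only at display time;
#' the returned object keeps full precision.
#'
#' Subjects are ranked by descending unrounded R, ties broken
#' alphabetically by subject id, and each subject receives the risk
#' grade whose interval contains its R (see [risk_grade()]).
#'
#' @param sheet a [score_sheet] with one column per subject.
#' @param model a `risk_model` or [risk_hierarchy]; defaults to the
#'   bundled introduction-risk model.
#' @param strict passed to [validate_score_sheet()]; strict-mode rubric
#'   warnings are attached to the result, never fatal.
#' @param validate set to `FALSE` to skip score validation (used for
#'   algebraic checks on relaxed, non-integer sheets; ordinary use
#'   should validate).
#' @return An object of class `risk_assessment`: list with
#'   * `values`: full-precision matrix, one row per secondary, primary
#'     and total index (hierarchy order), one column per subject;
#'   * `rounded`: the same matrix rounded to 4 decimals (round-half-even)
#'     for reporting;
#'   * `grades`: named character vector of risk grades;
#'   * `ranking`: subjects in descending-R order;
#'   * `validation`: the [validate_score_sheet()] report.
#' @export
#' @examples
#' cs <- builtin_case_study()
#' a <- assess(cs$score_sheet)
#' a$rounded["R", ]
#' a$grades
assess <- function(sheet, model = default_model(), strict = FALSE,
                   validate = TRUE) {
  model <- .as_model(model)
  h <- model$hierarchy
  if (!inherits(sheet, "score_sheet")) sheet <- score_sheet(sheet)

  report <- validate_score_sheet(sheet, h, rubric = model$rubric,
                                 strict = strict)
  if (validate && !report$valid) {
    cond <- structure(
      class = c("aquarisk_invalid_sheet", "error", "condition"),
      list(message = paste0(
             "score sheet is not valid for model '", h$model_name, "': ",
             nrow(report$issues), " issue(s); first: ",
             report$issues$message[1]),
           call = sys.call(-1), report = report))
    stop(cond)
  }

  nodes <- h$nodes
  subj <- colnames(sheet)
  secondary <- nodes$id[nodes$level == "secondary"]
  primary <- nodes$id[nodes$level == "primary"]
  out_ids <- c(secondary, primary, h$root_id)
  vals <- matrix(NA_real_, nrow = length(out_ids), ncol = length(subj),
                 dimnames = list(out_ids, subj))

  weight_of <- stats::setNames(nodes$weight, nodes$id)
  for (p in secondary) {
    kids <- .children(h, p)
    vals[p, ] <- weight_of[kids] %*% sheet[kids, , drop = FALSE]
  }
  for (p in primary) {
    kids <- .children(h, p)
    vals[p, ] <- weight_of[kids] %*% vals[kids, , drop = FALSE]
  }
  kids <- .children(h, h$root_id)
  vals[h$root_id, ] <- weight_of[kids] %*% vals[kids, , drop = FALSE]

  r_total <- vals[h$root_id, ]
  grades <- risk_grade(r_total, grades = model$grades)
  # snap to 9 decimals before ordering so that mathematically tied
  # subjects are not separated by ulp-level summation noise
  ranking <- subj[order(-round(r_total, 9), subj)]

  structure(
    list(values = vals, rounded = round(vals, 4), grades = grades,
         ranking = ranking, subjects = subj, root_id = h$root_id,
         model_name = h$model_name, validation = report),
    class = "risk_assessment"
  )
}

#' Five-level risk-grade intervals
#'
#' The total risk value R partitions into five lower-open, upper-closed
#' intervals: negligible (0, 1], low (1, 2], medium (2, 3], high (3, 4]
#' and extremely high (4, 5]. R = 0 — possible for an all-zero sheet —
#' is graded negligible by closure. Each grade carries a policy
#' recommendation, from "the introduction can be carried out" up to
#' "introduction cannot take place".
#'
#' @return Data frame with columns `name`, `lower`, `upper`,
#'   `recommendation`.
#' @export
risk_grade_table <- function() {
  data.frame(
    name = c("negligible", "low", "medium", "high", "extremely_high"),
    lower = 0:4, upper = 1:5,
    recommendation = c(
      "The risk is negligible, and the introduction can be carried out.",
      paste("The risk is low, and the introduction can be carried out",
            "if the national policy allows."),
      paste("The risk is medium, and limited introduction can be",
            "carried out, but strict management measures must be taken."),
      paste("The risk is high, and introduction is not recommended; if",
            "the introduction is required, close communication with",
            "customs and other relevant departments must be conducted,",
            "and strict introduction strategies and risk prevention and",
            "control measures must be developed."),
      "The risk is extremely high, and introduction cannot take place."),
    stringsAsFactors = FALSE
  )
}

#' Grade a total risk value
#'
#' @param R numeric vector of total risk values in \[0, 5\].
#' @param grades grade-interval table (see [risk_grade_table()]).
#' @return Character vector of grade names; names of `R` are preserved.
#' @export
#' @examples
#' risk_grade(c(3.6973, 2.0, 1.9742))
risk_grade <- function(R, grades = risk_grade_table()) {
  R <- as.numeric(R) |> stats::setNames(names(R))
  if (anyNA(R) || any(R < grades$lower[1] - 1e-12) ||
      any(R > grades$upper[nrow(grades)] + 1e-12))
    stop("R outside the graded range [", grades$lower[1], ", ",
         grades$upper[nrow(grades)], "]", call. = FALSE)
  out <- vapply(R, function(r) {
    if (r <= grades$lower[1]) return(grades$name[1])  # closure at R = 0
    grades$name[which(r > grades$lower & r <= grades$upper + 1e-12)[1]]
  }, character(1))
  out
}

#' Policy recommendation for a grade
#' @param grade grade name(s) as returned by [risk_grade()].
#' @param grades grade table.
#' @return Character vector of recommendation texts.
#' @export
grade_recommendation <- function(grade, grades = risk_grade_table()) {
  i <- match(grade, grades$name)
  if (anyNA(i))
    stop("unknown grade(s): ", paste(grade[is.na(i)], collapse = ", "),
         call. = FALSE)
  grades$recommendation[i]
}

#' Subjects in descending risk order
#'
#' @param result a `risk_assessment` from [assess()].
#' @return Character vector of subject ids, highest total risk first;
#'   ties broken alphabetically.
#' @export
rank_subjects <- function(result) {
  stopifnot(inherits(result, "risk_assessment"))
  result$ranking
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("<risk_assessment> model '", x$model_name, "', ",
      length(x$subjects), " subject(s)\n\n", sep = "")
  tab <- format(x$rounded, nsmall = 4)
  tab <- rbind(tab, `Risk grade` = x$grades)
  print(as.data.frame(tab), right = TRUE)
  cat("\nRanking (descending R):",
      paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Write an assessment report
#'
#' `format = "csv"` writes the familiar results table (one row per
#' secondary/primary index, the total R and the risk grade; values at
#' four decimals). `format = "json"` writes a machine-readable record
#' with full-precision values, grades, recommendations and the ranking.
#'
#' @param result a `risk_assessment`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(result, path, format = c("csv", "json")) {
  stopifnot(inherits(result, "risk_assessment"))
  format <- match.arg(format)
  if (format == "csv") {
    tab <- formatC(result$rounded, format = "f", digits = 4)
    df <- data.frame(index = c(rownames(tab), "Risk grade"),
                     rbind(tab, result$grades[colnames(tab)]),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       quote = TRUE)
  } else {
    payload <- list(
      model = result$model_name,
      subjects = result$subjects,
      values = as.data.frame(t(result$values)),
      grades = as.list(result$grades),
      recommendations = as.list(stats::setNames(
        grade_recommendation(result$grades), names(result$grades))),
      ranking = result$ranking
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
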