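#' Scoring rubric for tertiary indices
#'
#' Each tertiary index is scored on an integer 0-5 risk scale. The rubric
#' stores, per index, the verbatim criterion text for every defined score
#' level. Two kinds of entry exist:
#'
#' * *enumerated* indices print a distinct criterion per level (a few of
#'   them define levels 1-5 only, with no level-0 text);
#' * *discussion* indices carry a single guidance paragraph that applies
#'   to all six levels; scoring them relies on expert discussion guided
#'   by the general evaluation rules (`discussion_rules`).
#'
#' The rubric is metadata: it documents and (in strict mode) advises on
#' scores, it never computes them.
#'
#' @name risk_rubric
NULL

.rubric_from_config <- function(rubric_list, discussion_rules = NULL) {
  entries <- lapply(rubric_list, function(e) {
    if (!is.null(e$levels)) {
      levels <- lapply(e$levels, as.character)
    } else if (!is.null(e$guidance)) {
      levels <- stats::setNames(rep(list(as.character(e$guidance)), 6L),
                                as.character(0:5))
    } else {
      stop("rubric entry without 'levels' or 'guidance'", call. = FALSE)
    }
    lv <- sort(as.integer(names(levels)))
    if (!all(diff(lv) == 1L) || lv[1] < 0L || lv[length(lv)] > 5L)
      stop("rubric levels must be a contiguous subset of 0..5",
           call. = FALSE)
    list(source_table = e$source_table %||% NA_character_,
         discussion = isTRUE(e$discussion),
         levels = levels)
  })
  structure(list(entries = entries,
                 discussion_rules = discussion_rules),
            class = "risk_rubric")
}

#' Look up the criterion text for a score level
#'
#' @param rubric a `risk_rubric` (e.g. `default_model()$rubric`).
#' @param index_id tertiary index id, e.g. `"p21"`.
#' @param score integer score level 0-5.
#' @return The verbatim criterion text, or `NA_character_` when the
#'   rubric defines no text for that level of that index (e.g. indices
#'   whose printed scale starts at 1).
#' @export
#' @examples
#' r <- default_model()$rubric
#' rubric_lookup(r, "p21", 0)
#' rubric_lookup(r, "p44", 0)   # no level-0 criterion: NA
rubric_lookup <- function(rubric, index_id, score) {
  stopifnot(inherits(rubric, "risk_rubric"))
  e <- rubric$entries[[index_id]]
  if (is.null(e))
    stop("unknown index id '", index_id, "' in rubric", call. = FALSE)
  if (length(score) != 1L || is.na(score) || score != round(score) ||
      score < 0 || score > 5)
    stop("`score` must be a single integer in 0..5", call. = FALSE)
  txt <- e$levels[[as.character(as.integer(score))]]
  if (is.null(txt)) NA_character_ else txt
}

#' Score levels a rubric defines for an index
#' @inheritParams rubric_lookup
#' @return Integer vector of defined levels (a contiguous subset of 0:5).
#' @export
rubric_defined_levels <- function(rubric, index_id) {
  stopifnot(inherits(rubric, "risk_rubric"))
  e <- rubric$entries[[index_id]]
  if (is.null(e))
    stop("unknown index id '", index_id, "' in rubric", call. = FALSE)
  sort(as.integer(names(e$levels)))
}

#' Validate a score sheet against a hierarchy (and optionally a rubric)
#'
#' Checks that every subject scores every tertiary index of the model,
#' with integer values inside the admissible 0-5 range, and nothing else.
#' All problems are *reported*, never thrown: validation is total over
#' arbitrary input sheets.
#'
#' In strict mode (requires a rubric) a score that falls on a level the
#' rubric does not define for that index — e.g. 0 for an index whose
#' printed scale starts at 1 — is flagged as a warning. Warnings never
#' make a sheet invalid: the global scoring rule gives every index the
#' same 0-5 range, strict mode merely surfaces the per-index rubric
#' reading.
#'
#' @param sheet a [score_sheet] (or a bare matrix with tertiary ids as
#'   row names and subjects as column names).
#' @param hierarchy a [risk_hierarchy]; defaults to the bundled model's.
#' @param rubric a `risk_rubric`, required for `strict = TRUE`.
#' @param strict enable advisory rubric-level warnings.
#' @return An object of class `score_validation`: list with `valid`
#'   (logical), `issues` and `warnings` (data frames with columns
#'   `subject`, `index`, `kind`, `message`).
#' @export
validate_score_sheet <- function(sheet, hierarchy = default_hierarchy(),
                                 rubric = NULL, strict = FALSE) {
  stopifnot(inherits(hierarchy, "risk_hierarchy"))
  issues <- list()
  warns <- list()
  add <- function(pool, subject, index, kind, message) {
    c(pool, list(data.frame(subject = subject, index = index, kind = kind,
                            message = message, stringsAsFactors = FALSE)))
  }

  m <- if (inherits(sheet, "score_sheet")) unclass(sheet) else
    tryCatch(as.matrix(sheet), error = function(e) NULL)
  if (is.null(m) || is.null(rownames(m)) || ncol(m) == 0L) {
    issues <- add(issues, NA_character_, NA_character_, "no_subjects",
                  "score sheet has no subjects or no index row names")
    return(.validation_report(issues, warns))
  }

  need <- tertiary_ids(hierarchy)
  subjects <- colnames(m) %||% paste0("subject", seq_len(ncol(m)))

  missing <- setdiff(need, rownames(m))
  for (id in missing)
    issues <- add(issues, NA_character_, id, "missing_index",
                  paste0("tertiary index '", id, "' absent from sheet"))
  unknown <- setdiff(rownames(m), need)
  for (id in unknown)
    issues <- add(issues, NA_character_, id, "unknown_index",
                  paste0("'", id, "' is not a tertiary index of model '",
                         hierarchy$model_name, "'"))

  present <- intersect(need, rownames(m))
  for (s in seq_along(subjects)) {
    for (id in present) {
      v <- suppressWarnings(as.numeric(m[id, s]))
      if (is.na(v)) {
        issues <- add(issues, subjects[s], id, "not_a_number",
                      paste0("score for ", id, " is missing or ",
                             "non-numeric"))
      } else if (v < 0 || v > 5) {
        issues <- add(issues, subjects[s], id, "out_of_range",
                      sprintf("score %g for %s outside [0, 5]", v, id))
      } else if (v != round(v)) {
        issues <- add(issues, subjects[s], id, "non_integer",
                      sprintf("score %g for %s is not a whole level", v,
                              id))
      } else if (strict && !is.null(rubric) &&
                 !(v %in% rubric_defined_levels(rubric, id))) {
        warns <- add(warns, subjects[s], id, "undefined_rubric_level",
                     sprintf(paste0("score %d for %s falls on a level the",
                                    " rubric does not define (defined: ",
                                    "%s)"), as.integer(v), id,
                             paste(rubric_defined_levels(rubric, id),
                                   collapse = ",")))
      }
    }
  }
  if (strict && is.null(rubric))
    warning("strict = TRUE without a rubric: rubric-level checks skipped",
            call. = FALSE)
  .validation_report(issues, warns)
}

.validation_report <- function(issues, warns) {
  empty <- data.frame(subject = character(), index = character(),
                      kind = character(), message = character(),
                      stringsAsFactors = FALSE)
  issues <- if (length(issues)) do.call(rbind, issues) else empty
  warns <- if (length(warns)) do.call(rbind, warns) else empty
  structure(list(valid = nrow(issues) == 0L, issues = issues,
                 warnings = warns),
            class = "score_validation")
}

#' @export
print.score_validation <- function(x, ...) {
  cat("<score_validation>", if (x$valid) "VALID" else "INVALID", "\n")
  if (nrow(x$issues)) {
    cat(" issues:\n")
    for (i in seq_len(nrow(x$issues)))
      cat("  -", x$issues$message[i],
          if (!is.na(x$issues$subject[i]))
            paste0("[", x$issues$subject[i], "]") else "", "\n")
  }
  if (nrow(x$warnings))
    cat(sprintf(" %d advisory warning(s) (strict mode)\n",
                nrow(x$warnings)))
  invisible(x)
}
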