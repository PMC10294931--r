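#' Load a full risk-assessment model
#'
#' A model configuration bundles everything needed to run an assessment:
#' the weighted index hierarchy, the scoring rubric for every tertiary
#' index, the risk-grade intervals with their policy recommendations, and
#' the random-index (RI) table used for AHP consistency checks.
#'
#' @param config path to a YAML model configuration, or a parsed list.
#' @return An object of class `risk_model`: a list with elements
#'   `hierarchy` ([risk_hierarchy]), `rubric` ([risk_rubric]), `grades`
#'   (data frame of grade intervals, see [risk_grade_table()]),
#'   `ri_table` (numeric vector indexed by matrix order) and
#'   `score_levels` (min/max admissible scores).
#' @seealso [default_model()] for the bundled model.
#' @export
load_model <- function(config) {
  cfg <- .read_config(config)
  hierarchy <- load_hierarchy(cfg)
  rubric <- if (!is.null(cfg$rubric))
    .rubric_from_config(cfg$rubric, cfg$discussion_rules) else NULL
  grades <- if (!is.null(cfg$grades))
    .grades_from_config(cfg$grades) else risk_grade_table()
  ri <- if (!is.null(cfg$ri_table)) as.numeric(unlist(cfg$ri_table))
        else saaty_ri()
  score_levels <- list(
    min = cfg$score_levels$min %||% 0L,
    max = cfg$score_levels$max %||% 5L
  )
  structure(
    list(hierarchy = hierarchy, rubric = rubric, grades = grades,
         ri_table = ri, score_levels = score_levels,
         description = cfg$description %||% ""),
    class = "risk_model"
  )
}

#' The bundled introduction-risk model
#'
#' Returns the default model shipped with the package: a 4/12/60 index
#' hierarchy for aquatic-animal introduction risk (hazard, entry,
#' exposure and consequence assessment), published weight coefficients
#' carried to four decimal places, a six-level (0-5) scoring rubric for
#' each tertiary index, and the five risk-grade intervals on the total
#' value R.
#'
#' The parsed model is cached for the session; the YAML source lives at
#' `system.file("extdata", "aquarisk_model.yaml", package = "aquarisk")`
#' and can serve as a template for custom models.
#'
#' @return A `risk_model` (see [load_model()]).
#' @export
#' @examples
#' m <- default_model()
#' m$hierarchy
default_model <- function() {
  if (is.null(.aquarisk_env$default_model)) {
    path <- system.file("extdata", "aquarisk_model.yaml",
                        package = "aquarisk")
    .aquarisk_env$default_model <- load_model(path)
  }
  .aquarisk_env$default_model
}

#' @rdname default_model
#' @export
default_hierarchy <- function() default_model()$hierarchy

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model>\n")
  print(x$hierarchy)
  cat("  rubric entries:", if (is.null(x$rubric)) 0L
      else length(x$rubric$entries), "\n")
  cat("  grades:", paste(x$grades$name, collapse = " < "), "\n")
  invisible(x)
}

.grades_from_config <- function(grade_list) {
  df <- do.call(rbind, lapply(grade_list, function(g)
    data.frame(name = g$name, lower = as.numeric(g$lower),
               upper = as.numeric(g$upper),
               recommendation = g$recommendation %||% "",
               stringsAsFactors = FALSE)))
  df <- df[order(df$lower), , drop = FALSE]
  # intervals must partition (lower_1, upper_k] without gaps
  if (any(df$upper <= df$lower) ||
      (nrow(df) > 1 && any(abs(df$lower[-1] - df$upper[-nrow(df)]) > 1e-12)))
    stop("grade intervals must be contiguous and increasing", call. = FALSE)
  rownames(df) <- NULL
  df
}

# resolve a risk_model / risk_hierarchy argument into both pieces
.as_model <- function(model) {
  if (inherits(model, "risk_model")) return(model)
  if (inherits(model, "risk_hierarchy"))
    return(structure(list(hierarchy = model, rubric = NULL,
                          grades = risk_grade_table(),
                          ri_table = saaty_ri(),
                          score_levels = list(min = 0L, max = 5L)),
                     class = "risk_model"))
  stop("`model` must be a risk_model or risk_hierarchy", call. = FALSE)
}
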