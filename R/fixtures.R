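#' The embedded five-species case study
#'
#' The package ships the worked example the default model was validated
#' on: 0-5 scores for all 60 tertiary indices across five aquatic
#' animals commonly introduced into southern China (*Pterygoplichthys
#' pardalis*, *Macrobrachium rosenbergii*, *Crassostrea gigas*,
#' *Trachemys scripta elegans*, *Ambystoma mexicanum*), together with
#' the published secondary/primary/total values and risk grades.
#' Expected values are stored exactly as printed (four decimals) so
#' regression tests compare against the literal published figures.
#'
#' One published cell is internally inconsistent: the consequence
#' assessment (R4) of *P. pardalis* prints 3.8843, while its own
#' coefficients give 0.8000 x 3.7002 + 0.2000 x 4.6164 = 3.8834 under
#' every propagation order — a digit transposition in the printed table.
#' The stored expectation keeps the printed value; see the methods
#' vignette for the analysis.
#'
#' @return An object of class `case_study`: list with
#'   * `score_sheet`: the 60 x 5 [score_sheet];
#'   * `expected$values`: numeric 17 x 5 matrix of published P1-P12,
#'     R1-R4 and R values;
#'   * `expected$printed`: the same values as printed strings;
#'   * `expected$grades`: named character vector of published grades.
#' @export
#' @examples
#' cs <- builtin_case_study()
#' cs$score_sheet["p11", ]
#' cs$expected$grades
builtin_case_study <- function() {
  scores_path <- system.file("extdata", "case_study_scores.csv",
                             package = "aquarisk")
  expected_path <- system.file("extdata", "case_study_expected.csv",
                               package = "aquarisk")
  sheet <- read_score_sheet(scores_path)

  raw <- utils::read.csv(expected_path, check.names = FALSE,
                         colClasses = "character")
  ids <- raw$index
  printed <- as.matrix(raw[, -1, drop = FALSE])
  rownames(printed) <- ids
  grade_row <- printed["grade", ]
  printed <- printed[ids != "grade", , drop = FALSE]
  values <- apply(printed, 2, as.numeric)
  rownames(values) <- rownames(printed)

  structure(
    list(score_sheet = sheet,
         expected = list(values = values, printed = printed,
                         grades = grade_row),
         source = c(scores = scores_path, results = expected_path)),
    class = "case_study"
  )
}

#' @export
print.case_study <- function(x, ...) {
  cat("<case_study> ", nrow(x$score_sheet), " tertiary indices x ",
      ncol(x$score_sheet), " species\n", sep = "")
  cat("  species:", paste(colnames(x$score_sheet), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a random score sheet
#'
#' Draws uniform integer scores in 0-5 for every tertiary index of the
#' hierarchy — the generator behind the package's property tests. The
#' uniform level distribution is a neutral choice (no empirical score
#' distribution is assumed); identical seeds give identical sheets, and
#' the calling session's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param n_subjects number of subjects (columns), `>= 1`.
#' @param hierarchy target [risk_hierarchy].
#' @return A valid [score_sheet] with subjects `S1, S2, ...`.
#' @export
#' @examples
#' s <- random_score_sheet(1, 3)
#' range(s)
random_score_sheet <- function(seed, n_subjects = 1L,
                               hierarchy = default_hierarchy()) {
  stopifnot(n_subjects >= 1L)
  ids <- tertiary_ids(hierarchy)
  draw <- .with_seed(seed, {
    matrix(sample.int(6L, length(ids) * n_subjects, replace = TRUE) - 1L,
           nrow = length(ids), ncol = n_subjects)
  })
  dimnames(draw) <- list(ids, paste0("S", seq_len(n_subjects)))
  score_sheet(draw)
}

# evaluate `expr` under a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
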