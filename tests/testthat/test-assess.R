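test_that("aggregate_node is an exact dot product", {
  expect_equal(aggregate_node(c(5, 0), c(0.6667, 0.3333)), 3.3335)
  expect_equal(aggregate_node(rep(0, 6), runif(6)), 0)
  # a published secondary value from the case study
  expect_equal(
    aggregate_node(c(5, 4, 5, 4, 5, 4),
                   c(0.0866, 0.2150, 0.0433, 0.3408, 0.2544, 0.0599)),
    4.3843, tolerance = 1e-12)
  expect_error(aggregate_node(1:3, 1:2), "must align")
})

test_that("assess matches a naive three-pass oracle on random sheets", {
  h <- default_hierarchy()
  for (seed in 1:5) {
    sheet <- random_score_sheet(seed, n_subjects = 3)
    a <- assess(sheet)
    expect_equal(a$values, naive_assess(sheet, h), tolerance = 1e-12)
  }
  # and on an arbitrary non-default hierarchy
  toy <- toy_hierarchy()
  sheet <- random_score_sheet(11, n_subjects = 2, hierarchy = toy)
  a <- assess(sheet, toy)
  expect_equal(a$values, naive_assess(sheet, toy), tolerance = 1e-12)
})

test_that("constant sheets propagate the constant to every level", {
  h <- default_hierarchy()
  for (k in c(0, 3, 5)) {
    sheet <- score_sheet(matrix(k, nrow = 60, ncol = 2,
                                dimnames = list(tertiary_ids(h),
                                                c("x", "y"))))
    a <- assess(sheet)
    expect_equal(unname(a$values), matrix(k, nrow(a$values), 2),
                 tolerance = 1e-9)
  }
})

test_that("raising one tertiary score raises all its ancestors", {
  sheet <- random_score_sheet(3, n_subjects = 1)
  base <- assess(sheet)
  h <- default_hierarchy()
  for (id in c("p11", "p42", "p83", "p126")) {
    bumped <- unclass(sheet)
    if (bumped[id, 1] == 5) bumped[id, 1] <- bumped[id, 1] - 1
    else bumped[id, 1] <- bumped[id, 1] + 1
    delta <- bumped[id, 1] - unclass(sheet)[id, 1]
    a2 <- assess(score_sheet(bumped))
    sec <- h$nodes$parent[h$nodes$id == id]
    pri <- h$nodes$parent[h$nodes$id == sec]
    for (anc in c(sec, pri, "R"))
      expect_true(sign(a2$values[anc, 1] - base$values[anc, 1]) ==
                    sign(delta), info = paste(id, anc))
  }
})

test_that("aggregation is linear in the score sheet", {
  s1 <- unclass(random_score_sheet(21, n_subjects = 2))
  s2 <- unclass(random_score_sheet(22, n_subjects = 2))
  a1 <- assess(score_sheet(s1), validate = FALSE)
  a2 <- assess(score_sheet(s2), validate = FALSE)
  for (alpha in c(0.25, 0.6)) {
    mix <- alpha * s1 + (1 - alpha) * s2  # non-integer: relaxed sheet
    am <- assess(score_sheet(mix), validate = FALSE)
    expect_equal(am$values, alpha * a1$values + (1 - alpha) * a2$values,
                 tolerance = 1e-12)
  }
})

test_that("risk grades honor the lower-open, upper-closed intervals", {
  # upper boundaries belong to the lower grade
  expect_identical(risk_grade(c(1, 2, 3, 4, 5)),
                   c("negligible", "low", "medium", "high",
                     "extremely_high"))
  # just above a boundary, the next grade starts
  expect_identical(risk_grade(c(1 + 1e-9, 2 + 1e-9, 3 + 1e-9, 4 + 1e-9)),
                   c("low", "medium", "high", "extremely_high"))
  expect_identical(risk_grade(0), "negligible")   # closure at zero
  expect_identical(risk_grade(3.6973), "high")
  expect_identical(risk_grade(1.9742), "low")
  expect_error(risk_grade(5.2), "outside")
  expect_error(risk_grade(-0.1), "outside")

  expect_match(grade_recommendation("extremely_high"), "cannot take place")
  expect_error(grade_recommendation("catastrophic"), "unknown grade")
})

test_that("ranking is by descending R with lexicographic tie-break", {
  sheet <- random_score_sheet(5, n_subjects = 1)
  dup <- cbind(unclass(sheet), unclass(sheet), unclass(sheet))
  colnames(dup) <- c("zeta", "alpha", "mid")
  a <- assess(score_sheet(dup))
  expect_identical(rank_subjects(a), c("alpha", "mid", "zeta"))

  single <- assess(sheet)
  expect_identical(rank_subjects(single), "S1")
})

test_that("invalid sheets are rejected with the validation report attached", {
  sheet <- unclass(builtin_case_study()$score_sheet)
  sheet["p21", 1] <- 9
  err <- tryCatch(assess(score_sheet(sheet)), error = identity)
  expect_s3_class(err, "aquarisk_invalid_sheet")
  expect_s3_class(err$report, "score_validation")
  expect_identical(err$report$issues$kind, "out_of_range")
})

test_that("assessment reports round-trip and display at four decimals", {
  a <- assess(builtin_case_study()$score_sheet)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_assessment(a, csv, "csv")
  tab <- read.csv(csv, check.names = FALSE, colClasses = "character")
  expect_identical(tab$index, c(rownames(a$rounded), "Risk grade"))
  expect_identical(tab[tab$index == "R", 2],
                   sprintf("%.4f", a$rounded["R", 1]))

  js <- withr::local_tempfile(fileext = ".json")
  write_assessment(a, js, "json")
  parsed <- jsonlite::read_json(js)
  expect_identical(parsed$ranking[[1]], a$ranking[1])
  expect_equal(parsed$values[[1]]$R, unname(a$values["R", 1]),
               tolerance = 1e-12)
})
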