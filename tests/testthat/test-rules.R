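test_that("rule parsing builds the expected expression trees", {
  r2 <- parse_rule("Q2&Q4&Q6")
  hand <- boolean_rule(list(and = list(list(and = list(list(q = 2L),
                                                       list(q = 4L))),
                                       list(q = 6L))))
  pats <- answer_patterns()
  expect_identical(evaluate_rule(r2, pats), evaluate_rule(hand, pats))
  expect_s3_class(r2, "screening_rule")
})

test_that("structural errors surface at construction, not evaluation", {
  expect_error(boolean_rule(list(q = 8)), "1\\.\\.7")
  expect_error(boolean_rule(list(q = 0)), "1\\.\\.7")
  expect_error(parse_rule("Q2&Q9"), "symbol")
  expect_error(boolean_rule(list(xor = list(list(q = 1)))), "unknown")
  expect_error(logistic_rule(c(q1 = 1), intercept = 0, cutoff = 1),
               "cutoff")
  expect_error(logistic_rule(c(z9 = 1), intercept = 0), "named")
})

test_that("boolean rules evaluate the published example patterns", {
  r2 <- eceq_rule("rule2")
  r3 <- eceq_rule("rule3")
  all_yes <- as.data.frame(matrix(TRUE, 1, 7,
                                  dimnames = list(NULL, paste0("q", 1:7))))
  expect_true(evaluate_rule(r3, all_yes))
  only_q7 <- as.data.frame(matrix(FALSE, 1, 7,
                                  dimnames = list(NULL, paste0("q", 1:7))))
  only_q7$q7 <- TRUE
  expect_true(evaluate_rule(r3, only_q7))
  expect_false(evaluate_rule(r2, only_q7))
  # Q1 & Q3 substitute for a missing Q4 in rule 3 only
  v <- data.frame(q1 = TRUE, q2 = TRUE, q3 = TRUE, q4 = FALSE,
                  q5 = FALSE, q6 = TRUE, q7 = FALSE)
  expect_false(evaluate_rule(r2, v))
  expect_true(evaluate_rule(r3, v))
})

test_that("truth tables agree with independent oracles on all 128 patterns", {
  pats <- answer_patterns()
  expect_identical(nrow(pats), 128L)
  for (nm in c("rule1", "rule2", "rule3", "rule4")) {
    tt <- rule_truth_table(eceq_rule(nm))
    expect_identical(tt$positive, oracle_over_patterns(oracle_rules[[nm]]),
                     info = nm)
  }
  tt_alt <- rule_truth_table(eceq_rule("rule4_alt"))
  expect_identical(tt_alt$positive,
                   oracle_over_patterns(function(a) {
                     oracle_rules$rule4(a, intercept = -4.84)
                   }))
})

test_that("three fixed conjuncts leave 16 positive patterns", {
  expect_identical(sum(rule_truth_table(eceq_rule("rule1"))$positive), 16L)
  expect_identical(sum(rule_truth_table(eceq_rule("rule2"))$positive), 16L)
})

test_that("logistic probabilities match hand-computed transforms", {
  r4 <- eceq_rule("rule4")
  av <- function(...) {
    v <- as.list(setNames(rep(FALSE, 7), paste0("q", 1:7)))
    v[c(...)] <- TRUE
    as.data.frame(v)
  }
  # all modelled answers yes: y = 9.463 - 4.483 = 4.980
  expect_equal(logistic_probability(r4, av("q1", "q2", "q3", "q4", "q6")),
               1 / (1 + exp(-4.980)), tolerance = 1e-10)
  expect_equal(round(logistic_probability(r4, av("q1", "q2", "q3", "q4",
                                                 "q6")), 4), 0.9932)
  expect_equal(round(logistic_probability(r4, av()), 4), 0.0112)
  r0 <- logistic_rule(c(q1 = 1.5), intercept = 0, cutoff = 0.5)
  expect_equal(logistic_probability(r0, av()), 0.5)
})

test_that("logistic classification applies cutoff, strictness and override", {
  alt <- eceq_rule("rule4_alt")
  v246 <- data.frame(q1 = FALSE, q2 = TRUE, q3 = FALSE, q4 = TRUE,
                     q5 = FALSE, q6 = TRUE, q7 = FALSE)
  # y = 6.612 - 4.84 = 1.772, p = 0.8547 > 0.849
  expect_true(evaluate_rule(alt, v246))
  only_q7 <- data.frame(q1 = FALSE, q2 = FALSE, q3 = FALSE, q4 = FALSE,
                        q5 = FALSE, q6 = FALSE, q7 = TRUE)
  expect_true(evaluate_rule(alt, only_q7))
  none <- only_q7; none$q7 <- FALSE
  expect_false(evaluate_rule(eceq_rule("rule4"), none))
  expect_false(evaluate_rule(alt, none))
  # boundary probability: strict excludes, non-strict includes
  at_cut <- logistic_rule(c(q1 = 1), intercept = -1, cutoff = 0.5,
                          strict = TRUE, q7_override = FALSE)
  v1 <- none; v1$q1 <- TRUE
  expect_false(evaluate_rule(at_cut, v1))
  at_cut$strict <- FALSE
  expect_true(evaluate_rule(at_cut, v1))
})

test_that("the two published intercepts disagree on the {Q2,Q3,Q4} pattern", {
  v <- data.frame(q1 = FALSE, q2 = TRUE, q3 = TRUE, q4 = TRUE,
                  q5 = FALSE, q6 = FALSE, q7 = FALSE)
  expect_true(evaluate_rule(eceq_rule("rule4"), v))       # p = 0.886
  expect_false(evaluate_rule(eceq_rule("rule4_alt"), v))  # p = 0.844
})

test_that("AND/OR rules and the positive-coefficient score are monotone", {
  set.seed(11)
  rules <- lapply(c("rule1", "rule2", "rule3", "rule4"), eceq_rule)
  for (i in seq_len(60)) {
    a <- random_answers(1)
    base <- vapply(rules, function(r) evaluate_rule(r, a), logical(1))
    for (q in paste0("q", 1:7)) {
      if (a[[q]]) next
      b <- a
      b[[q]] <- TRUE
      flipped <- vapply(rules, function(r) evaluate_rule(r, b), logical(1))
      expect_true(all(flipped >= base))
    }
  }
})

test_that("rule 3 positives are a superset of rule 2 positives", {
  pats <- answer_patterns()
  p2 <- evaluate_rule(eceq_rule("rule2"), pats)
  p3 <- evaluate_rule(eceq_rule("rule3"), pats)
  expect_true(all(p3[p2]))
})

test_that("logistic probability ignores coefficient order", {
  co <- c(q1 = 1.484, q2 = 2.415, q3 = 1.367, q4 = 2.749, q6 = 1.448)
  a <- logistic_rule(co, -4.483)
  b <- logistic_rule(rev(co), -4.483)
  pats <- answer_patterns()
  expect_equal(logistic_probability(a, pats), logistic_probability(b, pats))
})

test_that("rules round-trip through JSON definition files", {
  tmp <- tempfile(fileext = ".json")
  pats <- answer_patterns()
  for (nm in c("rule3", "rule4")) {
    r <- eceq_rule(nm)
    write_rule(r, tmp)
    r2 <- read_rule(tmp)
    expect_identical(evaluate_rule(r2, pats), evaluate_rule(r, pats))
    expect_identical(r2$name, r$name)
  }
  unlink(tmp)
})
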