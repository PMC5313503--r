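test_that("the built-in instrument has the published shape and intents", {
  ctx <- queds_context()
  expect_s3_class(ctx, "clinical_context")
  expect_equal(nrow(ctx$incidence), 41)
  expect_equal(ncol(ctx$incidence), 23)
  expect_identical(item_intent(ctx, 27), c("A12", "A13", "A20"))
  expect_identical(item_intent(ctx, 39), c("A8", "A9", "A18", "A20"))
  expect_identical(item_intent(ctx, 34), "A1")
  expect_identical(item_intent(ctx, 2), c("A6", "A7"))
  # incidence rows are exactly the intent indicators
  for (id in ctx$items$id) {
    expect_identical(colnames(ctx$incidence)[ctx$incidence[id, ] == 1L],
                     item_intent(ctx, id))
  }
})

test_that("the three factors partition the items with sizes 15/14/12", {
  f <- queds_factors()
  expect_named(f, c("cognitive", "somatic", "affective"))
  expect_equal(unname(lengths(f)), c(15, 14, 12))
  expect_setequal(unlist(f), 1:41)
  expect_equal(anyDuplicated(unlist(f)), 0)
})

test_that("the built-in context passes content validation", {
  rep <- validate_context(queds_context())
  expect_true(rep$ok)
  expect_length(rep$empty_rows, 0)
  expect_length(rep$empty_cols, 0)
  # equal-intent items are reported informationally, not rejected
  expect_true(all(c(22, 23) %in% rep$duplicate_rows))
})

test_that("validation flags empty rows, empty columns and duplicates", {
  ctx <- mk_context(list("a", c("a", "b"), "a"), attrs = c("a", "b", "c"))
  ctx$incidence[3, ] <- 0L  # damage row 3
  rep <- validate_context(ctx)
  expect_false(rep$ok)
  expect_equal(rep$empty_rows, 3)
  expect_equal(rep$empty_cols, "c")
  ctx2 <- mk_context(list("a", "a", c("a", "b")))
  expect_setequal(validate_context(ctx2)$duplicate_rows, c(1, 2))
})

test_that("context CSV and JSON round-trips are the identity", {
  ctx <- queds_context()
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_context(ctx, path)
    back <- read_context(path)
    expect_identical(back$incidence, ctx$incidence)
    expect_identical(back$items$id, ctx$items$id)
    expect_identical(back$items$text, ctx$items$text)
    expect_identical(back$attributes$id, ctx$attributes$id)
  }
})

test_that("malformed context files raise parse errors naming the cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_id,text,A1,A2", "1,first,1,0", "2,second,2,1"), path)
  err <- expect_error(read_context(path), class = "queds_input_error")
  expect_match(conditionMessage(err), "row 2, column A1")
  # missing header
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("foo,bar", "1,0"), path2)
  expect_error(read_context(path2), class = "queds_input_error")
  # duplicate item id
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_id,A1,A2", "1,1,0", "1,0,1"), path3)
  expect_error(read_context(path3), class = "queds_input_error")
})

test_that("factor subcontexts restrict rows and drop uncovered attributes", {
  ctx <- queds_context()
  f <- queds_factors()
  expect_setequal(subcontext(ctx, f$somatic)$attributes$id,
                  c("A3", "A4", "A5", "A6", "A7", "A8", "A9", "A12", "A18",
                    "A20", "A22"))
  expect_setequal(subcontext(ctx, f$affective)$attributes$id,
                  c("A1", "A2", "A7", "A12", "A17", "A19", "A20", "A23"))
  # the cognitive restriction keeps every attribute its items investigate,
  # including A20 carried by item 27
  expect_setequal(subcontext(ctx, f$cognitive)$attributes$id,
                  c("A1", "A10", "A11", "A12", "A13", "A14", "A15", "A16",
                    "A17", "A18", "A20", "A21"))
  one <- subcontext(ctx, 34)
  expect_equal(nrow(one$incidence), 1)
  expect_identical(one$attributes$id, "A1")
  expect_error(subcontext(ctx, integer(0)), class = "queds_input_error")
  expect_error(subcontext(ctx, 99), class = "queds_input_error")
})

test_that("attribute coverage maps criteria to the factors observing them", {
  cov <- attribute_coverage(queds_context())
  expect_setequal(cov$A12, c("cognitive", "somatic", "affective"))
  expect_setequal(cov$A1, c("cognitive", "affective"))
  expect_setequal(cov$A17, c("cognitive", "affective"))
  expect_setequal(cov$A18, c("cognitive", "somatic"))
  expect_setequal(cov$A7, c("somatic", "affective"))
  expect_identical(cov$A22, "somatic")
  expect_identical(cov$A15, "cognitive")
  expect_identical(cov$A23, "affective")
  expect_error(attribute_coverage(queds_context(), list(a = 1:40)),
               class = "queds_input_error")
})

test_that("Cohen's kappa matches its definition and is symmetric", {
  m1 <- matrix(c(1, 0, 0, 1), 2)
  m2 <- matrix(c(1, 1, 0, 1), 2)
  # hand evaluation: p_o = 3/4; p_e = .5*.75 + .5*.25 = 0.5; kappa = 0.5
  expect_equal(cohen_kappa(m1, m2), 0.5)
  expect_equal(cohen_kappa(m2, m1), cohen_kappa(m1, m2))
  expect_equal(cohen_kappa(m1, m1), 1.0)
  expect_equal(mean_pairwise_kappa(list(m1, m1, m1)), 1.0)
  expect_error(cohen_kappa(m1, matrix(0, 3, 2)), class = "queds_input_error")
  # all-ones tables: chance agreement 1, kappa undefined
  expect_warning(k <- cohen_kappa(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_true(is.nan(k))
})

test_that("kappa is symmetric on random 0/1 tables", {
  set.seed(42)
  for (rep in 1:20) {
    a <- matrix(rbinom(12, 1, 0.4), 3)
    b <- matrix(rbinom(12, 1, 0.6), 3)
    if (mean(a) %in% c(0, 1) && mean(b) %in% c(0, 1)) next
    expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
  }
})
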