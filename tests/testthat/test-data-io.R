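test_that("catalogue CSV round-trips exactly", {
  cat1 <- tiny_catalogue()
  path <- withr::local_tempfile(fileext = ".csv")
  write_meal_catalogue(cat1, path)
  cat2 <- read_meal_catalogue(path)
  expect_identical(attr(cat2, "n_skipped"), 0L)
  attr(cat2, "n_skipped") <- NULL
  expect_equal(as.data.frame(cat2), as.data.frame(cat1))
})

test_that("malformed catalogue rows are skipped and counted", {
  cat1 <- tiny_catalogue()
  cat1$calories <- as.character(cat1$calories)
  cat1$calories[2] <- "abc"
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cat1, path)
  expect_warning(out <- read_meal_catalogue(path), "skipped 1")
  expect_equal(nrow(out), 3L)
  expect_identical(attr(out, "n_skipped"), 1L)
})

test_that("a missing required column is a hard error naming it", {
  cat1 <- tiny_catalogue()
  cat1$sodium_mg <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cat1, path)
  expect_error(read_meal_catalogue(path), "sodium_mg")
})

test_that("interactions reader rejects out-of-range ratings per row", {
  ints <- tiny_interactions()
  ints$rating[3] <- 7L
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ints, path)
  expect_warning(out <- read_interactions(path), "rejected 1")
  expect_equal(nrow(out), 4L)
  expect_true(all(out$rating %in% 1:5))
})

test_that("duplicate (user, meal) pairs keep the latest timestamp", {
  ints <- tibble::tibble(
    user_id = c("u1", "u1", "u2", "u1", "u2"),
    meal_id = c("m1", "m2", "m1", "m1", "m2"),
    rating = c(2L, 4L, 3L, 5L, 1L),
    timestamp = c(1, 2, 3, 9, 4)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ints, path)
  out <- read_interactions(path)
  expect_equal(nrow(out), 4L)
  kept <- out$rating[out$user_id == "u1" & out$meal_id == "m1"]
  expect_equal(kept, 5L)
})

test_that("distinct-rater filter counts users, not interactions", {
  # meal A: 10 distinct raters; meal B: 9; meal C: 12 ratings from 6 users
  ints <- tibble::tibble(
    user_id = c(sprintf("u%02d", 1:10), sprintf("u%02d", 1:9),
                rep(sprintf("u%02d", 1:6), 2)),
    meal_id = c(rep("A", 10), rep("B", 9), rep("C", 12)),
    rating = 3L,
    timestamp = 1:31
  )
  cat1 <- tibble::tibble(meal_id = c("A", "B", "C"))
  suppressMessages({
    out10 <- filter_min_distinct_raters(ints, cat1, min_raters = 10)
    out1 <- filter_min_distinct_raters(ints, cat1, min_raters = 1)
  })
  expect_equal(out10$catalogue$meal_id, "A")
  expect_true(all(out10$interactions$meal_id == "A"))
  expect_equal(out1$catalogue$meal_id, c("A", "B", "C"))
  # idempotent and monotone
  suppressMessages(again <- filter_min_distinct_raters(out10$interactions,
                                                       out10$catalogue, 10))
  expect_equal(again$catalogue, out10$catalogue)
  suppressMessages(out11 <- filter_min_distinct_raters(ints, cat1, 11))
  expect_true(all(out11$catalogue$meal_id %in% out10$catalogue$meal_id))
})

test_that("train/test split partitions interactions reproducibly", {
  w <- small_world()
  ints <- w$interactions[1:100, ]
  s1 <- split_interactions(ints, 0.7, seed = 1)
  s2 <- split_interactions(ints, 0.7, seed = 1)
  expect_equal(nrow(s1$train), 70L)
  expect_equal(nrow(s1$test), 30L)
  expect_identical(s1, s2)
  key <- function(d) paste(d$user_id, d$meal_id, d$timestamp)
  expect_length(intersect(key(s1$train), key(s1$test)), 0L)
  expect_setequal(c(key(s1$train), key(s1$test)), key(ints))
  s3 <- split_interactions(ints, 0.7, seed = 2)
  expect_false(identical(key(s1$train), key(s3$train)))
  expect_error(split_interactions(ints, 1.2), "train_frac")
})

test_that("hard constraints filter by registry predicates", {
  cat1 <- tiny_catalogue()
  gf <- apply_hard_constraints(cat1, "gluten_free")
  expect_false("b1" %in% gf$meal_id)
  expect_equal(nrow(apply_hard_constraints(cat1, character())), nrow(cat1))
  # sodium cut-off at 600 mg over the printed example amounts
  sodium_cat <- tiny_catalogue()[1:3, ]
  sodium_cat$sodium_mg <- c(39, 900, 1280)
  low <- apply_hard_constraints(sodium_cat, "low_sodium")
  expect_equal(low$sodium_mg, 39)
  expect_error(apply_hard_constraints(cat1, "keto"), "known tags")
})

test_that("user profiles round-trip through JSON", {
  p <- user_profile("u9", demographics = list(age = 45, sex = "female"),
                    hard_constraints = c("gluten_free", "low_sodium"),
                    criteria_prefs = list(weights = list(nutrition = 2, cost = 1)))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE)
  p2 <- read_user_profile(path)
  expect_equal(p2$user_id, "u9")
  expect_equal(p2$hard_constraints, c("gluten_free", "low_sodium"))
  expect_error(user_profile("u1", hard_constraints = "no_such_tag"),
               "unknown hard constraint")
})
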