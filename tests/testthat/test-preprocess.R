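test_that("min-max fitting records per-item extremes from the fitted records only", {
  d <- tiny_dataset(8L, 4L)
  d$age <- c(2, 8, 5, rep(5, 9))
  p <- fit_minmax(d)
  expect_identical(p$min[p$column == "age"], 2)
  expect_identical(p$max[p$column == "age"], 8)

  sub <- d[4:12, ] # excludes the extremes
  p_sub <- fit_minmax(sub)
  expect_identical(p_sub$min[p_sub$column == "age"], 5)
  expect_identical(p_sub$max[p_sub$column == "age"], 5)
  expect_true(p_sub$degenerate[p_sub$column == "age"])

  expect_error(fit_minmax(d[0, ]), "empty")
})

test_that("standard normalization maps the fitted range onto [0, 1]", {
  d <- tiny_dataset()
  d$age <- seq(10, 30, length.out = nrow(d))
  p <- fit_minmax(d)
  expect_equal(apply_minmax(10, "age", p), 0)
  expect_equal(apply_minmax(20, "age", p), 0.5)
  expect_equal(apply_minmax(30, "age", p), 1)
  # out-of-range values at prediction time are clamped
  expect_equal(apply_minmax(c(5, 35), "age", p), c(0, 1))
  expect_error(apply_minmax(1, "nonexistent", p), "No fitted")
})

test_that("literal mode divides by the range and matches standard when min = 0", {
  d <- tiny_dataset()
  d$tooth_wear <- rep(c(0, 2, 4), length.out = nrow(d))
  lit <- fit_minmax(d, mode = "literal")
  expect_equal(apply_minmax(c(0, 2, 4), "tooth_wear", lit), c(0, 0.5, 1))

  # for min > 0 the two modes differ by the constant min / (max - min)
  d$age <- seq(40, 60, length.out = nrow(d))
  std <- fit_minmax(d)
  lit2 <- fit_minmax(d, mode = "literal")
  x <- seq(40, 60, by = 2.5)
  offset <- 40 / (60 - 40)
  expect_equal(
    apply_minmax(x, "age", lit2),
    apply_minmax(x, "age", std) + offset
  )
})

test_that("degenerate items normalize to zero instead of failing", {
  d <- tiny_dataset()
  d$periodontal_condition <- rep(2, nrow(d))
  for (mode in c("standard", "literal")) {
    p <- fit_minmax(d, mode = mode)
    expect_true(p$degenerate[p$column == "periodontal_condition"])
    expect_equal(apply_minmax(c(1, 2, 3), "periodontal_condition", p), c(0, 0, 0))
  }
})

test_that("standard normalization is monotone and order-preserving", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- tiny_dataset(seed = seed)
    p <- fit_minmax(d)
    x <- sort(runif(50, min(d$age), max(d$age)))
    y <- apply_minmax(x, "age", p)
    expect_true(all(y >= 0 & y <= 1))
    expect_true(all(diff(y) >= 0))
  }
})

test_that("the codebook walks items and options in printed order from code 1", {
  cb <- build_codebook()
  expect_identical(cb$code, 1:30)
  expect_identical(anyDuplicated(cb$code), 0L)
  look <- function(col, opt) cb$code[cb$column == col & cb$option == opt]
  expect_identical(look("sex", "Male"), 1L)
  expect_identical(look("sex", "Female"), 2L)
  expect_identical(look("tooth_position", "Mandibular premolar"), 18L)
  expect_identical(look("post_type", "Fiber post"), 22L)
  expect_identical(look("apical_surgery", "Root amputation"), 30L)
  # deterministic for a fixed schema
  expect_identical(as.data.frame(build_codebook()), as.data.frame(cb))
})

test_that("the codebook generalizes to user-supplied schemas", {
  sch <- default_schema()[c(1, 7, 11), ]
  sch$item_id <- c(1L, 2L, 3L)
  cb <- build_codebook(tsfnn:::new_schema(sch))
  expect_identical(cb$code, 1:8) # 2 sex options + 6 positions
  expect_identical(max(cb$code), sum(lengths(sch$options)))
})

test_that("categorical encoding yields one global code per item", {
  sch <- default_schema()
  cb <- build_codebook(sch)
  d <- tiny_dataset(4L, 4L)
  first_opts <- vapply(
    sch$options[1:10], function(o) o[1], character(1)
  )
  for (j in seq_along(first_opts)) d[[sch$column[j]]] <- first_opts[j]
  m <- encode_categorical(d, cb)
  expect_identical(unname(m[1, ]), c(1L, 3L, 5L, 7L, 9L, 11L, 13L, 19L, 24L, 28L))

  d$sex[1] <- "Female"
  d$post_type[1] <- "Fiber post"
  m2 <- encode_categorical(d, cb)
  expect_identical(unname(m2[1, c(1, 8)]), c(2L, 22L))
  expect_true(all(m2 >= 1 & m2 <= 30))

  d$sex[2] <- "Other"
  expect_error(encode_categorical(d, cb), "not in the codebook")
})

test_that("records differing in any categorical item get distinct code vectors", {
  cb <- build_codebook()
  d <- tiny_dataset(20L, 10L, seed = 3L)
  m <- encode_categorical(d, cb)
  cats <- d[, unique(cb$column)]
  keys <- apply(as.matrix(cats), 1, paste, collapse = "|")
  codes <- apply(m, 1, paste, collapse = "|")
  expect_identical(duplicated(keys), duplicated(codes))
})

test_that("preprocessing artifacts serialize to JSON and back", {
  d <- tiny_dataset()
  p <- fit_minmax(d, mode = "literal")
  f <- withr::local_tempfile(fileext = ".json")
  write_preprocess(p, f)
  p2 <- read_preprocess(f)
  expect_s3_class(p2, "minmax_params")
  expect_identical(attr(p2, "mode"), "literal")
  expect_equal(as.data.frame(p2), as.data.frame(p))

  cb <- build_codebook()
  f2 <- withr::local_tempfile(fileext = ".json")
  write_preprocess(cb, f2)
  expect_identical(as.data.frame(read_preprocess(f2)), as.data.frame(cb))
})
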