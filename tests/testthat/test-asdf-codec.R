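canonical <- c(1, 2, 3, 3, 2, 1, 0, -1, -2, -3)
forms <- c("FIX", "PAC", "SQZ", "DIF", "DIFDUP")

test_that("pseudo-digit classification follows the ASDF alphabet", {
  cases <- list(
    list("@", "SQZ", 0), list("I", "SQZ", 9), list("a", "SQZ", -1),
    list("i", "SQZ", -9), list("%", "DIF", 0), list("J", "DIF", 1),
    list("R", "DIF", 9), list("j", "DIF", -1), list("r", "DIF", -9),
    list("S", "DUP", 1), list("X", "DUP", 6), list("s", "DUP", 9),
    list("7", "ASCII_DIGIT", 7), list("+", "SIGN", 1),
    list("-", "SIGN", -1), list(" ", "SEPARATOR", 0),
    list(",", "SEPARATOR", 0))
  for (cs in cases) {
    got <- asdf_classify(cs[[1]])
    expect_identical(got$kind, cs[[2]], info = cs[[1]])
    expect_equal(got$digit, cs[[3]], info = cs[[1]])
  }
  expect_error(asdf_classify("~"), "invalid")
  expect_error(asdf_classify("!"), "invalid")
})

test_that("all printed encodings of the worked example decode to it", {
  strings <- c(FIX = "1 2 3 3 2 1 0 -1 -2 -3",
               PAC = "1+2+3+3+2+1+0-1-2-3",
               SQZ = "1BCCBA@abc",
               DIF = "1JJ%jjjjjj",
               DIFDUP = "1JT%jX")
  for (s in strings) {
    dl <- asdf_decode_line(s)
    expect_identical(dl$y, canonical, info = s)
    expect_identical(nrow(dl$errors), 0L, info = s)
  }
  expect_true(asdf_decode_line("1JT%jX")$ends_in_dif)
  expect_false(asdf_decode_line("1BCCBA@abc")$ends_in_dif)
  expect_identical(asdf_decode_line("42")$y, 42)
})

test_that("encoding reproduces the canonical strings in every form", {
  expect_identical(asdf_encode(canonical, "FIX"),
                   "1 2 3 3 2 1 0 -1 -2 -3")
  expect_identical(asdf_encode(canonical, "PAC"), "1+2+3+3+2+1+0-1-2-3")
  expect_identical(asdf_encode(canonical, "SQZ"), "1BCCBA@abc")
  expect_identical(asdf_encode(canonical, "DIF"), "1JJ%jjjjjj")
  expect_identical(asdf_encode(canonical, "DIFDUP"), "1JT%jX")
  for (f in forms) expect_identical(asdf_encode(5, f), "5")
  expect_error(asdf_encode(numeric(0), "FIX"), "non-empty")
  expect_error(asdf_encode(1.5, "FIX"), "integer")
})

test_that("multi-digit tokens extend the magnitude of their pseudo-digit", {
  expect_identical(asdf_decode_line("A23")$y, 123)       # SQZ +1, "23"
  expect_identical(asdf_decode_line("c4")$y, -34)        # SQZ -3, "4"
  expect_identical(asdf_decode_line("100J5")$y, c(100, 115))  # DIF +15
  expect_identical(asdf_decode_line("1jS2")$y, as.numeric(1:-11))  # DUP 12 total
  expect_identical(asdf_encode(c(100, 115), "DIF"), "100J5")
  expect_identical(asdf_encode(-34, "FIX"), "-34")
})

test_that("decoder annotates malformed content without aborting", {
  dl <- asdf_decode_line("J5")  # difference with nothing to differ from
  expect_identical(length(dl$y), 0L)
  expect_match(dl$errors$message, "no preceding value")
  dl <- asdf_decode_line("T3")  # duplicate of nothing
  expect_match(dl$errors$message, "no preceding item")
  dl <- asdf_decode_line("1~2")
  expect_match(dl$errors$message, "invalid character '~'")
  expect_identical(dl$y, c(1, 2))
  dl <- asdf_decode_line("1 ? 3")  # missing value convention
  expect_identical(dl$y, c(1, 0, 3))
  expect_match(dl$errors$message, "missing value")
  # DIF continuation across lines via prev_y
  expect_identical(asdf_decode_line("jj", prev_y = 5)$y, c(4, 3))
})

test_that("form detection is deterministic with FIX as the fallback", {
  expect_identical(asdf_detect_form("1JT%jX"), "DIFDUP")
  expect_identical(asdf_detect_form("1BCCBA@abc"), "SQZ")
  expect_identical(asdf_detect_form("1JJ%jjjjjj"), "DIF")
  expect_identical(asdf_detect_form("1+2+3-1"), "PAC")
  expect_identical(asdf_detect_form("1 2 3"), "FIX")
  expect_identical(asdf_detect_form("42"), "FIX")
})

test_that("decode(encode(seq)) is the identity for random sequences", {
  set.seed(101)
  fails <- 0L
  for (i in 1:300) {
    len <- sample(c(1:50, sample(51:500, 5)), 1)
    v <- as.numeric(sample.int(2000001L, len, replace = TRUE) - 1000001L)
    ref <- NULL
    for (f in forms) {
      d <- asdf_decode_line(asdf_encode(v, f))$y
      if (!identical(d, v)) fails <- fails + 1L
      if (is.null(ref)) ref <- d
      else if (!identical(ref, d)) fails <- fails + 1L  # cross-form
    }
  }
  expect_identical(fails, 0L)
})

test_that("long duplicate runs are chunked into valid DUP tokens", {
  v <- c(0, rep(7, 25), 3)  # 25 identical values -> runs of zero diffs
  for (f in forms) {
    expect_identical(asdf_decode_line(asdf_encode(v, f))$y, v, info = f)
  }
  enc <- asdf_encode(rep(4, 30), "DIFDUP")
  expect_identical(asdf_decode_line(enc)$y, rep(4, 30))
})

test_that("decode_line agrees with the independent oracle on random input", {
  set.seed(202)
  fails <- 0L
  for (i in 1:400) {
    v <- as.numeric(sample(-3:3, sample(1:6, 1), replace = TRUE))
    for (f in forms) {
      s <- asdf_encode(v, f)
      if (!identical(asdf_decode_line(s)$y, v)) fails <- fails + 1L
      if (!identical(oracle_decode_line(s), v)) fails <- fails + 1L
    }
  }
  expect_identical(fails, 0L)
})

test_that("table decoding verifies and consumes DIF check values", {
  axis <- axis_spec(firstx = 0, lastx = 9, npoints = 10)
  # single-line case reduces to decode_line
  dt <- asdf_decode_table("0, 1JJ%jjjjjj", axis = axis)
  expect_identical(dt$raw_y, canonical)
  expect_identical(nrow(dt$entries), 0L)
  # line 2 begins with a Y-check equal to line 1's final Y: consumed
  dt <- asdf_decode_table(c("0 1JJ%j", "4 2jjjjj"), axis = axis)
  expect_identical(dt$raw_y, canonical)
  expect_identical(nrow(dt$entries), 0L)
  expect_identical(dt$form, "DIF")
  # mismatched Y-check: one entry, decoding continues
  dt <- asdf_decode_table(c("0 1JJ%j", "4 3jjjjj"), axis = axis)
  expect_identical(nrow(dt$entries), 1L)
  expect_match(dt$entries$message, "Y-check mismatch")
  expect_identical(length(dt$raw_y), 10L)
  # X-check mismatch annotated
  dt <- asdf_decode_table(c("0 1 2 3", "7 4 5"), axis = axis)
  expect_match(dt$entries$message, "X-check mismatch")
  # empty table is a data-missing entry
  dt <- asdf_decode_table(character(0))
  expect_match(dt$entries$message, "no data lines")
})
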