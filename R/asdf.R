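# ASDF (ASCII Squeezed Difference Form) codec.
#
# JCAMP-DX tabular data may be stored in five forms: FIX (plain
# space-delimited integers), PAC (sign-delimited, no spaces), SQZ (the
# leading digit and sign of each value replaced by a pseudo-digit), DIF
# (successive differences as pseudo-digits) and DIFDUP (DIF with run-length
# compression of repeated items via DUP pseudo-digits).  The pseudo-digit
# alphabet:
#
#   SQZ  positive  @ A B C D E F G H I   (0..9)
#   SQZ  negative    a b c d e f g h i   (-1..-9)
#   DIF  positive  % J K L M N O P Q R   (0..9)
#   DIF  negative    j k l m n o p q r   (-1..-9)
#   DUP            S T U V W X Y Z s     (1..9)
#
# A DUP digit gives the TOTAL occurrence count of the immediately preceding
# value (FIX/SQZ context) or difference (DIF context).

.K_INVALID <- 0L
.K_DIGIT   <- 1L
.K_SQZ     <- 2L
.K_DIF     <- 3L
.K_DUP     <- 4L
.K_SIGN    <- 5L
.K_SEP     <- 6L
.K_MISSING <- 7L

.build_asdf_tables <- function() {
  kind <- rep(.K_INVALID, 127L)
  val <- rep(0L, 127L)
  ix <- function(ch) utf8ToInt(ch)
  for (d in 0:9) {
    kind[ix("0") + d] <- .K_DIGIT
    val[ix("0") + d] <- d
  }
  kind[ix("@")] <- .K_SQZ
  kind[ix("%")] <- .K_DIF
  for (d in 1:9) {
    kind[ix("A") + d - 1L] <- .K_SQZ; val[ix("A") + d - 1L] <- d
    kind[ix("a") + d - 1L] <- .K_SQZ; val[ix("a") + d - 1L] <- -d
    kind[ix("J") + d - 1L] <- .K_DIF; val[ix("J") + d - 1L] <- d
    kind[ix("j") + d - 1L] <- .K_DIF; val[ix("j") + d - 1L] <- -d
  }
  for (d in 1:8) {
    kind[ix("S") + d - 1L] <- .K_DUP; val[ix("S") + d - 1L] <- d
  }
  kind[ix("s")] <- .K_DUP; val[ix("s")] <- 9L
  kind[ix("+")] <- .K_SIGN; val[ix("+")] <- 1L
  kind[ix("-")] <- .K_SIGN; val[ix("-")] <- -1L
  for (ch in c(" ", ",", ";", "\t")) kind[ix(ch)] <- .K_SEP
  kind[ix("?")] <- .K_MISSING
  list(kind = kind, val = val)
}

.asdf_tab <- .build_asdf_tables()

.asdf_kind_names <- c("ASCII_DIGIT", "SQZ", "DIF", "DUP", "SIGN", "SEPARATOR",
                      "MISSING")

#' Classify one ASDF character
#'
#' Maps a single character to its pseudo-digit class and signed digit value:
#' `@`..`I` are positive SQZ digits 0..9, `a`..`i` negative SQZ digits,
#' `%`,`J`..`R` positive DIF digits, `j`..`r` negative DIF digits,
#' `S`..`Z`,`s` DUP counts 1..9, `0`-`9` plain ASCII digits, and
#' `+ - space , ;` signs/separators.
#'
#' @param c A single character.
#' @return A list with elements `kind` (one of `"ASCII_DIGIT"`, `"SQZ"`,
#'   `"DIF"`, `"DUP"`, `"SIGN"`, `"SEPARATOR"`, `"MISSING"`) and `digit`
#'   (signed integer value; the sign multiplier for `SIGN` tokens).
#' @examples
#' asdf_classify("@")  # SQZ 0
#' asdf_classify("a")  # SQZ -1
#' asdf_classify("X")  # DUP 6
#' @export
asdf_classify <- function(c) {
  if (!is.character(c) || length(c) != 1L || nchar(c) != 1L)
    stop("`c` must be a single character", call. = FALSE)
  cc <- utf8ToInt(c)
  k <- if (cc >= 1L && cc <= 126L) .asdf_tab$kind[cc] else .K_INVALID
  if (k == .K_INVALID)
    stop(sprintf("invalid ASDF character '%s'", c), call. = FALSE)
  list(kind = .asdf_kind_names[k], digit = .asdf_tab$val[cc])
}

#' Decode one ASDF data line
#'
#' Decodes the Y body of a JCAMP data line in any of the ASDF forms.  A SQZ
#' pseudo-digit (or a plain/signed number) starts a new value; a DIF
#' pseudo-digit starts a difference added to the previous value; a DUP
#' pseudo-digit repeats the preceding value-or-difference so that its total
#' occurrence count equals the DUP value.  Trailing ASCII digits extend the
#' magnitude of whichever token they follow.
#'
#' Malformed content (invalid characters, a difference with no previous
#' value, a duplicate with no preceding item, `?` missing-value markers) is
#' recorded in the returned `errors` table rather than raised, so a whole
#' table can be decoded and annotated in one pass.
#'
#' @param line Character scalar, the Y portion of a data line.
#' @param prev_y Optional previous Y value, needed when the line may begin
#'   in DIF context (a difference as its first token).
#' @return A list with `y` (numeric vector of decoded values),
#'   `ends_in_dif` (was the last logical item a difference?),
#'   `starts_with_value` (was the first decoded item a plain value, as
#'   opposed to a difference?), and `errors` (data frame with `position`
#'   and `message`).
#' @examples
#' asdf_decode_line("1BCCBA@abc")$y  # 1 2 3 3 2 1 0 -1 -2 -3
#' asdf_decode_line("1JT%jX")$y      # same sequence, DIFDUP form
#' @export
asdf_decode_line <- function(line, prev_y = NULL) {
  stopifnot(is.character(line), length(line) == 1L)
  codes <- utf8ToInt(line)
  ktab <- .asdf_tab$kind
  vtab <- .asdf_tab$val
  n <- length(codes)
  y <- numeric(n + 1L)
  ny <- 0L
  ep <- integer(0)
  em <- character(0)
  pk <- 0L        # pending token kind: 0 none, 1 value, 3 dif, 4 dup
  psign <- 1
  pmag <- 0
  pcontent <- FALSE
  last_is_dif <- FALSE
  last_dif <- 0
  last_y <- if (is.null(prev_y)) NA_real_ else as.numeric(prev_y)
  starts_with_value <- NA
  first_done <- FALSE

  grow <- function(k) {
    if (ny + k > length(y)) y <<- c(y, numeric(max(k, length(y))))
  }
  err <- function(pos, msg) {
    ep <<- c(ep, pos)
    em <<- c(em, msg)
  }
  flush <- function(pos) {
    if (pk == 1L) {
      if (!pcontent) {
        err(pos, "dangling sign with no digits")
      } else {
        v <- psign * pmag
        grow(1L)
        ny <<- ny + 1L
        y[ny] <<- v
        last_y <<- v
        last_is_dif <<- FALSE
        if (!first_done) {
          starts_with_value <<- TRUE
          first_done <<- TRUE
        }
      }
    } else if (pk == 3L) {
      if (is.na(last_y)) {
        err(pos, "difference with no preceding value")
      } else {
        d <- psign * pmag
        grow(1L)
        ny <<- ny + 1L
        last_y <<- last_y + d
        y[ny] <<- last_y
        last_is_dif <<- TRUE
        last_dif <<- d
      }
      if (!first_done) {
        starts_with_value <<- FALSE
        first_done <<- TRUE
      }
    } else if (pk == 4L) {
      cnt <- pmag
      if (ny == 0L) {
        err(pos, "duplicate count with no preceding item")
      } else if (cnt < 1) {
        err(pos, "duplicate count must be at least 1")
      } else if (cnt > 1) {
        reps <- cnt - 1L
        grow(reps)
        if (last_is_dif) {
          for (r in seq_len(reps)) {
            last_y <<- last_y + last_dif
            ny <<- ny + 1L
            y[ny] <<- last_y
          }
        } else {
          for (r in seq_len(reps)) {
            ny <<- ny + 1L
            y[ny] <<- last_y
          }
        }
      }
    }
    pk <<- 0L
    pcontent <<- FALSE
  }

  for (i in seq_len(n)) {
    cc <- codes[i]
    k <- if (cc >= 1L && cc <= 126L) ktab[cc] else .K_INVALID
    if (k == .K_DIGIT) {
      if (pk == 0L) {
        pk <- 1L
        psign <- 1
        pmag <- vtab[cc]
      } else {
        pmag <- pmag * 10 + vtab[cc]
      }
      pcontent <- TRUE
    } else if (k == .K_SEP) {
      if (pk != 0L) flush(i)
    } else if (k == .K_SQZ) {
      if (pk != 0L) flush(i)
      pk <- 1L
      v <- vtab[cc]
      psign <- if (v < 0L) -1 else 1
      pmag <- abs(v)
      pcontent <- TRUE
    } else if (k == .K_DIF) {
      if (pk != 0L) flush(i)
      pk <- 3L
      v <- vtab[cc]
      psign <- if (v < 0L) -1 else 1
      pmag <- abs(v)
      pcontent <- TRUE
    } else if (k == .K_DUP) {
      if (pk != 0L) flush(i)
      pk <- 4L
      psign <- 1
      pmag <- vtab[cc]
      pcontent <- TRUE
    } else if (k == .K_SIGN) {
      if (pk != 0L) flush(i)
      pk <- 1L
      psign <- vtab[cc]
      pmag <- 0
      pcontent <- FALSE
    } else if (k == .K_MISSING) {
      if (pk != 0L) flush(i)
      err(i, "missing value '?' replaced with 0")
      pk <- 1L
      psign <- 1
      pmag <- 0
      pcontent <- TRUE
      flush(i)
    } else {
      if (pk != 0L) flush(i)
      err(i, sprintf("invalid character '%s'", intToUtf8(cc)))
    }
  }
  if (pk != 0L) flush(n)

  errors <- if (length(ep)) {
    data.frame(position = ep, message = em, stringsAsFactors = FALSE)
  } else {
    .no_line_errors
  }
  list(y = y[seq_len(ny)],
       ends_in_dif = last_is_dif && ny > 0L,
       starts_with_value = starts_with_value,
       errors = errors)
}

.no_line_errors <- data.frame(position = integer(0), message = character(0),
                              stringsAsFactors = FALSE)

#' Detect the ASDF form of a data-line body
#'
#' Deterministic classification of a tabular Y body: DIFDUP when both DUP
#' and DIF pseudo-digits occur, DIF when a DIF pseudo-digit occurs, SQZ when
#' a SQZ pseudo-digit occurs, PAC when signs act as delimiters between
#' digits without spaces, FIX otherwise (the fallback).
#'
#' @param y_body Non-empty character scalar.
#' @return One of `"FIX"`, `"PAC"`, `"SQZ"`, `"DIF"`, `"DIFDUP"`.
#' @export
asdf_detect_form <- function(y_body) {
  stopifnot(is.character(y_body), length(y_body) == 1L, nzchar(y_body))
  has_dup <- grepl("[S-Zs]", y_body)
  has_dif <- grepl("[%J-Rj-r]", y_body)
  has_sqz <- grepl("[@A-Ia-i]", y_body)
  if (has_dup && has_dif) return("DIFDUP")
  if (has_dif) return("DIF")
  if (has_sqz) return("SQZ")
  if (grepl("[0-9][+-][0-9]", y_body)) return("PAC")
  "FIX"
}

.int_str <- function(v) sprintf("%.0f", v)

.sqz_pos_chr <- c("@", LETTERS[1:9])
.sqz_neg_chr <- letters[1:9]
.dif_pos_chr <- c("%", LETTERS[10:18])
.dif_neg_chr <- letters[10:18]
.dup_chr <- c(LETTERS[19:26], "s")

.sqz_tok <- function(v) {
  s <- .int_str(abs(v))
  d <- as.integer(substr(s, 1L, 1L))
  ch <- if (v < 0) .sqz_neg_chr[d] else .sqz_pos_chr[d + 1L]
  paste0(ch, substr(s, 2L, nchar(s)))
}

.dif_tok <- function(v) {
  s <- .int_str(abs(v))
  d <- as.integer(substr(s, 1L, 1L))
  ch <- if (v < 0) .dif_neg_chr[d] else .dif_pos_chr[d + 1L]
  paste0(ch, substr(s, 2L, nchar(s)))
}

# DIF/DIFDUP item stream for a difference vector: list of units, each a
# list(str = token text, npts = number of points the unit emits).  With
# dup = TRUE runs of >= 2 identical differences are compressed; runs longer
# than 9 emit additional DUP tokens (a DUP digit encodes a total count of
# at most 9).
.dif_units <- function(d, dup) {
  if (length(d) == 0L) return(list())
  if (!dup) {
    return(lapply(d, function(v) list(str = .dif_tok(v), npts = 1L)))
  }
  r <- rle(d)
  out <- vector("list", 0L)
  for (k in seq_along(r$lengths)) {
    tok <- .dif_tok(r$values[k])
    len <- r$lengths[k]
    while (len > 0L) {
      chunk <- min(len, 9L)
      str <- if (chunk > 1L) paste0(tok, .dup_chr[chunk]) else tok
      out[[length(out) + 1L]] <- list(str = str, npts = as.integer(chunk))
      len <- len - chunk
    }
  }
  out
}

#' Encode an integer sequence in an ASDF form
#'
#' The inverse of [asdf_decode_line()].  FIX emits single-space-delimited
#' ASCII integers; PAC delimits values only by their sign characters; SQZ
#' replaces the leading digit and sign of every value after the first by a
#' SQZ pseudo-digit; DIF emits the first value plainly and subsequent values
#' as pseudo-digit differences; DIFDUP additionally compresses runs of two
#' or more identical consecutive differences with a DUP digit (total-count
#' semantics, capped at 9 per DUP token).
#'
#' @param y Non-empty vector of integer-valued numbers.
#' @param form One of `"FIX"`, `"PAC"`, `"SQZ"`, `"DIF"`, `"DIFDUP"`.
#' @return Character scalar, the encoded (unwrapped) line body.
#' @examples
#' v <- c(1, 2, 3, 3, 2, 1, 0, -1, -2, -3)
#' asdf_encode(v, "SQZ")     # "1BCCBA@abc"
#' asdf_encode(v, "DIFDUP")  # "1JT%jX"
#' @export
asdf_encode <- function(y, form = c("FIX", "PAC", "SQZ", "DIF", "DIFDUP")) {
  form <- match.arg(form)
  if (length(y) < 1L) stop("`y` must be non-empty", call. = FALSE)
  if (!is.numeric(y) || any(!is.finite(y)) || any(y != round(y)))
    stop("`y` must contain finite integer values", call. = FALSE)
  y <- round(y)
  if (length(y) == 1L) return(.int_str(y))
  first <- .int_str(y[1])
  rest <- y[-1]
  switch(form,
    FIX = paste(vapply(y, .int_str, character(1)), collapse = " "),
    PAC = paste0(first, paste(vapply(rest, function(v) {
      if (v < 0) .int_str(v) else paste0("+", .int_str(v))
    }, character(1)), collapse = "")),
    SQZ = paste0(first,
                 paste(vapply(rest, .sqz_tok, character(1)), collapse = "")),
    DIF = paste0(first,
                 paste(vapply(diff(y), .dif_tok, character(1)),
                       collapse = "")),
    DIFDUP = paste0(first, paste(
      vapply(.dif_units(diff(y), dup = TRUE), `[[`, character(1), "str"),
      collapse = "")))
}

#' Decode a multi-line ASDF table
#'
#' Decodes the data lines of an `##XYDATA=` table.  Each line begins with an
#' X check value followed by the Y body.  When a line continues in DIF mode,
#' the first Y of the next line is a duplicate Y-check value: it is compared
#' to the last decoded Y and dropped.  X check values are compared to the
#' expected grid position (within half an X step).  Every mismatch becomes a
#' report entry; decoding never aborts.
#'
#' @param lines Character vector of data lines (the variable list line,
#'   e.g. `"(X++(Y..Y))"`, must already be removed).
#' @param axis Optional [axis_spec()] used for X-check verification.
#' @return A list with `raw_y` (decoded integer Y sequence), `form`
#'   (detected [asdf_detect_form()] aggregated over lines) and `entries`
#'   (data frame of `line`, `message` report entries).
#' @export
asdf_decode_table <- function(lines, axis = NULL) {
  stopifnot(is.character(lines))
  raw_y <- numeric(0)
  lnos <- integer(0)
  msgs <- character(0)
  record <- function(li, msg) {
    lnos <<- c(lnos, li)
    msgs <<- c(msgs, msg)
  }
  ends_dif <- FALSE
  forms <- character(0)
  nonempty <- FALSE
  for (li in seq_along(lines)) {
    ln <- trimws(lines[[li]])
    if (!nzchar(ln)) next
    nonempty <- TRUE
    m <- regexpr("^[+-]?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", ln)
    if (m == 1L) {
      xlen <- attr(m, "match.length")
      x_tok <- as.numeric(substr(ln, 1L, xlen))
      body <- substr(ln, xlen + 1L, nchar(ln))
    } else {
      x_tok <- NA_real_
      body <- ln
      record(li, "data line lacks a leading X value")
    }
    if (!nzchar(trimws(body))) {
      # a bare X value line (e.g. a terminal check) contributes nothing
      next
    }
    prev <- if (length(raw_y)) raw_y[length(raw_y)] else NULL
    dl <- asdf_decode_line(body, prev_y = prev)
    if (nrow(dl$errors)) {
      for (r in seq_len(nrow(dl$errors))) {
        record(li, sprintf("position %d: %s",
                           dl$errors$position[r], dl$errors$message[r]))
      }
    }
    ys <- dl$y
    consumed_check <- FALSE
    if (ends_dif && length(raw_y) && length(ys) &&
        isTRUE(dl$starts_with_value)) {
      if (ys[1] != raw_y[length(raw_y)]) {
        record(li, sprintf(
          "Y-check mismatch: expected %s, found %s",
          format(raw_y[length(raw_y)]), format(ys[1])))
      }
      ys <- ys[-1]
      consumed_check <- TRUE
    }
    if (!is.na(x_tok) && !is.null(axis)) {
      expected_idx <- length(raw_y) - if (consumed_check) 1L else 0L
      expected_x <- axis$firstx + expected_idx * axis$deltax
      tol <- max(abs(axis$deltax) / 2, 1e-6 * max(1, abs(expected_x)))
      if (abs(x_tok - expected_x) > tol) {
        record(li, sprintf(
          "X-check mismatch: expected %s at point %d, found %s",
          format(expected_x), expected_idx + 1L, format(x_tok)))
      }
    }
    raw_y <- c(raw_y, ys)
    ends_dif <- dl$ends_in_dif
    forms <- c(forms, asdf_detect_form(body))
  }
  if (!nonempty) record(0L, "data table contains no data lines")
  ranking <- c(FIX = 1L, PAC = 2L, SQZ = 3L, DIF = 4L, DIFDUP = 5L)
  form <- if (length(forms)) names(ranking)[max(ranking[forms])] else "UNKNOWN"
  list(raw_y = raw_y, form = form,
       entries = data.frame(line = lnos, message = msgs,
                            stringsAsFactors = FALSE))
}
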