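# Independent brute-force ASDF decoder used as an oracle.  Written
# separately from the package implementation: named-vector lookups and
# string digit accumulation instead of integer code tables, so a shared
# bug is unlikely.  Only handles well-formed encodable strings.

.oracle_sqz <- c(
  "@" = 0, setNames(1:9, strsplit("ABCDEFGHI", "")[[1]]),
  setNames(-(1:9), strsplit("abcdefghi", "")[[1]]))
.oracle_dif <- c(
  "%" = 0, setNames(1:9, strsplit("JKLMNOPQR", "")[[1]]),
  setNames(-(1:9), strsplit("jklmnopqr", "")[[1]]))
.oracle_dup <- setNames(1:9, strsplit("STUVWXYZs", "")[[1]])

oracle_decode_line <- function(s, prev_y = NULL) {
  chars <- strsplit(s, "")[[1]]
  out <- numeric(0)
  pending_kind <- NULL   # "val" | "dif" | "dup"
  pending_sign <- 1
  pending_digits <- ""   # decimal magnitude as text
  last_item <- NULL      # list(kind = "val"/"dif", value = )

  last_y <- function() {
    if (length(out)) out[length(out)] else prev_y
  }
  settle <- function() {
    if (is.null(pending_kind)) return(invisible())
    mag <- as.numeric(pending_digits)
    v <- pending_sign * mag
    if (pending_kind == "val") {
      out <<- c(out, v)
      last_item <<- list(kind = "val", value = v)
    } else if (pending_kind == "dif") {
      out <<- c(out, last_y() + v)
      last_item <<- list(kind = "dif", value = v)
    } else {
      reps <- mag - 1
      if (reps > 0) {
        if (last_item$kind == "dif") {
          for (r in seq_len(reps)) out <<- c(out, last_y() + last_item$value)
        } else {
          out <<- c(out, rep(last_item$value, reps))
        }
      }
    }
    pending_kind <<- NULL
    pending_sign <<- 1
    pending_digits <<- ""
  }

  for (ch in chars) {
    if (ch %in% c(" ", ",", ";")) {
      settle()
    } else if (ch %in% c("+", "-")) {
      settle()
      pending_kind <- "val"
      pending_sign <- if (ch == "-") -1 else 1
      pending_digits <- "0"
    } else if (grepl("^[0-9]$", ch)) {
      if (is.null(pending_kind)) {
        pending_kind <- "val"
        pending_sign <- 1
        pending_digits <- ch
      } else {
        pending_digits <- paste0(pending_digits, ch)
      }
    } else if (ch %in% names(.oracle_sqz)) {
      settle()
      d <- .oracle_sqz[[ch]]
      pending_kind <- "val"
      pending_sign <- if (d < 0) -1 else 1
      pending_digits <- as.character(abs(d))
    } else if (ch %in% names(.oracle_dif)) {
      settle()
      d <- .oracle_dif[[ch]]
      pending_kind <- "dif"
      pending_sign <- if (d < 0) -1 else 1
      pending_digits <- as.character(abs(d))
    } else if (ch %in% names(.oracle_dup)) {
      settle()
      pending_kind <- "dup"
      pending_sign <- 1
      pending_digits <- as.character(.oracle_dup[[ch]])
    } else {
      stop(sprintf("oracle: unexpected character '%s'", ch))
    }
  }
  settle()
  out
}

# Vectorized encodings of an exhaustive sequence grid (one sequence per
# matrix row, small values) for the oracle-equivalence sweep.  FIX, PAC,
# SQZ and DIF are built columnwise; DIFDUP falls back to the package
# encoder per row.
encode_grid <- function(m) {
  stopifnot(is.matrix(m))
  len <- ncol(m)
  sqz_tok <- setNames(
    c("@", LETTERS[1:9], letters[1:9]),
    as.character(c(0:9, -(1:9))))
  dif_tok <- setNames(
    c("%", LETTERS[10:18], letters[10:18]),
    as.character(c(0:9, -(1:9))))
  first <- as.character(m[, 1])
  fix <- first
  pac <- first
  sqz <- first
  if (len > 1) {
    for (j in 2:len) {
      col <- m[, j]
      fix <- paste(fix, col)
      pac <- paste0(pac, ifelse(col < 0, col, paste0("+", col)))
      sqz <- paste0(sqz, sqz_tok[as.character(col)])
    }
  }
  dif <- first
  if (len > 1) {
    for (j in 2:len) {
      d <- m[, j] - m[, j - 1]
      dif <- paste0(dif, dif_tok[as.character(d)])
    }
  }
  difdup <- vapply(seq_len(nrow(m)), function(r) {
    specdx::asdf_encode(as.numeric(m[r, ]), "DIFDUP")
  }, character(1))
  list(FIX = fix, PAC = pac, SQZ = sqz, DIF = dif, DIFDUP = difdup)
}
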