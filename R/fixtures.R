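# Seeded generator of realistic synthetic spectra, serialized as JCAMP-DX
# in any ASDF form, plus a controlled corruptor.  Every other module is
# testable against these with no downloads.
#
# Continuous techniques are sums of Gaussian peaks on a uniform X grid plus
# Gaussian noise, quantized to integers through YFACTOR (instrument writers
# store factor-scaled integers, which is exactly what the decompressor must
# invert).  MS is a stick spectrum written as a PEAKTABLE.  All randomness
# flows from the integer seed through R's default Mersenne-Twister
# generator, so a spec generates byte-identical text on every platform.

#' Describe a synthetic spectrum fixture
#'
#' Defaults are technique-typical: UV/Vis absorbance on 200-800 nm (301
#' points, 3 peaks of ~30 nm width, YFACTOR 1e-4), IR transmittance on
#' 4000-400 1/cm (a decreasing grid; 441 points, 8 bands, YFACTOR 0.01) and
#' MS stick spectra on m/z 15-350 (12 peaks, integer intensities, base peak
#' 9999).
#'
#' @param technique One of `"UVVIS"`, `"IR"`, `"MS"`.
#' @param n_points Grid size for continuous techniques (>= 2).
#' @param x_range Numeric `(low, high)` in technique units; for IR the grid
#'   runs high-to-low.
#' @param n_peaks Number of Gaussian peaks / MS sticks.
#' @param peak_width Gaussian sigma in X units.
#' @param noise_sd Noise standard deviation in physical Y units.
#' @param yfactor Y quantization factor (stored integers = y / yfactor).
#' @param form ASDF form for the written table (MS always writes a
#'   PEAKTABLE regardless).
#' @param seed Integer seed; same spec, same bytes.
#' @return A `jdx_fixture_spec`.
#' @export
fixture_spec <- function(technique = c("UVVIS", "IR", "MS"),
                         n_points = NULL, x_range = NULL, n_peaks = NULL,
                         peak_width = NULL, noise_sd = NULL, yfactor = NULL,
                         form = "FIX", seed = 1L) {
  technique <- match.arg(technique)
  def <- switch(technique,
    UVVIS = list(n_points = 301L, x_range = c(200, 800), n_peaks = 3L,
                 peak_width = 30, noise_sd = 0.002, yfactor = 1e-4),
    IR = list(n_points = 441L, x_range = c(4000, 400), n_peaks = 8L,
              peak_width = 40, noise_sd = 0.15, yfactor = 0.01),
    MS = list(n_points = 12L, x_range = c(15, 350), n_peaks = 12L,
              peak_width = 0, noise_sd = 0, yfactor = 1))
  spec <- list(technique = technique,
               n_points = as.integer(n_points %||% def$n_points),
               x_range = x_range %||% def$x_range,
               n_peaks = as.integer(n_peaks %||% def$n_peaks),
               peak_width = peak_width %||% def$peak_width,
               noise_sd = noise_sd %||% def$noise_sd,
               yfactor = yfactor %||% def$yfactor,
               form = match.arg(form, c("FIX", "PAC", "SQZ", "DIF",
                                        "DIFDUP")),
               seed = as.integer(seed))
  lo <- min(spec$x_range)
  hi <- max(spec$x_range)
  if (!(lo < hi)) stop("x_range must span a non-empty interval",
                       call. = FALSE)
  if (technique != "MS" && spec$n_points < 2L)
    stop("continuous techniques need n_points >= 2", call. = FALSE)
  if (spec$n_peaks < 1L) stop("n_peaks must be positive", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative",
                              call. = FALSE)
  if (spec$yfactor <= 0) stop("yfactor must be positive", call. = FALSE)
  structure(spec, class = "jdx_fixture_spec")
}

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a synthetic spectrum and its JCAMP-DX text
#'
#' Fully deterministic given the spec's seed.  Continuous techniques put
#' `n_peaks` Gaussian peaks at uniformly drawn centers on the grid
#' (absorbance peaks for UV/Vis; transmittance dips from a 100 % baseline
#' for IR), add Gaussian noise, quantize to integers through `yfactor` and
#' serialize with [write_jcamp()] in the requested form.  MS draws distinct
#' integer m/z values and intensities with a base peak of 9999 and writes a
#' PEAKTABLE.  The generated text carries all labels the validator
#' requires.
#'
#' @param spec A [fixture_spec()].
#' @param id Optional 9-digit identifier for the parsed record.
#' @return A list with `record` (the parsed `jdx_spectrum`), `text` (the
#'   JCAMP-DX file content) and `spec`.
#' @export
generate_fixture <- function(spec, id = NULL) {
  stopifnot(inherits(spec, "jdx_fixture_spec"))
  .with_seed(spec$seed, {
    if (spec$technique == "MS") .generate_ms(spec, id)
    else .generate_continuous(spec, id)
  })
}

.fixture_header <- function(spec, firstx, lastx, deltax, npoints, firsty) {
  datatype <- switch(spec$technique, UVVIS = "UV/VIS SPECTRUM",
                     IR = "INFRARED SPECTRUM", MS = "MASS SPECTRUM")
  xunits <- switch(spec$technique, UVVIS = "NANOMETERS", IR = "1/CM",
                   MS = "M/Z")
  yunits <- switch(spec$technique, UVVIS = "ABSORBANCE",
                   IR = "TRANSMITTANCE", MS = "RELATIVE ABUNDANCE")
  c(sprintf("##TITLE=Synthetic %s spectrum (seed %d)", spec$technique,
            spec$seed),
    "##JCAMP-DX=4.24",
    sprintf("##DATA TYPE=%s", datatype),
    "##ORIGIN=specdx synthetic fixture generator",
    "##OWNER=public domain",
    sprintf("##XUNITS=%s", xunits),
    sprintf("##YUNITS=%s", yunits),
    "##XFACTOR=1",
    sprintf("##YFACTOR=%s", format(spec$yfactor, scientific = FALSE,
                                   trim = TRUE, digits = 10)),
    sprintf("##FIRSTX=%s", .fmt_x(firstx)),
    sprintf("##LASTX=%s", .fmt_x(lastx)),
    sprintf("##DELTAX=%s", .fmt_x(deltax)),
    sprintf("##NPOINTS=%d", npoints),
    sprintf("##FIRSTY=%s", format(firsty, scientific = FALSE, trim = TRUE,
                                  digits = 10)))
}

.generate_continuous <- function(spec, id) {
  n <- spec$n_points
  firstx <- spec$x_range[1]
  lastx <- spec$x_range[2]
  deltax <- (lastx - firstx) / (n - 1)
  x <- firstx + (seq_len(n) - 1) * deltax
  centers <- stats::runif(spec$n_peaks, min(spec$x_range),
                          max(spec$x_range))
  widths <- spec$peak_width * stats::runif(spec$n_peaks, 0.6, 1.4)
  amps <- stats::runif(spec$n_peaks, 0.2, 1)
  peak_sum <- rowSums(vapply(seq_len(spec$n_peaks), function(k) {
    amps[k] * exp(-0.5 * ((x - centers[k]) / widths[k])^2)
  }, numeric(n)))
  if (spec$technique == "IR") {
    y <- 100 - 90 * peak_sum / max(max(peak_sum), 1)
    y <- y + stats::rnorm(n, 0, spec$noise_sd)
    y <- pmin(pmax(y, 0), 100)
  } else {
    y <- peak_sum + stats::rnorm(n, 0, spec$noise_sd)
    y <- pmax(y, 0)
  }
  raw_y <- round(y / spec$yfactor)
  header <- .fixture_header(spec, firstx, lastx, deltax, n,
                            raw_y[1] * spec$yfactor)
  axis <- axis_spec(firstx = firstx, lastx = lastx, npoints = n,
                    yfactor = spec$yfactor)
  body <- .encode_xydata_lines(raw_y, axis, spec$form, 78L)
  text <- paste0(paste(c(header, "##XYDATA=(X++(Y..Y))", body, "##END="),
                       collapse = "\n"), "\n")
  list(record = jdx_parse(text, id = id,
                          source_name = sprintf("synthetic-%s-seed%d.jdx",
                                                tolower(spec$technique),
                                                spec$seed)),
       text = text, spec = spec)
}

.generate_ms <- function(spec, id) {
  lo <- ceiling(min(spec$x_range))
  hi <- floor(max(spec$x_range))
  mz <- sort(sample(seq(lo, hi), spec$n_peaks))
  intens <- sample(50:9999, spec$n_peaks, replace = TRUE)
  intens[sample(spec$n_peaks, 1)] <- 9999L  # base peak convention
  header <- .fixture_header(spec, firstx = mz[1], lastx = mz[length(mz)],
                            deltax = if (spec$n_peaks > 1)
                              (mz[length(mz)] - mz[1]) / (spec$n_peaks - 1)
                            else 0,
                            npoints = spec$n_peaks, firsty = intens[1])
  pairs <- .encode_peaktable_lines(mz, intens, 78L)
  text <- paste0(paste(c(header, "##PEAKTABLE=(XY..XY)", pairs, "##END="),
                       collapse = "\n"), "\n")
  list(record = jdx_parse(text, id = id,
                          source_name = sprintf("synthetic-ms-seed%d.jdx",
                                                spec$seed)),
       text = text, spec = spec)
}

#' Apply one seeded corruption to JCAMP-DX text
#'
#' Exercises the error-annotation contract of the pipeline: `BAD_CHAR`
#' inserts an invalid character into a data line, `TRUNCATE_TABLE` drops
#' the last data line, `DROP_LDR` removes one required header record, and
#' `BAD_YCHECK` perturbs the Y-check value at the start of a DIF-mode
#' continuation line (requires a multi-line DIF/DIFDUP table).  The output
#' always differs from the input.
#'
#' @param jcamp_text Parseable JCAMP-DX text.
#' @param mode One of `"BAD_CHAR"`, `"TRUNCATE_TABLE"`, `"DROP_LDR"`,
#'   `"BAD_YCHECK"`.
#' @param seed Integer seed controlling the corruption site.
#' @return The corrupted text.
#' @export
corrupt_fixture <- function(jcamp_text,
                            mode = c("BAD_CHAR", "TRUNCATE_TABLE",
                                     "DROP_LDR", "BAD_YCHECK"),
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.character(jcamp_text), length(jcamp_text) == 1L)
  lines <- strsplit(jcamp_text, "\n", fixed = TRUE)[[1]]
  tab_start <- grep("^##(XYDATA|XY DATA|PEAKTABLE|PEAK TABLE)", lines)
  if (!length(tab_start))
    stop("input has no data table to corrupt", call. = FALSE)
  tab_start <- tab_start[1]
  end_line <- grep("^##END", lines)
  end_line <- if (length(end_line)) end_line[1] else length(lines) + 1L
  data_lines <- seq(tab_start + 1L, end_line - 1L)
  data_lines <- data_lines[nzchar(trimws(lines[data_lines]))]
  .with_seed(seed, {
    out <- switch(mode,
      BAD_CHAR = {
        li <- data_lines[sample(length(data_lines), 1)]
        ln <- lines[li]
        pos <- sample(nchar(ln), 1)
        lines[li] <- paste0(substr(ln, 1, pos), "~",
                            substr(ln, pos + 1L, nchar(ln)))
        lines
      },
      TRUNCATE_TABLE = {
        if (length(data_lines) < 2L)
          stop("table too short to truncate", call. = FALSE)
        lines[-data_lines[length(data_lines)]]
      },
      DROP_LDR = {
        droppable <- grep("^##(NPOINTS|XUNITS|YUNITS|FIRSTX|LASTX)=", lines)
        if (!length(droppable))
          stop("no droppable required LDR found", call. = FALSE)
        lines[-droppable[sample(length(droppable), 1)]]
      },
      BAD_YCHECK = {
        cont <- data_lines[-1]
        cont <- cont[grepl("[%J-Rj-r]", lines[cont])]
        if (!length(cont))
          stop("BAD_YCHECK requires a multi-line DIF-mode table",
               call. = FALSE)
        li <- cont[sample(length(cont), 1)]
        # bump the Y-check (first value after the X token) by one
        m <- regexec("^(\\s*[+-]?[0-9.]+\\s+)([+-]?[0-9]+)", lines[li])
        g <- regmatches(lines[li], m)[[1]]
        if (length(g) != 3L)
          stop("could not locate Y-check on DIF continuation line",
               call. = FALSE)
        bumped <- .int_str(as.numeric(g[3]) + 1)
        lines[li] <- paste0(g[2], bumped,
                            substr(lines[li], nchar(g[2]) + nchar(g[3]) + 1L,
                                   nchar(lines[li])))
        lines
      })
    paste0(paste(out, collapse = "\n"), "\n")
  })
}
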