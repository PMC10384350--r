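# Centroided spectrum container.

#' Construct an MS/MS spectrum
#'
#' A centroided peak list with precursor information. Peaks are sorted by
#' m/z; peaks with identical m/z are merged by summing intensities, so the
#' stored m/z axis is strictly increasing.
#'
#' @param mz,intensity Numeric vectors of equal length; intensities must
#'   be finite and non-negative.
#' @param precursor_mz Precursor m/z in Da.
#' @param charge Positive charge count (the polarity is carried
#'   separately).
#' @param polarity `"negative"` or `"positive"`.
#' @param rt Retention time in minutes (`NA` if unknown).
#' @param id Spectrum identifier.
#' @param peak_charge Optional integer vector of per-peak charge states
#'   (kept by the in-silico simulator; not representable in MGF).
#' @param metadata Named list of additional fields (e.g. `NAME`,
#'   collision-energy level).
#' @return An object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(mz, intensity, precursor_mz = NA_real_, charge = 1L,
                        polarity = "negative", rt = NA_real_,
                        id = "spectrum", peak_charge = NULL,
                        metadata = list()) {
  stopifnot(length(mz) == length(intensity))
  if (length(intensity) > 0 && (any(!is.finite(intensity)) || any(intensity < 0))) {
    abort("Intensities must be finite and non-negative.")
  }
  peaks <- tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
  if (!is.null(peak_charge)) peaks$peak_charge <- as.integer(peak_charge)
  if (nrow(peaks) > 0) {
    peaks <- peaks |>
      group_by(.data$mz) |>
      summarise(
        intensity = sum(.data$intensity),
        across(any_of("peak_charge"), dplyr::first),
        .groups = "drop"
      ) |>
      arrange(.data$mz)
  }
  structure(
    list(
      id = id, peaks = peaks, precursor_mz = as.numeric(precursor_mz),
      charge = as.integer(charge), polarity = polarity,
      rt = as.numeric(rt), metadata = metadata
    ),
    class = "ms_spectrum"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms_spectrum> %s: %d peaks, precursor m/z %.4f (%d%s)%s\n",
    x$id, nrow(x$peaks), x$precursor_mz, x$charge,
    if (identical(x$polarity, "negative")) "-" else "+",
    if (is.na(x$rt)) "" else sprintf(", RT %.2f min", x$rt)
  ))
  invisible(x)
}

#' @export
tidy.ms_spectrum <- function(x, ...) {
  x$peaks |> mutate(id = x$id, .before = 1)
}

#' @export
glance.ms_spectrum <- function(x, ...) {
  tibble(
    id = x$id, n_peaks = nrow(x$peaks), precursor_mz = x$precursor_mz,
    charge = x$charge, polarity = x$polarity, rt = x$rt,
    base_peak_mz = if (nrow(x$peaks)) x$peaks$mz[which.max(x$peaks$intensity)] else NA_real_
  )
}

#' Read spectra from a Mascot Generic Format file
#'
#' Supports `BEGIN IONS`/`END IONS` blocks with `PEPMASS` (required;
#' records without it are skipped with a warning), optional `CHARGE` in
#' `"2-"`/`"2+"` notation (negative-mode convention), `TITLE`,
#' `RTINSECONDS`, and arbitrary further `KEY=VALUE` headers, which are
#' kept in the spectrum metadata. Peak lines are whitespace-separated
#' m/z / intensity pairs.
#'
#' @param path MGF file path.
#' @return A list of [ms_spectrum()] objects (empty for an empty file).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block <- NULL
  begin_line <- NA_integer_
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) abort(sprintf("Line %d: BEGIN IONS inside an open block.", ln))
      in_block <- TRUE
      begin_line <- ln
      block <- list(headers = character(), mz = numeric(), int = numeric())
      next
    }
    if (line == "END IONS") {
      if (!in_block) abort(sprintf("Line %d: END IONS without BEGIN IONS.", ln))
      in_block <- FALSE
      sp <- .mgf_block_to_spectrum(block, begin_line, length(spectra) + 1L)
      if (!is.null(sp)) spectra[[length(spectra) + 1]] <- sp
      next
    }
    if (!in_block) {
      abort(sprintf("Line %d: content outside BEGIN IONS/END IONS block.", ln))
    }
    if (grepl("^[A-Za-z][A-Za-z0-9_]*=", line)) {
      block$headers <- c(block$headers, line)
    } else {
      vals <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1]]))
      if (length(vals) < 2 || anyNA(vals[1:2])) {
        abort(sprintf("Line %d: malformed peak line '%s'.", ln, line))
      }
      block$mz <- c(block$mz, vals[1])
      block$int <- c(block$int, vals[2])
    }
  }
  if (in_block) {
    abort(sprintf("Line %d: BEGIN IONS block never closed.", begin_line))
  }
  spectra
}

.mgf_block_to_spectrum <- function(block, begin_line, index) {
  kv <- strsplit(block$headers, "=", fixed = TRUE)
  keys <- toupper(vapply(kv, `[`, character(1), 1))
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_

  pep <- get("PEPMASS")
  if (is.na(pep)) {
    warn(sprintf(
      "MGF block starting at line %d has no PEPMASS; record skipped.", begin_line
    ))
    return(NULL)
  }
  precursor <- as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1])

  ch_raw <- get("CHARGE")
  charge <- 1L
  polarity <- "negative"
  if (!is.na(ch_raw)) {
    ch_raw <- trimws(ch_raw)
    sign <- if (grepl("-$", ch_raw) || grepl("^-", ch_raw)) "negative" else "positive"
    charge <- as.integer(gsub("[^0-9]", "", ch_raw))
    polarity <- sign
  }
  rt_s <- get("RTINSECONDS")
  rt <- if (is.na(rt_s)) NA_real_ else as.numeric(rt_s) / 60

  title <- get("TITLE")
  id <- if (is.na(title)) sprintf("spectrum_%03d", index) else title

  std <- c("PEPMASS", "CHARGE", "RTINSECONDS", "TITLE")
  meta_keys <- keys[!(keys %in% std)]
  metadata <- as.list(vals[!(keys %in% std)])
  names(metadata) <- meta_keys

  ms_spectrum(
    mz = block$mz, intensity = block$int, precursor_mz = precursor,
    charge = charge, polarity = polarity, rt = rt, id = id,
    metadata = metadata
  )
}

#' Write spectra to a Mascot Generic Format file
#'
#' The writer emits a normalised dialect (m/z to 4 decimals, headers in a
#' fixed order, metadata keys alphabetical), so that
#' `write_mgf(read_mgf(write_mgf(x)))` is byte-identical to
#' `write_mgf(x)`.
#'
#' @param spectra List of [ms_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    lines <- c("BEGIN IONS", paste0("TITLE=", sp$id))
    if (!is.na(sp$precursor_mz)) {
      lines <- c(lines, sprintf("PEPMASS=%.4f", sp$precursor_mz))
    }
    if (!is.na(sp$charge)) {
      lines <- c(lines, sprintf(
        "CHARGE=%d%s", sp$charge,
        if (identical(sp$polarity, "negative")) "-" else "+"
      ))
    }
    if (!is.na(sp$rt)) {
      lines <- c(lines, sprintf("RTINSECONDS=%.3f", sp$rt * 60))
    }
    if (length(sp$metadata) > 0) {
      keys <- sort(names(sp$metadata), method = "radix")
      lines <- c(lines, paste0(toupper(keys), "=",
                               vapply(sp$metadata[keys], as.character, character(1))))
    }
    if (nrow(sp$peaks) > 0) {
      lines <- c(lines, sprintf("%.4f %.6g", sp$peaks$mz, sp$peaks$intensity))
    }
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}
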