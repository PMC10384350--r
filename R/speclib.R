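# Spectral-library matching: cosine similarity on square-root-scaled
# intensities with greedy one-to-one peak pairing, precursor filtering,
# and a retention-time gate for isomer disambiguation.

# Greedy one-to-one pairing of peaks across two spectra. `shift` allows a
# second match channel offset by the precursor mass difference (used by
# the modified cosine). Pairs are taken best-weight-first; each peak is
# used once.
.match_peaks <- function(mza, wa, mzb, wb, tol, shift = NULL) {
  cand <- list()
  for (i in seq_along(mza)) {
    d <- abs(mzb - mza[i])
    hit <- which(d <= tol)
    if (!is.null(shift) && shift != 0) {
      hit <- union(hit, which(abs(mzb - mza[i] - shift) <= tol))
    }
    if (length(hit) > 0) {
      cand[[length(cand) + 1]] <- tibble(
        i = i, j = hit, w = wa[i] * wb[hit]
      )
    }
  }
  if (length(cand) == 0) {
    return(tibble(i = integer(), j = integer(), w = numeric()))
  }
  cand <- dplyr::bind_rows(cand) |>
    arrange(dplyr::desc(.data$w), .data$i, .data$j)
  used_i <- logical(length(mza))
  used_j <- logical(length(mzb))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used_i[cand$i[r]] && !used_j[cand$j[r]]) {
      keep[r] <- TRUE
      used_i[cand$i[r]] <- TRUE
      used_j[cand$j[r]] <- TRUE
    }
  }
  cand[keep, ]
}

.cosine_impl <- function(a, b, frag_tol, shift = NULL) {
  if (nrow(a$peaks) == 0 || nrow(b$peaks) == 0) {
    return(list(score = 0, n_matched = 0L))
  }
  wa <- sqrt(a$peaks$intensity)
  wb <- sqrt(b$peaks$intensity)
  m <- .match_peaks(a$peaks$mz, wa, b$peaks$mz, wb, frag_tol, shift)
  denom <- sqrt(sum(wa^2)) * sqrt(sum(wb^2))
  if (denom == 0) return(list(score = 0, n_matched = 0L))
  list(score = min(sum(m$w) / denom, 1), n_matched = nrow(m))
}

#' Cosine similarity of two spectra
#'
#' Peaks are paired one-to-one within `frag_tol` (greedy, best
#' intensity-product pairs first) and scored as the cosine of the
#' square-root-scaled intensity vectors. Symmetric; empty spectra score 0.
#'
#' @param a,b [ms_spectrum()] objects.
#' @param frag_tol Fragment m/z tolerance in Da.
#' @return A one-row tibble with `score` (in `[0, 1]`) and `n_matched`.
#' @export
cosine_score <- function(a, b, frag_tol = 0.05) {
  r <- .cosine_impl(a, b, frag_tol)
  tibble(score = r$score, n_matched = r$n_matched)
}

#' Modified cosine similarity (analog-aware)
#'
#' Like [cosine_score()], but fragment pairs may also match when their
#' m/z difference equals the precursor mass difference of the two
#' spectra, linking structural analogs whose fragment series are shifted
#' en bloc. With equal precursors it reduces exactly to the plain cosine.
#'
#' @inheritParams cosine_score
#' @return A one-row tibble with `score`, `n_matched` and `delta_mz`
#'   (precursor difference `b - a`).
#' @export
modified_cosine <- function(a, b, frag_tol = 0.05) {
  shift <- b$precursor_mz - a$precursor_mz
  if (is.na(shift)) shift <- 0
  r <- .cosine_impl(a, b, frag_tol, shift = shift)
  tibble(score = r$score, n_matched = r$n_matched, delta_mz = shift)
}

#' Attach a structure to a reference spectrum
#'
#' A library record is a spectrum plus an optional [glycoside()] and
#' free-text provenance. When both a structure and a precursor m/z are
#' present, their consistency is checked to 20 ppm (warning otherwise).
#'
#' @param spectrum An [ms_spectrum()].
#' @param glycoside Optional [glycoside()].
#' @param provenance Free-text origin of the record.
#' @return The spectrum with `glycoside`/`provenance` stored in its
#'   metadata, classed `library_record` as well.
#' @export
library_record <- function(spectrum, glycoside = NULL, provenance = NA_character_) {
  if (!is.null(glycoside) && !is.na(spectrum$precursor_mz)) {
    z <- max(1L, sum(glycoside$glycan$sulfated))
    calc <- precursor_mz(glycoside, n_charges = if (z >= 2) z else 1L)$mz
    if (abs(ppm_error(calc, spectrum$precursor_mz)) > 20) {
      warn(sprintf(
        "Record '%s': measured precursor %.4f differs from the structure's %.4f by > 20 ppm.",
        spectrum$id, spectrum$precursor_mz, calc
      ))
    }
  }
  spectrum$glycoside <- glycoside
  spectrum$provenance <- provenance
  class(spectrum) <- unique(c("library_record", class(spectrum)))
  spectrum
}

#' Search a query spectrum against a spectral library
#'
#' Candidates are restricted to library records whose precursor m/z lies
#' within `precursor_tol` of the query, scored with [cosine_score()], and
#' gated on retention time when both sides have one: records within
#' `rt_tol` minutes pass the gate; failures are kept but ranked strictly
#' below all passers. Results are sorted by (gate, cosine) descending.
#'
#' @param query An [ms_spectrum()].
#' @param library List of [ms_spectrum()] / [library_record()] objects.
#' @param precursor_tol Precursor m/z tolerance (Da).
#' @param frag_tol Fragment m/z tolerance (Da).
#' @param rt_tol Retention-time tolerance (minutes).
#' @return A tibble with one row per candidate: `query_id`, `record_id`,
#'   `cosine`, `n_matched`, `ppm_error` (library precursor taken as
#'   calculated), `rt_delta_min` (`NA` if either side lacks RT) and
#'   `passed_rt_gate`.
#' @export
library_search <- function(query, library, precursor_tol = 0.02,
                           frag_tol = 0.05, rt_tol = 0.3) {
  if (length(library) == 0) abort("The library is empty.")
  rows <- purrr::map_dfr(library, function(rec) {
    if (is.na(rec$precursor_mz) || is.na(query$precursor_mz)) return(NULL)
    if (abs(rec$precursor_mz - query$precursor_mz) > precursor_tol) return(NULL)
    cs <- cosine_score(query, rec, frag_tol = frag_tol)
    rt_delta <- if (is.na(query$rt) || is.na(rec$rt)) NA_real_ else query$rt - rec$rt
    tibble(
      query_id = query$id, record_id = rec$id,
      cosine = cs$score, n_matched = cs$n_matched,
      ppm_error = ppm_error(rec$precursor_mz, query$precursor_mz),
      rt_delta_min = rt_delta,
      passed_rt_gate = is.na(rt_delta) | abs(rt_delta) <= rt_tol
    )
  })
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble(
      query_id = character(), record_id = character(), cosine = numeric(),
      n_matched = integer(), ppm_error = numeric(), rt_delta_min = numeric(),
      passed_rt_gate = logical()
    ))
  }
  rows |> arrange(dplyr::desc(.data$passed_rt_gate), dplyr::desc(.data$cosine),
                  .data$record_id)
}

#' Read centroided spectra from an mzML file
#'
#' Thin read-only wrapper over Bioconductor's mzR for centroided peak
#' lists with precursor information; MS1 scans get `NA` precursors.
#' Vendor-format conversion and profile-mode data are out of scope.
#'
#' @param path mzML file path.
#' @return A list of [ms_spectrum()] objects.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("Reading mzML requires the 'mzR' package.")
  }
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  purrr::map(seq_len(nrow(h)), function(i) {
    pk <- mzR::peaks(f, i)
    ch <- h$precursorCharge[i]
    ms_spectrum(
      mz = pk[, 1], intensity = pk[, 2],
      precursor_mz = if (h$msLevel[i] >= 2) h$precursorMZ[i] else NA_real_,
      charge = if (!is.na(ch) && ch > 0) ch else 1L,
      polarity = if (identical(h$polarity[i], 1L)) "positive" else "negative",
      rt = h$retentionTime[i] / 60,
      id = sprintf("scan=%d", h$acquisitionNum[i])
    )
  })
}
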