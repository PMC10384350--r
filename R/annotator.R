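# Rule-based structural inference from negative-mode CID spectra:
# sulfation state, glycan sequence (Y-ladder walking), aglycon feature
# flags, side-chain classification, and precursor-difference analog
# hypotheses.
#
# Neutral-loss arithmetic is done on singly-charged-equivalent masses:
# a peak of charge z is mapped to z*mz + (z-1)*proton (re-protonating the
# extra charge sites), so that losses of charged sulfated residues from
# multiply-charged precursors line up with the neutral residue + SO3
# increments.

.equiv_mass <- function(mz, charge, mode = "mono") {
  p <- mass_constants(mode)[["proton"]]
  charge * mz + (charge - 1) * p
}

.peak_table <- function(s, mode = "mono") {
  pk <- s$peaks
  ch <- if ("peak_charge" %in% names(pk)) {
    ifelse(is.na(pk$peak_charge), 1L, pk$peak_charge)
  } else {
    rep(1L, nrow(pk))
  }
  tibble(
    peak = seq_len(nrow(pk)), mz = pk$mz, intensity = pk$intensity,
    charge = as.integer(ch), equiv = .equiv_mass(pk$mz, ch, mode)
  )
}

.root_equiv <- function(s, mode = "mono") {
  .equiv_mass(s$precursor_mz, s$charge, mode)
}

.default_tol <- function(mode, tol) {
  if (!is.null(tol)) return(tol)
  if (mode == "nominal") 0.5 else 0.05
}

.sulfo_diagnostics <- function(mode = "mono") {
  k <- mass_constants(mode)
  tab <- monosaccharides() |> distinct(.data$code, .keep_all = TRUE)
  res <- .residue_mass(tab$code, mode)
  tibble(
    rule = c("bisulfate anion", paste0("sulfated ", tab$code, " anion")),
    code = c(NA_character_, tab$code),
    mz = c(k[["HSO4_anion"]], res + k[["SO3"]] - k[["H"]])
  )
}

#' Infer the sulfation state of a spectrum
#'
#' Multiply-charged negative precursors of glycoside sodium salts carry
#' one charge per sulfate, so for charge >= 2 the estimate equals the
#' precursor charge. For singly-charged precursors the presence of any
#' sulfate diagnostic ion (bisulfate at m/z 96.96 or a sulfated
#' monosaccharide anion) indicates at least one sulfate.
#'
#' @param s An [ms_spectrum()] with known precursor.
#' @param frag_tol Fragment matching tolerance (Da); default 0.05 mono /
#'   0.5 nominal.
#' @param mode `"mono"` or `"nominal"`.
#' @return A one-row tibble with `estimate`, `basis`, and a list-column
#'   `evidence` of diagnostic hits (rule, expected m/z, peak index/m/z).
#' @export
infer_sulfation <- function(s, frag_tol = NULL, mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  frag_tol <- .default_tol(mode, frag_tol)
  if (is.na(s$precursor_mz) || is.na(s$charge)) {
    abort("The spectrum has no precursor m/z / charge.")
  }
  pk <- .peak_table(s, mode)
  diag <- .sulfo_diagnostics(mode)
  hits <- purrr::map_dfr(seq_len(nrow(diag)), function(i) {
    j <- which(abs(pk$mz - diag$mz[i]) <= frag_tol)
    if (length(j) == 0) return(NULL)
    tibble(
      rule = diag$rule[i], expected_mz = diag$mz[i],
      peak = j, peak_mz = pk$mz[j]
    )
  })
  if (s$charge >= 2) {
    est <- s$charge
    basis <- "precursor charge ([M-nNa]n-)"
    hits <- dplyr::bind_rows(
      tibble(
        rule = "multiply-charged precursor", expected_mz = NA_real_,
        peak = NA_integer_, peak_mz = s$precursor_mz
      ),
      hits
    )
  } else {
    est <- if (nrow(hits) > 0) 1L else 0L
    basis <- if (nrow(hits) > 0) "diagnostic ions" else "no sulfate evidence"
  }
  tibble(estimate = as.integer(est), basis = basis, evidence = list(hits))
}

.residue_diff_table <- function(mode = "mono", sulfate_aware = TRUE) {
  k <- mass_constants(mode)
  tab <- monosaccharides()
  base <- tibble(
    code = c("MeGlc", "Glc", "Qui|MeXyl", "Xyl"),
    mass = .residue_mass(c("MeGlc", "Glc", "Qui", "Xyl"), mode),
    sulfated = FALSE,
    ord = 1:4
  )
  if (!sulfate_aware) return(base)
  dplyr::bind_rows(
    base,
    base |> mutate(mass = .data$mass + k[["SO3"]], sulfated = TRUE,
                   ord = .data$ord + 0.5)
  )
}

#' Glycan sequence candidates from a fragment ladder
#'
#' Walks peak-to-peak neutral-loss differences matching monosaccharide
#' residue masses (176.0685 MeGlc, 162.0528 Glc, 146.0579 Qui or MeXyl,
#' 132.0423 Xyl; optionally their +SO3 sulfated variants) depth-first
#' from the precursor, and reports maximal ladders as terminal-to-root
#' residue sequences. 146-Da steps are intrinsically ambiguous
#' (`"Qui|MeXyl"`) and are never resolved by mass. Candidates are ranked
#' by matched-step count, then summed matched intensity; ties in the
#' walk are broken by the fixed residue order MeGlc < Glc < Qui|MeXyl <
#' Xyl for determinism.
#'
#' @param s An [ms_spectrum()] (at least 2 peaks for a non-trivial walk).
#' @param tol Mass-difference tolerance (Da); default 0.05 mono /
#'   0.5 nominal.
#' @param mode `"mono"` or `"nominal"`.
#' @param sulfate_aware Also match residue + SO3 steps (charged losses of
#'   sulfated units from multiply-charged precursors).
#' @param max_candidates Maximum number of ladders returned.
#' @return A tibble with one row per candidate: `candidate`, `sequence`
#'   (terminal-to-root, `-`-joined), `n_steps`, `score` (step count
#'   relative to the best candidate), `sum_intensity` and a list-column
#'   `steps` (code, mass, sulfated, from/to equivalent masses). The
#'   attribute `"branch_hypotheses"` lists candidate pairs that share a
#'   ladder prefix and then diverge, indicating a branched chain.
#' @export
sequence_glycan <- function(s, tol = NULL, mode = c("mono", "nominal"),
                            sulfate_aware = TRUE, max_candidates = 20) {
  mode <- match.arg(mode)
  tol <- .default_tol(mode, tol)
  pk <- .peak_table(s, mode)
  diffs <- .residue_diff_table(mode, sulfate_aware)
  root <- .root_equiv(s, mode)

  nodes <- dplyr::bind_rows(
    tibble(peak = 0L, mz = s$precursor_mz, intensity = 0,
           charge = s$charge, equiv = root),
    pk |> filter(.data$equiv < root + tol)
  )
  # edges: node u -> node v when equiv difference matches a residue step
  edges <- purrr::map_dfr(seq_len(nrow(nodes)), function(u) {
    delta <- nodes$equiv[u] - nodes$equiv
    hit <- purrr::map_dfr(seq_len(nrow(diffs)), function(d) {
      v <- which(abs(delta - diffs$mass[d]) <= tol & seq_len(nrow(nodes)) != u)
      if (length(v) == 0) return(NULL)
      tibble(u = u, v = v, code = diffs$code[d], mass = diffs$mass[d],
             sulfated = diffs$sulfated[d], ord = diffs$ord[d])
    })
    hit
  })

  paths <- list()
  expansions <- 0L
  walk <- function(v, path_edges) {
    expansions <<- expansions + 1L
    if (expansions > 5000L || length(paths) >= 200L) return()
    out <- edges[edges$u == v, , drop = FALSE]
    if (nrow(out) == 0) {
      if (length(path_edges) > 0) paths[[length(paths) + 1]] <<- path_edges
      return()
    }
    out <- out[order(out$ord, -nodes$equiv[out$v], out$v), , drop = FALSE]
    for (r in seq_len(nrow(out))) {
      walk(out$v[r], c(path_edges, list(out[r, ])))
    }
  }
  walk(1L, list())

  if (length(paths) == 0) {
    out <- tibble(
      candidate = integer(), sequence = character(), n_steps = integer(),
      score = numeric(), sum_intensity = numeric(), steps = list()
    )
    attr(out, "branch_hypotheses") <- tibble(
      cand_a = integer(), cand_b = integer(), shared_steps = integer()
    )
    return(out)
  }

  cand <- purrr::map_dfr(seq_along(paths), function(i) {
    st <- dplyr::bind_rows(paths[[i]])
    tibble(
      idx = i,
      sequence = paste(ifelse(st$sulfated, paste0(st$code, "(S)"), st$code),
                       collapse = "-"),
      n_steps = nrow(st),
      sum_intensity = sum(nodes$intensity[st$v])
    )
  }) |>
    distinct(.data$sequence, .keep_all = TRUE) |>
    arrange(dplyr::desc(.data$n_steps), dplyr::desc(.data$sum_intensity),
            .data$sequence) |>
    utils::head(max_candidates)

  steps_list <- purrr::map(cand$idx, function(i) {
    st <- dplyr::bind_rows(paths[[i]])
    tibble(
      code = st$code, mass = st$mass, sulfated = st$sulfated,
      from_equiv = nodes$equiv[st$u], to_equiv = nodes$equiv[st$v],
      to_peak = nodes$peak[st$v]
    )
  })
  out <- cand |>
    mutate(
      candidate = dplyr::row_number(),
      score = .data$n_steps / max(.data$n_steps),
      steps = steps_list
    ) |>
    select("candidate", "sequence", "n_steps", "score", "sum_intensity", "steps")

  bh <- list()
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1)) {
      for (j in seq(i + 1, nrow(out))) {
        a <- out$steps[[i]]
        b <- out$steps[[j]]
        kmax <- min(nrow(a), nrow(b))
        shared <- 0L
        while (shared < kmax && isTRUE(all.equal(a$to_equiv[shared + 1],
                                                 b$to_equiv[shared + 1]))) {
          shared <- shared + 1L
        }
        if (shared >= 1 && nrow(a) > shared && nrow(b) > shared &&
            abs(a$to_equiv[shared + 1] - b$to_equiv[shared + 1]) > tol) {
          bh[[length(bh) + 1]] <- tibble(
            cand_a = i, cand_b = j, shared_steps = shared
          )
        }
      }
    }
  }
  attr(out, "branch_hypotheses") <- if (length(bh) > 0) {
    dplyr::bind_rows(bh)
  } else {
    tibble(cand_a = integer(), cand_b = integer(), shared_steps = integer())
  }
  out
}

#' Estimate the monosaccharide composition of a spectrum
#'
#' Combines the best [sequence_glycan()] ladder with the sulfation
#' evidence: when the sulfate count implied by the precursor charge (or
#' the diagnostics, for singly-charged precursors) exceeds the number of
#' sulfated ladder steps, sulfated-monosaccharide diagnostic ions supply
#' the units the ladder cannot reach (losing them would strip the
#' remaining charge).
#'
#' @inheritParams sequence_glycan
#' @return A tibble with columns `code` (possibly `"Qui|MeXyl"`),
#'   `sulfated` and `source` (`"ladder"` or `"diagnostic"`), one row per
#'   inferred unit; zero rows when nothing can be inferred. The attribute
#'   `"ambiguous"` is `TRUE` when equally long ladders with different
#'   residue-mass multisets compete (coincidental isobaric collisions,
#'   e.g. Xyl + CO2 vs MeGlc, or the pair sums Glc + Qui vs MeGlc + Xyl).
#' @export
estimate_composition <- function(s, tol = NULL, mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  tol <- .default_tol(mode, tol)
  cand <- sequence_glycan(s, tol = tol, mode = mode)
  ladder <- if (nrow(cand) > 0) {
    cand$steps[[1]] |>
      transmute(code = .data$code, sulfated = .data$sulfated, source = "ladder")
  } else {
    tibble(code = character(), sulfated = logical(), source = character())
  }
  # log isobaric ambiguity: competing best ladders with different
  # residue-mass multisets cannot be resolved by mass alone
  ambiguous <- FALSE
  if (nrow(cand) > 1) {
    best <- cand |> filter(.data$n_steps == max(.data$n_steps))
    comps <- purrr::map_chr(best$steps, function(st) {
      paste(sort(round(st$mass)), collapse = ",")
    })
    ambiguous <- length(unique(comps)) > 1
  }
  sulf <- infer_sulfation(s, frag_tol = tol, mode = mode)
  deficit <- sulf$estimate - sum(ladder$sulfated)
  if (deficit > 0) {
    ev <- sulf$evidence[[1]]
    diag_codes <- sub("^sulfated (\\w+) anion$", "\\1",
                      ev$rule[grepl("^sulfated", ev$rule)])
    diag_codes <- ifelse(diag_codes %in% c("Qui", "MeXyl"), "Qui|MeXyl", diag_codes)
    diag_codes <- unique(diag_codes)
    add <- utils::head(diag_codes, deficit)
    if (length(add) > 0) {
      ladder <- dplyr::bind_rows(
        ladder,
        tibble(code = add, sulfated = TRUE, source = "diagnostic")
      )
    }
  }
  attr(ladder, "ambiguous") <- ambiguous
  ladder
}

#' Detect aglycon-related neutral-loss features
#'
#' Flags water loss (18 Da), lactone-related CO2 loss (44 Da), acetic
#' acid loss (60 Da, acetoxy group) and the combined AcOH + CO2 loss
#' (104 Da), the last implying both an acetoxy group and an
#' 18(20)-lactone. Differences are taken between all pairs of
#' singly-charged-equivalent masses, precursor included.
#'
#' @inheritParams sequence_glycan
#' @return A one-row tibble of logical flags `water_losses`,
#'   `lactone_co2_loss`, `acetoxy_60`, `acetoxy_lactone_104`, with a
#'   list-column `evidence` (rule, parent/child equivalent masses).
#' @export
detect_aglycon_features <- function(s, tol = NULL, mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  tol <- .default_tol(mode, tol)
  if (is.na(s$precursor_mz)) abort("The spectrum has no precursor m/z.")
  k <- mass_constants(mode)
  targets <- tibble(
    rule = c("water_losses", "lactone_co2_loss", "acetoxy_60", "acetoxy_lactone_104"),
    mass = c(k[["H2O"]], k[["CO2"]], k[["AcOH"]], k[["AcOH_CO2"]])
  )
  eq <- sort(c(.root_equiv(s, mode), .peak_table(s, mode)$equiv))
  ev <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    hit <- list()
    for (a in seq_along(eq)) {
      lo <- eq[a] - targets$mass[i] - tol
      hi <- eq[a] - targets$mass[i] + tol
      b <- which(eq >= lo & eq <= hi)
      if (length(b) > 0) {
        hit[[length(hit) + 1]] <- tibble(
          rule = targets$rule[i], parent_equiv = eq[a], child_equiv = eq[b]
        )
      }
    }
    dplyr::bind_rows(hit)
  })
  hit_rules <- if (nrow(ev) > 0) ev$rule else character(0)
  flags <- stats::setNames(targets$rule %in% hit_rules, targets$rule)
  out <- tibble(
    water_losses = flags[["water_losses"]],
    lactone_co2_loss = flags[["lactone_co2_loss"]],
    acetoxy_60 = flags[["acetoxy_60"]],
    acetoxy_lactone_104 = flags[["acetoxy_lactone_104"]]
  )
  out$evidence <- list(ev)
  out
}

#' Classify the aglycon side chain from neutral losses
#'
#' Counts, for each side-chain class of [side_chain_classes()], how many
#' of its diagnostic neutral-loss masses are observed as losses from a
#' reference mass (by default the singly-charged-equivalent precursor).
#' Classes are ranked by hit count, then by the fraction of their
#' signature observed; classes with identical (hits, coverage) share a
#' rank (ties are reported as ties, not broken arbitrarily).
#'
#' @param s An [ms_spectrum()].
#' @param reference_mass Reference for the losses; default the
#'   deconvoluted precursor. Supply a Y0/Y1 equivalent mass to classify
#'   losses from an inner fragment instead.
#' @param tol Matching tolerance in Da (signatures are nominal; default
#'   0.5).
#' @param mode `"mono"` or `"nominal"` (affects only the equivalent-mass
#'   deconvolution).
#' @return Tibble with `class_id`, `example`, `hits`, `n_signature`,
#'   `coverage`, `rank`, sorted best-first.
#' @export
classify_side_chain <- function(s, reference_mass = NULL, tol = 0.5,
                                mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  if (is.null(reference_mass)) reference_mass <- .root_equiv(s, mode)
  losses <- reference_mass - .peak_table(s, mode)$equiv
  losses <- losses[losses > 0]
  t <- side_chain_classes()
  sig_cols <- c("b1", "b2", "f_C6H8O4", "f_C4H6O4", "f_C3H4O4", "f_CO2", "h")
  res <- purrr::map_dfr(seq_len(nrow(t)), function(i) {
    sig <- as.numeric(t[i, sig_cols])
    sig <- sig[!is.na(sig)]
    hits <- sum(vapply(sig, function(m) any(abs(losses - m) <= tol), logical(1)))
    tibble(
      class_id = t$class_id[i], example = t$example[i],
      hits = hits, n_signature = length(sig),
      coverage = hits / length(sig)
    )
  }) |>
    arrange(dplyr::desc(.data$hits), dplyr::desc(.data$coverage), .data$class_id)
  key <- paste(res$hits, signif(res$coverage, 10))
  res$rank <- match(key, unique(key))
  res
}

.ANALOG_DIFFS <- tibble::tribble(
  ~nominal, ~mono,     ~interpretation,
  176,      176.06847, "3-O-methylglucose unit",
  162,      162.05282, "glucose unit",
  146,      146.05791, "quinovose (or 3-O-methylxylose) unit",
  132,      132.04226, "xylose unit",
  58,       58.00548,  "acetate group",
  30,       30.01057,  "glucose <-> xylose substitution (CH2O)",
  18,       18.01056,  "H2O",
  16,       15.99491,  "O (e.g. hydroxylation)",
  14,       14.01565,  "CH2 (methylation)",
  12,       12.0,      "C",
  2,        2.01565,   "H2 (double bond)"
)

#' Propose analog relationships by precursor mass difference
#'
#' Compares a query precursor m/z with each library precursor and reports
#' matches to the characteristic structural mass differences (residue
#' masses 176/162/146/132, acetate 58, Glc/Xyl swap 30, and the small
#' modifications 18/16/14/12/2 Da), in both directions. A query equal to
#' a library precursor (within `tol`) is reported on the `"exact"`
#' channel instead (a zero difference is not an analog relationship).
#'
#' @param query_precursor Query precursor m/z (Da).
#' @param library List of [ms_spectrum()] objects, or a tibble/data frame
#'   with columns `id` and `precursor_mz`.
#' @param tol Precursor tolerance (Da).
#' @param mode `"nominal"` matches the integer difference table,
#'   `"mono"` the monoisotopic equivalents.
#' @return Tibble with `record_id`, `record_mz`, `delta` (query - record),
#'   `matched_difference`, `direction` (`"gain"` if the query is heavier),
#'   `interpretation` and `channel` (`"exact"` or `"analog"`).
#' @export
annotate_analogs <- function(query_precursor, library, tol = 0.02,
                             mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  if (is.data.frame(library)) {
    lib <- as_tibble(library)[, c("id", "precursor_mz")]
  } else {
    if (length(library) == 0) abort("The library is empty.")
    lib <- purrr::map_dfr(library, function(r) {
      tibble(id = r$id, precursor_mz = r$precursor_mz)
    })
  }
  if (nrow(lib) == 0) abort("The library is empty.")
  dtab <- .ANALOG_DIFFS
  dmass <- if (mode == "mono") dtab$mono else dtab$nominal
  purrr::map_dfr(seq_len(nrow(lib)), function(i) {
    delta <- query_precursor - lib$precursor_mz[i]
    if (abs(delta) <= tol) {
      return(tibble(
        record_id = lib$id[i], record_mz = lib$precursor_mz[i],
        delta = delta, matched_difference = 0,
        direction = "equal", interpretation = "exact precursor match",
        channel = "exact"
      ))
    }
    j <- which(abs(abs(delta) - dmass) <= tol)
    if (length(j) == 0) return(NULL)
    tibble(
      record_id = lib$id[i], record_mz = lib$precursor_mz[i],
      delta = delta, matched_difference = dmass[j],
      direction = ifelse(delta > 0, "gain", "loss"),
      interpretation = dtab$interpretation[j],
      channel = "analog"
    )
  })
}

#' Full annotation report for a query spectrum
#'
#' Runs the sulfation, glycan-sequence, composition, aglycon-feature and
#' side-chain inferences on one spectrum, plus analog hypotheses against
#' an optional library, and collects the results with the major peaks no
#' rule could explain.
#'
#' @inheritParams sequence_glycan
#' @param library Optional library for [annotate_analogs()].
#' @param precursor_tol Precursor tolerance for analog matching.
#' @return An object of class `saponin_annotation` (a list); see
#'   [tidy.saponin_annotation()] and [glance.saponin_annotation()].
#' @export
annotate <- function(s, library = NULL, tol = NULL,
                     mode = c("mono", "nominal"), precursor_tol = 0.02) {
  mode <- match.arg(mode)
  tol <- .default_tol(mode, tol)
  sulf <- infer_sulfation(s, frag_tol = tol, mode = mode)
  seqs <- sequence_glycan(s, tol = tol, mode = mode)
  comp <- estimate_composition(s, tol = tol, mode = mode)
  agl <- detect_aglycon_features(s, tol = tol, mode = mode)
  sc <- classify_side_chain(s, mode = mode)
  analogs <- if (!is.null(library)) {
    annotate_analogs(s$precursor_mz, library, tol = precursor_tol, mode = mode)
  } else {
    NULL
  }

  pk <- .peak_table(s, mode)
  explained <- unique(c(
    unlist(purrr::map(seqs$steps, "to_peak")),
    unlist(purrr::map(sulf$evidence, "peak"))
  ))
  unexplained <- pk |>
    filter(!(.data$peak %in% explained)) |>
    arrange(dplyr::desc(.data$intensity)) |>
    utils::head(10)

  structure(
    list(
      id = s$id, precursor_mz = s$precursor_mz, charge = s$charge,
      sulfation = sulf, glycan_candidates = seqs, composition = comp,
      aglycon_flags = agl, side_chain = sc, analogs = analogs,
      unexplained = unexplained, mode = mode, tol = tol
    ),
    class = "saponin_annotation"
  )
}

#' @export
print.saponin_annotation <- function(x, ...) {
  cat(sprintf("<saponin_annotation> %s (precursor %.4f, %d-)\n",
              x$id, x$precursor_mz, x$charge))
  cat(sprintf("  sulfates: %d (%s)\n", x$sulfation$estimate, x$sulfation$basis))
  if (nrow(x$glycan_candidates) > 0) {
    cat(sprintf("  glycan ladder: %s\n", x$glycan_candidates$sequence[1]))
  }
  top <- x$side_chain[x$side_chain$rank == 1 & x$side_chain$hits > 0, ]
  if (nrow(top) > 0) {
    cat(sprintf("  side chain: %s\n", paste(top$example, collapse = " | ")))
  }
  invisible(x)
}

#' Tidy method for annotation reports
#'
#' @param x A `saponin_annotation`.
#' @param ... Unused.
#' @return A tibble of evidence lines (component, rule, value).
#' @export
tidy.saponin_annotation <- function(x, ...) {
  dplyr::bind_rows(
    tibble(component = "sulfation", rule = x$sulfation$basis,
           value = as.character(x$sulfation$estimate)),
    if (nrow(x$glycan_candidates) > 0) {
      tibble(component = "glycan", rule = "ladder candidate",
             value = x$glycan_candidates$sequence)
    },
    tibble(component = "composition", rule = x$composition$source,
           value = paste0(x$composition$code,
                          ifelse(x$composition$sulfated, "(S)", ""))),
    x$aglycon_flags |>
      select(-"evidence") |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "rule",
                          values_to = "flag") |>
      transmute(component = "aglycon", rule = .data$rule,
                value = as.character(.data$flag)),
    x$side_chain |>
      filter(.data$rank == 1) |>
      transmute(component = "side_chain", rule = .data$class_id,
                value = sprintf("%d/%d hits", .data$hits, .data$n_signature))
  )
}

#' Glance method for annotation reports
#'
#' @param x A `saponin_annotation`.
#' @param ... Unused.
#' @return One-row tibble of summary quantities.
#' @export
glance.saponin_annotation <- function(x, ...) {
  tibble(
    id = x$id, precursor_mz = x$precursor_mz, charge = x$charge,
    sulfate_estimate = x$sulfation$estimate,
    n_ladder_steps = if (nrow(x$glycan_candidates) > 0) x$glycan_candidates$n_steps[1] else 0L,
    n_units_inferred = nrow(x$composition),
    top_side_chain = if (any(x$side_chain$hits > 0)) x$side_chain$example[1] else NA_character_,
    n_unexplained = nrow(x$unexplained)
  )
}
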