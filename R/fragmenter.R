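# Theoretical CID fragment generation under negative-mode conventions.
#
# Conventions validated against published ladders of sulfated saponins:
#   Y  (aglycon side retained):   neutral loss of the cleaved residues;
#       if a cleaved subtree carries k sulfate charges it departs as an
#       anion of mass sum(residues) + k*SO3 - k*H and the fragment charge
#       drops by k.
#   B  (non-reducing side):       m/z = (sum(residues) + nSO3*SO3 - z*H)/z,
#       generated only for sulfate-carrying subtrees (the charge has to
#       ride on a sulfate in this chemistry).
#   C = B + H2O, Z = Y - H2O.

.unit_depth <- function(gt) {
  depth <- integer(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    d <- 0L
    v <- gt$parent[i]
    while (!is.na(v)) {
      d <- d + 1L
      v <- gt$parent[match(v, gt$unit)]
    }
    depth[i] <- d
  }
  depth
}

.subtree_units <- function(gt, u) {
  out <- u
  repeat {
    kids <- gt$unit[!is.na(gt$parent) & gt$parent %in% out & !(gt$unit %in% out)]
    if (length(kids) == 0) break
    out <- c(out, kids)
  }
  sort(out)
}

#' Enumerate removable unit sets of a glycan tree
#'
#' All non-empty, descendant-closed unit sets: the sets of units that can
#' be detached by one or more simultaneous glycosidic cleavages (each lost
#' set is a union of complete subtrees, removed leaves-first across
#' branches). These index the combined Y-type cleavages.
#'
#' @param gt A [glycan_tree()].
#' @return List of integer vectors of unit ids.
#' @export
removable_unit_sets <- function(gt) {
  n <- nrow(gt)
  ids <- gt$unit
  sets <- list()
  for (mask in seq_len(2^n - 1)) {
    s <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    kids_of_s <- gt$unit[!is.na(gt$parent) & gt$parent %in% s]
    if (all(kids_of_s %in% s)) sets[[length(sets) + 1]] <- s
  }
  sets
}

.charge_suffix <- function(z) if (z == 1) "-" else sprintf("%d-", z)

.unit_token <- function(gt, u) {
  i <- match(u, gt$unit)
  paste0(gt$code[i], ifelse(gt$sulfated[i], "SO3", ""))
}

#' Glycosidic-bond fragment ladder
#'
#' Generates the Y-type series (all combined cleavages across branches),
#' the sulfate-retaining B-type series (one ion per sulfated subtree) and
#' optionally C (= B + H2O) and Z (= Y - H2O) ions, for the negative-mode
#' precursor of a glycoside. The precursor itself is included as the
#' trivial root row.
#'
#' @param g A [glycoside()].
#' @param n_charges Precursor charge; default per [precursor_mz()].
#' @param mode `"mono"` or `"nominal"`.
#' @param include_C,include_Z Gate the C- and Z-type series.
#' @return A tibble with columns `label`, `ion_type`, `charge`, `mz`,
#'   `cleaved_units` (comma-separated unit ids; `""` for the precursor),
#'   `sulfates_retained` and `parent` (label of the parent fragment),
#'   sorted by m/z and deduplicated by (label, charge).
#' @export
glycosidic_ladder <- function(g, n_charges = NULL, mode = c("mono", "nominal"),
                              include_C = FALSE, include_Z = FALSE) {
  mode <- match.arg(mode)
  g <- validate_glycoside(g)
  gt <- g$glycan
  if (nrow(gt) == 0) abort("The glycan is empty.")
  k <- mass_constants(mode)
  prec <- precursor_mz(g, n_charges = n_charges, mode = mode)
  z <- prec$charge
  ns <- prec$n_sulfates
  base <- sub("\\]-?.*$", "", sub("^\\[", "", prec$adduct))
  base <- sub("\\].*$", "", base)
  depth <- .unit_depth(gt)

  rows <- list(tibble(
    label = prec$adduct, ion_type = "precursor", charge = z, mz = prec$mz,
    cleaved_units = "", sulfates_retained = ns, parent = NA_character_
  ))

  total_mass <- z * prec$mz
  res_all <- .residue_mass(gt$code, mode)

  for (s in removable_unit_sets(gt)) {
    i <- match(s, gt$unit)
    s_lost <- sum(gt$sulfated[i])
    z2 <- z - s_lost
    if (z2 < 1) next
    loss <- sum(res_all[i]) + s_lost * k[["SO3"]] - s_lost * k[["H"]]
    ord <- i[order(-depth[i], gt$unit[i])]
    toks <- vapply(gt$unit[ord], function(u) .unit_token(gt, u), character(1))
    lab <- paste0("[", base, paste0("-", toks, collapse = ""), "]",
                  .charge_suffix(z2))
    mz2 <- (total_mass - loss) / z2
    rows[[length(rows) + 1]] <- tibble(
      label = lab, ion_type = "Y", charge = z2, mz = mz2,
      cleaved_units = paste(sort(s), collapse = ","),
      sulfates_retained = ns - s_lost, parent = prec$adduct
    )
    if (include_Z) {
      rows[[length(rows) + 1]] <- tibble(
        label = sub("\\]", "-H2O]", lab), ion_type = "Z", charge = z2,
        mz = mz2 - k[["H2O"]] / z2,
        cleaved_units = paste(sort(s), collapse = ","),
        sulfates_retained = ns - s_lost, parent = lab
      )
    }
  }

  n_skipped <- 0L
  for (u in gt$unit) {
    sub_u <- .subtree_units(gt, u)
    i <- match(sub_u, gt$unit)
    ns_sub <- sum(gt$sulfated[i])
    if (ns_sub == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    zb <- min(ns_sub, z)
    mzb <- (sum(res_all[i]) + ns_sub * k[["SO3"]] - zb * k[["H"]]) / zb
    ord <- i[order(-depth[i], gt$unit[i])]
    toks <- vapply(gt$unit[ord], function(uu) .unit_token(gt, uu), character(1))
    na_part <- if (zb == 1) "-Na" else sprintf("-%dNa", zb)
    lab <- paste0("[", paste(toks, collapse = "+"), na_part, "]",
                  .charge_suffix(zb))
    rows[[length(rows) + 1]] <- tibble(
      label = lab, ion_type = "B", charge = zb, mz = mzb,
      cleaved_units = paste(setdiff(gt$unit, sub_u), collapse = ","),
      sulfates_retained = ns_sub, parent = prec$adduct
    )
    if (include_C) {
      rows[[length(rows) + 1]] <- tibble(
        label = paste0("[", paste(toks, collapse = "+"), "+H2O", na_part, "]",
                       .charge_suffix(zb)),
        ion_type = "C", charge = zb, mz = mzb + k[["H2O"]] / zb,
        cleaved_units = paste(setdiff(gt$unit, sub_u), collapse = ","),
        sulfates_retained = ns_sub, parent = lab
      )
    }
  }
  if (n_skipped > 0) {
    rlang::inform(
      sprintf("%d sulfate-free subtree(s) cannot retain charge; B/C ions omitted.", n_skipped),
      class = "saponinMS_b_omitted"
    )
  }

  dplyr::bind_rows(rows) |>
    arrange(.data$mz, .data$label) |>
    distinct(.data$label, .data$charge, .keep_all = TRUE)
}

.insert_loss <- function(label, what) sub("\\]", paste0("-", what, "]"), label)

#' Secondary (aglycon-related) losses
#'
#' Expands a fragment list with the aglycon-dependent neutral losses:
#' CO2 (and CO2 + H2O) for lactone-bearing aglycons, acetic acid (60 Da)
#' for acetoxylated aglycons, the combined AcOH + CO2 loss (104 Da) for
#' aglycons carrying both an acetoxy group and an 18(20)-lactone, and
#' optional water loss on every fragment. Aglycon-dependent losses are
#' applied only to fragments that retain the aglycon (precursor, Y, Z).
#'
#' @param fragments Tibble from [glycosidic_ladder()].
#' @param aglycon The [aglycon()] of the fragmented glycoside.
#' @param mode `"mono"` or `"nominal"`.
#' @param water Add -H2O variants of all fragments.
#' @return The expanded, m/z-sorted, deduplicated tibble; each new row's
#'   `parent` is the label of the fragment it derives from.
#' @export
secondary_losses <- function(fragments, aglycon, mode = c("mono", "nominal"),
                             water = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(aglycon, "aglycon"))
  k <- mass_constants(mode)
  agl_rows <- fragments |> filter(.data$ion_type %in% c("precursor", "Y", "Z"))

  variant <- function(df, loss, tag, type) {
    if (nrow(df) == 0) return(NULL)
    df |>
      mutate(
        parent = .data$label,
        label = .insert_loss(.data$label, tag),
        ion_type = type,
        mz = .data$mz - loss / .data$charge
      )
  }
  out <- list(fragments)
  if (aglycon$lactone != "none") {
    out <- c(out, list(
      variant(agl_rows, k[["CO2"]], "CO2", "loss_CO2"),
      variant(agl_rows, k[["CO2"]] + k[["H2O"]], "CO2-H2O", "loss_CO2_H2O")
    ))
  }
  if (aglycon$n_acetoxy >= 1) {
    out <- c(out, list(variant(agl_rows, k[["AcOH"]], "AcOH", "loss_AcOH")))
    if (aglycon$lactone == "lac18_20") {
      out <- c(out, list(
        variant(agl_rows, k[["AcOH_CO2"]], "AcOH-CO2", "loss_AcOH_CO2")
      ))
    }
  }
  if (water) {
    out <- c(out, list(variant(fragments, k[["H2O"]], "H2O", "loss_H2O")))
  }
  dplyr::bind_rows(out) |>
    arrange(.data$mz, .data$label) |>
    distinct(.data$label, .data$charge, .keep_all = TRUE)
}

#' Sulfate-related losses and diagnostic ions
#'
#' For every multiply-charged fragment, adds the charge-reduced variant
#' from loss of the bisulfate anion HSO4- and the neutral SO3 loss at
#' unchanged charge. Always appends the diagnostic bisulfate anion at
#' m/z 96.9601 and the sulfated-monosaccharide anions (residue + SO3 - H;
#' nominal 255 MeGlc, 241 Glc, 225 Qui/MeXyl, 211 Xyl) for the sulfated
#' unit codes present in the structure.
#'
#' @param fragments Fragment tibble.
#' @param sulfated_codes Character vector of monosaccharide codes carrying
#'   sulfate in the structure (possibly with repeats); if empty the input
#'   is returned unchanged and no diagnostics are added.
#' @param mode `"mono"` or `"nominal"`.
#' @return Expanded fragment tibble.
#' @export
sulfate_losses <- function(fragments, sulfated_codes = character(),
                           mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  if (length(sulfated_codes) == 0) return(fragments)
  k <- mass_constants(mode)
  out <- list(fragments)

  multi <- fragments |> filter(.data$charge >= 2)
  if (nrow(multi) > 0) {
    out <- c(out, list(
      multi |> mutate(
        parent = .data$label,
        label = paste0(
          sub("\\].*$", "]", .insert_loss(.data$label, "HSO4")),
          vapply(.data$charge - 1L, .charge_suffix, character(1))
        ),
        ion_type = "loss_HSO4",
        mz = (.data$charge * .data$mz - k[["HSO4"]]) / (.data$charge - 1),
        charge = .data$charge - 1L,
        sulfates_retained = pmax(.data$sulfates_retained - 1L, 0L)
      ),
      multi |> mutate(
        parent = .data$label,
        label = .insert_loss(.data$label, "SO3"),
        ion_type = "loss_SO3",
        mz = .data$mz - k[["SO3"]] / .data$charge,
        sulfates_retained = pmax(.data$sulfates_retained - 1L, 0L)
      )
    ))
  }

  diag_codes <- unique(sulfated_codes)
  res <- .residue_mass(diag_codes, mode)
  out <- c(out, list(
    tibble(
      label = "[HSO4]-", ion_type = "diagnostic_HSO4", charge = 1L,
      mz = k[["HSO4_anion"]], cleaved_units = "", sulfates_retained = 1L,
      parent = NA_character_
    ),
    tibble(
      label = paste0("[", diag_codes, "SO3-Na]-"),
      ion_type = "diagnostic_sulfomonosaccharide", charge = 1L,
      mz = res + k[["SO3"]] - k[["H"]],
      cleaved_units = "", sulfates_retained = 1L, parent = NA_character_
    )
  ))
  dplyr::bind_rows(out) |>
    filter(.data$charge >= 1) |>
    arrange(.data$mz, .data$label) |>
    distinct(.data$label, .data$charge, .keep_all = TRUE)
}

#' Full theoretical CID spectrum of a glycoside
#'
#' Composes the glycosidic ladder with sulfate losses, aglycon-related
#' secondary losses, side-chain diagnostic losses (when the aglycon has a
#' known side-chain class) and, when enabled, the single 0,2-type
#' cross-ring variant (+/- C2H2O2, 58 Da nominal) on B ions.
#'
#' @inheritParams glycosidic_ladder
#' @param cross_ring Enable the 0,2-type cross-ring variants of B ions.
#' @param include_side_chain Apply the side-chain neutral-loss signature
#'   of the aglycon's class to the precursor.
#' @param water Add -H2O variants (see [secondary_losses()]).
#' @return Deterministic, duplicate-free, m/z-sorted fragment tibble with
#'   attributes `precursor` (the [precursor_mz()] row) and `mode`.
#' @export
theoretical_spectrum <- function(g, n_charges = NULL, mode = c("mono", "nominal"),
                                 cross_ring = FALSE, include_C = FALSE,
                                 include_Z = FALSE, include_side_chain = TRUE,
                                 water = TRUE) {
  mode <- match.arg(mode)
  g <- validate_glycoside(g)
  prec <- precursor_mz(g, n_charges = n_charges, mode = mode)
  k <- mass_constants(mode)

  frags <- withCallingHandlers(
    glycosidic_ladder(g, n_charges = n_charges, mode = mode,
                      include_C = include_C, include_Z = include_Z),
    saponinMS_b_omitted = function(c) invokeRestart("muffleMessage")
  )
  sulf_codes <- g$glycan$code[g$glycan$sulfated]
  frags <- sulfate_losses(frags, sulfated_codes = sulf_codes, mode = mode)
  frags <- secondary_losses(frags, g$aglycon, mode = mode, water = water)

  if (include_side_chain && !is.na(g$aglycon$side_chain_class)) {
    sig <- side_chain_losses(g$aglycon)
    prec_row <- frags |> filter(.data$ion_type == "precursor")
    sc <- prec_row[rep(1, nrow(sig)), ] |>
      mutate(
        parent = .data$label,
        label = stringr::str_replace(
          .data$label, "\\]", paste0("-", format(sig$mass, trim = TRUE), "]")
        ),
        ion_type = paste0(
          "sidechain_",
          ifelse(startsWith(sig$loss_type, "f_"), "f_series", sig$loss_type)
        ),
        mz = .data$mz - sig$mass / .data$charge
      )
    frags <- dplyr::bind_rows(frags, sc)
  }

  if (cross_ring) {
    b_rows <- frags |> filter(.data$ion_type == "B")
    if (nrow(b_rows) > 0) {
      plus <- b_rows |> mutate(
        parent = .data$label,
        label = sub("(-\\d*Na\\])", "+C2H2O2\\1", .data$label),
        ion_type = "A02",
        mz = .data$mz + k[["C2H2O2"]] / .data$charge
      )
      minus <- b_rows |> mutate(
        parent = .data$label,
        label = sub("(-\\d*Na\\])", "-C2H2O2\\1", .data$label),
        ion_type = "A02",
        mz = .data$mz - k[["C2H2O2"]] / .data$charge
      )
      frags <- dplyr::bind_rows(frags, plus, minus)
    }
  }

  out <- frags |>
    filter(.data$mz > 0) |>
    arrange(.data$mz, .data$label) |>
    distinct(.data$label, .data$charge, .keep_all = TRUE)
  attr(out, "precursor") <- prec
  attr(out, "mode") <- mode
  attr(out, "glycoside") <- g$name
  out
}
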