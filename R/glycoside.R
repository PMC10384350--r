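# Structural data model: rooted glycan trees, aglycon specifications,
# and whole glycosides, plus a plain-text round-trip format.

.LACTONES <- c("lac18_20", "lac18_16", "none")

#' Aglycon specification
#'
#' The triterpene (lanostane-type) core of a glycoside. Because published
#' fragment ladders are usually interpreted without knowing the aglycon's
#' molecular formula, the aglycon may be specified either by an elemental
#' formula or by a bare neutral monoisotopic mass (the mass of the free
#' aglycon as it sits in the glycoside, i.e. the glycoside minus all
#' glycan residues and sulfates).
#'
#' @param mass Neutral monoisotopic mass in Da (ignored if `formula` given).
#' @param formula Elemental formula string, e.g. `"C30H44O8"`.
#' @param lactone One of `"lac18_20"` (18(20)-lactone), `"lac18_16"`, `"none"`.
#' @param n_acetoxy Number of acetoxy groups.
#' @param side_chain_class Optional side-chain class id or example-compound
#'   name from [side_chain_classes()]; `NA` when unknown.
#' @return An object of class `aglycon`.
#' @export
aglycon <- function(mass = NULL, formula = NULL,
                    lactone = c("lac18_20", "lac18_16", "none"),
                    n_acetoxy = 0L, side_chain_class = NA_character_) {
  lactone <- match.arg(lactone)
  if (is.null(mass) && is.null(formula)) {
    abort("An aglycon needs either `mass` or `formula`.")
  }
  if (!is.null(formula)) parse_formula(formula)  # validate early
  if (!is.na(side_chain_class)) {
    side_chain_class <- resolve_side_chain_class(side_chain_class)
  }
  structure(
    list(
      mass = if (is.null(mass)) NA_real_ else as.numeric(mass),
      formula = formula,
      lactone = lactone,
      n_acetoxy = as.integer(n_acetoxy),
      side_chain_class = side_chain_class
    ),
    class = "aglycon"
  )
}

#' Neutral mass of an aglycon
#'
#' @param a An `aglycon`.
#' @param mode `"mono"` or `"nominal"`. With a formula the nominal mass is
#'   the rounded monoisotopic mass; with a bare mass the stored value is
#'   used unchanged in both modes (supply an integer for nominal-mode
#'   bookkeeping).
#' @return Mass in Da.
#' @export
aglycon_mass <- function(a, mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "aglycon"))
  if (!is.null(a$formula)) {
    m <- formula_mass(a$formula)
    if (mode == "nominal") round(m) else m
  } else {
    a$mass
  }
}

#' Build a glycan tree
#'
#' A rooted tree of monosaccharide units; the root is the unit attached to
#' C-3 of the aglycon. Either pass a tibble with columns `unit` (integer
#' id), `code`, `parent` (id of the parent unit, `NA` for the root),
#' `sulfated`, or a chain string such as
#' `"Xyl(S)-Qui-Glc-MeGlc | branch@2: Xyl"` (main chain root-first;
#' `(S)` marks a sulfated unit; `branch@k` attaches a side chain to the
#' k-th main-chain unit, or `branch@Code` to the first main-chain unit
#' with that code).
#'
#' @param x Chain string or tibble as described above.
#' @return A tibble of class `glycan_tree`.
#' @export
glycan_tree <- function(x) {
  if (is.character(x)) x <- .parse_glycan_string(x)
  x <- as_tibble(x)
  stopifnot(all(c("unit", "code", "parent", "sulfated") %in% names(x)))
  if (!"branch" %in% names(x)) x$branch <- "main"
  x <- x |>
    mutate(
      unit = as.integer(.data$unit),
      parent = as.integer(.data$parent),
      sulfated = as.logical(.data$sulfated)
    ) |>
    select("unit", "code", "parent", "sulfated", "branch")
  class(x) <- c("glycan_tree", class(x))
  validate_glycan(x)
}

.parse_glycan_string <- function(s) {
  parts <- strsplit(s, "\\|")[[1]]
  parts <- trimws(parts)
  main <- parts[1]
  parse_units <- function(chain) {
    toks <- trimws(strsplit(chain, "-(?![0-9])", perl = TRUE)[[1]])
    toks <- toks[toks != ""]
    sulf <- grepl("\\(S\\)$", toks)
    code <- sub("\\(S\\)$", "", toks)
    tibble(code = code, sulfated = sulf)
  }
  mu <- parse_units(main)
  units <- mu |>
    mutate(
      unit = dplyr::row_number(),
      parent = dplyr::lag(.data$unit),
      branch = "main"
    )
  bparts <- parts[-1]
  bi <- 0L
  for (bp in bparts) {
    if (!grepl("^branch@", bp)) abort(sprintf("Cannot parse branch clause '%s'.", bp))
    bi <- bi + 1L
    at <- sub("^branch@([^:]+):.*$", "\\1", bp)
    chain <- sub("^branch@[^:]+:\\s*", "", bp)
    anchor <- suppressWarnings(as.integer(at))
    if (is.na(anchor)) {
      anchor <- which(units$code == at & units$branch == "main")[1]
      if (is.na(anchor)) abort(sprintf("Branch anchor '%s' not found on the main chain.", at))
    }
    bu <- parse_units(chain)
    start <- max(units$unit)
    bu <- bu |>
      mutate(
        unit = start + dplyr::row_number(),
        parent = dplyr::lag(start + dplyr::row_number(), default = anchor),
        branch = paste0("b", bi)
      )
    units <- dplyr::bind_rows(units, bu)
  }
  units |> select("unit", "code", "parent", "sulfated", "branch")
}

#' Validate a glycan tree
#'
#' Checks tree shape (single root, acyclic, connected), the 1-6 unit and
#' <= 4 sulfate bounds, and known monosaccharide codes.
#'
#' @param gt A `glycan_tree`.
#' @param grammar If `TRUE`, additionally enforce the structural grammar of
#'   natural sea cucumber glycosides: xylose as the root unit and
#'   methylated monosaccharides only in terminal position.
#' @return `gt`, invisibly validated (errors otherwise).
#' @export
validate_glycan <- function(gt, grammar = FALSE) {
  n <- nrow(gt)
  if (n < 1 || n > 6) abort("A glycan tree must have 1-6 monosaccharide units.")
  .residue_mass(gt$code, "mono")
  if (sum(gt$sulfated) > 4) abort("At most 4 sulfate groups are allowed.")
  roots <- which(is.na(gt$parent))
  if (length(roots) != 1) abort("A glycan tree must have exactly one root unit.")
  if (anyDuplicated(gt$unit)) abort("Unit ids must be unique.")
  kids <- gt$parent[!is.na(gt$parent)]
  if (!all(kids %in% gt$unit)) abort("Every parent id must name an existing unit.")
  # connectivity / acyclicity: walk each unit to the root
  for (u in gt$unit) {
    seen <- integer(0)
    v <- u
    while (!is.na(v)) {
      if (v %in% seen) abort("Glycan tree contains a cycle.")
      seen <- c(seen, v)
      v <- gt$parent[match(v, gt$unit)]
    }
  }
  if (grammar) {
    root_code <- gt$code[is.na(gt$parent)]
    if (root_code != "Xyl") {
      abort("Grammar: xylose must be the first (aglycon-attached) unit.")
    }
    meth <- monosaccharides()$code[monosaccharides()$methylated]
    leaves <- setdiff(gt$unit, gt$parent[!is.na(gt$parent)])
    bad <- gt$unit[gt$code %in% meth & !(gt$unit %in% leaves)]
    if (length(bad) > 0) {
      abort("Grammar: methylated monosaccharides must be terminal.")
    }
  }
  invisible(gt)
}

#' Construct a glycoside
#'
#' @param name Compound name.
#' @param aglycon An [aglycon()].
#' @param glycan A [glycan_tree()] or chain string.
#' @param species,family Optional provenance (free text).
#' @param grammar Enforce the natural-product structural grammar
#'   (root xylose, methylated units terminal) on validation.
#' @return An object of class `glycoside`.
#' @export
glycoside <- function(name, aglycon, glycan, species = NA_character_,
                      family = NA_character_, grammar = FALSE) {
  if (is.character(glycan)) glycan <- glycan_tree(glycan)
  g <- structure(
    list(
      name = name, aglycon = aglycon, glycan = glycan,
      species = species, family = family, grammar = isTRUE(grammar)
    ),
    class = "glycoside"
  )
  validate_glycoside(g)
}

#' @export
print.glycoside <- function(x, ...) {
  ns <- sum(x$glycan$sulfated)
  cat(sprintf(
    "<glycoside> %s: %d units, %d sulfate(s), aglycon %s, lactone %s\n",
    x$name, nrow(x$glycan), ns,
    if (!is.null(x$aglycon$formula)) x$aglycon$formula
    else sprintf("%.4f Da", x$aglycon$mass),
    x$aglycon$lactone
  ))
  cat(" glycan:", write_glycan_string(x$glycan), "\n")
  invisible(x)
}

#' @rdname glycoside
#' @param g A `glycoside`.
#' @export
validate_glycoside <- function(g) {
  stopifnot(inherits(g, "glycoside"), inherits(g$aglycon, "aglycon"))
  validate_glycan(g$glycan, grammar = g$grammar)
  g
}

#' Serialise a glycan tree to its chain-string form
#'
#' Inverse of the string form accepted by [glycan_tree()].
#'
#' @param gt A `glycan_tree`.
#' @return A single string.
#' @export
write_glycan_string <- function(gt) {
  fmt <- function(i) paste0(gt$code[i], ifelse(gt$sulfated[i], "(S)", ""))
  main_idx <- which(gt$branch == "main")
  main <- paste(vapply(main_idx, fmt, character(1)), collapse = "-")
  out <- main
  for (b in unique(gt$branch[gt$branch != "main"])) {
    idx <- which(gt$branch == b)
    anchor_unit <- gt$parent[idx[1]]
    anchor_pos <- match(anchor_unit, gt$unit[main_idx])
    out <- paste0(
      out, " | branch@", anchor_pos, ": ",
      paste(vapply(idx, fmt, character(1)), collapse = "-")
    )
  }
  out
}

#' Read and write glycoside structure tables
#'
#' Tab-separated structure files with one glycoside per row and columns
#' `name`, `aglycon` (a bare neutral mass in Da or an elemental formula),
#' `lactone`, `n_acetoxy`, `side_chain_class`, `glycan` (chain string),
#' `species`, `family`. The round trip `read_structures(write_structures(x))`
#' is lossless.
#'
#' @param path File path.
#' @param grammar Enforce the natural-product grammar when validating.
#' @return `read_structures()`: a list of `glycoside` objects.
#' @export
read_structures <- function(path, grammar = FALSE) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  need <- c("name", "aglycon", "lactone", "n_acetoxy", "side_chain_class", "glycan")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Structure file lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  purrr::pmap(df, function(name, aglycon, lactone, n_acetoxy,
                           side_chain_class, glycan, ...) {
    extra <- list(...)
    agl_num <- suppressWarnings(as.numeric(aglycon))
    a <- if (is.na(agl_num)) {
      aglycon(formula = as.character(aglycon), lactone = lactone,
              n_acetoxy = n_acetoxy,
              side_chain_class = as.character(side_chain_class))
    } else {
      aglycon(mass = agl_num, lactone = lactone, n_acetoxy = n_acetoxy,
              side_chain_class = as.character(side_chain_class))
    }
    glycoside(
      name = name, aglycon = a, glycan = glycan,
      species = extra$species %||% NA_character_,
      family = extra$family %||% NA_character_,
      grammar = grammar
    )
  })
}

#' @rdname read_structures
#' @param glycosides List of `glycoside` objects.
#' @export
write_structures <- function(glycosides, path) {
  rows <- purrr::map_dfr(glycosides, function(g) {
    tibble(
      name = g$name,
      aglycon = if (!is.null(g$aglycon$formula)) g$aglycon$formula
                else format(g$aglycon$mass, digits = 12),
      lactone = g$aglycon$lactone,
      n_acetoxy = g$aglycon$n_acetoxy,
      side_chain_class = g$aglycon$side_chain_class %||% NA_character_,
      glycan = write_glycan_string(g$glycan),
      species = g$species, family = g$family
    )
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
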