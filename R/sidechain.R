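# Side-chain diagnostic neutral losses.
#
# For monosulfated holostane glycosides, cleavage of the aglycon side
# chain and the B-/D-rings produces a characteristic series of neutral
# losses whose masses depend on the side-chain substituents (R1..R4) and
# double-bond pattern: b1/b2 ions from retro-Diels-Alder fragmentation of
# the B-ring, f-type ions from C-20--C-22 cleavage combined with losses of
# CO2/C3H4O4/C4H6O4/C6H8O4 from the D-ring and lactone, and h-type ions
# from C-22--C-23 cleavage (loss of C5H10 and homologues), which occur
# only for side chains with a terminal 25-ene.

.SIDE_CHAIN <- local({
  t <- tibble::tribble(
    ~r1,   ~r2,  ~r3,  ~r4,  ~double_bonds, ~b1, ~b2, ~f_C6H8O4, ~f_C4H6O4, ~f_C3H4O4, ~f_CO2, ~h,  ~example,
    "OAc", "H",  "H",  "H",  "sat",         374, 362, 230,       204,       190,       130,    NA,  "Cucumarioside H7",
    "OAc", "H",  "H",  "H",  "d24",         372, 360, 228,       202,       188,       128,    NA,  "Lefevreoside B",
    "OAc", "H",  "H",  "H",  "d22E24",      370, 358, 226,       200,       NA,        NA,     NA,  "Typicoside A1",
    "OAc", "H",  "H",  "H",  "d22Z24",      370, 358, 226,       200,       NA,        NA,     NA,  "Cucumarioside H5",
    "OAc", "H",  "H",  "-",  "d25",         372, 360, 228,       202,       188,       128,    70,  "Colochiroside A1",
    "=O",  "H",  "H",  "-",  "d25",         328, 316, NA,        NA,        NA,        128,    70,  "Philinopside E",
    "H",   "H",  "H",  "-",  "d25",         314, 302, NA,        NA,        NA,        128,    70,  "Colochiroside A2",
    "H",   "H",  "H",  "H",  "d24",         314, 302, NA,        NA,        NA,        NA,     NA,  "Colochiroside A3",
    "OAc", "H",  "OH", "-",  "d25",         388, 376, 244,       218,       204,       144,    86,  "Colochiroside B1",
    "OAc", "H",  "H",  "OH", "d23",         388, 376, 244,       218,       NA,        NA,     NA,  "Colochiroside B2",
    "OAc", "H",  "=O", "-",  "d25",         386, 374, 242,       216,       202,       142,    84,  "Colochiroside B3",
    "OAc", "=O", "H",  "H",  "sat",         388, 376, 244,       218,       204,       144,    NA,  "Okhotoside A1-1",
    "OAc", "OH", "H",  "H",  "sat",         390, 378, 246,       220,       206,       NA,     NA,  "Frondoside D"
  )
  t$class_id <- paste(t$r1, t$r2, t$r3, t$r4, t$double_bonds, sep = ".")
  t[, c("class_id", "r1", "r2", "r3", "r4", "double_bonds",
        "b1", "b2", "f_C6H8O4", "f_C4H6O4", "f_C3H4O4", "f_CO2", "h", "example")]
})

#' Side-chain fragmentation classes
#'
#' The catalogue of aglycon side-chain classes with their diagnostic
#' neutral-loss signatures (nominal Da). Each class is a combination of
#' the R1..R4 substituents and the side-chain double-bond pattern
#' (`sat`, `d24`, `d22E24`, `d22Z24`, `d25`, `d23`); signature columns are
#' `b1`, `b2`, `f_C6H8O4`, `f_C4H6O4`, `f_C3H4O4`, `f_CO2` and `h`
#' (`NA` where the loss is not observed for that class). h-type losses
#' occur only for classes with a 25-ene side chain.
#'
#' @return A 13-row tibble.
#' @export
side_chain_classes <- function() .SIDE_CHAIN

#' Resolve a side-chain class identifier
#'
#' Accepts a `class_id` (e.g. `"OAc.H.H.H.d24"`) or an example compound
#' name (e.g. `"Lefevreoside B"`, case-insensitive) and returns the
#' canonical `class_id`.
#'
#' @param x Identifier string.
#' @return Canonical class id.
#' @export
resolve_side_chain_class <- function(x) {
  if (is.na(x) || x == "NA") return(NA_character_)
  t <- side_chain_classes()
  if (x %in% t$class_id) return(x)
  i <- match(tolower(x), tolower(t$example))
  if (is.na(i)) {
    abort(sprintf(
      "Unknown side-chain class '%s'. Supported class ids: %s.",
      x, paste(t$class_id, collapse = ", ")
    ))
  }
  t$class_id[i]
}

#' Diagnostic neutral-loss signature of a side-chain class
#'
#' @param aglycon An [aglycon()] with a known `side_chain_class`, or a
#'   class id / example compound name directly.
#' @param mode Mass mode; the signatures are defined at nominal (integer)
#'   precision, which is also used in `"mono"` matching with a wide
#'   tolerance.
#' @return A tibble with columns `loss_type` (`b1`, `b2`, `f_C6H8O4`,
#'   `f_C4H6O4`, `f_C3H4O4`, `f_CO2`, `h`) and `mass` (Da); absent cells
#'   of the catalogue are dropped.
#' @examples
#' side_chain_losses("Colochiroside A1")$mass  # 372 360 228 202 188 128 70
#' @export
side_chain_losses <- function(aglycon, mode = "nominal") {
  cls <- if (inherits(aglycon, "aglycon")) aglycon$side_chain_class else aglycon
  cls <- resolve_side_chain_class(cls)
  if (is.na(cls)) {
    abort("The aglycon has no side-chain class assigned.")
  }
  t <- side_chain_classes()
  row <- t[t$class_id == cls, ]
  sig_cols <- c("b1", "b2", "f_C6H8O4", "f_C4H6O4", "f_C3H4O4", "f_CO2", "h")
  out <- tibble(
    loss_type = sig_cols,
    mass = as.numeric(row[1, sig_cols])
  )
  out[!is.na(out$mass), ]
}
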