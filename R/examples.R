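# Worked-example structures used throughout the documentation and tests.

#' Reference glycoside structures
#'
#' A small set of well-characterised sulfated and non-sulfated
#' triterpene glycosides whose negative-mode fragment ladders are fully
#' worked out in the literature, plus two structural analogs of
#' cucumarioside H6 observed in *Eupentacta fraudatrix* extract. Glycan
#' sequences and sulfation follow the published structures; the aglycon
#' neutral masses are synthetic bookkeeping values back-derived from the
#' published nominal precursor m/z (the compounds' molecular formulas are
#' not part of this package), so these structures reproduce the nominal
#' fragment ladders exactly and are intended for nominal-mode use.
#'
#' @return Named list of [glycoside()] objects: `psolusoside_C1`
#'   (`[M-H]-` 1407, non-sulfated branched hexaoside),
#'   `psolusoside_E` (`[M-Na]-` 1163, monosulfated linear tetraoside),
#'   `psolusoside_A` (`[M-2Na]2-` 621, disulfated linear tetraoside),
#'   `cucumarioside_H6` (`[M-Na]-` 1309, monosulfated branched
#'   pentaoside) and its analogs `feature_639` (terminal MeXyl replaced
#'   by Glc) and `feature_657` (terminal MeXyl replaced by MeGlc).
#' @export
reference_glycosides <- function() {
  list(
    psolusoside_C1 = glycoside(
      name = "psolusoside C1",
      aglycon = aglycon(mass = 498, lactone = "lac18_20", n_acetoxy = 0L),
      glycan = "Xyl-Glc-Glc-MeGlc | branch@2: Qui-Xyl",
      species = "Psolus fabricii", grammar = TRUE
    ),
    psolusoside_E = glycoside(
      name = "psolusoside E",
      aglycon = aglycon(mass = 468, lactone = "lac18_20", n_acetoxy = 0L),
      glycan = "Xyl-Qui-Glc(S)-MeGlc",
      species = "Psolus fabricii", grammar = TRUE
    ),
    psolusoside_A = glycoside(
      name = "psolusoside A",
      aglycon = aglycon(mass = 468, lactone = "lac18_20", n_acetoxy = 0L),
      glycan = "Xyl-Qui-Glc(S)-MeGlc(S)",
      species = "Psolus fabricii", grammar = TRUE
    ),
    cucumarioside_H6 = glycoside(
      name = "cucumarioside H6",
      aglycon = aglycon(mass = 512, lactone = "lac18_20", n_acetoxy = 1L,
                        side_chain_class = "Lefevreoside B"),
      glycan = "Xyl(S)-Qui-Glc-MeXyl | branch@2: Xyl",
      species = "Eupentacta fraudatrix", grammar = TRUE
    ),
    feature_639 = glycoside(
      name = "feature 639 (H6 analog, MeXyl -> Glc)",
      aglycon = aglycon(mass = 512, lactone = "lac18_20", n_acetoxy = 1L,
                        side_chain_class = "Lefevreoside B"),
      glycan = "Xyl(S)-Qui-Glc-Glc | branch@2: Xyl",
      species = "Eupentacta fraudatrix", grammar = TRUE
    ),
    feature_657 = glycoside(
      name = "feature 657 (H6 analog, MeXyl -> MeGlc)",
      aglycon = aglycon(mass = 512, lactone = "lac18_20", n_acetoxy = 1L,
                        side_chain_class = "Lefevreoside B"),
      glycan = "Xyl(S)-Qui-Glc-MeGlc | branch@2: Xyl",
      species = "Eupentacta fraudatrix", grammar = TRUE
    )
  )
}

#' Bundled dereplication reference table
#'
#' Curated reference values for 27 triterpene glycosides dereplicated
#' from an *Eupentacta fraudatrix* extract against an authentic-standard
#' library: library and observed retention times, calculated and measured
#' precursor m/z, the reported ppm error and the reported library match
#' score. Used to exercise the ppm-error arithmetic and the
#' retention-time gate at realistic values.
#'
#' @return A tibble.
#' @export
dereplication_reference <- function() {
  path <- system.file("extdata", "efraudatrix_matches.tsv",
                      package = "saponinMS", mustWork = TRUE)
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
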