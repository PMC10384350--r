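test_that("Y-series of a linear chain equals brute-force prefix removal", {
  for (k in 1:6) {
    g <- linear_glycoside(k)
    lad <- suppressMessages(glycosidic_ladder(g, mode = "mono"))
    yy <- lad[lad$ion_type == "Y", ]
    # a k-unit unbranched chain has exactly k Y ions (one per prefix)
    expect_identical(nrow(yy), k)
    res <- monosaccharides()$mass[match(rev(g$glycan$code), monosaccharides()$code)]
    prec <- precursor_mz(g)$mz
    expect_equal(sort(yy$mz), sort(unname(prec - cumsum(res))), tolerance = 1e-9)
  }
})

test_that("single-unit sulfate-free glycan: one Y ion, no B ions", {
  g <- linear_glycoside(1)
  expect_message(lad <- glycosidic_ladder(g), "omitted")
  expect_identical(nrow(lad[lad$ion_type == "B", ]), 0L)
  yy <- lad[lad$ion_type == "Y", ]
  expect_identical(nrow(yy), 1L)
  expect_equal(yy$mz, precursor_mz(g)$mz - 132.04226, tolerance = 1e-4)
})

test_that("combined Y cleavages match the enumeration of removable sets", {
  # one branch point: arms of 2 and 2 above a 2-unit stem
  g <- glycoside(
    "branched", aglycon(mass = 480, lactone = "none"),
    "Xyl-Qui-Glc-MeGlc | branch@2: Glc-MeXyl"
  )
  sets <- removable_unit_sets(g$glycan)
  ref <- ref_removable_sets(g$glycan$unit, g$glycan$parent)
  expect_identical(length(sets), length(ref))
  canon <- function(l) sort(vapply(l, function(s) paste(sort(s), collapse = ","), ""))
  expect_identical(canon(sets), canon(ref))
  # every removable set yields a Y ion; isobaric compositions (same lost
  # residue multiset) collapse into a single labelled fragment
  lad <- suppressMessages(glycosidic_ladder(g))
  comp_of <- function(s) paste(sort(g$glycan$code[match(s, g$glycan$unit)]),
                               collapse = "+")
  n_distinct_comp <- length(unique(vapply(ref, comp_of, "")))
  expect_identical(nrow(lad[lad$ion_type == "Y", ]), n_distinct_comp)
})

test_that("Y fragments conserve mass against the cleaved residues", {
  g <- glycoside(
    "cons", aglycon(mass = 512.3456, lactone = "lac18_20"),
    "Xyl-Glc-Qui-MeGlc | branch@2: Xyl"
  )
  lad <- suppressMessages(glycosidic_ladder(g, mode = "mono"))
  prec <- precursor_mz(g)$mz
  tab <- monosaccharides()
  for (r in which(lad$ion_type == "Y")) {
    ids <- as.integer(strsplit(lad$cleaved_units[r], ",")[[1]])
    res <- sum(tab$mass[match(g$glycan$code[match(ids, g$glycan$unit)], tab$code)])
    expect_equal(prec - lad$mz[r], res, tolerance = 1e-6)
  }
})

test_that("secondary losses depend on the aglycon features", {
  g_plain <- linear_glycoside(2)
  lad <- suppressMessages(glycosidic_ladder(g_plain))
  # lactone-free, acetoxy-free: only the optional water losses appear
  out <- secondary_losses(lad, g_plain$aglycon, water = FALSE)
  expect_identical(out$label, lad$label)
  # acetoxy + 18(20)-lactone: the -104 variant is the -60 variant minus CO2
  a <- aglycon(mass = 500, lactone = "lac18_20", n_acetoxy = 1)
  out2 <- secondary_losses(lad, a, mode = "mono")
  m60 <- out2$mz[out2$ion_type == "loss_AcOH" & out2$parent == "[M-H]-"]
  m104 <- out2$mz[out2$ion_type == "loss_AcOH_CO2" & out2$parent == "[M-H]-"]
  expect_equal(m104, m60 - formula_mass("CO2"), tolerance = 1e-6)
  # 18(16)-lactone gets CO2 losses but not the combined 104 loss
  a16 <- aglycon(mass = 500, lactone = "lac18_16", n_acetoxy = 1)
  out3 <- secondary_losses(lad, a16)
  expect_true("loss_CO2" %in% out3$ion_type)
  expect_false("loss_AcOH_CO2" %in% out3$ion_type)
})

test_that("sulfate losses: charge reduction, diagnostics, and the null case", {
  g <- reference_glycosides()$psolusoside_A
  lad <- glycosidic_ladder(g, n_charges = 2, mode = "nominal")
  out <- sulfate_losses(lad, sulfated_codes = c("Glc", "MeGlc"), mode = "nominal")
  # dianion 621 -> singly charged 1145 after bisulfate loss
  expect_true(any(out$ion_type == "loss_HSO4" & round(out$mz) == 1145 &
                    out$charge == 1))
  # diagnostics: bisulfate and the sulfated monosaccharides present
  expect_true(any(out$ion_type == "diagnostic_HSO4" &
                    abs(out$mz - 96.9601) < 1e-6))
  expect_true(any(round(out$mz) == 241 &
                    out$ion_type == "diagnostic_sulfomonosaccharide"))
  expect_true(any(round(out$mz) == 255 & out$charge == 1))
  # no sulfates: input returned unchanged, no 96.96 ion
  lad0 <- suppressMessages(glycosidic_ladder(linear_glycoside(3)))
  expect_identical(sulfate_losses(lad0, character()), lad0)
})

test_that("cross-ring variants are config-gated and shift B ions by C2H2O2", {
  g <- reference_glycosides()$psolusoside_E
  off <- theoretical_spectrum(g, mode = "nominal", cross_ring = FALSE)
  on <- theoretical_spectrum(g, mode = "nominal", cross_ring = TRUE)
  expect_false(475 %in% round(off$mz))
  expect_true(475 %in% round(on$mz))
  # everything generated without cross-ring is still there with it
  expect_true(all(off$label %in% on$label))
})

test_that("theoretical spectra are sorted, deduplicated and bounded", {
  for (g in reference_glycosides()[c("psolusoside_C1", "psolusoside_A")]) {
    sp <- theoretical_spectrum(g, mode = "mono", cross_ring = TRUE)
    expect_false(is.unsorted(sp$mz))
    expect_identical(anyDuplicated(sp[, c("label", "charge")]), 0L)
    prec <- attr(sp, "precursor")
    expect_true(all(sp$mz > 0))
    expect_true(all(sp$mz <= prec$charge * prec$mz + 1))
  }
})
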