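test_that("sulfation inference follows charge and diagnostic-ion rules", {
  # multiply-charged precursor: estimate equals the charge
  g <- reference_glycosides()$psolusoside_A
  sp <- toy_spectrum(
    mz = c(96.96, 255, 987, 1145), precursor = 621, charge = 2L, id = "psA"
  )
  est <- infer_sulfation(sp, mode = "nominal")
  expect_identical(est$estimate, 2L)
  expect_true(any(grepl("multiply-charged", est$evidence[[1]]$rule)))
  # z = 1 with no diagnostic within tolerance: 0
  clean <- toy_spectrum(mz = c(500, 700, 900), precursor = 1000)
  expect_identical(infer_sulfation(clean)$estimate, 0L)
  # z = 1 with the bisulfate ion: at least one sulfate
  s1 <- toy_spectrum(mz = c(96.9601, 500), precursor = 1000)
  expect_identical(infer_sulfation(s1)$estimate, 1L)
  # simulated trisulfated spectrum recovers 3 from its charge
  set.seed(5)
  tri <- glycoside("tri", aglycon(mass = 500, lactone = "lac18_20"),
                   "Xyl(S)-Qui(S)-Glc(S)-MeGlc")
  sp3 <- simulate_spectrum(tri)
  expect_identical(infer_sulfation(sp3)$estimate, 3L)
  expect_error(infer_sulfation(toy_spectrum(1, precursor = NA)), "precursor")
})

test_that("two-peak ladder gives a single one-step MeGlc candidate", {
  sp <- toy_spectrum(mz = c(824, 1000), precursor = 1000)
  cand <- sequence_glycan(sp, mode = "nominal")
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$sequence, "MeGlc")
  expect_identical(cand$n_steps, 1L)
})

test_that("published nominal peak list yields the MeGlc-then-Xyl ladder", {
  mz <- c(1407, 1363, 1231, 1213, 1187, 1169, 1099, 1081, 1055, 1037)
  int <- c(20, 30, 100, 30, 30, 30, 100, 30, 30, 30)  # Y series intense
  sp <- toy_spectrum(mz = mz, intensity = int, precursor = 1407, id = "psC1")
  cand <- sequence_glycan(sp, mode = "nominal")
  expect_identical(cand$sequence[1], "MeGlc-Xyl")
})

test_that("aglycon feature flags respond to the published loss rules", {
  mz <- c(1407, 1363, 1231, 1213, 1099)
  sp <- toy_spectrum(mz = mz, precursor = 1407, id = "psC1")
  fl <- detect_aglycon_features(sp, mode = "nominal")
  expect_true(fl$lactone_co2_loss)   # 1407 -> 1363
  expect_true(fl$water_losses)       # 1231 -> 1213
  expect_false(fl$acetoxy_60)
  expect_false(fl$acetoxy_lactone_104)
  # residue-difference-only spectrum: all flags false
  sp2 <- toy_spectrum(mz = c(1407, 1231, 1099), precursor = 1407)
  fl2 <- detect_aglycon_features(sp2, mode = "nominal")
  expect_false(any(unlist(fl2[, 1:4])))
  # simulated acetoxy + 18(20)-lactone structure sets both 60 and 104
  set.seed(8)
  g <- glycoside("oac", aglycon(mass = 520, lactone = "lac18_20",
                                n_acetoxy = 1), "Xyl-Qui-Glc-MeGlc")
  fl3 <- detect_aglycon_features(simulate_spectrum(g))
  expect_true(fl3$acetoxy_60)
  expect_true(fl3$acetoxy_lactone_104)
})

test_that("side-chain classification ranks the published signatures", {
  prec <- 1163
  mk <- function(losses) toy_spectrum(mz = prec - losses, precursor = prec)
  # full 25-ene acetoxy signature: its class ranks first, alone
  r1 <- classify_side_chain(mk(c(372, 360, 228, 202, 188, 128, 70)))
  expect_identical(r1$example[1], "Colochiroside A1")
  expect_identical(sum(r1$rank == 1), 1L)
  # the 5-loss series characteristic of a Delta-24 side chain
  r2 <- classify_side_chain(mk(c(128, 202, 228, 360, 372)))
  expect_identical(r2$example[1], "Lefevreoside B")
  expect_identical(sum(r2$rank == 1), 1L)
  # empty loss set: every class scores zero
  r3 <- classify_side_chain(toy_spectrum(mz = prec, precursor = prec))
  expect_true(all(r3$hits == 0))
})

test_that("fragmenter output ranks its own side-chain class first (all 13)", {
  classes <- side_chain_classes()
  for (i in seq_len(nrow(classes))) {
    g <- glycoside(
      paste0("cls", i),
      aglycon(mass = 505, lactone = "lac18_20",
              n_acetoxy = as.integer(classes$r1[i] == "OAc"),
              side_chain_class = classes$class_id[i]),
      "Xyl(S)-Qui-Glc-MeGlc"
    )
    set.seed(100 + i)
    sp <- simulate_spectrum(g)
    rk <- classify_side_chain(sp)
    top <- rk$class_id[rk$rank == 1]
    expect_true(classes$class_id[i] %in% top,
                label = sprintf("class %s in top rank", classes$class_id[i]))
  }
})

test_that("analog hypotheses use the characteristic difference table", {
  lib <- tibble::tibble(
    id = c("H6-like", "other", "far"),
    precursor_mz = c(1309, 1307, 900)
  )
  # +16: additional oxygen vs the H6-like record
  out <- annotate_analogs(1325, lib, tol = 0.02, mode = "nominal")
  expect_true(any(out$record_id == "H6-like" & out$matched_difference == 16 &
                    out$direction == "gain"))
  expect_true(any(out$record_id == "other" & out$matched_difference == 18))
  expect_false("far" %in% out$record_id)
  # +176: extra methylglucose (both signs must work)
  out2 <- annotate_analogs(1483, tibble::tibble(id = "x", precursor_mz = 1307),
                           mode = "nominal")
  expect_identical(out2$matched_difference, 176)
  out2b <- annotate_analogs(1307, tibble::tibble(id = "x", precursor_mz = 1483),
                            mode = "nominal")
  expect_identical(out2b$direction, "loss")
  # equal precursor: exact channel, never an analog difference
  out3 <- annotate_analogs(1309, lib, mode = "nominal")
  expect_identical(out3$channel[out3$record_id == "H6-like"], "exact")
})

test_that("noiseless composition recovery over random structures", {
  lib <- simulate_library(30, seed = 42)
  ok <- 0
  for (i in seq_along(lib$structures)) {
    comp <- estimate_composition(lib$spectra[[i]])
    if (identical(comp_masses(comp$code),
                  comp_masses(lib$structures[[i]]$glycan$code))) ok <- ok + 1
  }
  expect_gte(ok / 30, 0.95)
  # sulfate counts exact for all multiply-charged cases
  for (i in seq_along(lib$structures)) {
    ns <- sum(lib$structures[[i]]$glycan$sulfated)
    if (ns >= 2) {
      expect_identical(infer_sulfation(lib$spectra[[i]])$estimate, as.integer(ns))
    }
  }
})

test_that("annotation report assembles all evidence channels", {
  set.seed(21)
  g <- reference_glycosides()$cucumarioside_H6
  sp <- simulate_spectrum(g)
  lib <- tibble::tibble(id = "H6", precursor_mz = sp$precursor_mz + 16)
  a <- annotate(sp, library = lib)
  expect_s3_class(a, "saponin_annotation")
  expect_identical(a$sulfation$estimate, 1L)
  expect_true(nrow(a$glycan_candidates) >= 1)
  expect_true(a$aglycon_flags$acetoxy_60)
  td <- tidy(a)
  expect_true(all(c("component", "rule", "value") %in% names(td)))
  gl <- glance(a)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$sulfate_estimate, 1L)
})
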