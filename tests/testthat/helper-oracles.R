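# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results by enumeration rather than calling
# the package's own algorithms.

# Exhaustive optimal-assignment cosine: enumerates every one-to-one
# matching of candidate peak pairs and maximises the summed weight.
ref_assignment_cosine <- function(mza, ia, mzb, ib, tol, shift = 0) {
  wa <- sqrt(ia); wb <- sqrt(ib)
  cand <- list()
  for (i in seq_along(mza)) {
    for (j in seq_along(mzb)) {
      if (abs(mzb[j] - mza[i]) <= tol ||
          (shift != 0 && abs(mzb[j] - mza[i] - shift) <= tol)) {
        cand[[length(cand) + 1]] <- c(i, j)
      }
    }
  }
  best <- 0
  recurse <- function(k, used_i, used_j, acc) {
    if (acc > best) best <<- acc
    if (k > length(cand)) return()
    recurse(k + 1, used_i, used_j, acc)  # skip pair k
    p <- cand[[k]]
    if (!(p[1] %in% used_i) && !(p[2] %in% used_j)) {
      recurse(k + 1, c(used_i, p[1]), c(used_j, p[2]),
              acc + wa[p[1]] * wb[p[2]])
    }
  }
  recurse(1, integer(0), integer(0), 0)
  denom <- sqrt(sum(ia)) * sqrt(sum(ib))
  if (denom == 0) 0 else best / denom
}

# Independent enumeration of descendant-closed (removable) unit sets of a
# glycan tree given as a tibble with columns unit/parent.
ref_removable_sets <- function(units, parents) {
  n <- length(units)
  out <- list()
  for (mask in 1:(2^n - 1)) {
    s <- units[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ok <- TRUE
    for (k in seq_len(n)) {
      # every child of a member must be a member
      if (!is.na(parents[k]) && parents[k] %in% s && !(units[k] %in% s)) {
        ok <- FALSE; break
      }
    }
    if (ok) out[[length(out) + 1]] <- sort(s)
  }
  out
}

# Linear unbranched test chain: root Xyl, interior Glc, terminal MeGlc
# (or shorter prefixes of that pattern).
linear_glycoside <- function(k, aglycon_mass = 500, sulf_root = FALSE) {
  codes <- if (k == 1) "Xyl" else c("Xyl", rep("Glc", k - 2), "MeGlc")
  units <- tibble::tibble(
    unit = seq_len(k), code = codes,
    parent = c(NA_integer_, seq_len(k - 1))[seq_len(k)],
    sulfated = c(sulf_root, rep(FALSE, k - 1)), branch = "main"
  )
  glycoside(
    name = sprintf("linear_%d", k),
    aglycon = aglycon(mass = aglycon_mass, lactone = "none"),
    glycan = glycan_tree(units)
  )
}

toy_spectrum <- function(mz, intensity = rep(100, length(mz)),
                         precursor = max(mz), charge = 1L, rt = NA_real_,
                         id = "toy") {
  ms_spectrum(mz, intensity, precursor_mz = precursor, charge = charge,
              rt = rt, id = id)
}

# Brute-force reference for the three molecular-network edge filters,
# given precomputed scores.
ref_filter_edges <- function(scores, cosine_min, min_matched, top_k) {
  e <- scores[scores$s > cosine_min & scores$m >= min_matched, , drop = FALSE]
  if (nrow(e) == 0) return(e)
  keep <- rep(TRUE, nrow(e))
  for (r in seq_len(nrow(e))) {
    for (node in c(e$a[r], e$b[r])) {
      inc <- e[e$a == node | e$b == node, , drop = FALSE]
      inc <- inc[order(-inc$s, -inc$m,
                       ifelse(inc$a == node, inc$b, inc$a)), , drop = FALSE]
      rr <- which(inc$a == e$a[r] & inc$b == e$b[r])
      if (rr > top_k) keep[r] <- FALSE
    }
  }
  e[keep, , drop = FALSE]
}

# Composition comparison helper: residue nominal-mass multisets, with the
# Qui/MeXyl ambiguity collapsed by mass.
comp_masses <- function(codes) {
  sort(residue_nominal_mass(sub("[|].*", "", codes)))
}

mini_mzml <- function(path, mz, intensity, precursor = 1163.45, charge = 1,
                      rt_min = 8.4) {
  enc <- function(x) jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                   size = 8, endian = "little"))
  xml <- sprintf(
    '<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="x"/></cvList>
  <fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>
  <softwareList count="1"><software id="sw" version="1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="1" defaultDataProcessingRef="dp">
      <spectrum index="0" id="scan=1" defaultArrayLength="%d">
        <cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>
        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>
        <cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>
        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>
        <scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%f" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan></scanList>
        <precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>
          <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%f"/>
          <cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>
        </selectedIon></selectedIonList></precursor></precursorList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/><binary>%s</binary></binaryDataArray>
          <binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/><binary>%s</binary></binaryDataArray>
        </binaryDataArrayList>
      </spectrum>
    </spectrumList>
  </run>
</mzML>',
    length(mz), rt_min, precursor, charge,
    nchar(enc(mz)), enc(mz), nchar(enc(intensity)), enc(intensity)
  )
  writeLines(xml, path)
  path
}
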