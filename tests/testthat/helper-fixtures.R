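# small unit-width grid starting at 0, for hand-checkable vectors
toy_config <- function(n) bin_config(mz_min = 0, mz_max = n, bin_width = 1)

# binned spectrum holding exactly the dense vector `values`
toy_spectrum <- function(values, config = toy_config(length(values))) {
  binned_spectrum(config, seq_along(values) - 1L, values)
}

toy_series <- function(mat, label = "toy", config = toy_config(nrow(mat))) {
  # columns of `mat` are scans
  binned_series(label, lapply(seq_len(ncol(mat)), function(j) {
    toy_spectrum(mat[, j], config)
  }))
}

# dense-arithmetic oracles, independent of the sparse implementation
oracle_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / (sqrt(sum(dx^2)) * sqrt(sum(dy^2)))
}
oracle_cosine <- function(x, y) {
  sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
}

random_sparse_values <- function(n_bins, n_nonzero) {
  v <- numeric(n_bins)
  v[sample.int(n_bins, n_nonzero)] <- stats::rlnorm(n_nonzero, log(10), 1)
  v
}

# minimal mzML writer for reader tests (uncompressed 64-bit little-endian)
write_test_mzml <- function(path, scans, centroided = TRUE) {
  enc <- function(x) {
    jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                  endian = "little"))
  }
  if (length(centroided) == 1L) centroided <- rep(centroided, length(scans))
  spec_xml <- function(i, mz, inten, cent) {
    mode <- if (cent) {
      'accession="MS:1000127" name="centroid spectrum"'
    } else {
      'accession="MS:1000128" name="profile spectrum"'
    }
    bmz <- enc(mz)
    bint <- enc(inten)
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<cvParam cvRef="MS" %s value=""/>',
      '<scanList count="1">',
      '<cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
      '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" ',
      'value="%f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'
    ), i, i + 1L, length(mz), mode, i * 1.0,
    nchar(bmz), bmz, nchar(bint), bint)
  }
  body <- paste0(vapply(seq_along(scans), function(k) {
    spec_xml(k - 1L, scans[[k]]$mz, scans[[k]]$intensity, centroided[k])
  }, character(1)), collapse = "\n")
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://unit-ontology.example/uo.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">\n',
            length(scans)),
    body,
    '\n</spectrumList>\n</run>\n</mzML>'
  )
  writeLines(xml, path)
  invisible(path)
}
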