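#' Default chromatogram naming dialect
#'
#' Maps the chromatogram ids written by common RAW-to-mzML converters to
#' the package's detector labels. Both `$`- and `_`-separated spellings of
#' the PDA/CAD ids occur in the wild, so both are accepted.
#'
#' @return A named character vector: mzML chromatogram id -> detector label.
#' @export
cad_dialect <- function() {
  c(
    "BasePeak_0" = "BPI",
    "PDA.1$TotalAbsorbance_0" = "PDA",
    "PDA.1_TotalAbsorbance_0" = "PDA",
    "UV.1$CAD_1_0" = "CAD",
    "UV.1_CAD_1_0" = "CAD"
  )
}

#' Read multi-detector chromatograms from mzML
#'
#' Reads the chromatogram list of an mzML file (spectra are ignored),
#' keeping the chromatograms whose ids the dialect recognizes and warning
#' about the rest. Times are normalized to minutes using the time-array
#' unit accession recorded in the file (converters emit seconds or
#' minutes); this conversion happens exactly once, here at the boundary.
#' A missing CAD chromatogram is not an error — the set is still returned
#' and CAD-dependent steps refuse later.
#'
#' @param path Path to an mzML file with a chromatogram list.
#' @param dialect Named character vector mapping chromatogram ids to
#'   detector labels (default [cad_dialect()]).
#' @return A chromatogram set tibble (`detector_id`, `time` in minutes,
#'   `intensity`) with attributes `source_path` and `cad_present`.
#' @export
read_chromatograms <- function(path, dialect = cad_dialect()) {
  if (!file.exists(path)) abort(sprintf("mzML file not found: %s", path))
  units <- mzml_time_units(path)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::chromatogramHeader(handle)
  if (nrow(hdr) == 0L) abort(sprintf("no chromatogram list in %s", path))

  traces <- purrr::map(seq_len(nrow(hdr)), function(i) {
    id <- hdr$chromatogramId[i]
    det <- unname(dialect[id])
    if (is.na(det)) {
      warn(sprintf("ignoring unrecognized chromatogram `%s`.", id))
      return(NULL)
    }
    raw <- mzR::chromatogram(handle, hdr$chromatogramIndex[i])
    t <- raw[[1]]
    if (identical(units[[id]] %||% "minute", "second")) t <- t / 60
    tibble(detector_id = det, time = t, intensity = raw[[2]])
  })
  out <- purrr::list_rbind(purrr::compact(traces))
  if (is.null(out) || nrow(out) == 0L) {
    abort(sprintf("no recognized chromatograms in %s", path))
  }
  dups <- out |> distinct(detector_id)
  attr(out, "source_path") <- path
  attr(out, "cad_present") <- "CAD" %in% dups$detector_id
  if (!attr(out, "cad_present")) {
    warn("no CAD chromatogram found; CAD-dependent steps will refuse to run.")
  }
  out
}

# the pwiz backend does not expose chromatogram time units, so pull the
# time-array unit accession per chromatogram id straight from the XML
mzml_time_units <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(m = "http://psi.hupo.org/ms/mzml")
  chroms <- xml2::xml_find_all(doc, ".//m:chromatogram", ns)
  units <- purrr::map_chr(chroms, function(ch) {
    cv <- xml2::xml_find_first(
      ch,
      ".//m:binaryDataArray[m:cvParam[@accession='MS:1000595']]/m:cvParam[@accession='MS:1000595']",
      ns
    )
    u <- xml2::xml_attr(cv, "unitName")
    if (is.na(u)) "minute" else u
  })
  setNames(as.list(units), xml2::xml_attr(chroms, "id"))
}

#' Write a minimal chromatogram-only mzML fixture
#'
#' Writes the traces of a chromatogram set as an mzML chromatogram list
#' (64-bit floats, no compression, times in seconds as converters emit
#' them). This is deliberately minimal fixture support — enough for
#' [read_chromatograms()] and other mzML chromatogram readers — not a
#' general mzML writer.
#'
#' @param chromatograms Chromatogram set tibble (`detector_id`, `time` in
#'   minutes, `intensity`).
#' @param path Output path.
#' @param dialect Detector label -> chromatogram id map; defaults to the
#'   inverse of [cad_dialect()] (canonical `$` spellings).
#' @return `path`, invisibly.
#' @export
write_fixture_mzml <- function(chromatograms, path,
                               dialect = c(
                                 BPI = "BasePeak_0",
                                 PDA = "PDA.1$TotalAbsorbance_0",
                                 CAD = "UV.1$CAD_1_0"
                               )) {
  dets <- unique(chromatograms$detector_id)
  enc <- function(x) {
    # base64_enc wraps lines; the binary element must be a single token
    gsub("\n", "", jsonlite::base64_enc(
      writeBin(as.double(x), raw(), size = 8, endian = "little")
    ), fixed = TRUE)
  }
  chrom_xml <- purrr::imap_chr(dets, function(det, i) {
    tr <- chromatograms[chromatograms$detector_id == det, ]
    id <- dialect[det]
    if (is.na(id)) id <- det
    tsec <- enc(tr$time * 60)
    ints <- enc(tr$intensity)
    sprintf(
      paste0(
        '<chromatogram index="%d" id="%s" defaultArrayLength="%d">',
        '<binaryDataArrayList count="2">',
        '<binaryDataArray encodedLength="%d">',
        '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000595" name="time array" value="" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>',
        '<binary>%s</binary></binaryDataArray>',
        '<binaryDataArray encodedLength="%d">',
        '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
        '<binary>%s</binary></binaryDataArray>',
        "</binaryDataArrayList></chromatogram>"
      ),
      i - 1L, xml_escape(id), nrow(tr),
      nchar(tsec), tsec, nchar(ints), ints
    )
  })
  doc <- sprintf(
    paste0(
      '<?xml version="1.0" encoding="utf-8"?>\n',
      '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="cadlink_fixture">',
      '<cvList count="2">',
      '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
      '<cv id="UO" fullName="UNIT-ONTOLOGY" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
      "</cvList>",
      '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000524" name="data file content" value=""/></fileContent></fileDescription>',
      '<softwareList count="1"><software id="sw" version="0.1.0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="cadlink"/></software></softwareList>',
      '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
      '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
      '<run id="run" defaultInstrumentConfigurationRef="ic">',
      '<chromatogramList count="%d" defaultDataProcessingRef="dp">%s</chromatogramList>',
      "</run></mzML></indexedmzML>\n"
    ),
    length(dets), paste(chrom_xml, collapse = "")
  )
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
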