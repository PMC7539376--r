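# Minimal writers for the two open MS XML dialects. They emit only what a
# reader needs — scan metadata plus uncompressed 64-bit peak arrays — and
# exist so synthetic runs can exercise the real parsing path end to end.

b64_doubles <- function(x, endian) {
  # base64_enc wraps long output; the binary containers need one line
  gsub("[\r\n]", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8L, endian = endian)))
}

#' Write a SpectraRun as minimal mzML 1.1
#'
#' Peak arrays are stored as uncompressed little-endian 64-bit floats;
#' retention times are written in minutes with an explicit unit accession
#' (readers must convert back to seconds). The output is valid enough for
#' standard mzML readers, not a full vendor-grade document.
#'
#' @param run A `SpectraRun`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "SpectraRun"))
  sp <- character(length(run$scans))
  for (i in seq_along(run$scans)) {
    s <- run$scans[[i]]
    mzb <- b64_doubles(s$peaks[, 1L], "little")
    inb <- b64_doubles(s$peaks[, 2L], "little")
    sp[i] <- sprintf('
  <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">
    <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>
    <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>
    <scanList count="1">
      <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>
      <scan>
        <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.10g" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>
      </scan>
    </scanList>
    <binaryDataArrayList count="2">
      <binaryDataArray encodedLength="%d">
        <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
        <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
        <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
        <binary>%s</binary>
      </binaryDataArray>
      <binaryDataArray encodedLength="%d">
        <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
        <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
        <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
        <binary>%s</binary>
      </binaryDataArray>
    </binaryDataArrayList>
  </spectrum>',
      i - 1L, s$scan_index, nrow(s$peaks), s$ms_level,
      s$retention_time / 60, nchar(mzb), mzb, nchar(inb), inb)
  }
  xml <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
    </fileContent>
  </fileDescription>
  <softwareList count="1"><software id="sw" version="0"/></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC"/></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"/></dataProcessing></dataProcessingList>
  <run id="%s" defaultInstrumentConfigurationRef="IC">
    <spectrumList count="%d" defaultDataProcessingRef="dp">%s
    </spectrumList>
  </run>
</mzML>', run$run_id, length(run$scans), paste(sp, collapse = ""))
  writeLines(xml, path)
  invisible(path)
}

#' Write a SpectraRun as minimal mzXML 3.2
#'
#' Peaks are the interleaved (m/z, intensity) pairs of the dialect, 64-bit
#' network (big-endian) byte order, no compression; retention times use the
#' `PT<sec>S` duration form.
#'
#' @param run A `SpectraRun`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(run, path) {
  stopifnot(inherits(run, "SpectraRun"))
  sp <- character(length(run$scans))
  for (i in seq_along(run$scans)) {
    s <- run$scans[[i]]
    pk <- b64_doubles(as.numeric(rbind(s$peaks[, 1L], s$peaks[, 2L])), "big")
    sp[i] <- sprintf('
  <scan num="%d" msLevel="%d" peaksCount="%d" retentionTime="PT%.10gS">
   <peaks precision="64" byteOrder="network" contentType="m/z-int" compressionType="none" compressedLen="0">%s</peaks>
  </scan>', s$scan_index, s$ms_level, nrow(s$peaks), s$retention_time, pk)
  }
  xml <- sprintf('<?xml version="1.0" encoding="ISO-8859-1"?>
<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2"
 xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"
 xsi:schemaLocation="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2 http://sashimi.sourceforge.net/schema_revision/mzXML_3.2/mzXML_idx_3.2.xsd">
 <msRun scanCount="%d">%s
 </msRun>
</mzXML>', length(run$scans), paste(sp, collapse = ""))
  writeLines(xml, path)
  invisible(path)
}
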