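# Minimal uncompressed mzML writer for S2I reader fixtures. Each spectrum is
# list(scan=, mslevel=, mz=, intensity=, precursor=NULL|list(ms1scan, center,
# lower, upper, mz, charge)).

write_toy_mzml <- function(path, spectra) {
  b64d <- function(x)
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  one <- function(index, s) {
    prec <- ""
    if (!is.null(s$precursor)) {
      p <- s$precursor
      prec <- sprintf('
      <precursorList count="1"><precursor spectrumRef="controllerType=0 controllerNumber=1 scan=%d">
        <isolationWindow>
          <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
          <cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="%f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
          <cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="%f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
        </isolationWindow>
        <selectedIonList count="1"><selectedIon>
          <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
          <cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>
        </selectedIon></selectedIonList>
        <activation><cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation" value=""/></activation>
      </precursor></precursorList>',
        p$ms1scan, p$center, p$lower, p$upper, p$mz, p$charge)
    }
    mzb <- b64d(s$mz); inb <- b64d(s$intensity)
    sprintf('<spectrum index="%d" id="controllerType=0 controllerNumber=1 scan=%d" defaultArrayLength="%d">
    <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>
    <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>
    <cvParam cvRef="MS" accession="MS:1000%s" name="MS%d spectrum" value=""/>
    <scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%f" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan></scanList>%s
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
      index, s$scan, length(s$mz), s$mslevel,
      if (s$mslevel == 1) "579" else "580", s$mslevel, index * 0.1, prec,
      nchar(mzb), mzb, nchar(inb), inb)
  }
  body <- paste(mapply(one, seq_along(spectra) - 1L, spectra), collapse = "\n")
  doc <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<indexedmzML xmlns="http://psi.hupo.org/ms/mzml"><mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>
  </cvList>
  <fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>
  <softwareList count="1"><software id="sw" version="1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="%d" defaultDataProcessingRef="dp">
%s
    </spectrumList>
  </run>
</mzML></indexedmzML>', length(spectra), body)
  writeLines(doc, path)
  invisible(path)
}
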