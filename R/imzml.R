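# Minimal imzML 1.1 (processed mode, centroided) writer/reader.
# The .imzML XML carries spectrum metadata and byte offsets into the
# companion .ibd binary, which stores the m/z and intensity arrays as
# little-endian 64-bit floats, prefixed by the 16-byte UUID echoed in the
# XML. Only the subset of the standard needed for centroided processed-mode
# data is produced; the reader validates the UUID link and offsets.

CV_MZ_ARRAY <- "MS:1000514"
CV_INT_ARRAY <- "MS:1000515"
CV_POS_X <- "IMS:1000050"
CV_POS_Y <- "IMS:1000051"

imzmlUuid <- function() {
  b <- sprintf("%02x", sample(0:255, 16, replace = TRUE))
  paste0(paste(b[1:4], collapse = ""), "-", paste(b[5:6], collapse = ""), "-",
         paste(b[7:8], collapse = ""), "-", paste(b[9:10], collapse = ""), "-",
         paste(b[11:16], collapse = ""))
}

#' Write an IMSDataset as imzML (processed mode, centroided)
#'
#' Writes \code{<path>.imzML} plus the binary container \code{<path>.ibd}.
#' Both arrays are stored as little-endian 64-bit floats so the round trip
#' is exact.
#'
#' @param ds an [IMSDataset-class].
#' @param path output path without extension (or ending in .imzML).
#' @return the .imzML path, invisibly.
#' @seealso [readImzml()]
#' @export
writeImzml <- function(ds, path) {
  stopIfNot(is(ds, "IMSDataset"), "ds must be an IMSDataset")
  path <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  xmlPath <- paste0(path, ".imzML")
  ibdPath <- paste0(path, ".ibd")
  uuid <- imzmlUuid()

  con <- file(ibdPath, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(strtoi(substring(gsub("-", "", uuid),
                                   seq(1, 31, 2), seq(2, 32, 2)), 16L)), con)
  offset <- 16
  cd <- ds@coords
  n <- nrow(cd)
  spectrumXml <- character(n)
  for (i in seq_len(n)) {
    p <- ds@peaks[[i]]
    len <- nrow(p)
    mzOff <- offset
    writeBin(as.numeric(p$mz), con, size = 8, endian = "little")
    offset <- offset + 8 * len
    intOff <- offset
    writeBin(as.numeric(p$intensity), con, size = 8, endian = "little")
    offset <- offset + 8 * len
    spectrumXml[i] <- sprintf(paste0(
      '   <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n',
      '    <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>\n',
      '    <scanList count="1">\n',
      '     <scan>\n',
      '      <cvParam cvRef="IMS" accession="%s" name="position x" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="%s" name="position y" value="%d"/>\n',
      '     </scan>\n',
      '    </scanList>\n',
      '    <binaryDataArrayList count="2">\n',
      '     <binaryDataArray encodedLength="0">\n',
      '      <cvParam cvRef="MS" accession="%s" name="m/z array"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
      '      <binary/>\n',
      '     </binaryDataArray>\n',
      '     <binaryDataArray encodedLength="0">\n',
      '      <cvParam cvRef="MS" accession="%s" name="intensity array"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
      '      <binary/>\n',
      '     </binaryDataArray>\n',
      '    </binaryDataArrayList>\n',
      '   </spectrum>'),
      i, i - 1L, len,
      CV_POS_X, cd$x[i], CV_POS_Y, cd$y[i],
      CV_MZ_ARRAY, mzOff, len, 8 * len,
      CV_INT_ARRAY, intOff, len, 8 * len)
  }

  header <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    ' <fileDescription>\n',
    '  <fileContent>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>\n',
    '  </fileContent>\n',
    ' </fileDescription>\n',
    ' <referenceableParamGroupList count="0"/>\n',
    ' <scanSettingsList count="1">\n',
    '  <scanSettings id="scanSettings1">\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%g"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>\n',
    '   <userParam name="mass range low" value="%.9g"/>\n',
    '   <userParam name="mass range high" value="%.9g"/>\n',
    '   <userParam name="tic normalized" value="%s"/>\n',
    '  </scanSettings>\n',
    ' </scanSettingsList>\n',
    ' <run id="run1">\n',
    '  <spectrumList count="%d">\n'),
    uuid, ds@spatialResolution, ds@spatialResolution,
    ds@massRange[1], ds@massRange[2], ds@normalized, n)

  writeLines(c(header, spectrumXml, "  </spectrumList>", " </run>", "</mzML>"),
             xmlPath, sep = "\n")
  invisible(xmlPath)
}

#' Read an imzML file (processed mode, centroided)
#'
#' Parses the XML with \pkg{xml2}, then reads the m/z and intensity arrays
#' from the companion .ibd container at the recorded byte offsets. Only
#' 64-bit float and 32-bit float encodings are supported.
#'
#' @param path path to the .imzML file; the .ibd container is expected next
#'   to it with the same stem.
#' @return an [IMSDataset-class].
#' @export
readImzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ibdPath <- paste0(sub("\\.imzML$", "", path, ignore.case = TRUE), ".ibd")
  if (!file.exists(ibdPath)) stop("missing binary container: ", ibdPath,
                                  call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed imzML (", path, "): ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)

  num <- function(nodes, xp) as.numeric(xml2::xml_attr(xml2::xml_find_first(nodes, xp), "value"))
  resolution <- num(doc, ".//scanSettings/cvParam[@accession='IMS:1000046']")
  if (is.na(resolution)) resolution <- 25
  mrLow <- num(doc, ".//userParam[@name='mass range low']")
  mrHigh <- num(doc, ".//userParam[@name='mass range high']")
  ticNorm <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//userParam[@name='tic normalized']"), "value")

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra) == 0L) stop("no spectra in imzML file: ", path,
                                  call. = FALSE)
  px <- vapply(spectra, function(s)
    num(s, ".//cvParam[@accession='IMS:1000050']"), numeric(1))
  py <- vapply(spectra, function(s)
    num(s, ".//cvParam[@accession='IMS:1000051']"), numeric(1))
  getArr <- function(s, accession) {
    bda <- xml2::xml_find_first(s, sprintf(
      ".//binaryDataArray[cvParam/@accession='%s']", accession))
    off <- num(bda, ".//cvParam[@accession='IMS:1000102']")
    len <- num(bda, ".//cvParam[@accession='IMS:1000103']")
    size <- if (length(xml2::xml_find_all(
      bda, ".//cvParam[@accession='MS:1000521']")) > 0) 4L else 8L
    c(off, len, size)
  }
  meta <- lapply(spectra, function(s)
    rbind(getArr(s, CV_MZ_ARRAY), getArr(s, CV_INT_ARRAY)))

  con <- file(ibdPath, "rb")
  on.exit(close(con), add = TRUE)
  readArr <- function(off, len, size) {
    if (is.na(off) || is.na(len))
      stop("missing external offset/length in imzML binary metadata",
           call. = FALSE)
    seek(con, where = off)
    readBin(con, "double", n = len, size = size, endian = "little")
  }
  peaks <- lapply(meta, function(m) {
    data.frame(mz = readArr(m[1, 1], m[1, 2], m[1, 3]),
               intensity = readArr(m[2, 1], m[2, 2], m[2, 3]))
  })

  allMz <- unlist(lapply(peaks, `[[`, "mz"), use.names = FALSE)
  if (is.na(mrLow)) mrLow <- floor(min(allMz))
  if (is.na(mrHigh)) mrHigh <- ceiling(max(allMz))
  imsDataset(coords = data.frame(x = px, y = py), peaks = peaks,
             massRange = c(mrLow, mrHigh), spatialResolution = resolution,
             normalized = identical(ticNorm, "TRUE"))
}
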