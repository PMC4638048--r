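#' Read a minimal subset of an mzIdentML 1.1 file
#'
#' Read-only support limited to what the PSM post-processing needs:
#' `SpectrumIdentificationResult`/`SpectrumIdentificationItem` elements are
#' flattened to one PSM per item, with the peptide sequence resolved through
#' the `Peptide` elements, the score taken from the first numeric `cvParam`
#' on the item (or the one named by `score_accession`), and decoy status
#' from the referenced `PeptideEvidence@isDecoy` (all-decoy evidence marks
#' the PSM decoy). Full schema support is deliberately out of scope.
#'
#' @param path Path to an mzIdentML 1.1 file.
#' @param score_accession Optional cvParam accession (e.g.
#'   `"MS:1002053"`) selecting the score; default: first cvParam with a
#'   numeric value.
#' @return A PSM frame as from [read_psm_table()].
#' @export
read_mzid <- function(path, score_accession = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(m = xml2::xml_ns(doc)[[1]])
  f <- function(node, xp) xml2::xml_find_all(node, xp, ns)
  peps <- f(doc, ".//m:Peptide")
  pep_seq <- stats::setNames(
    xml2::xml_text(f(doc, ".//m:Peptide/m:PeptideSequence")),
    xml2::xml_attr(peps, "id"))
  pev <- f(doc, ".//m:PeptideEvidence")
  pev_decoy <- stats::setNames(xml2::xml_attr(pev, "isDecoy") == "true",
                               xml2::xml_attr(pev, "id"))
  pev_prot <- stats::setNames(xml2::xml_attr(pev, "dBSequence_ref"),
                              xml2::xml_attr(pev, "id"))
  rows <- list()
  for (res in f(doc, ".//m:SpectrumIdentificationResult")) {
    sid <- xml2::xml_attr(res, "spectrumID")
    for (item in f(res, "./m:SpectrumIdentificationItem")) {
      pref <- xml2::xml_attr(item, "peptide_ref")
      cv <- f(item, "./m:cvParam")
      vals <- xml2::xml_attr(cv, "value")
      accs <- xml2::xml_attr(cv, "accession")
      pick <- if (!is.null(score_accession)) which(accs == score_accession)[1]
              else which(!is.na(suppressWarnings(as.numeric(vals))))[1]
      if (is.na(pick)) next
      refs <- xml2::xml_attr(f(item, "./m:PeptideEvidenceRef"),
                             "peptideEvidence_ref")
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = sid,
        peptide = unname(pep_seq[pref]),
        modifications = "",
        score = as.numeric(vals[pick]),
        proteins = paste(stats::na.omit(unname(pev_prot[refs])),
                         collapse = ";"),
        is_decoy = length(refs) > 0 && all(pev_decoy[refs], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(list(data.frame(
    spectrum_id = character(), peptide = character(),
    modifications = character(), score = numeric(), proteins = character(),
    is_decoy = logical(), stringsAsFactors = FALSE)), rows))
}
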