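#' Defence-system marker panel
#'
#' A marker panel is the reference set of proteins used for
#' guilt-by-association detection of phage defence systems: each entry is
#' a key gene diagnostic for a defence system (BREX, restriction-
#' modification types, CRISPR-Cas, CBASS, toxin-antitoxin types, Wadjet,
#' Zorya, Thoeris, Pycsar, ...).  On disk it is a protein FASTA plus a TSV
#' mapping `marker_id` to `system_name`, `system_class` and optional
#' `subtype`.
#'
#' @param entries data frame with columns `marker_id`, `protein_seq`,
#'   `system_name`, `system_class`, `subtype` (optional).
#' @return object of class `marker_panel` (a validated data frame).
#' @export
marker_panel <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (is.null(entries$subtype)) entries$subtype <- NA_character_
  assert_that(!anyDuplicated(entries$marker_id), "marker_id must be unique")
  assert_that(all(nzchar(entries$system_class) & !is.na(entries$system_class)),
              "every panel entry needs a system_class")
  assert_that(all(nzchar(entries$system_name) & !is.na(entries$system_name)),
              "every panel entry needs a system_name")
  class(entries) <- c("marker_panel", "data.frame")
  entries
}

#' Read a marker panel from protein FASTA + mapping TSV
#'
#' @param fasta_path protein FASTA whose record ids are marker ids.
#' @param tsv_path TSV with header columns `marker_id`, `system_name`,
#'   `system_class` and optionally `subtype`.
#' @return a [marker_panel()].
#' @export
read_panel <- function(fasta_path, tsv_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  seqs <- setNames(toupper(as.character(aa)), sub("\\s.*$", "", names(aa)))
  map <- read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("marker_id", "system_name", "system_class")
  miss <- setdiff(need, names(map))
  assert_that(length(miss) == 0,
              paste0("panel mapping missing column(s): ", paste(miss, collapse = ", ")))
  idx <- match(map$marker_id, names(seqs))
  assert_that(!anyNA(idx), paste0(
    "panel mapping refers to markers absent from the FASTA: ",
    paste(map$marker_id[is.na(idx)], collapse = ", ")))
  map$protein_seq <- unname(seqs[idx])
  marker_panel(map[, c("marker_id", "protein_seq", "system_name",
                       "system_class",
                       if ("subtype" %in% names(map)) "subtype")])
}

#' Write a marker panel as protein FASTA + mapping TSV
#' @param panel a [marker_panel()].
#' @param fasta_path,tsv_path output paths.
#' @return named character vector of the paths written, invisibly.
#' @export
write_panel <- function(panel, fasta_path, tsv_path) {
  aa <- Biostrings::AAStringSet(panel$protein_seq)
  names(aa) <- panel$marker_id
  Biostrings::writeXStringSet(aa, fasta_path, width = 80L)
  write.table(panel[, c("marker_id", "system_name", "system_class", "subtype")],
              tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, tsv = tsv_path))
}
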