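#' Genome, replicon and gene-feature containers
#'
#' The pipeline's genome model is deliberately light: a `genome` object is a
#' list holding two data frames (one row per replicon, one row per CDS
#' feature) plus an optional taxonomic lineage.  All internal coordinates
#' are 0-based half-open; file readers and writers convert to and from the
#' 1-based inclusive convention of GFF3 and GenBank.
#'
#' @param assembly_id single string identifying the assembly.
#' @param replicons data frame with columns `replicon_id`, `sequence`
#'   (uppercase A/C/G/T/N), `replicon_type` (`chromosome`, `plasmid` or
#'   `unknown`) and `topology` (`linear` or `circular`).
#' @param features data frame with columns `feature_id`, `replicon_id`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `product`,
#'   `protein_seq` (may be `NA`).
#' @param lineage optional named character vector mapping rank name to
#'   taxon name (e.g. `c(genus = "Pseudomonas", phylum = "Proteobacteria")`).
#' @return an object of class `genome`.
#' @export
genome <- function(assembly_id, replicons, features = NULL, lineage = NULL) {
  if (is.null(features)) {
    features <- empty_features()
  }
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(replicons$topology)) replicons$topology <- "linear"
  if (is.null(replicons$replicon_type)) replicons$replicon_type <- "unknown"
  if (is.null(features$product)) features$product <- NA_character_
  if (is.null(features$protein_seq)) features$protein_seq <- NA_character_
  g <- structure(
    list(assembly_id = assembly_id, lineage = lineage,
         replicons = replicons, features = features),
    class = "genome"
  )
  validate_genome(g)
  g
}

empty_features <- function() {
  empty_df(feature_id = "character", replicon_id = "character",
           start = "integer", end = "integer", strand = "character",
           product = "character", protein_seq = "character")
}

#' Validate internal consistency of a genome object
#'
#' Checks the model invariants: non-empty uppercase A/C/G/T/N sequences,
#' unique replicon ids, every feature resolving to a replicon, and every
#' feature interval within `[0, replicon length)`.
#'
#' @param g a `genome`.
#' @return `g`, invisibly; stops with a validation error otherwise.
#' @export
validate_genome <- function(g) {
  r <- g$replicons
  f <- g$features
  assert_that(nrow(r) >= 1, "genome has no replicons")
  assert_that(!anyDuplicated(r$replicon_id),
              "replicon_id values must be unique within a genome")
  assert_that(all(nchar(r$sequence) > 0), "replicon sequences must be non-empty")
  bad <- grepl("[^ACGTN]", r$sequence)
  assert_that(!any(bad), paste0(
    "replicon sequence contains characters outside {A,C,G,T,N}: ",
    paste(r$replicon_id[bad], collapse = ", ")))
  assert_that(all(r$replicon_type %in% c("chromosome", "plasmid", "unknown")),
              "replicon_type must be chromosome, plasmid or unknown")
  if (nrow(f)) {
    idx <- match(f$replicon_id, r$replicon_id)
    assert_that(!anyNA(idx), paste0(
      "features reference unknown replicons: ",
      paste(unique(f$replicon_id[is.na(idx)]), collapse = ", ")))
    len <- nchar(r$sequence)[idx]
    ok <- f$start >= 0 & f$start < f$end & f$end <= len
    assert_that(all(ok), paste0(
      "features outside replicon bounds: ",
      paste(f$feature_id[!ok], collapse = ", ")))
    assert_that(all(f$strand %in% c("+", "-")), "strand must be '+' or '-'")
    assert_that(!anyDuplicated(f$feature_id), "feature_id values must be unique")
  }
  invisible(g)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d replicon(s), %d CDS feature(s)\n",
              x$assembly_id, nrow(x$replicons), nrow(x$features)))
  for (i in seq_len(nrow(x$replicons))) {
    cat(sprintf("  %s  %s/%s  %d bp\n", x$replicons$replicon_id[i],
                x$replicons$replicon_type[i], x$replicons$topology[i],
                nchar(x$replicons$sequence[i])))
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' Uppercases the input; `N` maps to `N`.  Involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq single DNA string over A/C/G/T/N (case-insensitive).
#' @return the reverse complement, uppercase.
#' @examples
#' reverse_complement("AAAT") # "ATTT"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  assert_that(!grepl("[^ACGTN]", seq),
              "reverse_complement: invalid character in sequence")
  if (nchar(seq) == 0L) return(seq)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

replicon_seq <- function(g, replicon_id) {
  i <- match(replicon_id, g$replicons$replicon_id)
  assert_that(!is.na(i), paste0("unknown replicon: ", replicon_id))
  g$replicons$sequence[i]
}

get_feature <- function(g, feature_id) {
  i <- match(feature_id, g$features$feature_id)
  assert_that(!is.na(i), paste0("unknown feature: ", feature_id))
  g$features[i, , drop = FALSE]
}

#' Extract the sequence immediately 5' of a gene
#'
#' Returns up to `length` bases upstream of `feature` on its coding strand
#' (reverse-complemented for minus-strand genes).  On linear replicons the
#' extract is silently truncated at the replicon edge; for circular
#' replicons wrap-around is applied only when `circular_wrap = TRUE`.
#'
#' @param g a `genome`.
#' @param feature a one-row slice of `g$features`, or a feature_id string.
#' @param length maximum number of bases to return (> 0).
#' @param circular_wrap allow wrap-around across the origin of circular
#'   replicons (default `FALSE`; the conservative choice, since enabling it
#'   changes results on plasmids).
#' @return a DNA string of `length` bases or fewer.
#' @export
extract_upstream <- function(g, feature, length = 200L, circular_wrap = FALSE) {
  assert_that(length > 0, "extract_upstream: length must be > 0")
  if (is.character(feature)) feature <- get_feature(g, feature)
  ri <- match(feature$replicon_id, g$replicons$replicon_id)
  assert_that(!is.na(ri), "feature does not belong to this genome")
  s <- g$replicons$sequence[ri]
  L <- nchar(s)
  circ <- identical(g$replicons$topology[ri], "circular") && circular_wrap
  if (feature$strand == "+") {
    from <- feature$start - length
    to <- feature$start                      # [from, to) 0-based
    if (from >= 0 || circ) {
      if (from >= 0) {
        out <- substr(s, from + 1L, to)
      } else {
        out <- paste0(substr(s, L + from + 1L, L), substr(s, 1L, to))
      }
    } else {
      out <- substr(s, 1L, to)
    }
    out
  } else {
    from <- feature$end
    to <- feature$end + length               # [from, to) 0-based
    if (to <= L || circ) {
      if (to <= L) {
        out <- substr(s, from + 1L, to)
      } else {
        out <- paste0(substr(s, from + 1L, L), substr(s, 1L, to - L))
      }
    } else {
      out <- substr(s, from + 1L, L)
    }
    reverse_complement(out)
  }
}

#' Strand-aware gap between two gene features
#'
#' Distance is the gap between the nearest feature edges (0 when the
#' features overlap).  Direction is defined relative to the anchor's coding
#' strand: `downstream` when `other` lies 3' of the anchor.
#'
#' @param anchor,other one-row feature data frames on the same replicon.
#' @return list with elements `distance` (bp) and `direction`
#'   (`"downstream"`, `"upstream"` or `"overlapping"`).
#' @export
distance_between <- function(anchor, other) {
  assert_that(identical(anchor$replicon_id, other$replicon_id),
              "distance_between: features on different replicons")
  if (other$start < anchor$end && anchor$start < other$end) {
    return(list(distance = 0L, direction = "overlapping"))
  }
  if (other$start >= anchor$end) {
    d <- other$start - anchor$end
    dir <- if (anchor$strand == "+") "downstream" else "upstream"
  } else {
    d <- anchor$start - other$end
    dir <- if (anchor$strand == "+") "upstream" else "downstream"
  }
  list(distance = as.integer(d), direction = dir)
}

#' Translate a CDS to protein
#'
#' Standard bacterial code (translation table 11); the terminal stop is
#' dropped and any internal stop is reported as `*`.
#'
#' @param nt in-frame CDS nucleotide string (length divisible by 3).
#' @return amino-acid string.
#' @export
translate_cds <- function(nt) {
  nt <- toupper(nt)
  assert_that(nchar(nt) %% 3 == 0, "CDS length not divisible by 3")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}
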