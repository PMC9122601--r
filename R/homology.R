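#' Scoring scheme for protein local alignment
#'
#' Bundles a symmetric substitution matrix, affine gap penalties (a gap of
#' length k costs `gap_open + k * gap_extend`) and the Karlin-Altschul
#' parameters used to convert raw scores into E-values.  The default
#' mirrors a default protein BLAST run: BLOSUM62, gap open 11 / extend 1,
#' with the published gapped constants for that combination
#' (lambda = 0.267, K = 0.041, H = 0.14).
#'
#' @param matrix integer substitution matrix with residue dimnames
#'   (default: BLOSUM62 shipped with Biostrings).
#' @param gap_open,gap_extend positive gap penalties.
#' @param lambda,kappa Karlin-Altschul lambda and K (> 0).
#' @param H relative entropy (nats) used only by the edge-effect length
#'   correction.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, kappa = 0.041, H = 0.14) {
  if (is.null(matrix)) {
    matrix <- blosum62()
  }
  storage.mode(matrix) <- "integer"
  assert_that(isTRUE(all.equal(matrix, t(matrix))),
              "substitution matrix must be symmetric")
  assert_that(gap_open > 0 && gap_extend > 0, "gap penalties must be > 0")
  assert_that(lambda > 0 && kappa > 0, "lambda and kappa must be > 0")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, kappa = kappa, H = H),
            class = "scoring_scheme")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
            "P","S","T","W","Y","V","X","*")
  m[keep, keep]
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (Gotoh recurrences), exact full dynamic
#' programming -- no heuristic seeding.  Traceback tie-breaks are fixed:
#' diagonal over gap-in-subject over gap-in-query, and among equal-scoring
#' end cells the smallest (subject end, query end) coordinates.
#'
#' @param query_seq,subject_seq protein strings (20-letter alphabet plus
#'   X/*); an empty sequence yields score 0 and empty spans.
#' @param scheme a [scoring_scheme()].
#' @return list with `score`, `query_span` and `subject_span` (1-based
#'   inclusive, `c(0, 0)` when empty), `identity_frac` (matches over
#'   alignment columns, gaps included), `n_match`, `aln_len`.
#' @export
local_align <- function(query_seq, subject_seq, scheme = scoring_scheme()) {
  r <- .gotoh_local(toupper(query_seq), toupper(subject_seq),
                    scheme$matrix, scheme$gap_open, scheme$gap_extend)
  list(score = r$score,
       query_span = c(r$q_start, r$q_end),
       subject_span = c(r$s_start, r$s_end),
       identity_frac = r$identity_frac,
       n_match = r$n_match, aln_len = r$aln_len)
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m' * n' * exp(-lambda * S)`.  In `"simple"` mode (the tested
#' default) the effective lengths equal the raw lengths (edge-effect
#' correction l = 0).  In `"corrected"` mode l is the standard
#' edge-effect length adjustment solved iteratively from
#' `l = log(K * m' * n') / H`, with `m' = max(1, m - l)` and
#' `n' = max(1, n - n_seq * l)`.
#'
#' @param score raw alignment score S (>= 0).
#' @param query_len,db_len residue counts m and n (> 0).
#' @param scheme a [scoring_scheme()].
#' @param mode `"simple"` or `"corrected"`.
#' @param n_seq number of database sequences (corrected mode only).
#' @return the expectation E.
#' @export
evalue <- function(score, query_len, db_len, scheme = scoring_scheme(),
                   mode = c("simple", "corrected"), n_seq = 1L) {
  mode <- match.arg(mode)
  assert_that(score >= 0, "evalue: score must be >= 0")
  assert_that(query_len > 0 && db_len > 0, "evalue: lengths must be > 0")
  ell <- 0
  if (mode == "corrected") {
    for (it in 1:5) {
      mp <- max(1, query_len - ell)
      np <- max(1, db_len - n_seq * ell)
      ell <- max(0, log(scheme$kappa * mp * np) / scheme$H)
    }
  }
  mp <- max(1, query_len - ell)
  np <- max(1, db_len - n_seq * ell)
  scheme$kappa * mp * np * exp(-scheme$lambda * score)
}

#' Search thresholds
#'
#' @param evalue_max retain hits with `E < evalue_max` (strict, matching
#'   the "E-value < 1e-5" convention).  Default 1e-5; the sensitivity
#'   setting used for re-checks is 1e-3.
#' @param min_aln_len minimum alignment length in residues (default 0).
#' @return object of class `search_thresholds`.
#' @export
search_thresholds <- function(evalue_max = 1e-5, min_aln_len = 0L) {
  assert_that(evalue_max > 0, "evalue_max must be > 0")
  structure(list(evalue_max = evalue_max, min_aln_len = as.integer(min_aln_len)),
            class = "search_thresholds")
}

hit_columns <- c("query_id", "subject_feature_id", "genome_id", "replicon_id",
                 "subject_start", "subject_strand", "score", "bitscore",
                 "evalue", "identity_frac", "aln_len",
                 "q_start", "q_end", "s_start", "s_end")

empty_hits <- function() {
  empty_df(query_id = "character", subject_feature_id = "character",
           genome_id = "character", replicon_id = "character",
           subject_start = "integer", subject_strand = "character",
           score = "integer", bitscore = "double", evalue = "double",
           identity_frac = "double", aln_len = "integer",
           q_start = "integer", q_end = "integer",
           s_start = "integer", s_end = "integer")
}

#' Protein homology search over a set of genomes
#'
#' Aligns each query against the protein product of every CDS feature in
#' every genome (full Smith-Waterman; one optimal alignment per pair, so
#' one best hit per (query, CDS)).  E-values use the total residue count
#' of all proteins searched as the database length.  Hits with
#' `E < evalue_max` (and alignment length >= `min_aln_len`) are returned
#' in deterministic order (genome, replicon, feature start).
#'
#' @param queries named character vector of protein sequences, or a path
#'   to a protein FASTA.
#' @param genomes a `genome` or list of `genome` objects.
#' @param scheme a [scoring_scheme()].
#' @param thresholds a [search_thresholds()].
#' @param evalue_mode passed to [evalue()].
#' @return data frame of hits (one row per retained query/CDS pair) with
#'   1-based inclusive alignment spans.
#' @export
search <- function(queries, genomes, scheme = scoring_scheme(),
                   thresholds = search_thresholds(),
                   evalue_mode = "simple") {
  if (is.character(queries) && length(queries) == 1L && file.exists(queries)) {
    aa <- Biostrings::readAAStringSet(queries)
    queries <- setNames(toupper(as.character(aa)), sub("\\s.*$", "", names(aa)))
  }
  assert_that(!is.null(names(queries)) && all(nzchar(names(queries))),
              "queries must be named")
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  subj <- do.call(rbind, lapply(genomes, function(g) {
    f <- g$features
    if (!nrow(f)) return(NULL)
    data.frame(genome_id = g$assembly_id, feature_id = f$feature_id,
               replicon_id = f$replicon_id, start = f$start,
               strand = f$strand, protein_seq = f$protein_seq,
               stringsAsFactors = FALSE)
  }))
  if (is.null(subj) || !nrow(subj)) return(empty_hits())
  has_prot <- !is.na(subj$protein_seq) & nzchar(subj$protein_seq)
  if (!any(has_prot)) {
    stop("search: no CDS carries a protein sequence; supply a companion ",
         "protein FASTA to read_genome() or ensure CDS lengths permit ",
         "translation", call. = FALSE)
  }
  subj <- subj[has_prot, , drop = FALSE]
  subj <- subj[order(subj$genome_id, subj$replicon_id, subj$start), , drop = FALSE]
  db_len <- sum(nchar(subj$protein_seq))
  n_seq <- nrow(subj)
  rows <- vector("list", length(queries) * nrow(subj))
  ri <- 0L
  for (q in seq_along(queries)) {
    qseq <- queries[[q]]
    m <- nchar(qseq)
    for (s in seq_len(nrow(subj))) {
      aln <- local_align(qseq, subj$protein_seq[s], scheme)
      if (aln$score <= 0) next
      E <- evalue(aln$score, m, db_len, scheme, mode = evalue_mode,
                  n_seq = n_seq)
      if (E >= thresholds$evalue_max) next
      if (aln$aln_len < thresholds$min_aln_len) next
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        query_id = names(queries)[q],
        subject_feature_id = subj$feature_id[s],
        genome_id = subj$genome_id[s],
        replicon_id = subj$replicon_id[s],
        subject_start = subj$start[s],
        subject_strand = subj$strand[s],
        score = aln$score,
        bitscore = (scheme$lambda * aln$score - log(scheme$kappa)) / log(2),
        evalue = E,
        identity_frac = aln$identity_frac,
        aln_len = aln$aln_len,
        q_start = aln$query_span[1], q_end = aln$query_span[2],
        s_start = aln$subject_span[1], s_end = aln$subject_span[2],
        stringsAsFactors = FALSE)
    }
  }
  if (ri == 0L) return(empty_hits())
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}

#' Ingest externally produced tabular homology results
#'
#' Reads the standard 12-column tabular homology dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, evalue, bitscore), filters by `thresholds`, and
#' maps rows onto the internal hit table (percent identity converted to a
#' fraction).  Subject ids are taken as feature ids; genome/replicon
#' placement must be resolved downstream against the loaded genomes.
#'
#' @param path tab-separated file; `#` comment lines allowed.
#' @param thresholds a [search_thresholds()].
#' @return hit data frame as from [search()] (placement columns `NA`).
#' @export
ingest_tabular <- function(path, thresholds = search_thresholds()) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^(#|\\s*$)", lines))
  if (!length(keep)) return(empty_hits())
  rows <- vector("list", length(keep))
  ri <- 0L
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L) {
      parse_error(sprintf("%s line %d: expected 12 tab-separated columns, got %d",
                          path, i, length(f)))
    }
    E <- as.numeric(f[11])
    if (is.na(E)) parse_error(sprintf("%s line %d: bad evalue '%s'", path, i, f[11]))
    if (E >= thresholds$evalue_max) next
    if (as.integer(f[4]) < thresholds$min_aln_len) next
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      query_id = f[1], subject_feature_id = f[2],
      genome_id = NA_character_, replicon_id = NA_character_,
      subject_start = NA_integer_, subject_strand = NA_character_,
      score = NA_integer_, bitscore = as.numeric(f[12]), evalue = E,
      identity_frac = as.numeric(f[3]) / 100, aln_len = as.integer(f[4]),
      q_start = as.integer(f[7]), q_end = as.integer(f[8]),
      s_start = as.integer(f[9]), s_end = as.integer(f[10]),
      stringsAsFactors = FALSE)
  }
  if (ri == 0L) return(empty_hits())
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}

#' Write / read the hit table as TSV
#' @param hits hit data frame.
#' @param path file path.
#' @return `write_hits`: `path` invisibly; `read_hits`: hit data frame.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
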