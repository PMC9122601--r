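#' Read an annotated genome from FASTA + GFF3 or from a GenBank flat file
#'
#' CDS features are read from the annotation; GFF3/GenBank 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention.  Protein sequences are taken from a companion protein FASTA
#' keyed by `feature_id` when supplied, else translated from the CDS
#' (bacterial code, table 11).  A CDS whose length is not divisible by 3
#' and that has no supplied protein is kept, with a warning, without a
#' protein sequence.  Replicon type is inferred from record metadata: a
#' header/DEFINITION containing the keyword "plasmid" (or "chromosome")
#' sets the type, otherwise it is `unknown`.  Lowercase (soft-masked)
#' sequence is uppercased on read.
#'
#' @param fasta_path nucleotide FASTA (one record per replicon).
#' @param gff3_path GFF3 annotation for `fasta_path`.
#' @param genbank_path GenBank flat file (alternative to FASTA+GFF3).
#' @param protein_fasta_path optional protein FASTA keyed by feature id.
#' @param assembly_id assembly identifier; defaults to the file base name.
#' @return a `genome`.
#' @export
read_genome <- function(fasta_path = NULL, gff3_path = NULL,
                        genbank_path = NULL, protein_fasta_path = NULL,
                        assembly_id = NULL) {
  if (!is.null(genbank_path)) {
    g <- read_genbank(genbank_path, assembly_id = assembly_id)
  } else {
    assert_that(!is.null(fasta_path) && !is.null(gff3_path),
                "read_genome: supply fasta_path + gff3_path, or genbank_path")
    g <- read_fasta_gff3(fasta_path, gff3_path, assembly_id = assembly_id)
  }
  attach_proteins(g, protein_fasta_path)
}

infer_replicon_type <- function(description) {
  lo <- tolower(description)
  ifelse(grepl("plasmid", lo), "plasmid",
         ifelse(grepl("chromosome", lo), "chromosome", "unknown"))
}

read_fasta_gff3 <- function(fasta_path, gff3_path, assembly_id = NULL) {
  if (!file.exists(fasta_path)) parse_error(paste0("no such file: ", fasta_path))
  if (!file.exists(gff3_path)) parse_error(paste0("no such file: ", gff3_path))
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                   error = function(e) parse_error(
                     paste0("malformed FASTA ", fasta_path, ": ", conditionMessage(e))))
  full_names <- names(seqs)
  ids <- sub("\\s.*$", "", full_names)
  replicons <- data.frame(
    replicon_id = ids,
    sequence = toupper(as.character(seqs)),
    replicon_type = infer_replicon_type(full_names),
    topology = ifelse(grepl("circular", tolower(full_names)), "circular", "linear"),
    stringsAsFactors = FALSE
  )
  feats <- parse_gff3_cds(gff3_path)
  genome(assembly_id %||% sub("\\.(fa|fna|fasta)$", "", basename(fasta_path)),
         replicons, feats)
}

# Minimal line-oriented GFF3 CDS reader.  Kept deliberately simple (the
# pipeline only needs CDS rows with ID/product attributes) so that parse
# failures can be reported with a line number.
parse_gff3_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^(#|\\s*$)", lines))
  rows <- list()
  for (i in keep) {
    if (grepl("^>", lines[i])) break  # trailing ##FASTA section
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      parse_error(sprintf("%s line %d: expected 9 tab-separated columns, got %d",
                          path, i, length(f)))
    }
    if (!identical(f[3], "CDS")) next
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || start1 > end1) {
      parse_error(sprintf("%s line %d: bad coordinates '%s..%s'", path, i, f[4], f[5]))
    }
    attrs <- parse_gff3_attrs(f[9])
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = attrs[["ID"]] %||% sprintf("cds_%d", i),
      replicon_id = f[1],
      start = start1 - 1L, end = end1,    # to 0-based half-open
      strand = f[7],
      product = attrs[["product"]] %||% NA_character_,
      protein_seq = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty_features())
  do.call(rbind, rows)
}

parse_gff3_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(x) utils::URLdecode(paste(x[-1], collapse = "=")))
  names(out) <- vapply(kv, `[`, "", 1L)
  out
}

attach_proteins <- function(g, protein_fasta_path) {
  f <- g$features
  if (!nrow(f)) return(g)
  supplied <- character(0)
  if (!is.null(protein_fasta_path)) {
    aa <- Biostrings::readAAStringSet(protein_fasta_path)
    supplied <- setNames(toupper(as.character(aa)), sub("\\s.*$", "", names(aa)))
  }
  for (i in seq_len(nrow(f))) {
    if (!is.na(f$protein_seq[i])) next
    fid <- f$feature_id[i]
    if (fid %in% names(supplied)) {
      f$protein_seq[i] <- supplied[[fid]]
      next
    }
    nt <- substr(replicon_seq(g, f$replicon_id[i]), f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") nt <- reverse_complement(nt)
    if (nchar(nt) %% 3 != 0) {
      warning(sprintf("CDS %s length %d not divisible by 3; kept without protein",
                      fid, nchar(nt)), call. = FALSE)
      next
    }
    f$protein_seq[i] <- translate_cds(nt)
  }
  g$features <- f
  g
}

#' Write a genome as FASTA + GFF3 (+ protein FASTA)
#'
#' Inverse of [read_genome()]: coordinates are emitted 1-based inclusive;
#' replicon type and topology are recorded as keywords on the FASTA
#' header so that a re-read reconstructs them.
#'
#' @param g a `genome`.
#' @param dir output directory (created if needed).
#' @param basename file stem; defaults to the assembly id.
#' @return named character vector of the paths written.
#' @export
write_genome <- function(g, dir, basename = g$assembly_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fna <- file.path(dir, paste0(basename, ".fna"))
  gff <- file.path(dir, paste0(basename, ".gff3"))
  faa <- file.path(dir, paste0(basename, ".faa"))
  r <- g$replicons
  seqs <- Biostrings::DNAStringSet(r$sequence)
  names(seqs) <- sprintf("%s %s %s", r$replicon_id, r$replicon_type, r$topology)
  Biostrings::writeXStringSet(seqs, fna, width = 80L)
  f <- g$features
  gff_lines <- "##gff-version 3"
  if (nrow(f)) {
    ord <- order(f$replicon_id, f$start)
    f <- f[ord, , drop = FALSE]
    attrs <- sprintf("ID=%s", f$feature_id)
    has_prod <- !is.na(f$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=", f$product[has_prod])
    gff_lines <- c(gff_lines, sprintf("%s\tbrxrscan\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                      f$replicon_id, f$start + 1L, f$end,
                                      f$strand, attrs))
  }
  writeLines(gff_lines, gff)
  paths <- c(fasta = fna, gff3 = gff)
  prot <- f[!is.na(f$protein_seq), , drop = FALSE]
  if (nrow(prot)) {
    aa <- Biostrings::AAStringSet(prot$protein_seq)
    names(aa) <- prot$feature_id
    Biostrings::writeXStringSet(aa, faa, width = 80L)
    paths <- c(paths, protein = faa)
  }
  paths
}

#' Serialize / restore a genome as JSON (fixture format)
#' @param g a `genome`.
#' @param path JSON file path.
#' @return `write_genome_json`: `path` invisibly; `read_genome_json`: a `genome`.
#' @export
write_genome_json <- function(g, path) {
  jsonlite::write_json(
    list(assembly_id = g$assembly_id,
         lineage = as.list(g$lineage),
         replicons = g$replicons, features = g$features),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_genome_json
#' @export
read_genome_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lineage <- if (length(x$lineage)) unlist(x$lineage) else NULL
  feats <- if (is.data.frame(x$features) && nrow(x$features)) x$features else NULL
  genome(x$assembly_id, x$replicons, feats, lineage = lineage)
}

# --- GenBank flat file (minimal: LOCUS/DEFINITION/CDS/ORIGIN) ---------------

read_genbank <- function(path, assembly_id = NULL) {
  if (!file.exists(path)) parse_error(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) parse_error(paste0(path, ": no LOCUS record found"))
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts)) parse_error(paste0(path, ": record not terminated by //"))
  reps <- list(); feats <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    rec <- parse_genbank_record(block, path, starts[k])
    reps[[k]] <- rec$replicon
    if (nrow(rec$features)) feats[[length(feats) + 1L]] <- rec$features
  }
  genome(assembly_id %||% sub("\\.(gb|gbk|gbff)$", "", basename(path)),
         do.call(rbind, reps),
         if (length(feats)) do.call(rbind, feats) else NULL)
}

parse_genbank_record <- function(block, path, offset) {
  locus <- strsplit(trimws(sub("^LOCUS", "", block[1])), "\\s+")[[1]]
  rid <- locus[1]
  topo <- if (any(tolower(locus) == "circular")) "circular" else "linear"
  defn <- grep("^DEFINITION", block, value = TRUE)
  rtype <- if (length(defn)) infer_replicon_type(paste(defn, collapse = " ")) else "unknown"
  ori <- grep("^ORIGIN", block)
  if (!length(ori)) parse_error(sprintf("%s line %d: record %s has no ORIGIN",
                                        path, offset, rid))
  seq_lines <- block[(ori[1] + 1L):(length(block) - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  fstart <- grep("^FEATURES", block)
  features <- empty_features()
  if (length(fstart)) {
    ftext <- block[(fstart[1] + 1L):(ori[1] - 1L)]
    features <- parse_genbank_cds(ftext, rid)
  }
  list(replicon = data.frame(replicon_id = rid, sequence = seq,
                             replicon_type = rtype, topology = topo,
                             stringsAsFactors = FALSE),
       features = features)
}

parse_genbank_cds <- function(ftext, rid) {
  # a new feature starts at indentation 5; qualifier lines at indentation 21
  key_idx <- grep("^ {5}\\S", ftext)
  rows <- list()
  for (j in seq_along(key_idx)) {
    i <- key_idx[j]
    key <- sub("^\\s+", "", substr(ftext[i], 1, 20))
    key <- sub("\\s.*$", "", key)
    if (key != "CDS") next
    to <- if (j < length(key_idx)) key_idx[j + 1] - 1L else length(ftext)
    body <- ftext[i:to]
    loc <- trimws(substr(body[1], 21, nchar(body[1])))
    m <- regmatches(loc, regexec("^(complement\\()?<?(\\d+)\\.\\.>?(\\d+)\\)?$", loc))[[1]]
    if (!length(m)) {
      warning(sprintf("skipping CDS with unsupported location '%s'", loc),
              call. = FALSE)
      next
    }
    quals <- parse_genbank_quals(body[-1])
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = quals[["locus_tag"]] %||% quals[["protein_id"]] %||%
        sprintf("%s_cds_%d", rid, j),
      replicon_id = rid,
      start = as.integer(m[3]) - 1L, end = as.integer(m[4]),
      strand = if (nzchar(m[2])) "-" else "+",
      product = quals[["product"]] %||% NA_character_,
      protein_seq = quals[["translation"]] %||% NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty_features())
  do.call(rbind, rows)
}

parse_genbank_quals <- function(lines) {
  txt <- paste(trimws(lines), collapse = "\n")
  pieces <- strsplit(txt, "\n/", fixed = TRUE)[[1]]
  pieces[1] <- sub("^/", "", pieces[1])
  out <- list()
  for (p in pieces) {
    if (!nzchar(p)) next
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) { out[[p]] <- TRUE; next }
    key <- substr(p, 1, eq - 1)
    val <- substr(p, eq + 1, nchar(p))
    val <- gsub('"', "", val)
    if (key == "translation") val <- gsub("\\s", "", val) else val <- gsub("\n", " ", val)
    out[[key]] <- val
  }
  out
}
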