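# FASTA and GFF3 input/output.
#
# Coordinate convention: GFF3 is 1-based inclusive at the file boundary.
# Internal interval arithmetic (ur_extract, storf_find) uses 0-based
# half-open spans; the conversion happens only in this file and in
# to_genome_coordinates().

#' Read a FASTA file
#'
#' Reads a (DNA or protein) FASTA file into a named character vector.
#' Residues are uppercased; record order is preserved; the id is the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a text FASTA file.
#' @param alphabet `"any"` (default) or `"dna"`; with `"dna"` every residue
#'   must be an IUPAC DNA code (including ambiguity codes and `N`).
#' @return Named character vector of sequences, one element per record.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtacgt"), tf)
#' read_fasta(tf, alphabet = "dna")
#' @export
read_fasta <- function(path, alphabet = c("any", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file (no records): ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("FASTA record with empty id in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  w <- Biostrings::width(set)
  if (any(w == 0L)) {
    stop("FASTA record(s) with no sequence: ",
         paste(ids[w == 0L], collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (alphabet == "dna") {
    bad <- ids[grepl("[^ACGTRYSWKMBDHVN]", seqs)]
    if (length(bad)) {
      stop("non-IUPAC DNA residues in record(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of sequences (DNA or protein;
#'   `*` characters are preserved).
#' @param path Output path.
#' @param line_width Residues per line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  stopifnot(is.character(records), line_width >= 1)
  if (length(records)) {
    if (is.null(names(records)) || any(!nzchar(names(records)))) {
      stop("every FASTA record needs a non-empty name", call. = FALSE)
    }
    empty <- names(records)[!nzchar(records)]
    if (length(empty)) {
      stop("refusing to write empty sequence for record(s): ",
           paste(empty, collapse = ", "), call. = FALSE)
    }
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}

#' Select annotation features that define occupancy
#'
#' A selector picks which GFF3 records count as "annotated" when computing
#' unannotated regions.  `by_type` matches column 3 (e.g. `"gene"` for
#' Ensembl-style files, `"CDS"` for CDS-only predictor output);
#' `by_attribute_prefix` matches a prefix of any `key=value` token in
#' column 9 (e.g. `"ID=gene"`).
#'
#' @param mode `"by_type"` or `"by_attribute_prefix"`.
#' @param values Non-empty character vector of types or prefixes.
#' @return A `feature_selector` object.
#' @export
feature_selector <- function(mode = c("by_type", "by_attribute_prefix"),
                             values = "gene") {
  mode <- match.arg(mode)
  if (!is.character(values) || !length(values) || any(!nzchar(values))) {
    stop("selector values must be a non-empty character vector", call. = FALSE)
  }
  structure(list(mode = mode, values = values), class = "feature_selector")
}

.apply_selector <- function(features, selector) {
  if (is.null(selector)) {
    return(features)
  }
  stopifnot(inherits(selector, "feature_selector"))
  keep <- switch(selector$mode,
    by_type = features$type %in% selector$values,
    by_attribute_prefix = vapply(features$attributes, function(a) {
      toks <- trimws(strsplit(a, ";", fixed = TRUE)[[1]])
      any(vapply(selector$values, function(v) any(startsWith(toks, v)),
                 logical(1)))
    }, logical(1), USE.NAMES = FALSE)
  )
  features[keep, , drop = FALSE]
}

.gff_columns <- c("contig", "source", "type", "start", "end",
                  "score", "strand", "phase", "attributes")

.empty_gff <- function() {
  data.frame(contig = character(), source = character(), type = character(),
             start = integer(), end = integer(), score = character(),
             strand = character(), phase = character(),
             attributes = character(), raw = character(),
             stringsAsFactors = FALSE)
}

#' Read a GFF3 file
#'
#' Parses the 9-column body of a GFF3 file into a data frame.  Comment and
#' directive lines are skipped and anything after a `##FASTA` directive is
#' ignored.  The original line of every record is retained in a `raw`
#' column so that downstream writers can re-emit records byte-identically.
#'
#' @param path Path to a GFF3 file.
#' @param selector A [feature_selector()] applied after parsing, or `NULL`
#'   (default) to keep every record.
#' @return Data frame with columns `contig`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase`, `attributes` (the verbatim column-9
#'   string) and `raw`, sorted by (`contig`, `start`).
#' @export
read_gff <- function(path, selector = NULL) {
  if (!file.exists(path)) {
    stop("GFF file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- rep(TRUE, length(lines))
  fasta_at <- which(startsWith(lines, "##FASTA"))
  if (length(fasta_at)) {
    keep[fasta_at[1]:length(lines)] <- FALSE
  }
  keep <- keep & nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (!length(idx)) {
    out <- .empty_gff()
    return(.apply_selector(out, selector))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- idx[which(nf < 9L)[1]]
    stop("GFF line ", bad, ": expected 9 tab-separated columns, got ",
         nf[which(nf < 9L)[1]], call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:9], character(9)))
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1]]
    stop("GFF line ", bad, ": non-numeric start/end", call. = FALSE)
  }
  rev_span <- end < start
  if (any(rev_span)) {
    bad <- idx[which(rev_span)[1]]
    stop("GFF line ", bad, ": end < start", call. = FALSE)
  }
  if (any(start < 1L)) {
    bad <- idx[which(start < 1L)[1]]
    stop("GFF line ", bad, ": start < 1", call. = FALSE)
  }
  out <- data.frame(contig = m[, 1], source = m[, 2], type = m[, 3],
                    start = start, end = end, score = m[, 6],
                    strand = m[, 7], phase = m[, 8], attributes = m[, 9],
                    raw = lines[idx], stringsAsFactors = FALSE)
  out <- .apply_selector(out, selector)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write features to a GFF3 file
#'
#' Records that carry a `raw` column (as produced by [read_gff()]) are
#' re-emitted verbatim; records without one are assembled from their
#' columns.  The file starts with a `##gff-version 3` header.
#'
#' @param features Data frame with at least the nine GFF3 columns (see
#'   [read_gff()]); a `raw` column is honoured when present and non-`NA`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(features, path) {
  header <- "##gff-version 3"
  if (is.null(features) || nrow(features) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  missing_cols <- setdiff(.gff_columns, names(features))
  if (length(missing_cols)) {
    stop("features lack GFF column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  assembled <- paste(features$contig, features$source, features$type,
                     features$start, features$end, features$score,
                     features$strand, features$phase, features$attributes,
                     sep = "\t")
  if ("raw" %in% names(features)) {
    use_raw <- !is.na(features$raw)
    assembled[use_raw] <- features$raw[use_raw]
  }
  writeLines(c(header, assembled), path)
  invisible(path)
}

# GFF3 column-9 escaping: percent-encode the structural characters inside
# keys and values (RFC 3986 style, as the GFF3 spec requires).
.gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

#' Assemble a GFF3 attribute string from key-value pairs
#'
#' @param ... Named scalar values, or a single named vector/list.
#' @return A single `key=value;key=value` string with GFF3 percent-encoding
#'   applied to keys and values.
#' @export
gff_attributes <- function(...) {
  kv <- list(...)
  if (length(kv) == 1L && is.null(names(kv)) && !is.null(names(kv[[1]]))) {
    kv <- as.list(kv[[1]])
  }
  if (!length(kv) || is.null(names(kv)) || any(!nzchar(names(kv)))) {
    stop("gff_attributes() needs named values", call. = FALSE)
  }
  paste(paste0(.gff_escape(names(kv)), "=",
               .gff_escape(vapply(kv, as.character, character(1)))),
        collapse = ";")
}

#' Extract one attribute from GFF3 features
#'
#' @param features Data frame from [read_gff()] (or any frame with an
#'   `attributes` column).
#' @param key Attribute key to extract.
#' @return Character vector of decoded values, `NA` where the key is absent.
#' @export
gff_attr <- function(features, key) {
  vapply(features$attributes, function(a) {
    toks <- strsplit(a, ";", fixed = TRUE)[[1]]
    kv <- strsplit(trimws(toks), "=", fixed = TRUE)
    for (p in kv) {
      if (length(p) >= 2 && utils::URLdecode(p[1]) == key) {
        return(utils::URLdecode(paste(p[-1], collapse = "=")))
      }
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}
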