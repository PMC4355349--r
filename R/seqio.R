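#' Read a nucleotide FASTA file
#'
#' Parses a multi-FASTA of nucleotide sequences into a data frame of records.
#' Two dialects are supported: `"pseudo"` (the permissive default) tolerates
#' blank lines between records and a missing trailing newline; `"ncbi"` is
#' strict and rejects both. Sequences are uppercased on input and validated
#' against the alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @param path Path to a FASTA file, or a character vector of already-read
#'   lines (useful for in-memory parsing).
#' @param dialect `"pseudo"` or `"ncbi"`.
#' @return A data frame with columns `id`, `desc`, `seq`, one row per record
#'   in input order.
#' @details Record ids (the first whitespace-delimited token after `>`) must
#'   be unique; a duplicate id, an empty sequence under a header, or a
#'   character outside the alphabet is a hard error, the latter reported with
#'   its line number.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "ACGTAC", ">b", "GGGTTT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, dialect = c("pseudo", "ncbi")) {
  dialect <- match.arg(dialect)
  if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    incomplete <- FALSE
    lines <- withCallingHandlers(
      readLines(path),
      warning = function(w) {
        if (grepl("incomplete final line", conditionMessage(w))) {
          incomplete <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (incomplete && dialect == "ncbi")
      stop("ncbi dialect requires a trailing newline at end of file")
  } else {
    lines <- as.character(path)
  }
  nb <- which(!grepl("^\\s*$", lines))
  if (length(nb) == 0L) stop("empty FASTA input")
  if (!startsWith(lines[nb[1L]], ">"))
    stop("not FASTA: first non-blank character must be '>'")

  ids <- character(0); descs <- character(0); seqs <- character(0)
  cur_id <- NULL; cur_desc <- NULL; cur_chunks <- character(0)
  cur_header_line <- NA_integer_

  flush_record <- function() {
    if (is.null(cur_id)) return()
    s <- paste0(cur_chunks, collapse = "")
    if (nchar(s) == 0L)
      stop(sprintf("empty sequence under header '%s' (line %d)",
                   cur_id, cur_header_line))
    if (cur_id %in% ids)
      stop(sprintf("duplicate sequence id '%s' (line %d)",
                   cur_id, cur_header_line))
    ids[length(ids) + 1L] <<- cur_id
    descs[length(descs) + 1L] <<- cur_desc
    seqs[length(seqs) + 1L] <<- s
  }

  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*$", line)) {
      if (dialect == "ncbi" && ln < max(nb))
        stop(sprintf("ncbi dialect forbids blank lines (line %d)", ln))
      next
    }
    if (startsWith(line, ">")) {
      flush_record()
      header <- sub("^>\\s*", "", line)
      cur_id <- sub("\\s.*$", "", header)
      if (nchar(cur_id) == 0L)
        stop(sprintf("empty sequence id in header (line %d)", ln))
      cur_desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
      cur_chunks <- character(0)
      cur_header_line <- ln
    } else {
      s <- toupper(gsub("\\s+", "", line))
      bad <- regmatches(s, regexpr("[^ACGTN]", s))
      if (length(bad) > 0L && nchar(bad) > 0L)
        stop(sprintf("disallowed character '%s' in sequence (line %d)", bad, ln))
      cur_chunks[length(cur_chunks) + 1L] <- s
    }
  }
  flush_record()
  data.frame(id = ids, desc = descs, seq = seqs, stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records Data frame with columns `id`, `seq` and optionally `desc`.
#' @param path Output file path.
#' @param line_width Sequence characters per line (positive integer).
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(is.data.frame(records), line_width >= 1L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("desc" %in% names(records)) records$desc[i] else ""
    header <- if (nzchar(desc)) paste0(">", records$id[i], " ", desc)
              else paste0(">", records$id[i])
    writeLines(header, con)
    s <- records$seq[i]
    starts <- seq.int(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Remove likely-genomic (overlong) sequences
#'
#' Long inputs such as contigs or scaffolds are unlikely to be single genes
#' and are removed before probe design; the default cutoff of 20 kb
#' comfortably exceeds typical single-gene lengths.
#'
#' @param records Data frame of sequence records.
#' @param max_len Maximum sequence length kept (nt).
#' @return `list(kept = , removed = )`, both preserving input order and
#'   together partitioning the input exactly.
#' @export
filter_genomic <- function(records, max_len = 20000L) {
  stopifnot(is.data.frame(records), max_len >= 1L)
  keep <- nchar(records$seq) <= max_len
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Classify a list of sequence-database identifiers
#'
#' Splits free text on newlines, commas and whitespace and classifies each
#' token as a nucleotide accession, protein accession, GI number, or invalid.
#' Classification is purely syntactic (no network lookups): all-digit tokens
#' are GI numbers; RefSeq nucleotide prefixes (`NM_`, `NR_`, `XM_`, `XR_`,
#' `NC_`, `NG_`, `NT_`, `NW_`, `NZ_`) and 1-2 letters + 5-8 digits are
#' nucleotide accessions; RefSeq protein prefixes (`NP_`, `XP_`, `YP_`,
#' `AP_`, `WP_`) and 3 letters + 5-7 digits are protein accessions. A
#' trailing `.version` is allowed throughout.
#'
#' @param text A character scalar (or vector of lines) of identifiers.
#' @return Data frame with columns `raw_token`, `kind` where `kind` is one of
#'   `"nucleotide_accession"`, `"protein_accession"`, `"gi_number"`,
#'   `"invalid"`.
#' @export
parse_id_list <- function(text) {
  tokens <- unlist(strsplit(paste(text, collapse = "\n"), "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  classify <- function(tok) {
    core <- sub("\\.[0-9]+$", "", tok)
    if (grepl("^[0-9]+$", core)) return("gi_number")
    if (grepl("^(NM|NR|XM|XR|NC|NG|NT|NW|NZ)_[0-9]+$", core))
      return("nucleotide_accession")
    if (grepl("^(NP|XP|YP|AP|WP)_[0-9]+$", core))
      return("protein_accession")
    if (grepl("^[A-Za-z]{3}[0-9]{5,7}$", core)) return("protein_accession")
    if (grepl("^[A-Za-z]{1,2}[0-9]{5,8}$", core)) return("nucleotide_accession")
    "invalid"
  }
  data.frame(raw_token = tokens,
             kind = vapply(tokens, classify, character(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
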