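#' Read query sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the first record character (\code{>} FASTA,
#' \code{@} FASTQ), through gzip if needed.  Parsing goes through
#' Biostrings; sequences are uppercased and the alphabet policy applied
#' (strict: A,C,G,T only; lenient: other IUPAC codes become N, and N
#' mismatches everything).  FASTQ qualities are carried along but ignored
#' by all scoring.
#'
#' @param path FASTA/FASTQ file, plain or gzipped.
#' @param format \code{"auto"}, \code{"fasta"} or \code{"fastq"}.
#' @param alphabet_policy \code{"strict"} or \code{"iupac_to_n"}.
#' @return A \code{data.frame} with columns \code{id}, \code{sequence},
#'   \code{quality} (NA for FASTA).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           alphabet_policy = c("strict", "iupac_to_n")) {
  format <- match.arg(format)
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- ""
    while (!nzchar(first)) {
      ln <- readLines(con, 1L)
      if (length(ln) == 0L)
        return(data.frame(id = character(0), sequence = character(0),
                          quality = character(0), stringsAsFactors = FALSE))
      first <- trimws(ln)
    }
    format <- if (startsWith(first, "@")) "fastq" else if (startsWith(first, ">"))
      "fasta" else stop("cannot detect sequence format of ", path,
                        " (first record line: ", substr(first, 1, 20), ")")
  }
  if (format == "fastq") {
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    qual <- as.character(Biostrings::quality(x))
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(x))
  }
  ids <- sub("\\s.*$", "", names(x))
  seqs <- vapply(as.character(x), function(s) {
    paste(apply_alphabet_policy(chars(s), alphabet_policy), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  data.frame(id = ids, sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

# Run-length encode a per-base operation string into a CIGAR-style string
# over {=, X, I, D}, e.g. "===X=" -> "3=1X1=".
ops_to_cigar <- function(ops) {
  r <- rle(chars(ops))
  paste0(r$lengths, r$values, collapse = "")
}

cigar_to_ops <- function(cig) {
  m <- gregexpr("[0-9]+[=XID]", cig)[[1]]
  parts <- regmatches(cig, gregexpr("[0-9]+[=XID]", cig))[[1]]
  paste(unlist(lapply(parts, function(p) {
    k <- as.integer(sub("[=XID]$", "", p))
    strrep(substr(p, nchar(p), nchar(p)), k)
  })), collapse = "")
}

# Render a node path in segment space (">seg" / "<seg" runs) when segment
# provenance exists, else as an explicit node-id path ">id>id...".
format_path <- function(g, path) {
  sm <- g$segment_map
  if (is.null(sm)) return(paste0(">", paste(path, collapse = ">")))
  seg <- sm$segment[match(path, sm$node)]
  strand <- sm$strand[match(path, sm$node)]
  r <- rle(paste0(ifelse(strand == "-", "<", ">"), seg))
  paste(r$values, collapse = "")
}

#' Write alignment results in GAF-style TSV
#'
#' One line per read with the PAF-derived GAF columns: query name, query
#' length, query start and end (always 0 and the query length:
#' the alignment is semi-global in the query), strand \code{+}, path
#' (segment orientations when GFA provenance exists, else node ids), path
#' length in nodes, alignment start and end on the path, number of matches,
#' alignment block length, plus tags \code{NM:i:} (edit distance) and
#' \code{cg:Z:} (CIGAR-style operations over =, X, I, D).
#'
#' @param results A list of \code{"alignment_result"} objects.
#' @param path Output file.
#' @param g The graph aligned against (for segment-space paths).
#' @return \code{path}, invisibly.
#' @export
write_gaf <- function(results, path, g) {
  lines <- vapply(results, function(r) {
    ops <- chars(r$operations)
    paste(r$query_id,
          r$query_length,
          0L,
          r$query_length,
          "+",
          format_path(g, r$path),
          length(r$path),
          0L,
          length(r$path),
          sum(ops == "="),
          length(ops),
          sprintf("NM:i:%d", r$edit_distance),
          sprintf("cg:Z:%s", ops_to_cigar(r$operations)),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a GAF-style file written by \code{\link{write_gaf}}
#'
#' Used for round-trip validation; node-space paths are decoded back to
#' integer node ids.
#'
#' @param path GAF file.
#' @return A \code{data.frame} with the numeric columns, the decoded
#'   per-base \code{operations}, and \code{path} as a character column.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(query_id = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  tags <- lapply(f, function(x) x[-(1:11)])
  tagval <- function(prefix) vapply(tags, function(tg) {
    hit <- tg[startsWith(tg, prefix)]
    if (length(hit) == 0L) NA_character_ else sub(prefix, "", hit[[1L]])
  }, character(1))
  data.frame(query_id = get(1), query_length = as.integer(get(2)),
             query_start = as.integer(get(3)), query_end = as.integer(get(4)),
             strand = get(5), path = get(6),
             path_length = as.integer(get(7)),
             path_start = as.integer(get(8)), path_end = as.integer(get(9)),
             matches = as.integer(get(10)), block_length = as.integer(get(11)),
             edit_distance = as.integer(tagval("NM:i:")),
             operations = vapply(tagval("cg:Z:"), cigar_to_ops, character(1),
                                 USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Write exact-match results as TSV
#'
#' One line per (read, match end node): read id, end node, witness path as
#' comma-separated node ids.
#'
#' @param matches Named list (per read id) of results from
#'   \code{\link{extract_matches}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_exact_tsv <- function(matches, path) {
  lines <- character(0)
  for (id in names(matches)) {
    mt <- matches[[id]]
    if (length(mt$end_nodes) > 0L) {
      lines <- c(lines, vapply(seq_along(mt$end_nodes), function(i) {
        paste(id, mt$end_nodes[[i]],
              paste(mt$witnesses[[i]], collapse = ","), sep = "\t")
      }, character(1)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
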