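#' Read a GFA 1.0 file into a sequence graph
#'
#' Supports the overlap-free GFA 1.0 dialect: S-lines must carry explicit
#' sequences and L-lines must have overlap \code{0M} or \code{*}.  Every
#' segment of length L expands into a chain of L single-character nodes; a
#' link connects the last character of the source (in link orientation) to
#' the first character of the sink.  A \code{-} orientation refers to the
#' reverse-complement copy of the segment, which is materialized only for
#' segments actually referenced with \code{-} (or for all segments when
#' \code{double_strand = TRUE}).  Per-node provenance (segment name, offset
#' in original segment coordinates, strand) is recorded in
#' \code{segment_map} for segment-space reporting.
#'
#' P-lines and GFA 2.0 records are not supported and are skipped with a
#' warning.
#'
#' @param path Path to a GFA 1.0 file.
#' @param alphabet_policy \code{"strict"} (A,C,G,T only) or
#'   \code{"iupac_to_n"} (other IUPAC codes become N; N mismatches
#'   everything).
#' @param double_strand Materialize the reverse-complement copy of every
#'   segment, not only those referenced with \code{-}.
#' @return A \code{\link{seq_graph}} with \code{segment_map} provenance.
#' @export
read_gfa <- function(path, alphabet_policy = c("strict", "iupac_to_n"),
                     double_strand = FALSE) {
  alphabet_policy <- match.arg(alphabet_policy)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rectype <- substr(lines, 1L, 1L)
  unknown <- !(rectype %in% c("S", "L", "H", "#"))
  if (any(unknown))
    warning("skipping unsupported GFA record type(s): ",
            paste(unique(rectype[unknown]), collapse = ", "))

  segs <- strsplit(lines[rectype == "S"], "\t", fixed = TRUE)
  if (length(segs) == 0L) stop("GFA file has no S-lines")
  seg_name <- vapply(segs, `[[`, character(1), 2L)
  seg_seq <- vapply(segs, `[[`, character(1), 3L)
  if (anyDuplicated(seg_name)) stop("duplicate segment names")
  if (any(seg_seq == "*" | seg_seq == ""))
    stop("segment without an explicit sequence")

  links <- strsplit(lines[rectype == "L"], "\t", fixed = TRUE)
  parse_link <- function(f) {
    if (length(f) < 5L) stop("malformed L-line: ", paste(f, collapse = "\t"))
    ov <- if (length(f) >= 6L) f[[6L]] else "*"
    if (!(ov %in% c("0M", "*")))
      stop("unsupported L-line overlap '", ov,
           "': only the overlap-free dialect (0M or *) is supported")
    list(from = f[[2L]], from_orient = f[[3L]],
         to = f[[4L]], to_orient = f[[5L]])
  }
  links <- lapply(links, parse_link)

  # which oriented segment copies are needed
  oriented <- unique(c(paste0(seg_name, "+"),
                       if (double_strand) paste0(seg_name, "-"),
                       unlist(lapply(links, function(l) {
                         c(paste0(l$from, l$from_orient),
                           paste0(l$to, l$to_orient))
                       }))))
  base <- substr(oriented, 1L, nchar(oriented) - 1L)
  orient <- substr(oriented, nchar(oriented), nchar(oriented))
  if (!all(base %in% seg_name))
    stop("link references unknown segment: ",
         paste(unique(base[!(base %in% seg_name)]), collapse = ", "))

  labels <- character(0)
  sm_node <- integer(0); sm_seg <- character(0)
  sm_off <- integer(0); sm_strand <- character(0)
  first <- integer(length(oriented)); last <- integer(length(oriented))
  for (i in seq_along(oriented)) {
    sq <- seg_seq[match(base[i], seg_name)]
    x <- apply_alphabet_policy(chars(sq), alphabet_policy)
    L <- length(x)
    off <- seq_len(L)
    if (orient[i] == "-") {
      x <- rev(unname(.complement[x]))
      off <- rev(off)
    }
    first[i] <- length(labels) + 1L
    last[i] <- length(labels) + L
    labels <- c(labels, x)
    sm_node <- c(sm_node, first[i]:last[i])
    sm_seg <- c(sm_seg, rep(base[i], L))
    sm_off <- c(sm_off, off)
    sm_strand <- c(sm_strand, rep(orient[i], L))
  }
  names(first) <- names(last) <- oriented

  intra <- do.call(rbind, lapply(seq_along(oriented), function(i) {
    if (last[i] > first[i]) {
      a <- first[i]:(last[i] - 1L)
      cbind(a, a + 1L)
    } else NULL
  }))
  inter <- do.call(rbind, lapply(links, function(l) {
    src <- paste0(l$from, l$from_orient)
    dst <- paste0(l$to, l$to_orient)
    cbind(last[[src]], first[[dst]])
  }))
  seq_graph(labels, rbind(intra, inter),
            segment_map = data.frame(node = sm_node, segment = sm_seg,
                                     offset = sm_off, strand = sm_strand,
                                     stringsAsFactors = FALSE))
}

#' Write a sequence graph as GFA 1.0
#'
#' Each node becomes a 1-bp segment named \code{n<id>}; each edge becomes a
#' \code{+/+} link with overlap \code{0M}.  The character-graph export is
#' lossless for the internal representation but forgets any original
#' segment grouping.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_gfa <- function(g, path) {
  n <- n_nodes(g)
  s_lines <- sprintf("S\tn%d\t%s", seq_len(n), g$labels)
  l_lines <- if (n_edges(g) > 0L)
    sprintf("L\tn%d\t+\tn%d\t+\t0M", g$edges[, 1L], g$edges[, 2L]) else character(0)
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}

#' Write a sequence graph as a simple node/edge TSV (for debugging)
#'
#' One \code{N <id> <label>} line per node and one \code{E <from> <to>}
#' line per edge.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  n <- n_nodes(g)
  nl <- sprintf("N\t%d\t%s", seq_len(n), g$labels)
  el <- if (n_edges(g) > 0L)
    sprintf("E\t%d\t%d", g$edges[, 1L], g$edges[, 2L]) else character(0)
  writeLines(c(nl, el), path)
  invisible(path)
}
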