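#' End-to-end alignment pipeline
#'
#' Loads a graph (GFA path or \code{\link{seq_graph}}) and reads (FASTA /
#' FASTQ path or a \code{data.frame} with \code{id} and \code{sequence}),
#' aligns every read with the requested solver, optionally re-runs each
#' read through the Dijkstra oracle (\code{crosscheck}) and stops on any
#' disagreement, and writes GAF-style output.  Deterministic: the same
#' inputs and configuration produce byte-identical output.
#'
#' @param graph GFA file path or a \code{\link{seq_graph}}.
#' @param reads FASTA/FASTQ file path or a \code{data.frame}.
#' @param mode \code{"bitvector"}, \code{"cellwise"} or \code{"dijkstra"}.
#' @param word_size Word size for the bitvector mode.
#' @param out Output GAF path, or \code{NULL} to skip writing.
#' @param crosscheck Verify every read's full score matrix against the
#'   Dijkstra oracle.
#' @param alphabet_policy Alphabet policy for graph and reads.
#' @param verbose Log per-read distances and pop diagnostics to stderr.
#' @return Invisibly, a list with \code{results} (alignment results),
#'   \code{gaf} (output path or NULL) and \code{status} (0 on success).
#' @export
run_pipeline <- function(graph, reads, mode = c("bitvector", "cellwise", "dijkstra"),
                         word_size = 64L, out = NULL, crosscheck = FALSE,
                         alphabet_policy = c("strict", "iupac_to_n"),
                         verbose = FALSE) {
  mode <- match.arg(mode)
  alphabet_policy <- match.arg(alphabet_policy)
  g <- if (inherits(graph, "seq_graph")) graph else
    read_gfa(graph, alphabet_policy = alphabet_policy)
  rd <- if (is.data.frame(reads)) reads else
    read_sequences(reads, alphabet_policy = alphabet_policy)
  if (nrow(rd) == 0L) {
    if (!is.null(out)) writeLines(character(0), out)
    return(invisible(list(results = list(), gaf = out, status = 0L)))
  }
  results <- vector("list", nrow(rd))
  for (i in seq_len(nrow(rd))) {
    res <- align_graph(g, rd$sequence[[i]], mode = mode,
                       word_size = word_size, query_id = rd$id[[i]],
                       crosscheck = crosscheck)
    validate_alignment(res, g, rd$sequence[[i]])
    attr(res, "matrix") <- NULL
    results[[i]] <- res
    if (verbose)
      message(sprintf("%s: length %d, edit distance %d, path %d node(s)",
                      res$query_id, res$query_length, res$edit_distance,
                      length(res$path)))
  }
  if (!is.null(out)) write_gaf(results, out, g)
  invisible(list(results = results, gaf = out, status = 0L))
}

#' Exact-matching pipeline
#'
#' Runs the Shift-And matcher for every read and writes a TSV of match end
#' nodes and witness paths.
#'
#' @inheritParams run_pipeline
#' @param enumerate,max_paths Passed to \code{\link{extract_matches}}.
#' @return Invisibly, a named list of per-read match sets.
#' @export
run_exact_pipeline <- function(graph, reads, word_size = 64L, out = NULL,
                               enumerate = FALSE, max_paths = 1000L,
                               alphabet_policy = c("strict", "iupac_to_n")) {
  alphabet_policy <- match.arg(alphabet_policy)
  g <- if (inherits(graph, "seq_graph")) graph else
    read_gfa(graph, alphabet_policy = alphabet_policy)
  rd <- if (is.data.frame(reads)) reads else
    read_sequences(reads, alphabet_policy = alphabet_policy)
  acyclic <- is_acyclic(g)
  matches <- list()
  for (i in seq_len(nrow(rd))) {
    st <- if (acyclic) shift_and_dag(g, rd$sequence[[i]], word_size) else
      shift_and_cyclic(g, rd$sequence[[i]], word_size)
    matches[[rd$id[[i]]]] <- extract_matches(st, g, enumerate = enumerate,
                                             max_paths = max_paths)
  }
  if (!is.null(out)) write_exact_tsv(matches, out)
  invisible(matches)
}
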