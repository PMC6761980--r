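#' Bucket priority queue with monotone decrease-key
#'
#' Priorities are small integers bounded by the query length, so the queue
#' is an array of buckets (one per priority) plus a per-item record of the
#' current priority, giving amortized constant-time push and pop.
#' \code{bucket_push(q, p, v)} inserts \code{v} at priority \code{p} if it
#' is absent, lowers its priority if \code{p} is smaller than the current
#' one, and otherwise does nothing.  \code{bucket_pop} returns a
#' minimum-priority item, advancing a scan pointer over the buckets; a push
#' below the scan pointer moves it back (counted in \code{backward_moves}).
#'
#' @param n_items Number of distinct items (ids 1..n_items).
#' @param max_priority Largest priority that can be pushed.
#' @return An environment of class \code{"bucket_queue"}.
#' @examples
#' q <- bucket_queue(5, 10)
#' bucket_push(q, 3, 1); bucket_push(q, 1, 1)
#' bucket_pop(q)  # item 1 at priority 1 (decrease-key)
#' @export
bucket_queue <- function(n_items, max_priority) {
  q <- new.env(parent = emptyenv())
  q$buckets <- vector("list", max_priority + 1L)   # bucket i holds priority i-1
  q$cur <- rep(NA_integer_, n_items)
  q$scan <- 0L
  q$backward_moves <- 0L
  q$max_priority <- as.integer(max_priority)
  class(q) <- "bucket_queue"
  q
}

#' @rdname bucket_queue
#' @param q A \code{bucket_queue}.
#' @param p Priority (0..max_priority).
#' @param v Item id.
#' @export
bucket_push <- function(q, p, v) {
  p <- as.integer(p); v <- as.integer(v)
  if (p < 0L || p > q$max_priority) stop("priority out of range")
  cur <- q$cur[v]
  if (!is.na(cur) && cur <= p) return(invisible(FALSE))  # no-op
  q$cur[v] <- p
  q$buckets[[p + 1L]] <- c(q$buckets[[p + 1L]], v)       # lazy: stale copy may remain
  if (p < q$scan) {
    q$scan <- p
    q$backward_moves <- q$backward_moves + 1L
  }
  invisible(TRUE)
}

#' @rdname bucket_queue
#' @return \code{bucket_pop}: a list \code{(priority, item)}, or \code{NULL}
#'   when the queue is empty.
#' @export
bucket_pop <- function(q) {
  while (q$scan <= q$max_priority) {
    b <- q$buckets[[q$scan + 1L]]
    while (length(b) > 0L) {
      v <- b[[length(b)]]
      b <- b[-length(b)]
      q$buckets[[q$scan + 1L]] <- b
      if (!is.na(q$cur[v]) && q$cur[v] == q$scan) {
        q$cur[v] <- NA_integer_
        return(list(priority = q$scan, item = v))
      }
    }
    q$scan <- q$scan + 1L
  }
  NULL
}

#' @rdname bucket_queue
#' @export
bucket_empty <- function(q) {
  all(is.na(q$cur))
}
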