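## Store-and-forward outbox
##
## Records produced while the uplink is down are held locally and
## re-sent after recovery: entries are drained in insertion order,
## failures stay pending with their attempt count incremented, and a
## record is marked sent exactly once (at-least-once delivery towards
## the sink).

#' Create an in-memory outbox
#'
#' @returns an `outbox` object.
#' @export
#' @examples
#' ob <- create_outbox()
#' outbox_enqueue(ob, lifelog_record("u1", "pedometer",
#'                                   "2026-01-05T12:00:00",
#'                                   list(c(steps = "4200"))))
#' outbox_drain(ob, sink = function(record) TRUE)
#' outbox_status(ob)
create_outbox <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  env$status <- character(0)
  env$attempts <- integer(0)
  structure(env, class = "outbox")
}

#' Enqueue a record
#'
#' @param outbox an `outbox`.
#' @param record the record to hold (any R object, typically a one-row
#'   `lifelog` tibble).
#' @returns the entry id (position), invisibly.
#' @export
outbox_enqueue <- function(outbox, record) {
  stopifnot(inherits(outbox, "outbox"))
  i <- length(outbox$records) + 1L
  outbox$records[[i]] <- record
  outbox$status[i] <- "pending"
  outbox$attempts[i] <- 0L
  invisible(i)
}

#' Drain pending entries through a sink
#'
#' Attempts every pending entry, in insertion order, against
#' `sink(record)`. A sink call returning `TRUE` marks the entry sent;
#' `FALSE` (or an error) leaves it pending with its attempt count
#' incremented, to be retried on the next drain.
#'
#' @param outbox an `outbox`.
#' @param sink function of one argument returning `TRUE` on successful
#'   delivery.
#' @returns delivery report tibble: `id`, `status`, `attempts`.
#' @export
outbox_drain <- function(outbox, sink) {
  stopifnot(inherits(outbox, "outbox"), is.function(sink))
  for (i in seq_along(outbox$records)) {
    if (outbox$status[i] != "pending") next
    outbox$attempts[i] <- outbox$attempts[i] + 1L
    ok <- tryCatch(isTRUE(sink(outbox$records[[i]])),
                   error = function(e) FALSE)
    if (ok) outbox$status[i] <- "sent"
  }
  outbox_status(outbox)
}

#' Outbox delivery state
#'
#' @param outbox an `outbox`.
#' @returns tibble `id`, `status` (`pending`/`sent`), `attempts`.
#' @export
outbox_status <- function(outbox) {
  stopifnot(inherits(outbox, "outbox"))
  tibble::tibble(id = seq_along(outbox$records),
                 status = outbox$status,
                 attempts = outbox$attempts)
}

#' @export
print.outbox <- function(x, ...) {
  cat(sprintf("<outbox> %d entries (%d pending, %d sent)\n",
              length(x$records), sum(x$status == "pending"),
              sum(x$status == "sent")))
  invisible(x)
}
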