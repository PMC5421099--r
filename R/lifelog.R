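## Life-log records and XML serialisation
##
## Daily-life records (sleep, activity, diet, anthropometrics) travel
## between the phone and the server as a small XML dialect: one
## <record> element per entry with user/kind/timestamp attributes and one
## <field name=...> element per payload value. The contract is the
## round-trip property, not an external schema.

LIFELOG_KINDS <- c("height", "age", "weight", "body_temperature", "meal",
                   "bedtime", "awaking", "acceleration", "pedometer",
                   "gps", "travel_distance", "calorie")
## kinds recorded once at registration; all others are timestamped events
LIFELOG_PRIMARY <- c("height", "age")

#' Construct a life-log record table
#'
#' @param user_id user (system) identifier.
#' @param kind record kind, one of the supported items (height, age,
#'   weight, body_temperature, meal, bedtime, awaking, acceleration,
#'   pedometer, gps, travel_distance, calorie).
#' @param timestamp ISO-8601 character timestamp; required for every kind
#'   except the registration items height and age.
#' @param payload list of named character vectors with kind-specific
#'   values (e.g. a meal carries image, place, gps and date).
#' @returns a `lifelog` tibble.
#' @export
#' @examples
#' lifelog_record("u1", "weight", "2026-01-05T08:00:00",
#'                payload = list(c(value = "72.5")))
lifelog_record <- function(user_id, kind, timestamp = NA_character_,
                           payload = list(character(0))) {
  bad <- setdiff(unique(kind), LIFELOG_KINDS)
  if (length(bad)) {
    ppgbp_abort(paste0("unknown life-log kind(s): ",
                       paste(bad, collapse = ", ")),
                "ppgbp_error_schema")
  }
  out <- tibble::tibble(user_id = user_id, kind = kind,
                        timestamp = timestamp,
                        payload = payload)
  class(out) <- c("lifelog", class(out))
  out
}

check_lifelog_row <- function(kind, timestamp) {
  if (!kind %in% LIFELOG_KINDS) {
    return(paste0("unknown kind: ", kind))
  }
  if (!kind %in% LIFELOG_PRIMARY &&
      (is.na(timestamp) || !nzchar(timestamp))) {
    return(paste0("missing timestamp for event kind: ", kind))
  }
  NA_character_
}

#' Serialise life-log records to XML
#'
#' @param records a `lifelog` tibble (see [lifelog_record()]).
#' @param path optional file path; when omitted the `xml2` document is
#'   returned.
#' @returns the document (invisibly when written to `path`).
#' @export
write_lifelog_xml <- function(records, path = NULL) {
  bad <- setdiff(unique(records$kind), LIFELOG_KINDS)
  if (length(bad)) {
    ppgbp_abort(paste0("unknown life-log kind(s): ",
                       paste(bad, collapse = ", ")),
                "ppgbp_error_schema")
  }
  doc <- xml2::xml_new_root("lifelog")
  for (i in seq_len(nrow(records))) {
    rec <- xml2::xml_add_child(doc, "record",
                               user = records$user_id[i],
                               kind = records$kind[i])
    if (!is.na(records$timestamp[i])) {
      xml2::xml_set_attr(rec, "timestamp", records$timestamp[i])
    }
    pl <- records$payload[[i]]
    for (nm in names(pl)) {
      xml2::xml_add_child(rec, "field", pl[[nm]], name = nm)
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Parse life-log records from XML
#'
#' Valid records are returned in document order; malformed records
#' (unknown kind, missing timestamp on an event kind) are collected into
#' a rejects table with the reason.
#'
#' @param x an `xml2` document, a path, or an XML string.
#' @returns list with `records` (a `lifelog` tibble) and `rejects`
#'   (tibble `index`, `reason`).
#' @export
read_lifelog_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  nodes <- xml2::xml_find_all(doc, "/lifelog/record")
  rows <- list(); rejects <- list()
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    kind <- xml2::xml_attr(nd, "kind")
    ts <- xml2::xml_attr(nd, "timestamp")
    if (is.na(ts)) ts <- NA_character_
    reason <- check_lifelog_row(kind, ts)
    if (!is.na(reason)) {
      rejects[[length(rejects) + 1L]] <- tibble::tibble(index = i,
                                                        reason = reason)
      next
    }
    fields <- xml2::xml_find_all(nd, "field")
    pl <- setNames(xml2::xml_text(fields), xml2::xml_attr(fields, "name"))
    rows[[length(rows) + 1L]] <- lifelog_record(
      user_id = xml2::xml_attr(nd, "user"), kind = kind, timestamp = ts,
      payload = list(pl))
  }
  records <- if (length(rows)) dplyr::bind_rows(rows) else
    lifelog_record(character(0), character(0), character(0), list())[0, ]
  list(records = records,
       rejects = if (length(rejects)) dplyr::bind_rows(rejects) else
         tibble::tibble(index = integer(0), reason = character(0)))
}
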