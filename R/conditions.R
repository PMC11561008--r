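#' @title Classed error conditions
#' @description All fatal errors raised by cyclehealth carry a machine-readable
#'   code as a condition class (`cyclehealth_error_<CODE>`) plus the generic
#'   class `cyclehealth_error`, so callers can branch on the code without
#'   string-matching messages. Errors that concern a specific input row name
#'   the row index in the `row` field.
#' @noRd
ch_abort <- function(code, message, row = NULL, data = NULL) {
  cond <- structure(
    class = c(paste0("cyclehealth_error_", code), "cyclehealth_error",
              "error", "condition"),
    list(message = if (is.null(row)) message
                   else sprintf("%s (row %s)", message, row),
         call = sys.call(-1), code = code, row = row, data = data)
  )
  stop(cond)
}

#' Structured warning record used by [validate_log()]
#' @noRd
ch_warning_record <- function(kind, message, detail = NA_character_) {
  data.frame(kind = kind, message = message, detail = as.character(detail),
             stringsAsFactors = FALSE)
}
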