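#' Canonical JSON serialization of analysis parameters
#'
#' The analysis log stores every operation's parameters in a canonical text
#' form: object keys sorted, numbers written with 17 significant digits so
#' that doubles round-trip exactly, no insignificant whitespace. Two
#' parameter sets are the same analysis step if and only if their canonical
#' documents are equal.
#'
#' @param x a list (possibly nested) of parameters: numbers, strings,
#'   logicals, vectors and lists thereof.
#' @return A single JSON string.
#' @export
canonical_json <- function(x) {
  fmt <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v) && !is.null(names(v)) && length(v) > 0) {
      nm <- sort(names(v))
      inner <- vapply(nm, function(k) {
        paste0(jsonlite::toJSON(k, auto_unbox = TRUE), ":", fmt(v[[k]]))
      }, character(1))
      return(paste0("{", paste(inner, collapse = ","), "}"))
    }
    if (is.list(v)) {
      return(paste0("[", paste(vapply(v, fmt, character(1)), collapse = ","), "]"))
    }
    if (is.numeric(v)) {
      s <- vapply(v, function(z) {
        if (!is.finite(z)) stop("non-finite value in parameters", call. = FALSE)
        if (z == round(z) && abs(z) < 2^53) {
          sprintf("%.0f", z)
        } else {
          sprintf("%.17g", z)
        }
      }, character(1))
      return(if (length(s) == 1L) s else paste0("[", paste(s, collapse = ","), "]"))
    }
    if (is.logical(v)) {
      s <- ifelse(v, "true", "false")
      return(if (length(s) == 1L) s else paste0("[", paste(s, collapse = ","), "]"))
    }
    if (is.character(v)) {
      s <- vapply(v, function(z) as.character(jsonlite::toJSON(z, auto_unbox = TRUE)),
                  character(1))
      return(if (length(s) == 1L) s else paste0("[", paste(s, collapse = ","), "]"))
    }
    stop("unsupported parameter type: ", class(v)[1], call. = FALSE)
  }
  fmt(x)
}

parse_canonical_json <- function(txt) {
  jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}
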