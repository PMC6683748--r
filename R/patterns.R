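#' Define a fluorescent channel panel
#'
#' A panel is the ordered set of fluorescent channels available for
#' combinatorial barcoding (e.g. Con A conjugated to distinct fluorophores,
#' one conjugate per channel). The order is fixed for the lifetime of an
#' experiment: barcode strings such as `"101"` are always read in panel
#' order.
#'
#' @param names Character vector of unique channel identifiers, between 1
#'   and 8 channels.
#' @return An object of class `channel_panel` with fields `names` and
#'   `count`.
#' @examples
#' channel_panel(c("blue", "green", "orange"))
#' @export
channel_panel <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L || length(names) > 8L) {
    stop("a channel panel must have between 1 and 8 channels, got ",
         length(names))
  }
  if (anyDuplicated(names)) {
    stop("channel names must be unique")
  }
  if (any(!nzchar(names)) || anyNA(names)) {
    stop("channel names must be non-empty strings")
  }
  structure(list(names = names, count = length(names)),
            class = "channel_panel")
}

#' @export
print.channel_panel <- function(x, ...) {
  cat("channel_panel:", x$count, "channels:",
      paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

as_panel <- function(panel) {
  if (inherits(panel, "channel_panel")) return(panel)
  channel_panel(panel)
}

#' Enumerate all usable barcode patterns for a panel
#'
#' Each channel is either present (1) or absent (0) in a barcode; the
#' all-absent combination is excluded because an unstained cell cannot be
#' told apart from a failed stain. A panel of n channels therefore yields
#' 2^n - 1 patterns: 7 for three channels, 15 for four, 31 for five.
#'
#' Patterns are returned in ascending binary order, reading the first
#' channel of the panel as the most significant bit, so the order matches
#' a lexicographic sort of the pattern strings.
#'
#' @param panel A [channel_panel()] (or a character vector of channel
#'   names).
#' @return A list of integer 0/1 vectors, each of length `panel$count` and
#'   named by channel. Each vector carries its string form (e.g. `"101"`)
#'   as attribute `"label"`.
#' @examples
#' length(enumerate_patterns(channel_panel(c("R", "G", "B")))) # 7
#' @export
enumerate_patterns <- function(panel) {
  panel <- as_panel(panel)
  n <- panel$count
  lapply(seq_len(2L^n - 1L), function(v) {
    bits <- as.integer(intToBits(v))[n:1]  # first channel = MSB
    names(bits) <- panel$names
    attr(bits, "label") <- paste(bits, collapse = "")
    bits
  })
}

#' Format a barcode pattern as a string in panel order
#'
#' @param bits Integer 0/1 vector (one element per channel).
#' @return A string such as `"101"`.
#' @export
pattern_label <- function(bits) {
  paste(as.integer(bits), collapse = "")
}

#' Parse a barcode pattern string back to a bit vector
#'
#' @param label A string of 0s and 1s in panel order, e.g. `"101"`.
#' @param panel The [channel_panel()] the string refers to.
#' @return Named integer 0/1 vector.
#' @export
parse_pattern <- function(label, panel) {
  panel <- as_panel(panel)
  chars <- strsplit(label, "")[[1L]]
  if (length(chars) != panel$count || !all(chars %in% c("0", "1"))) {
    stop("pattern '", label, "' is not a ", panel$count,
         "-bit binary string")
  }
  bits <- as.integer(chars)
  names(bits) <- panel$names
  attr(bits, "label") <- label
  bits
}

# Validate a patterns-in-use list against a panel; returns the list with
# labels attached, erroring on zero patterns, duplicates or foreign bits.
check_patterns <- function(patterns, panel) {
  panel <- as_panel(panel)
  if (length(patterns) < 1L) stop("at least one pattern is required")
  patterns <- lapply(patterns, function(p) {
    if (is.character(p)) p <- parse_pattern(p, panel)
    p <- as.integer(p)
    if (length(p) != panel$count || !all(p %in% c(0L, 1L))) {
      stop("patterns must be 0/1 vectors of length ", panel$count)
    }
    if (sum(p) == 0L) stop("the all-zero pattern is not a valid barcode")
    names(p) <- panel$names
    attr(p, "label") <- pattern_label(p)
    p
  })
  labels <- vapply(patterns, attr, "", which = "label")
  if (anyDuplicated(labels)) stop("duplicate patterns in use")
  patterns
}
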