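#' GenBank feature location parsing
#'
#' Parses the subset of the GenBank location grammar used by CDS features:
#' plain ranges `a..b`, single bases `a`, `join(...)`, a single outer
#' `complement(...)`, and the open-end markers `<` / `>` that flag
#' incomplete 5' / 3' ends. `order()` and `bond()` operators and
#' mixed-strand joins (a `complement()` nested inside `join()`) are
#' rejected: trans-spliced features are out of scope.
#'
#' @param text Location string, e.g. `"complement(join(10..20,30..40))"`.
#' @return A `gb_location`: list with `intervals` (two-column matrix of
#'   1-based inclusive start/end, in coding order), `strand` (+1 or -1),
#'   `left_open`, `right_open` (logical `<` / `>` markers, in plus-strand
#'   orientation of the location string).
#' @export
#' @examples
#' parse_location("<1..300")
#' parse_location("complement(join(10..20,30..40))")
parse_location <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("parse_location: empty location")
  s <- gsub("[[:space:]]", "", text)
  if (grepl("order\\(|bond\\(|site\\(", s))
    stop("parse_location: unsupported operator in '", text, "'")

  strand <- 1L
  if (grepl("^complement\\(", s)) {
    inner <- .strip_call(s, "complement")
    strand <- -1L
    s <- inner
  }
  if (grepl("complement\\(", s))
    stop("parse_location: mixed-strand location '", text, "'")

  parts <- if (grepl("^join\\(", s)) {
    strsplit(.strip_call(s, "join"), ",", fixed = TRUE)[[1]]
  } else s
  if (length(parts) < 1L || any(!nzchar(parts)))
    stop("parse_location: cannot parse '", text, "'")

  left_open <- FALSE
  right_open <- FALSE
  iv <- matrix(0L, nrow = length(parts), ncol = 2L,
               dimnames = list(NULL, c("start", "end")))
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (i == 1L && startsWith(p, "<")) { left_open <- TRUE; p <- substring(p, 2L) }
    if (i == length(parts) && grepl(">", p, fixed = TRUE)) {
      right_open <- TRUE; p <- sub(">", "", p, fixed = TRUE)
    }
    if (grepl("[<>^]", p))
      stop("parse_location: cannot parse segment '", parts[i], "' in '", text, "'")
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      ab <- rep(as.integer(p), 2L)
    } else {
      stop("parse_location: cannot parse segment '", parts[i], "' in '", text, "'")
    }
    if (ab[1] > ab[2])
      stop("parse_location: start > end in '", parts[i], "'")
    iv[i, ] <- ab
  }
  # coding order: a minus-strand join lists plus-strand coordinates, the
  # coding sequence reads the intervals last-to-first
  if (strand < 0L) iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
  structure(list(intervals = iv, strand = strand,
                 left_open = left_open, right_open = right_open),
            class = "gb_location")
}

.strip_call <- function(s, fn) {
  pre <- paste0(fn, "(")
  if (!startsWith(s, pre) || !endsWith(s, ")"))
    stop("parse_location: unbalanced '", fn, "' in '", s, "'")
  substr(s, nchar(pre) + 1L, nchar(s) - 1L)
}

#' Strand-corrected partial-end flags
#'
#' The `<` marker sits on the smallest plus-strand coordinate and `>` on
#' the largest. On the plus strand these are the 5' and 3' ends; on the
#' minus strand the mapping is swapped.
#'
#' @param loc A `gb_location` from [parse_location()].
#' @return Named logical vector `c(partial5=, partial3=)`.
#' @export
partial_flags <- function(loc) {
  stopifnot(inherits(loc, "gb_location"))
  if (loc$strand >= 0L) {
    c(partial5 = loc$left_open, partial3 = loc$right_open)
  } else {
    c(partial5 = loc$right_open, partial3 = loc$left_open)
  }
}

#' Total nucleotide span of a location
#' @param loc A `gb_location`.
#' @return Integer sum of interval lengths.
#' @export
location_width <- function(loc) {
  sum(loc$intervals[, "end"] - loc$intervals[, "start"] + 1L)
}

#' Extract the spliced coding-strand sequence for a location
#'
#' Slices each interval from the plus-strand entry sequence, concatenates
#' in plus-strand order, and reverse-complements for minus-strand
#' locations so the result reads 5' to 3' on the coding strand.
#'
#' @param loc A `gb_location`.
#' @param origin Uppercase plus-strand nucleotide sequence of the entry.
#' @return Spliced CDS nucleotide string.
#' @export
splice_sequence <- function(loc, origin) {
  iv <- loc$intervals
  if (loc$strand < 0L) iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
  if (max(iv[, "end"]) > nchar(origin))
    stop("splice_sequence: location exceeds sequence length")
  plus <- paste(substring(origin, iv[, "start"], iv[, "end"]), collapse = "")
  if (loc$strand < 0L) reverse_complement(plus) else toupper(plus)
}

#' @export
print.gb_location <- function(x, ...) {
  cat(sprintf("<gb_location strand=%+d %s%s>\n", x$strand,
              paste(sprintf("%d..%d", x$intervals[, 1], x$intervals[, 2]),
                    collapse = ","),
              paste0(if (x$left_open) " 5'<" else "",
                     if (x$right_open) " 3'>" else "")))
  invisible(x)
}
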