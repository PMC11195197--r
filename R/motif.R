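# Degenerate FBE consensus classes and exact pattern matching.

# Allowed bases for each consensus symbol. Literal bases match only
# themselves; R and Y are the purine/pyrimidine two-fold degeneracies of the
# FBE grammar; n is any of the four bases. The ambiguous input base N is
# deliberately absent from every set: an exact-match search gives no credit
# for ambiguity (see `normalize_sequence`).
.FBE_SYMBOL_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"),
  Y = c("C", "U"),
  n = c("A", "C", "G", "U")
)

.FBE_CONSENSI <- c(
  FBE9    = "UGURnnAUn",
  CFBE8   = "UGURnAUn",
  ASTAR9  = "UGUYRnAUn",
  ASTAR10 = "UGUnRnnAUn"
)

#' FBE consensus pattern
#'
#' Construct a degenerate RNA consensus pattern over the symbols
#' `{A, C, G, U, R, Y, n}` (R = A/G, Y = C/U, n = any base).
#'
#' @param name Element-class label.
#' @param consensus Consensus string, e.g. `"UGURnnAUn"`.
#' @param is_canonical Logical; `TRUE` only for the canonical 9-nt FBE.
#' @return An object of class `fbe_pattern` with fields `name`, `symbols`,
#'   `length` and `is_canonical`.
#' @examples
#' fbe_pattern("FBE9", "UGURnnAUn", is_canonical = TRUE)
#' @export
fbe_pattern <- function(name, consensus, is_canonical = FALSE) {
  symbols <- strsplit(consensus, "", fixed = TRUE)[[1]]
  bad <- which(!symbols %in% names(.FBE_SYMBOL_SETS))
  if (length(bad) > 0L) {
    stop("invalid consensus symbol '", symbols[bad[1L]], "' at position ",
         bad[1L], " of pattern '", name, "'")
  }
  if (length(symbols) < 3L || !identical(symbols[1:3], c("U", "G", "U"))) {
    stop("FBE consensus must start with UGU: '", consensus, "'")
  }
  structure(
    list(name = name, symbols = symbols, length = length(symbols),
         is_canonical = isTRUE(is_canonical)),
    class = "fbe_pattern"
  )
}

#' @export
print.fbe_pattern <- function(x, ...) {
  cat(sprintf("<fbe_pattern> %s: 5'-%s-3' (%d nt%s)\n", x$name,
              paste(x$symbols, collapse = ""), x$length,
              if (x$is_canonical) ", canonical" else ""))
  invisible(x)
}

#' The four FBE element classes
#'
#' Returns the default set of FBF-binding-element consensus classes used in
#' the adjacent-element search: the canonical 9-nt FBE (`FBE9`,
#' `UGURnnAUn`), the compact 8-nt FBE (`CFBE8`, `UGURnAUn`) and the two
#' FBEa*-like variants (`ASTAR9`, `UGUYRnAUn`; `ASTAR10`, `UGUnRnnAUn`).
#' Only `FBE9` is flagged canonical.
#'
#' @param names Optional character vector selecting a subset by name.
#' @return A named list of [fbe_pattern] objects.
#' @examples
#' fbe_patterns()
#' @export
fbe_patterns <- function(names = NULL) {
  pats <- mapply(function(nm, cons) {
    fbe_pattern(nm, cons, is_canonical = (nm == "FBE9"))
  }, names(.FBE_CONSENSI), .FBE_CONSENSI, SIMPLIFY = FALSE)
  if (!is.null(names)) {
    unknown <- setdiff(names, base::names(pats))
    if (length(unknown) > 0L) stop("unknown pattern class: ",
                                   paste(unknown, collapse = ", "))
    pats <- pats[names]
  }
  pats
}

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases, maps T to U, and validates the alphabet, so DNA-alphabet peak
#' FASTA can be scanned unchanged. The ambiguous base N is retained but is
#' never matched by any consensus symbol during exact matching (not even by
#' `n`, unless explicitly enabled in [match_positions]).
#'
#' @param raw Character scalar over `{A,C,G,T,U,N}` (either case).
#' @return Uppercase RNA string.
#' @examples
#' normalize_sequence("catgt")  # "CAUGU"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  up <- chartr("acgtun", "ACGUUN", raw)
  up <- chartr("T", "U", up)
  chars <- strsplit(up, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U", "N"))
  if (length(bad) > 0L) {
    stop("invalid nucleotide character '",
         substr(raw, bad[1L], bad[1L]), "' at position ", bad[1L])
  }
  up
}

#' Does a consensus symbol match a base?
#'
#' Literal symbols match only themselves, `R` matches A/G, `Y` matches C/U,
#' and `n` matches any of the four bases. The ambiguous base N matches
#' nothing.
#'
#' @param symbol One of `A,C,G,U,R,Y,n`.
#' @param base Base character(s); vectorized over `base`.
#' @return Logical vector.
#' @examples
#' symbol_matches("R", c("A", "G", "C"))
#' @export
symbol_matches <- function(symbol, base) {
  allowed <- .FBE_SYMBOL_SETS[[symbol]]
  if (is.null(allowed)) stop("invalid consensus symbol '", symbol, "'")
  base %in% allowed
}

.empty_matches <- function() {
  data.frame(seq_id = character(), pattern = character(),
             start = integer(), length = integer(),
             end = integer(), match = character(),
             is_canonical = logical(), stringsAsFactors = FALSE)
}

#' Find all exact matches of a consensus pattern
#'
#' Reports every start offset at which all symbols of `pattern` match the
#' corresponding bases of `seq`, including overlapping occurrences.
#' Coordinates are 1-based inclusive.
#'
#' @param seq Normalized RNA string (see [normalize_sequence]).
#' @param pattern An [fbe_pattern].
#' @param seq_id Identifier recorded in the output.
#' @param n_matches_ambiguous If `TRUE`, the consensus symbol `n` also
#'   accepts the ambiguous input base N. Default `FALSE` (exact matching).
#' @return data.frame with columns `seq_id`, `pattern`, `start`, `length`,
#'   `end`, `match`, `is_canonical`, ordered by `start`.
#' @examples
#' match_positions("UGUGCCAUA", fbe_patterns()$FBE9)
#' @export
match_positions <- function(seq, pattern, seq_id = "seq",
                            n_matches_ambiguous = FALSE) {
  stopifnot(inherits(pattern, "fbe_pattern"))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  m <- pattern$length
  if (L < m) return(.empty_matches())
  n_starts <- L - m + 1L
  ok <- rep(TRUE, n_starts)
  for (j in seq_len(m)) {
    allowed <- .FBE_SYMBOL_SETS[[pattern$symbols[j]]]
    if (n_matches_ambiguous && pattern$symbols[j] == "n") {
      allowed <- c(allowed, "N")
    }
    ok <- ok & chars[seq_len(n_starts) + (j - 1L)] %in% allowed
    if (!any(ok)) return(.empty_matches())
  }
  starts <- which(ok)
  data.frame(
    seq_id = seq_id, pattern = pattern$name,
    start = starts, length = m, end = starts + m - 1L,
    match = substring(seq, starts, starts + m - 1L),
    is_canonical = pattern$is_canonical,
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence with all FBE classes
#'
#' Union of [match_positions] over a set of consensus classes. Matches of
#' different classes at the same start are reported as distinct records.
#'
#' @inheritParams match_positions
#' @param patterns A list of [fbe_pattern] objects; defaults to the four
#'   classes of [fbe_patterns].
#' @return data.frame as in [match_positions], ordered by `start` then
#'   pattern name.
#' @examples
#' scan_all("AUCAUGUGCCAUACAUCAUGUUGCCAUUU")
#' @export
scan_all <- function(seq, patterns = fbe_patterns(), seq_id = "seq",
                     n_matches_ambiguous = FALSE) {
  hits <- lapply(patterns, match_positions, seq = seq, seq_id = seq_id,
                 n_matches_ambiguous = n_matches_ambiguous)
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0L) return(.empty_matches())
  out <- out[order(out$start, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}
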