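# Independent brute-force oracles, written against the element definitions
# directly and kept free of the package's matching code paths.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"),
  Y = c("C", "U"),
  n = c("A", "C", "G", "U")
)

ORACLE_CONSENSI <- c(
  FBE9    = "UGURnnAUn",
  CFBE8   = "UGURnAUn",
  ASTAR9  = "UGUYRnAUn",
  ASTAR10 = "UGUnRnnAUn"
)

# All 1-based start offsets where the consensus matches, by explicit
# position-by-position checking at every offset.
oracle_match_starts <- function(seq, consensus) {
  sym <- strsplit(consensus, "")[[1]]
  chars <- strsplit(seq, "")[[1]]
  m <- length(sym)
  L <- length(chars)
  starts <- integer(0)
  if (L < m) return(starts)
  for (s in seq_len(L - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(chars[s + j - 1L] %in% ORACLE_SETS[[sym[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# Every (pattern, start) hit over the four element classes.
oracle_scan <- function(seq) {
  hits <- lapply(names(ORACLE_CONSENSI), function(nm) {
    st <- oracle_match_starts(seq, ORACLE_CONSENSI[[nm]])
    if (length(st) == 0L) return(NULL)
    data.frame(pattern = nm, start = st,
               length = nchar(ORACLE_CONSENSI[[nm]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(pattern = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  out[order(out$start, out$pattern), , drop = FALSE]
}

# Qualifying adjacent pairs by direct enumeration over the oracle hits.
oracle_pair_count <- function(seq, min_gap = 1L, max_gap = 20L) {
  hits <- oracle_scan(seq)
  n <- nrow(hits)
  if (n < 2L) return(0L)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (hits$pattern[i] != "FBE9" && hits$pattern[j] != "FBE9") next
      up <- if (hits$start[i] <= hits$start[j]) i else j
      dn <- if (up == i) j else i
      gap <- hits$start[dn] - hits$start[up] - hits$length[up]
      if (gap >= min_gap && gap <= max_gap) count <- count + 1L
    }
  }
  count
}

random_rna <- function(len, with_n = FALSE) {
  alphabet <- c("A", "C", "G", "U")
  prob <- rep(0.2375, 4)
  if (with_n) {
    alphabet <- c(alphabet, "N")
    prob <- c(prob, 0.05)
  } else {
    prob <- rep(0.25, 4)
  }
  paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
}

GLD1_29NT <- "AUCAUGUGCCAUACAUCAUGUUGCCAUUU"

# Printed thermodynamic table (both technical replicates per interaction):
# N (sites), Kd (uM), dH, dG, -TdS (kJ/mol).
TABLE1 <- data.frame(
  line = c(1, 1, 2, 2, 3, 3, 5, 5, 6, 6, 7, 7),
  n_sites = c(0.50, 0.57, 1.02, 0.98, 1.06, 0.89,
              0.46, 0.46, 1.15, 1.05, 0.83, 0.86),
  kd_um = c(1.1, 1.9, 2.8, 3.7, 24.1, 46.2,
            0.48, 0.52, 0.13, 0.12, 1.46, 1.54),
  dh = c(-61.9, -45.1, -47.9, -48.3, -46.3, -48.3,
         -139, -157, -64.1, -68.9, -50.8, -52.5),
  dg = c(-33.4, -32.1, -31.2, -30.5, -25.9, -24.4,
         -35.5, -35.3, -38.7, -38.9, -32.8, -32.6),
  mtds = c(28.5, 13.0, 16.7, 17.8, 20.3, 23.9,
           104, 122, 25.4, 30.0, 18.0, 19.9)
)

# Half a unit in the last printed decimal place.
half_ulp <- function(x) {
  dec <- vapply(as.character(x), function(s) {
    if (grepl("\\.", s)) nchar(sub(".*\\.", "", s)) else 0L
  }, integer(1))
  0.5 * 10^(-dec)
}
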