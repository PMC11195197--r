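# Pairing of adjacent elements within a peak and peak/gene/region summaries.

#' Gap between two elements on the same sequence
#'
#' Distance between motifs by the start-position convention:
#' `downstream_start - upstream_start - upstream_length`. With 1-based
#' inclusive starts this counts the number of bases strictly between the two
#' elements; it may be zero (abutting) or negative (overlapping). The same
#' formula serves both the core-element convention (9/10-nt consensus
#' matches) and the flank-inclusive convention (e.g. the 11-nt and 12-nt
#' gld-1 FBEa/FBEa* elements, which lie 3 nt apart while their cores lie
#' 5 nt apart).
#'
#' @param upstream_start,downstream_start 1-based start positions,
#'   `downstream_start >= upstream_start`.
#' @param upstream_length Length in nt of the 5'-most element.
#' @return Integer gap in nt.
#' @examples
#' element_gap(5, 9, 19)   # gld-1 FBEa/FBEa* cores: 5
#' element_gap(3, 11, 17)  # flank-inclusive gld-1 elements: 3
#' @export
element_gap <- function(upstream_start, upstream_length, downstream_start) {
  stopifnot(all(downstream_start >= upstream_start))
  as.integer(downstream_start - upstream_start - upstream_length)
}

.empty_pairs <- function() {
  data.frame(seq_id = character(),
             up_pattern = character(), up_start = integer(),
             up_length = integer(), up_match = character(),
             down_pattern = character(), down_start = integer(),
             down_length = integer(), down_match = character(),
             gap = integer(), stringsAsFactors = FALSE)
}

#' Find qualifying adjacent element pairs
#'
#' From the matches of one sequence, emits every unordered pair in which at
#' least one member is a canonical FBE and the gap between the elements
#' (see [element_gap]) lies within `[min_gap, max_gap]`. The second element
#' may lie upstream or downstream of the canonical FBE; each pair is
#' reported once, oriented 5' to 3' by start position. Overlapping or
#' abutting matches (gap <= 0) never qualify under the default bounds.
#'
#' @param matches data.frame of element matches from a single sequence, as
#'   produced by [scan_all].
#' @param min_gap,max_gap Inclusive gap bounds in nt (defaults 1 and 20).
#' @return data.frame with one row per qualifying pair: `seq_id`,
#'   `up_pattern`, `up_start`, `up_length`, `up_match`, `down_pattern`,
#'   `down_start`, `down_length`, `down_match`, `gap`.
#' @export
find_pairs <- function(matches, min_gap = 1L, max_gap = 20L) {
  stopifnot(min_gap <= max_gap)
  n <- nrow(matches)
  if (n < 2L) return(.empty_pairs())
  if (length(unique(matches$seq_id)) > 1L) {
    stop("find_pairs expects matches from a single sequence")
  }
  idx <- utils::combn(n, 2L)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1L, k]; j <- idx[2L, k]
    if (!(matches$is_canonical[i] || matches$is_canonical[j])) return(NULL)
    if (matches$start[j] < matches$start[i]) { tmp <- i; i <- j; j <- tmp }
    gap <- element_gap(matches$start[i], matches$length[i], matches$start[j])
    if (gap < min_gap || gap > max_gap) return(NULL)
    data.frame(seq_id = matches$seq_id[i],
               up_pattern = matches$pattern[i], up_start = matches$start[i],
               up_length = matches$length[i], up_match = matches$match[i],
               down_pattern = matches$pattern[j],
               down_start = matches$start[j],
               down_length = matches$length[j],
               down_match = matches$match[j],
               gap = gap, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(.empty_pairs())
  out <- do.call(rbind, rows)
  out <- out[order(out$up_start, out$down_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan one peak sequence for adjacent FBE pairs
#'
#' @param sequence Peak sequence (normalized with [normalize_sequence] if
#'   `normalize = TRUE`).
#' @param peak_id Identifier recorded in the output.
#' @inheritParams find_pairs
#' @param patterns Consensus classes to scan with (default all four).
#' @param normalize Normalize the sequence first (default `TRUE`).
#' @return List with `matches` (all element matches) and `pairs`
#'   (qualifying adjacent pairs). A peak "has adjacent FBEs" iff `pairs` is
#'   nonempty.
#' @examples
#' scan_peak("AUCAUGUGCCAUACAUCAUGUUGCCAUUU", peak_id = "gld-1_a")$pairs
#' @export
scan_peak <- function(sequence, peak_id = "peak", min_gap = 1L,
                      max_gap = 20L, patterns = fbe_patterns(),
                      normalize = TRUE) {
  if (normalize) sequence <- normalize_sequence(sequence)
  matches <- scan_all(sequence, patterns = patterns, seq_id = peak_id)
  list(matches = matches,
       pairs = find_pairs(matches, min_gap = min_gap, max_gap = max_gap))
}

#' Scan a whole peak set
#'
#' Runs [scan_peak] over every peak of an annotated peak table and joins
#' pair calls with the peak annotation.
#'
#' @param peaks data.frame with at least `peak_id`, `gene_id`, `region`,
#'   `height_wt` (see [read_peak_table]); `peak_id` values must be unique.
#' @param sequences Named character vector of peak sequences keyed by
#'   `peak_id` (e.g. from [read_peak_fasta]).
#' @inheritParams scan_peak
#' @return Object of class `fbe_scan`: list with `peaks` (annotation plus
#'   logical `has_pair` and integer `n_pairs`) and `pairs` (pair table with
#'   `gene_id` and `region` joined in).
#' @export
scan_peaks <- function(peaks, sequences, min_gap = 1L, max_gap = 20L,
                       patterns = fbe_patterns()) {
  if (anyDuplicated(peaks$peak_id)) {
    stop("duplicate peak_id: ",
         paste(unique(peaks$peak_id[duplicated(peaks$peak_id)]),
               collapse = ", "))
  }
  missing_seq <- setdiff(peaks$peak_id, names(sequences))
  if (length(missing_seq) > 0L) {
    stop("no sequence for peak(s): ",
         paste(utils::head(missing_seq, 5L), collapse = ", "))
  }
  pair_list <- lapply(peaks$peak_id, function(id) {
    scan_peak(sequences[[id]], peak_id = id, min_gap = min_gap,
              max_gap = max_gap, patterns = patterns)$pairs
  })
  pairs <- if (length(pair_list) == 0L) .empty_pairs() else
    do.call(rbind, c(pair_list, list(make.row.names = FALSE)))
  names(pairs)[names(pairs) == "seq_id"] <- "peak_id"
  ann <- peaks[match(pairs$peak_id, peaks$peak_id),
               c("gene_id", "region"), drop = FALSE]
  pairs <- cbind(pairs, ann)
  rownames(pairs) <- NULL
  peaks$n_pairs <- vapply(pair_list, nrow, integer(1))
  peaks$has_pair <- peaks$n_pairs > 0L
  structure(list(peaks = peaks, pairs = pairs), class = "fbe_scan")
}

#' Summarize an adjacent-element scan
#'
#' Peak-, gene- and region-level counts of the peaks carrying at least one
#' qualifying adjacent pair. Each peak counts once regardless of how many
#' pairs it contains; distinct genes are counted by `gene_id` among the
#' peaks with pairs.
#'
#' @param scan An `fbe_scan` object from [scan_peaks].
#' @return List of class `fbe_scan_summary`: `n_peaks_scanned`,
#'   `n_peaks_with_pairs`, `n_distinct_genes`, `n_by_region` (named integer
#'   vector over the region classes present among peaks with pairs) and the
#'   `pairs` table.
#' @export
summarize_scan <- function(scan) {
  stopifnot(inherits(scan, "fbe_scan"))
  with_pairs <- scan$peaks[scan$peaks$has_pair, , drop = FALSE]
  by_region <- table(factor(with_pairs$region,
                            levels = sort(unique(scan$peaks$region))))
  out <- list(
    n_peaks_scanned = nrow(scan$peaks),
    n_peaks_with_pairs = nrow(with_pairs),
    n_distinct_genes = length(unique(with_pairs$gene_id)),
    n_by_region = c(by_region),
    pairs = scan$pairs
  )
  structure(out, class = "fbe_scan_summary")
}

#' @export
print.fbe_scan_summary <- function(x, ...) {
  cat(sprintf("FBE adjacent-element scan: %d/%d peaks with pairs (%d genes)\n",
              x$n_peaks_with_pairs, x$n_peaks_scanned, x$n_distinct_genes))
  if (length(x$n_by_region) > 0L && x$n_peaks_with_pairs > 0L) {
    nz <- x$n_by_region[x$n_by_region > 0L]
    cat("  by region:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  }
  invisible(x)
}
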