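# Readers and writers: FASTA via Biostrings, tab-delimited tables with
# validation. All user-facing tables are headered TSV with 1-based
# inclusive coordinates.

#' Read peak sequences from FASTA
#'
#' Sequences are keyed by the first whitespace-delimited token of each
#' header and normalized to the RNA alphabet (T mapped to U). Duplicate
#' ids and empty records are rejected.
#'
#' @param path FASTA file.
#' @return Named character vector of normalized RNA sequences.
#' @export
read_peak_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- as.character(set)
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) stop("empty FASTA record: ", ids[empty[1L]])
  out <- vapply(seqs, normalize_sequence, character(1), USE.NAMES = FALSE)
  names(out) <- ids
  out
}

#' Write peak sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peak_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.REGION_LEVELS <- c("three_prime_utr", "five_prime_utr", "cds", "other")

#' Read and validate a peak annotation table
#'
#' Headered TSV with required columns `peak_id`, `gene_id`, `region`,
#' `height_wt` and optional `height_mut` and `category`. Unknown extra
#' columns are preserved. Errors name the offending row and column.
#'
#' @param path TSV file.
#' @return data.frame of validated peak records.
#' @export
read_peak_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  required <- c("peak_id", "gene_id", "region", "height_wt")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("peak table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$peak_id)) {
    stop("duplicate peak_id in peak table: ",
         tab$peak_id[duplicated(tab$peak_id)][1L])
  }
  for (col in intersect(c("height_wt", "height_mut"), names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0L) {
      stop("non-numeric ", col, " at row ", bad[1L], ": '",
           tab[[col]][bad[1L]], "'")
    }
    neg <- which(v < 0)
    if (length(neg) > 0L) {
      stop("negative ", col, " at row ", neg[1L])
    }
    tab[[col]] <- v
  }
  bad_region <- which(!tab$region %in% .REGION_LEVELS)
  if (length(bad_region) > 0L) {
    stop("unknown region '", tab$region[bad_region[1L]], "' at row ",
         bad_region[1L], " (expected one of ",
         paste(.REGION_LEVELS, collapse = ", "), ")")
  }
  if ("category" %in% names(tab)) {
    ok <- tab$category %in% c("lower", "higher", "unchanged") |
      is.na(tab$category)
    if (!all(ok)) {
      stop("unknown category '", tab$category[!ok][1L], "' at row ",
           which(!ok)[1L])
    }
  }
  tab
}

#' Read an ITC titration table
#'
#' Headered TSV with columns `injection`, `volume_ul` and `heat`; the heat
#' dialect (`uJ` or `kJ/mol`) and cell/syringe setup are passed as
#' arguments because they are instrument metadata, not per-row data.
#'
#' @param path TSV file.
#' @param cell_conc0,syringe_conc,cell_volume Concentrations (molar) and
#'   cell volume (liters).
#' @param heat_unit `"uJ"` or `"kJ/mol"`.
#' @return A [titration_series].
#' @export
read_titration_tsv <- function(path, cell_conc0, syringe_conc,
                               cell_volume = 200e-6,
                               heat_unit = c("uJ", "kJ/mol")) {
  heat_unit <- match.arg(heat_unit)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("injection", "volume_ul", "heat")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("titration table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[order(tab$injection), , drop = FALSE]
  titration_series(cell_conc0 = cell_conc0, syringe_conc = syringe_conc,
                   injection_volumes = tab$volume_ul * 1e-6,
                   cell_volume = cell_volume, heats = tab$heat,
                   heat_unit = heat_unit)
}

#' Read EMSA measurements
#'
#' Headered TSV with columns `replicate`, `conc_nM` and either
#' `fraction_bound` or the band intensities `intensity_bound` and
#' `intensity_unbound` (converted with [fraction_bound]).
#'
#' @param path TSV file.
#' @param rna_conc Trace RNA concentration (molar).
#' @return Named list of [emsa_curve] objects, one per replicate.
#' @export
read_emsa_tsv <- function(path, rna_conc = 5e-9) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("replicate", "conc_nM") %in% names(tab))) {
    stop("EMSA table must have columns replicate and conc_nM")
  }
  if (!"fraction_bound" %in% names(tab)) {
    if (!all(c("intensity_bound", "intensity_unbound") %in% names(tab))) {
      stop("EMSA table needs fraction_bound or intensity_bound/intensity_unbound")
    }
    tab$fraction_bound <- fraction_bound(tab$intensity_bound,
                                         tab$intensity_unbound)
  }
  lapply(split(tab, tab$replicate), function(r) {
    r <- r[order(r$conc_nM), , drop = FALSE]
    emsa_curve(r$conc_nM * 1e-9, r$fraction_bound, rna_conc = rna_conc)
  })
}

#' Read FRET intensity rows
#'
#' Headered TSV with columns `condition`, `i_564`, `i_668`; returns the
#' table with a computed `fret_efficiency` column.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_fret_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "i_564", "i_668")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("FRET table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab$fret_efficiency <- fret_efficiency(tab$i_564, tab$i_668)
  tab
}

#' Read germline intensity profiles
#'
#' Long-format headered TSV with columns `gonad_id`, `genotype`,
#' `position_um`, `intensity`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_profile_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_profiles(tab)
}

#' Write a headered TSV
#'
#' Single tabular dialect of the package: tab-delimited, headered, UTF-8,
#' "." decimal separator, no quoting or row names.
#'
#' @param x data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
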