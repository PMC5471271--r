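#' Read an annotated variant table
#'
#' Reads a tab-separated table of annotated exonic variants in the dialect
#' used throughout the package (the layout of the study's mutation table:
#' columns \code{symbol}, \code{description}, \code{allele_freq},
#' \code{base_change}, \code{aa_change}).  Each row is validated: the
#' allele frequency must lie in [0, 1], the base change must be two
#' \code{/}-separated nucleotides in A/C/G/T, and the amino-acid change must
#' have exactly two \code{/}-separated fields (the second may be the stop
#' token).  Malformed rows raise an error naming the offending row numbers.
#'
#' @param path path to the TSV file.
#' @return data.frame of validated variant records (possibly zero rows).
#' @export
read_variant_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("symbol", "description", "allele_freq", "base_change", "aa_change")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  tab <- tab[, req]
  if (nrow(tab) == 0) return(tab)
  tab$allele_freq <- suppressWarnings(as.numeric(tab$allele_freq))
  bad_af <- which(is.na(tab$allele_freq) | tab$allele_freq < 0 | tab$allele_freq > 1)
  if (length(bad_af))
    stop("allele_freq outside [0, 1] in row(s): ", paste(bad_af, collapse = ", "))
  bad_bc <- which(!grepl("^[ACGT]/[ACGT]$", tab$base_change))
  if (length(bad_bc))
    stop("malformed base_change in row(s): ", paste(bad_bc, collapse = ", "))
  nslash <- vapply(strsplit(tab$aa_change, "/", fixed = TRUE), length, 0L)
  bad_aa <- which(nslash != 2)
  if (length(bad_aa))
    stop("malformed aa_change in row(s): ", paste(bad_aa, collapse = ", "))
  tab
}

#' Classify amino-acid changes
#'
#' Maps each \code{"A/B"} amino-acid change to one of \code{stop_gain}
#' (second field is the stop token, spelled \code{stop} case-insensitively
#' or \code{*} as in VCF-derived annotations), \code{synonymous} (both
#' fields equal), \code{missense} (two different single residues) or
#' \code{other}.
#'
#' @param aa_change character vector of \code{"A/B"} changes, or a variant
#'   record data.frame with an \code{aa_change} column.
#' @return character vector of classes.
#' @export
classify_variant <- function(aa_change) {
  if (is.data.frame(aa_change)) aa_change <- aa_change$aa_change
  parts <- strsplit(aa_change, "/", fixed = TRUE)
  if (any(vapply(parts, length, 0L) != 2))
    stop("unparseable aa_change: expected exactly two '/'-separated fields")
  from <- vapply(parts, `[[`, "", 1)
  to <- vapply(parts, `[[`, "", 2)
  is_stop <- tolower(to) == "stop" | to == "*"
  is_res <- function(x) grepl("^[A-Za-z]$", x)
  ifelse(is_stop, "stop_gain",
         ifelse(from == to & is_res(from), "synonymous",
                ifelse(is_res(from) & is_res(to), "missense", "other")))
}

#' Filter variants by class and allele frequency
#'
#' Keeps records whose class belongs to \code{classes} and whose allele
#' frequency is at least \code{min_af}, preserving input order, and tallies
#' the kept records per class.
#'
#' @param records variant data.frame (as from
#'   \code{\link{read_variant_table}}).
#' @param classes character vector of classes to keep; default the study's
#'   filter, stop-gain plus exonic missense.
#' @param min_af minimum allele frequency (default 0, i.e. no cutoff).
#' @return list with \code{records} (filtered data.frame, with a
#'   \code{variant_class} column added) and \code{counts} (named integer
#'   vector over stop_gain / missense / synonymous / other, zeros for
#'   classes not kept).
#' @export
filter_and_count <- function(records, classes = c("stop_gain", "missense"),
                             min_af = 0) {
  all_classes <- c("stop_gain", "missense", "synonymous", "other")
  cls <- if (nrow(records)) classify_variant(records) else character(0)
  keep <- cls %in% classes & records$allele_freq >= min_af
  out <- records[keep, , drop = FALSE]
  out$variant_class <- cls[keep]
  counts <- table(factor(cls[keep], levels = all_classes))
  list(records = out, counts = setNames(as.integer(counts), all_classes))
}

#' Allele-frequency summary
#'
#' @param records nonempty variant data.frame with an \code{allele_freq}
#'   column.
#' @return list with \code{min}, \code{max}, \code{mean}.
#' @export
af_summary <- function(records) {
  if (nrow(records) == 0) stop("empty record list")
  af <- records$allele_freq
  list(min = min(af), max = max(af), mean = mean(af))
}

#' Truncated protein length after a premature stop
#'
#' A stop codon at (1-based) residue position \code{p} yields a protein of
#' \code{p - 1} residues.
#'
#' @param stop_codon_position 1-based residue index of the premature stop.
#' @param wildtype_length wildtype protein length in residues.
#' @return truncated protein length.
#' @export
truncation_length <- function(stop_codon_position, wildtype_length) {
  if (stop_codon_position < 1 || stop_codon_position > wildtype_length)
    stop("stop position out of range [1, wildtype_length]")
  stop_codon_position - 1
}
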