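#' Parse a structured allele name
#'
#' Splits an allele identifier into its locus and ordered resolution fields
#' under the naming scheme of its gene family:
#' \describe{
#'   \item{HLA}{`A*01:01:01:01`: locus before `*`, colon-delimited fields.}
#'   \item{KIR}{`KIR3DL1*0150201`: locus before `*`, digit string grouped into
#'     a 3-digit protein field followed by 2-digit fields (widths
#'     configurable via `kir_widths`).}
#'   \item{CYP}{`CYP2D6*4.001`: star allele `n` then sub-allele `m`, dot
#'     delimited.}
#'   \item{IG/TCR}{`IGHV1-69*01`: locus before `*`, a single allele field.}
#' }
#'
#' @param name character vector of allele identifiers.
#' @param family one of `"HLA"`, `"KIR"`, `"CYP"`, `"IG"`, `"TCR"`.
#' @param kir_widths integer vector of KIR digit-group widths, first entry the
#'   protein field. Default `c(3, 2, 2, 2)`.
#' @return a list with one element per name, each `list(locus=, fields=)`;
#'   unparseable names yield `NULL`.
#' @export
parse_allele_name <- function(name, family = "HLA", kir_widths = c(3L, 2L, 2L, 2L)) {
  family <- match.arg(family, c("HLA", "KIR", "CYP", "IG", "TCR"))
  lapply(name, function(nm) {
    if (is.na(nm) || !nzchar(nm) || !grepl("*", nm, fixed = TRUE)) return(NULL)
    parts <- strsplit(nm, "*", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L]) || !nzchar(parts[2L])) return(NULL)
    locus <- parts[1L]; suffix <- parts[2L]
    fields <- switch(family,
      HLA = strsplit(suffix, ":", fixed = TRUE)[[1L]],
      CYP = strsplit(suffix, ".", fixed = TRUE)[[1L]],
      KIR = {
        if (!grepl("^[0-9]+$", suffix)) return(NULL)
        out <- character(0); pos <- 1L; k <- 1L
        while (pos <= nchar(suffix)) {
          w <- kir_widths[min(k, length(kir_widths))]
          out <- c(out, substr(suffix, pos, min(pos + w - 1L, nchar(suffix))))
          pos <- pos + w; k <- k + 1L
        }
        out
      },
      suffix) # IG / TCR: one field
    if (any(!nzchar(fields))) return(NULL)
    list(locus = locus, fields = fields)
  })
}

#' Reassemble an allele name from locus and fields
#' @param locus locus identifier.
#' @param fields character vector of resolution fields.
#' @inheritParams parse_allele_name
#' @return allele name string.
#' @export
format_allele_name <- function(locus, fields, family = "HLA") {
  family <- match.arg(family, c("HLA", "KIR", "CYP", "IG", "TCR"))
  sep <- switch(family, HLA = ":", CYP = ".", KIR = "", "")
  paste0(locus, "*", paste(fields, collapse = sep))
}

#' Truncate an allele name to its first k resolution fields
#'
#' Idempotent when the name already has `k` or fewer fields.
#'
#' @param name character vector of allele names.
#' @param k number of fields to keep (`k >= 1`).
#' @inheritParams parse_allele_name
#' @return character vector of truncated names.
#' @export
truncate_name <- function(name, k, family = "HLA", kir_widths = c(3L, 2L, 2L, 2L)) {
  if (k < 1L) stop("'k' must be >= 1")
  parsed <- parse_allele_name(name, family, kir_widths)
  vapply(seq_along(name), function(i) {
    p <- parsed[[i]]
    if (is.null(p)) stop(sprintf("unparseable allele name '%s'", name[i]))
    format_allele_name(p$locus, p$fields[seq_len(min(k, length(p$fields)))], family)
  }, character(1))
}

#' Construct an allele database
#'
#' @param alleles data.frame with columns `name`, `locus`, `family`,
#'   `sequence`; `length` is derived.
#' @param loci optional data.frame of locus definitions with columns `locus`,
#'   `family`, `chrom`, `start`, `end` (0-based half-open) and optionally
#'   `gene_class`. Loci absent from it carry no reference geometry.
#' @return an object of class `allele_db`.
#' @export
allele_database <- function(alleles, loci = NULL) {
  stopifnot(is.data.frame(alleles),
            all(c("name", "locus", "family", "sequence") %in% names(alleles)))
  if (anyDuplicated(alleles$name))
    stop("duplicate allele names in database")
  bad <- grepl("[^ACGTNacgtn]", alleles$sequence)
  if (any(bad)) {
    warning(sprintf("rejecting %d allele(s) with non-ACGTN characters", sum(bad)))
    alleles <- alleles[!bad, , drop = FALSE]
  }
  if (nrow(alleles) == 0L) stop("empty allele database")
  alleles$sequence <- toupper(alleles$sequence)
  alleles$length <- nchar(alleles$sequence)
  if (is.null(loci)) {
    loci <- data.frame(locus = sort(unique(alleles$locus)),
                       family = alleles$family[match(sort(unique(alleles$locus)),
                                                     alleles$locus)],
                       chrom = NA_character_, start = NA_integer_,
                       end = NA_integer_, gene_class = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("locus", "chrom", "start", "end") %in% names(loci)))
    if (anyDuplicated(loci$locus)) stop("duplicate locus definitions")
    ok <- is.na(loci$start) | loci$start < loci$end
    if (!all(ok)) stop("locus intervals must satisfy start < end")
    if (!all(alleles$locus %in% loci$locus))
      stop("alleles reference loci missing from the locus table")
    if (is.null(loci$gene_class)) loci$gene_class <- NA_character_
    if (is.null(loci$family))
      loci$family <- alleles$family[match(loci$locus, alleles$locus)]
  }
  rownames(alleles) <- alleles$name
  structure(list(alleles = alleles, loci = loci), class = "allele_db")
}

#' @export
print.allele_db <- function(x, ...) {
  cat(sprintf("Allele database: %d alleles over %d loci (%s)\n",
              nrow(x$alleles), nrow(x$loci),
              paste(unique(x$alleles$family), collapse = ", ")))
  tab <- table(x$alleles$locus)
  cat(sprintf("  alleles per locus: median %d, range %d-%d\n",
              as.integer(stats::median(tab)), min(tab), max(tab)))
  invisible(x)
}

#' Load a multi-FASTA allele database
#'
#' FASTA headers must carry allele names in the family's naming scheme (first
#' whitespace-separated token). Records with unparseable names are reported
#' and skipped; sequences with non-ACGTN characters are rejected with a
#' warning.
#'
#' @param path FASTA file.
#' @inheritParams parse_allele_name
#' @param loci optional locus-definition data.frame (see
#'   [allele_database()]) or path to a BED-like TSV with columns
#'   chrom, start, end, locus, family, gene_class.
#' @return an `allele_db` object.
#' @export
load_allele_fasta <- function(path, family = "HLA", loci = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty allele database")
  nms <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  parsed <- parse_allele_name(nms, family)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    warning(sprintf("skipping %d record(s) with unparseable names: %s",
                    sum(bad), paste(head(nms[bad], 5), collapse = ", ")))
    seqs <- seqs[!bad]; nms <- nms[!bad]; parsed <- parsed[!bad]
  }
  if (length(seqs) == 0L) stop("no parseable allele records")
  if (is.character(loci)) loci <- read_locus_table(loci)
  allele_database(
    data.frame(name = nms,
               locus = vapply(parsed, `[[`, character(1), "locus"),
               family = family,
               sequence = as.character(seqs),
               stringsAsFactors = FALSE),
    loci = loci)
}

#' Write an allele database to multi-FASTA
#' @param db an `allele_db`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(db, path) {
  stopifnot(inherits(db, "allele_db"))
  x <- Biostrings::DNAStringSet(db$alleles$sequence)
  names(x) <- db$alleles$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED-like locus definition table
#'
#' Tab-separated columns: chrom, start, end, locus, family, gene_class
#' (0-based half-open coordinates, no header).
#'
#' @param path TSV file.
#' @return data.frame of locus definitions.
#' @export
read_locus_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "locus")
  if (ncol(df) >= 5) names(df)[5] <- "family"
  if (ncol(df) >= 6) names(df)[6] <- "gene_class"
  df
}

#' Distance between two loci on the linear reference
#'
#' Gap in bases between the two reference intervals; 0 when they overlap or
#' abut. Loci on different chromosomes are unlinked and yield `NA` (the
#' unlinked sentinel -- never a finite distance).
#'
#' @param a,b locus definitions: lists or one-row data.frames with `chrom`,
#'   `start`, `end`.
#' @return integer distance in bases, or `NA` if unlinked.
#' @export
reference_locus_distance <- function(a, b) {
  if (is.na(a$chrom) || is.na(b$chrom) || a$chrom != b$chrom) return(NA_integer_)
  as.integer(max(0L, a$start - b$end, b$start - a$end))
}

#' Condensed candidate allele set for a locus
#'
#' Ranks a locus's alleles by alignment depth -- total aligned bases divided by
#' allele length -- and keeps the deepest `top_k`. Depth ties break
#' lexicographically by allele name, so the set is stable under alignment
#' record reordering.
#'
#' @param alignments alignment data.frame (see [naive_align()]) restricted to
#'   the locus, with columns `allele` and `aln_len`.
#' @param allele_lengths named vector of allele lengths.
#' @param top_k maximum number of alleles retained (default 200).
#' @return character vector of allele names, deepest first.
#' @export
condensed_candidate_set <- function(alignments, allele_lengths, top_k = 200L) {
  if (nrow(alignments) == 0L) return(character(0))
  tot <- tapply(alignments$aln_len, alignments$allele, sum)
  lens <- allele_lengths[names(tot)]
  if (anyNA(lens)) stop("missing allele lengths for some aligned alleles")
  depth <- as.numeric(tot) / as.numeric(lens)
  nm <- names(tot)
  ord <- order(-depth, nm)
  head(nm[ord], top_k)
}
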