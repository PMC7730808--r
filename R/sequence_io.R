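#' @useDynLib essembler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")
# IUPAC ambiguity codes collapsed to N under tolerant parsing
IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")

#' Construct a gene sequence record
#'
#' A `gene_sequence` holds one nucleotide sequence with an identifier and an
#' optional binary essentiality label (1 = essential, 0 = non-essential).
#' The sequence is uppercased on ingest and restricted to the alphabet
#' `A/C/G/T/N`; with `tolerant = TRUE` the remaining IUPAC ambiguity codes
#' are mapped to `N` instead of raising an error.
#'
#' @param id Character scalar, unique sequence identifier.
#' @param seq Character scalar, non-empty nucleotide sequence.
#' @param label Optional 0/1 label, `NA` for unlabeled.
#' @param tolerant Map IUPAC ambiguity codes to `N` instead of erroring.
#' @return An object of class `gene_sequence` (a named list with `id`,
#'   `seq`, `label`).
#' @export
gene_sequence <- function(id, seq, label = NA, tolerant = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence for id '", id, "'")
  if (tolerant) seq <- chartr(paste(IUPAC_EXTRA, collapse = ""),
                              strrep("N", length(IUPAC_EXTRA)), seq)
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), VALID_BASES)
  if (length(bad) > 0L)
    stop("sequence '", id, "' contains invalid characters: ",
         paste(bad, collapse = ", "),
         " (use tolerant = TRUE to map IUPAC codes to N)")
  if (!is.na(label) && !label %in% c(0, 1)) stop("label must be 0, 1 or NA")
  structure(list(id = id, seq = seq, label = if (is.na(label)) NA_integer_
                 else as.integer(label)),
            class = "gene_sequence")
}

#' Read a FASTA file into gene sequence records
#'
#' Parses standard `>`-header FASTA. Multi-line sequences are concatenated,
#' lowercase is mapped to uppercase, and ids (first whitespace-delimited
#' token of the header) must be unique. Malformed input raises an error
#' naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param label Optional label assigned to every record (0, 1 or `NA`).
#' @param tolerant Passed to [gene_sequence()].
#' @return A list of `gene_sequence` records (empty list for an empty file).
#' @export
read_fasta <- function(path, label = NA, tolerant = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines but flag interior blanks inside records later
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(list())
  lines <- lines[seq_len(max(nonblank))]
  is_header <- startsWith(lines, ">")
  if (!is_header[1])
    stop("FASTA parse error at line 1: expected '>' header, got: ", lines[1])
  header_at <- which(is_header)
  ids <- vapply(lines[header_at], function(h) {
    strsplit(trimws(sub("^>", "", h)), "\\s+")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(ids) || any(!nzchar(ids) | is.na(ids))) {
    bad <- header_at[which(!nzchar(ids) | is.na(ids))[1]]
    stop("FASTA parse error at line ", bad, ": empty header id")
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dups, collapse = ", "))
  }
  bounds <- c(header_at, length(lines) + 1L)
  records <- vector("list", length(header_at))
  for (i in seq_along(header_at)) {
    body <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[seq_len(max(0L, bounds[i + 1L] - bounds[i] - 1L))]
    seq <- paste(trimws(body), collapse = "")
    if (!nzchar(seq))
      stop("FASTA parse error at line ", header_at[i],
           ": record '", ids[i], "' has an empty sequence")
    records[[i]] <- gene_sequence(ids[i], seq, label = label,
                                  tolerant = tolerant)
  }
  records
}

#' Write gene sequence records to FASTA
#'
#' @param records List of `gene_sequence` records.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    starts <- seq(1L, nchar(r$seq), by = width)
    writeLines(substring(r$seq, starts, pmin(starts + width - 1L,
                                             nchar(r$seq))), con)
  }
  invisible(path)
}

#' Assemble a labeled dataset from positive and negative FASTA files
#'
#' The benchmark construction S = S+ \eqn{\cup} S-: one FASTA of
#' essential (positive, label 1) genes and one of non-essential
#' (negative, label 0) genes. Record order is file order, positives first.
#'
#' @param pos_path FASTA of positive-class sequences.
#' @param neg_path FASTA of negative-class sequences.
#' @param tolerant Passed to [read_fasta()].
#' @return A `gene_dataset`: list with `records`, `n_pos`, `n_neg`.
#' @export
load_dataset <- function(pos_path, neg_path, tolerant = FALSE) {
  pos <- read_fasta(pos_path, label = 1, tolerant = tolerant)
  neg <- read_fasta(neg_path, label = 0, tolerant = tolerant)
  if (length(pos) == 0L) stop("empty class: no sequences in ", pos_path)
  if (length(neg) == 0L) stop("empty class: no sequences in ", neg_path)
  gene_dataset(c(pos, neg))
}

#' Build a labeled dataset from records
#'
#' @param records List of `gene_sequence` records, all labeled.
#' @return A `gene_dataset`.
#' @export
gene_dataset <- function(records) {
  labels <- vapply(records, function(r) r$label, integer(1))
  if (anyNA(labels)) stop("all records must be labeled")
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) across classes: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(records = records,
                 n_pos = sum(labels == 1L),
                 n_neg = sum(labels == 0L)),
            class = "gene_dataset")
}

#' @export
print.gene_dataset <- function(x, ...) {
  cat("gene_dataset:", length(x$records), "sequences (",
      x$n_pos, "positive /", x$n_neg, "negative )\n")
  lens <- dataset_lengths(x)
  cat("  lengths:", min(lens), "-", max(lens), "nt (median",
      stats::median(lens), ")\n")
  invisible(x)
}

#' @export
length.gene_dataset <- function(x) length(x$records)

dataset_ids <- function(dataset)
  vapply(dataset$records, function(r) r$id, character(1))

dataset_labels <- function(dataset)
  vapply(dataset$records, function(r) r$label, integer(1))

dataset_seqs <- function(dataset)
  vapply(dataset$records, function(r) r$seq, character(1))

dataset_lengths <- function(dataset) nchar(dataset_seqs(dataset))

#' Read a tab-separated id/label table
#'
#' Alternative labeling route: a TSV with columns `id` and `label`
#' (0/1) is joined to records parsed from a single FASTA.
#'
#' @param fasta_path FASTA with all sequences.
#' @param table_path TSV with header columns `id` and `label`.
#' @param tolerant Passed to [read_fasta()].
#' @return A `gene_dataset`.
#' @export
load_dataset_table <- function(fasta_path, table_path, tolerant = FALSE) {
  records <- read_fasta(fasta_path, tolerant = tolerant)
  tab <- utils::read.delim(table_path, header = TRUE,
                           colClasses = c("character", "integer"))
  if (!all(c("id", "label") %in% names(tab)))
    stop("label table must have columns 'id' and 'label'")
  if (!all(tab$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  lab <- stats::setNames(tab$label, tab$id)
  records <- lapply(records, function(r) {
    if (is.na(lab[r$id])) stop("no label for sequence id '", r$id, "'")
    r$label <- lab[[r$id]]
    r
  })
  gene_dataset(records)
}
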