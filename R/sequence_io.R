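#' Read a multi-record FASTA file
#'
#' Thin wrapper around \code{Biostrings::readBStringSet} that uppercases
#' sequences, validates the DNA alphabet (\code{A,C,G,T,N,-}; ambiguity codes
#' beyond \code{N} are rejected), and preserves headers verbatim (first token
#' plus description). Wrapped lines and CRLF endings are handled by the parser.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns \code{header} and \code{sequence}, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  seqs <- toupper(as.character(set))
  headers <- names(set)
  for (i in seq_along(seqs)) {
    .validate_dna(seqs[i], what = sprintf("record '%s'", headers[i]))
  }
  data.frame(header = headers, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param headers Character vector of record headers (written verbatim).
#' @param sequences Character vector of sequences (may contain gaps).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(headers, sequences, path, width = 70L) {
  stopifnot(length(headers) == length(sequences))
  set <- Biostrings::BStringSet(setNames(as.character(sequences), headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a symbiont/gene metadata table
#'
#' The TSV must have columns \code{symbiont_id}, \code{gene_id}, \code{clade}
#' (one of \code{I}, \code{II}, \code{outgroup}) and \code{status} (one of
#' \code{intact}, \code{degraded}, \code{absent}).
#'
#' @param path Path to the TSV file.
#' @return A data.frame of the metadata.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("symbiont_id", "gene_id", "clade", "status")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  bad_clade <- setdiff(unique(meta$clade), c("I", "II", "outgroup"))
  if (length(bad_clade)) stop("unknown clade value(s): ", paste(bad_clade, collapse = ", "))
  bad_status <- setdiff(unique(meta$status), c("intact", "degraded", "absent"))
  if (length(bad_status)) stop("unknown status value(s): ", paste(bad_status, collapse = ", "))
  meta
}

# in-frame internal stop check for intact ORFs (validation flag, not a failure)
.orf_ok <- function(seq) {
  s <- .strip_gaps(seq)
  n <- nchar(s)
  if (n == 0L || n %% 3L != 0L) return(FALSE)
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .genetic_code()[codons]
  # internal positions only; last codon may (should) be the terminator
  !any(aa[-length(aa)] == "*", na.rm = TRUE)
}

#' Assemble a gene-by-symbiont matrix from FASTA records and metadata
#'
#' FASTA headers follow the \code{"symbiont_id|gene_id"} convention (the
#' delimiter is configurable); the first whitespace-delimited token of the
#' header is used as the key. Metadata rows with \code{status = "absent"} need
#' no FASTA record and get an empty sequence. Intact records whose gap-stripped
#' sequence is not a clean ORF (length divisible by 3, no internal stop) are
#' flagged via the \code{orf_ok} column with a warning, not rejected.
#'
#' @param fasta A data.frame from \code{\link{read_fasta}}.
#' @param metadata A data.frame from \code{\link{read_metadata}}.
#' @param delim Delimiter between symbiont and gene in the header key.
#' @return A \code{gene_matrix}: list with \code{records} (data.frame with
#'   columns symbiont_id, gene_id, clade, status, sequence, orf_ok),
#'   \code{gene_order}, \code{symbiont_order}, \code{outgroup_id}.
#' @export
build_matrix <- function(fasta, metadata, delim = "|") {
  keys <- vapply(strsplit(fasta$header, "[ \t]"), `[`, "", 1L)
  parts <- strsplit(keys, delim, fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("FASTA header '%s' does not follow the 'symbiont%sgene' convention",
                 fasta$header[bad[1]], delim))
  }
  rec_sym <- vapply(parts, `[`, "", 1L)
  rec_gene <- vapply(parts, `[`, "", 2L)
  rec_key <- paste(rec_gene, rec_sym, sep = "\r")
  if (anyDuplicated(rec_key)) {
    stop("duplicate (gene, symbiont) record(s): ",
         paste(unique(keys[duplicated(rec_key)]), collapse = ", "))
  }
  meta_key <- paste(metadata$gene_id, metadata$symbiont_id, sep = "\r")
  if (anyDuplicated(meta_key)) {
    stop("duplicate (gene, symbiont) metadata row(s): ",
         paste(unique(meta_key[duplicated(meta_key)]), collapse = ", "))
  }
  orphan <- !(rec_key %in% meta_key)
  if (any(orphan)) {
    stop("FASTA record(s) with no metadata row: ",
         paste(keys[orphan], collapse = ", "))
  }
  seqs <- setNames(fasta$sequence, rec_key)
  records <- data.frame(
    symbiont_id = metadata$symbiont_id,
    gene_id = metadata$gene_id,
    clade = metadata$clade,
    status = metadata$status,
    sequence = ifelse(meta_key %in% rec_key, seqs[meta_key], ""),
    stringsAsFactors = FALSE
  )
  missing_seq <- records$status != "absent" & !nzchar(records$sequence)
  if (any(missing_seq)) {
    stop("metadata row(s) with status != 'absent' but no FASTA record: ",
         paste(paste(records$gene_id[missing_seq], records$symbiont_id[missing_seq],
                     sep = delim), collapse = ", "))
  }
  records$orf_ok <- TRUE
  intact <- records$status == "intact"
  records$orf_ok[intact] <- vapply(records$sequence[intact], .orf_ok, NA)
  if (any(!records$orf_ok)) {
    warning("intact record(s) failing the clean-ORF check (flagged, not removed): ",
            paste(paste(records$gene_id[!records$orf_ok],
                        records$symbiont_id[!records$orf_ok], sep = delim),
                  collapse = ", "))
  }
  symbiont_order <- unique(metadata$symbiont_id)
  outg <- unique(metadata$symbiont_id[metadata$clade == "outgroup"])
  if (length(outg) > 1L) stop("more than one outgroup symbiont: ", paste(outg, collapse = ", "))
  structure(list(
    records = records,
    gene_order = unique(metadata$gene_id),
    symbiont_order = symbiont_order,
    outgroup_id = if (length(outg)) outg else NA_character_
  ), class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("gene_matrix: %d genes x %d symbionts (outgroup: %s)\n",
              length(x$gene_order), length(x$symbiont_order), x$outgroup_id))
  tab <- table(x$records$status)
  cat("  records:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Fetch one record of a gene matrix
#'
#' @param gm A \code{gene_matrix}.
#' @param gene_id,symbiont_id Cell key.
#' @return One-row data.frame, or an error if the cell does not exist.
#' @export
gm_record <- function(gm, gene_id, symbiont_id) {
  i <- which(gm$records$gene_id == gene_id & gm$records$symbiont_id == symbiont_id)
  if (!length(i)) stop(sprintf("no record for (%s, %s)", gene_id, symbiont_id))
  gm$records[i, , drop = FALSE]
}

#' Construct a parameter table (genes x symbionts)
#'
#' @param values Numeric matrix, rows = genes, columns = symbionts.
#' @param parameter One of \code{"distance"}, \code{"gc"},
#'   \code{"repeat_density"}, \code{"dnds"}.
#' @param status Optional character matrix of the same shape
#'   (intact/degraded/absent).
#' @param clade_map Named character vector, symbiont -> clade.
#' @export
parameter_table <- function(values, parameter = c("distance", "gc", "repeat_density", "dnds"),
                            status = NULL, clade_map = NULL) {
  parameter <- match.arg(parameter)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (!is.null(status)) stopifnot(identical(dim(status), dim(values)))
  structure(list(parameter = parameter, values = values, status = status,
                 clade_map = clade_map), class = "parameter_table")
}

#' @export
print.parameter_table <- function(x, ...) {
  cat(sprintf("parameter_table '%s': %d genes x %d symbionts, %d NA cells\n",
              x$parameter, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  print(round(x$values, 4))
  invisible(x)
}

#' Write a parameter table to TSV (lossless round trip)
#'
#' Genes as rows, symbionts as columns, missing cells as \code{NA}; numbers are
#' written with \code{\%.17g} so re-reading reproduces values exactly.
#'
#' @param table A \code{parameter_table} (or bare numeric matrix).
#' @param path Output path.
#' @export
write_parameter_table <- function(table, path) {
  values <- if (inherits(table, "parameter_table")) table$values else table
  fmt <- matrix(sprintf("%.17g", values), nrow = nrow(values))
  fmt[is.na(values)] <- "NA"
  out <- cbind(gene = rownames(values), fmt)
  colnames(out) <- c("gene", colnames(values))
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write parameter table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a parameter table written by \code{\link{write_parameter_table}}
#'
#' @param path Path to the TSV.
#' @param parameter Parameter label for the resulting table.
#' @export
read_parameter_table <- function(path, parameter = "distance") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#")
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df[[1]]
  parameter_table(values, parameter)
}
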