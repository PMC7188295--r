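#' Read and write FASTQ (Sanger Phred+33)
#'
#' Minimal strict readers/writers for the four-line FASTQ layout used by
#' the simulator and caller.  Malformed records raise an error naming the
#' offending line.
#'
#' @param path File path.
#' @param reads Data frame with columns `id`, `sequence`, `quality`.
#' @return `read_fastq()` returns a read data frame; writers return
#'   `path` invisibly.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ: ", length(lines), " lines")
  n <- length(lines) %/% 4
  idx <- seq_len(n)
  hd <- lines[(idx - 1) * 4 + 1]
  sq <- lines[(idx - 1) * 4 + 2]
  pl <- lines[(idx - 1) * 4 + 3]
  qu <- lines[(idx - 1) * 4 + 4]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop("malformed FASTQ header at line ", (bad[1] - 1) * 4 + 1)
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop("malformed FASTQ separator ('+' line) at line ", (bad[1] - 1) * 4 + 3)
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad))
    stop("sequence/quality length mismatch at line ", (bad[1] - 1) * 4 + 2)
  out <- data.frame(id = sub("^@", "", hd), sequence = sq, quality = qu,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(rbind(paste0("@", reads$id), reads$sequence, "+",
                   reads$quality), con)
  invisible(path)
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings keeping sequences as named character
#' vectors.
#'
#' @param path File path.
#' @param sequences Named character vector.
#' @return `read_fasta()` returns a named character vector; the writer
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a frequency table (or any module output) as TSV
#'
#' Unknown extra columns are preserved; [read_frequency_table()] warns on
#' unrecognised columns but keeps them.
#'
#' @param table Data frame.
#' @param path Output TSV path.
#' @return The writer returns `path` invisibly, the reader a
#'   `frequency_table`.
#' @export
write_frequency_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("population_id", "country", "continent", "year", "segment_id",
            "haplotype_name", "read_count", "frequency")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("frequency table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), c(need, "sequence", "label"))
  if (length(extra))
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  class(df) <- c("frequency_table", "data.frame")
  df
}

#' Write a segment model as a JSON sidecar (+ reference FASTA)
#'
#' The JSON stores exon intervals, codon offset, frame phase, primers and
#' the kdr catalogue; the amplicon sequence travels in the FASTA.
#'
#' @param model A [segment_model()].
#' @param json_path,fasta_path Output paths.
#' @return `read_segment_json()` reconstructs the [segment_model()].
#' @export
write_segment_json <- function(model, json_path, fasta_path) {
  write_fasta(setNames(model$sequence, model$segment_id), fasta_path)
  jsonlite::write_json(
    list(segment_id = model$segment_id,
         fasta = basename(fasta_path),
         exon_intervals = model$exon_intervals,
         codon_offset = model$codon_offset,
         frame_phase = model$frame_phase,
         primer_fwd = model$primer_fwd,
         primer_rev = model$primer_rev,
         kdr_catalogue = model$kdr_catalogue),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

#' @rdname write_segment_json
#' @export
read_segment_json <- function(json_path, fasta_path = NULL) {
  j <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(fasta_path))
    fasta_path <- file.path(dirname(json_path), j$fasta)
  seqs <- read_fasta(fasta_path)
  segment_model(segment_id = j$segment_id, sequence = seqs[[j$segment_id]],
                exon_intervals = matrix(unlist(j$exon_intervals), ncol = 2),
                codon_offset = j$codon_offset, frame_phase = j$frame_phase,
                primer_fwd = j$primer_fwd, primer_rev = j$primer_rev,
                kdr_catalogue = as.data.frame(j$kdr_catalogue))
}
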