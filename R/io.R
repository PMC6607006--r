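#' Read a FASTQ file into a read tibble
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns that FASTQ metadata columns are dropped; we only keep
  # id/sequence/quality by design, so that warning is noise here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(Biostrings::quality(x))))
}

#' Write a read tibble as FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality))
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a contig FASTA (decoys, rRNA) into a tibble
#'
#' @param path FASTA path.
#' @return Tibble with `contig_id`, `sequence`.
#' @export
read_contig_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(contig_id = sub("\\s.*$", "", names(x)),
                 sequence = as.character(x))
}

#' Write contigs as FASTA
#'
#' @param contigs Tibble with `contig_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contig_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- contigs$contig_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
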