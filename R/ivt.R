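#' In-vitro transcript simulation
#'
#' T7 run-off transcription from a DNA template with partial substitution of
#' ATP by N6-methyl-ATP (m6ATP). Each adenosine of the run-off transcript is
#' independently drawn as modified with probability `m6atp_fraction`; the
#' post-transcriptional polyA tail (added enzymatically with unmodified ATP)
#' is never modified.
#'
#' The template is the sense (non-template) DNA strand, 5'->3', containing the
#' promoter once. Transcription starts at the first base after the promoter's
#' last nucleotide and runs off at the template 3' end; the transcript is the
#' downstream sense sequence with T replaced by U.
#'
#' @param template DNA template (sense strand, character scalar, ACGT).
#' @param promoter promoter sequence; default the canonical T7 promoter.
#' @param m6atp_fraction probability in [0, 1] that any given adenosine is m6A.
#' @param n number of transcripts to simulate.
#' @param seed integer seed; the call is deterministic per seed.
#' @param polya_tail_length length of the appended polyA tail (0 for none).
#'
#' @return A tibble with one row per transcript: `transcript` (index),
#'   `sequence` (RNA, tail included), `n_adenosine` (substitutable A count,
#'   tail excluded), `n_modified`, `modified_positions` (list column of
#'   0-based indices into `sequence`), `has_polya_tail`.
#' @seealso [expected_modified_count()]
#' @export
simulate_ivt <- function(template, promoter = T7_PROMOTER, m6atp_fraction,
                         n = 1L, seed = NULL, polya_tail_length = 30L) {
  runoff <- t7_runoff(template, promoter)
  stopifnot(m6atp_fraction >= 0, m6atp_fraction <= 1, n >= 1)
  tail_seq <- strrep("A", max(0L, as.integer(polya_tail_length)))
  a_pos <- which(strsplit(runoff, "")[[1]] == "A")  # 1-based, body only
  with_seed(seed, {
    mods <- lapply(seq_len(n), function(i) {
      a_pos[stats::runif(length(a_pos)) < m6atp_fraction] - 1L
    })
    tibble::tibble(
      transcript = seq_len(n),
      sequence = paste0(runoff, tail_seq),
      n_adenosine = length(a_pos),
      n_modified = lengths(mods),
      modified_positions = mods,
      has_polya_tail = polya_tail_length > 0L
    )
  })
}

#' Expected m6A load per transcript
#'
#' Deterministic expectation of the number of m6ATP nucleotides incorporated
#' per run-off transcript: the adenosine count of the run-off sequence times
#' the m6ATP substitution fraction. The polyA tail is excluded because it is
#' added post-transcriptionally with unmodified ATP.
#'
#' @inheritParams simulate_ivt
#' @return A single number (expected modified adenosines per transcript).
#' @export
expected_modified_count <- function(template, promoter = T7_PROMOTER,
                                    m6atp_fraction) {
  stopifnot(m6atp_fraction >= 0, m6atp_fraction <= 1)
  runoff <- t7_runoff(template, promoter)
  n_a <- sum(strsplit(runoff, "")[[1]] == "A")
  n_a * m6atp_fraction
}

#' Canonical T7 promoter (sense strand)
#' @export
T7_PROMOTER <- "TAATACGACTCACTATA"

# Run-off transcript (RNA alphabet) downstream of a unique promoter.
t7_runoff <- function(template, promoter = T7_PROMOTER) {
  stopifnot(is.character(template), length(template) == 1L)
  template <- toupper(gsub("\\s", "", template))
  promoter <- toupper(promoter)
  hits <- gregexpr(promoter, template, fixed = TRUE)[[1]]
  if (identical(as.integer(hits), -1L)) {
    stop(sprintf("promoter '%s' not found in template", promoter), call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop(sprintf("promoter '%s' occurs %d times in template; must be unique",
                 promoter, length(hits)), call. = FALSE)
  }
  start <- hits[1] + nchar(promoter)
  if (start > nchar(template)) {
    stop("promoter lies at the template 3' end; empty run-off", call. = FALSE)
  }
  chartr("T", "U", substr(template, start, nchar(template)))
}

#' The 197-nt IVT control template
#'
#' The synthetic DNA oligo used as the modification-defined in-vitro
#' transcription control: a T7 promoter followed by a 167-nt run-off region.
#' @export
ivt_control_template <- function() {
  paste0(
    "GGCCAGTGAATTGTAATACGACTCACTATAGGGAGGCGGTAACACCTTCTGGACTCTTCATAGAGTTGG",
    "TCTATTTGTCTCCACGCTGCCAGGTTGTTGTGGCCTGTTTTCGGGCGTCTGCGGCGAAGATCTCTTGT",
    "CAGAGCCTTAGGTGTATCTAGATTGTGATCCCCTTTCCTCACTTGGTAGTCTGTCGACTT"
  )
}

#' Write simulated transcripts to FASTA
#'
#' @param transcripts tibble from [simulate_ivt()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  headers <- sprintf(">ivt_%d n_modified=%d positions=%s",
                     transcripts$transcript, transcripts$n_modified,
                     vapply(transcripts$modified_positions,
                            function(p) paste(p, collapse = ","), character(1)))
  writeLines(as.vector(rbind(headers, transcripts$sequence)), path)
  invisible(path)
}
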