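#' @name probe_design
#' @title seqFISH probe design
#'
#' @description Deterministic sequence pipeline for designing gene-specific
#' primary probes and screening fluorescent readout sequences. Candidate
#' 25-30 nt windows on an exon-consensus mRNA sequence are filtered by GC
#' content (45-70%), homopolymer runs (< 5), and inter-probe spacing (at
#' least 2 nt of gap between footprints); cross-hybridizing probes sharing a
#' 17-nt-or-longer exact substring with any other probe are removed; sets
#' over 32 probes are trimmed toward 55% GC; readouts with 15-nt-or-longer
#' exact matches to the transcriptome reference are discarded; and each
#' primary oligo is assembled as the hybridizing sequence, a "TA" gap, and
#' the reverse complement of the gene's readout.
NULL

#' Reverse complement of a DNA/RNA sequence
#' @param x character vector of sequences (ACGTU, case-insensitive).
#' @return Reverse complement(s), uppercase DNA alphabet.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("U", "T", toupper(s))
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of a sequence, in percent
#' @param x character vector of sequences.
#' @return Numeric vector of GC percentages.
#' @export
gc_percent <- function(x) {
  vapply(x, function(s) {
    b <- strsplit(toupper(s), "")[[1]]
    100 * sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

max_homopolymer_run <- function(s) {
  r <- rle(strsplit(toupper(s), "")[[1]])
  max(r$lengths)
}

#' Enumerate and select primary-probe candidates on one gene
#'
#' Slides windows of every length in `lengths` over the exon-consensus
#' sequence; drops windows with GC outside `gc_bounds` (inclusive), with a
#' homopolymer run of `max_run + 1` or more, or containing ambiguous bases;
#' then selects a non-conflicting subset by a deterministic greedy
#' left-to-right scan requiring at least `min_gap` nt between adjacent probe
#' footprints (candidates ordered by start, then end; the earliest compatible
#' candidate is always taken).
#'
#' @param consensus exon-consensus mRNA sense sequence (ACGT/U).
#' @param gene gene name attached to the candidates.
#' @param gc_bounds inclusive GC bounds in percent, default `c(45, 70)`.
#' @param max_run maximum allowed homopolymer run length (default 4).
#' @param lengths probe length range `c(min, max)`, default `c(25, 30)`.
#' @param min_gap minimum gap in nt between adjacent probe footprints.
#' @return Tibble of selected probes: `gene`, `start`, `end` (0-based,
#'   half-open on the consensus), `sequence` (consensus sense window),
#'   `gc_percent`. Attribute `"n_dropped_ambiguous"` counts windows dropped
#'   for ambiguous bases.
#' @export
extract_candidates <- function(consensus, gene = "gene",
                               gc_bounds = c(45, 70), max_run = 4,
                               lengths = c(25, 30), min_gap = 2) {
  consensus <- chartr("U", "T", toupper(gsub("\\s", "", consensus)))
  L <- nchar(consensus)
  if (L < lengths[1]) stop("consensus shorter than minimum probe length",
                           call. = FALSE)
  cand <- list(); n_ambig <- 0L
  for (len in lengths[1]:lengths[2]) {
    if (len > L) next
    starts <- 0:(L - len)
    for (s in starts) {
      w <- substr(consensus, s + 1, s + len)
      if (grepl("[^ACGT]", w)) { n_ambig <- n_ambig + 1L; next }
      gc <- gc_percent(w)
      if (gc < gc_bounds[1] || gc > gc_bounds[2]) next
      if (max_homopolymer_run(w) > max_run) next
      cand[[length(cand) + 1]] <- list(start = s, end = s + len,
                                       sequence = w, gc = gc)
    }
  }
  if (!length(cand)) {
    out <- tibble::tibble(gene = character(), start = integer(),
                          end = integer(), sequence = character(),
                          gc_percent = numeric())
    attr(out, "n_dropped_ambiguous") <- n_ambig
    return(out)
  }
  df <- dplyr::bind_rows(lapply(cand, tibble::as_tibble))
  df <- dplyr::arrange(df, .data$start, .data$end)
  # greedy left-to-right selection with footprint gap >= min_gap
  keep <- integer(); last_end <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$start[i] >= last_end + min_gap) {
      keep <- c(keep, i)
      last_end <- df$end[i]
    }
  }
  out <- tibble::tibble(gene = gene,
                        start = as.integer(df$start[keep]),
                        end = as.integer(df$end[keep]),
                        sequence = df$sequence[keep],
                        gc_percent = df$gc[keep])
  attr(out, "n_dropped_ambiguous") <- n_ambig
  out
}

# k-mers of a sequence, canonicalized against the reverse complement so one
# index covers both strands.
canonical_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character())
  km <- substring(s, 1:(L - k + 1), k:L)
  rc <- revcomp(km)
  pmin(km, rc)
}

#' Remove cross-hybridizing probes
#'
#' Drops any probe sharing an exact substring of `min_match` nt or longer
#' (either strand) with a probe of another gene or another probe of the same
#' gene. Probes are scanned in input order (gene order, then start); on a
#' collision the later-scanned probe is the one dropped, so the filter is
#' deterministic.
#'
#' @param probes tibble of probes from [extract_candidates()] (one or more
#'   genes bound together).
#' @param min_match minimum shared exact substring length (default 17).
#' @return The filtered probe tibble; dropped probes are recorded in the
#'   attribute `"dropped"`.
#' @export
cross_hyb_filter <- function(probes, min_match = 17) {
  if (nrow(probes) < 2) {
    attr(probes, "dropped") <- probes[0, ]
    return(probes)
  }
  index <- new.env(parent = emptyenv())
  keep <- logical(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    kms <- unique(canonical_kmers(probes$sequence[i], min_match))
    hit <- any(vapply(kms, function(k) !is.null(index[[k]]), logical(1)))
    if (!hit) {
      keep[i] <- TRUE
      for (k in kms) index[[k]] <- i
    }
  }
  out <- probes[keep, ]
  attr(out, "dropped") <- probes[!keep, ]
  out
}

#' Trim an oversized probe set toward the target GC
#'
#' While a gene's set exceeds `max_size` probes, the probe whose GC content
#' is farthest from `gc_target` is removed; ties are broken by dropping the
#' probe with the larger start coordinate.
#'
#' @param probes probe tibble (one or more genes; trimming is per gene).
#' @param max_size maximum probes per gene (default 32).
#' @param gc_target target GC in percent (default 55).
#' @return Trimmed probe tibble.
#' @export
trim_set <- function(probes, max_size = 32, gc_target = 55) {
  if (nrow(probes) == 0) return(probes)
  split(probes, probes$gene) |>
    lapply(function(g) {
      while (nrow(g) > max_size) {
        d <- abs(g$gc_percent - gc_target)
        worst <- which(d == max(d))
        if (length(worst) > 1) worst <- worst[which.max(g$start[worst])]
        g <- g[-worst, ]
      }
      g
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(match(.data$gene, unique(probes$gene)), .data$start)
}

#' Screen readout sequences against a transcriptome reference
#'
#' A 20-nt readout is kept only if its longest exact contiguous match to the
#' reference (either strand) is at most `max_homology` nt; anything of
#' `max_homology + 1` nt or longer disqualifies it.
#'
#' @param readouts character vector of 20-nt readout sequences.
#' @param reference character vector of reference transcript sequences.
#' @param max_homology longest tolerated exact match (default 14 nt).
#' @return The kept readouts (named logical attribute `"kept"` maps all
#'   inputs).
#' @export
filter_readouts <- function(readouts, reference, max_homology = 14) {
  stopifnot(all(nchar(readouts) == 20))
  k <- max_homology + 1
  ref <- paste(chartr("U", "T", toupper(reference)), collapse = "|")
  kept <- vapply(readouts, function(r) {
    r <- toupper(r)
    kms <- unique(c(substring(r, 1:(nchar(r) - k + 1), k:nchar(r)),
                    substring(revcomp(r), 1:(nchar(r) - k + 1), k:nchar(r))))
    !any(vapply(kms, function(km) grepl(km, ref, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  out <- readouts[kept]
  attr(out, "kept") <- kept
  out
}

#' Assemble primary probe oligos
#'
#' Each primary oligo is the mRNA-hybridizing sequence (reverse complement of
#' the consensus sense window), a fixed "TA" gap, and the reverse complement
#' of the gene's readout sequence, so the dye-carrying readout probe can
#' hybridize to the oligo's 3' end.
#'
#' @param probes probe tibble for one gene.
#' @param readout the gene's 20-nt readout sequence (already screened by
#'   [filter_readouts()]).
#' @param readout_id label for the readout.
#' @return Tibble with `gene`, `start`, `end`, `target_sequence` (the
#'   hybridizing strand), `gap`, `readout_revcomp`, `oligo`, `readout_id`.
#' @export
assemble_primary_probes <- function(probes, readout, readout_id = "R1") {
  target <- revcomp(probes$sequence)
  rc <- revcomp(readout)
  tibble::tibble(
    gene = probes$gene,
    start = probes$start,
    end = probes$end,
    target_sequence = target,
    gap = "TA",
    readout_revcomp = rc,
    oligo = paste0(target, "TA", rc),
    readout_id = readout_id
  )
}

#' Full probe-design pipeline
#'
#' Runs candidate extraction per gene, the cross-hybridization filter over
#' the pooled candidates, per-gene trimming, readout screening, and oligo
#' assembly. Sets outside the 20-32 target band are flagged, not dropped.
#'
#' @param consensus named character vector: exon-consensus sense sequence per
#'   gene.
#' @param readouts character vector of candidate 20-nt readouts (at least as
#'   many passing the screen as genes).
#' @param reference reference transcript sequences for the readout screen;
#'   defaults to the consensus sequences themselves.
#' @param gc_bounds,max_run,lengths,min_gap see [extract_candidates()].
#' @param min_match see [cross_hyb_filter()].
#' @param max_size,gc_target see [trim_set()].
#' @param max_homology see [filter_readouts()].
#' @param set_size_band acceptable probes-per-gene band; sets outside it are
#'   flagged in the report.
#' @return A `probe_design` object: `probes` (assembled oligo tibble),
#'   `report` (per-gene design report tibble), `readouts_kept`.
#' @export
design_probes <- function(consensus, readouts, reference = NULL,
                          gc_bounds = c(45, 70), max_run = 4,
                          lengths = c(25, 30), min_gap = 2, min_match = 17,
                          max_size = 32, gc_target = 55, max_homology = 14,
                          set_size_band = c(20, 32)) {
  stopifnot(!is.null(names(consensus)), length(readouts) >= 1)
  cands <- dplyr::bind_rows(lapply(names(consensus), function(g) {
    extract_candidates(consensus[[g]], gene = g, gc_bounds = gc_bounds,
                       max_run = max_run, lengths = lengths,
                       min_gap = min_gap)
  }))
  n_cand <- table(factor(cands$gene, levels = names(consensus)))
  filtered <- cross_hyb_filter(cands, min_match = min_match)
  trimmed <- trim_set(filtered, max_size = max_size, gc_target = gc_target)
  reference <- reference %||% unname(unlist(consensus))
  kept_readouts <- filter_readouts(readouts, reference,
                                   max_homology = max_homology)
  if (length(kept_readouts) < length(consensus)) {
    stop(sprintf("only %d readout(s) pass the homology screen for %d genes",
                 length(kept_readouts), length(consensus)), call. = FALSE)
  }
  assembled <- dplyr::bind_rows(lapply(seq_along(names(consensus)), function(i) {
    g <- names(consensus)[i]
    assemble_primary_probes(trimmed[trimmed$gene == g, ],
                            kept_readouts[i],
                            readout_id = sprintf("R%d", i))
  }))
  n_final <- table(factor(trimmed$gene, levels = names(consensus)))
  report <- tibble::tibble(
    gene = names(consensus),
    n_candidates = as.integer(n_cand),
    n_after_crosshyb = as.integer(table(factor(filtered$gene,
                                               levels = names(consensus)))),
    n_final = as.integer(n_final),
    flagged = n_final < set_size_band[1] | n_final > set_size_band[2]
  )
  structure(list(probes = assembled, report = report,
                 readouts_kept = as.character(kept_readouts)),
            class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("probe design: %d oligos over %d gene(s); %d set(s) flagged\n",
              nrow(x$probes), nrow(x$report), sum(x$report$flagged)))
  invisible(x)
}

#' Independently re-verify a designed probe set
#'
#' Direct re-check of every design rule on the emitted probes: GC bounds,
#' homopolymer run, footprint spacing per gene, and absence of shared
#' substrings of `min_match` nt or more between any two probes (all-pairs,
#' both strands). Used to validate the pipeline against its own rules.
#'
#' @param probes probe tibble with `gene`, `start`, `end`, `sequence` (sense
#'   windows; pass the design's pre-assembly table or rebuild from oligos).
#' @inheritParams design_probes
#' @return Tibble of violations (zero rows when the set is sound).
#' @export
verify_probe_set <- function(probes, gc_bounds = c(45, 70), max_run = 4,
                             min_gap = 2, min_match = 17) {
  v <- list()
  bad_gc <- gc_percent(probes$sequence) < gc_bounds[1] |
    gc_percent(probes$sequence) > gc_bounds[2]
  if (any(bad_gc)) v[["gc"]] <- tibble::tibble(rule = "gc",
                                               index = which(bad_gc))
  runs <- vapply(probes$sequence, max_homopolymer_run, numeric(1))
  if (any(runs > max_run)) {
    v[["run"]] <- tibble::tibble(rule = "homopolymer", index = which(runs > max_run))
  }
  for (g in unique(probes$gene)) {
    p <- probes[probes$gene == g, ]
    p <- p[order(p$start), ]
    if (nrow(p) > 1) {
      gap <- p$start[-1] - p$end[-nrow(p)]
      if (any(gap < min_gap)) {
        v[[paste0("sp", g)]] <- tibble::tibble(rule = "spacing",
                                               index = which(gap < min_gap))
      }
    }
  }
  # all-pairs shared-substring check (both strands)
  n <- nrow(probes)
  shares <- function(a, b) {
    ka <- unique(canonical_kmers(a, min_match))
    kb <- unique(canonical_kmers(b, min_match))
    length(intersect(ka, kb)) > 0
  }
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    if (shares(probes$sequence[i], probes$sequence[j])) {
      v[[paste0("xh", i, "_", j)]] <- tibble::tibble(rule = "cross_hyb",
                                                     index = c(i, j))
    }
  }
  if (!length(v)) tibble::tibble(rule = character(), index = integer())
  else dplyr::bind_rows(v)
}

#' Write designed probes to FASTA
#'
#' Headers follow `gene|start|end|gc|readout_id`.
#'
#' @param design a `probe_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probes_fasta <- function(design, path) {
  p <- design$probes
  gc <- gc_percent(p$target_sequence)
  headers <- sprintf(">%s|%d|%d|%.1f|%s", p$gene, p$start, p$end, gc,
                     p$readout_id)
  writeLines(as.vector(rbind(headers, p$oligo)), path)
  invisible(path)
}
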