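# Independent brute-force probe-candidate oracle (plain loops, no package
# helpers beyond base R). Enumerates every window, applies the GC /
# homopolymer / spacing rules, and selects greedily left to right.
oracle_candidates <- function(consensus, gc_lo = 45, gc_hi = 70,
                              max_run = 4, len_lo = 25, len_hi = 30,
                              min_gap = 2) {
  consensus <- toupper(chartr("U", "T", consensus))
  L <- nchar(consensus)
  cand <- data.frame()
  for (len in len_lo:len_hi) {
    if (len > L) next
    for (s in 0:(L - len)) {
      w <- substr(consensus, s + 1, s + len)
      ch <- strsplit(w, "")[[1]]
      if (any(!ch %in% c("A", "C", "G", "T"))) next
      gc <- 100 * sum(ch %in% c("G", "C")) / len
      if (gc < gc_lo || gc > gc_hi) next
      if (max(rle(ch)$lengths) > max_run) next
      cand <- rbind(cand, data.frame(start = s, end = s + len, seq = w,
                                     gc = gc))
    }
  }
  cand <- cand[order(cand$start, cand$end), ]
  sel <- data.frame(); last_end <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end + min_gap) {
      sel <- rbind(sel, cand[i, ]); last_end <- cand$end[i]
    }
  }
  sel
}

# Brute-force per-gene trim: drop the probe farthest from the GC target,
# later start first on ties, until at most max_size remain.
oracle_trim <- function(df, max_size = 32, gc_target = 55) {
  out <- NULL
  for (g in unique(df$gene)) {
    p <- df[df$gene == g, ]
    while (nrow(p) > max_size) {
      d <- abs(p$gc - gc_target)
      worst <- which(d == max(d))
      if (length(worst) > 1) worst <- worst[which.max(p$start[worst])]
      p <- p[-worst, ]
    }
    out <- rbind(out, p)
  }
  out
}
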