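# Independent oracles used to freeze expected values.  These deliberately
# re-derive results by a different route than the package code.

# Mutational steps by exhaustive memoised recursion over alignment states:
# maximise alignment score (match +1, mismatch -2, gap of length L costs
# 4 + L), and among score-optimal alignments report the fewest steps
# (mismatches + gap runs).  Written as plain recursion, independent of the
# package's iterative DP.
oracle_steps <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  # state: 0 = last column was a match/mismatch, 1 = gap in a, 2 = gap in b
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(a) && j > length(b)) return(c(score = 0, steps = 0))
    best <- c(score = -1e9, steps = 0)
    consider <- function(nxt, dscore, dsteps) {
      v <- c(nxt[1] + dscore, nxt[2] + dsteps)
      if (v[1] > best[1] || (v[1] == best[1] && v[2] < best[2]))
        best <<- c(score = v[[1]], steps = v[[2]])
    }
    if (i <= length(a) && j <= length(b)) {
      eq <- a[i] == b[j]
      consider(rec(i + 1, j + 1, 0), if (eq) 1 else -2, if (eq) 0 else 1)
    }
    if (j <= length(b))   # gap in a
      consider(rec(i, j + 1, 1), if (state == 1) -1 else -5,
               if (state == 1) 0 else 1)
    if (i <= length(a))   # gap in b
      consider(rec(i + 1, j, 2), if (state == 2) -1 else -5,
               if (state == 2) 0 else 1)
    memo[[key]] <- best
    best
  }
  unname(rec(1, 1, 0)[2])
}

# Straight transcription of the parsimony-probability formula: the chance
# that j mutations on L sites all strike distinct sites is
# L! / ((L-j)! L^j); the limit is the largest j keeping it >= conf.
oracle_limit <- function(L, conf) {
  j <- 0
  while (j < L) {
    p <- exp(lfactorial(L) - lfactorial(L - (j + 1)) - (j + 1) * log(L))
    if (p < conf) break
    j <- j + 1
  }
  max(j, 1)
}

# Random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Perturb a sequence with point substitutions at given positions
sub_at <- function(seq, pos, base) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- base[i]
  seq
}

# Tiny frequency-table constructor for desk fixtures
freq_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(population_id = r$pop, country = r$country %||% "X",
               continent = r$continent %||% "X", year = r$year %||% 2010L,
               segment_id = r$seg, haplotype_name = names(r$freqs),
               read_count = as.integer(round(1000 * r$freqs)),
               frequency = as.numeric(r$freqs), stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  class(df) <- c("frequency_table", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures: packaged panel, sequences, annotations
panel_fx <- build_default_panel()
panel_seqs <- setNames(panel_fx$haplotypes$sequence, panel_fx$haplotypes$name)
panel_ann <- lapply(seq_len(nrow(panel_fx$haplotypes)), function(i) {
  h <- panel_fx$haplotypes[i, ]
  annotate_haplotype(h$sequence, panel_fx$models[[h$segment_id]], h$name)
})
names(panel_ann) <- panel_fx$haplotypes$name
panel_clades <- classify_clades(panel_seqs[startsWith(names(panel_seqs), "2s6")],
                                panel_fx$models$IIS6)
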