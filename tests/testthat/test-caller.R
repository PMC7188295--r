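man2 <- data.frame(barcode = c("AACCGGTT", "ACGTACGT"),
                   population_id = c("p1", "p2"),
                   country = c("Brazil", "Kenya"),
                   continent = c("South America", "Africa"),
                   year = c(2010L, 2012L), stringsAsFactors = FALSE)

fake_reads <- function(seqs, qual_char = "I") {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = strrep(qual_char, nchar(seqs)),
             stringsAsFactors = FALSE)
}

test_that("demultiplexing follows the unique-barcode-within-k rule", {
  body <- strrep("ACGT", 20)
  reads <- fake_reads(c(
    paste0("AACCGGTT", body),    # exact p1
    paste0("AACCGGTA", body),    # 1 mismatch from p1 (and 4+ from p2)
    paste0("ACGTACGT", body),    # exact p2
    paste0("TTTTTTTT", body)))   # matches nothing
  bins <- demultiplex(reads, man2, caller_params(barcode_max_mismatch = 1))
  expect_equal(nrow(bins$p1), 2)
  expect_equal(nrow(bins$p2), 1)
  expect_equal(nrow(bins$.unassigned), 1)
  # barcode is stripped, quality kept in register
  expect_true(all(bins$p1$sequence == body))
  expect_equal(nchar(bins$p1$quality), nchar(bins$p1$sequence))
  # conservation across bins
  expect_equal(sum(vapply(bins, nrow, 1L)), nrow(reads))
  # a read within k of two barcodes is ambiguous, hence unassigned
  amb <- data.frame(barcode = c("AAAAAAAA", "AAAAAAAT"),
                    population_id = c("x", "y"), country = "c",
                    continent = "c", year = 2000L)
  r <- fake_reads(paste0("AAAAAAAA", body))
  bins2 <- demultiplex(r, amb, caller_params(barcode_max_mismatch = 1))
  expect_equal(nrow(bins2$.unassigned), 1)
  expect_error(demultiplex(r, man2[0, ], caller_params()), "empty manifest")
})

test_that("simulated error-free reads demultiplex with an empty unassigned bin", {
  cfgs <- list(
    population_config("p1", "Brazil", "South America", 2010, "AACCGGTT",
                      c("2s6_A_03" = 1), c("3s6_00" = 1), 250L),
    population_config("p2", "Kenya", "Africa", 2012, "ACGTACGT",
                      c("2s6_B_00" = 1), c("3s6_01" = 1), 250L))
  em0 <- error_model(substitution_rate = 0, indel_rate = 0)
  reads <- rbind(simulate_pool(cfgs[[1]], panel_fx, em0, seed = 1),
                 simulate_pool(cfgs[[2]], panel_fx, em0, seed = 2))
  bins <- demultiplex(reads, man2, caller_params())
  expect_equal(nrow(bins$.unassigned), 0)
  expect_equal(nrow(bins$p1), 500)
  expect_equal(nrow(bins$p2), 500)
})

test_that("read filtering trims primers, enforces the windows, re-orients", {
  m <- panel_fx$models$IIS6
  amplicon <- panel_seqs[["2s6_A_03"]]
  insert <- panel_inserts(panel_fx)[["2s6_A_03"]]
  reads <- fake_reads(c(amplicon, substr(amplicon, 1, 50)))
  kept <- filter_reads(reads, m, caller_params())
  expect_equal(nrow(kept), 1)
  expect_equal(nchar(kept$sequence),
               nchar(amplicon) - nchar(m$primer_fwd) - nchar(m$primer_rev))
  expect_equal(kept$sequence, unname(insert))
  # reverse-strand read comes back forward-oriented and identical
  rc <- fake_reads(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(amplicon))))
  kept_rc <- filter_reads(rc, m, caller_params())
  expect_equal(kept_rc$sequence, unname(insert))
  # low-quality reads are dropped ('#' = Phred 2)
  lowq <- fake_reads(amplicon, qual_char = "#")
  expect_equal(nrow(filter_reads(lowq, m, caller_params())), 0)
  # reads from the other segment carry the wrong primers
  other <- fake_reads(panel_seqs[["3s6_00"]])
  expect_equal(nrow(filter_reads(other, m, caller_params())), 0)
})

test_that("denoiser keeps distant true haplotypes and absorbs error shoulders", {
  h1 <- strrep("ACGTGATCCA", 31)
  h2 <- sub_at(h1, c(11, 57, 103, 149, 195), c("T", "A", "C", "T", "C"))
  stopifnot(adist(h1, h2) == 5)
  # two real haplotypes beyond collapse distance: never merged
  calls <- call_haplotypes(c(rep(h1, 900), rep(h2, 100)), caller_params())
  expect_equal(nrow(calls), 2)
  expect_equal(calls$frequency, c(0.9, 0.1))
  # a 1% error shoulder at distance 1 is absorbed into a single call
  h1e <- sub_at(h1, 23, "T")
  calls2 <- call_haplotypes(c(rep(h1, 990), rep(h1e, 10)), caller_params())
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$frequency, 1)
  expect_equal(calls2$read_count, 1000L)
  # homopolymer-length-only differences merge regardless of the ratio
  hp <- paste0(substr(h1, 1, 100), "AAAAA", substr(h1, 101, nchar(h1)))
  hp_del <- paste0(substr(h1, 1, 100), "AAAA", substr(h1, 101, nchar(h1)))
  calls3 <- call_haplotypes(c(rep(hp, 60), rep(hp_del, 40)), caller_params())
  expect_equal(nrow(calls3), 1)
  expect_equal(calls3$read_count, 100L)
  # empty input: warned and dropped
  expect_warning(out <- call_haplotypes(character(0)), "dropped")
  expect_equal(nrow(out), 0)
})

test_that("denoiser is idempotent and monotone in the frequency floor", {
  h1 <- strrep("ACGTGATCCA", 31)
  h2 <- sub_at(h1, c(11, 57, 103, 149, 195), c("T", "A", "C", "T", "C"))
  h3 <- sub_at(h1, c(31, 87, 143, 199, 255), c("C", "A", "A", "G", "A"))
  reads <- c(rep(h1, 700), rep(h2, 200), rep(h3, 100))
  params <- caller_params()
  calls <- call_haplotypes(reads, params)
  rebuilt <- rep(calls$sequence, calls$read_count)
  expect_equal(call_haplotypes(rebuilt, params), calls)
  # raising the floor never increases the number of calls
  floors <- c(0, 0.01, 0.05, 0.15, 0.25, 0.45)
  ncalls <- vapply(floors, function(fl)
    nrow(suppressWarnings(call_haplotypes(reads, caller_params(frequency_floor = fl)))),
    integer(1))
  expect_true(all(diff(ncalls) <= 0))
})

test_that("a simulated pool is recovered without spurious calls", {
  truth <- c("2s6_B_00" = 0.6, "2s6_A_02" = 0.3, "2s6_A_03" = 0.1)
  cfg <- population_config("p1", "Brazil", "South America", 2010,
                           "AACCGGTT", truth, c("3s6_01" = 1), 2000L)
  em <- error_model(substitution_rate = 0.005, indel_rate = 0.001)
  reads <- simulate_pool(cfg, panel_fx, em, seed = 99)
  man <- man2[1, ]
  bins <- demultiplex(reads, man, caller_params())
  kept <- filter_reads(bins$p1, panel_fx$models$IIS6, caller_params())
  calls <- call_haplotypes(kept, caller_params())
  ins <- panel_inserts(panel_fx)
  called <- setNames(calls$frequency, names(ins)[match(calls$sequence, ins)])
  expect_setequal(names(called), names(truth))
  expect_true(all(abs(called[names(truth)] - truth) <= 0.03))
})

test_that("merged tables share names across populations and rank by abundance", {
  ins <- panel_inserts(panel_fx)
  mk_calls <- function(seqs, counts) {
    data.frame(sequence = seqs, read_count = as.integer(counts),
               frequency = counts / sum(counts), stringsAsFactors = FALSE)
  }
  calls <- list(
    p1 = list(IIS6 = mk_calls(ins[c("2s6_B_00", "2s6_A_02")], c(900, 100))),
    p2 = list(IIS6 = mk_calls(ins[c("2s6_B_00", "2s6_A_03")], c(500, 500))))
  tab <- merge_tables(calls, man2)
  # the shared sequence gets one name in both populations
  shared <- tab$haplotype_name[tab$sequence == ins[["2s6_B_00"]]]
  expect_equal(length(shared), 2)
  expect_equal(length(unique(shared)), 1)
  # globally most abundant sequence is ranked _00
  expect_equal(unique(shared), "2s6_00")
  expect_setequal(unique(tab$haplotype_name), c("2s6_00", "2s6_01", "2s6_02"))
  # per population+segment frequencies still sum to 1
  sums <- tapply(tab$frequency, paste(tab$population_id, tab$segment_id), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # panel name map overrides rank names
  tab2 <- merge_tables(calls, man2, name_map = ins)
  expect_setequal(unique(tab2$haplotype_name),
                  c("2s6_B_00", "2s6_A_02", "2s6_A_03"))
})
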