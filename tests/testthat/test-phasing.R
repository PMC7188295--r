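# The five-population worked example: every population fixed for the
# IIIS6 1534C haplotype, segregating a clade-B wild type against the
# clade-A 1016I haplotype at IIS6.
five_pop_table <- function() {
  rows <- list()
  pops <- list(c("PuertoRico", 0.7), c("NewOrleans", 0.5), c("Iguala", 0.6),
               c("Amacuzac", 0.8), c("RibeiraoPreto", 0.4))
  for (p in pops) {
    f <- as.numeric(p[2])
    rows <- c(rows, list(
      list(pop = p[1], seg = "IIS6",
           freqs = setNames(c(f, 1 - f), c("2s6_B_00", "2s6_A_02"))),
      list(pop = p[1], seg = "IIIS6", freqs = c("3s6_01" = 1))))
  }
  freq_table(rows)
}

test_that("phaseability requires a monomorphic segment", {
  tab <- five_pop_table()
  pops <- two_segment_populations(tab)
  expect_true(all(vapply(pops, is_phaseable, logical(1))))
  # polymorphic in both segments: not phaseable
  both <- freq_table(list(
    list(pop = "x", seg = "IIS6", freqs = c("2s6_B_00" = 0.5, "2s6_A_02" = 0.5)),
    list(pop = "x", seg = "IIIS6", freqs = c("3s6_00" = 0.5, "3s6_01" = 0.5))))
  expect_false(is_phaseable(two_segment_populations(both)$x))
  # both monomorphic: phaseable
  fixed <- freq_table(list(
    list(pop = "y", seg = "IIS6", freqs = c("2s6_B_00" = 1)),
    list(pop = "y", seg = "IIIS6", freqs = c("3s6_01" = 1))))
  expect_true(is_phaseable(two_segment_populations(fixed)$y))
  expect_error(phase_population(two_segment_populations(both)$x, panel_clades),
               "cannot be phased")
})

test_that("phasing a monomorphic-IIIS6 population yields the two known pairs", {
  tab <- five_pop_table()
  pops <- two_segment_populations(tab)
  ph <- phase_population(pops$PuertoRico, panel_clades)
  expect_setequal(ph$name, c("Phased_00B-01", "Phased_02A-01"))
  expect_equal(ph$frequency[ph$name == "Phased_00B-01"], 0.7)
  expect_equal(ph$frequency[ph$name == "Phased_02A-01"], 0.3)
  expect_equal(sum(ph$frequency), 1)
  # both fixed -> a single phased haplotype at frequency 1
  fixed <- freq_table(list(
    list(pop = "y", seg = "IIS6", freqs = c("2s6_B_00" = 1)),
    list(pop = "y", seg = "IIIS6", freqs = c("3s6_01" = 1))))
  ph2 <- phase_population(two_segment_populations(fixed)$y, panel_clades)
  expect_equal(nrow(ph2), 1)
  expect_equal(ph2$name, "Phased_00B-01")
  expect_equal(ph2$frequency, 1)
  # IIS6 fixed against three IIIS6 haplotypes -> three phased haplotypes
  tri <- freq_table(list(
    list(pop = "z", seg = "IIS6", freqs = c("2s6_A_06" = 1)),
    list(pop = "z", seg = "IIIS6",
         freqs = c("3s6_00" = 0.5, "3s6_01" = 0.3, "3s6_13" = 0.2))))
  ph3 <- phase_population(two_segment_populations(tri)$z, panel_clades)
  expect_equal(nrow(ph3), 3)
  expect_true(all(abs(sum(ph3$frequency) - 1) < 1e-6))
  expect_setequal(ph3$name,
                  c("Phased_06A-00", "Phased_06A-01", "Phased_06A-13"))
})

test_that("1534C on both clades gives two origins; single clade gives one", {
  tab <- five_pop_table()
  phased <- phase_table(tab, panel_clades)
  expect_equal(nrow(phased), 10)   # two per polymorphic population
  rep2 <- infer_min_origins(phased, "F1534C", panel_ann)
  expect_equal(rep2$min_origins, 2L)
  expect_setequal(rep2$backgrounds$iis6_clade, c("A", "B"))
  # restricted to clade-A partners only: a single origin is inferred
  rep1 <- infer_min_origins(phased[phased$iis6_clade == "A", , drop = FALSE],
                            "F1534C", panel_ann)
  expect_equal(rep1$min_origins, 1L)
  # IIS6 mutation observed in a single haplotype: one origin
  repV <- infer_min_origins(phased, "V1016I", panel_ann)
  expect_equal(repV$min_origins, 1L)
  expect_equal(unique(repV$backgrounds$iis6_name), "2s6_A_02")
})

test_that("unobserved mutations are flagged, not counted as zero", {
  tab <- five_pop_table()
  phased <- phase_table(tab, panel_clades)
  rep0 <- infer_min_origins(phased, "T1520I", panel_ann)
  expect_equal(rep0$status, "unobserved")
  expect_true(is.na(rep0$min_origins))
})

test_that("adding populations never decreases the origin count", {
  tab <- five_pop_table()
  phased <- phase_table(tab, panel_clades)
  counts <- integer(0)
  for (k in seq_len(nrow(phased))) {
    r <- infer_min_origins(phased[seq_len(k), , drop = FALSE], "F1534C",
                           panel_ann)
    counts <- c(counts, ifelse(is.na(r$min_origins), 0L, r$min_origins))
  }
  expect_true(all(diff(counts) >= 0))
})

test_that("a relaxed monomorphism threshold tolerates trace haplotypes", {
  noisy <- freq_table(list(
    list(pop = "n", seg = "IIS6", freqs = c("2s6_B_00" = 0.6, "2s6_A_02" = 0.4)),
    list(pop = "n", seg = "IIIS6", freqs = c("3s6_01" = 0.985, "3s6_00" = 0.015))))
  pop <- two_segment_populations(noisy)$n
  expect_false(is_phaseable(pop))                    # strict default
  expect_true(is_phaseable(pop, threshold = 0.95))
  ph <- phase_population(pop, panel_clades, threshold = 0.95)
  expect_setequal(ph$name, c("Phased_00B-01", "Phased_02A-01"))
})
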