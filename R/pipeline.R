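#' Packaged demonstration scenario
#'
#' A synthetic multi-population survey wired to the packaged panel.  The
#' `"two_origin"` world reproduces the observational situation from which
#' two independent origins of F1534C are inferable: five populations
#' (Puerto Rico, New Orleans, Iguala, Amacuzac, Ribeirao Preto) fixed for
#' the IIIS6 1534C haplotype `3s6_01` and segregating the clade-B wild
#' type `2s6_B_00` against the clade-A kdr haplotype `2s6_A_02`; an Asian
#' population fixed for `2s6_A_06` (989P+1016G); a Brazilian series
#' spanning 2001-2015 in which `3s6_01` rises; and an old Brazilian
#' population fixed for `2s6_A_01` (1011M).  The `"single_origin"` world
#' differs only in that `3s6_01` is always phased with clade-A IIS6
#' haplotypes.
#'
#' Pools emulate ~30 individuals each; 2000 reads per segment per
#' population is the simulator default.
#'
#' @param world `"two_origin"` (default) or `"single_origin"`.
#' @param reads_per_segment Simulated reads per segment per population.
#' @return List with `configs` (list of [population_config()]), `panel`,
#'   `models`, `error_model`.
#' @export
demo_scenario <- function(world = c("two_origin", "single_origin"),
                          reads_per_segment = 2000L) {
  world <- match.arg(world)
  panel <- build_default_panel()
  bc <- default_barcodes(10L)
  B <- if (world == "two_origin") "2s6_B_00" else "2s6_A_03"
  cfg <- list(
    population_config("PuertoRico_10", "Puerto Rico", "North America", 2010,
                      bc[1], setNames(c(0.7, 0.3), c(B, "2s6_A_02")),
                      c("3s6_01" = 1), reads_per_segment),
    population_config("NewOrleans_11", "USA", "North America", 2011,
                      bc[2], setNames(c(0.5, 0.5), c(B, "2s6_A_02")),
                      c("3s6_01" = 1), reads_per_segment),
    population_config("Iguala_12", "Mexico", "North America", 2012,
                      bc[3], setNames(c(0.6, 0.4), c(B, "2s6_A_02")),
                      c("3s6_01" = 1), reads_per_segment),
    population_config("Amacuzac_12", "Mexico", "North America", 2012,
                      bc[4], setNames(c(0.8, 0.2), c(B, "2s6_A_02")),
                      c("3s6_01" = 1), reads_per_segment),
    population_config("RibeiraoPreto_15", "Brazil", "South America", 2015,
                      bc[5], setNames(c(0.3, 0.7), c(B, "2s6_A_02")),
                      c("3s6_01" = 1), reads_per_segment),
    population_config("Bangkok_13", "Thailand", "Asia", 2013,
                      bc[6], c("2s6_A_06" = 1),
                      c("3s6_00" = 0.4, "3s6_01" = 0.3, "3s6_13" = 0.2,
                        "3s6_02" = 0.1), reads_per_segment),
    population_config("Santiago_01", "Brazil", "South America", 2001,
                      bc[7], c("2s6_A_01" = 1),
                      c("3s6_00" = 0.9, "3s6_01" = 0.1), reads_per_segment),
    population_config("Recife_05", "Brazil", "South America", 2005,
                      bc[8], c("2s6_B_00" = 0.5, "2s6_B_04" = 0.3,
                               "2s6_A_01" = 0.2),
                      c("3s6_00" = 0.7, "3s6_01" = 0.3), reads_per_segment),
    population_config("Campinas_08", "Brazil", "South America", 2008,
                      bc[9], c("2s6_B_00" = 0.5, "2s6_A_02" = 0.5),
                      c("3s6_00" = 0.5, "3s6_01" = 0.5), reads_per_segment),
    population_config("Rio_11", "Brazil", "South America", 2011,
                      bc[10], c("2s6_B_00" = 0.4, "2s6_A_02" = 0.6),
                      c("3s6_00" = 0.3, "3s6_01" = 0.7), reads_per_segment))
  list(configs = cfg, panel = panel, models = panel$models,
       error_model = error_model())
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) pooled reads, then demultiplexes, filters, calls
#' haplotypes, annotates codon changes, builds per-segment parsimony
#' networks, classifies IIS6 clades, phases monomorphic populations,
#' infers minimum origins for the requested mutations, and extracts
#' temporal trajectories.  All outputs land in `out_dir` together with a
#' JSON run manifest recording parameters and seed; all randomness flows
#' from `seed`.
#'
#' @param scenario A [demo_scenario()]-shaped list, or `NULL` to read
#'   reads/manifest from files.
#' @param fastq,manifest Paths used when `scenario` is `NULL`.
#' @param out_dir Output directory (created if missing).
#' @param params A [caller_params()].
#' @param mutations Character vector of change labels to report origins
#'   for.
#' @param confidence Network connection-limit confidence.
#' @param trend_country Country for the temporal module (`NA` to skip;
#'   skipped with a message when fewer than two years are present).
#' @param seed Integer seed driving the simulation.
#' @return Invisibly, a list bundle: `table`, `annotated`, `clades`,
#'   `networks`, `phased`, `origins`, `trends`, `out_dir`.
#' @export
run_pipeline <- function(scenario = NULL, fastq = NULL, manifest = NULL,
                         out_dir = tempfile("kdrhaplo_run_"),
                         params = caller_params(),
                         mutations = c("F1534C", "V1016I", "V1016G",
                                       "S989P", "I1011M", "T1520I"),
                         confidence = 0.95, trend_country = "Brazil",
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scenario)) {
    if (is.null(fastq) || is.null(manifest))
      stop("either a scenario or fastq + manifest paths are required")
    if (!file.exists(fastq)) stop("no such FASTQ file: ", fastq)
    if (!file.exists(manifest)) stop("no such manifest file: ", manifest)
    reads <- read_fastq(fastq)
    man <- read_manifest(manifest)
    panel <- build_default_panel()
  } else {
    panel <- scenario$panel
    man_path <- file.path(out_dir, "manifest.tsv")
    man <- write_manifest(scenario$configs, man_path)
    reads <- do.call(rbind, lapply(seq_along(scenario$configs), function(i)
      simulate_pool(scenario$configs[[i]], panel, scenario$error_model,
                    seed = seed + i)))
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
  }
  models <- panel$models

  message("demultiplexing ", nrow(reads), " reads across ", nrow(man),
          " populations")
  bins <- demultiplex(reads, man, params)

  calls <- list()
  for (pop in man$population_id) {
    calls[[pop]] <- list()
    for (seg in c("IIS6", "IIIS6")) {
      kept <- filter_reads(bins[[pop]], models[[seg]], params)
      cc <- call_haplotypes(kept, params)
      if (nrow(cc)) calls[[pop]][[seg]] <- cc
    }
  }
  table <- merge_tables(calls, man, name_map = panel_inserts(panel))
  write_frequency_table(table, file.path(out_dir, "frequency_table.tsv"))
  for (seg in c("IIS6", "IIIS6")) {
    seqs <- table_sequences(table[table$segment_id == seg, ])
    if (length(seqs))
      write_fasta(seqs, file.path(out_dir, sprintf("haplotypes_%s.fasta", seg)))
  }

  annotated <- annotate_table(table, models)
  labs <- vapply(annotated$annotations, `[[`, "", "label")
  ann_df <- data.frame(haplotype_name = names(labs), label = unname(labs))
  write.table(ann_df, file.path(out_dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(annotated$summary, file.path(out_dir, "kdr_share.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  networks <- list()
  for (seg in c("IIS6", "IIIS6")) {
    sub <- table[table$segment_id == seg, , drop = FALSE]
    if (!nrow(sub)) next
    networks[[seg]] <- build_network(sub, seg, confidence = confidence,
                                     labels = labs)
    export_network(networks[[seg]],
                   file.path(out_dir, sprintf("network_%s.graphml", seg)))
  }

  iis6_seqs <- table_sequences(table[table$segment_id == "IIS6", ])
  clades <- classify_clades(iis6_seqs, models$IIS6)
  write.table(data.frame(haplotype_name = names(clades$labels),
                         clade = unname(clades$labels)),
              file.path(out_dir, "clades.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  phased <- phase_table(table, clades)
  write.table(phased, file.path(out_dir, "phased.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  origins <- lapply(mutations, function(mu)
    infer_min_origins(phased, mu, annotated$annotations))
  names(origins) <- mutations
  jsonlite::write_json(
    lapply(origins, function(o)
      list(mutation = o$mutation, segment = o$segment_id,
           status = o$status, min_origins = o$min_origins,
           backgrounds = o$backgrounds, populations = o$populations)),
    file.path(out_dir, "origins.json"), auto_unbox = TRUE, digits = NA,
    na = "null")

  trends <- NULL
  if (!is.na(trend_country)) {
    yrs <- unique(table$year[table$country == trend_country])
    if (length(yrs) >= 2) {
      trends <- trajectories(table, trend_country)
      write.table(as.data.frame(trends),
                  file.path(out_dir, sprintf("trends_%s.tsv", trend_country)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    } else message("fewer than two years for ", trend_country,
                   "; temporal module skipped")
  }

  jsonlite::write_json(
    list(package = "kdrhaplo",
         version = as.character(utils::packageVersion("kdrhaplo")),
         seed = seed,
         params = unclass(params),
         mutations = mutations,
         confidence = confidence,
         outputs = list.files(out_dir)),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(table = table, annotated = annotated, clades = clades,
                 networks = networks, phased = phased, origins = origins,
                 trends = trends, out_dir = out_dir))
}
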