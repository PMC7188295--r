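#' Haplotype frequency trajectories over collection years
#'
#' For every haplotype observed in a country, assembles its frequency in
#' each of the country's populations (0 when absent from a population) and
#' summarises the temporal trend as the Spearman rank correlation of year
#' versus frequency.  The direction label is `increasing` when the
#' correlation exceeds `rho_threshold`, `decreasing` below its negative,
#' `flat` otherwise (including the degenerate constant-frequency case).
#'
#' @param table A `frequency_table` (annotation label column optional).
#' @param country Country to extract; must span at least two distinct
#'   collection years.
#' @param rho_threshold Direction threshold on the rank correlation
#'   (default 0.3).
#' @return Object of class `trajectory_set`: data frame with columns
#'   `country`, `segment_id`, `haplotype_name`, `n_points`, `trend_rho`,
#'   `direction`, with the per-point data in `attr(, "points")` (a data
#'   frame `haplotype_name`, `year`, `population_id`, `frequency`).
#' @export
trajectories <- function(table, country, rho_threshold = 0.3) {
  sub <- table[table$country == country, , drop = FALSE]
  if (length(unique(sub$year)) < 2)
    stop("need at least two distinct collection years for ", country)
  rows <- list(); pts <- list()
  for (seg in unique(sub$segment_id)) {
    ss <- sub[sub$segment_id == seg, , drop = FALSE]
    pops <- unique(ss[, c("population_id", "year")])
    for (h in sort(unique(ss$haplotype_name))) {
      freq <- vapply(seq_len(nrow(pops)), function(i) {
        f <- ss$frequency[ss$population_id == pops$population_id[i] &
                            ss$haplotype_name == h]
        if (length(f)) sum(f) else 0
      }, numeric(1))
      ord <- order(pops$year, pops$population_id)
      pt <- data.frame(haplotype_name = h, year = pops$year[ord],
                       population_id = pops$population_id[ord],
                       frequency = freq[ord], stringsAsFactors = FALSE)
      rho <- suppressWarnings(cor(pt$year, pt$frequency,
                                  method = "spearman"))
      if (is.na(rho)) rho <- 0
      dir <- if (rho > rho_threshold) "increasing"
             else if (rho < -rho_threshold) "decreasing" else "flat"
      rows[[length(rows) + 1L]] <- data.frame(
        country = country, segment_id = seg, haplotype_name = h,
        n_points = nrow(pt), trend_rho = rho, direction = dir,
        stringsAsFactors = FALSE)
      pts[[length(pts) + 1L]] <- pt
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "points") <- do.call(rbind, pts)
  class(out) <- c("trajectory_set", "data.frame")
  out
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %s: %d haplotype trajectories\n",
              x$country[1], nrow(x)))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
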