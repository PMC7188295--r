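#' Mutational steps between two haplotypes
#'
#' The number of mutational steps separating two sequences of one segment:
#' aligned substitutions count one step each and every contiguous indel
#' run, whatever its length, counts a single step (an indel is one
#' mutational event).  Steps are counted on the score-optimal global
#' alignment (match +1, mismatch -2, gap open -4, gap extension -1);
#' among score-tied alignments the smallest step count is reported.
#'
#' @param a,b Nucleotide sequences.
#' @return Non-negative integer step count.
#' @examples
#' mutational_steps("ACGT", "ACGT")    # 0
#' mutational_steps("ACGT", "AGGT")    # 1
#' mutational_steps("ACTTTTGT", "ACGT")  # 1 run + 1 substitution = 2
#' @export
mutational_steps <- function(a, b) {
  .steps_dp(toupper(a), toupper(b))
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps at which two haplotypes of
#' length `seq_length` may be connected while the probability that the
#' observed differences reflect single hits (no site struck twice, hence
#' no hidden homoplasy) stays at or above `confidence`.  Under uniform
#' placement of `j` mutations over `L` sites that probability is
#' `prod_{i=0}^{j-1} (1 - i/L)`; the limit is the largest `j` keeping it
#' `>= confidence`.  As `confidence` tends to 0 every pair becomes
#' connectable (`limit -> L`).
#'
#' @param seq_length Alignment length in bases (>= 1).
#' @param confidence Probability-of-parsimony threshold in (0, 1);
#'   0.95 by convention.
#' @return Integer step limit (>= 1).
#' @export
connection_limit <- function(seq_length, confidence = 0.95) {
  stopifnot(seq_length >= 1, confidence > 0, confidence < 1)
  L <- as.integer(seq_length)
  p <- 1
  j <- 0L
  while (j < L) {
    p_next <- p * (1 - j / L)          # probability all j+1 hits distinct
    if (p_next < confidence) break
    p <- p_next
    j <- j + 1L
  }
  max(j, 1L)
}

#' Build a statistical-parsimony haplotype network
#'
#' Nodes are the distinct haplotypes of one segment, annotated with their
#' summed frequency across populations; candidate edges are weighted by
#' [mutational_steps()] and added in ascending step order (ties: higher
#' joint frequency first, then lexicographic name pair), skipping any edge
#' whose endpoints were already connected at a strictly smaller step count.
#' Score-tied alternative connections at the same step level are kept,
#' giving the reticulations typical of parsimony networks.  Pairs beyond
#' the connection limit are never linked, so the network may have several
#' components.
#'
#' @param table A `frequency_table` restricted to one segment (rows of
#'   other segments are dropped with a message).
#' @param segment_id `"IIS6"` or `"IIIS6"`.
#' @param limit Connection limit in steps; default computed by
#'   [connection_limit()] from the median sequence length.
#' @param confidence Passed to [connection_limit()] when `limit` is NULL.
#' @param labels Optional named character vector of annotation labels per
#'   haplotype name (e.g. `"V1016I"`).
#' @return Object of class `parsimony_network`: `nodes` (data frame
#'   `name`, `frequency`, `label`), `edges` (data frame `from`, `to`,
#'   `steps`), `limit`, `components` (named membership vector).
#' @export
build_network <- function(table, segment_id = NULL, limit = NULL,
                          confidence = 0.95, labels = NULL) {
  if (!is.null(segment_id) && any(table$segment_id != segment_id)) {
    table <- table[table$segment_id == segment_id, , drop = FALSE]
  }
  stopifnot(nrow(table) >= 1, length(unique(table$segment_id)) == 1)
  seqs <- table_sequences(table)
  freq <- tapply(table$frequency, table$haplotype_name, sum)
  nm <- sort(names(seqs))
  n <- length(nm)
  if (is.null(limit))
    limit <- connection_limit(stats::median(nchar(seqs)), confidence)

  nodes <- data.frame(name = nm, frequency = as.numeric(freq[nm]),
                      label = if (is.null(labels)) NA_character_
                              else as.character(labels[nm]),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0))
  if (n >= 2) {
    pairs <- t(combn(nm, 2))
    steps <- apply(pairs, 1, function(pr)
      mutational_steps(seqs[[pr[1]]], seqs[[pr[2]]]))
    jointf <- freq[pairs[, 1]] + freq[pairs[, 2]]
    cand <- data.frame(from = pairs[, 1], to = pairs[, 2],
                       steps = as.integer(steps),
                       joint = as.numeric(jointf), stringsAsFactors = FALSE)
    cand <- cand[cand$steps <= limit & cand$steps > 0, , drop = FALSE]
    cand <- cand[order(cand$steps, -cand$joint, cand$from, cand$to), ,
                 drop = FALSE]
    comp <- setNames(seq_len(n), nm)         # union-find by relabelling
    keep <- logical(nrow(cand))
    for (s in unique(cand$steps)) {
      batch <- which(cand$steps == s)
      comp_before <- comp                    # connectivity prior to level s
      for (k in batch) {
        a <- cand$from[k]; b <- cand$to[k]
        if (comp_before[a] != comp_before[b]) {
          keep[k] <- TRUE
          if (comp[a] != comp[b]) comp[comp == comp[b]] <- comp[a]
        }
      }
    }
    edges <- cand[keep, c("from", "to", "steps"), drop = FALSE]
    rownames(edges) <- NULL
  }
  comp <- setNames(seq_len(n), nm)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    if (comp[a] != comp[b]) comp[comp == comp[b]] <- comp[a]
  }
  comp <- setNames(match(comp, unique(comp)), nm)
  structure(list(nodes = nodes, edges = edges, limit = as.integer(limit),
                 components = comp, segment_id = unique(table$segment_id)),
            class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat(sprintf("<parsimony_network> %s: %d node(s), %d edge(s), limit %d step(s), %d component(s)\n",
              x$segment_id, nrow(x$nodes), nrow(x$edges), x$limit,
              length(unique(x$components))))
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -- %s  (%d)\n", x$edges$from[i], x$edges$to[i],
                  x$edges$steps[i]))
  }
  invisible(x)
}

#' Export / import a parsimony network as GraphML
#'
#' Node attributes `frequency` and `label` and the edge attribute `steps`
#' are preserved, so export followed by import reproduces the network.
#'
#' @param net A `parsimony_network`.
#' @param path GraphML file path.
#' @return `export_network()` returns `path` invisibly; `import_network()`
#'   returns a `parsimony_network` (components recomputed, limit restored
#'   from the graph attribute).
#' @export
export_network <- function(net, path) {
  if (nrow(net$nodes) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(net$edges)) net$edges else
        data.frame(from = character(0), to = character(0), steps = integer(0)),
      directed = FALSE, vertices = net$nodes)
  }
  g <- igraph::set_graph_attr(g, "limit", net$limit)
  g <- igraph::set_graph_attr(g, "segment_id", net$segment_id)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0) {
    nodes <- data.frame(name = character(0), frequency = numeric(0),
                        label = character(0))
    edges <- data.frame(from = character(0), to = character(0),
                        steps = integer(0))
    comp <- setNames(integer(0), character(0))
  } else {
    nodes <- data.frame(name = igraph::V(g)$name,
                        frequency = igraph::V(g)$frequency,
                        label = igraph::V(g)$label,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        steps = as.integer(igraph::E(g)$steps),
                        stringsAsFactors = FALSE)
    ord <- order(nodes$name)
    nodes <- nodes[ord, , drop = FALSE]; rownames(nodes) <- NULL
    comp <- setNames(igraph::components(g)$membership[nodes$name],
                     nodes$name)
  }
  structure(list(nodes = nodes, edges = edges,
                 limit = as.integer(igraph::graph_attr(g, "limit")),
                 components = comp,
                 segment_id = igraph::graph_attr(g, "segment_id")),
            class = "parsimony_network")
}
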