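test_that("mutational steps count substitutions plus gap runs", {
  expect_equal(mutational_steps("ACGTACGT", "ACGTACGT"), 0)
  expect_equal(mutational_steps(panel_seqs[["2s6_A_02"]],
                                panel_seqs[["2s6_A_03"]]), 1)
  # one 4-bp gap run plus one substitution = 2 steps
  a <- "ACGGTTACGGATCGATTACG"
  b <- paste0(substr(a, 1, 8), substr(a, 13, 20))   # drop 4 bases
  b <- sub_at(b, 3, "T")
  expect_equal(mutational_steps(a, b), 2)
  expect_equal(oracle_steps(a, b), 2)
})

test_that("step counts agree with the exhaustive alignment oracle", {
  set.seed(33)
  for (i in 1:40) {
    a <- rand_dna(sample(5:16, 1))
    b <- a
    nedit <- sample(0:3, 1)
    for (k in seq_len(nedit)) {
      op <- sample(3, 1)
      if (op == 1 && nchar(b) > 2) {
        p <- sample(nchar(b), 1)
        substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
      } else if (op == 2) {
        p <- sample(nchar(b), 1)
        b <- paste0(substr(b, 1, p), rand_dna(sample(1:3, 1)),
                    substr(b, p + 1, nchar(b)))
      } else if (nchar(b) > 4) {
        p <- sample(nchar(b) - 2, 1)
        b <- paste0(substr(b, 1, p - 1), substr(b, p + sample(1:2, 1),
                                                nchar(b)))
      }
    }
    expect_equal(mutational_steps(a, b), oracle_steps(a, b),
                 info = paste(a, b))
  }
})

test_that("connection limit transcribes the parsimony probability and is monotone", {
  for (L in c(50, 100, 200, 352, 354, 500))
    expect_equal(connection_limit(L, 0.95), oracle_limit(L, 0.95))
  lims <- vapply(seq(50, 500, by = 10), connection_limit,
                 integer(1), confidence = 0.95)
  expect_true(all(diff(lims) >= 0))
  # vanishing confidence makes everything connectable
  expect_equal(connection_limit(20, 1e-30), 20)
})

test_that("the clade-A kdr haplotypes attach to their wild-type ancestor", {
  sub <- freq_table(list(list(
    pop = "x", seg = "IIS6",
    freqs = c("2s6_A_01" = 0.1, "2s6_A_02" = 0.3, "2s6_A_03" = 0.5,
              "2s6_A_06" = 0.1))))
  sub$sequence <- panel_seqs[sub$haplotype_name]
  net <- build_network(sub, "IIS6")
  ekey <- sprintf("%s|%s|%d", net$edges$from, net$edges$to, net$edges$steps)
  expect_true("2s6_A_01|2s6_A_03|1" %in% ekey)
  expect_true("2s6_A_02|2s6_A_03|1" %in% ekey)
  expect_true("2s6_A_03|2s6_A_06|2" %in% ekey)
  expect_equal(length(unique(net$components)), 1)
  # node frequency is the summed global frequency
  expect_equal(net$nodes$frequency[net$nodes$name == "2s6_A_03"], 0.5)
})

test_that("the IIIS6 double mutant neighbours the 1534C haplotype", {
  sub <- freq_table(list(list(
    pop = "x", seg = "IIIS6",
    freqs = c("3s6_00" = 0.5, "3s6_01" = 0.3, "3s6_13" = 0.1,
              "3s6_02" = 0.1))))
  sub$sequence <- panel_seqs[sub$haplotype_name]
  net <- build_network(sub, "IIIS6")
  adj13 <- with(net$edges, c(to[from == "3s6_13"], from[to == "3s6_13"]))
  expect_true("3s6_01" %in% adj13)
})

test_that("degenerate networks behave: singletons and out-of-limit pairs", {
  one <- freq_table(list(list(pop = "x", seg = "IIS6",
                              freqs = c("2s6_A_03" = 1))))
  one$sequence <- panel_seqs[one$haplotype_name]
  net1 <- build_network(one, "IIS6")
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)
  # two haplotypes beyond the limit stay in separate components
  two <- freq_table(list(list(pop = "x", seg = "IIS6",
                              freqs = c("h1" = 0.5, "h2" = 0.5))))
  set.seed(9)
  two$sequence <- c(rand_dna(300), rand_dna(300))
  net2 <- build_network(two, "IIS6", limit = 5)
  expect_equal(nrow(net2$edges), 0)
  expect_equal(length(unique(net2$components)), 2)
})

test_that("retained edges contain a minimum spanning tree", {
  set.seed(21)
  for (rep in 1:5) {
    base <- rand_dna(25)
    seqs <- c(base, vapply(1:4, function(i) {
      s <- base
      for (k in seq_len(sample(1:3, 1))) {
        p <- sample(nchar(s), 1)
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    }, ""))
    names(seqs) <- sprintf("h%d", seq_along(seqs))
    tab <- freq_table(list(list(pop = "x", seg = "IIS6",
                                freqs = setNames(rep(0.2, 5), names(seqs)))))
    tab$sequence <- seqs[tab$haplotype_name]
    net <- build_network(tab, "IIS6", limit = 25)
    # complete step graph for reference MST weight
    pairs <- t(combn(names(seqs), 2))
    w <- apply(pairs, 1, function(pr)
      mutational_steps(seqs[[pr[1]]], seqs[[pr[2]]]))
    gfull <- igraph::graph_from_data_frame(
      data.frame(pairs, weight = w), directed = FALSE)
    mst_w <- sum(igraph::E(igraph::mst(gfull))$weight)
    gnet <- igraph::graph_from_data_frame(
      data.frame(net$edges[, c("from", "to")], weight = net$edges$steps),
      directed = FALSE, vertices = names(seqs))
    expect_true(igraph::is_connected(gnet))
    expect_equal(sum(igraph::E(igraph::mst(gnet))$weight), mst_w)
  }
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  sub <- freq_table(list(list(
    pop = "x", seg = "IIS6",
    freqs = c("2s6_A_02" = 0.25, "2s6_A_03" = 0.5, "2s6_B_00" = 0.25))))
  sub$sequence <- panel_seqs[sub$haplotype_name]
  net <- build_network(sub, "IIS6",
                       labels = c("2s6_A_02" = "V1016I",
                                  "2s6_A_03" = "wild-type",
                                  "2s6_B_00" = "wild-type"))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path)
  back <- import_network(path)
  expect_equal(back$nodes$name, net$nodes$name)
  expect_equal(back$nodes$frequency, net$nodes$frequency)
  expect_equal(back$nodes$label, net$nodes$label)
  ek <- function(n) sort(sprintf("%s|%s|%d", pmin(n$edges$from, n$edges$to),
                                 pmax(n$edges$from, n$edges$to),
                                 n$edges$steps))
  expect_equal(ek(back), ek(net))
  expect_equal(back$limit, net$limit)
  # empty network still round-trips
  empty <- structure(list(nodes = data.frame(name = character(0),
                                             frequency = numeric(0),
                                             label = character(0)),
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             steps = integer(0)),
                          limit = 6L, components = setNames(integer(0),
                                                            character(0)),
                          segment_id = "IIS6"),
                     class = "parsimony_network")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, p2)
  expect_equal(nrow(import_network(p2)$nodes), 0)
})
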