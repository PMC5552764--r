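expected_pathways <- data.frame(
  pre = c("TCR", "IN", "IN", "TRN", "TRN", "RET", "RET"),
  post = c("TRN", "TCR", "IN", "TCR", "TRN", "TCR", "IN"),
  p_conn = c(0.35, 0.232, 0.236, 0.077, 0.20, 0.071, 0.474),
  w_syn = c(3, 8, 2, 2, 2, 5, 4),
  d_conn = c(8, 6, 4, 8, 4, 10, 10),
  sign = c("excitatory", "inhibitory", "inhibitory", "inhibitory",
           "inhibitory", "excitatory", "excitatory"),
  stringsAsFactors = FALSE)

test_that("the base network carries the published structure and attributes", {
  net <- build_lgn(lgn_config())
  expect_equal(net$n_neurons, 140)
  expect_equal(setNames(net$pops$size, net$pops$role),
               c(TCR = 80, IN = 20, TRN = 40))
  expect_equal(net$n_sources, 144)
  got <- net$projections[order(net$projections$pre, net$projections$post),
                         c("pre", "post", "p_conn", "w_syn", "d_conn", "sign")]
  want <- expected_pathways[order(expected_pathways$pre,
                                  expected_pathways$post), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # no feed-forward excitation from relay cells onto interneurons
  expect_false(any(net$projections$pre == "TCR" & net$projections$post == "IN"))
  # total inhibitory connection probability onto TCR is 30.9%
  inh <- net$projections$post == "TCR" & net$projections$sign == "inhibitory"
  expect_equal(sum(net$projections$p_conn[inh]), 0.309)
  # Izhikevich cells carry no bias current in the wired network
  expect_true(all(vapply(net$params, function(p) p$i_dc, 1) == 0))
})

test_that("projection realization is Bernoulli-per-pair with exact limits", {
  full <- realize_projection(projection_spec("TCR", "TRN", 1, 3, 8, "excitatory"),
                             n_pre = 3, n_post = 2, seed = 1)
  expect_equal(nrow(full), 6)          # complete bipartite at p = 1
  expect_true(all(full$delay_steps == 80L))
  tiny <- realize_projection(projection_spec("TCR", "TRN", 1e-9, 3, 8, "excitatory"),
                             n_pre = 20, n_post = 20, seed = 1)
  expect_equal(nrow(tiny), 0)          # empty in the p -> 0 limit
  expect_error(projection_spec("TCR", "TRN", 1.5, 3, 8, "excitatory"),
               "p_conn")
  # RET -> IN edge count within 4 binomial standard deviations of the mean
  m <- 144 * 20 * 0.474
  s4 <- 4 * sqrt(144 * 20 * 0.474 * (1 - 0.474))
  for (seed in 1:3) {
    e <- realize_projection(projection_spec("RET", "IN", 0.474, 4, 10, "excitatory"),
                            n_pre = 144, n_post = 20, seed = seed)
    expect_true(abs(nrow(e) - m) < s4)
  }
})

test_that("realized wiring is seed-deterministic, autapse-free, with expected fan-in", {
  net <- build_lgn(lgn_config())
  e1 <- realize_network(net, 42)
  e2 <- realize_network(net, 42)
  expect_identical(e1, e2)                       # bit-exact
  expect_false(identical(e1, realize_network(net, 43)))
  for (pw in c("IN->IN", "TRN->TRN")) {
    self <- e1[e1$pathway == pw, ]
    expect_false(any(self$pre == self$post))     # no autapses
  }
  # mean retinal fan-in per TCR cell ~ 144 * 0.071 = 10.2
  indeg <- sapply(1:3, function(s) {
    e <- realize_network(net, s)
    nrow(e[e$pathway == "RET->TCR", ]) / 80
  })
  expect_true(abs(mean(indeg) - 10.224) < 1.5)
})

test_that("suppressing feed-forward inhibition changes exactly the published fields", {
  base <- lgn_config()
  supp <- apply_in_suppression(base)
  key <- function(cfg, pre, post)
    cfg$projections[cfg$projections$pre == pre & cfg$projections$post == post, ]
  expect_equal(key(supp, "IN", "TCR")$p_conn, 0.07)
  expect_equal(key(supp, "IN", "TCR")$w_syn, 1)
  expect_equal(key(supp, "TRN", "TCR")$p_conn, 0.309)
  expect_equal(supp$variant, "in_suppressed")
  # delays and all other pathways untouched
  expect_equal(supp$projections$d_conn, base$projections$d_conn)
  others <- !(supp$projections$pre %in% c("IN", "TRN") &
                supp$projections$post == "TCR")
  expect_equal(supp$projections[others, ], base$projections[others, ])
  expect_warning(apply_in_suppression(supp), "already")
})

test_that("the multi-node build replicates nodes and wires TCR/TRN across them", {
  net3 <- build_multi_node(lgn_config(), 3)
  expect_equal(net3$n_neurons, 420)
  expect_equal(sum(net3$pops$size[net3$pops$node == 1]), 140)
  inter <- net3$projections[sub("@.*", "", net3$projections$pre_name) != "RET" &
    sub(".*@", "", net3$projections$pre_name) !=
      sub(".*@", "", net3$projections$post_name), ]
  # no inter-node projection touches an interneuron population
  expect_false(any(grepl("^IN", inter$pre_name) | grepl("^IN", inter$post_name)))
  expect_setequal(unique(paste(inter$pre, inter$post, sep = "->")),
                  c("TCR->TRN", "TRN->TCR", "TRN->TRN"))
  # two nodes: 3 pathway types x 2 ordered pairs
  net2 <- build_multi_node(lgn_config(), 2)
  inter2 <- net2$projections[sub("@.*", "", net2$projections$pre_name) != "RET" &
    sub(".*@", "", net2$projections$pre_name) !=
      sub(".*@", "", net2$projections$post_name), ]
  expect_equal(nrow(inter2), 6)
  expect_error(build_multi_node(lgn_config(), 1), "n_nodes")
  # each node restricted to itself is structurally the basic network
  node1 <- net3$projections[grepl("@1$", net3$projections$post_name) &
    (net3$projections$pre == "RET" | grepl("@1$", net3$projections$pre_name)), ]
  expect_setequal(paste(node1$pre, node1$post, sep = "->"),
                  paste(expected_pathways$pre, expected_pathways$post, sep = "->"))
  # inter-node attributes equal the corresponding intra-node pathway
  tt <- inter[inter$pre == "TRN" & inter$post == "TCR", ][1, ]
  expect_equal(tt[, c("p_conn", "w_syn", "d_conn")],
               expected_pathways[expected_pathways$pre == "TRN" &
                 expected_pathways$post == "TCR",
                 c("p_conn", "w_syn", "d_conn")],
               ignore_attr = TRUE)
})

test_that("configuration loading validates and honors overrides", {
  expect_silent(cfg <- load_config(NULL, quiet = TRUE))
  expect_equal(cfg$variant, "base")
  # empty override file gives the exact defaults
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg2 <- load_config(f, quiet = TRUE)
  expect_equal(cfg2$projections, cfg$projections)
  # variant override applies the suppression semantics
  writeLines("variant: in_suppressed", f)
  cfg3 <- load_config(f, quiet = TRUE)
  expect_equal(cfg3$projections$p_conn[cfg3$projections$pre == "IN" &
                                         cfg3$projections$post == "TCR"], 0.07)
  # malformed probability rejected with the field path
  writeLines(c("projections:",
               "  - {pre: RET, post: TCR, p_conn: 1.5}"), f)
  expect_error(load_config(f, quiet = TRUE), "RET->TCR.*p_conn|p_conn.*RET->TCR")
  writeLines("no_such_section: 1", f)
  expect_error(load_config(f, quiet = TRUE), "unknown configuration keys")
  # snapshot round-trip preserves the projection table
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f2)
  cfg4 <- load_config(f2, quiet = TRUE)
  expect_equal(cfg4$projections, cfg$projections)
})
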