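test_that("node feature vectors have dimension 22 and the stated row sums", {
  X <- node_features(c("A", "G", "X", "W"), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(dim(X), c(4L, 22L))
  expect_equal(rowSums(X), c(2, 1, 2, 1))   # loop residues sum to 2
  expect_equal(which(X[1, ] == 1), c(1L, 22L))         # ALA slot + loop flag
  expect_equal(which(X[2, ] == 1), 8L)                 # GLY
  expect_equal(which(X[3, ] == 1), c(21L, 22L))        # unknown + loop flag
  # non-standard residues map through their analogue, others to unknown
  expect_equal(which(node_features(aa_one_letter("MSE"), FALSE) == 1), 13L)  # MET
  expect_equal(which(node_features(aa_one_letter("UNK"), FALSE) == 1), 21L)
})

test_that("edge features hold a covalent flag plus 8 RBFs with unit peaks", {
  cfg <- graph_config()
  E <- edge_features(c(0, 10), c(TRUE, FALSE), cfg)
  expect_equal(dim(E), c(2L, 9L))
  expect_equal(E[, 1], c(1, 0))
  expect_equal(E[1, 2], 1)                      # mu_0 = 0 at d = 0
  expect_equal(E[2, 9], 1)                      # mu_7 = 10 at d = 10
  expect_true(all(E[, -1] > 0 & E[, -1] <= 1))
  # scalar oracle evaluation of the Gaussian formula at d = 5
  d <- 5; sigma <- 10 / 7
  mu <- seq(0, 10, length.out = 8)
  expect_equal(as.numeric(rbf_encode(d, cfg)),
               exp(-(d - mu)^2 / (2 * sigma^2)), tolerance = 1e-10)
})

test_that("context selection applies the 10 A rule per chain scope", {
  fix <- generate_hairpin(6, seed = 2)
  rt <- residue_table(fix$structure)
  motif <- mine_loops(fix$structure, ann = fix$ss)[[1]]
  # everything close: the whole chain is context
  sel <- select_context(fix$structure, motif, graph_config(context_radius = 1e6))
  expect_equal(sel$key, rt$key)

  # a far residue is excluded; brute-force distance check agrees
  a <- fix$structure$atoms
  far <- a[a$resno == 1, ]
  far$resno <- 99L
  far[, c("x", "y", "z")] <- far[, c("x", "y", "z")] + 500
  s2 <- structure_model(rbind(a, far), experimental_method = "xray",
                        resolution = 2)
  sel2 <- select_context(s2, motif, graph_config())
  expect_false("A:99:." %in% sel2$key)
  ca_all <- ca_coords(s2)
  loop_ca <- ca_all[match(motif$residues$key, residue_table(s2)$key), ]
  brute <- vapply(seq_len(nrow(ca_all)), function(i) {
    min(sqrt(rowSums(sweep(loop_ca, 2, ca_all[i, ])^2))) <= 10
  }, TRUE)
  expect_setequal(sel2$key, residue_table(s2)$key[brute])

  # partner-chain residues join only in both_chains scope
  b <- a[a$resno %in% 7:8, ]
  b$chain <- "L"
  s3 <- structure_model(rbind(a, b), experimental_method = "xray",
                        resolution = 2)
  same <- select_context(s3, motif, graph_config(chain_scope = "same_chain"))
  both <- select_context(s3, motif, graph_config(chain_scope = "both_chains"))
  expect_false(any(same$chain == "L"))
  expect_true(any(both$chain == "L"))

  # loop-only ablation
  only <- select_context(fix$structure, motif, graph_config(loop_only = TRUE))
  expect_equal(only$key, motif$residues$key)
})

test_that("graphs carry n x 22 node and m x 9 edge features with symmetric edges", {
  fix <- generate_hairpin(4, strand_length = 3, seed = 3)
  motif <- mine_loops(fix$structure, ann = fix$ss)[[1]]
  g <- build_graph(fix$structure, motif, graph_config())
  expect_equal(ncol(g$nodes), 22L)
  expect_equal(ncol(g$edge_attr), 9L)
  expect_equal(nrow(g$edge_attr), nrow(g$edges))
  expect_equal(sum(g$loop_mask), 4L)
  # edges are symmetric and self-loop free
  expect_true(all(g$edges[, 1] != g$edges[, 2]))
  key <- paste(g$edges[, 1], g$edges[, 2])
  rev_key <- paste(g$edges[, 2], g$edges[, 1])
  expect_setequal(key, rev_key)
  # edge set equals brute-force all-pairs thresholding
  D <- as.matrix(dist(g$coords))
  expect_equal(nrow(g$edges), sum(D <= 10 & row(D) != col(D)))
  # covalent flags exactly on sequence-adjacent same-chain pairs
  cov <- g$edges[g$edge_attr[, 1] == 1, , drop = FALSE]
  expect_true(all(abs(cov[, 1] - cov[, 2]) == 1))
})

test_that("a compact 10-residue hairpin is fully connected: 90 directed edges", {
  fix <- generate_hairpin(4, strand_length = 3, seed = 5)
  motif <- mine_loops(fix$structure, ann = fix$ss)[[1]]
  g <- build_graph(fix$structure, motif,
                   graph_config(edge_cutoff = 1e6, context_radius = 1e6))
  expect_equal(nrow(g$nodes), 10L)
  expect_equal(nrow(g$edges), 10L * 9L)
  g2 <- build_graph(fix$structure, motif, graph_config(loop_only = TRUE))
  expect_equal(nrow(g2$nodes), motif$loop_length)
})

test_that("graph features are invariant under rigid motion and reflection", {
  fix <- generate_hairpin(5, seed = 6)
  motif <- mine_loops(fix$structure, ann = fix$ss)[[1]]
  ref <- build_graph(fix$structure, motif, graph_config())
  for (reflect in c(FALSE, TRUE)) {
    set.seed(7 + reflect)
    rigid <- random_rigid(reflect)
    s2 <- fix$structure
    s2$atoms[, c("x", "y", "z")] <-
      apply_rigid(as.matrix(s2$atoms[, c("x", "y", "z")]), rigid)
    g2 <- build_graph(s2, motif, graph_config())
    expect_equal(g2$nodes, ref$nodes)
    expect_equal(g2$edges, ref$edges)
    expect_equal(g2$edge_attr, ref$edge_attr, tolerance = 1e-9)
  }
  # plain translation case
  s3 <- fix$structure
  s3$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(s3$atoms[, c("x", "y", "z")]), 2, c(100, -50, 7), FUN = "+")
  g3 <- build_graph(s3, motif, graph_config())
  expect_equal(g3$edge_attr, ref$edge_attr, tolerance = 1e-9)
})

test_that("biophysical features count planted context residues", {
  fix <- generate_hairpin(10, strand_length = 2, seed = 8)
  motif <- mine_loops(fix$structure, ann = fix$ss)[[1]]
  expect_equal(unname(biophysical_features(fix$structure, motif)["length"]), 10)
  # isolated loop: strip the strands far away -> exposure 0
  a <- fix$structure$atoms
  strand_rows <- a$resno %in% c(1:2, 13:14)
  a[strand_rows, c("x", "y", "z")] <- a[strand_rows, c("x", "y", "z")] + 1e4
  s2 <- structure_model(a, experimental_method = "xray", resolution = 2)
  expect_equal(unname(biophysical_features(s2, motif)["exposure"]), 0)
  # plant exactly 7 context residues inside 10 A
  loop_ca <- motif$ca
  ctx <- a[a$resno == 1 & a$elety == "CA", ][rep(1, 7), ]
  ctx$resno <- 50:56
  ctx[, c("x", "y", "z")] <- loop_ca[rep(1, 7), ] +
    matrix(c(3, 0, 0), 7, 3, byrow = TRUE) * seq(0.5, 2, length.out = 7)
  s3 <- structure_model(rbind(a, ctx), experimental_method = "xray",
                        resolution = 2)
  expect_equal(unname(biophysical_features(s3, motif)["exposure"]), 7)
})
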